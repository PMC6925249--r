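## Chou-Talalay median-effect and combination-index analysis for two-drug
## constant-ratio designs. fa (fraction affected) = growth inhibition / 100.

#' Fit the median-effect equation
#'
#' The median-effect model `fa/fu = (D/Dm)^m` linearises to
#' `log(fa/(1-fa)) = m log(D) - m log(Dm)`; a least-squares line gives the
#' sigmoidicity `m` (slope) and the median-effect dose `Dm`. fa values are
#' clipped to `(eps, 1-eps)` before the logit.
#'
#' @param doses Doses in uM, positive.
#' @param fa Fraction affected in (0, 1), same length.
#' @param eps Clipping bound. Default 1e-4.
#' @return List of class `median_effect_fit`: `Dm`, `m`, `r2`, `valid`
#'   (FALSE when the slope is non-positive).
#' @export
median_effect_fit <- function(doses, fa, eps = 1e-4) {
  ok <- is.finite(doses) & is.finite(fa) & doses > 0
  doses <- doses[ok]; fa <- fa[ok]
  if (length(doses) < 3) stop("need at least 3 usable doses")
  fa <- pmin(pmax(fa, eps), 1 - eps)
  y <- log(fa / (1 - fa)); x <- log(doses)
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else NA_real_
  valid <- is.finite(m) && m > 0
  Dm <- if (valid) exp(-b / m) else NA_real_
  structure(list(Dm = Dm, m = m, r2 = r2, valid = valid),
            class = "median_effect_fit")
}

# dose of a single agent needed to reach fraction affected fa
.dose_for_fa <- function(fit, fa) fit$Dm * (fa / (1 - fa))^(1 / fit$m)

#' Chou-Talalay combination index profile
#'
#' For each combination point (d1, d2, fa), the CI in the mutually exclusive
#' form is
#' \deqn{CI = d_1 / D_{x,1} + d_2 / D_{x,2},\quad
#'       D_{x,i} = Dm_i (fa/(1-fa))^{1/m_i},}
#' the doses of each single agent that would alone produce the observed
#' effect. CI < 1 indicates synergy, 1 additivity, > 1 antagonism.
#'
#' @param single1,single2 `median_effect_fit` objects for the single agents.
#' @param combo Data frame with columns `d1`, `d2` (uM) and `fa`.
#' @param eps fa clipping bound. Default 1e-4.
#' @return Object of class `ci_profile`: data frame (`fa`, `ci`, `d1`, `d2`)
#'   sorted by fa.
#' @export
combination_index <- function(single1, single2, combo, eps = 1e-4) {
  if (!isTRUE(single1$valid) || !isTRUE(single2$valid))
    stop("both single-agent median-effect fits must be valid")
  fa <- pmin(pmax(combo$fa, eps), 1 - eps)
  ci <- combo$d1 / .dose_for_fa(single1, fa) +
        combo$d2 / .dose_for_fa(single2, fa)
  out <- data.frame(fa = fa, ci = ci, d1 = combo$d1, d2 = combo$d2)
  out <- out[order(out$fa), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ci_profile", "data.frame"))
}

#' Interpolate a CI profile at a given fraction affected
#'
#' Linear interpolation of CI versus fa (e.g. CI at fa = 0.5 is the
#' conventional CI50 summary). Requesting a level outside the observed fa
#' range is an error.
#'
#' @param profile A `ci_profile`.
#' @param fa_level Fraction affected at which to evaluate.
#' @return Interpolated CI value.
#' @export
ci_at <- function(profile, fa_level) {
  if (fa_level < min(profile$fa) || fa_level > max(profile$fa))
    stop("fa_level ", fa_level, " outside observed fa range [",
         signif(min(profile$fa), 3), ", ", signif(max(profile$fa), 3), "]")
  stats::approx(profile$fa, profile$ci, xout = fa_level, ties = mean)$y
}
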