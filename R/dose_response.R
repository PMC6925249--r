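#' Four-parameter logistic (4PL) dose-response model
#'
#' Percent growth inhibition as a function of concentration:
#' \deqn{y = A + (B - A) / (1 + (C/x)^D)}
#' with A/B the minimum/maximum inhibition, C the EC50 (same unit as x,
#' micromolar throughout the package) and D the Hill slope.
#'
#' @param x Concentrations (uM), positive.
#' @param A,B,C,D Model parameters.
#' @return Predicted percent growth inhibition.
#' @export
fourpl <- function(x, A, B, C, D) A + (B - A) / (1 + (C / x)^D)

#' Normalize a viability plate and compute the Z'-factor
#'
#' Converts raw luminescence to percent growth inhibition using the in-plate
#' DMSO-with-cells (positive) and no-cell (negative) controls:
#' viability = (L - mean_neg) / (mean_pos - mean_neg), GI% = 100 (1 - viability).
#' Plate quality is summarised by the Z'-factor
#' \deqn{Z' = 1 - 3(\sigma_{pos} + \sigma_{neg}) / |\mu_{pos} - \mu_{neg}|.}
#'
#' @param plate Data frame with columns `content` (one of `"compound"`,
#'   `"dmso_cells"`, `"no_cells"`), `dose_uM` (NA for controls) and
#'   `luminescence`.
#' @return List: `wells` (the compound rows with added `viability` and `gi`
#'   columns), `z_prime`, `usable` (FALSE when controls are degenerate).
#' @export
normalize_plate <- function(plate) {
  req <- c("content", "dose_uM", "luminescence")
  if (!all(req %in% names(plate)))
    stop("plate must have columns: ", paste(req, collapse = ", "))
  pos <- plate$luminescence[plate$content == "dmso_cells"]
  neg <- plate$luminescence[plate$content == "no_cells"]
  if (length(pos) < 1 || length(neg) < 1)
    stop("plate is missing dmso_cells and/or no_cells control wells")
  mp <- mean(pos); mn <- mean(neg)
  if (!is.finite(mp) || !is.finite(mn) || mp == mn)
    return(list(wells = NULL, z_prime = NA_real_, usable = FALSE))
  sp <- if (length(pos) > 1) stats::sd(pos) else 0
  sn <- if (length(neg) > 1) stats::sd(neg) else 0
  zp <- 1 - 3 * (sp + sn) / abs(mp - mn)
  wells <- plate[plate$content == "compound", , drop = FALSE]
  wells$viability <- (wells$luminescence - mn) / (mp - mn)
  wells$gi <- 100 * (1 - wells$viability)
  list(wells = wells, z_prime = zp, usable = TRUE)
}

# rss of the 4PL model; used by the multistart refinement
.fourpl_rss <- function(par, x, y) {
  p <- fourpl(x, par[1], par[2], par[3], par[4])
  sum((y - p)^2)
}

#' Fit the 4PL dose-response model by multistart least squares
#'
#' Least-squares fit of `gi ~ A + (B-A)/(1 + (C/x)^D)`. Initialisation is a
#' deterministic multistart grid: A = min(gi), B = max(gi), D in {0.5, 1, 2},
#' C on a 5-point log grid spanning the tested dose range; the grid points are
#' ranked by residual sum of squares and the best few are refined with
#' Levenberg-Marquardt (bounded), keeping the lowest-RSS solution.
#'
#' @param doses Concentrations in uM, positive, at least 4 distinct values.
#' @param gi Percent growth inhibition, same length as `doses`.
#' @param lower,upper Parameter bounds c(A, B, C, D). Defaults:
#'   A in [-20, 50], B in [30, 120], C in [min_dose/100, max_dose*100],
#'   D in (0, 10].
#' @param n_refine Number of top-ranked grid starts refined. Default 3.
#' @return Object of class `dose_response_fit`: list with `A`, `B`, `C`, `D`,
#'   `rss`, `converged`, `doses`, `gi`.
#' @export
fit_4pl <- function(doses, gi, lower = NULL, upper = NULL, n_refine = 3) {
  if (length(doses) != length(gi)) stop("doses and gi must have equal length")
  ok <- is.finite(doses) & is.finite(gi)
  doses <- doses[ok]; gi <- gi[ok]
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(unique(doses)) < 4) stop("need at least 4 distinct doses")

  if (is.null(lower)) lower <- c(A = -20, B = 30, C = min(doses) / 100, D = 1e-3)
  if (is.null(upper)) upper <- c(A = 50, B = 120, C = max(doses) * 100, D = 10)

  A0 <- min(gi); B0 <- max(gi)
  A0 <- min(max(A0, lower[1]), upper[1])
  B0 <- min(max(B0, lower[2]), upper[2])
  Cs <- 10^seq(log10(min(doses)), log10(max(doses)), length.out = 5)
  starts <- expand.grid(C = Cs, D = c(0.5, 1, 2))
  rss0 <- apply(starts, 1, function(s) .fourpl_rss(c(A0, B0, s[1], s[2]), doses, gi))
  ord <- order(rss0)[seq_len(min(n_refine, nrow(starts)))]

  best <- NULL
  dat <- data.frame(x = doses, y = gi)
  for (i in ord) {
    st <- list(A = A0, B = B0, C = starts$C[i], D = starts$D[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A + (B - A) / (1 + (C / x)^D), data = dat,
                        start = st, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- c(as.list(stats::coef(fit)), list(rss = rss))
  }
  if (is.null(best)) {
    i <- ord[1]
    best <- list(A = A0, B = B0, C = starts$C[i], D = starts$D[i],
                 rss = rss0[i], converged = FALSE)
  } else best$converged <- TRUE
  structure(list(A = best$A, B = best$B, C = best$C, D = best$D,
                 rss = best$rss, converged = best$converged,
                 doses = doses, gi = gi),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("4PL fit: A=%.2f B=%.2f C=%.4g uM D=%.2f (rss=%.3g, %s)\n",
              x$A, x$B, x$C, x$D, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Extract the IC50 from a 4PL fit, capped at the top tested concentration
#'
#' Solves y(x) = `level` analytically,
#' \deqn{x = C ((B - level)/(level - A))^{-1/D},}
#' when `level` lies strictly between A and B and the fitted inhibition at
#' `cap_uM` reaches `level`; otherwise the IC50 is reported as `cap_uM` with
#' `capped = TRUE` (the convention for compounds that never reach 50%
#' inhibition in the tested range).
#'
#' @param fit A `dose_response_fit` (or any list with A, B, C, D and
#'   `converged`).
#' @param cap_uM Cap concentration in uM. Default 10.
#' @param level Target percent inhibition. Default 50.
#' @return List of class `ic50_result`: `ic50_uM`, `capped`, `log10_ic50`.
#' @export
ic50 <- function(fit, cap_uM = 10, level = 50) {
  capped <- TRUE
  val <- cap_uM
  if (isTRUE(fit$converged) && fit$A < level && level < fit$B) {
    y_cap <- fourpl(cap_uM, fit$A, fit$B, fit$C, fit$D)
    if (is.finite(y_cap) && y_cap >= level) {
      x <- fit$C * ((fit$B - level) / (level - fit$A))^(-1 / fit$D)
      if (is.finite(x) && x > 0 && x <= cap_uM) {
        val <- x
        capped <- FALSE
      }
    }
  }
  structure(list(ic50_uM = val, capped = capped, log10_ic50 = log10(val)),
            class = "ic50_result")
}

#' Combine replicate IC50 estimates
#'
#' Assay replicates are summarised by the geometric mean of the per-replicate
#' IC50s (configurable to the median); the combined value is flagged capped
#' only when every replicate was capped.
#'
#' @param results List of `ic50_result` objects.
#' @param method `"geometric"` (default) or `"median"`.
#' @return A single `ic50_result`.
#' @export
combine_ic50 <- function(results, method = c("geometric", "median")) {
  method <- match.arg(method)
  v <- vapply(results, function(r) r$ic50_uM, numeric(1))
  val <- switch(method,
                geometric = exp(mean(log(v))),
                median = stats::median(v))
  structure(list(ic50_uM = val,
                 capped = all(vapply(results, function(r) r$capped, logical(1))),
                 log10_ic50 = log10(val)),
            class = "ic50_result")
}

#' Dose-response analysis of a full plate set
#'
#' Normalizes every plate, fits the 4PL model per (compound, cell line,
#' replicate), extracts capped IC50s, and combines replicates by geometric
#' mean.
#'
#' @param plates Data frame of wells with columns `plate_id`, `drug`, `line`,
#'   `replicate`, `content`, `dose_uM`, `luminescence` (the format emitted by
#'   [gen_viability_plates()]).
#' @param cap_uM IC50 cap in uM. Default 10.
#' @return Data frame: `drug`, `line`, `ic50_uM`, `log10_ic50`, `capped`,
#'   `z_prime` (mean across replicate plates), `converged`.
#' @export
dose_response_panel <- function(plates, cap_uM = 10) {
  out <- list()
  for (key in unique(paste(plates$drug, plates$line, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- plates[plates$drug == parts[1] & plates$line == parts[2], , drop = FALSE]
    reps <- list(); zps <- c(); conv <- TRUE
    for (r in unique(sub$replicate)) {
      pl <- sub[sub$replicate == r, , drop = FALSE]
      np <- normalize_plate(pl)
      if (!np$usable) stop("degenerate controls on plate ", pl$plate_id[1])
      fit <- fit_4pl(np$wells$dose_uM, np$wells$gi)
      conv <- conv && fit$converged
      reps[[length(reps) + 1]] <- ic50(fit, cap_uM = cap_uM)
      zps <- c(zps, np$z_prime)
    }
    comb <- combine_ic50(reps)
    out[[length(out) + 1]] <- data.frame(
      drug = parts[1], line = parts[2], ic50_uM = comb$ic50_uM,
      log10_ic50 = comb$log10_ic50, capped = comb$capped,
      z_prime = mean(zps), converged = conv, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
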