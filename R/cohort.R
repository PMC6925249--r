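#' Normalize a cohort expression matrix
#'
#' Normalized counts are floored at 1, divided per gene by the median across
#' cases, and log2-transformed: `log2(max(x,1) / median_case(max(x,1)))`.
#' A case sitting at its gene's median maps to 0.
#'
#' @param counts Normalized-count matrix, cases in rows, genes in columns.
#' @return Matrix of median-centred log2 values, same dimnames.
#' @export
normalize_cohort <- function(counts) {
  x <- pmax(as.matrix(counts), 1)
  med <- apply(x, 2, stats::median)
  if (any(med <= 0)) stop("non-positive gene median after flooring")
  log2(sweep(x, 2, med, "/"))
}

#' Hierarchical clustering of cohort cases
#'
#' Agglomerative Ward clustering of cases, either on Euclidean distance of
#' expression values or on correlation distance (1 - Pearson) of
#' module-score profiles.
#'
#' @param mat Numeric matrix, cases in rows (expression or module scores).
#' @param distance `"euclidean"` or `"pearson"` (1 - Pearson correlation
#'   between case rows).
#' @param k Number of clusters for the returned labels. Default 2.
#' @return List: `hclust` (the dendrogram), `labels` (named cluster ids).
#' @export
cluster_cases <- function(mat, distance = c("euclidean", "pearson"), k = 2) {
  distance <- match.arg(distance)
  d <- switch(distance,
              euclidean = stats::dist(mat),
              pearson = stats::as.dist(1 - stats::cor(t(mat))))
  h <- stats::hclust(d, method = "ward.D2")
  list(hclust = h, labels = stats::cutree(h, k = k))
}

#' Kaplan-Meier curves and the two-group log-rank test
#'
#' Product-limit survival estimate per group and the standard log-rank
#' statistic: at each distinct event time the observed minus expected
#' events in group 1 are accumulated with the hypergeometric variance, and
#' \eqn{\chi^2 = (\sum(O-E))^2 / \sum V} is referred to chi-square(1).
#' Tied event times are handled by the hypergeometric formulation.
#'
#' @param time Survival times (> 0).
#' @param event Event indicator, 1 = event, 0 = censored.
#' @param group Two-level grouping vector.
#' @return List of class `km_logrank`: `km` (data frame with `group`,
#'   `time`, `n_risk`, `n_event`, `surv`), `chisq`, `p`, `observed`,
#'   `expected` (per group).
#' @export
km_logrank <- function(time, event, group) {
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  group <- factor(group)
  if (nlevels(group) != 2) stop("log-rank test implemented for two groups")
  if (sum(event) == 0) stop("no events in either group; log-rank undefined")

  km_one <- function(t, e) {
    ut <- sort(unique(t[e == 1]))
    n_risk <- vapply(ut, function(u) sum(t >= u), numeric(1))
    n_event <- vapply(ut, function(u) sum(t == u & e == 1), numeric(1))
    data.frame(time = ut, n_risk = n_risk, n_event = n_event,
               surv = cumprod(1 - n_event / n_risk))
  }
  km <- do.call(rbind, lapply(levels(group), function(g) {
    d <- km_one(time[group == g], event[group == g])
    if (nrow(d)) cbind(group = g, d) else NULL
  }))

  ut <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (u in ut) {
    at_risk <- time >= u
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == levels(group)[1])
    d <- sum(time == u & event == 1)
    d1 <- sum(time == u & event == 1 & group == levels(group)[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- if (v > 0) stats::pchisq(chisq, df = 1, lower.tail = FALSE) else 1
  structure(list(km = km, chisq = chisq, p = p,
                 observed = stats::setNames(c(o1, sum(event) - o1), levels(group)),
                 expected = stats::setNames(c(e1, sum(event) - e1), levels(group))),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("log-rank: chisq = %.3f (1 df), p = %.4g\n", x$chisq, x$p))
  invisible(x)
}

#' Select the high-module-activity case group
#'
#' Either the top `q` fraction of cases by module score (`mode =
#' "quantile"`, default q = 0.25) or, in `mode = "cluster"`, a Ward
#' clustering of the supplied expression (or score) matrix into `k` groups
#' followed by picking the cluster with the highest mean module score.
#'
#' @param scores Named per-case module-score vector (a `module_score$score`).
#' @param mode `"quantile"` or `"cluster"`.
#' @param q Top fraction for quantile mode. Default 0.25.
#' @param expr Case-by-gene matrix for cluster mode (defaults to the score
#'   vector itself as a one-column matrix).
#' @param k Number of clusters for cluster mode. Default 2.
#' @return Character vector of case ids in the high-activity group.
#' @export
high_activity_group <- function(scores, mode = c("quantile", "cluster"),
                                q = 0.25, expr = NULL, k = 2) {
  mode <- match.arg(mode)
  cases <- names(scores)
  if (mode == "quantile") {
    n_top <- max(1L, ceiling(q * length(scores)))
    return(cases[order(-scores)][seq_len(n_top)])
  }
  if (is.null(expr)) expr <- matrix(scores, ncol = 1,
                                    dimnames = list(cases, "score"))
  cl <- cluster_cases(expr, distance = "euclidean", k = k)
  means <- tapply(scores[names(cl$labels)], cl$labels, mean)
  best <- names(means)[which.max(means)]
  names(cl$labels)[cl$labels == as.integer(best)]
}
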