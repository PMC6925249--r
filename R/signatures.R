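#' Per-gene expression fold changes
#'
#' Pseudocounted fold change `(treated + pc) / (control + pc)`; the
#' pseudocount stabilises ratios of weakly expressed genes.
#'
#' @param treated,control Named numeric RPKM vectors aligned on gene ids.
#' @param pseudocount Added to both numerator and denominator. Default 1.
#' @return Named numeric vector of fold changes.
#' @export
fold_changes <- function(treated, control, pseudocount = 1) {
  if (length(treated) != length(control))
    stop("treated and control must have equal length")
  if (!is.null(names(treated)) && !is.null(names(control)) &&
      !identical(names(treated), names(control)))
    stop("treated and control must be aligned on the same gene ids")
  (treated + pseudocount) / (control + pseudocount)
}

#' Extract an up/down perturbation signature
#'
#' The signature universe is the set of genes expressed above
#' `min_expr_rpkm` (strict >) in treated OR control; within it, genes with
#' fold change strictly above `fc_up` form the up set and strictly below
#' `fc_down` the down set.
#'
#' @param fc Named fold-change vector from [fold_changes()].
#' @param treated,control RPKM vectors defining the expression universe.
#' @param fc_up Up threshold (strict >). Default 4.
#' @param fc_down Down threshold (strict <). Default 0.25.
#' @param min_expr_rpkm Expression threshold (strict >). Default 10.
#' @param source Optional provenance list (cell line, compound, dose, time).
#' @return Object of class `signature`: list with `up`, `down`, `universe`
#'   gene-id vectors and `source`.
#' @export
extract_signature <- function(fc, treated, control, fc_up = 4, fc_down = 0.25,
                              min_expr_rpkm = 10, source = list()) {
  genes <- names(fc)
  if (is.null(genes)) stop("fc must be a named vector")
  expressed <- treated > min_expr_rpkm | control > min_expr_rpkm
  if (!any(expressed)) stop("empty signature universe: no expressed genes")
  universe <- genes[expressed]
  up <- genes[expressed & fc > fc_up]
  down <- genes[expressed & fc < fc_down]
  structure(list(up = up, down = down, universe = universe, source = source),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature: %d up / %d down of %d expressed genes\n",
              length(x$up), length(x$down), length(x$universe)))
  invisible(x)
}

#' Write / read a signature as JSON
#'
#' @param sig A `signature`.
#' @param path File path.
#' @return `read_signature_json` returns a `signature`.
#' @export
write_signature_json <- function(sig, path) {
  jsonlite::write_json(unclass(sig), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_signature_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "signature")
}

# signed KS-style running-sum enrichment of `set` in the ranked gene list:
# +1/|set| at members, -1/(N-|set|) elsewhere; ES is the extremum.
.ks_enrichment <- function(ranked, set) {
  hit <- ranked %in% set
  s <- sum(hit)
  if (s == 0 || s == length(ranked)) return(0)
  step <- ifelse(hit, 1 / s, -1 / (length(ranked) - s))
  cs <- cumsum(step)
  if (max(cs) >= abs(min(cs))) max(cs) else min(cs)
}

#' Connectivity-style signature score
#'
#' Rank-based similarity between a perturbation signature and a fold-change
#' profile: genes are ranked by log2 fold change in decreasing order and the
#' up/down sets are scored with signed Kolmogorov-Smirnov running-sum
#' enrichment statistics (unit increments inside the set, balanced
#' decrements outside); the score is `(ES_up - ES_down) / 2`, in [-1, 1],
#' positive for a concordant perturbation. This is an in-package
#' reconstruction of connectivity-map-style scoring, not a reproduction of
#' any external service's values.
#'
#' @param sig A `signature`.
#' @param profile Named numeric per-gene fold-change vector (linear scale).
#' @return Numeric score in [-1, 1].
#' @export
connectivity_score <- function(sig, profile) {
  if (is.null(names(profile))) stop("profile must be a named vector")
  ranked <- names(sort(profile, decreasing = TRUE))
  es_up <- .ks_enrichment(ranked, sig$up)
  es_down <- .ks_enrichment(ranked, sig$down)
  (es_up - es_down) / 2
}
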