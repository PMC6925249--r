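#' Call per-line aberration status for cancer-related genes
#'
#' Combines mutation calls with basal expression (and optional promoter
#' methylation) into an aberrant / wild-type call per (cell line, gene),
#' using class-specific rules:
#' \itemize{
#'   \item oncogene: aberrant iff mutated AND expression > `expr_thresh` rpkm
#'     (a mutant allele that is not expressed cannot drive);
#'   \item tumour suppressor (tsg): aberrant iff mutated OR expression <
#'     `expr_thresh` rpkm OR promoter methylated (loss by any route);
#'   \item other (chromatin factors, fusions, ...): aberrant iff mutated.
#' }
#' An oncogene/tsg absent from the expression matrix gets status `"unknown"`.
#'
#' @param mutations Logical matrix, cell lines in rows, genes in columns.
#' @param expression RPKM matrix, genes in rows, cell lines in columns.
#' @param gene_classes Named character vector gene -> one of `"oncogene"`,
#'   `"tsg"`, `"other"`.
#' @param methylation Optional logical matrix like `mutations` flagging
#'   promoter hypermethylation (counts as aberrant for tsg).
#' @param expr_thresh RPKM threshold. Default 5.
#' @return Character matrix (lines x genes) with entries `"aberrant"`,
#'   `"wild-type"` or `"unknown"`.
#' @export
call_aberrations <- function(mutations, expression, gene_classes,
                             methylation = NULL, expr_thresh = 5) {
  lines <- rownames(mutations); genes <- colnames(mutations)
  if (is.null(lines) || is.null(genes)) stop("mutations needs dimnames")
  miss <- setdiff(genes, names(gene_classes))
  if (length(miss)) stop("no class for genes: ", paste(miss, collapse = ", "))
  status <- matrix("wild-type", length(lines), length(genes),
                   dimnames = list(lines, genes))
  for (g in genes) {
    cls <- gene_classes[[g]]
    mut <- mutations[, g]
    meth <- if (!is.null(methylation) && g %in% colnames(methylation))
      methylation[, g] else rep(FALSE, length(lines))
    if (cls %in% c("oncogene", "tsg")) {
      if (!g %in% rownames(expression)) { status[, g] <- "unknown"; next }
      ex <- expression[g, lines]
      ab <- if (cls == "oncogene") mut & ex > expr_thresh
            else mut | ex < expr_thresh | meth
    } else ab <- mut
    status[, g] <- ifelse(ab, "aberrant", "wild-type")
  }
  status
}

#' Split a cell-line panel at the maximum IC50 separation
#'
#' Sorts cell lines by log10 IC50 and places the sensitive/resistant boundary
#' at the largest gap between consecutive values. Ties on the gap are broken
#' toward the more balanced split, then toward the lower boundary. Capped
#' IC50s participate at the cap value. With all values identical there is no
#' separation and `NULL` is returned (the compound is skipped).
#'
#' @param ic50s Named numeric vector of IC50s in uM (names = cell lines), or
#'   a list of `ic50_result` objects.
#' @return `NULL`, or a list of class `sensitivity_split`: `lines` (sorted),
#'   `boundary` (index of the last sensitive line), `group` (named factor
#'   `"sensitive"`/`"resistant"`), `gap` (log10 units).
#' @export
max_separation_split <- function(ic50s) {
  if (is.list(ic50s) && !is.data.frame(ic50s))
    ic50s <- vapply(ic50s, function(r) r$ic50_uM, numeric(1),
                    USE.NAMES = TRUE)
  if (length(ic50s) < 3) stop("need IC50s for at least 3 lines")
  lv <- log10(ic50s)
  ord <- order(lv, names(lv))    # stable within ties
  sorted <- lv[ord]
  gaps <- diff(sorted)
  if (max(gaps) <= 0) return(NULL)
  n <- length(sorted)
  cand <- which(gaps == max(gaps))
  imbalance <- abs(2 * cand - n)         # |n1 - n2| with n1 = cand
  cand <- cand[imbalance == min(imbalance)]
  b <- min(cand)
  grp <- factor(rep(c("sensitive", "resistant"), c(b, n - b)),
                levels = c("sensitive", "resistant"))
  names(grp) <- names(sorted)
  structure(list(lines = names(sorted), boundary = b, group = grp,
                 gap = max(gaps)),
            class = "sensitivity_split")
}

#' Two-sided Fisher's exact test for a 2x2 association table
#'
#' Exact two-sided p-value by exhaustive hypergeometric enumeration: with
#' margins fixed, the probabilities of all tables no more probable than the
#' observed one (up to a 1e-7 relative tolerance) are summed.
#'
#' @param aberrant Named logical vector per cell line (TRUE = aberrant), or a
#'   2x2 integer matrix given directly.
#' @param split A `sensitivity_split`; ignored when `aberrant` is a matrix.
#' @return List: `p`, `table` (2x2: aberrant status x sensitivity group).
#' @export
fisher_association <- function(aberrant, split = NULL) {
  if (is.matrix(aberrant)) {
    tab <- aberrant
  } else {
    if (is.null(split)) stop("supply a sensitivity_split")
    ab <- aberrant[split$lines]
    tab <- table(factor(ifelse(ab, "aberrant", "wild-type"),
                        levels = c("aberrant", "wild-type")),
                 split$group)
    tab <- matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
  }
  list(p = .fisher_p(tab), table = tab)
}

# two-sided exact p: sum of dhyper over tables with prob <= observed*(1+tol)
.fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  sum(probs[probs <= probs[x - lo + 1] * (1 + 1e-7)])
}

#' Genotype versus drug-sensitivity association screen
#'
#' For every (gene, compound): split the panel at the maximum IC50
#' separation, test the enrichment of aberrant lines in either group with
#' Fisher's exact test, and compute the fold separation between the
#' resistant and sensitive groups' IC50 summary (geometric mean by default,
#' configurable to median).
#'
#' @param ic50_table Data frame from [dose_response_panel()] (columns `drug`,
#'   `line`, `ic50_uM`).
#' @param aberrations Character matrix from [call_aberrations()].
#' @param summary `"geometric"` or `"median"` group IC50 summary.
#' @return Data frame, one row per tested pair: `gene`, `drug`, `p`, `fold`,
#'   `n_sensitive`, `n_resistant`, `n_aberrant`.
#' @export
association_screen <- function(ic50_table, aberrations,
                               summary = c("geometric", "median")) {
  summary <- match.arg(summary)
  res <- list()
  for (drug in unique(ic50_table$drug)) {
    sub <- ic50_table[ic50_table$drug == drug, ]
    ic <- stats::setNames(sub$ic50_uM, sub$line)
    ic <- ic[names(ic) %in% rownames(aberrations)]
    if (length(ic) < 3) next
    split <- max_separation_split(ic)
    if (is.null(split)) next
    g_sum <- function(v) if (summary == "geometric") exp(mean(log(v)))
                         else stats::median(v)
    fold <- g_sum(ic[names(split$group)[split$group == "resistant"]]) /
            g_sum(ic[names(split$group)[split$group == "sensitive"]])
    for (gene in colnames(aberrations)) {
      st <- aberrations[split$lines, gene]
      if (any(st == "unknown")) next
      fa <- fisher_association(st == "aberrant", split)
      res[[length(res) + 1]] <- data.frame(
        gene = gene, drug = drug, p = fa$p, fold = fold,
        n_sensitive = sum(split$group == "sensitive"),
        n_resistant = sum(split$group == "resistant"),
        n_aberrant = sum(st == "aberrant"), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(gene = character(), drug = character(), p = numeric(),
               fold = numeric(), n_sensitive = integer(),
               n_resistant = integer(), n_aberrant = integer())
  rownames(out) <- NULL
  out
}

#' Extract significant gene-compound pairs
#'
#' Keeps pairs whose resistant/sensitive IC50 fold separation exceeds
#' `fold_thresh` and whose Fisher p-value is below `p_thresh`. No
#' multiple-testing correction is applied by default, mirroring a p < 0.05
#' screen; set `adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param results Data frame from [association_screen()].
#' @param fold_thresh Fold-separation threshold (strict >). Default 5.
#' @param p_thresh P-value threshold (strict <). Default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return The significant subset, ordered by p.
#' @export
extract_pairs <- function(results, fold_thresh = 5, p_thresh = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p <- if (adjust == "BH") stats::p.adjust(results$p, "BH") else results$p
  keep <- results$fold > fold_thresh & p < p_thresh
  out <- results[keep, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}
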