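## Co-expression module analytics: unsigned adjacency -> topological overlap
## -> average-linkage clustering with a static height cut; module eigengenes
## as first principal components of the per-gene standardized submatrix.

# WGCNA-style module label palette, assigned in decreasing module size
.module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

#' Build a topological-overlap co-expression network
#'
#' From a genes-by-samples RPKM matrix: soft-threshold the absolute Pearson
#' correlation of log2 expression into an unsigned adjacency
#' \eqn{a_{ij} = |cor|^\beta}, then compute the topological overlap matrix
#' \deqn{TOM_{ij} = (\sum_u a_{iu} a_{uj} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})}
#' with unit diagonal. Constant (zero-variance) genes are excluded with a
#' warning; genes below `min_expr` mean RPKM are filtered first.
#'
#' @param expr RPKM matrix, genes in rows, samples in columns. At least 8
#'   samples.
#' @param beta Soft-threshold power. Default 6.
#' @param min_expr Mean-RPKM expression filter (genes with mean below it are
#'   dropped). Default 0 (keep all).
#' @return Symmetric TOM matrix with gene dimnames.
#' @export
build_network <- function(expr, beta = 6, min_expr = 0) {
  if (ncol(expr) < 8) stop("need at least 8 samples to build a network")
  if (min_expr > 0) expr <- expr[rowMeans(expr) >= min_expr, , drop = FALSE]
  lx <- log2(pmax(expr, .Machine$double.xmin))
  sds <- apply(lx, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) excluded from the network")
    lx <- lx[sds > 0, , drop = FALSE]
  }
  a <- abs(stats::cor(t(lx)))^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- list(rownames(lx), rownames(lx))
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM,
#' cut at a static height; clusters of at least `min_size` genes become
#' modules (labelled with color-style names in decreasing size order), all
#' remaining genes are `"grey"`. Candidate modules are then cleaned by the
#' standard eigengene-membership step: genes whose correlation with their
#' module's eigengene (kME) falls below `kme_min` are returned to `"grey"`,
#' which removes background genes that attach to a cluster through chance
#' correlation when samples are few. Set `kme_min = 0` to disable. The
#' `expr` matrix is required for the cleanup (kME needs expression).
#'
#' @param tom TOM matrix from [build_network()].
#' @param min_size Minimum module size. Default 30.
#' @param cut_height Static tree-cut height on 1 - TOM. Default 0.99.
#' @param expr RPKM matrix (genes x samples) for the kME cleanup; genes must
#'   cover the TOM's rownames. Optional when `kme_min = 0`.
#' @param kme_min Minimum kME for module membership. Default 0.7.
#' @return Named character vector gene -> module label.
#' @export
detect_modules <- function(tom, min_size = 30, cut_height = 0.99,
                           expr = NULL, kme_min = 0.7) {
  d <- stats::as.dist(1 - tom)
  h <- stats::hclust(d, method = "average")
  cl <- stats::cutree(h, h = cut_height)
  sizes <- sort(table(cl), decreasing = TRUE)
  big <- names(sizes)[sizes >= min_size]
  labels <- rep("grey", length(cl))
  pal <- c(.module_palette,
           paste0("module", seq_len(max(0, length(big) - length(.module_palette)))))
  for (i in seq_along(big)) labels[cl == as.integer(big[i])] <- pal[i]
  labels <- stats::setNames(labels, rownames(tom))
  if (kme_min > 0 && length(big)) {
    if (is.null(expr))
      stop("expr is required for the kME membership cleanup (or set kme_min = 0)")
    me <- module_eigengene(expr[rownames(tom), , drop = FALSE], labels)
    drop <- names(labels)[labels != "grey" & me$kme[names(labels)] < kme_min]
    labels[drop] <- "grey"
    for (m in setdiff(unique(labels), "grey"))    # size check after cleanup
      if (sum(labels == m) < min_size) labels[labels == m] <- "grey"
  }
  labels
}

#' Module eigengenes and per-gene kME
#'
#' The module eigengene (ME) is the first principal component of the
#' per-gene standardized (z-scored log2) expression submatrix of the
#' module's members: the module's activity per sample. ME vectors are scaled
#' to unit sample variance and sign-oriented so the correlation with the
#' mean member profile is non-negative. kME is each member gene's Pearson
#' correlation with its module's ME. The `"grey"` (unassigned) label is
#' skipped.
#'
#' @param expr RPKM matrix, genes x samples.
#' @param assignment Named character vector gene -> module label.
#' @return List of class `module_eigengene`: `me` (module x sample matrix),
#'   `kme` (named numeric vector over assigned genes).
#' @export
module_eigengene <- function(expr, assignment) {
  assignment <- assignment[names(assignment) %in% rownames(expr)]
  mods <- setdiff(unique(assignment), "grey")
  lx <- log2(pmax(expr, .Machine$double.xmin))
  me <- matrix(NA_real_, length(mods), ncol(expr),
               dimnames = list(mods, colnames(expr)))
  kme <- stats::setNames(rep(NA_real_, length(assignment)), names(assignment))
  for (m in mods) {
    genes <- names(assignment)[assignment == m]
    sub <- lx[genes, , drop = FALSE]
    z <- t(scale(t(sub)))                      # per-gene z-score
    z[!is.finite(z)] <- 0                      # constant gene -> flat profile
    if (length(genes) < 2) {
      v <- as.numeric(z[1, ])
    } else {
      sv <- svd(z, nu = 0, nv = 1)
      v <- sv$v[, 1]
    }
    s <- stats::sd(v)
    v <- if (s > 0) v / s else v               # unit sample variance
    if (stats::cor(v, colMeans(z)) < 0) v <- -v
    me[m, ] <- v
    kme[genes] <- as.numeric(stats::cor(t(sub), v))
  }
  structure(list(me = me, kme = kme), class = "module_eigengene")
}

#' Cohort module score
#'
#' Projects a co-expression module onto an external cohort in three steps:
#' (1) log2-transform the normalized counts after adding 1; (2) average, per
#' case, the log2 values of the 10 module members with the highest kME
#' (ties broken by gene id) that are present in the cohort matrix; (3)
#' z-score across cases.
#'
#' @param cohort_expr Normalized-count matrix, cases in rows, genes in
#'   columns.
#' @param module Character vector of the module's member genes.
#' @param kme Named numeric kME vector covering the members.
#' @param n_genes Number of representative genes. Default 10.
#' @return List of class `module_score`: `score` (named per-case z-scores),
#'   `genes` (the representative genes used).
#' @export
module_score <- function(cohort_expr, module, kme, n_genes = 10) {
  present <- intersect(module, colnames(cohort_expr))
  if (!length(present)) stop("no module member is present in the cohort matrix")
  ord <- order(-kme[present], present)         # top kME, ties by gene id
  genes <- present[ord][seq_len(min(n_genes, length(present)))]
  if (length(genes) < n_genes)
    warning("only ", length(genes), " member genes present; using all")
  lx <- log2(cohort_expr[, genes, drop = FALSE] + 1)
  avg <- rowMeans(lx)
  z <- stats::setNames(as.numeric(scale(avg)), rownames(cohort_expr))
  structure(list(score = z, genes = genes), class = "module_score")
}

#' Screen metabolites for correlation with a module eigengene
#'
#' Replicate concentrations are averaged with the not-detected (N.D.) rule:
#' if one replicate is N.D. and the other detected, the detected value is
#' used; if both are N.D. the concentration is 0. Only metabolites detected
#' in more than `min_detected` cell lines are tested. Association is the
#' Spearman correlation with the module eigengene; hits satisfy
#' `r > r_thresh` and `p < p_thresh`.
#'
#' @param me Named numeric ME vector per cell line.
#' @param metab List with numeric matrices `rep1` and `rep2`
#'   (metabolites x lines, NA = not detected), as emitted by
#'   [gen_metabolites()].
#' @param r_thresh Spearman correlation threshold (strict >). Default 0.65.
#' @param p_thresh P-value threshold (strict <). Default 0.002.
#' @param min_detected Detection threshold in lines (strict >). Default 10.
#' @return Data frame over tested metabolites: `metabolite`, `n_detected`,
#'   `spearman_r`, `p`, `hit`.
#' @export
metabolite_screen <- function(me, metab, r_thresh = 0.65, p_thresh = 0.002,
                              min_detected = 10) {
  lines <- names(me)
  r1 <- metab$rep1[, lines, drop = FALSE]
  r2 <- metab$rep2[, lines, drop = FALSE]
  res <- list()
  for (i in seq_len(nrow(r1))) {
    a <- r1[i, ]; b <- r2[i, ]
    conc <- ifelse(is.na(a) & is.na(b), 0,
                   ifelse(is.na(a), b, ifelse(is.na(b), a, (a + b) / 2)))
    n_det <- sum(!(is.na(a) & is.na(b)))
    if (n_det <= min_detected) next
    ct <- suppressWarnings(
      stats::cor.test(conc, me, method = "spearman", exact = FALSE))
    res[[length(res) + 1]] <- data.frame(
      metabolite = rownames(r1)[i], n_detected = n_det,
      spearman_r = unname(ct$estimate), p = ct$p.value,
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(metabolite = character(), n_detected = integer(),
               spearman_r = numeric(), p = numeric())
  out$hit <- out$spearman_r > r_thresh & out$p < p_thresh
  rownames(out) <- NULL
  out
}

#' Extract core module members differentially co-expressed in a cohort
#'
#' For each member gene, a two-sided Wilcoxon rank-sum test compares
#' log2(x + 1) expression between the high-module-activity cases and the
#' rest; Bonferroni correction is applied over the module's member count and
#' genes with adjusted p below `alpha` are kept.
#'
#' @param cohort_expr Normalized-count matrix, cases x genes.
#' @param module Character vector of member genes.
#' @param high_group Character vector of case ids forming the high-activity
#'   group.
#' @param alpha Adjusted-p threshold (strict <). Default 0.05.
#' @return Data frame: `gene`, `p`, `p_bonferroni`, `kept`.
#' @export
core_members <- function(cohort_expr, module, high_group, alpha = 0.05) {
  present <- intersect(module, colnames(cohort_expr))
  hi <- rownames(cohort_expr) %in% high_group
  if (!any(hi) || all(hi)) stop("high_group must be a strict subset of cases")
  p <- vapply(present, function(g) {
    x <- log2(cohort_expr[, g] + 1)
    suppressWarnings(stats::wilcox.test(x[hi], x[!hi])$p.value)
  }, numeric(1))
  adj <- pmin(p * length(present), 1)          # Bonferroni over members
  data.frame(gene = present, p = unname(p), p_bonferroni = unname(adj),
             kept = unname(adj) < alpha, stringsAsFactors = FALSE)
}
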