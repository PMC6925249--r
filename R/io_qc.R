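#' Compute RPKM from raw counts
#'
#' Converts a gene-by-sample matrix of read counts into reads per kilobase
#' of transcript per million mapped reads (RPKM), the expression unit used
#' throughout the panel pipeline:
#' \deqn{rpkm = count \times 10^9 / (length_{bp} \times total\ mapped)}
#'
#' @param counts Integer/numeric matrix, genes in rows, samples in columns.
#' @param gene_length_bp Numeric vector of transcript lengths in base pairs,
#'   one per row of `counts` (recycled names checked if present).
#' @param total_mapped Numeric vector of per-sample total mapped read counts,
#'   one per column of `counts`.
#' @return Numeric matrix of RPKM values with the dimnames of `counts`.
#' @examples
#' compute_rpkm(matrix(10, 1, 1), gene_length_bp = 1000, total_mapped = 1e6)
#' @export
compute_rpkm <- function(counts, gene_length_bp, total_mapped) {
  counts <- as.matrix(counts)
  if (length(gene_length_bp) != nrow(counts))
    stop("gene_length_bp must have one entry per gene (row)")
  if (length(total_mapped) != ncol(counts))
    stop("total_mapped must have one entry per sample (column)")
  if (any(!is.finite(gene_length_bp)) || any(gene_length_bp <= 0))
    stop("gene lengths must be positive")
  if (any(!is.finite(total_mapped)) || any(total_mapped <= 0))
    stop("total mapped read counts must be positive; drop the offending sample")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  rpkm <- sweep(counts, 1, gene_length_bp, "/")
  rpkm <- sweep(rpkm, 2, total_mapped, "/") * 1e9
  rpkm
}

#' Per-sample RNA-seq quality control
#'
#' Applies the three RNA-seq acceptance criteria used for high-throughput
#' plate sequencing: a minimum number of mapped reads, a maximum intron-mapped
#' fraction, and a spike-in RPKM within `spike_sd` standard deviations of its
#' plate average. The spike-in plate mean/sd are computed over samples that
#' pass the read-count criterion, so a failed library cannot drag the plate
#' statistics.
#'
#' @param stats Data frame with columns `sample_id`, `total_mapped_reads`,
#'   `intron_fraction`, `spikein_rpkm`, `plate_id`.
#' @param min_reads Minimum total mapped reads (inclusive). Default 5e5.
#' @param max_intron Maximum intron fraction (exclusive). Default 0.15.
#' @param spike_sd Allowed deviation of the spike-in RPKM from the plate
#'   mean, in plate standard deviations (inclusive). Default 2.
#' @param single_plate_pass What the spike-in criterion yields on a plate
#'   where it is not evaluable (fewer than 2 read-count-passing samples):
#'   `TRUE` (default) treats it as passing, `FALSE` as failing.
#' @return Data frame: `sample_id`, `pass` (logical), `reasons` (comma-joined
#'   labels among `"min_reads"`, `"intron"`, `"spikein"`; empty when passing).
#' @export
qc_rnaseq <- function(stats, min_reads = 5e5, max_intron = 0.15, spike_sd = 2,
                      single_plate_pass = TRUE) {
  req <- c("sample_id", "total_mapped_reads", "intron_fraction",
           "spikein_rpkm", "plate_id")
  miss <- setdiff(req, names(stats))
  if (length(miss)) stop("stats is missing columns: ", paste(miss, collapse = ", "))
  if (any(stats$intron_fraction < 0 | stats$intron_fraction > 1))
    stop("intron_fraction must lie in [0, 1]")

  ok_reads  <- stats$total_mapped_reads >= min_reads
  ok_intron <- stats$intron_fraction < max_intron

  ok_spike <- rep(NA, nrow(stats))
  for (pl in unique(stats$plate_id)) {
    idx <- which(stats$plate_id == pl)
    ref <- idx[ok_reads[idx]]          # plate stats over read-passing samples
    if (length(ref) >= 2) {
      m <- mean(stats$spikein_rpkm[ref])
      s <- stats::sd(stats$spikein_rpkm[ref])
      ok_spike[idx] <- abs(stats$spikein_rpkm[idx] - m) <= spike_sd * s
    } else {
      ok_spike[idx] <- single_plate_pass
    }
  }

  reasons <- mapply(function(r, i, s) {
    paste(c(if (!r) "min_reads", if (!i) "intron", if (!s) "spikein"),
          collapse = ",")
  }, ok_reads, ok_intron, ok_spike)
  data.frame(sample_id = stats$sample_id,
             pass = ok_reads & ok_intron & ok_spike,
             reasons = unname(reasons),
             stringsAsFactors = FALSE)
}

#' Per-sample ATAC-seq quality control
#'
#' Accepts a sample when its MACS peak count reaches `min_peaks`.
#'
#' @param stats Data frame with columns `sample_id` and `macs_peak_count`.
#' @param min_peaks Minimum peak count (inclusive). Default 10000.
#' @return Data frame with `sample_id`, `pass`, `reasons`.
#' @export
qc_atac <- function(stats, min_peaks = 10000) {
  if (!all(c("sample_id", "macs_peak_count") %in% names(stats)))
    stop("stats must have columns sample_id and macs_peak_count")
  pass <- stats$macs_peak_count >= min_peaks
  data.frame(sample_id = stats$sample_id, pass = pass,
             reasons = ifelse(pass, "", "macs_peaks"),
             stringsAsFactors = FALSE)
}

#' Replicate reproducibility: Pearson r and Lin's concordance correlation
#'
#' Restricts two aligned expression vectors to genes expressed at or above
#' `min_rpkm` in both, optionally log2-transforms, and returns the Pearson
#' correlation together with Lin's concordance correlation coefficient
#' \deqn{ccc = 2\,cov(x,y) / (var\,x + var\,y + (\bar x - \bar y)^2),}
#' which penalises location and scale disagreement that Pearson r ignores.
#' Sample (n-1) moments are used consistently.
#'
#' @param x,y Named numeric vectors on the RPKM scale, aligned on gene ids
#'   (names, when present, must match).
#' @param min_rpkm Joint expression filter applied before the transform
#'   (inclusive). Default 2.
#' @param log2_transform Correlate log2 values (default) or raw values.
#' @return List with `pearson_r`, `ccc`, `n_used`.
#' @export
reproducibility <- function(x, y, min_rpkm = 2, log2_transform = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!is.null(names(x)) && !is.null(names(y)) && !identical(names(x), names(y)))
    stop("x and y must be aligned on the same gene ids")
  keep <- x >= min_rpkm & y >= min_rpkm
  keep[is.na(keep)] <- FALSE
  if (sum(keep) < 3)
    stop("fewer than 3 genes pass the joint >=", min_rpkm, " rpkm filter; ",
         "reproducibility undefined")
  xv <- x[keep]; yv <- y[keep]
  if (log2_transform) { xv <- log2(xv); yv <- log2(yv) }
  r <- stats::cor(xv, yv)
  ccc <- 2 * stats::cov(xv, yv) /
    (stats::var(xv) + stats::var(yv) + (mean(xv) - mean(yv))^2)
  list(pearson_r = r, ccc = ccc, n_used = sum(keep))
}

## ---- TSV / report I/O -------------------------------------------------

#' Read / write a genes-by-samples matrix as TSV
#'
#' Plain TSV with gene ids in the first column and sample ids in the header,
#' the interchange format for every expression/accessibility matrix in the
#' pipeline.
#'
#' @param path File path.
#' @param mat Numeric matrix with rownames (genes/regions) and colnames.
#' @param id_column Header label for the id column on write. Default "gene_id".
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(mat, path, id_column = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a QC report as TSV plus a JSON log
#'
#' @param report Data frame from [qc_rnaseq()] or [qc_atac()].
#' @param path Output TSV path; a `.json` sidecar with pass/fail tallies is
#'   written next to it.
#' @return The TSV path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  log <- list(n_samples = nrow(report),
              n_pass = sum(report$pass),
              n_fail = sum(!report$pass),
              fail_reasons = as.list(table(report$reasons[!report$pass])))
  jsonlite::write_json(log, sub("\\.tsv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
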