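## Regulatory-region definition and annotation.
## All coordinates follow the BED convention externally (0-based, half-open);
## internally regions are GRanges (1-based, closed). bed_to_granges /
## granges_to_bed do the +/-1 shift in one place.

#' Convert between BED-convention data frames and GRanges
#'
#' BED intervals are 0-based half-open `[start, end)`; GRanges are 1-based
#' closed. These helpers are the single conversion point for the package.
#'
#' @param bed Data frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `strand`.
#' @param gr A `GRanges`.
#' @return A `GRanges`, or a BED-convention data frame.
#' @export
bed_to_granges <- function(bed) {
  if (any(bed$start >= bed$end)) stop("BED intervals require start < end")
  strand <- if ("strand" %in% names(bed)) bed$strand else "*"
  strand[strand == "."] <- "*"            # BED's unstranded marker
  gr <- GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end),
    strand = strand)
  if ("name" %in% names(bed)) names(gr) <- bed$name
  gr
}

#' @rdname bed_to_granges
#' @export
granges_to_bed <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  if (!is.null(names(gr))) df$name <- names(gr)
  df$strand <- as.character(GenomicRanges::strand(gr))
  df
}

#' Read / write BED files (3 or 6 columns)
#'
#' @param path File path.
#' @param gr A `GRanges` to write.
#' @return `read_bed` returns a `GRanges`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 6) names(df)[6] <- "strand"
  bed_to_granges(df)
}

#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  df <- granges_to_bed(gr)
  out <- data.frame(df$chrom, df$start, df$end,
                    name = if (!is.null(df$name)) df$name else ".",
                    score = 0L,
                    strand = ifelse(df$strand == "*", ".", df$strand))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Define promoter regions around representative TSSs
#'
#' A gene's promoter is the symmetric window `[tss - flank, tss + flank)`
#' (BED convention, clipped at zero) around its representative TSS; one
#' region per gene.
#'
#' @param tss Data frame with columns `gene_id`, `chrom`, `tss_position`
#'   (0-based) and `strand`; one row per gene.
#' @param flank_bp Flank size in bp on each side. Default 1500.
#' @return `GRanges` named by `gene_id`.
#' @export
define_promoters <- function(tss, flank_bp = 1500) {
  if (anyDuplicated(tss$gene_id)) stop("duplicate gene ids in TSS table")
  start0 <- pmax(tss$tss_position - flank_bp, 0)
  end0 <- tss$tss_position + flank_bp
  bed_to_granges(data.frame(chrom = tss$chrom, start = start0, end = end0,
                            name = tss$gene_id, strand = tss$strand,
                            stringsAsFactors = FALSE))
}

#' Define enhancer regions from histone peak sets
#'
#' Union-merges all supplied peak sets (overlapping or bookended intervals
#' coalesce, as in `bedtools merge`), subtracts promoter intervals (splitting
#' regions where a promoter falls inside), and keeps only pieces overlapping
#' at least 1 bp of a basal open-chromatin (ATAC) peak.
#'
#' @param peak_sets List of `GRanges` (e.g. H3K27ac and H3K4me1 peaks from
#'   many cell lines).
#' @param promoters `GRanges` from [define_promoters()].
#' @param basal_atac `GRanges` of open-chromatin peaks under basal conditions.
#' @return `GRanges` of enhancer regions, named `enh_1`, `enh_2`, ...
#' @export
define_enhancers <- function(peak_sets, promoters, basal_atac) {
  if (!length(peak_sets)) stop("need at least one peak set")
  all_peaks <- do.call(c, unname(lapply(peak_sets, function(g) {
    GenomicRanges::strand(g) <- "*"
    names(g) <- NULL
    g <- GenomicRanges::granges(g)  # drop metadata so sets concatenate
    g
  })))
  merged <- GenomicRanges::reduce(all_peaks)       # bookended intervals merge
  prom <- GenomicRanges::reduce({p <- promoters; GenomicRanges::strand(p) <- "*"; p})
  enh <- GenomicRanges::setdiff(merged, prom)
  enh <- enh[GenomicRanges::width(enh) > 0]
  atac <- {a <- basal_atac; GenomicRanges::strand(a) <- "*"; a}
  enh <- IRanges::subsetByOverlaps(enh, atac, minoverlap = 1L)
  if (length(enh)) names(enh) <- paste0("enh_", seq_along(enh))
  enh
}

#' Assign enhancers to genes within a TSS window
#'
#' An enhancer is assigned to every gene whose TSS lies within `window_bp`
#' of its nearest base, distance measured as the coordinate difference
#' between the TSS (0-based) and the nearest covered base (0-based); a TSS
#' inside the enhancer has distance 0. Multi-assignment is allowed.
#'
#' @param enhancers Named `GRanges` (e.g. from [define_enhancers()]).
#' @param tss TSS table (see [define_promoters()]).
#' @param window_bp Maximum distance in bp (inclusive). Default 1e5.
#' @return Data frame: `enhancer_id`, `gene_id`, `distance`.
#' @export
assign_to_genes <- function(enhancers, tss, window_bp = 1e5) {
  if (!length(enhancers))
    return(data.frame(enhancer_id = character(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  # tss0 assigned iff start0 - window <= tss0 <= (end0 - 1) + window;
  # equivalently the TSS point overlaps the enhancer expanded by window_bp.
  ex <- enhancers
  GenomicRanges::start(ex) <- pmax(GenomicRanges::start(ex) - window_bp, 1L)
  GenomicRanges::end(ex) <- GenomicRanges::end(ex) + window_bp
  tss_gr <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(tss$tss_position + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(ex, tss_gr, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(enhancer_id = character(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  s0 <- GenomicRanges::start(enhancers)[qi] - 1L
  e0 <- GenomicRanges::end(enhancers)[qi] - 1L  # last covered base, 0-based
  t0 <- tss$tss_position[si]
  dist <- pmax(s0 - t0, t0 - e0, 0L)
  data.frame(enhancer_id = names(enhancers)[qi],
             gene_id = tss$gene_id[si],
             distance = as.integer(dist),
             stringsAsFactors = FALSE)
}

#' Per-module transcription-factor binding proportion
#'
#' A gene is "bound" when a TF peak overlaps its promoter or any enhancer
#' assigned to it. Returns the bound fraction per co-expression module and a
#' hypergeometric upper-tail enrichment p-value against the full assigned
#' gene universe (the enrichment test is an extension beyond a plain
#' proportion display).
#'
#' @param modules Named character vector gene -> module label.
#' @param tf_peaks `GRanges` of TF ChIP peaks.
#' @param promoters Named `GRanges` from [define_promoters()].
#' @param enhancer_map Data frame from [assign_to_genes()].
#' @param enhancers Named `GRanges` matching `enhancer_map$enhancer_id`;
#'   may be omitted when the map is empty.
#' @return Data frame: `module`, `n_members`, `n_bound`, `fraction`,
#'   `p_enrichment`.
#' @export
tf_binding_proportion <- function(modules, tf_peaks, promoters, enhancer_map,
                                  enhancers = NULL) {
  genes <- names(modules)
  bound_prom <- character(0)
  if (length(tf_peaks) && length(promoters)) {
    hits <- GenomicRanges::findOverlaps(promoters, tf_peaks, ignore.strand = TRUE)
    bound_prom <- unique(names(promoters)[S4Vectors::queryHits(hits)])
  }
  bound_enh <- character(0)
  if (length(tf_peaks) && nrow(enhancer_map) && !is.null(enhancers)) {
    hits <- GenomicRanges::findOverlaps(enhancers, tf_peaks, ignore.strand = TRUE)
    ov <- unique(names(enhancers)[S4Vectors::queryHits(hits)])
    bound_enh <- unique(enhancer_map$gene_id[enhancer_map$enhancer_id %in% ov])
  }
  bound <- union(bound_prom, bound_enh)
  is_bound <- genes %in% bound
  K <- sum(is_bound); N <- length(genes)
  out <- lapply(split(seq_along(genes), modules), function(idx) {
    n <- length(idx); k <- sum(is_bound[idx])
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(n_members = n, n_bound = k, fraction = k / n, p_enrichment = p)
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(module = names(out), stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}
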