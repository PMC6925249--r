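gr_to_bed3 <- function(gr) granges_to_bed(gr)[, c("chrom", "start", "end")]

test_that("promoters are symmetric TSS flanks, clipped at zero", {
  tss <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                    tss_position = c(10000, 1000), strand = c("+", "-"))
  p <- define_promoters(tss)
  bed <- granges_to_bed(p)
  expect_equal(bed$start, c(8500, 0))
  expect_equal(bed$end, c(11500, 2500))
  expect_equal(bed$name, c("g1", "g2"))
  expect_error(define_promoters(rbind(tss, tss[1, ])), "duplicate")
  # random instances against a per-row oracle
  set.seed(4)
  tss2 <- data.frame(gene_id = sprintf("g%03d", 1:100), chrom = "chr1",
                     tss_position = sample.int(50000, 100), strand = "+")
  bed2 <- granges_to_bed(define_promoters(tss2, flank_bp = 700))
  expect_equal(bed2$start, pmax(tss2$tss_position - 700, 0))
  expect_equal(bed2$end, tss2$tss_position + 700)
})

test_that("enhancer definition merges, subtracts promoters and requires ATAC", {
  peaks <- bed_to_granges(data.frame(chrom = "chr1",
                                     start = c(100, 150), end = c(200, 300)))
  prom <- bed_to_granges(data.frame(chrom = "chr1", start = 180, end = 220))
  atac <- bed_to_granges(data.frame(chrom = "chr1", start = 0, end = 1000))
  enh <- define_enhancers(list(peaks), prom, atac)
  expect_equal(gr_to_bed3(enh),
               data.frame(chrom = "chr1", start = c(100, 220), end = c(180, 300)),
               ignore_attr = TRUE)
  # bookended intervals merge (bedtools merge semantics)
  book <- bed_to_granges(data.frame(chrom = "chr1",
                                    start = c(100, 200), end = c(200, 300)))
  merged <- define_enhancers(list(book), prom[0], atac)
  expect_equal(gr_to_bed3(merged),
               data.frame(chrom = "chr1", start = 100, end = 300),
               ignore_attr = TRUE)
  # no ATAC overlap -> dropped
  far_atac <- bed_to_granges(data.frame(chrom = "chr1", start = 5000, end = 6000))
  expect_length(define_enhancers(list(peaks), prom[0], far_atac), 0)
})

test_that("interval operations agree with base-coverage oracles", {
  set.seed(5)
  for (i in 1:60) {
    a <- random_bed(sample(5:40, 1))
    b <- random_bed(sample(5:40, 1))
    ga <- bed_to_granges(a); gb <- bed_to_granges(b)
    merged <- GenomicRanges::reduce(ga)
    expect_equal(gr_to_bed3(merged), oracle_merge(a), ignore_attr = TRUE)
    sub <- GenomicRanges::setdiff(GenomicRanges::reduce(ga),
                                  GenomicRanges::reduce(gb))
    expect_equal(gr_to_bed3(sub), oracle_subtract(a, b), ignore_attr = TRUE)
    ov <- IRanges::overlapsAny(ga, gb)
    expect_equal(unname(ov), oracle_overlaps(a, b))
  }
})

test_that("enhancer-gene assignment uses TSS-to-nearest-base distance", {
  enh <- bed_to_granges(data.frame(chrom = "chr1", start = 0, end = 1000,
                                   name = "e1"))
  # nearest base is 999 (0-based): TSS at 101,000 is 100,001 bp away
  tss_far <- data.frame(gene_id = "g1", chrom = "chr1",
                        tss_position = 101000, strand = "+")
  expect_equal(nrow(assign_to_genes(enh, tss_far)), 0)
  tss_edge <- data.frame(gene_id = "g1", chrom = "chr1",
                         tss_position = 100999, strand = "+")
  hit <- assign_to_genes(enh, tss_edge)
  expect_equal(hit$gene_id, "g1")
  expect_equal(hit$distance, 100000)
  tss_in <- data.frame(gene_id = "g2", chrom = "chr1",
                       tss_position = 500, strand = "-")
  expect_equal(assign_to_genes(enh, tss_in)$distance, 0)
  # random instances against base enumeration
  set.seed(6)
  for (i in 1:15) {
    bed <- random_bed(8, max_coord = 3000, max_width = 60)
    tss <- data.frame(gene_id = sprintf("g%02d", 1:10), chrom = "chr1",
                      tss_position = sample.int(3500, 10), strand = "+")
    got <- assign_to_genes(bed_to_granges(bed), tss, window_bp = 400)
    want <- oracle_assign(bed, tss, 400)
    key <- function(d) if (is.null(d) || nrow(d) == 0) character(0) else
      sort(sprintf("%s|%s|%d", d$enhancer_id, d$gene_id, d$distance))
    expect_equal(key(got), key(want))
  }
})

test_that("TF binding proportions and enrichment match direct computation", {
  modules <- setNames(rep(c("m1", "m2"), c(10, 190)), sprintf("g%03d", 1:200))
  tss <- data.frame(gene_id = names(modules), chrom = "chr1",
                    tss_position = seq(5000, by = 5000, length.out = 200),
                    strand = "+")
  prom <- define_promoters(tss)
  empty_map <- data.frame(enhancer_id = character(), gene_id = character(),
                          distance = integer())
  no_peaks <- prom[0]
  res0 <- tf_binding_proportion(modules, no_peaks, prom, empty_map)
  expect_equal(res0$fraction, c(0, 0))
  all_peaks <- prom
  res1 <- tf_binding_proportion(modules, all_peaks, prom, empty_map)
  expect_equal(res1$fraction, c(1, 1))
  # 3 bound of 10 members vs 30 bound of 200 genes: exhaustive tail sum
  bound_genes <- c(names(modules)[1:3], names(modules)[11:37])
  peaks <- prom[bound_genes]
  res2 <- tf_binding_proportion(modules, peaks, prom, empty_map)
  m1 <- res2[res2$module == "m1", ]
  expect_equal(m1$fraction, 0.3)
  tail_p <- sum(vapply(3:10, function(k)
    choose(30, k) * choose(170, 10 - k) / choose(200, 10), numeric(1)))
  expect_equal(m1$p_enrichment, tail_p, tolerance = 1e-12)
  # binding through an assigned enhancer also counts
  enh <- bed_to_granges(data.frame(chrom = "chr1", start = 3000, end = 3200,
                                   name = "e1"))
  emap <- data.frame(enhancer_id = "e1", gene_id = "g200", distance = 50)
  res3 <- tf_binding_proportion(modules, enh, prom, emap, enhancers = enh)
  expect_equal(res3$n_bound[res3$module == "m2"], 1)
})

test_that("BED files round-trip through GRanges", {
  bed <- random_bed(20)
  gr <- bed_to_granges(bed)
  path <- tempfile(fileext = ".bed")
  write_bed(gr, path)
  back <- read_bed(path)
  expect_equal(gr_to_bed3(back), bed[, c("chrom", "start", "end")],
               ignore_attr = TRUE)
})
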