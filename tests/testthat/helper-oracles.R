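# Independent oracles and small utilities shared by the tests.

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  sn <- sum(choose(tab, 2))
  sr <- sum(choose(rowSums(tab), 2))
  sc <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  e <- sr * sc / n2
  (sn - e) / ((sr + sc) / 2 - e)
}

# --- interval oracles on BED data frames (single chrom, small coords) ----
# base-coverage representation: merge/subtract fall out of painting covered
# bases and reading off runs; independent of any interval-sweep logic.

coverage_vec <- function(bed, max_coord) {
  v <- rep(FALSE, max_coord)
  for (i in seq_len(nrow(bed))) {
    idx <- seq(bed$start[i] + 1, bed$end[i])  # 0-based half-open -> 1-based
    v[idx] <- TRUE
  }
  v
}

runs_to_bed <- function(v, chrom = "chr1") {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep])
}

oracle_merge <- function(bed, max_coord = 5000) {
  runs_to_bed(coverage_vec(bed, max_coord))
}

oracle_subtract <- function(a, b, max_coord = 5000) {
  runs_to_bed(coverage_vec(a, max_coord) & !coverage_vec(b, max_coord))
}

oracle_overlaps <- function(a, b) {       # which rows of a touch >=1 bp of b
  vapply(seq_len(nrow(a)), function(i) {
    any(a$start[i] < b$end & b$start < a$end[i])
  }, logical(1))
}

# enhancer->gene assignment by explicit base enumeration
oracle_assign <- function(bed, tss, window) {
  out <- NULL
  for (i in seq_len(nrow(bed))) {
    bases <- seq(bed$start[i], bed$end[i] - 1)
    for (j in seq_len(nrow(tss))) {
      d <- min(abs(tss$tss_position[j] - bases))
      if (d <= window)
        out <- rbind(out, data.frame(enhancer_id = bed$name[i],
                                     gene_id = tss$gene_id[j], distance = d))
    }
  }
  out
}

random_bed <- function(n, max_coord = 4000, max_width = 200) {
  start <- sample.int(max_coord - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = "chr1", start = start, end = start + width,
             name = sprintf("iv_%03d", seq_len(n)))
}

# --- two-sided Fisher p by direct choose() enumeration -------------------
oracle_fisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  lo <- max(0, k - n); hi <- min(k, m)
  denom <- choose(m + n, k)
  probs <- vapply(lo:hi, function(a) choose(m, a) * choose(n, k - a) / denom,
                  numeric(1))
  obs <- probs[x - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# --- first principal component scores by power iteration -----------------
oracle_pc1 <- function(z, iter = 2000) {
  cp <- crossprod(z)                      # samples x samples
  v <- rep(1, ncol(z)) / sqrt(ncol(z))
  for (i in seq_len(iter)) {
    v2 <- cp %*% v
    v <- v2 / sqrt(sum(v2^2))
  }
  as.numeric(v)
}

# --- greedy Ward agglomeration from the ESS-increase definition ----------
# merge cost Delta(A,B) = |A||B|/(|A|+|B|) * ||mean_A - mean_B||^2
oracle_ward_labels <- function(mat, k) {
  clusters <- lapply(seq_len(nrow(mat)), function(i) i)
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      a <- clusters[[i]]; b <- clusters[[j]]
      mu <- colMeans(mat[a, , drop = FALSE]) - colMeans(mat[b, , drop = FALSE])
      d <- length(a) * length(b) / (length(a) + length(b)) * sum(mu^2)
      if (d < best[1]) best <- c(d, i, j)
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  lab <- integer(nrow(mat))
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# partitions equal up to label renaming
same_partition <- function(a, b) {
  all(apply(table(a, b) > 0, 1, sum) == 1) &&
    all(apply(table(a, b) > 0, 2, sum) == 1)
}
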