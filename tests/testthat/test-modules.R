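test_that("TOM matches a direct triple-loop oracle", {
  set.seed(14)
  expr <- 2^matrix(rnorm(30 * 12, 6, 1), 30, 12,
                   dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:12)))
  tom <- build_network(expr, beta = 6)
  a <- abs(cor(t(log2(expr))))^6
  diag(a) <- 0
  k <- rowSums(a)
  oracle <- matrix(NA_real_, 30, 30)
  for (i in 1:30) for (j in 1:30) {
    l <- 0
    for (u in 1:30) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    oracle[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  diag(oracle) <- 1
  expect_equal(unname(tom), oracle, tolerance = 1e-10)
})

test_that("two perfectly correlated genes give unit adjacency and TOM", {
  expr <- rbind(g1 = 2^seq(1, 12), g2 = 2^(seq(1, 12) * 2 + 3))
  colnames(expr) <- sprintf("s%02d", 1:12)
  tom <- build_network(expr, beta = 6)
  expect_equal(tom[1, 2], 1, tolerance = 1e-12)
})

test_that("independent noise genes have near-zero adjacency", {
  set.seed(15)
  expr <- 2^matrix(rnorm(20 * 200), 20, 200,
                   dimnames = list(sprintf("g%02d", 1:20), sprintf("s%03d", 1:200)))
  a <- abs(cor(t(log2(expr))))^6
  diag(a) <- 0
  expect_lt(max(a), 0.01)
})

test_that("planted modules are recovered and gene order does not matter", {
  sim <- gen_expression_panel(n_genes = 500, n_modules = 3,
                              genes_per_module = 40, n_lines = 25,
                              noise_sd = 0.3, seed = 16)
  tom <- build_network(sim$expr$rpkm)
  asn <- detect_modules(tom, expr = sim$expr$rpkm)
  expect_gte(ari(asn, sim$truth$module_membership), 0.9)
  perm <- sample(nrow(tom))
  asn2 <- detect_modules(tom[perm, perm], expr = sim$expr$rpkm[perm, ])
  expect_equal(ari(asn2[names(asn)], asn), 1)
})

test_that("pure-noise matrices yield no modules", {
  set.seed(17)
  expr <- 2^matrix(rnorm(300 * 25, 6, 1), 300, 25,
                   dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:25)))
  tom <- build_network(expr)
  asn <- detect_modules(tom, min_size = 30, expr = expr)
  expect_true(all(asn == "grey"))
})

test_that("module eigengene is the first PC of the standardized submatrix", {
  # identical profiles: ME equals the shared z-profile, kME = 1
  prof <- 2^c(1, 3, 5, 2, 8, 4, 6, 7, 2, 5)
  expr <- matrix(rep(prof, each = 5), 5, 10, byrow = FALSE,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%02d", 1:10)))
  asn <- setNames(rep("m1", 5), rownames(expr))
  me <- module_eigengene(expr, asn)
  zp <- as.numeric(scale(log2(prof)))
  expect_equal(unname(me$me["m1", ]), zp, tolerance = 1e-9)
  expect_equal(unname(me$kme), rep(1, 5), tolerance = 1e-12)
  # noiseless rank-1 factor model: |cor(ME, factor)| = 1
  sim <- gen_expression_panel(n_genes = 80, n_modules = 2,
                              genes_per_module = 25, n_lines = 15,
                              noise_sd = 0, seed = 18)
  me2 <- module_eigengene(sim$expr$rpkm, sim$truth$module_membership)
  for (m in rownames(sim$truth$latent_factors))
    expect_equal(abs(cor(me2$me[m, ], sim$truth$latent_factors[m, ])), 1,
                 tolerance = 1e-9)
  # ME vectors have unit sample variance
  expect_equal(apply(me2$me, 1, sd), setNames(c(1, 1), rownames(me2$me)),
               tolerance = 1e-9)
})

test_that("first-PC scores match a power-iteration oracle up to sign", {
  set.seed(19)
  expr <- 2^matrix(rnorm(20 * 10, 5, 1.5), 20, 10,
                   dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  asn <- setNames(rep("m1", 20), rownames(expr))
  me <- module_eigengene(expr, asn)
  z <- t(scale(t(log2(expr))))
  v <- oracle_pc1(z)
  v <- v / sd(v)
  agree <- min(sum((me$me["m1", ] - v)^2), sum((me$me["m1", ] + v)^2))
  expect_lt(agree, 1e-8)
})

test_that("ME is invariant to per-gene affine rescaling of expression", {
  sim <- gen_expression_panel(n_genes = 80, n_modules = 2,
                              genes_per_module = 25, n_lines = 15, seed = 20)
  me1 <- module_eigengene(sim$expr$rpkm, sim$truth$module_membership)
  scaled <- sim$expr$rpkm * runif(80, 0.5, 4)   # per-gene scale on rpkm
  me2 <- module_eigengene(scaled, sim$truth$module_membership)
  for (m in rownames(me1$me))
    expect_equal(abs(cor(me1$me[m, ], me2$me[m, ])), 1, tolerance = 1e-9)
})

test_that("module score reproduces the three-step recipe by hand", {
  # single-gene module, 3 cases: score = z(log2(x + 1))
  counts <- matrix(c(3, 1, 0), 3, 1,
                   dimnames = list(c("c1", "c2", "c3"), "gA"))
  expect_warning(ms <- module_score(counts, "gA", c(gA = 1)), "member genes")
  expect_equal(unname(ms$score),
               as.numeric(scale(log2(c(3, 1, 0) + 1))), tolerance = 1e-12)
  # adding a constant to all cases leaves scores invariant
  set.seed(21)
  counts2 <- matrix(2^rnorm(300, 5, 1), 30, 10,
                    dimnames = list(sprintf("c%02d", 1:30), sprintf("g%02d", 1:10)))
  kme <- setNames(runif(10, 0.5, 1), colnames(counts2))
  s1 <- module_score(counts2, colnames(counts2), kme)
  s2 <- module_score(2 * counts2 + 1, colnames(counts2), kme)
  expect_equal(length(s1$genes), 10)
  expect_gt(cor(s1$score, s2$score), 0.999)
  sc <- scale(s1$score)
  expect_equal(attr(sc, "scaled:center"), 0, tolerance = 1e-12)
})

test_that("cohort module scores track the planted activity", {
  sim <- gen_expression_panel(seed = 22)
  tom <- build_network(sim$expr$rpkm)
  asn <- detect_modules(tom, expr = sim$expr$rpkm)
  me <- module_eigengene(sim$expr$rpkm, asn)
  co <- gen_cohort(sim$truth, n_cases = 200, seed = 23)
  lab <- names(which.max(table(
    asn[sim$truth$module_membership == rownames(sim$truth$latent_factors)[1]])))
  members <- names(asn)[asn == lab]
  ms <- module_score(co$counts, members, me$kme)
  expect_gt(abs(cor(ms$score[names(co$factor)], co$factor)), 0.9)
})

test_that("metabolite screen applies the N.D. rules and thresholds", {
  me <- setNames(seq(-2, 2, length.out = 20), sprintf("l%02d", 1:20))
  mk <- function(v) matrix(v, 1, 20, dimnames = list("m1", names(me)))
  # monotone transform of ME -> Spearman r = 1, kept
  res <- metabolite_screen(me, list(rep1 = mk(exp(me)), rep2 = mk(exp(me))))
  expect_true(res$hit[1]); expect_equal(res$spearman_r[1], 1)
  # both replicates N.D. everywhere -> excluded from testing
  res2 <- metabolite_screen(me, list(rep1 = mk(NA_real_), rep2 = mk(NA_real_)))
  expect_equal(nrow(res2), 0)
  # one replicate N.D. uses the detected value; both N.D. counts 0
  r1 <- mk(exp(me)); r1[1, 1] <- NA
  res3 <- metabolite_screen(me, list(rep1 = r1, rep2 = mk(exp(me))))
  expect_equal(res3$n_detected, 20)
  expect_equal(res3$spearman_r[1], 1)     # detected replicate preserves order
})

test_that("planted metabolite links are recovered without false calls", {
  sim <- gen_expression_panel(seed = 24)
  f <- sim$truth$latent_factors[1, ]
  ok <- 0
  for (s in 1:20) {
    metab <- gen_metabolites(sim$truth, seed = 600 + s)
    hits <- metabolite_screen(f, metab)
    if (setequal(hits$metabolite[hits$hit], metab$linked)) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("core-member extraction controls the null and finds planted shifts", {
  set.seed(25)
  cases <- sprintf("c%03d", 1:200)
  genes <- sprintf("g%02d", 1:60)
  counts <- matrix(2^rnorm(200 * 60, 5, 1), 200, 60,
                   dimnames = list(cases, genes))
  hi <- cases[1:50]
  null_res <- core_members(counts, genes, hi)
  expect_equal(sum(null_res$kept), 0)
  # shift 30 of 60 genes in the high group by 2 log2 units
  shifted <- counts
  shifted[hi, 1:30] <- shifted[hi, 1:30] * 2^2
  res <- core_members(shifted, genes, hi)
  expect_setequal(res$gene[res$kept], genes[1:30])
})

test_that("rank-sum p on a small fixture matches exhaustive enumeration", {
  x <- c(1.1, 2.3, 3.1); y <- c(4.2, 5.0, 6.7)   # complete separation, n=3+3
  p <- suppressWarnings(wilcox.test(x, y)$p.value)
  # enumerate all 20 assignments of ranks to group 1
  ranks <- combn(6, 3)
  w_obs <- sum(rank(c(x, y))[1:3]) - 6
  ws <- apply(ranks, 2, sum) - 6
  p_enum <- mean(abs(ws - 4.5) >= abs(w_obs - 4.5))
  expect_equal(p, p_enum, tolerance = 1e-12)
})
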