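test_that("generators are byte-deterministic under a fixed seed", {
  a <- gen_expression_panel(n_genes = 200, n_modules = 2, genes_per_module = 30,
                            n_lines = 12, seed = 42)
  b <- gen_expression_panel(n_genes = 200, n_modules = 2, genes_per_module = 30,
                            n_lines = 12, seed = 42)
  expect_identical(a, b)
  pa <- gen_viability_plates(a$truth, seed = 7)
  pb <- gen_viability_plates(b$truth, seed = 7)
  expect_identical(pa, pb)
  expect_false(identical(
    a$expr$rpkm,
    gen_expression_panel(n_genes = 200, n_modules = 2, genes_per_module = 30,
                         n_lines = 12, seed = 43)$expr$rpkm))
})

test_that("noiseless factor model gives perfect within-module correlation", {
  sim <- gen_expression_panel(n_genes = 120, n_modules = 2,
                              genes_per_module = 50, n_lines = 20,
                              noise_sd = 0, seed = 1)
  lx <- log2(sim$expr$rpkm)
  for (m in rownames(sim$truth$latent_factors)) {
    genes <- names(sim$truth$module_membership)[sim$truth$module_membership == m]
    cc <- cor(t(lx[genes[1:10], ]))
    expect_equal(unname(cc), matrix(1, 10, 10), tolerance = 1e-12)
  }
})

test_that("within-module correlation exceeds between-module correlation", {
  sim <- gen_expression_panel(n_genes = 300, n_modules = 3,
                              genes_per_module = 40, n_lines = 25,
                              noise_sd = 0.3, seed = 3)
  lx <- log2(sim$expr$rpkm)
  mm <- sim$truth$module_membership
  m1 <- names(mm)[mm == rownames(sim$truth$latent_factors)[2]]
  m2 <- names(mm)[mm == rownames(sim$truth$latent_factors)[3]]
  within <- abs(cor(t(lx[m1, ])))
  between <- abs(cor(t(lx[m1, ]), t(lx[m2, ])))
  expect_gt(mean(within[upper.tri(within)]), mean(between))
})

test_that("viability wells follow the 4PL model exactly when cv = 0", {
  truth <- list(drug_params = data.frame(
    drug = "d1", line = "l1", A = 0, B = 100, C = 1, D = 1))
  pl <- gen_viability_plates(truth, doses = c(0.1, 0.5, 1, 2, 10),
                             rep = 1, cv = 0, seed = 1)
  np <- normalize_plate(pl)
  # y(x = C) = (A+B)/2 = 50% inhibition -> viability fraction 0.5
  expect_equal(np$wells$viability[np$wells$dose_uM == 1], 0.5, tolerance = 1e-12)
  expect_equal(np$z_prime, 1, tolerance = 1e-12)
})

test_that("positive-control well noise matches the requested cv", {
  truth <- list(drug_params = data.frame(
    drug = "d1", line = "l1", A = 0, B = 90, C = 1, D = 1))
  cvs <- replicate(200, {
    pl <- gen_viability_plates(truth, rep = 1, cv = 0.05,
                               seed = sample.int(1e6, 1))
    pos <- pl$luminescence[pl$content == "dmso_cells"]
    sd(pos) / mean(pos)
  })
  set.seed(99)
  expect_lt(abs(mean(cvs) - 0.05), 0.01)
})

test_that("perturbation profiles scale targets and leave the rest unchanged", {
  sim <- gen_expression_panel(n_genes = 1200, n_modules = 2,
                              genes_per_module = 30, n_lines = 10, seed = 5)
  targets <- rownames(sim$expr$rpkm)[101:130]
  exact <- gen_perturbation_profiles(sim$expr, targets, log2fc = -2,
                                     noise_sd = 0, seed = 1)
  expect_equal(exact[targets, ] / sim$expr$rpkm[targets, ],
               matrix(0.25, 30, 10, dimnames = dimnames(exact[targets, ])),
               tolerance = 1e-12)
  ident <- gen_perturbation_profiles(sim$expr, targets, log2fc = 0,
                                     noise_sd = 0, seed = 1)
  expect_equal(ident, sim$expr$rpkm, tolerance = 1e-12)
  noisy <- gen_perturbation_profiles(sim$expr, targets, log2fc = -2,
                                     noise_sd = 0.1, seed = 2)
  non_targets <- setdiff(rownames(noisy), targets)[1:1000]
  med_fc <- median(noisy[non_targets, 1] / sim$expr$rpkm[non_targets, 1])
  expect_gt(med_fc, 0.9); expect_lt(med_fc, 1.1)
  expect_error(gen_perturbation_profiles(sim$expr, "nope", seed = 1),
               "not in panel")
})

test_that("noise-free linked metabolites track the factor with Spearman r = 1", {
  sim <- gen_expression_panel(n_genes = 100, n_modules = 2,
                              genes_per_module = 20, n_lines = 15, seed = 2)
  metab <- gen_metabolites(sim$truth, n_linked = 1, n_null = 2, seed = 1,
                           noise_sd = 0, nd_rate = 0, rep_sd = 0)
  conc <- (metab$rep1[1, ] + metab$rep2[1, ]) / 2
  expect_equal(unname(cor(conc, sim$truth$latent_factors[1, ],
                          method = "spearman")), 1)
})

test_that("null-hazard cohorts show no survival difference between groups", {
  sim <- gen_expression_panel(n_genes = 100, n_modules = 2,
                              genes_per_module = 20, n_lines = 15, seed = 2)
  ps <- vapply(1:30, function(s) {
    co <- gen_cohort(sim$truth, n_cases = 120, seed = 100 + s, hazard_beta = 0)
    grp <- ifelse(co$survival$case %in% co$high_group, "high", "other")
    km_logrank(co$survival$os_days, co$survival$os_event, grp)$p
  }, numeric(1))
  # p roughly uniform: no mass collapse at small values
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.25)
  co <- gen_cohort(sim$truth, n_cases = 50, seed = 1)
  expect_true(all(co$survival$os_days > 0))
  expect_true(all(co$survival$os_event %in% 0:1))
})

test_that("planted QC failures are flagged exactly, by mode", {
  sim <- gen_expression_panel(n_genes = 60, n_modules = 1,
                              genes_per_module = 30, n_lines = 10, seed = 4)
  reg <- gen_regions_and_peaks(sim$truth, seed = 11, n_samples = 200,
                               fail_frac = 0.1)
  expect_equal(nrow(reg$qc_truth), 20)   # 10% of 200
  qr <- qc_rnaseq(reg$sample_stats)
  planted_rna <- reg$qc_truth$sample_id[reg$qc_truth$mode != "macs_peaks"]
  expect_setequal(qr$sample_id[!qr$pass], planted_rna)
  qa <- qc_atac(reg$sample_stats)
  expect_setequal(qa$sample_id[!qa$pass],
                  reg$qc_truth$sample_id[reg$qc_truth$mode == "macs_peaks"])
  # flagged reasons match the planted failure mode
  merged <- merge(qr[!qr$pass, ], reg$qc_truth, by = "sample_id")
  expect_true(all(mapply(grepl, merged$mode, merged$reasons)))
})

test_that("generator argument validation rejects impossible designs", {
  expect_error(gen_expression_panel(n_genes = 10, n_modules = 2,
                                    genes_per_module = 30, seed = 1),
               "must not exceed")
  expect_error(gen_expression_panel(seed = 1, noise_sd = -1), "noise_sd")
  expect_error(gen_expression_panel(n_genes = 100),
               "seed is required")
  truth <- list(drug_params = data.frame(drug = "d", line = "l",
                                         A = 0, B = 90, C = 1, D = 1))
  expect_error(gen_viability_plates(truth, doses = c(1, 0.5), seed = 1),
               "sorted")
  expect_error(gen_viability_plates(truth, doses = c(-1, 1), seed = 1),
               "positive")
})
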