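## Synthetic cell-line panel with known ground truth.
##
## The generator emulates the data structure of a ~25-line lung-cancer panel
## profiled under basal conditions: planted co-expression modules driven by
## latent per-line activity factors, one module shifted in lines carrying a
## planted aberration, 4PL viability responses with one genotype-linked
## compound, drug-induced fold-change profiles, metabolites tracking one
## module's activity, a survival cohort where high module activity shortens
## survival, and region/QC fixtures. Every generator takes an explicit seed
## and is byte-deterministic given it.

#' Light container for a genes-by-samples expression matrix
#'
#' @param rpkm Numeric matrix, genes in rows, samples in columns.
#' @param gene_length_bp Per-gene transcript lengths.
#' @param meta Per-sample metadata data frame (`sample_id`, `cell_line`,
#'   `drug`, `dose_uM`, `time_h`).
#' @return List of class `expression_matrix`.
#' @export
expression_matrix <- function(rpkm, gene_length_bp = NULL, meta = NULL) {
  if (any(rpkm < 0)) stop("rpkm must be non-negative")
  if (!is.null(gene_length_bp) && any(gene_length_bp <= 0))
    stop("gene lengths must be positive")
  structure(list(rpkm = rpkm, gene_length_bp = gene_length_bp, meta = meta),
            class = "expression_matrix")
}

#' Generate the basal expression panel and its ground truth
#'
#' Log2 expression of a module gene g in line s is
#' `mu_g + loading_g * factor_{m(g),s} + eps`, `eps ~ N(0, noise_sd)`, with
#' per-module latent factors `~ N(0, 1)`; background genes are pure noise
#' around their baseline. RPKM = 2^log2. The first module's factor is
#' shifted by `+mut_shift` in the lines carrying the planted aberration
#' (emulating pathway activation by loss of a negative regulator), and the
#' module's first gene doubles as the aberration gene (tumour-suppressor
#' class, high baseline). Per-(drug, line) 4PL parameters are drawn so that
#' one compound is potent only in aberrant lines while the rest have narrow,
#' genotype-independent potency.
#'
#' @param n_genes Total genes. Default 2000.
#' @param n_modules Number of planted modules. Default 5.
#' @param genes_per_module Members per module. Default 60.
#' @param n_lines Cell lines. Default 25.
#' @param noise_sd Residual log2 noise sd for module genes. Default 0.3.
#' @param seed Integer seed (required).
#' @param mut_shift Factor shift in mutant lines. Default 2.
#' @param n_mutant Number of mutant lines; defaults to ~1/3 of the panel
#'   (8 of the default 25 lines).
#' @param n_drugs Compounds in the viability screen. Default 6.
#' @param bg_sd Background-gene log2 noise sd. Default 1.
#' @param plant_association Plant the genotype-sensitivity link in drug 1
#'   (default TRUE); FALSE makes all compounds genotype-independent (null
#'   panels for false-positive checks).
#' @return List: `expr` (an `expression_matrix`) and `truth` (a `panel_truth`
#'   list: `module_membership`, `latent_factors`, `mutant_lines`,
#'   `mut_gene`, `drug_params`, `planted_pair`, `hazard_beta`, `loadings`,
#'   `baseline`).
#' @export
gen_expression_panel <- function(n_genes = 2000, n_modules = 5,
                                 genes_per_module = 60, n_lines = 25,
                                 noise_sd = 0.3, seed,
                                 mut_shift = 2,
                                 n_mutant = max(1, round(0.32 * n_lines)),
                                 n_drugs = 6,
                                 bg_sd = 1, plant_association = TRUE) {
  if (missing(seed)) stop("seed is required")
  if (n_genes <= 0 || n_modules <= 0 || genes_per_module <= 0 || n_lines <= 0)
    stop("counts must be positive")
  if (n_modules * genes_per_module > n_genes)
    stop("n_modules * genes_per_module must not exceed n_genes")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_mutant < 1 || n_mutant >= n_lines)
    stop("n_mutant must lie in [1, n_lines - 1]")
  set.seed(seed)

  genes <- sprintf("gene_%04d", seq_len(n_genes))
  lines <- sprintf("line_%02d", seq_len(n_lines))
  module_names <- .module_palette[seq_len(n_modules)]
  membership <- stats::setNames(rep("grey", n_genes), genes)
  for (m in seq_len(n_modules)) {
    idx <- ((m - 1) * genes_per_module + 1):(m * genes_per_module)
    membership[idx] <- module_names[m]
  }

  mutant_lines <- sort(sample(lines, n_mutant))
  # latent activities: distinct transcriptional programs, so the planted
  # factors are made exactly uncorrelated in-sample (QR of the centered
  # Gaussian draw); chance factor-factor correlation at ~25 lines would
  # otherwise blur the planted module boundaries
  g <- matrix(stats::rnorm(n_lines * n_modules), n_lines, n_modules)
  g <- scale(g, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(g))[, seq_len(n_modules), drop = FALSE]
  factors <- t(apply(t(q), 1, function(v) v / stats::sd(v)))
  dimnames(factors) <- list(module_names, lines)
  factors[1, mutant_lines] <- factors[1, mutant_lines] + mut_shift

  baseline <- stats::runif(n_genes, 2, 8)
  loadings <- stats::runif(n_genes, 0.5, 1.5)
  mut_gene <- genes[1]                    # first member of the shifted module
  baseline[1] <- 8                        # high floor: expression stays > 5 rpkm

  log2e <- matrix(stats::rnorm(n_genes * n_lines, sd = bg_sd), n_genes, n_lines,
                  dimnames = list(genes, lines))
  for (m in seq_len(n_modules)) {
    idx <- which(membership == module_names[m])
    noise <- matrix(stats::rnorm(length(idx) * n_lines, sd = noise_sd),
                    length(idx), n_lines)
    log2e[idx, ] <- loadings[idx] %o% factors[m, ] + noise
  }
  log2e <- log2e + baseline
  rpkm <- 2^log2e

  drugs <- sprintf("cmpd_%02d", seq_len(n_drugs))
  dp <- expand.grid(line = lines, drug = drugs, stringsAsFactors = FALSE)
  dp <- dp[, c("drug", "line")]
  dp$A <- 0
  dp$B <- stats::runif(nrow(dp), 70, 100)
  dp$C <- 10^stats::rnorm(nrow(dp), 0, 0.15)   # narrow genotype-free potency
  dp$D <- stats::runif(nrow(dp), 0.8, 2)
  if (plant_association) {
    sel <- dp$drug == drugs[1]
    mut <- sel & dp$line %in% mutant_lines
    dp$B[mut] <- stats::runif(sum(mut), 85, 100)
    dp$C[mut] <- 10^stats::rnorm(sum(mut), -1.3, 0.15)
    dp$D[mut] <- stats::runif(sum(mut), 1, 2)
    res <- sel & !dp$line %in% mutant_lines
    dp$B[res] <- stats::runif(sum(res), 20, 35)  # never reaches 50% inhibition
  }

  truth <- structure(list(
    module_membership = membership,
    latent_factors = factors,
    mutant_lines = mutant_lines,
    mut_gene = mut_gene,
    drug_params = dp,
    planted_pair = if (plant_association)
      c(gene = mut_gene, drug = drugs[1]) else NULL,
    hazard_beta = log(2),
    loadings = stats::setNames(loadings, genes),
    baseline = stats::setNames(baseline, genes)), class = "panel_truth")

  meta <- data.frame(sample_id = lines, cell_line = lines, drug = "none",
                     dose_uM = 0, time_h = 0, stringsAsFactors = FALSE)
  expr <- expression_matrix(rpkm,
                            gene_length_bp = stats::setNames(
                              round(stats::runif(n_genes, 500, 5000)), genes),
                            meta = meta)
  list(expr = expr, truth = truth)
}

#' Generate the mutation table for the association screen
#'
#' The planted aberration gene carries mutations exactly in the truth's
#' mutant lines (tumour-suppressor class; its panel expression stays above
#' the rpkm threshold so the mutation alone drives the call). Additional
#' decoy genes of class "other" are mutated independently at `mut_rate`.
#'
#' @param truth A `panel_truth`.
#' @param n_other Decoy mutation genes. Default 5.
#' @param mut_rate Decoy per-line mutation probability. Default 0.15.
#' @param seed Integer seed (required).
#' @return List: `mutations` (lines x genes logical matrix), `gene_classes`.
#' @export
gen_mutation_table <- function(truth, n_other = 5, mut_rate = 0.15, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  lines <- colnames(truth$latent_factors)
  genes <- c(truth$mut_gene, sprintf("mutg_%02d", seq_len(n_other)))
  mut <- matrix(FALSE, length(lines), length(genes),
                dimnames = list(lines, genes))
  mut[truth$mutant_lines, 1] <- TRUE
  if (n_other > 0)
    mut[, -1] <- stats::runif(length(lines) * n_other) < mut_rate
  classes <- stats::setNames(c("tsg", rep("other", n_other)), genes)
  list(mutations = mut, gene_classes = classes)
}

#' Generate viability plates from the truth's dose-response parameters
#'
#' One plate per (drug, line, replicate): 8 compound wells (one per dose),
#' plus DMSO-with-cells (positive) and no-cell (negative) control wells.
#' Luminescence follows
#' `L = L_neg + (L_pos - L_neg) * (1 - y/100) * (1 + N(0, cv))` with y from
#' the 4PL model at the truth's parameters (controls sit at y = 0 and
#' y = 100).
#'
#' @param truth A `panel_truth` with `drug_params`.
#' @param doses Dose series in uM, positive and sorted. Default 8-point log
#'   series from 0.001 to 10 uM.
#' @param rep Replicate plates per (drug, line). Default 2.
#' @param cv Multiplicative well noise coefficient of variation. Default 0.05.
#' @param seed Integer seed (required).
#' @param n_ctrl Control wells of each type per plate. Default 8.
#' @param l_pos,l_neg Control luminescence levels. Defaults 50000 / 500.
#' @return Data frame of wells: `plate_id`, `drug`, `line`, `replicate`,
#'   `content`, `dose_uM`, `luminescence`.
#' @export
gen_viability_plates <- function(truth, doses = 10^seq(-3, 1, length.out = 8),
                                 rep = 2, cv = 0.05, seed, n_ctrl = 8,
                                 l_pos = 50000, l_neg = 500) {
  if (missing(seed)) stop("seed is required")
  if (any(doses <= 0)) stop("doses must be positive")
  if (is.unsorted(doses)) stop("doses must be sorted increasing")
  if (cv < 0) stop("cv must be >= 0")
  set.seed(seed)
  dp <- truth$drug_params
  out <- vector("list", nrow(dp) * rep)
  k <- 0
  for (i in seq_len(nrow(dp))) {
    y <- fourpl(doses, dp$A[i], dp$B[i], dp$C[i], dp$D[i])
    for (r in seq_len(rep)) {
      yy <- c(y, base::rep(0, n_ctrl), base::rep(100, n_ctrl))
      lum <- l_neg + (l_pos - l_neg) * (1 - yy / 100) *
        (1 + stats::rnorm(length(yy), 0, cv))
      k <- k + 1
      out[[k]] <- data.frame(
        plate_id = sprintf("%s_%s_r%d", dp$drug[i], dp$line[i], r),
        drug = dp$drug[i], line = dp$line[i], replicate = r,
        content = base::rep(c("compound", "dmso_cells", "no_cells"),
                            c(length(doses), n_ctrl, n_ctrl)),
        dose_uM = c(doses, base::rep(NA_real_, 2 * n_ctrl)),
        luminescence = lum, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Generate drug-treated expression profiles
#'
#' Target genes are scaled by `2^log2fc` with multiplicative log-normal
#' noise; non-targets receive noise only (unchanged in expectation).
#'
#' @param panel An `expression_matrix` (or plain RPKM matrix), the control
#'   profiles.
#' @param target_genes Genes to perturb; must exist in the panel.
#' @param log2fc Planted log2 fold change. Default -2.
#' @param noise_sd Log2 multiplicative noise sd. Default 0.1 (0 = exact).
#' @param seed Integer seed (required).
#' @return RPKM matrix of treated profiles, same dimnames as the control.
#' @export
gen_perturbation_profiles <- function(panel, target_genes, log2fc = -2,
                                      noise_sd = 0.1, seed) {
  if (missing(seed)) stop("seed is required")
  rpkm <- if (inherits(panel, "expression_matrix")) panel$rpkm else panel
  missing_g <- setdiff(target_genes, rownames(rpkm))
  if (length(missing_g))
    stop("target genes not in panel: ", paste(missing_g, collapse = ", "))
  set.seed(seed)
  shift <- matrix(0, nrow(rpkm), ncol(rpkm), dimnames = dimnames(rpkm))
  shift[target_genes, ] <- log2fc
  noise <- if (noise_sd > 0)
    matrix(stats::rnorm(length(rpkm), 0, noise_sd), nrow(rpkm)) else 0
  rpkm * 2^(shift + noise)
}

#' Generate a metabolite concentration table
#'
#' `n_linked` metabolites track the shifted module's latent activity
#' (`conc = intercept + a * factor + noise`, two replicate measurements);
#' `n_null` metabolites are independent noise. A small fraction of single
#' replicates is not detected (NA); the last two null metabolites are made
#' rare (detected in fewer lines than the screen's detection threshold) to
#' exercise the exclusion rule.
#'
#' @param truth A `panel_truth`.
#' @param n_linked Linked metabolites. Default 3.
#' @param n_null Null metabolites. Default 50.
#' @param seed Integer seed (required).
#' @param a Link slope. Default 1.
#' @param noise_sd Link noise sd. Default 0.2.
#' @param nd_rate Per-replicate not-detected probability. Default 0.05.
#' @param rep_sd Replicate measurement noise sd. Default 0.05.
#' @return List: `rep1`, `rep2` (metabolite x line matrices, NA = N.D.),
#'   `linked` (names of the planted metabolites).
#' @export
gen_metabolites <- function(truth, n_linked = 3, n_null = 50, seed,
                            a = 1, noise_sd = 0.2, nd_rate = 0.05,
                            rep_sd = 0.05) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  lines <- colnames(truth$latent_factors)
  f <- truth$latent_factors[1, ]
  mets <- c(sprintf("met_link_%02d", seq_len(n_linked)),
            sprintf("met_null_%02d", seq_len(n_null)))
  n <- length(mets)
  base <- matrix(NA_real_, n, length(lines), dimnames = list(mets, lines))
  for (i in seq_len(n_linked))
    base[i, ] <- 10 + a * f + stats::rnorm(length(lines), 0, noise_sd)
  for (i in seq_len(n_null))
    base[n_linked + i, ] <- 10 + stats::rnorm(length(lines), 0, 1.5)
  base <- pmax(base, 0.01)
  rep_noise <- function() matrix(stats::rnorm(length(base), 0, rep_sd),
                                 n, length(lines))
  r1 <- pmax(base + rep_noise(), 0.01)
  r2 <- pmax(base + rep_noise(), 0.01)
  nd1 <- matrix(stats::runif(length(base)) < nd_rate, n, length(lines))
  nd2 <- matrix(stats::runif(length(base)) < nd_rate, n, length(lines))
  r1[nd1] <- NA; r2[nd2] <- NA
  if (n_null >= 2) {            # rare metabolites: detected in too few lines
    rare <- n_linked + n_null - c(1, 0)
    for (i in rare) {
      hide <- sample(length(lines), length(lines) - 9)
      r1[i, hide] <- NA; r2[i, hide] <- NA
    }
  }
  list(rep1 = r1, rep2 = r2, linked = mets[seq_len(n_linked)])
}

#' Generate a survival cohort tied to module activity
#'
#' Case expression follows the panel's factor model (fresh per-case latent
#' factors; the counts are on the same positive scale as normalized counts).
#' Survival is exponential; the log-hazard is `hazard_beta` times either the
#' top-quartile indicator of the planted module's activity (`hazard_model =
#' "group"`, so `exp(hazard_beta)` is the hazard ratio between the
#' top-quartile and the rest) or the standardized activity itself
#' (`"linear"`). Censoring is independent exponential, calibrated to
#' `censor_frac` in the baseline group.
#'
#' @param truth A `panel_truth`.
#' @param n_cases Cohort size. Default 500.
#' @param seed Integer seed (required).
#' @param hazard_beta Log-hazard coefficient. Default `truth$hazard_beta`
#'   (log 2).
#' @param hazard_model `"group"` (default) or `"linear"`.
#' @param noise_sd Case-level residual expression noise sd. Default 0.3.
#' @param censor_frac Target censoring fraction at baseline hazard.
#'   Default 0.2.
#' @param median_days Baseline median survival in days. Default 700.
#' @return List of class `cohort_data`: `counts` (case x gene), `survival`
#'   (data frame `case`, `os_days`, `os_event`), `factor` (planted module
#'   activity per case), `high_group` (true top-quartile cases).
#' @export
gen_cohort <- function(truth, n_cases = 500, seed,
                       hazard_beta = truth$hazard_beta,
                       hazard_model = c("group", "linear"),
                       noise_sd = 0.3, censor_frac = 0.2, median_days = 700) {
  if (missing(seed)) stop("seed is required")
  hazard_model <- match.arg(hazard_model)
  set.seed(seed)
  cases <- sprintf("case_%04d", seq_len(n_cases))
  genes <- names(truth$module_membership)
  mods <- rownames(truth$latent_factors)
  fac <- matrix(stats::rnorm(length(mods) * n_cases), length(mods), n_cases,
                dimnames = list(mods, cases))
  log2e <- matrix(stats::rnorm(length(genes) * n_cases, sd = 1),
                  length(genes), n_cases, dimnames = list(genes, cases))
  for (m in mods) {
    idx <- which(truth$module_membership == m)
    noise <- matrix(stats::rnorm(length(idx) * n_cases, sd = noise_sd),
                    length(idx), n_cases)
    log2e[idx, ] <- truth$loadings[idx] %o% fac[m, ] + noise
  }
  log2e <- log2e + truth$baseline[genes]
  counts <- t(2^log2e)                     # cases x genes

  s <- as.numeric(scale(fac[1, ]))
  names(s) <- cases
  high <- cases[order(-s)][seq_len(ceiling(0.25 * n_cases))]
  lp <- if (hazard_model == "group") hazard_beta * (cases %in% high)
        else hazard_beta * s
  lambda0 <- log(2) / median_days
  t_event <- stats::rexp(n_cases, rate = lambda0 * exp(lp))
  rate_c <- lambda0 * censor_frac / (1 - censor_frac)
  t_cens <- stats::rexp(n_cases, rate = rate_c)
  os <- pmin(t_event, t_cens)
  structure(list(counts = counts,
                 survival = data.frame(case = cases, os_days = os,
                                       os_event = as.integer(t_event <= t_cens),
                                       stringsAsFactors = FALSE),
                 factor = s, high_group = high),
            class = "cohort_data")
}

#' Generate region fixtures and per-sample QC statistics
#'
#' Produces a strand-mixed TSS table for the panel genes (genes tiled along
#' synthetic chromosomes), histone peak sets and basal open-chromatin peaks
#' placed inside and outside promoters, TF peaks enriched at the shifted
#' module's promoters, a small promoter accessibility (ppm) matrix, and a
#' per-sample QC stats table with a planted fraction of failures spread over
#' the four failure modes (low reads, high intron fraction, spike-in
#' outlier, low peak count). Spike-in values for clean samples sit on a
#' fixed low-dispersion grid so the plate 2-sd rule separates planted
#' outliers from clean samples deterministically.
#'
#' @param truth A `panel_truth`.
#' @param seed Integer seed (required).
#' @param n_samples QC stats rows. Default 200.
#' @param fail_frac Planted failure fraction. Default 0.1.
#' @param plate_size Samples per plate. Default 25.
#' @return List: `tss`, `histone_peaks` (list of 2 GRanges), `basal_atac`,
#'   `tf_peaks` (GRanges), `accessibility` (ppm matrix), `sample_stats`
#'   (data frame), `qc_truth` (data frame `sample_id`, `mode`).
#' @export
gen_regions_and_peaks <- function(truth, seed, n_samples = 200,
                                  fail_frac = 0.1, plate_size = 25) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  genes <- names(truth$module_membership)
  n <- length(genes)
  chroms <- paste0("chr", 1 + (seq_len(n) - 1) %% 5)
  tss_pos <- 10000 + 20000 * ((seq_len(n) - 1) %/% 5)
  tss <- data.frame(gene_id = genes, chrom = chroms, tss_position = tss_pos,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    stringsAsFactors = FALSE)

  mk_peaks <- function(center, width) {
    keep <- !is.na(center)
    GenomicRanges::GRanges(chroms[keep],
      IRanges::IRanges(start = center[keep] - width %/% 2 + 1, width = width))
  }
  # histone peaks: enhancer-like, 3-8 kb downstream of the TSS (outside the
  # +/-1.5 kb promoter), present for ~60% of genes per mark with jitter
  h3k27 <- mk_peaks(ifelse(stats::runif(n) < 0.6,
                           tss_pos + round(stats::runif(n, 3000, 8000)), NA), 800)
  h3k4 <- mk_peaks(ifelse(stats::runif(n) < 0.6,
                          tss_pos + round(stats::runif(n, 3000, 8000)), NA), 1000)
  # basal ATAC: promoter-proximal peaks for ~70% of genes, plus distal peaks
  atac_prom <- mk_peaks(ifelse(stats::runif(n) < 0.7, tss_pos, NA), 400)
  atac_dist <- mk_peaks(ifelse(stats::runif(n) < 0.5,
                               tss_pos + round(stats::runif(n, 3000, 8000)), NA), 400)
  basal_atac <- c(atac_prom, atac_dist)
  # TF peaks: promoter binding enriched in the shifted module
  in_mod <- truth$module_membership == rownames(truth$latent_factors)[1]
  p_bind <- ifelse(in_mod, 0.6, 0.1)
  tf_peaks <- mk_peaks(ifelse(stats::runif(n) < p_bind, tss_pos, NA), 300)

  lines <- colnames(truth$latent_factors)
  accessibility <- matrix(2^stats::rnorm(n * length(lines), 3, 1), n,
                          dimnames = list(genes, lines))

  samples <- sprintf("qc_sample_%03d", seq_len(n_samples))
  plates <- paste0("plate_", 1 + (seq_len(n_samples) - 1) %/% plate_size)
  spike_base <- 100; spike_spread <- 3
  stats_df <- data.frame(
    sample_id = samples, plate_id = plates,
    total_mapped_reads = round(stats::runif(n_samples, 8e5, 2e6)),
    intron_fraction = stats::runif(n_samples, 0.05, 0.12),
    spikein_rpkm = NA_real_,
    macs_peak_count = round(stats::runif(n_samples, 12000, 40000)),
    stringsAsFactors = FALSE)
  for (pl in unique(plates)) {          # fixed low-dispersion spike grid
    idx <- which(plates == pl)
    grid <- spike_base + seq(-1.5, 1.5, length.out = length(idx)) * spike_spread
    stats_df$spikein_rpkm[idx] <- sample(grid)
  }

  n_fail <- round(fail_frac * n_samples)
  fail_idx <- sample(n_samples, n_fail)
  modes <- base::rep(c("min_reads", "intron", "spikein", "macs_peaks"),
                     length.out = n_fail)
  for (j in seq_len(n_fail)) {
    i <- fail_idx[j]
    switch(modes[j],
      min_reads = stats_df$total_mapped_reads[i] <- round(stats::runif(1, 1e5, 4e5)),
      intron = stats_df$intron_fraction[i] <- stats::runif(1, 0.2, 0.4),
      spikein = stats_df$spikein_rpkm[i] <- spike_base +
        sample(c(-1, 1), 1) * 12 * spike_spread,
      macs_peaks = stats_df$macs_peak_count[i] <- round(stats::runif(1, 1000, 8000)))
  }
  qc_truth <- data.frame(sample_id = samples[fail_idx], mode = modes,
                         stringsAsFactors = FALSE)
  qc_truth <- qc_truth[order(qc_truth$sample_id), , drop = FALSE]
  rownames(qc_truth) <- NULL

  list(tss = tss, histone_peaks = list(H3K27ac = h3k27, H3K4me1 = h3k4),
       basal_atac = basal_atac, tf_peaks = tf_peaks,
       accessibility = accessibility, sample_stats = stats_df,
       qc_truth = qc_truth)
}
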