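## Pipeline orchestration over the synthetic bundle: subcommand-style stages,
## a flat config carrying every threshold used by the analysis modules, and
## provenance (config + seed + hash) written next to the outputs.

#' Pipeline configuration
#'
#' Flat key-value configuration naming every tunable threshold of the
#' pipeline with the standard defaults (0.5 M reads, 15% intron, 2 sd
#' spike-in, 10,000 peaks, +/-1.5 kb promoters, +/-100 kb enhancer windows,
#' 5 rpkm aberration expression, >4 / <0.25 signature fold changes over a
#' >10 rpkm universe, Spearman r > 0.65 and p < 0.002 metabolite screen,
#' >5-fold and p < 0.05 association screen, 10 uM IC50 cap, top-10 module
#' score genes, top-25% high-activity group). Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # synthetic panel
    n_genes = 2000, n_modules = 5, genes_per_module = 60, n_lines = 25,
    noise_sd = 0.3, n_cases = 500,
    # qc
    min_reads = 5e5, max_intron = 0.15, spike_sd = 2, min_peaks = 10000,
    min_rpkm_repro = 2,
    # regions
    promoter_flank_bp = 1500, enhancer_window_bp = 1e5,
    # dose response / association
    ic50_cap_uM = 10, expr_thresh_rpkm = 5, fold_thresh = 5, p_thresh = 0.05,
    viability_cv = 0.05, viability_rep = 2,
    # signatures
    fc_up = 4, fc_down = 0.25, sig_min_rpkm = 10, perturb_log2fc = -3,
    # modules
    module_beta = 6, module_min_size = 30, module_cut_height = 0.99,
    metab_r_thresh = 0.65, metab_p_thresh = 0.002, metab_min_detected = 10,
    # cohort
    score_n_genes = 10, high_quantile = 0.25)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

# cheap order-sensitive checksum of the serialized config
.config_hash <- function(cfg) {
  b <- utf8ToInt(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE))
  sprintf("%08x", sum(b * (seq_along(b) %% 97 + 1)) %% 2147483647)
}

#' Run the analysis pipeline on the synthetic bundle
#'
#' Generates the synthetic panel deterministically from `seed`, runs the
#' requested stage (or all stages), writes TSV/BED/JSON artifacts plus a
#' `provenance.json` (config, seed, config hash) under `outdir`, and
#' returns the in-memory results.
#'
#' Stages: `simulate` (fixtures + truth sidecar), `qc`, `regions`,
#' `doseresponse`, `associate`, `modules` (network, eigengenes, metabolite
#' screen), `score` (cohort module scores), `signature`, `synergy`,
#' `survival`, `all`.
#'
#' @param stage Stage name; `"all"` runs everything.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed driving every generator.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results.
#' @export
run_pipeline <- function(stage = "all", outdir, seed,
                         config = pipeline_config()) {
  stages <- c("all", "simulate", "qc", "regions", "doseresponse", "associate",
              "modules", "score", "signature", "synergy", "survival")
  stage <- match.arg(stage, stages)
  if (missing(outdir)) stop("outdir is required")
  if (missing(seed)) stop("seed is required")
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  want <- function(s) stage %in% c("all", s)
  res <- list(seed = seed, config = config)

  jsonlite::write_json(list(config = unclass(config), seed = seed,
                            config_hash = .config_hash(config)),
                       file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  ## -- simulate (always needed as input to the other stages) --------------
  sim <- gen_expression_panel(
    n_genes = config$n_genes, n_modules = config$n_modules,
    genes_per_module = config$genes_per_module, n_lines = config$n_lines,
    noise_sd = config$noise_sd, seed = seed)
  regio <- gen_regions_and_peaks(sim$truth, seed = seed + 1)
  res$sim <- sim
  if (want("simulate")) {
    write_matrix_tsv(sim$expr$rpkm, file.path(outdir, "expression_rpkm.tsv"))
    utils::write.table(regio$sample_stats, file.path(outdir, "sample_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(regio$tss, file.path(outdir, "tss.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(regio$basal_atac, file.path(outdir, "basal_atac.bed"))
    write_bed(regio$tf_peaks, file.path(outdir, "tf_peaks.bed"))
    jsonlite::write_json(
      list(module_membership = as.list(sim$truth$module_membership),
           mutant_lines = sim$truth$mutant_lines,
           mut_gene = sim$truth$mut_gene,
           planted_pair = as.list(sim$truth$planted_pair),
           qc_failures = regio$qc_truth),
      file.path(outdir, "truth.json"), auto_unbox = TRUE)
  }

  if (want("qc")) {
    qr <- qc_rnaseq(regio$sample_stats, min_reads = config$min_reads,
                    max_intron = config$max_intron, spike_sd = config$spike_sd)
    qa <- qc_atac(regio$sample_stats, min_peaks = config$min_peaks)
    write_qc_report(qr, file.path(outdir, "qc_rnaseq.tsv"))
    write_qc_report(qa, file.path(outdir, "qc_atac.tsv"))
    res$qc <- list(rnaseq = qr, atac = qa, truth = regio$qc_truth)
  }

  if (want("regions")) {
    prom <- define_promoters(regio$tss, flank_bp = config$promoter_flank_bp)
    enh <- define_enhancers(regio$histone_peaks, prom, regio$basal_atac)
    emap <- assign_to_genes(enh, regio$tss, window_bp = config$enhancer_window_bp)
    write_bed(prom, file.path(outdir, "promoters.bed"))
    write_bed(enh, file.path(outdir, "enhancers.bed"))
    utils::write.table(emap, file.path(outdir, "enhancer_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$regions <- list(promoters = prom, enhancers = enh, map = emap,
                        tf_peaks = regio$tf_peaks)
  }

  plates <- gen_viability_plates(sim$truth, rep = config$viability_rep,
                                 cv = config$viability_cv, seed = seed + 2)
  if (want("doseresponse") || want("associate")) {
    ic <- dose_response_panel(plates, cap_uM = config$ic50_cap_uM)
    utils::write.table(ic, file.path(outdir, "ic50.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$doseresponse <- ic
  }

  if (want("associate")) {
    mt <- gen_mutation_table(sim$truth, seed = seed + 3)
    ab <- call_aberrations(mt$mutations, sim$expr$rpkm, mt$gene_classes,
                           expr_thresh = config$expr_thresh_rpkm)
    screen <- association_screen(res$doseresponse, ab)
    pairs <- extract_pairs(screen, fold_thresh = config$fold_thresh,
                           p_thresh = config$p_thresh)
    utils::write.table(screen, file.path(outdir, "association_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pairs, file.path(outdir, "association_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$associate <- list(screen = screen, pairs = pairs, aberrations = ab)
  }

  if (want("modules") || want("score") || want("survival")) {
    tom <- build_network(sim$expr$rpkm, beta = config$module_beta)
    assign <- detect_modules(tom, min_size = config$module_min_size,
                             cut_height = config$module_cut_height,
                             expr = sim$expr$rpkm)
    me <- module_eigengene(sim$expr$rpkm, assign)
    metab <- gen_metabolites(sim$truth, seed = seed + 4)
    # screen against the module tracking the planted (shifted) activity
    planted_mod <- .matched_module(assign, sim$truth)
    hits <- metabolite_screen(me$me[planted_mod, ], metab,
                              r_thresh = config$metab_r_thresh,
                              p_thresh = config$metab_p_thresh,
                              min_detected = config$metab_min_detected)
    utils::write.table(
      data.frame(gene = names(assign), module = assign,
                 kme = me$kme[names(assign)], row.names = NULL),
      file.path(outdir, "module_membership.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(me$me, file.path(outdir, "module_eigengenes.tsv"),
                     id_column = "module")
    utils::write.table(hits, file.path(outdir, "metabolite_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$modules <- list(assignment = assign, me = me, planted_module = planted_mod,
                        metabolites = metab, metabolite_hits = hits)
  }

  cohort <- gen_cohort(sim$truth, n_cases = config$n_cases, seed = seed + 5)
  if (want("score") || want("survival")) {
    planted_mod <- res$modules$planted_module
    members <- names(res$modules$assignment)[res$modules$assignment == planted_mod]
    ms <- module_score(cohort$counts, members, res$modules$me$kme,
                       n_genes = config$score_n_genes)
    utils::write.table(
      data.frame(case = names(ms$score), score = ms$score, row.names = NULL),
      file.path(outdir, "module_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    res$score <- ms
  }

  if (want("signature")) {
    members1 <- names(sim$truth$module_membership)[
      sim$truth$module_membership == rownames(sim$truth$latent_factors)[1]]
    targets <- members1[seq_len(min(30, length(members1)))]
    treated <- gen_perturbation_profiles(sim$expr, targets,
                                         log2fc = config$perturb_log2fc,
                                         noise_sd = 0.1, seed = seed + 6)
    ctrl <- sim$expr$rpkm[, 1]
    trt <- treated[, 1]
    fc <- fold_changes(trt, ctrl)
    sig <- extract_signature(fc, trt, ctrl, fc_up = config$fc_up,
                             fc_down = config$fc_down,
                             min_expr_rpkm = config$sig_min_rpkm,
                             source = list(cell_line = colnames(treated)[1],
                                           compound = "synthetic_perturbagen"))
    score <- connectivity_score(sig, fc)
    write_signature_json(sig, file.path(outdir, "signature.json"))
    res$signature <- list(signature = sig, self_connectivity = score,
                          targets = targets)
  }

  if (want("synergy")) {
    # constant-ratio combination built on two single-agent median-effect
    # models with a planted CI of 0.7 across the fa range
    me1 <- list(Dm = 0.5, m = 1.2, valid = TRUE)
    me2 <- list(Dm = 2.0, m = 0.8, valid = TRUE)
    fa_grid <- seq(0.2, 0.8, by = 0.05)
    planted_ci <- 0.7
    d <- planted_ci / (1 / .dose_for_fa(me1, fa_grid) +
                       1 / .dose_for_fa(me2, fa_grid))
    prof <- combination_index(structure(me1, class = "median_effect_fit"),
                              structure(me2, class = "median_effect_fit"),
                              data.frame(d1 = d, d2 = d, fa = fa_grid))
    utils::write.table(as.data.frame(prof), file.path(outdir, "ci_fa.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$synergy <- list(profile = prof, planted_ci = planted_ci,
                        ci50 = ci_at(prof, 0.5))
  }

  if (want("survival")) {
    hg <- high_activity_group(res$score$score, mode = "quantile",
                              q = config$high_quantile)
    grp <- ifelse(cohort$survival$case %in% hg, "high", "other")
    kl <- km_logrank(cohort$survival$os_days, cohort$survival$os_event, grp)
    utils::write.table(kl$km, file.path(outdir, "km_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$survival <- list(logrank = kl, high_group = hg, cohort = cohort)
  }

  invisible(res)
}

# module label whose eigengene-defining members best overlap the truth's
# shifted module (the generator's first module)
.matched_module <- function(assignment, truth) {
  target <- names(truth$module_membership)[
    truth$module_membership == rownames(truth$latent_factors)[1]]
  tab <- table(assignment[names(assignment) %in% target])
  tab <- tab[names(tab) != "grey"]
  if (!length(tab)) stop("no detected module overlaps the planted module")
  names(tab)[which.max(tab)]
}
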