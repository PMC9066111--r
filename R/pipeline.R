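#' Pipeline configuration schema
#'
#' Strict-schema configuration for [run_pipeline()]: unknown keys are
#' rejected, every omitted key takes the default below, and the full
#' resolved configuration is echoed into the output directory (no silent
#' defaults in the report). The three analysis resolutions default to the
#' standard 500 kb (compartments) / 40 kb (TADs) / 20 kb (differential
#' interactions); the compartment resolution is validated to be 500 kb
#' before any computation.
#'
#' @param config named list, or path to a YAML file.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1L, out_dir = "chromarch_out",
    n_chrom = 2L, chrom_length = 2e7, genes_per_chrom = 200L,
    compartment_res = 500000L, tad_res = 40000L, diff_res = 20000L,
    decay_exponent = 1, compartment_contrast = 0.4, tad_enrichment = 3,
    treated_tad_enrichment = 2, insulation = 0.3,
    sequencing_depth = 2e7, replicate_count = 2L,
    switch_frac_ab = 0.05, switch_frac_ba = 0,
    diff_block_chrom = "chr1", diff_block_start = 5e6,
    diff_block_end = 6e6, diff_block_fold = 4,
    dmr_fold_change = 4, n_hyper = 20L, n_hypo = 10L, dmr_width = 5000L,
    medip_depth = 2e6, medip_window = 1000L,
    peak_boundary = 100L, peak_promoter = 100L, peak_random = 100L,
    bias_sd = 0.25, tss_dip = 0.25, tes_rise = 2,
    ice_tol = 1e-5, ice_max_iter = 200L, ice_mask_fraction = 0.02,
    di_window = 2e6, flank_bins = 10L, hmm_seed = 13L,
    min_count = 10L, fdr = 0.05, lfc = 1,
    dmr_fdr = 0.05, dmr_lfc = 1, merge_gap = 1000L, metagene_flank = 2000L,
    promoter_bp = 2000L, proximal_bp = 10000L,
    enrich_span = 500000L, enrich_step = 25000L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_named("config", paste("unknown configuration key(s):",
                               paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  # YAML parses some exponent spellings (1.0e7) as strings; coerce numerics
  for (k in names(defaults))
    if (is.numeric(defaults[[k]]) && is.character(cfg[[k]])) {
      v <- suppressWarnings(as.numeric(cfg[[k]]))
      if (anyNA(v)) stop_named("config", paste0("key ", k, " must be numeric"))
      cfg[[k]] <- v
    }
  if (cfg$compartment_res != 500000L)
    stop_named("config", "compartment analysis requires 500 kb matrices")
  if (cfg$chrom_length %% cfg$compartment_res != 0)
    stop_named("config", "chrom_length must be a multiple of 500 kb")
  class(cfg) <- "run_config"
  cfg
}

sim_config_from <- function(cfg, gamma = cfg$tad_enrichment) {
  sim_config(decay_exponent = cfg$decay_exponent,
             compartment_contrast = cfg$compartment_contrast,
             tad_enrichment = gamma, insulation = cfg$insulation,
             sequencing_depth = cfg$sequencing_depth,
             replicate_count = cfg$replicate_count,
             dmr_fold_change = cfg$dmr_fold_change,
             n_hyper = cfg$n_hyper, n_hypo = cfg$n_hypo,
             dmr_width = cfg$dmr_width, medip_depth = cfg$medip_depth,
             medip_window = cfg$medip_window,
             peak_count = c(boundary = cfg$peak_boundary,
                            promoter = cfg$peak_promoter,
                            random = cfg$peak_random),
             bias_sd = cfg$bias_sd, tss_dip = cfg$tss_dip,
             tes_rise = cfg$tes_rise)
}

derive_seed <- function(seed, k) as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)

#' Pool replicate contact matrices
#'
#' Sums the raw layers of replicate matrices sharing one bin table.
#'
#' @param cms list of raw [contact_matrix()] objects.
#' @return one `contact_matrix` with the summed raw layer.
#' @export
pool_replicates <- function(cms) {
  mats <- lapply(names(cms[[1]]$layers$raw), function(ch)
    Reduce(`+`, lapply(cms, function(cm) cm$layers$raw[[ch]])))
  contact_matrix(cms[[1]]$bins, stats::setNames(mats, names(cms[[1]]$layers$raw)))
}

#' Simulate a complete ready-to-run input set
#'
#' Generates the toy genome, the control and treated truths (compartment
#' switching, the planted differential block, and the treated TAD-enrichment
#' change), contact matrices at the three resolutions for every condition
#' and replicate, MeDIP tracks, and ChIP peaks, writing everything as plain
#' text under `dir` with a full parameter echo.
#'
#' @param cfg a [run_config()].
#' @param dir output directory.
#' @return (invisibly) the in-memory simulation: list with `genome`,
#'   `truth_control`, `truth_treated`, `hic` (nested list
#'   `[[resolution]][[condition]][[replicate]]`), `medip`, `peaks`.
#' @export
simulate_inputs <- function(cfg, dir = file.path(cfg$out_dir, "inputs")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- sim_config_from(cfg)
  scfg_trt <- sim_config_from(cfg, gamma = cfg$treated_tad_enrichment)
  genome0 <- simulate_genome(cfg$n_chrom, cfg$chrom_length, genes_per_chrom = 0L,
                             seed = derive_seed(cfg$seed, 1))
  truth_c <- simulate_truth(genome0, scfg, seed = derive_seed(cfg$seed, 2))
  genome <- place_genes(genome0, truth = truth_c,
                        genes_per_chrom = cfg$genes_per_chrom,
                        seed = derive_seed(cfg$seed, 3))
  truth_t <- switch_compartments(truth_c, cfg$switch_frac_ab, cfg$switch_frac_ba,
                                 seed = derive_seed(cfg$seed, 4))
  if (cfg$diff_block_fold != 1)
    truth_t <- plant_diff_block(truth_t, cfg$diff_block_chrom,
                                cfg$diff_block_start, cfg$diff_block_end,
                                cfg$diff_block_fold)
  hic <- list()
  k <- 10L
  for (res in c(cfg$compartment_res, cfg$tad_res, cfg$diff_res)) {
    rn <- as.character(res)
    hic[[rn]] <- list(control = list(), treated = list())
    for (cond in c("control", "treated")) {
      tr <- if (cond == "control") truth_c else truth_t
      sc <- if (cond == "control") scfg else scfg_trt
      for (r in seq_len(cfg$replicate_count)) {
        k <- k + 1L
        cm <- simulate_contact_map(genome, tr, sc, res,
                                   seed = derive_seed(cfg$seed, k))
        hic[[rn]][[cond]][[r]] <- cm
        write_matrix(cm, file.path(dir, sprintf("hic_%s_%d_%d.matrix", cond, res, r)),
                     file.path(dir, sprintf("bins_%d.bed", res)))
      }
    }
  }
  medip <- simulate_medip_tracks(genome, truth_t, scfg,
                                 seed = derive_seed(cfg$seed, 40))
  write_medip(medip, dir)
  pk <- simulate_peaks(genome, truth_c, scfg, seed = derive_seed(cfg$seed, 41))
  write_narrowpeak(pk$peaks, file.path(dir, "peaks.narrowPeak"))
  write_bed(pk$truth, file.path(dir, "peak_truth.bed"))
  write_bed12(genome$genes, file.path(dir, "genes.bed12"))
  write_truth(truth_c, file.path(dir, "truth_control"))
  write_truth(truth_t, file.path(dir, "truth_treated"))
  write_keyvalue(unclass(cfg), file.path(dir, "config_echo.txt"))
  invisible(list(genome = genome, truth_control = truth_c,
                 truth_treated = truth_t, hic = hic, medip = medip,
                 peaks = pk))
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order — simulate (or use a prebuilt
#' input set), ICE balancing per resolution and condition, A/B compartments
#' and switching at 500 kb, directionality-index + HMM TAD calling with
#' boundary-strength scoring at 40 kb, differential-interaction calling at
#' 20 kb, MeDIP metagene/DMR analysis, and peak integration — writing all
#' stage outputs plus a single JSON report under the output directory. The
#' report contains only quantities recomputable from the written outputs and
#' is byte-identical across runs with the same seed.
#'
#' @param config a [run_config()], a named list, or a YAML path.
#' @param inputs optionally, a [simulate_inputs()] result to reuse.
#' @return (invisibly) the report list, also written to
#'   `<out_dir>/report.json`.
#' @export
run_pipeline <- function(config = list(), inputs = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out <- cfg$out_dir
  dir.create(file.path(out, "results"), showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- function(name) message(sprintf("[%s] %s (%.1f s elapsed)", "chromarch",
                                          name, as.numeric(Sys.time() - t0, "secs")))
  stage("simulate")
  if (is.null(inputs)) inputs <- simulate_inputs(cfg)
  genome <- inputs$genome
  lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  cfg_echo <- unclass(cfg)
  cfg_echo$out_dir <- NULL   # environment, not an analysis parameter
  report <- list(seed = cfg$seed, config = cfg_echo)

  stage("ice")
  balanced <- list()
  for (res in c(cfg$compartment_res, cfg$tad_res, cfg$diff_res)) {
    rn <- as.character(res)
    balanced[[rn]] <- list()
    for (cond in c("control", "treated")) {
      cm <- pool_replicates(inputs$hic[[rn]][[cond]])
      cm <- ice_balance(cm, max_iter = cfg$ice_max_iter, tol = cfg$ice_tol,
                        mask_fraction = cfg$ice_mask_fraction)
      balanced[[rn]][[cond]] <- oe_transform(cm)
    }
  }
  report$ice <- lapply(balanced, function(x)
    lapply(x, function(cm) list(cv = unname(max(attr(cm, "ice_cv"))),
                                masked_bins = sum(vapply(cm$mask, sum, integer(1))))))

  stage("compartments")
  rn <- as.character(cfg$compartment_res)
  trk_c <- compartment_pc1(balanced[[rn]]$control, genome$genes)
  trk_t <- compartment_pc1(balanced[[rn]]$treated, genome$genes)
  sw <- switch_classify(trk_c, trk_t)
  r <- pc1_correlation(trk_c, trk_t)$r
  pbc <- peaks_by_compartment(inputs$peaks$peaks, sw)
  for (nm in c("control", "treated")) {
    trk <- if (nm == "control") trk_c else trk_t
    write_bedgraph(data.frame(chrom = trk$chrom, start = trk$start, end = trk$end,
                              value = ifelse(is.na(trk$pc1), 0, trk$pc1)),
                   file.path(out, "results", paste0("pc1_", nm, ".bedgraph")))
  }
  write_bed(data.frame(sw$chrom, sw$start, sw$end, sw$class),
            file.path(out, "results", "compartment_switch.bed"))
  report$compartments <- list(pc1_r = r,
                              switch_fractions = as.list(attr(sw, "fractions")),
                              peak_composition = as.list(pbc$composition),
                              bound_fraction = as.list(pbc$bound_fraction))

  stage("tads")
  rn <- as.character(cfg$tad_res)
  tads <- list()
  for (cond in c("control", "treated")) {
    di <- directionality_index(balanced[[rn]][[cond]], cfg$di_window)
    di <- fit_hmm_and_decode(di, seed = cfg$hmm_seed)
    ts <- assemble_domains(di)
    ts <- boundary_strength(balanced[[rn]][[cond]], ts, w = cfg$flank_bins)
    tads[[cond]] <- ts
    write_bedgraph(data.frame(chrom = di$chrom, start = di$start, end = di$end,
                              value = ifelse(is.na(di$di), 0, di$di)),
                   file.path(out, "results", paste0("di_", cond, ".bedgraph")))
    write_tads(ts, file.path(out, "results", paste0("domains_", cond, ".bed")),
               file.path(out, "results", paste0("boundaries_", cond, ".bed")))
  }
  itad_c <- intra_tad_interaction(balanced[[rn]]$control, tads$control)
  itad_t <- intra_tad_interaction(balanced[[rn]]$treated, tads$treated)
  itad_cmp <- compare_conditions(itad_c$mean_z, itad_t$mean_z)
  sc_c <- tad_compartment_scores(tads$control, trk_c)
  sc_t <- tad_compartment_scores(tads$treated, trk_t)
  tsw <- tad_switch(sc_c, sc_t)
  strata <- boundary_strength_strata(tads$control, tads$treated, inputs$peaks$peaks)
  report$tads <- list(
    n_domains = lapply(tads, function(t) nrow(t$domains)),
    n_boundaries = lapply(tads, function(t) sum(t$boundaries$kind == "boundary")),
    intra_tad = list(median_diff = itad_cmp$median_diff, p = itad_cmp$p),
    tad_switch_fraction = tsw$switched_fraction,
    boundary_strata_p = as.list(stats::setNames(as.numeric(strata$p),
                                                paste(rep(rownames(strata$p), 2),
                                                      rep(colnames(strata$p), each = 2),
                                                      sep = "_"))))

  stage("differential interactions")
  rn <- as.character(cfg$diff_res)
  dtab <- call_differential(inputs$hic[[rn]]$control, inputs$hic[[rn]]$treated,
                            min_count = cfg$min_count, fdr = cfg$fdr, lfc = cfg$lfc)
  dbins <- differential_bins(dtab)
  venn <- overlap_with_peaks(dbins, inputs$peaks$peaks)
  cbb <- counts_by_binding(dtab, inputs$peaks$peaks)
  write_diff_table(dtab, file.path(out, "results", "differential_interactions.tsv"))
  write_bed(dbins, file.path(out, "results", "differential_bins.bed"))
  report$differential <- list(n_tested = nrow(dtab),
                              n_significant = sum(dtab$significant),
                              n_differential_bins = nrow(dbins),
                              venn = as.list(venn),
                              binding_p = cbb$p)

  stage("methylation")
  prof <- metagene_profile(inputs$medip, genome$genes,
                           flank_bp = cfg$metagene_flank, condition = "control")
  dmrs <- call_dmrs(inputs$medip, fdr = cfg$dmr_fdr, lfc = cfg$dmr_lfc,
                    merge_gap = cfg$merge_gap)
  ann <- annotate_dmrs(dmrs, genome$genes, promoter_bp = cfg$promoter_bp)
  dpo <- dmr_peak_overlap(dmrs, inputs$peaks$peaks)
  write.table(prof, file.path(out, "results", "metagene_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_dmrs(dmrs, file.path(out, "results", "dmrs.bed"))
  report$methylation <- list(
    n_dmrs = nrow(dmrs),
    n_hyper = sum(dmrs$direction == "hyper"),
    n_hypo = sum(dmrs$direction == "hypo"),
    metagene_min_bin = which.min(prof$signal),
    metagene_max_bin = which.max(prof$signal),
    feature_composition = as.list(ann$composition),
    peak_overlap_fraction = unname(dpo["fraction"]))

  stage("peak integration")
  ann_pk <- annotate_peaks(inputs$peaks$peaks, genome$genes,
                           promoter_bp = cfg$promoter_bp,
                           proximal_bp = cfg$proximal_bp)
  prof_bd <- boundary_enrichment_profile(inputs$peaks$peaks, tads$control, lens,
                                         span_bp = cfg$enrich_span,
                                         step_bp = cfg$enrich_step)
  pab <- peaks_at_boundaries(inputs$peaks$peaks, tads$control)
  write.table(ann_pk, file.path(out, "results", "peak_annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(prof_bd, file.path(out, "results", "boundary_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report$peaks <- list(class_fractions = as.list(attr(ann_pk, "fractions")),
                       boundary_overlap = as.list(pab),
                       enrichment_peak_bin = which.max(prof_bd$count_per_boundary))

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage("done")
  invisible(report)
}
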