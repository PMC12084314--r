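#' Default pipeline configuration
#'
#' One configuration object drives the full in-silico reproduction of the
#' crispant morphometry study design: a discovery experiment (controls vs
#' crispants carrying a programmed LCeP contraction), a replication
#' experiment with different guide RNAs (14 controls vs 17 crispants), a
#' three-group rescue experiment (16 controls, 14 crispants, 12 double
#' crispants; the double knockdown restores `contraction = 1`), and the
#' expression / qPCR sub-analyses.  Thresholds default to the analysis
#' settings of the study: voxelwise `alpha = 0.01`, base-mean filter 100,
#' FDR 0.1, wildtype-fraction cutoff 0.5; the cluster-extent minimum (50
#' voxels at 26-connectivity) and exact-mirror symmetry rule are this
#' package's declared defaults.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param shape,spacing grid geometry passed to [make_atlas()].
#' @param contraction programmed linear contraction of affected genotypes.
#' @param smoothness,amplitude background deformation parameters
#'   ([cohort_design()]).
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 1L, shape = c(48, 48, 48),
                           spacing = c(2, 2, 2), contraction = 0.9,
                           smoothness = 8, amplitude = 0.8) {
  structure(list(
    seed = as.integer(seed), shape = shape, spacing = spacing,
    smoothness = smoothness, amplitude = amplitude,
    contraction = contraction,
    groups = list(
      discovery = data.frame(genotype = c("ctl", "xrcc"), batch = "b1",
                             n = c(14L, 14L), contraction = c(1, contraction)),
      replication = data.frame(genotype = c("ctl", "xrcc"), batch = "b2",
                               n = c(14L, 17L), contraction = c(1, contraction)),
      rescue = data.frame(genotype = c("ctl", "xrcc", "dbl"), batch = "b3",
                          n = c(16L, 14L, 12L),
                          contraction = c(1, contraction, 1))),
    thresholds = list(alpha = 0.01, min_cluster = 50, symmetric = TRUE,
                      tol = 0, connectivity = 26, min_base_mean = 100,
                      fdr_alpha = 0.1, wildtype_threshold = 0.5)
  ), class = "run_config")
}

config_hash <- function(config) rlang::hash(config)

stage_design <- function(config, stage, seed_offset) {
  cohort_design(groups = config$groups[[stage]], shape = config$shape,
                spacing = config$spacing, smoothness = config$smoothness,
                amplitude = config$amplitude,
                seed = derive_seed(config$seed, seed_offset))
}

report_header <- function(config, stage) {
  list(stage = stage, seed = config$seed, config_hash = config_hash(config),
       thresholds = config$thresholds)
}

#' Discovery stage: simulate, map, and isolate the affected region
#'
#' Simulates the discovery cohort, computes per-subject LJD maps, runs the
#' voxelwise two-group t-test on voxel volume, and filters the p map by
#' threshold, bilateral symmetry and cluster extent to produce the ROI.
#' The report records the ROI size, its Dice overlap with the ground-truth
#' effect region (known here because the cohort is synthetic), and full
#' provenance.
#'
#' @param config a [default_config()] configuration.
#' @return list with `atlas`, `cohort`, `ljds`, `stat_map`, `roi`,
#'   `report`.
#' @export
run_discovery <- function(config = default_config()) {
  atlas <- make_atlas(config$shape, config$spacing)
  cohort <- make_cohort(stage_design(config, "discovery", 1L), atlas)
  ljds <- cohort_ljd(cohort)
  sm <- voxelwise_two_group(ljds, cohort$manifest$genotype,
                            brain_mask = atlas_mask(atlas, "brain"))
  th <- config$thresholds
  roi <- filter_significance(sm, alpha = th$alpha, min_cluster = th$min_cluster,
                             symmetric = th$symmetric, atlas = atlas,
                             tol = th$tol, connectivity = th$connectivity)
  truth <- effect_region_mask(atlas)
  report <- c(report_header(config, "discovery"),
              list(n_roi_voxels = roi$n_voxels,
                   n_components = length(roi$component_sizes),
                   dice_vs_truth = dice(roi$mask, truth),
                   min_p = min(sm$pvalue)))
  list(atlas = atlas, cohort = cohort, ljds = ljds, stat_map = sm,
       roi = roi, report = report)
}

#' Replication stage: test a discovered ROI in an independent cohort
#'
#' @param config a [default_config()] configuration.
#' @param roi the `roi_mask` discovered in the first experiment.
#' @param atlas the shared atlas (rebuilt from `config` if omitted).
#' @return list with `cohort`, `test` ([roi_replication_test()] result)
#'   and `report`.
#' @export
run_replication <- function(config, roi, atlas = NULL) {
  if (is.null(atlas)) atlas <- make_atlas(config$shape, config$spacing)
  cohort <- make_cohort(stage_design(config, "replication", 2L), atlas)
  test <- roi_replication_test(cohort, roi, atlas)
  report <- c(report_header(config, "replication"),
              list(t = test$t, df = test$df, p = test$p,
                   group_means = as.list(test$group_means)))
  list(cohort = cohort, test = test, report = report)
}

#' Rescue stage: three-group ROI ANOVA with post hoc comparisons
#'
#' @param config a [default_config()] configuration.
#' @param roi the ROI to measure (discovered mask, or the ground-truth
#'   LCeP mask).
#' @param atlas the shared atlas (rebuilt from `config` if omitted).
#' @return list with `cohort`, `test` ([three_group_roi_anova()] result)
#'   and `report`.
#' @export
run_rescue <- function(config, roi, atlas = NULL) {
  if (is.null(atlas)) atlas <- make_atlas(config$shape, config$spacing)
  cohort <- make_cohort(stage_design(config, "rescue", 3L), atlas)
  test <- three_group_roi_anova(cohort, roi, atlas)
  report <- c(report_header(config, "rescue"),
              list(anova = test$anova, posthoc = test$posthoc,
                   group_means = as.list(test$group_means)))
  list(cohort = cohort, test = test, report = report)
}

#' Combined-experiment voxelwise ANOVA map
#'
#' Pools the discovery and replication cohorts and computes the voxelwise
#' genotype main-effect F map from the additive two-way
#' (genotype + batch) model, then filters it like the discovery map.
#'
#' @param config a [default_config()] configuration.
#' @return list with `stat_map`, `roi`, `report`.
#' @export
run_combined_map <- function(config = default_config()) {
  atlas <- make_atlas(config$shape, config$spacing)
  c1 <- make_cohort(stage_design(config, "discovery", 1L), atlas)
  c2 <- make_cohort(stage_design(config, "replication", 2L), atlas)
  ljds <- c(cohort_ljd(c1), cohort_ljd(c2))
  genotype <- c(c1$manifest$genotype, c2$manifest$genotype)
  batch <- c(c1$manifest$batch, c2$manifest$batch)
  sm <- voxelwise_two_way_anova(ljds, genotype, batch,
                                brain_mask = atlas_mask(atlas, "brain"))
  th <- config$thresholds
  roi <- filter_significance(sm, alpha = th$alpha, min_cluster = th$min_cluster,
                             symmetric = th$symmetric, atlas = atlas,
                             tol = th$tol, connectivity = th$connectivity)
  report <- c(report_header(config, "combined_map"),
              list(n_roi_voxels = roi$n_voxels,
                   dice_vs_truth = dice(roi$mask, effect_region_mask(atlas)),
                   df = sm$df))
  list(atlas = atlas, stat_map = sm, roi = roi, report = report)
}

#' Expression stage: filter, FDR, and two-experiment overlap
#'
#' Simulates two differential-expression tables with planted shared true
#' genes, applies the base-mean filter, BH FDR at the configured
#' threshold, and the one-sided Fisher overlap test.
#'
#' @param config a [default_config()] configuration.
#' @param ... overrides passed to [make_gene_tables()].
#' @return list with `tables`, `significant` (per experiment), `overlap`
#'   and `report`.
#' @export
run_expression <- function(config = default_config(), ...) {
  th <- config$thresholds
  gt <- make_gene_tables(seed = derive_seed(config$seed, 4L), ...)
  joined <- filter_genes(gt$a, gt$b, min_base_mean = th$min_base_mean)
  tab_a <- data.frame(gene_id = joined$gene_id, log2FC = joined$log2FC_a,
                      pvalue = joined$pvalue_a)
  tab_b <- data.frame(gene_id = joined$gene_id, log2FC = joined$log2FC_b,
                      pvalue = joined$pvalue_b)
  sig_a <- significant_genes(tab_a, fdr_alpha = th$fdr_alpha)
  sig_b <- significant_genes(tab_b, fdr_alpha = th$fdr_alpha)
  dir_a <- stats::setNames(sig_a$direction, sig_a$gene_id)
  dir_b <- stats::setNames(sig_b$direction, sig_b$gene_id)
  ov <- overlap_analysis(sig_a$gene_id, sig_b$gene_id,
                         universe_size = attr(joined, "n_universe"),
                         directions_a = dir_a, directions_b = dir_b)
  report <- c(report_header(config, "expression"),
              list(n_universe = ov$n_universe, n_a = ov$n_a, n_b = ov$n_b,
                   n_overlap = ov$n_overlap,
                   n_same_direction = ov$n_same_direction,
                   fisher_p = ov$fisher_p))
  list(tables = gt, significant = list(a = sig_a, b = sig_b), overlap = ov,
       report = report)
}

#' qPCR stage: relative expression and group comparisons
#'
#' @param config a [default_config()] configuration.
#' @param ... overrides passed to [make_qpcr()].
#' @return list with `plate`, `result` ([qpcr_relative()]) and `report`.
#' @export
run_qpcr <- function(config = default_config(), ...) {
  plate <- make_qpcr(seed = derive_seed(config$seed, 5L), ...)
  res <- qpcr_relative(plate, control_group = "ctl")
  report <- c(report_header(config, "qpcr"),
              list(group_means = as.list(tapply(res$table$rel_expr,
                                                res$table$group, mean)),
                   tests = res$tests))
  list(plate = plate, result = res, report = report)
}

#' Write a stage report as JSON
#'
#' @param report a stage report list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
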