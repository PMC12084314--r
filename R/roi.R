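# Per-subject ROI volume percentage table for a cohort.
roi_percent_table <- function(cohort, roi, atlas = cohort$atlas, ljds = NULL) {
  mask <- if (inherits(roi, "roi_mask")) roi$mask else roi
  if (!any(mask)) stop("ROI mask is empty")
  if (is.null(ljds)) ljds <- cohort_ljd(cohort)
  brain <- atlas_mask(atlas, "brain")
  rows <- lapply(names(cohort$subjects), function(sid) {
    s <- cohort$subjects[[sid]]
    rv <- region_volume(ljds[[sid]], mask, brain)
    data.frame(id = sid, genotype = s$genotype, batch = s$batch,
               roi_volume_um3 = rv$volume, roi_percent = rv$percent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Replication test of a discovered ROI in an independent cohort
#'
#' Measures the subject-space volume of a previously discovered ROI (as a
#' percentage of total brain volume) in every subject of an independent
#' cohort, and compares the two genotype groups with a two-sided
#' two-sample t-test.  This is the confirmation step in which a mask drawn
#' from the affected region of one experiment is tested in a second
#' experiment with different guide RNAs.
#'
#' @param cohort the replication [make_cohort()] cohort (two genotypes,
#'   >= 2 subjects each).
#' @param roi a [filter_significance()] `roi_mask` (or logical array).
#' @param atlas atlas; defaults to the cohort's.
#' @param ljds optional precomputed [cohort_ljd()] list.
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @return list with `table` (per-subject ROI volume %), `t`, `df`, `p`,
#'   `group_means`.
#' @export
roi_replication_test <- function(cohort, roi, atlas = cohort$atlas,
                                 ljds = NULL, var_equal = TRUE) {
  tab <- roi_percent_table(cohort, roi, atlas, ljds)
  g <- factor(tab$genotype)
  if (nlevels(g) != 2 || any(table(g) < 2)) {
    stop("replication test needs exactly 2 genotype groups with >= 2 subjects each")
  }
  tt <- stats::t.test(roi_percent ~ g, data = tab, var.equal = var_equal)
  list(table = tab,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       group_means = tapply(tab$roi_percent, g, mean))
}

#' One-way ANOVA with pairwise post hoc t-tests on a response vector
#'
#' The statistical core of the three-group rescue analysis, exposed
#' directly so that ROI volume percentages (or any per-subject scalar) can
#' be tested without rebuilding imaging volumes.  The ANOVA has
#' `df = (k - 1, N - k)`; post hoc pairwise two-sided t-tests are reported
#' unadjusted by default, with optional Holm adjustment alongside.
#'
#' @param values numeric response, one per subject.
#' @param groups group labels (>= 3 levels, >= 2 subjects per level).
#' @param var_equal pooled-variance pairwise t-tests (default) or Welch.
#' @return list with `anova` (data.frame: F, df1, df2, p) and `posthoc`
#'   (data.frame: group1, group2, t, df, p, p_holm).
#' @export
roi_group_anova <- function(values, groups, var_equal = TRUE) {
  g <- factor(groups)
  if (nlevels(g) < 3) stop("need at least 3 groups")
  if (any(table(g) < 2)) {
    bad <- names(which(table(g) < 2))
    stop("fewer than 2 subjects in group(s): ", paste(bad, collapse = ", "))
  }
  fit <- stats::lm(values ~ g)
  an <- stats::anova(fit)
  res <- list(anova = data.frame(F = an$`F value`[1],
                                 df1 = an$Df[1], df2 = an$Df[2],
                                 p = an$`Pr(>F)`[1]))
  pairs <- utils::combn(levels(g), 2)
  ph <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sel <- g %in% c(a, b)
    tt <- stats::t.test(values[sel] ~ droplevels(g[sel]), var.equal = var_equal)
    data.frame(group1 = a, group2 = b, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  ph <- do.call(rbind, ph)
  ph$p_holm <- stats::p.adjust(ph$p, method = "holm")
  res$posthoc <- ph
  res$group_means <- tapply(values, g, mean)
  res
}

#' Three-group ROI ANOVA (rescue analysis)
#'
#' Measures ROI volume percentage per subject in a three-group cohort
#' (e.g. control, crispant, double crispant) and runs a one-way ANOVA with
#' pairwise post hoc t-tests via [roi_group_anova()].  With group sizes
#' `(n1, n2, n3)` the error degrees of freedom are `N - 3`, e.g. 39 for
#' groups of 16, 14 and 12.
#'
#' @inheritParams roi_replication_test
#' @return list with `table` (per-subject ROI volume %), `anova`,
#'   `posthoc`, `group_means`.
#' @export
three_group_roi_anova <- function(cohort, roi, atlas = cohort$atlas,
                                  ljds = NULL, var_equal = TRUE) {
  tab <- roi_percent_table(cohort, roi, atlas, ljds)
  res <- roi_group_anova(tab$roi_percent, tab$genotype, var_equal = var_equal)
  c(list(table = tab), res)
}
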