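#' Simulate a pair of differential-expression result tables
#'
#' Emulates the per-gene output of two independent crispant RNA-seq
#' experiments analysed against a common gene universe: null genes carry
#' uniform p-values and small random log2 fold changes; true genes carry
#' p-values from an enriched `Beta(beta_a, 1)` distribution (`beta_a < 1`)
#' and log2 fold changes of magnitude `lfc_effect`.  A configurable number
#' of true genes is shared between the experiments with a concordant fold
#' change sign; the remainder are private to each experiment.  Base mean
#' expression is drawn log-normally per experiment.  The planted truth is
#' recorded for recovery testing.
#'
#' @param n_genes size of the gene universe.
#' @param n_true_shared number of true genes common to both experiments.
#' @param n_true_private number of true genes private to each experiment
#'   (length 2 or scalar).
#' @param lfc_effect absolute log2 fold change of true genes.
#' @param beta_a shape of the enriched p-value distribution (default 0.05).
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters of the
#'   base mean expression.
#' @param frac_upregulated probability that a true gene is upregulated.
#' @param seed integer seed.
#' @return list with `a`, `b` (data.frames: `gene_id`, `baseMean`,
#'   `log2FC`, `pvalue`) and `truth` (data.frame: `gene_id`, `true_a`,
#'   `true_b`, `direction`).
#' @export
make_gene_tables <- function(n_genes = 20000, n_true_shared = 31,
                             n_true_private = c(94, 811), lfc_effect = 1,
                             beta_a = 0.05, base_mean_meanlog = log(300),
                             base_mean_sdlog = 1.5, frac_upregulated = 0.9,
                             seed = 1L) {
  n_true_private <- rep(n_true_private, length.out = 2)
  stopifnot(n_true_shared + sum(n_true_private) <= n_genes)
  set.seed(seed)
  ids <- sprintf("gene%05d", seq_len(n_genes))
  shared <- seq_len(n_true_shared)
  priv_a <- n_true_shared + seq_len(n_true_private[1])
  priv_b <- n_true_shared + n_true_private[1] + seq_len(n_true_private[2])
  dir_shared <- ifelse(stats::runif(n_true_shared) < frac_upregulated, 1, -1)
  one_table <- function(true_idx, shared_dirs) {
    baseMean <- stats::rlnorm(n_genes, base_mean_meanlog, base_mean_sdlog)
    pvalue <- stats::runif(n_genes)
    log2FC <- stats::rnorm(n_genes, 0, 0.2)
    pvalue[true_idx] <- stats::rbeta(length(true_idx), beta_a, 1)
    dirs <- ifelse(stats::runif(length(true_idx)) < frac_upregulated, 1, -1)
    dirs[true_idx %in% shared] <- shared_dirs[true_idx[true_idx %in% shared]]
    log2FC[true_idx] <- dirs * (lfc_effect + abs(stats::rnorm(length(true_idx), 0, 0.25)))
    data.frame(gene_id = ids, baseMean = baseMean, log2FC = log2FC,
               pvalue = pvalue, stringsAsFactors = FALSE)
  }
  a <- one_table(c(shared, priv_a), dir_shared)
  b <- one_table(c(shared, priv_b), dir_shared)
  direction <- rep(0, n_genes)
  direction[shared] <- dir_shared
  truth <- data.frame(
    gene_id = ids,
    true_a = seq_len(n_genes) %in% c(shared, priv_a),
    true_b = seq_len(n_genes) %in% c(shared, priv_b),
    direction = direction,
    stringsAsFactors = FALSE)
  list(a = a, b = b, truth = truth)
}

#' Simulate a qPCR plate
#'
#' Crossing-point (Cp) values for a target and a reference gene across
#' groups of biological replicates.  The reference gene has mean Cp
#' `cp_ref_mean`; the target Cp is
#' `Cp_target = Cp_ref_mean - log2(fold_change)` plus noise, so that one
#' cycle of earlier amplification corresponds to a two-fold expression
#' increase under the `2^(delta Cp)` readout.
#'
#' @param groups named integer vector: replicates per group.
#' @param true_fold_change named numeric vector (same names): true relative
#'   expression of the target per group.
#' @param cp_ref_mean mean reference-gene Cp (default 18).
#' @param sd per-well Cp noise standard deviation.
#' @param target,reference gene names.
#' @param seed integer seed.
#' @return data.frame (class `qpcr_table`) with columns `sample`, `group`,
#'   `gene`, `Cp`; attribute `truth` records the per-group fold changes.
#' @export
make_qpcr <- function(groups = c(ctl = 5L, xrcc = 5L, dbl = 5L),
                      true_fold_change = c(ctl = 1, xrcc = 2.5, dbl = 1.5),
                      cp_ref_mean = 18, sd = 0.2,
                      target = "tp53", reference = "eef1a1l1", seed = 1L) {
  stopifnot(setequal(names(groups), names(true_fold_change)), cp_ref_mean > 0)
  set.seed(seed)
  rows <- list()
  for (gname in names(groups)) {
    for (i in seq_len(groups[[gname]])) {
      sid <- sprintf("%s_%02d", gname, i)
      cp_ref <- cp_ref_mean + stats::rnorm(1, 0, sd)
      cp_tgt <- cp_ref_mean - log2(true_fold_change[[gname]]) + stats::rnorm(1, 0, sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sid, group = gname,
        gene = c(reference, target), Cp = c(cp_ref, cp_tgt),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("qpcr_table", "data.frame"),
            truth = true_fold_change, target = target, reference = reference)
}
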