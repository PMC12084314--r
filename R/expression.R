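#' Join two differential-expression tables and filter on base mean
#'
#' Joins two per-gene result tables on `gene_id` and keeps genes whose base
#' mean expression is at least `min_base_mean` in *both* experiments
#' (genes below the cutoff in either experiment are removed; the boundary
#' value itself is kept).  The surviving universe is the denominator of
#' the downstream overlap analysis.
#'
#' @param table_a,table_b data.frames with columns `gene_id`, `baseMean`,
#'   `log2FC`, `pvalue`.
#' @param min_base_mean cutoff (default 100).
#' @return data.frame with columns `gene_id`, `baseMean_a`, `log2FC_a`,
#'   `pvalue_a`, `baseMean_b`, `log2FC_b`, `pvalue_b`; attribute
#'   `n_universe` is the surviving gene count.
#' @export
filter_genes <- function(table_a, table_b, min_base_mean = 100) {
  need <- c("gene_id", "baseMean", "log2FC", "pvalue")
  stopifnot(all(need %in% names(table_a)), all(need %in% names(table_b)))
  m <- merge(table_a[need], table_b[need], by = "gene_id",
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stop("the two tables share no gene ids")
  m <- m[m$baseMean_a >= min_base_mean & m$baseMean_b >= min_base_mean, ,
         drop = FALSE]
  rownames(m) <- NULL
  attr(m, "n_universe") <- nrow(m)
  m
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard BH step-up adjusted p-values, delegated to
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Significant genes at an FDR threshold, with direction of change
#'
#' Applies [bh_fdr()] to the supplied p-value column (unless an `padj`
#' column is already present) and returns genes with adjusted p strictly
#' below `fdr_alpha`, tagged with the direction of change (sign of the
#' log2 fold change; exactly zero fold changes are tagged `0` and counted).
#'
#' @param table data.frame with `gene_id`, `log2FC` and either `pvalue` or
#'   `padj`.
#' @param fdr_alpha FDR threshold (strict inequality; default 0.1).
#' @return data.frame with `gene_id`, `log2FC`, `padj`, `direction`
#'   (+1/-1/0); attribute `n_zero_direction`.
#' @export
significant_genes <- function(table, fdr_alpha = 0.1) {
  padj <- if ("padj" %in% names(table)) table$padj else bh_fdr(table$pvalue)
  sig <- !is.na(padj) & padj < fdr_alpha
  out <- data.frame(gene_id = table$gene_id[sig],
                    log2FC = table$log2FC[sig],
                    padj = padj[sig],
                    direction = sign(table$log2FC[sig]),
                    stringsAsFactors = FALSE)
  attr(out, "n_zero_direction") <- sum(out$direction == 0)
  out
}

#' Two-experiment gene-list overlap with Fisher exact enrichment test
#'
#' Counts the overlap of two significant-gene sets drawn from a common
#' post-filter universe, the number of overlapping genes whose change goes
#' in the same direction in both experiments, and tests convergence with a
#' one-sided (enrichment) Fisher exact test on the 2x2 membership table
#' `[[|A and B|, |A only|], [|B only|, neither]]` via
#' [stats::fisher.test()].  Direction agreement is reported but does not
#' enter the test.
#'
#' @param set_a,set_b character vectors of significant gene ids.
#' @param universe_size size of the common gene universe.
#' @param directions_a,directions_b optional named vectors (gene id ->
#'   +1/-1) used for the same-direction count.
#' @return list of class `overlap_result`: `n_universe`, `n_a`, `n_b`,
#'   `n_overlap`, `n_same_direction`, `fisher_p`, `odds_ratio`,
#'   `expected_overlap` (hypergeometric mean), `table` (the 2x2 matrix).
#' @export
overlap_analysis <- function(set_a, set_b, universe_size,
                             directions_a = NULL, directions_b = NULL) {
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  n_union <- length(union(set_a, set_b))
  if (universe_size < n_union) {
    stop("universe (", universe_size, ") smaller than |A union B| (", n_union, ")")
  }
  ab <- intersect(set_a, set_b)
  n_same <- if (!is.null(directions_a) && !is.null(directions_b) && length(ab)) {
    sum(directions_a[ab] == directions_b[ab], na.rm = TRUE)
  } else NA_integer_
  tab <- matrix(c(length(ab), length(set_a) - length(ab),
                  length(set_b) - length(ab),
                  universe_size - n_union),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("in_a", "not_a"), c("in_b", "not_b")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  structure(list(n_universe = universe_size,
                 n_a = length(set_a), n_b = length(set_b),
                 n_overlap = length(ab), n_same_direction = n_same,
                 fisher_p = ft$p.value,
                 odds_ratio = unname(ft$estimate),
                 expected_overlap = length(set_a) * length(set_b) / universe_size,
                 table = tab),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap:", x$n_overlap, "of", x$n_a, "x", x$n_b,
      "significant genes (universe", x$n_universe, ")\n")
  cat("  expected by chance:", signif(x$expected_overlap, 3),
      "; same direction:", x$n_same_direction, "\n")
  cat("  Fisher exact (one-sided enrichment) p =", format(x$fisher_p, digits = 3),
      ", odds ratio =", signif(x$odds_ratio, 4), "\n")
  invisible(x)
}

#' Relative qPCR expression by the 2^(delta Cp) method
#'
#' For every sample, `delta Cp = Cp_reference - Cp_target` and relative
#' expression `2^(delta Cp)`: a target amplifying one cycle earlier than
#' the reference carries two-fold more transcript.  Expression normalized
#' to the control-group mean is reported alongside the raw values when a
#' control group is named.  Group pairs are compared with two-sided
#' t-tests.
#'
#' @param qpcr data.frame with columns `sample`, `group`, `gene`, `Cp`
#'   (e.g. from [make_qpcr()]).
#' @param target,reference gene names; every sample must have a reference
#'   well (samples without one are dropped and counted).
#' @param control_group optional group name used to normalize expression.
#' @param var_equal pooled-variance t-tests (default) or Welch.
#' @return list with `table` (per-sample `delta_cp`, `rel_expr`, and
#'   `rel_expr_norm` when normalized), `tests` (pairwise t-tests on
#'   `rel_expr`), `n_dropped`.
#' @export
qpcr_relative <- function(qpcr, target = attr(qpcr, "target") %||% "tp53",
                          reference = attr(qpcr, "reference") %||% "eef1a1l1",
                          control_group = NULL, var_equal = TRUE) {
  stopifnot(all(c("sample", "group", "gene", "Cp") %in% names(qpcr)),
            all(qpcr$Cp > 0))
  tgt <- qpcr[qpcr$gene == target, c("sample", "group", "Cp")]
  ref <- qpcr[qpcr$gene == reference, c("sample", "Cp")]
  names(tgt)[3] <- "cp_target"; names(ref)[2] <- "cp_reference"
  tab <- merge(tgt, ref, by = "sample")
  n_dropped <- nrow(tgt) - nrow(tab)
  if (nrow(tab) == 0) stop("no sample carries both target and reference wells")
  tab$delta_cp <- tab$cp_reference - tab$cp_target
  tab$rel_expr <- 2^tab$delta_cp
  if (!is.null(control_group)) {
    ctl_mean <- mean(tab$rel_expr[tab$group == control_group])
    tab$rel_expr_norm <- tab$rel_expr / ctl_mean
  }
  g <- factor(tab$group)
  tests <- NULL
  if (nlevels(g) >= 2) {
    pairs <- utils::combn(levels(g), 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      sel <- tab$group %in% c(a, b)
      tt <- stats::t.test(tab$rel_expr[sel] ~ droplevels(g[sel]),
                          var.equal = var_equal)
      data.frame(group1 = a, group2 = b, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(table = tab, tests = tests, n_dropped = n_dropped)
}
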