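# Stack a list of congruent 3D maps into a subjects x voxels matrix.
stack_maps <- function(maps) {
  maps <- lapply(maps, function(m) if (inherits(m, "ljd_map")) m$values else m)
  d <- dim(maps[[1]])
  for (m in maps) stopifnot(identical(dim(m), d))
  Y <- do.call(rbind, lapply(maps, as.vector))
  list(Y = Y, dim = d)
}

stat_map <- function(statistic, pvalue, df, kind, dim3, extra = list()) {
  structure(c(list(statistic = array(statistic, dim3),
                   pvalue = array(pvalue, dim3),
                   df = df, kind = kind), extra),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("stat_map (", x$kind, "): ", paste(dim(x$pvalue), collapse = " x "),
      " voxels, df = ", paste(x$df, collapse = ", "),
      ", min p = ", signif(min(x$pvalue), 3), "\n", sep = "")
  invisible(x)
}

#' Voxelwise two-group t-test
#'
#' At every voxel, a two-sided two-sample t-test between the two groups of
#' subject maps (LJD or intensity).  The default is the pooled-variance
#' Student test; set `var_equal = FALSE` for Welch.  Voxels outside
#' `brain_mask` are set to `p = 1`, `t = 0`.  Voxels where both groups have
#' zero variance are set to `p = 1` and counted in the returned
#' `n_zero_variance`.
#'
#' @param maps list of congruent 3D arrays (or `ljd_map`s), one per subject.
#' @param groups vector of group labels, exactly two levels, >= 2 subjects
#'   per group.
#' @param brain_mask optional logical 3D array restricting the test.
#' @param var_equal pooled-variance Student test (`TRUE`, default) or Welch.
#' @return a `stat_map` with `statistic` (t), `pvalue`, `df` (scalar for
#'   Student; voxelwise Welch df are summarized by their range in `df`),
#'   `kind`, and `n_zero_variance`.
#' @export
voxelwise_two_group <- function(maps, groups, brain_mask = NULL,
                                var_equal = TRUE) {
  groups <- as.factor(groups)
  stopifnot(length(maps) == length(groups), nlevels(groups) == 2,
            all(table(groups) >= 2))
  st <- stack_maps(maps)
  Y <- st$Y
  i1 <- groups == levels(groups)[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  m1 <- colMeans(Y[i1, , drop = FALSE]); m2 <- colMeans(Y[!i1, , drop = FALSE])
  v1 <- colSums(sweep(Y[i1, , drop = FALSE], 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(Y[!i1, , drop = FALSE], 2, m2)^2) / (n2 - 1)
  zero_var <- v1 <= 0 & v2 <= 0
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    tt <- ifelse(se > 0, (m1 - m2) / se, 0)
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  } else {
    se2 <- v1 / n1 + v2 / n2
    tt <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 n1 + n2 - 2)
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  }
  tt[zero_var] <- 0
  p[zero_var] <- 1
  if (!is.null(brain_mask)) {
    out <- !as.vector(brain_mask)
    tt[out] <- 0
    p[out] <- 1
  }
  stat_map(tt, p, if (var_equal) df else range(df), "t_two_group", st$dim,
           extra = list(n_zero_variance = sum(zero_var),
                        groups = levels(groups)))
}

#' Voxelwise two-way ANOVA (genotype main effect, additive model)
#'
#' At every voxel, fits the additive linear model
#' `y ~ genotype + batch` (no interaction) and reports the genotype main
#' effect as a Type II F statistic: the reduction in residual sum of
#' squares when genotype is added to the batch-only model, divided by the
#' full-model residual mean square.  For balanced designs this coincides
#' with the classical two-way ANOVA table; for unbalanced designs it is
#' the standard Type II test of the genotype main effect while controlling
#' for batch.  Used to combine two crispant experiments into one voxelwise
#' map.
#'
#' With a single batch level the model degenerates gracefully to the
#' one-way ANOVA on genotype.
#'
#' @param maps list of congruent 3D arrays (or `ljd_map`s), one per subject.
#' @param genotype factor with >= 2 levels; every (genotype, batch) cell
#'   must be non-empty.
#' @param batch batch factor.
#' @param brain_mask optional logical 3D array; outside voxels get `p = 1`.
#' @return a `stat_map` with `statistic` (F for genotype), `pvalue`,
#'   `df = c(df_genotype, df_residual)` and `n_zero_variance`.
#' @export
voxelwise_two_way_anova <- function(maps, genotype, batch, brain_mask = NULL) {
  genotype <- as.factor(genotype); batch <- as.factor(batch)
  stopifnot(length(maps) == length(genotype), length(maps) == length(batch),
            nlevels(genotype) >= 2)
  cells <- table(genotype, batch)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: genotype '", levels(genotype)[bad[1]],
         "' x batch '", levels(batch)[bad[2]], "'")
  }
  st <- stack_maps(maps)
  Y <- st$Y
  n <- nrow(Y)
  X_full <- if (nlevels(batch) > 1) stats::model.matrix(~ genotype + batch)
            else stats::model.matrix(~ genotype)
  X_red <- if (nlevels(batch) > 1) stats::model.matrix(~ batch)
           else matrix(1, n, 1)
  resid_op <- function(X) diag(n) - X %*% solve(crossprod(X), t(X))
  rss <- function(M) colSums((M %*% Y)^2)
  rss_full <- rss(resid_op(X_full))
  rss_red <- rss(resid_op(X_red))
  df1 <- nlevels(genotype) - 1
  df2 <- n - qr(X_full)$rank
  ss_g <- pmax(rss_red - rss_full, 0)
  # voxels where even the reduced model fits perfectly carry no variance
  zero_var <- rss_red <= 1e-18 * pmax(colSums(Y^2), 1)
  Fstat <- ifelse(rss_full > 0, (ss_g / df1) / (rss_full / df2), Inf)
  Fstat[zero_var] <- 0
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  p[zero_var] <- 1
  if (!is.null(brain_mask)) {
    out <- !as.vector(brain_mask)
    Fstat[out] <- 0
    p[out] <- 1
  }
  stat_map(Fstat, p, c(df1, df2), "F_genotype", st$dim,
           extra = list(n_zero_variance = sum(zero_var)))
}
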