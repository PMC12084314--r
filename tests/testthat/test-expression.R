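# Exhaustive enumeration oracle for the one-sided overlap test: with |A|
# fixed, draw every size-|B| subset of the universe and count overlaps.
enumerate_overlap_tail <- function(universe, n_a, n_b, k_obs) {
  sets <- utils::combn(universe, n_b)
  overlaps <- colSums(sets <= n_a)  # A = {1, ..., n_a}
  mean(overlaps >= k_obs)
}

test_that("base-mean filtering is strict, two-sided, and matches brute force", {
  a <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  baseMean = c(99, 100, 500, 40),
                  log2FC = 0, pvalue = 0.5)
  b <- data.frame(gene_id = c("g1", "g2", "g3", "g5"),
                  baseMean = c(500, 100, 99, 40),
                  log2FC = 0, pvalue = 0.5)
  m <- filter_genes(a, b)
  expect_equal(m$gene_id, "g2")  # g1 fails in A, g3 fails in B, boundary kept
  expect_equal(attr(m, "n_universe"), 1)
  set.seed(20)
  ra <- data.frame(gene_id = sprintf("g%03d", 1:300),
                   baseMean = rlnorm(300, 5, 1), log2FC = 0, pvalue = 0.5)
  rb <- data.frame(gene_id = sprintf("g%03d", 1:300),
                   baseMean = rlnorm(300, 5, 1), log2FC = 0, pvalue = 0.5)
  m2 <- filter_genes(ra, rb, min_base_mean = 120)
  brute <- sum(ra$baseMean >= 120 & rb$baseMean >= 120)
  expect_equal(nrow(m2), brute)
  expect_error(filter_genes(ra, data.frame(gene_id = "zz", baseMean = 1,
                                           log2FC = 0, pvalue = 0.5)),
               "share no gene ids")
})

test_that("BH adjustment reproduces the hand-computed step-up and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(5)
  p <- runif(200)^2
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # adjustment preserves the significance ranking of the raw p-values
  expect_true(all(diff(q[order(p)]) >= 0))
  perm <- sample(200)
  expect_equal(bh_fdr(p[perm]), q[perm])  # order-equivariant
})

test_that("significance is strict at the FDR threshold and carries direction", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2FC = c(2, -1, 0, 1),
                    padj = c(0.05, 0.099, 0.0999, 0.1))
  sig <- significant_genes(tab, fdr_alpha = 0.1)
  expect_setequal(sig$gene_id, c("a", "b", "c"))  # 0.1 itself excluded
  expect_equal(sig$direction[sig$gene_id == "a"], 1)
  expect_equal(sig$direction[sig$gene_id == "b"], -1)
  expect_equal(attr(sig, "n_zero_direction"), 1)
})

test_that("overlap counts and Fisher p match exhaustive enumeration", {
  # worked example: universe 10, |A| = 4, |B| = 5, all of B's overlap = 4
  ov <- overlap_analysis(paste0("g", 1:4), paste0("g", c(1:4, 9)), 10)
  expect_equal(ov$n_overlap, 4)
  expect_equal(ov$fisher_p, 6 / 252, tolerance = 1e-12)
  expect_equal(ov$fisher_p, enumerate_overlap_tail(10, 4, 5, 4), tolerance = 1e-12)
  # random small configurations against the enumeration oracle
  set.seed(30)
  for (rep in 1:10) {
    U <- sample(6:12, 1)
    n_a <- sample(U - 1, 1); n_b <- sample(U - 1, 1)
    ids <- paste0("g", seq_len(U))
    A <- ids[seq_len(n_a)]
    B <- sample(ids, n_b)
    ov <- overlap_analysis(A, B, U)
    expect_equal(ov$n_overlap, length(intersect(A, B)))
    expect_equal(ov$fisher_p,
                 enumerate_overlap_tail(U, n_a, n_b, ov$n_overlap),
                 tolerance = 1e-12)
    expect_lte(ov$n_overlap, min(ov$n_a, ov$n_b))
  }
  expect_error(overlap_analysis(paste0("g", 1:5), paste0("g", 6:9), 8),
               "universe")
  # empty sets: overlap 0, p = 1
  ov0 <- overlap_analysis(character(0), character(0), 100)
  expect_equal(ov0$n_overlap, 0)
  expect_equal(ov0$fisher_p, 1)
})

test_that("study-scale overlap counts give massive enrichment over chance", {
  ids <- sprintf("g%05d", 1:17629)
  A <- ids[1:125]
  B <- ids[c(1:31, 200:1010)]  # 842 genes, 31 shared
  ov <- overlap_analysis(A, B, 17629)
  expect_equal(ov$n_overlap, 31)
  expect_equal(ov$expected_overlap, 125 * 842 / 17629, tolerance = 1e-12)
  expect_lt(ov$fisher_p, 1e-10)
  expect_gt(ov$n_overlap, 4 * ov$expected_overlap)
})

test_that("same-direction counting uses the direction tags", {
  dirs_a <- c(g1 = 1, g2 = -1, g3 = 1)
  dirs_b <- c(g1 = 1, g2 = 1, g3 = 1)
  ov <- overlap_analysis(names(dirs_a), names(dirs_b), 50,
                         directions_a = dirs_a, directions_b = dirs_b)
  expect_equal(ov$n_overlap, 3)
  expect_equal(ov$n_same_direction, 2)
})

test_that("planted shared signal drives the overlap p-value down", {
  med_p <- vapply(c(0, 10, 30), function(k) {
    ps <- vapply(1:5, function(s) {
      gt <- make_gene_tables(n_genes = 3000, n_true_shared = k,
                             n_true_private = c(20, 30), seed = 100 + s)
      joined <- filter_genes(gt$a, gt$b, min_base_mean = 0)
      sa <- significant_genes(data.frame(gene_id = joined$gene_id,
                                         log2FC = joined$log2FC_a,
                                         pvalue = joined$pvalue_a))
      sb <- significant_genes(data.frame(gene_id = joined$gene_id,
                                         log2FC = joined$log2FC_b,
                                         pvalue = joined$pvalue_b))
      overlap_analysis(sa$gene_id, sb$gene_id, nrow(joined))$fisher_p
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_true(all(diff(med_p) < 0))
  expect_lt(med_p[3], 1e-6)
})

test_that("relative qPCR expression follows the 2^(delta Cp) rule", {
  q <- data.frame(sample = rep(c("s1", "s2", "s3"), each = 2),
                  group = rep(c("ctl", "ctl", "xrcc"), each = 2),
                  gene = rep(c("eef1a1l1", "tp53"), 3),
                  Cp = c(18, 18,    # equal -> fold 1
                         18, 17,    # target one cycle earlier -> fold 2
                         18, 16.5))
  res <- qpcr_relative(q, "tp53", "eef1a1l1")
  expect_equal(res$table$rel_expr[res$table$sample == "s1"], 1)
  expect_equal(res$table$rel_expr[res$table$sample == "s2"], 2)
  expect_equal(res$table$rel_expr[res$table$sample == "s3"], 2^1.5)
  # a sample missing its reference well is dropped and counted
  q_missing <- rbind(q, data.frame(sample = "s4", group = "xrcc",
                                   gene = "tp53", Cp = 15))
  res2 <- qpcr_relative(q_missing, "tp53", "eef1a1l1")
  expect_equal(res2$n_dropped, 1)
  expect_false("s4" %in% res2$table$sample)
  # group tests match a direct t-test
  plate <- make_qpcr(groups = c(ctl = 4L, xrcc = 4L),
                     true_fold_change = c(ctl = 1, xrcc = 2), sd = 0.2,
                     seed = 2)
  res3 <- qpcr_relative(plate, control_group = "ctl")
  tt <- t.test(rel_expr ~ group, data = res3$table, var.equal = TRUE)
  expect_equal(res3$tests$p, tt$p.value, tolerance = 1e-12)
  expect_equal(mean(res3$table$rel_expr_norm[res3$table$group == "ctl"]), 1)
})
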