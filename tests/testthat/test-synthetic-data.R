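test_that("null subject with zero amplitude is the identity with atlas volumes", {
  atl <- TINY_ATLAS
  des <- tiny_design(two_group_rows(), amplitude = 0)
  s <- make_subject(atl, "ctl", contraction = 1, design = des, seed = 3,
                    channels = FALSE, compute_truth = TRUE)
  expect_true(all(s$field$u == 0))
  voxvol <- prod(atl$spacing)
  for (id in names(atl$names)) {
    expect_equal(s$truth$division_volumes[[atl$names[[id]]]],
                 sum(atl$labels == as.integer(id)) * voxvol, tolerance = 1e-12)
  }
})

test_that("pure contraction yields the closed-form s^3 volume ratio over the LCeP", {
  atl <- TINY_ATLAS
  des <- tiny_design(two_group_rows(), amplitude = 0)
  s <- make_subject(atl, "xrcc", contraction = 0.9, design = des, seed = 1,
                    channels = FALSE)
  lcep <- atlas_mask(atl, "lcep")
  ratio <- warp_volume_oracle(s$field, lcep) / (sum(lcep) * prod(atl$spacing))
  expect_equal(ratio, 0.9^3, tolerance = 1e-10)
  # truth records the analytic ratio and a mirror-symmetric effect region
  expect_equal(s$truth$expected_effect_ratio, 0.729)
  er <- s$truth$effect_region
  expect_identical(mirror_volume(er, atl$mirror_axis, atl$mirror_plane), er)
  expect_true(all(er[lcep]))
  expect_true(all(atlas_mask(atl, "brain")[er]))
})

test_that("generated fields are orientation-preserving across seeds and contractions", {
  atl <- TINY_ATLAS
  des <- tiny_design(two_group_rows())
  for (seed in 1:4) {
    for (contr in c(1, 0.9, 0.8)) {
      s <- make_subject(atl, "x", contraction = contr, design = des,
                        seed = seed, channels = FALSE)
      detj <- exp(log_jacobian(s$field)$values)
      expect_gt(min(detj), 0)
    }
  }
})

test_that("subject and cohort generation are pure functions of the seed", {
  atl <- TINY_ATLAS
  des <- tiny_design(two_group_rows(n1 = 2L, n2 = 2L), seed = 9)
  s1 <- make_subject(atl, "xrcc", contraction = 0.9, design = des, seed = 77)
  s2 <- make_subject(atl, "xrcc", contraction = 0.9, design = des, seed = 77)
  expect_identical(s1$field$u, s2$field$u)
  expect_identical(s1$channels, s2$channels)
  c1 <- make_cohort(des, atl)
  c2 <- make_cohort(des, atl)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$subjects[[4]]$field$u, c2$subjects[[4]]$field$u)
  # different subjects get different fields
  expect_false(identical(c1$subjects[[1]]$field$u, c1$subjects[[2]]$field$u))
})

test_that("trace generator records normalized truth and exact peak areas", {
  tr <- make_trace(wt_fraction = 0.3, indel_sizes = c(185, 210),
                   indel_areas = c(0.5, 0.2), noise_sd = 0, seed = 2)
  truth <- attr(tr, "truth")
  expect_equal(sum(truth$fraction), 1)
  # noiseless trace: integral over each peak window matches the stated area
  total_area <- 1e4
  for (i in seq_len(nrow(truth))) {
    win <- abs(tr$size_bp - truth$size_bp[i]) <= 6
    area <- trapz_manual(tr$size_bp[win], tr$rfu[win] - 5)  # baseline = 5
    expect_equal(area, total_area * truth$fraction[i], tolerance = 0.01)
  }
  # pure wildtype: a single peak at the expected size
  tr1 <- make_trace(wt_fraction = 1, wt_size_bp = 250, noise_sd = 0)
  expect_equal(attr(tr1, "truth")$fraction, 1)
  expect_equal(tr1$size_bp[which.max(tr1$rfu)], 250, tolerance = 0.3)
  # unresolvable peaks are flagged
  expect_true(attr(make_trace(0.5, 200, 201, 1, seed = 1), "overlap_warning"))
  expect_error(make_trace(0.5, 200), "indel peak")
})

test_that("null gene tables carry uniform p-values; planted genes are concordant", {
  gt <- make_gene_tables(n_genes = 4000, n_true_shared = 0,
                         n_true_private = c(0, 0), seed = 5)
  frac <- mean(gt$a$pvalue < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
  gt2 <- make_gene_tables(n_genes = 2000, n_true_shared = 25,
                          n_true_private = c(30, 40), seed = 8)
  shared <- gt2$truth$gene_id[gt2$truth$direction != 0]
  ia <- match(shared, gt2$a$gene_id); ib <- match(shared, gt2$b$gene_id)
  expect_true(all(sign(gt2$a$log2FC[ia]) == sign(gt2$b$log2FC[ib])))
  expect_identical(make_gene_tables(n_genes = 500, seed = 3, n_true_shared = 5,
                                    n_true_private = c(5, 5))$a,
                   make_gene_tables(n_genes = 500, seed = 3, n_true_shared = 5,
                                    n_true_private = c(5, 5))$a)
})

test_that("qPCR generator encodes fold changes as Cp shifts", {
  q0 <- make_qpcr(groups = c(ctl = 3L), true_fold_change = c(ctl = 1), sd = 0)
  cp <- reshape(q0, direction = "wide", idvar = "sample", timevar = "gene",
                v.names = "Cp")
  expect_equal(cp$Cp.tp53, cp$Cp.eef1a1l1)
  q2 <- make_qpcr(groups = c(a = 4L), true_fold_change = c(a = 2), sd = 0)
  dcp <- q2$Cp[q2$gene == "eef1a1l1"] - q2$Cp[q2$gene == "tp53"]
  expect_equal(dcp, rep(1, 4))
  # noisy plate: recovered fold within 3 sd sqrt(2/n) on the log2 scale
  n <- 5L; sdv <- 0.2
  q <- make_qpcr(groups = c(a = n), true_fold_change = c(a = 1.5), sd = sdv,
                 seed = 11)
  rel <- qpcr_relative(q, target = "tp53", reference = "eef1a1l1")
  expect_lt(abs(mean(rel$table$delta_cp) - log2(1.5)), 3 * sdv * sqrt(2 / n))
})
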