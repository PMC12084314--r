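test_that("identity field gives an exactly zero LJD map", {
  f <- identity_field(c(8, 9, 10), spacing = c(1, 2, 3))
  expect_true(all(log_jacobian(f)$values == 0))
})

test_that("uniform linear scale gives LJD = 3 ln s everywhere", {
  s <- 0.9
  f <- uniform_scale_field(c(12, 12, 12), c(2, 2, 2), s)
  ljd <- log_jacobian(f)
  # finite differences are exact for affine maps, including the one-sided
  # boundary stencils
  expect_equal(max(abs(ljd$values - 3 * log(s))), 0, tolerance = 1e-6)
})

test_that("folded fields are rejected with a diagnostic", {
  f <- identity_field(c(8, 8, 8), spacing = c(1, 1, 1))
  # gradient of -2 along x => 1 + du/dx < 0
  f$u[, , , 1] <- -2 * (coord_arrays(c(8, 8, 8))$x - 1)
  expect_error(log_jacobian(f), "folded")
})

test_that("composing a uniform scale adds 3 ln s to the LJD", {
  atl <- TINY_ATLAS
  des <- tiny_design(two_group_rows())
  sub <- make_subject(atl, "ctl", contraction = 1, design = des, seed = 21,
                      channels = FALSE)
  base <- log_jacobian(displacement_field(sub$field$u, atl$spacing))
  s <- 0.95
  cc <- coord_arrays(dim(atl$labels))
  pos <- array(0, dim(sub$field$u))
  pos[, , , 1] <- (cc$x - 1) * atl$spacing[1]
  pos[, , , 2] <- (cc$y - 1) * atl$spacing[2]
  pos[, , , 3] <- (cc$z - 1) * atl$spacing[3]
  # phi'(x) = s * phi(x): u' = s(x + u) - x
  scaled <- displacement_field((s - 1) * pos + s * sub$field$u, atl$spacing)
  comp <- log_jacobian(scaled)
  expect_equal(comp$values, base$values + 3 * log(s), tolerance = 1e-8)
})

test_that("exp(LJD) integral agrees with the dense-lattice geometric oracle", {
  atl <- TINY_ATLAS
  des <- tiny_design(two_group_rows())
  sub <- make_subject(atl, "xrcc", contraction = 0.9, design = des, seed = 5,
                      channels = FALSE)
  ljd <- log_jacobian(sub$field)
  brain <- atlas_mask(atl, "brain")
  vol_ljd <- region_volume(ljd, brain)$volume
  vol_oracle <- warp_volume_oracle(sub$field, brain, refine = 2)
  expect_lt(abs(vol_ljd - vol_oracle) / vol_oracle, 0.01)
})

test_that("region volumes and percentages behave on the identity field", {
  atl <- TINY_ATLAS
  f <- identity_field(dim(atl$labels), atl$spacing)
  ljd <- log_jacobian(f)
  brain <- atlas_mask(atl, "brain")
  lcep <- atlas_mask(atl, "lcep")
  rv <- region_volume(ljd, lcep, brain)
  expect_equal(rv$volume, sum(lcep) * prod(atl$spacing))
  expect_equal(rv$percent, 100 * sum(lcep) / sum(brain))
  expect_error(region_volume(ljd, array(FALSE, dim(brain))), "empty")
})

test_that("division statistics report exact intensities and closed percentages", {
  atl <- TINY_ATLAS
  des <- tiny_design(two_group_rows(n1 = 2L, n2 = 2L), seed = 4)
  cohort <- make_cohort(des, atl, channels = TRUE)
  # overwrite one channel with a constant to pin the mean
  for (sid in names(cohort$subjects)) {
    cohort$subjects[[sid]]$channels$pan_mcar[] <- 123
  }
  ds <- division_stats(cohort, atl)
  expect_true(all(ds$mean_pan_mcar == 123))
  # the six division labels partition the brain: percentages sum to 100
  tot <- tapply(ds$volume_pct, ds$id, sum)
  expect_equal(as.vector(tot), rep(100, length(tot)), tolerance = 1e-9)
})

test_that("division-level group tests are calibrated on null cohorts", {
  atl <- TINY_ATLAS
  pvals <- c()
  for (seed in 1:8) {
    des <- tiny_design(data.frame(genotype = c("a", "b"), batch = "b1",
                                  n = 4L, contraction = 1), seed = seed)
    cohort <- make_cohort(des, atl)
    ds <- division_stats(cohort, atl)
    for (dv in unique(ds$division)) {
      d <- ds[ds$division == dv, ]
      pvals <- c(pvals, t.test(volume_pct ~ genotype, data = d,
                               var.equal = TRUE)$p.value)
    }
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
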