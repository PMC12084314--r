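fake_stat <- function(p) {
  structure(list(pvalue = p, statistic = 0 * p, kind = "t_two_group", df = 1),
            class = "stat_map")
}

# canonical labeling: each component tagged by its smallest linear index
canon <- function(lab) {
  out <- array(0L, dim(lab))
  for (k in unique(lab[lab > 0])) {
    vox <- which(lab == k)
    out[vox] <- min(vox)
  }
  out
}

test_that("connected-component labeling matches a flood-fill oracle", {
  set.seed(10)
  for (rep in 1:4) {
    mask <- array(runif(8^3) < 0.35, c(8, 8, 8))
    for (conn in c(26, 6)) {
      expect_identical(canon(label_components(mask, conn)),
                       canon(bfs_components(mask, conn)))
    }
  }
  # diagonal voxels: one component under 26-connectivity, two under 6
  m <- array(FALSE, c(4, 4, 4)); m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  expect_equal(max(label_components(m, 26)), 1)
  expect_equal(max(label_components(m, 6)), 2)
})

test_that("an all-nonsignificant map yields an empty ROI", {
  atl <- TINY_ATLAS
  roi <- filter_significance(fake_stat(array(1, dim(atl$labels))), atlas = atl)
  expect_equal(roi$n_voxels, 0)
  expect_false(any(roi$mask))
})

test_that("only mirror-symmetric clusters of sufficient extent survive", {
  atl <- TINY_ATLAS
  p <- array(1, dim(atl$labels))
  sym_l <- list(x = 9:11, y = 14:16, z = 14:16)
  sym_r <- list(x = 22:24, y = 14:16, z = 14:16)  # mirror of 9:11 about 16.5
  asym <- list(x = 9:11, y = 19:21, z = 19:21)
  p[sym_l$x, sym_l$y, sym_l$z] <- 0.001
  p[sym_r$x, sym_r$y, sym_r$z] <- 0.001
  p[asym$x, asym$y, asym$z] <- 0.001
  roi <- filter_significance(fake_stat(p), alpha = 0.01, min_cluster = 20,
                             symmetric = TRUE, atlas = atl)
  expect_equal(roi$n_voxels, 54)  # the symmetric pair only (2 x 27)
  expect_true(all(roi$mask[sym_l$x, sym_l$y, sym_l$z]))
  expect_true(all(roi$mask[sym_r$x, sym_r$y, sym_r$z]))
  expect_false(any(roi$mask[asym$x, asym$y, asym$z]))
  # the surviving mask is itself mirror-symmetric
  expect_identical(mirror_volume(roi$mask, atl$mirror_axis, atl$mirror_plane),
                   roi$mask)
  # raising the cluster minimum above 27 clears everything
  roi2 <- filter_significance(fake_stat(p), alpha = 0.01, min_cluster = 28,
                              symmetric = TRUE, atlas = atl)
  expect_equal(roi2$n_voxels, 0)
  # without the symmetry rule the asymmetric cluster survives too
  roi3 <- filter_significance(fake_stat(p), alpha = 0.01, min_cluster = 20,
                              symmetric = FALSE, atlas = atl)
  expect_equal(roi3$n_voxels, 81)
})

test_that("a tolerance radius admits approximately mirror-symmetric voxels", {
  atl <- TINY_ATLAS
  p <- array(1, dim(atl$labels))
  p[9:11, 14:16, 14:16] <- 0.001
  p[22:24, 15:17, 14:16] <- 0.001  # mirror partner shifted by 1 voxel in y
  strict <- filter_significance(fake_stat(p), min_cluster = 1, symmetric = TRUE,
                                atlas = atl, tol = 0)
  loose <- filter_significance(fake_stat(p), min_cluster = 1, symmetric = TRUE,
                               atlas = atl, tol = 1)
  expect_lt(strict$n_voxels, loose$n_voxels)
  expect_equal(loose$n_voxels, 54)
})

test_that("filter settings are recorded in provenance with study defaults", {
  atl <- TINY_ATLAS
  roi <- filter_significance(fake_stat(array(1, dim(atl$labels))), atlas = atl)
  expect_equal(roi$provenance$alpha, 0.01)
  expect_equal(roi$provenance$min_cluster, 50)
  expect_true(roi$provenance$symmetric)
  expect_equal(roi$provenance$connectivity, 26)
})
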