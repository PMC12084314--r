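#' Cohort simulation design
#'
#' Collects the parameters of a simulated registered-brain cohort: group
#' structure (genotype, experiment batch, group size, programmed LCeP
#' contraction), grid geometry, and the amplitude/correlation length of the
#' random background deformation that emulates residual registration
#' variability.
#'
#' Defaults emulate a two-group crispant imaging experiment: 14 controls vs
#' 14 crispants carrying a 10% linear contraction (`contraction = 0.9`,
#' i.e. a `0.9^3 ~ 0.73` volume ratio) of the lateral cerebellar plate, on
#' a 48^3 grid at 2 um isotropic spacing.  The background deformation has
#' an 8 um Gaussian correlation length and 0.8 um per-component amplitude,
#' small relative to the programmed effect so that residual registration
#' noise does not dominate a 10% volume phenotype, and well inside the
#' regime where `det grad phi > 0` is guaranteed.
#'
#' @param groups data.frame with columns `genotype`, `batch`, `n`,
#'   `contraction` (linear scale factor in (0, 1], 1 = unaffected).
#' @param shape,spacing atlas grid dimensions and voxel size (um).
#' @param smoothness Gaussian correlation length of the background
#'   deformation, um.
#' @param amplitude per-component standard deviation of the background
#'   displacement, um; 0 disables the background field.
#' @param channel_noise_sd standard deviation of the smooth intensity noise
#'   added to each fluorescence channel (arbitrary units).
#' @param seed master seed; per-subject seeds are derived deterministically.
#' @return object of class `cohort_design` (a list).
#' @export
cohort_design <- function(groups = data.frame(
                            genotype = c("ctl", "xrcc"),
                            batch = "b1",
                            n = c(14L, 14L),
                            contraction = c(1, 0.9)),
                          shape = c(48, 48, 48), spacing = c(2, 2, 2),
                          smoothness = 8, amplitude = 0.8,
                          channel_noise_sd = 30, seed = 1L) {
  stopifnot(all(c("genotype", "batch", "n", "contraction") %in% names(groups)),
            all(groups$n >= 2), all(groups$contraction > 0),
            all(groups$contraction <= 1))
  structure(list(groups = groups, shape = as.integer(shape),
                 spacing = as.numeric(spacing), smoothness = smoothness,
                 amplitude = amplitude, channel_noise_sd = channel_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

# Per-division baseline intensities for the three fluorescence channels
# (glutamatergic GFP, GABAergic RFP, pan-neuronal far-red), arbitrary units.
default_channel_means <- function() {
  m <- rbind(forebrain        = c(600, 300, 800),
             midbrain         = c(700, 250, 800),
             hindbrain        = c(500, 350, 800),
             cerebellar_plate = c(650, 200, 900),
             lcep_left        = c(650, 200, 900),
             lcep_right       = c(650, 200, 900))
  colnames(m) <- c("glut_gfp", "gaba_rfp", "pan_mcar")
  m
}

# Smooth random background displacement, per-component sd = amplitude (um).
background_field <- function(shape, spacing, smoothness, amplitude) {
  u <- array(0, c(shape, 3))
  if (amplitude <= 0) return(u)
  sigma_vox <- smoothness / spacing
  for (k in 1:3) {
    w <- gaussian_smooth_3d(array(stats::rnorm(prod(shape)), shape), sigma_vox)
    u[, , , k] <- w / stats::sd(w) * amplitude
  }
  u
}

# Displacement (um) of a radial contraction of linear scale s about each
# LCeP sphere centre: exact linear scaling out to the sphere radius plus a
# plateau margin (so every cell and interpolation stencil touching an
# effect-region voxel sees the pure linear map, making the s^3 volume
# ratio exact), then a raised-cosine falloff to the identity over a shell
# of width `falloff * radius`.
contraction_displacement <- function(atlas, contraction, falloff = 0.6,
                                     plateau_margin = 2) {
  shape <- dim(atlas$labels)
  u <- array(0, c(shape, 3))
  if (contraction == 1) return(u)
  cc <- coord_arrays(shape)
  R <- atlas$lcep$radius + plateau_margin
  w <- falloff * atlas$lcep$radius
  for (side in 1:2) {
    ctr <- atlas$lcep$centers[side, ]
    dx <- cc$x - ctr[1]; dy <- cc$y - ctr[2]; dz <- cc$z - ctr[3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    alpha <- ifelse(r <= R, 1,
                    ifelse(r >= R + w, 0, 0.5 * (1 + cos(pi * (r - R) / w))))
    fac <- (contraction - 1) * alpha
    u[, , , 1] <- u[, , , 1] + fac * dx * atlas$spacing[1]
    u[, , , 2] <- u[, , , 2] + fac * dy * atlas$spacing[2]
    u[, , , 3] <- u[, , , 3] + fac * dz * atlas$spacing[3]
  }
  u
}

# det(I + grad u) at every voxel; shared by the generator's invertibility
# check and by log_jacobian().
jacobian_determinant <- function(u, spacing) {
  g <- vector("list", 9)
  idx <- 1
  for (comp in 1:3) {
    for (ax in 1:3) {
      g[[idx]] <- diff_axis(u[, , , comp], ax) / spacing[ax]
      idx <- idx + 1
    }
  }
  a11 <- 1 + g[[1]]; a12 <- g[[2]]; a13 <- g[[3]]
  a21 <- g[[4]]; a22 <- 1 + g[[5]]; a23 <- g[[6]]
  a31 <- g[[7]]; a32 <- g[[8]]; a33 <- 1 + g[[9]]
  a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

#' Ground-truth effect region of the programmed contraction
#'
#' The set of brain voxels at which an affected subject's contraction
#' applies at full linear scale: the LCeP spheres extended by the plateau
#' margin of [make_subject()]'s contraction field, intersected with the
#' brain mask.  Mirror-symmetric by construction.  This is the target
#' region against which a discovered ROI is scored (e.g. by [dice()]).
#'
#' @param atlas a [make_atlas()] atlas.
#' @param plateau_margin margin in voxels (must match the generator's;
#'   default 2).
#' @return logical 3D array.
#' @export
effect_region_mask <- function(atlas, plateau_margin = 2) {
  shape <- dim(atlas$labels)
  cc <- coord_arrays(shape)
  R <- atlas$lcep$radius + plateau_margin
  m <- array(FALSE, shape)
  for (side in 1:2) {
    ctr <- atlas$lcep$centers[side, ]
    m <- m | ((cc$x - ctr[1])^2 + (cc$y - ctr[2])^2 + (cc$z - ctr[3])^2 <= R^2)
  }
  m & atlas_mask(atlas, "brain")
}

#' Simulate one registered subject
#'
#' Generates the post-registration representation of one subject: an
#' atlas-to-subject displacement field (smooth random background
#' deformation plus, for affected genotypes, a localized radial contraction
#' of the LCeP spheres) and atlas-space fluorescence channels, together
#' with ground truth for parameter-recovery testing.
#'
#' Over the labeled LCeP spheres the contraction is an exact linear scale
#' `s = contraction` (the full-scale plateau extends a 2-voxel margin
#' beyond them, see [effect_region_mask()]), so the true subject/atlas
#' volume ratio of the LCeP region is exactly `s^3` when the background
#' amplitude is zero.  The generated
#' field is checked to be orientation preserving (`det grad phi > 0`
#' everywhere); if the check fails the background is regenerated with 30%
#' lower amplitude, up to `max_attempts` times, and the number of attempts
#' is recorded in the returned ground truth.
#'
#' @param atlas a [make_atlas()] atlas.
#' @param genotype,batch labels stored in the subject record.
#' @param contraction linear scale factor in (0, 1]; 1 = no effect.
#' @param design a [cohort_design()] (grid parameters must match the atlas).
#' @param seed integer seed for this subject.
#' @param channels generate fluorescence channels (set `FALSE` to save time
#'   in volume-only simulations).
#' @param compute_truth record per-division subject-space volumes via
#'   [warp_volume_oracle()]; the analytic effect-region ratio and the
#'   effect-region mask are always recorded.
#' @param refine oracle subdivision factor when `compute_truth = TRUE`.
#' @return list with `field` ([displacement_field()]), `channels` (named
#'   list of 3D arrays or `NULL`), `truth` (list: `effect_region`,
#'   `contraction`, `expected_effect_ratio`, `attempts`, and when computed
#'   `division_volumes`/`total_volume` in um^3), plus `genotype`, `batch`,
#'   `seed`.
#' @export
make_subject <- function(atlas, genotype = "ctl", batch = "b1", contraction = 1,
                         design = cohort_design(), seed = 1L,
                         channels = TRUE, compute_truth = FALSE, refine = 1L) {
  stopifnot(inherits(atlas, "label_atlas"), contraction > 0, contraction <= 1)
  shape <- dim(atlas$labels)
  sp <- atlas$spacing
  u_eff <- contraction_displacement(atlas, contraction)
  set.seed(seed)
  amplitude <- design$amplitude
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    u <- u_eff + background_field(shape, sp, design$smoothness, amplitude)
    detj <- jacobian_determinant(u, sp)
    if (min(detj) > 0) break
    if (attempts >= 5L) {
      stop("could not generate an orientation-preserving field in 5 attempts; ",
           "reduce the deformation amplitude")
    }
    warning("folded field (min det = ", signif(min(detj), 3),
            "); retrying with amplitude reduced to ", signif(amplitude * 0.7, 3))
    amplitude <- amplitude * 0.7
  }
  field <- displacement_field(u, sp)
  field$detj <- detj  # cache for log_jacobian(); same stencil either way

  chan <- NULL
  if (isTRUE(channels)) {
    cm <- default_channel_means()
    chan <- list()
    brain <- atlas$labels > 0L
    for (ch in colnames(cm)) {
      base <- array(20, shape)  # off-brain background level
      for (lab in seq_len(nrow(cm))) {
        base[atlas$labels == lab] <- cm[lab, ch]
      }
      noise <- gaussian_smooth_3d(array(stats::rnorm(prod(shape)), shape), 2)
      base <- base + noise / stats::sd(noise) * design$channel_noise_sd
      base[!brain & base < 0] <- 0
      chan[[ch]] <- base
    }
  }

  truth <- list(effect_region = effect_region_mask(atlas),
                contraction = contraction,
                expected_effect_ratio = contraction^3,
                attempts = attempts)
  if (isTRUE(compute_truth)) {
    vv <- warp_cell_volumes(field, refine)
    vols <- vapply(names(atlas$names), function(id) {
      sum(vv[atlas$labels == as.integer(id)])
    }, numeric(1))
    names(vols) <- atlas$names
    truth$division_volumes <- vols
    truth$total_volume <- sum(vv[atlas$labels > 0L])
  }
  list(field = field, channels = chan, truth = truth,
       genotype = genotype, batch = batch, seed = seed)
}

#' Simulate a registered cohort
#'
#' One subject per row-expansion of `design$groups`, with per-subject seeds
#' derived deterministically from the design's master seed, and a manifest
#' table recording id, genotype, batch, programmed contraction and seed.
#'
#' @param design a [cohort_design()].
#' @param atlas a [make_atlas()] atlas (built from `design` geometry if
#'   omitted).
#' @param channels,compute_truth,refine passed to [make_subject()].
#' @return object of class `cohort`: list with `subjects` (list as returned
#'   by [make_subject()]), `manifest` (data.frame), `design`, `atlas`.
#' @export
make_cohort <- function(design = cohort_design(), atlas = NULL,
                        channels = FALSE, compute_truth = FALSE, refine = 1L) {
  if (is.null(atlas)) atlas <- make_atlas(design$shape, design$spacing)
  g <- design$groups
  subjects <- list()
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(g$n[i])) {
      k <- k + 1L
      sid <- sprintf("%s_%s_%02d", g$genotype[i], g$batch[i], j)
      seed_k <- derive_seed(design$seed, k)
      subjects[[sid]] <- make_subject(atlas, genotype = g$genotype[i],
                                      batch = g$batch[i],
                                      contraction = g$contraction[i],
                                      design = design, seed = seed_k,
                                      channels = channels,
                                      compute_truth = compute_truth,
                                      refine = refine)
      rows[[k]] <- data.frame(id = sid, genotype = g$genotype[i],
                              batch = g$batch[i],
                              contraction = g$contraction[i], seed = seed_k,
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(subjects = subjects, manifest = do.call(rbind, rows),
                 design = design, atlas = atlas),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort of", length(x$subjects), "subjects:\n")
  print(table(genotype = x$manifest$genotype, batch = x$manifest$batch))
  invisible(x)
}

#' Log-Jacobian maps for every subject of a cohort
#'
#' @param cohort a [make_cohort()] cohort.
#' @return named list of [log_jacobian()] maps.
#' @export
cohort_ljd <- function(cohort) {
  lapply(cohort$subjects, function(s) log_jacobian(s$field))
}
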