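#' Build a mirror-symmetric labeled phantom brain atlas
#'
#' Constructs a synthetic stand-in for an annotated larval zebrafish brain
#' atlas: an ellipsoidal brain partitioned into divisions (forebrain,
#' midbrain, hindbrain, cerebellar plate) plus a pair of spherical lateral
#' cerebellar plate (LCeP) subregions placed homotopically on either side of
#' the midsagittal plane.  The label volume is exactly mirror-symmetric
#' about that plane: reflecting voxel indices maps every division onto
#' itself and LCeP-left onto LCeP-right.
#'
#' All geometry is parametric (ellipsoids and spheres scaled to the grid),
#' so division volumes are known by construction and the atlas is
#' deterministic; `seed` is accepted for interface symmetry with the other
#' generators but does not alter the labels.
#'
#' @param shape integer length-3 grid dimensions; each axis must be >= 32
#'   so that all divisions fit.
#' @param spacing numeric length-3 voxel size in micrometres.
#' @param seed integer; kept for a uniform generator interface.
#' @return An object of class `label_atlas`: list with `labels` (3D integer
#'   array, 0 = background), `names` (named character vector mapping label
#'   to division name), `spacing`, `mirror_axis` (1 = left-right axis),
#'   `mirror_plane` (voxel coordinate of the midsagittal plane, may be
#'   half-integer) and `lcep` (sphere centres in voxel coordinates and
#'   radius, used to place the programmable contraction).
#' @examples
#' atl <- make_atlas(shape = c(32, 32, 32))
#' table(atl$labels[atl$labels > 0])
#' @export
make_atlas <- function(shape = c(48, 48, 48), spacing = c(2, 2, 2), seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, length(spacing) == 3, all(spacing > 0))
  if (any(shape < 32)) {
    stop("atlas grid too small: all divisions require at least 32 voxels per axis, got (",
         paste(shape, collapse = ", "), ")")
  }
  n1 <- shape[1]; n2 <- shape[2]; n3 <- shape[3]
  plane <- (n1 + 1) / 2
  cc <- coord_arrays(shape)
  cx <- plane; cy <- (n2 + 1) / 2; cz <- (n3 + 1) / 2
  a1 <- 0.42 * n1; a2 <- 0.40 * n2; a3 <- 0.44 * n3

  brain <- ((cc$x - cx) / a1)^2 + ((cc$y - cy) / a2)^2 + ((cc$z - cz) / a3)^2 <= 1
  # anterior-posterior fraction within the brain's z extent, in [0, 1]
  f <- (cc$z - (cz - a3)) / (2 * a3)

  labels <- array(0L, shape)
  labels[brain & f < 0.35] <- 1L                       # forebrain
  labels[brain & f >= 0.35 & f < 0.55] <- 2L           # midbrain
  labels[brain & f >= 0.55] <- 3L                      # hindbrain
  # dorsal slab of the anterior hindbrain = cerebellar plate
  slab <- brain & f >= 0.55 & f < 0.78 & cc$y >= cy
  labels[slab] <- 4L

  # paired spherical LCeP subregions, symmetric about the midsagittal plane
  r_lcep <- 0.09 * min(shape)
  d_lat <- 0.20 * n1
  y_lcep <- cy + 0.18 * n2
  z_lcep <- (cz - a3) + 0.66 * (2 * a3)
  for (side in c(-1, 1)) {
    ctr <- c(cx + side * d_lat, y_lcep, z_lcep)
    sph <- (cc$x - ctr[1])^2 + (cc$y - ctr[2])^2 + (cc$z - ctr[3])^2 <= r_lcep^2
    labels[sph & brain] <- if (side < 0) 5L else 6L
  }

  nm <- c(`1` = "forebrain", `2` = "midbrain", `3` = "hindbrain",
          `4` = "cerebellar_plate", `5` = "lcep_left", `6` = "lcep_right")
  atlas <- structure(list(
    labels = labels,
    names = nm,
    spacing = as.numeric(spacing),
    mirror_axis = 1L,
    mirror_plane = plane,
    lcep = list(
      centers = rbind(left  = c(cx - d_lat, y_lcep, z_lcep),
                      right = c(cx + d_lat, y_lcep, z_lcep)),
      radius = r_lcep
    )
  ), class = "label_atlas")
  for (lab in 1:6) {
    if (!any(labels == lab)) stop("atlas division '", nm[[as.character(lab)]],
                                  "' is empty at this grid size")
  }
  atlas
}

#' Extract a named region mask from a label atlas
#'
#' In addition to the individual division names, the composite names
#' `"brain"` (all labels), `"cerebellum"` (cerebellar plate plus both LCeP
#' subregions), `"lcep"` (both LCeP subregions) and `"hindbrain_all"`
#' (hindbrain plus cerebellum) are understood.
#'
#' @param atlas a `label_atlas`.
#' @param name region name.
#' @return logical 3D array.
#' @export
atlas_mask <- function(atlas, name = "brain") {
  lab <- atlas$labels
  m <- switch(name,
    brain = lab > 0L,
    cerebellum = lab %in% c(4L, 5L, 6L),
    lcep = lab %in% c(5L, 6L),
    hindbrain_all = lab %in% c(3L, 4L, 5L, 6L),
    {
      id <- names(atlas$names)[atlas$names == name]
      if (length(id) == 0) stop("unknown region name: ", name)
      lab == as.integer(id)
    })
  array(m, dim(lab))
}

#' Reflect a 3D grid about a mirror plane
#'
#' Reflects voxel indices along `mirror_axis` by `i -> 2 * mirror_plane - i`.
#' For a plane at the grid centre (the default produced by [make_atlas()])
#' this is a permutation of slices and the operation is an exact involution:
#' applying it twice restores the input.
#'
#' @param grid 3D array.
#' @param mirror_axis axis index (1, 2 or 3) of the left-right axis.
#' @param mirror_plane plane coordinate in voxel units; may be half-integer.
#' @return the reflected array.
#' @export
mirror_volume <- function(grid, mirror_axis = 1L, mirror_plane = (dim(grid)[mirror_axis] + 1) / 2) {
  n <- dim(grid)[mirror_axis]
  idx <- round(2 * mirror_plane - seq_len(n))
  if (any(idx < 1 | idx > n)) {
    stop("mirror plane at ", mirror_plane, " reflects indices outside the grid")
  }
  switch(mirror_axis, grid[idx, , , drop = FALSE],
         grid[, idx, , drop = FALSE], grid[, , idx, drop = FALSE])
}

#' @export
print.label_atlas <- function(x, ...) {
  cat("label_atlas:", paste(dim(x$labels), collapse = " x "),
      "voxels, spacing", paste(x$spacing, collapse = " x "), "um\n")
  cnt <- table(x$labels[x$labels > 0])
  for (id in names(cnt)) {
    cat(sprintf("  %-18s %6d voxels\n", x$names[[id]], cnt[[id]]))
  }
  invisible(x)
}
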