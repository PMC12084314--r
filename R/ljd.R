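#' Log-Jacobian-determinant (LJD) map of a displacement field
#'
#' Computes `LJD(x) = ln det(I + grad u(x))` at every voxel, with the
#' displacement gradient taken by central differences in the grid interior
#' and one-sided differences at the boundary slices, scaled by the voxel
#' spacing.  With the atlas-to-subject convention used throughout, negative
#' LJD means the subject is locally smaller (compressed) relative to the
#' reference brain, positive LJD locally larger.
#'
#' @param field a [displacement_field()] with at least 3 voxels per axis.
#' @return object of class `ljd_map`: list with `values` (3D array,
#'   dimensionless) and `spacing`.
#' @examples
#' f <- identity_field(c(8, 8, 8))
#' range(log_jacobian(f)$values)  # exactly 0
#' @export
log_jacobian <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  d <- dim(field$u)[1:3]
  if (any(d < 3)) stop("grid must have at least 3 voxels per axis")
  detj <- field$detj %||% jacobian_determinant(field$u, field$spacing)
  if (any(detj <= 0)) {
    bad <- which(detj <= 0, arr.ind = TRUE)
    stop("field is folded: det(grad phi) <= 0 at ", nrow(bad),
         " voxel(s), first at (", paste(bad[1, ], collapse = ", "),
         "), min det = ", signif(min(detj), 4))
  }
  structure(list(values = log(detj), spacing = field$spacing),
            class = "ljd_map")
}

#' @export
print.ljd_map <- function(x, ...) {
  cat("ljd_map:", paste(dim(x$values), collapse = " x "),
      "voxels, range [", signif(min(x$values), 4), ",",
      signif(max(x$values), 4), "]\n")
  invisible(x)
}

#' Subject-space volume of a region from an LJD map
#'
#' The subject-space volume of an atlas-defined region is the integral of
#' the local volume ratio over the region:
#' `V = sum_{x in mask} exp(LJD(x)) * voxel volume`.  The relative volume is
#' reported as a percentage of the total brain volume computed the same
#' way.
#'
#' @param ljd an [log_jacobian()] map.
#' @param mask logical 3D array selecting the region; must be non-empty.
#' @param brain_mask logical 3D array for the whole brain (denominator of
#'   the percentage); `NULL` omits the percentage.
#' @return list with `volume` (um^3), and `percent` plus `brain_volume`
#'   when `brain_mask` is supplied.
#' @export
region_volume <- function(ljd, mask, brain_mask = NULL) {
  stopifnot(inherits(ljd, "ljd_map"), identical(dim(mask), dim(ljd$values)))
  if (!any(mask)) stop("empty region mask")
  voxvol <- prod(ljd$spacing)
  vol <- sum(exp(ljd$values[mask])) * voxvol
  out <- list(volume = vol)
  if (!is.null(brain_mask)) {
    bv <- sum(exp(ljd$values[brain_mask])) * voxvol
    out$brain_volume <- bv
    out$percent <- 100 * vol / bv
  }
  out
}

#' Per-subject, per-division volume and intensity table
#'
#' For every subject of a registered cohort and every atlas division,
#' reports the subject-space division volume (um^3), the volume as a
#' percentage of that subject's total brain volume, and the mean
#' fluorescence intensity over the division mask for each available
#' channel.  This is the table behind division-level screening for volume
#' or intensity phenotypes.
#'
#' @param cohort a [make_cohort()] cohort (channels optional).
#' @param atlas atlas; defaults to the cohort's own.
#' @param ljds optional precomputed [cohort_ljd()] list.
#' @return data.frame with one row per (subject, division).
#' @export
division_stats <- function(cohort, atlas = cohort$atlas, ljds = NULL) {
  if (is.null(ljds)) ljds <- cohort_ljd(cohort)
  brain <- atlas_mask(atlas, "brain")
  division_masks <- lapply(names(atlas$names), function(id) {
    atlas$labels == as.integer(id)
  })
  names(division_masks) <- atlas$names
  rows <- list()
  for (sid in names(cohort$subjects)) {
    s <- cohort$subjects[[sid]]
    ljd <- ljds[[sid]]
    for (dv in names(division_masks)) {
      rv <- region_volume(ljd, division_masks[[dv]], brain)
      row <- data.frame(id = sid, genotype = s$genotype, batch = s$batch,
                        division = dv, volume_um3 = rv$volume,
                        volume_pct = rv$percent, stringsAsFactors = FALSE)
      if (!is.null(s$channels)) {
        for (ch in names(s$channels)) {
          row[[paste0("mean_", ch)]] <- mean(s$channels[[ch]][division_masks[[dv]]])
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
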