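# NIfTI and CSV interchange, built on RNifti.  Scalar volumes are written
# as 3D images, displacement fields as 4D images with the vector component
# on the 4th axis; voxel spacing is carried in pixdim.

#' Write / read a 3D scalar volume as NIfTI
#'
#' @param vol 3D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel size in micrometres.
#' @return `path`, invisibly (write) or a list with `data` and `spacing`
#'   (read).
#' @export
write_volume <- function(vol, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       spacing = RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))])
}

#' Write / read a displacement field as 4D NIfTI
#'
#' @param field a [displacement_field()].
#' @param path output path.
#' @return `path`, invisibly (write) or a [displacement_field()] (read).
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  img <- RNifti::asNifti(field$u)
  RNifti::pixdim(img) <- c(field$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stopifnot(length(d) == 4, d[4] == 3)
  displacement_field(array(as.numeric(img), d), RNifti::pixdim(img)[1:3])
}

#' Write a simulated cohort to a directory
#'
#' Writes one displacement field (and any channels) per subject as NIfTI,
#' the atlas labels, and a CSV manifest (id, genotype, batch, programmed
#' contraction, seed, file paths).
#'
#' @param cohort a [make_cohort()] cohort.
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- cohort$atlas
  write_volume(atlas$labels, file.path(dir, "atlas_labels.nii.gz"), atlas$spacing)
  man <- cohort$manifest
  man$field_path <- NA_character_
  for (i in seq_len(nrow(man))) {
    sid <- man$id[i]
    s <- cohort$subjects[[sid]]
    fp <- file.path(dir, paste0(sid, "_field.nii.gz"))
    write_field(s$field, fp)
    man$field_path[i] <- fp
    if (!is.null(s$channels)) {
      for (ch in names(s$channels)) {
        write_volume(s$channels[[ch]],
                     file.path(dir, paste0(sid, "_", ch, ".nii.gz")),
                     atlas$spacing)
      }
    }
  }
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}
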