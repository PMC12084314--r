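#' Displacement field constructor
#'
#' A displacement field stores the atlas-to-subject transform
#' `phi(x) = x + u(x)` sampled at atlas voxel centres, with `u` in
#' micrometres.  Under this convention a locally contracted subject region
#' (smaller than the reference) has `det grad phi < 1`, i.e. negative
#' log-Jacobian.
#'
#' @param u 4D numeric array `(nx, ny, nz, 3)`; last axis is the vector
#'   component, in micrometres.
#' @param spacing voxel size in micrometres (length 3).
#' @return object of class `displacement_field`.
#' @export
displacement_field <- function(u, spacing) {
  stopifnot(length(dim(u)) == 4, dim(u)[4] == 3, length(spacing) == 3)
  if (!all(is.finite(u))) stop("displacement field contains non-finite values")
  structure(list(u = u, spacing = as.numeric(spacing),
                 convention = "atlas_to_subject"),
            class = "displacement_field")
}

#' Identity displacement field
#'
#' @param shape grid dimensions (length 3).
#' @param spacing voxel size in micrometres.
#' @return a `displacement_field` with `u == 0` everywhere.
#' @export
identity_field <- function(shape, spacing = c(2, 2, 2)) {
  displacement_field(array(0, c(shape, 3)), spacing)
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$u)
  cat("displacement_field (atlas -> subject):", paste(d[1:3], collapse = " x "),
      "voxels, max |u| =", signif(max(abs(x$u)), 4), "um\n")
  invisible(x)
}

# Trilinear interpolation of one displacement component at arbitrary
# voxel-unit coordinates (clamped to the grid, i.e. constant extension).
interp_component <- function(a, px, py, pz) {
  d <- dim(a)
  px <- pmin(pmax(px, 1), d[1]); py <- pmin(pmax(py, 1), d[2]); pz <- pmin(pmax(pz, 1), d[3])
  x0 <- pmin(floor(px), d[1] - 1); y0 <- pmin(floor(py), d[2] - 1); z0 <- pmin(floor(pz), d[3] - 1)
  fx <- px - x0; fy <- py - y0; fz <- pz - z0
  i000 <- x0 + d[1] * (y0 - 1) + d[1] * d[2] * (z0 - 1)
  v <- a[i000]           * (1 - fx) * (1 - fy) * (1 - fz) +
       a[i000 + 1]       * fx       * (1 - fy) * (1 - fz) +
       a[i000 + d[1]]    * (1 - fx) * fy       * (1 - fz) +
       a[i000 + d[1] + 1] * fx      * fy       * (1 - fz)
  off <- d[1] * d[2]
  v + a[i000 + off]            * (1 - fx) * (1 - fy) * fz +
      a[i000 + off + 1]        * fx       * (1 - fy) * fz +
      a[i000 + off + d[1]]     * (1 - fx) * fy       * fz +
      a[i000 + off + d[1] + 1] * fx       * fy       * fz
}
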