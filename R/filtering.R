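#' Label connected components of a 3D binary mask
#'
#' Builds the voxel adjacency graph of the foreground (26- or
#' 6-connectivity) and labels its connected components via
#' [igraph::components()].
#'
#' @param mask logical 3D array.
#' @param connectivity 26 (vertices/edges/faces) or 6 (faces only).
#' @return integer 3D array; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0) return(lab)
  vid <- array(0L, d)
  vid[idx] <- seq_along(idx)
  ai <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  # half of the offsets suffice for an undirected graph
  keep <- offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
    (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0)
  offs <- offs[keep, , drop = FALSE]
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(ai, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    nb_id <- vid[nb_lin]
    src <- which(ok)[nb_id > 0]
    if (length(src)) edges[[length(edges) + 1L]] <- cbind(src, nb_id[nb_id > 0])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  lab
}

#' Threshold, symmetry-filter and cluster-filter a voxelwise p map
#'
#' Reproduces the ROI-definition step of deformation-based morphometry:
#' keep voxels with `p < alpha`; optionally keep a voxel only if its mirror
#' voxel across the atlas midsagittal plane (within a Chebyshev tolerance
#' radius of `tol` voxels, default exact) also passes the threshold; then
#' remove connected components (26-connectivity by default) smaller than
#' `min_cluster` voxels.  An empty mask is a valid result.
#'
#' @param stat a `stat_map` from [voxelwise_two_group()] or
#'   [voxelwise_two_way_anova()].
#' @param alpha significance threshold on the uncorrected voxelwise p
#'   values (default 0.01).
#' @param min_cluster minimum component size in voxels (default 50).
#' @param symmetric apply the bilateral-symmetry rule (default `TRUE`).
#' @param atlas atlas supplying the mirror plane and the brain mask.
#' @param tol symmetry tolerance radius in voxels (0 = exact mirror voxel).
#' @param connectivity 26 or 6.
#' @return object of class `roi_mask`: list with `mask` (logical 3D
#'   array), `n_voxels`, `component_sizes` and a `provenance` record of all
#'   filter settings.
#' @export
filter_significance <- function(stat, alpha = 0.01, min_cluster = 50,
                                symmetric = TRUE, atlas = NULL, tol = 0,
                                connectivity = 26) {
  stopifnot(alpha > 0, alpha < 1, min_cluster >= 1)
  pass <- stat$pvalue < alpha
  if (!is.null(atlas)) pass <- pass & atlas_mask(atlas, "brain")
  if (symmetric) {
    if (is.null(atlas)) stop("symmetry filtering requires an atlas (mirror plane)")
    mir <- mirror_volume(pass, atlas$mirror_axis, atlas$mirror_plane)
    if (tol > 0) {
      acc <- mir
      d <- dim(mir)
      for (s1 in -tol:tol) for (s2 in -tol:tol) for (s3 in -tol:tol) {
        if (s1 == 0 && s2 == 0 && s3 == 0) next
        i1 <- pmin(pmax(seq_len(d[1]) + s1, 1), d[1])
        i2 <- pmin(pmax(seq_len(d[2]) + s2, 1), d[2])
        i3 <- pmin(pmax(seq_len(d[3]) + s3, 1), d[3])
        acc <- acc | mir[i1, i2, i3]
      }
      mir <- acc
    }
    pass <- pass & mir
  }
  lab <- label_components(pass, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_cluster)
  mask <- array(lab %in% keep & lab > 0, dim(pass))
  structure(list(
    mask = mask,
    n_voxels = sum(mask),
    component_sizes = sort(sizes[keep], decreasing = TRUE),
    provenance = list(alpha = alpha, min_cluster = min_cluster,
                      symmetric = symmetric, tol = tol,
                      connectivity = connectivity, kind = stat$kind,
                      df = stat$df)
  ), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("roi_mask:", x$n_voxels, "voxels in", length(x$component_sizes),
      "component(s); alpha =", x$provenance$alpha,
      ", min_cluster =", x$provenance$min_cluster,
      ", symmetric =", x$provenance$symmetric, "\n")
  invisible(x)
}
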