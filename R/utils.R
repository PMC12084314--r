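`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-subject seed stream; stays inside 32-bit integer range.
derive_seed <- function(master, offset) {
  m <- as.numeric(master) %% 2147483629
  as.integer((m * 7919 + as.numeric(offset) * 104729) %% 2147483629) + 1L
}

# Voxel-index coordinate arrays (1-based, voxel units) for a 3D grid.
coord_arrays <- function(shape) {
  n1 <- shape[1]; n2 <- shape[2]; n3 <- shape[3]
  list(
    x = array(rep.int(seq_len(n1), n2 * n3), shape),
    y = array(rep.int(rep(seq_len(n2), each = n1), n3), shape),
    z = array(rep(seq_len(n3), each = n1 * n2), shape)
  )
}

# Row-normalized 1D Gaussian smoothing matrix (kernel truncated at 3 sigma).
smooth_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - half):(i + half)
    ok <- idx >= 1 & idx <= n
    w <- k[ok]
    S[i, idx[ok]] <- w / sum(w)
  }
  S
}

# Separable Gaussian smoothing of a 3D array, sigma in voxels (per axis).
gaussian_smooth_3d <- function(a, sigma) {
  d <- dim(a)
  sigma <- rep(sigma, length.out = 3)
  if (sigma[1] > 0) a <- array(smooth_kernel_matrix(d[1], sigma[1]) %*% matrix(a, d[1]), d)
  if (sigma[2] > 0) {
    a <- aperm(a, c(2, 1, 3))
    a <- array(smooth_kernel_matrix(d[2], sigma[2]) %*% matrix(a, d[2]), d[c(2, 1, 3)])
    a <- aperm(a, c(2, 1, 3))
  }
  if (sigma[3] > 0) {
    a <- aperm(a, c(3, 2, 1))
    a <- array(smooth_kernel_matrix(d[3], sigma[3]) %*% matrix(a, d[3]), d[c(3, 2, 1)])
    a <- aperm(a, c(3, 2, 1))
  }
  a
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b logical arrays of identical dimension.
#' @return `2 |a & b| / (|a| + |b|)`; defined as 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

# One-sided/central finite difference of a 3D array along an axis
# (central in the interior, one-sided at the two boundary slices).
diff_axis <- function(a, axis) {
  n <- dim(a)[axis]
  if (n < 2) stop("need at least 2 voxels along axis ", axis)
  ip <- c(2:n, n)
  im <- c(1L, 1:(n - 1))
  denom <- ip - im
  idx_p <- switch(axis,
    a[ip, , , drop = FALSE], a[, ip, , drop = FALSE], a[, , ip, drop = FALSE])
  idx_m <- switch(axis,
    a[im, , , drop = FALSE], a[, im, , drop = FALSE], a[, , im, drop = FALSE])
  sweep(idx_p - idx_m, axis, denom, "/")
}
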