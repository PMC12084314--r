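# Shared small fixtures, built once per test run.

TINY_SHAPE <- c(32L, 32L, 32L)
TINY_ATLAS <- make_atlas(TINY_SHAPE)

tiny_design <- function(groups, seed = 1L, amplitude = 0.8) {
  cohort_design(groups = groups, shape = TINY_SHAPE, spacing = c(2, 2, 2),
                amplitude = amplitude, seed = seed)
}

two_group_rows <- function(n1 = 3L, n2 = 3L, contraction = 0.9, batch = "b1") {
  data.frame(genotype = c("ctl", "xrcc"), batch = batch, n = c(n1, n2),
             contraction = c(1, contraction))
}

# A displacement field for the uniform linear scale phi(x) = s * x about
# the physical origin, on the atlas grid (u in micrometres).
uniform_scale_field <- function(shape, spacing, s) {
  cc <- coord_arrays(shape)
  u <- array(0, c(shape, 3))
  u[, , , 1] <- (s - 1) * (cc$x - 1) * spacing[1]
  u[, , , 2] <- (s - 1) * (cc$y - 1) * spacing[2]
  u[, , , 3] <- (s - 1) * (cc$z - 1) * spacing[3]
  displacement_field(u, spacing)
}

# Independent flood-fill connected-components oracle (slow, queue-based).
bfs_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ci <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        nb <- ci + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# Trapezoidal integration written out, independent of pracma.
trapz_manual <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}
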