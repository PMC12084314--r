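#' Simulate a capillary-electrophoresis fragment-analysis trace
#'
#' Generates an electropherogram (fragment size vs fluorescence) as a sum
#' of Gaussian peaks over a size axis, plus a constant baseline and white
#' noise: one peak at the expected wildtype product size carrying
#' `wt_fraction` of the total area, and one peak per indel size carrying
#' the remaining area split according to `indel_areas`.  The true area
#' fractions are recorded as ground truth.  Peaks whose apexes are closer
#' than four peak widths are flagged as potentially unresolvable.
#'
#' @param wt_fraction true wildtype area fraction in `[0, 1]`.
#' @param wt_size_bp expected wildtype product size (bp).
#' @param indel_sizes sizes (bp) of indel products; may be empty when
#'   `wt_fraction = 1`.
#' @param indel_areas relative areas of the indel peaks (>= 0; normalized
#'   internally to sum to `1 - wt_fraction`).
#' @param noise_sd standard deviation of additive white noise (rfu).
#' @param peak_sd Gaussian peak width (bp).
#' @param size_range,size_step extent and sampling of the size axis (bp).
#' @param baseline constant baseline level (rfu).
#' @param total_area total integrated peak area (rfu * bp).
#' @param sample_id,target_id metadata labels.
#' @param seed integer seed.
#' @return object of class `electropherogram`: data.frame with columns
#'   `size_bp`, `rfu`; attributes `wt_size_bp`, `truth` (data.frame of true
#'   sizes and fractions), `overlap_warning`, `sample_id`, `target_id`.
#' @export
make_trace <- function(wt_fraction, wt_size_bp = 200, indel_sizes = numeric(0),
                       indel_areas = rep(1, length(indel_sizes)),
                       noise_sd = 1, peak_sd = 1.2,
                       size_range = c(100, 400), size_step = 0.25,
                       baseline = 5, total_area = 1e4,
                       sample_id = "s1", target_id = "t1", seed = 1L) {
  stopifnot(wt_fraction >= 0, wt_fraction <= 1, all(indel_areas >= 0),
            length(indel_sizes) == length(indel_areas))
  if (wt_fraction < 1 && (length(indel_sizes) == 0 || sum(indel_areas) == 0)) {
    stop("wt_fraction < 1 requires at least one indel peak with positive area")
  }
  fr_indel <- if (length(indel_areas) && sum(indel_areas) > 0) {
    indel_areas / sum(indel_areas) * (1 - wt_fraction)
  } else numeric(0)
  sizes <- c(wt_size_bp, indel_sizes)
  fracs <- c(wt_fraction, fr_indel)
  keep <- fracs > 0
  truth <- data.frame(size_bp = sizes, fraction = fracs,
                      is_wildtype = c(TRUE, rep(FALSE, length(indel_sizes))))
  overlap <- FALSE
  s_kept <- sort(sizes[keep])
  if (length(s_kept) > 1 && min(diff(s_kept)) < 4 * peak_sd) overlap <- TRUE
  set.seed(seed)
  x <- seq(size_range[1], size_range[2], by = size_step)
  y <- rep(baseline, length(x))
  for (i in which(keep)) {
    y <- y + total_area * fracs[i] * stats::dnorm(x, sizes[i], peak_sd)
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(x), 0, noise_sd)
  structure(data.frame(size_bp = x, rfu = y),
            class = c("electropherogram", "data.frame"),
            wt_size_bp = wt_size_bp, truth = truth,
            overlap_warning = overlap,
            sample_id = sample_id, target_id = target_id)
}

#' Detect and integrate peaks in a fragment-analysis trace
#'
#' Subtracts a rolling-minimum baseline (window much wider than a peak),
#' clamps at zero, finds local maxima exceeding a prominence threshold,
#' delimits each peak window by the minima between neighbouring retained
#' apexes, and integrates each window by the trapezoidal rule.  Peaks
#' whose area is below `min_area_fraction` of the total are discarded.
#'
#' @param trace data.frame with strictly increasing `size_bp` and `rfu`
#'   columns (e.g. from [make_trace()]).
#' @param min_prominence minimum apex prominence in rfu after baseline
#'   subtraction; `NULL` uses 2% of the maximum signal.
#' @param min_area_fraction discard peaks with area below this fraction of
#'   the total peak area (default 0.01).
#' @param baseline_window rolling-minimum window width in bp (default 40).
#' @return object of class `peak_set`: data.frame with one row per peak
#'   (`apex_bp`, `height`, `area`, `from_bp`, `to_bp`), ordered by size.
#'   An all-zero or featureless trace yields zero rows.
#' @export
detect_peaks <- function(trace, min_prominence = NULL, min_area_fraction = 0.01,
                         baseline_window = 40) {
  x <- trace$size_bp; y <- trace$rfu
  stopifnot(length(x) == length(y), all(diff(x) > 0))
  step <- stats::median(diff(x))
  win <- max(3L, 2L * floor(baseline_window / step / 2) + 1L)  # odd, in samples
  base <- zoo::rollapply(y, win, min, partial = TRUE)
  ys <- pmax(y - base, 0)
  empty <- structure(
    data.frame(apex_bp = numeric(0), height = numeric(0), area = numeric(0),
               from_bp = numeric(0), to_bp = numeric(0)),
    class = c("peak_set", "data.frame"))
  if (max(ys) <= 0) return(empty)
  if (is.null(min_prominence)) min_prominence <- 0.02 * max(ys)
  n <- length(ys)
  is_max <- c(FALSE, ys[2:(n - 1)] > ys[1:(n - 2)] & ys[2:(n - 1)] >= ys[3:n], FALSE)
  cand <- which(is_max & ys > 0)
  if (length(cand) == 0) return(empty)
  # prominence: drop to the highest of the two key saddles flanking the apex
  prominence <- vapply(cand, function(i) {
    h <- ys[i]
    left_higher <- which(ys[seq_len(i - 1)] > h)
    lo_l <- if (length(left_higher)) min(ys[(max(left_higher) + 1):i]) else min(ys[1:i])
    right_higher <- which(ys[(i + 1):n] > h)
    lo_r <- if (length(right_higher)) min(ys[i:(i + min(right_higher))]) else min(ys[i:n])
    h - max(lo_l, lo_r)
  }, numeric(1))
  apex <- cand[prominence >= min_prominence]
  if (length(apex) == 0) return(empty)
  apex <- sort(apex)
  # windows: split at the minimum between adjacent apexes
  bounds <- integer(length(apex) + 1)
  bounds[1] <- 1L
  bounds[length(apex) + 1] <- n
  if (length(apex) > 1) {
    for (j in seq_len(length(apex) - 1)) {
      seg <- apex[j]:apex[j + 1]
      bounds[j + 1] <- seg[which.min(ys[seg])]
    }
  }
  # trim each window to the contiguous region above 2% of the apex height,
  # so that broad inter-peak stretches of residual noise do not accumulate
  # into the integral (a 2% cut keeps > 99.5% of a Gaussian peak's area,
  # and cancels in area ratios)
  lims <- vapply(seq_along(apex), function(j) {
    thr <- 0.02 * ys[apex[j]]
    i0 <- apex[j]
    while (i0 > bounds[j] && ys[i0 - 1] > thr) i0 <- i0 - 1L
    i1 <- apex[j]
    while (i1 < bounds[j + 1] && ys[i1 + 1] > thr) i1 <- i1 + 1L
    c(i0, i1)
  }, integer(2))
  peaks <- data.frame(
    apex_bp = x[apex],
    height = ys[apex],
    area = vapply(seq_along(apex), function(j) {
      pracma::trapz(x[lims[1, j]:lims[2, j]], ys[lims[1, j]:lims[2, j]])
    }, numeric(1)),
    from_bp = x[lims[1, ]],
    to_bp = x[lims[2, ]]
  )
  tot <- sum(peaks$area)
  peaks <- peaks[peaks$area >= min_area_fraction * tot, , drop = FALSE]
  rownames(peaks) <- NULL
  structure(peaks, class = c("peak_set", "data.frame"))
}

#' Wildtype area fraction of a peak set
#'
#' Fraction of total peak area carried by peaks whose apex lies within
#' `tol_bp` of the expected wildtype product size; the CRISPR-efficiency
#' readout of fragment analysis.  Invariant under uniform rescaling of the
#' fluorescence signal.
#'
#' @param peaks a [detect_peaks()] `peak_set`.
#' @param expected_size_bp expected wildtype product size (bp).
#' @param tol_bp assignment tolerance (default 2 bp).
#' @return fraction in `[0, 1]`; 0 when no peak falls in the window.
#' @export
wildtype_fraction <- function(peaks, expected_size_bp, tol_bp = 2) {
  stopifnot(tol_bp > 0)
  tot <- sum(peaks$area)
  if (nrow(peaks) == 0 || tot <= 0) stop("no peak area to apportion")
  wt <- abs(peaks$apex_bp - expected_size_bp) <= tol_bp
  sum(peaks$area[wt]) / tot
}

#' Guide efficiency and larva inclusion from wildtype fractions
#'
#' A guide is called efficient when its wildtype fraction is strictly below
#' `threshold` (default 0.5: the wildtype peak is depleted to less than
#' half of the total product); a larva is included in downstream analysis
#' when at least one of its guides is efficient.  Missing fractions are
#' excluded from the rule and counted.
#'
#' @param fractions data.frame with columns `larva`, `guide`,
#'   `wildtype_fraction`.
#' @param threshold efficiency cutoff (strict inequality; default 0.5).
#' @return list with `guides` (input plus logical `efficient`), `larvae`
#'   (data.frame: `larva`, `included`, `n_guides`, `n_missing`).
#' @export
classify_efficiency <- function(fractions, threshold = 0.5) {
  stopifnot(all(c("larva", "guide", "wildtype_fraction") %in% names(fractions)))
  fr <- fractions
  fr$efficient <- !is.na(fr$wildtype_fraction) & fr$wildtype_fraction < threshold
  larvae <- do.call(rbind, lapply(split(fr, fr$larva), function(d) {
    data.frame(larva = d$larva[1],
               included = any(d$efficient),
               n_guides = nrow(d),
               n_missing = sum(is.na(d$wildtype_fraction)),
               stringsAsFactors = FALSE)
  }))
  rownames(larvae) <- NULL
  list(guides = fr, larvae = larvae)
}
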