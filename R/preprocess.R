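#' Processing parameters for the preprocessing and peak pipeline
#'
#' Defaults are the published biotyping workflow values: trim to 1.5-20 kDa,
#' square-root transform, Savitzky-Golay smoothing, SNIP baseline removal,
#' TIC normalization, peak detection at SNR 6 with half-window 7 points,
#' binning at relative tolerance 0.001, feature filter at minimum frequency
#' 0.05 and peak-pattern simplification at 0.8.
#'
#' @param sqrt_transform apply the square-root variance stabilization first.
#' @param sg_half_window Savitzky-Golay half window (points).
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param snip_iterations SNIP clipping iterations (maximum half window).
#' @param snip_decreasing run the clipping window in decreasing order.
#' @param tic_target total intensity after TIC normalization.
#' @param trim_range mass range of interest, Da.
#' @param snr_threshold signal-to-noise ratio for peak retention.
#' @param peak_half_window local-maximum half window (points).
#' @param bin_tolerance_rel relative mass tolerance for peak binning.
#' @param min_frequency minimum occupancy fraction for a feature column.
#' @param pattern_min_frequency minimum within-species occupancy for the
#'   peak-pattern table.
#' @return a list of class `processing_params`.
#' @export
processing_params <- function(sqrt_transform = TRUE, sg_half_window = 10,
                              sg_polyorder = 3, snip_iterations = 100,
                              snip_decreasing = TRUE, tic_target = 1,
                              trim_range = c(1500, 20000), snr_threshold = 6,
                              peak_half_window = 7, bin_tolerance_rel = 0.001,
                              min_frequency = 0.05, pattern_min_frequency = 0.8) {
  p <- list(sqrt_transform = isTRUE(sqrt_transform),
            sg_half_window = as.integer(sg_half_window),
            sg_polyorder = as.integer(sg_polyorder),
            snip_iterations = as.integer(snip_iterations),
            snip_decreasing = isTRUE(snip_decreasing),
            tic_target = tic_target, trim_range = as.numeric(trim_range),
            snr_threshold = snr_threshold,
            peak_half_window = as.integer(peak_half_window),
            bin_tolerance_rel = bin_tolerance_rel,
            min_frequency = min_frequency,
            pattern_min_frequency = pattern_min_frequency)
  with(p, {
    if (sg_half_window < 1 || sg_polyorder < 0 || snip_iterations < 1 ||
        peak_half_window < 1 || tic_target <= 0 || snr_threshold <= 0 ||
        bin_tolerance_rel <= 0)
      stop_msg("processing parameters must be positive")
    if (min_frequency <= 0 || min_frequency > 1 ||
        pattern_min_frequency <= 0 || pattern_min_frequency > 1)
      stop_msg("frequency thresholds must be in (0, 1]")
    if (trim_range[1] >= trim_range[2]) stop_msg("trim_range must be [low, high]")
  })
  structure(p, class = "processing_params")
}

#' Trim a spectrum to the mass range of interest
#' @param s a [raw_spectrum()].
#' @param range numeric length-2, Da; points with low <= m/z <= high are kept.
#' @return the trimmed [raw_spectrum()], metadata preserved.
#' @export
trim_range <- function(s, range = c(1500, 20000)) {
  stopifnot(inherits(s, "raw_spectrum"))
  if (range[1] >= range[2]) stop_msg("range must be [low, high] with low < high")
  keep <- s$mass >= range[1] & s$mass <= range[2]
  if (sum(keep) < 2L)
    stop_msg("empty spectrum: no points in [%g, %g]", range[1], range[2])
  raw_spectrum(s$mass[keep], s$intensity[keep], s$meta)
}

#' Square-root intensity transform
#' @param s a [raw_spectrum()] with non-negative intensities.
#' @return the transformed [raw_spectrum()].
#' @export
sqrt_transform <- function(s) {
  stopifnot(inherits(s, "raw_spectrum"))
  if (any(s$intensity < 0)) stop_msg("negative intensity: cannot sqrt-transform")
  raw_spectrum(s$mass, sqrt(s$intensity), s$meta)
}

# Savitzky-Golay convolution weights: row `at` of the least-squares smoother
# for a window of positions -h..h and polynomial order p.
sg_coef <- function(h, p, at = 0L) {
  x <- (-h):h
  X <- outer(x, 0:p, `^`)
  H <- X %*% solve(crossprod(X), t(X))  # hat matrix
  H[at + h + 1L, ]
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with window `2 * half_window + 1`.
#' Edge points are smoothed with the fit of the first/last full window
#' evaluated at their own position, so polynomials up to the configured
#' order pass through unchanged everywhere.
#'
#' @param s a [raw_spectrum()].
#' @param half_window half window size in points.
#' @param polyorder polynomial order, less than the window size.
#' @return the smoothed [raw_spectrum()].
#' @export
smooth_sg <- function(s, half_window = 10, polyorder = 3) {
  stopifnot(inherits(s, "raw_spectrum"))
  h <- as.integer(half_window); p <- as.integer(polyorder)
  w <- 2L * h + 1L
  if (w <= p) stop_msg("window (2*half_window+1 = %d) must exceed polyorder %d", w, p)
  n <- length(s$mass)
  if (n < w) stop_msg("window (%d) larger than spectrum (%d points)", w, n)
  y <- s$intensity
  out <- stats::filter(y, sg_coef(h, p, 0L), sides = 2)
  out <- as.numeric(out)
  # transient handling: evaluate the boundary-window fit at the edge offsets
  for (i in seq_len(h)) {
    out[i] <- sum(sg_coef(h, p, at = i - h - 1L) * y[1:w])
    out[n - i + 1L] <- sum(sg_coef(h, p, at = h + 1L - i) * y[(n - w + 1L):n])
  }
  raw_spectrum(s$mass, out, s$meta)
}

#' SNIP baseline estimation
#'
#' Statistics-sensitive non-linear iterative peak clipping: starting from the
#' intensities, each pass replaces `b(i)` by
#' `min(b(i), (b(i-k) + b(i+k)) / 2)` for every point whose clipping window
#' fits inside the spectrum (the `k` boundary points on each side pass
#' through unchanged, so linear trends are fixed points), for clipping half
#' windows `k` running from `iterations` down to 1 (the decreasing finishing
#' order; set `decreasing = FALSE` for 1..iterations).
#' The result is a smooth lower envelope: `baseline <= intensity` pointwise.
#'
#' @param s a [raw_spectrum()] (already transformed/smoothed).
#' @param iterations maximum clipping half window, points.
#' @param decreasing clipping-window order.
#' @return numeric baseline vector, same length as the spectrum.
#' @export
snip_baseline <- function(s, iterations = 100, decreasing = TRUE) {
  stopifnot(inherits(s, "raw_spectrum"))
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop_msg("iterations must be >= 1")
  b <- s$intensity
  n <- length(b)
  kmax <- min(iterations, (n - 1L) %/% 2L)
  ks <- if (decreasing) rev(seq_len(kmax)) else seq_len(kmax)
  for (k in ks) {
    # only points whose full window fits are clipped; the k boundary points
    # on each side pass through unchanged (so a linear trend is a fixed point)
    idx <- (k + 1L):(n - k)
    b[idx] <- pmin(b[idx], (b[idx - k] + b[idx + k]) / 2)
  }
  b
}

#' Subtract a baseline, clipping at zero
#' @param s a [raw_spectrum()].
#' @param baseline numeric vector of the same length.
#' @return the baseline-corrected [raw_spectrum()].
#' @export
remove_baseline <- function(s, baseline = snip_baseline(s)) {
  stopifnot(inherits(s, "raw_spectrum"))
  if (length(baseline) != length(s$intensity))
    stop_msg("baseline length (%d) does not match spectrum (%d)",
             length(baseline), length(s$intensity))
  raw_spectrum(s$mass, pmax(s$intensity - baseline, 0), s$meta)
}

#' Total-ion-current normalization
#' @param s a [raw_spectrum()].
#' @param target total intensity after scaling (default 1).
#' @return the normalized [raw_spectrum()].
#' @export
tic_normalize <- function(s, target = 1) {
  stopifnot(inherits(s, "raw_spectrum"))
  tot <- sum(s$intensity)
  if (tot <= 0) stop_msg("total ion current is zero: cannot normalize")
  raw_spectrum(s$mass, s$intensity * (target / tot), s$meta)
}

#' Robust noise level of a spectrum
#'
#' Scaled median absolute deviation of the intensities,
#' `1.4826 * median(|x - median(x)|)`; a single constant noise level for the
#' whole spectrum, consistent for Gaussian noise.
#'
#' @param s a [raw_spectrum()].
#' @return the noise level (intensity units).
#' @export
estimate_noise <- function(s) {
  stopifnot(inherits(s, "raw_spectrum"))
  mad(s$intensity, constant = 1.4826)
}

#' Detect significant peaks
#'
#' A point is a peak when it is a strict local maximum over a window of
#' `2 * half_window + 1` points and its intensity reaches
#' `snr_threshold * noise`, with noise from [estimate_noise()].
#'
#' @param s a preprocessed [raw_spectrum()].
#' @param snr_threshold minimum signal-to-noise ratio.
#' @param half_window local-maximum half window, points.
#' @param noise optional externally supplied noise level.
#' @return an object of class `peak_list`: list with `masses`, `intensities`,
#'   `snr`, `meta`. Empty peak lists are allowed.
#' @export
detect_peaks <- function(s, snr_threshold = 6, half_window = 7,
                         noise = estimate_noise(s)) {
  stopifnot(inherits(s, "raw_spectrum"))
  h <- as.integer(half_window)
  y <- s$intensity
  n <- length(y)
  thr <- snr_threshold * noise
  cand <- which(y >= thr & y > 0)
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    win <- y[max(1L, i - h):min(n, i + h)]
    keep[j] <- sum(win == y[i]) == 1L && y[i] == max(win)
  }
  apex <- cand[keep]
  structure(list(masses = s$mass[apex], intensities = y[apex],
                 snr = if (noise > 0) y[apex] / noise else rep(Inf, length(apex)),
                 meta = s$meta),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks%s\n", length(x$masses),
              if (!is.null(x$meta$label)) paste0(", label=", x$meta$label) else ""))
  invisible(x)
}

#' Run the full preprocessing chain on one spectrum
#'
#' Fixed order: trim -> sqrt -> Savitzky-Golay smoothing -> SNIP baseline
#' removal -> TIC normalization.
#'
#' @param s a [raw_spectrum()].
#' @param params a [processing_params()].
#' @return the preprocessed [raw_spectrum()].
#' @export
preprocess_spectrum <- function(s, params = processing_params()) {
  stopifnot(inherits(params, "processing_params"))
  s <- trim_range(s, params$trim_range)
  if (params$sqrt_transform) s <- sqrt_transform(s)
  s <- smooth_sg(s, params$sg_half_window, params$sg_polyorder)
  # smoothing can undershoot slightly below zero; clip before SNIP
  s$intensity <- pmax(s$intensity, 0)
  s <- remove_baseline(s, snip_baseline(s, params$snip_iterations,
                                        params$snip_decreasing))
  tic_normalize(s, params$tic_target)
}
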