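#' Processing parameters
#'
#' @param apodization `"squared-cosine"` (the half-cosine-squared window,
#'   i.e. the SSB = 2 squared sine bell used throughout) or `"none"`.
#' @param zero_fill_factor integer >= 1; the time-domain vector of `N`
#'   complex points is padded to `2 * zero_fill_factor * N` points before
#'   the transform, so the default 2 gives a fourfold-oversampled frequency
#'   axis.
#' @param effective_points optional truncation count applied before
#'   apodization (the TDEFF mechanism used to reprocess a long acquisition
#'   at a shorter effective t1max).
#' @param residual_correction apply the schedule's per-increment residual
#'   factors to SR interferograms before apodization (time domain)?
#' @param first_point_scale multiplier for the first time-domain point
#'   (default 0.5, suppressing the constant baseline offset of the one-sided
#'   transform).
#' @param spectrometer_freq_mhz nucleus Larmor frequency used for the ppm
#'   axis; default 176.05 (\eqn{^{13}}C at a 700 MHz \eqn{^1}H field).
#' @return An object of class `processing_params`.
#' @export
processing_params <- function(apodization = c("squared-cosine", "none"),
                              zero_fill_factor = 2L,
                              effective_points = NULL,
                              residual_correction = TRUE,
                              first_point_scale = 0.5,
                              spectrometer_freq_mhz = 176.05) {
  apodization <- match.arg(apodization)
  zero_fill_factor <- as.integer(zero_fill_factor)
  if (is.na(zero_fill_factor) || zero_fill_factor < 1L)
    stop("`zero_fill_factor` must be an integer >= 1", call. = FALSE)
  structure(list(apodization = apodization,
                 zero_fill_factor = zero_fill_factor,
                 effective_points = effective_points,
                 residual_correction = residual_correction,
                 first_point_scale = first_point_scale,
                 spectrometer_freq_mhz = spectrometer_freq_mhz),
            class = "processing_params")
}

#' Process an interferogram into a real spectrum
#'
#' Pipeline: residual correction (SR interferograms only, time domain),
#' optional truncation to `effective_points`, apodization, first-point
#' scaling, zero filling to `2 * zero_fill_factor * N` complex points,
#' discrete Fourier transform, and frequency shift to a centred axis. The
#' real part is returned with the axis calibrated from the schedule's dwell
#' time; ppm values are offsets from the carrier at
#' `spectrometer_freq_mhz`.
#'
#' @param fid an `interferogram`.
#' @param params a [processing_params()] object.
#' @return An object of class `nmr_spectrum`: list with `intensity`,
#'   `axis_hz`, `axis_ppm` and `meta`.
#' @examples
#' sched <- build_schedule(sr_preset("hnca-conv"), "conventional")
#' sp <- process_interferogram(simulate_interferogram(
#'   spin_group(100, 35, 0.1), sched))
#' @export
process_interferogram <- function(fid, params = processing_params()) {
  stopifnot(inherits(fid, "interferogram"),
            inherits(params, "processing_params"))
  vals <- fid$values
  if (params$residual_correction && fid$schedule$mode == "sr" &&
      is.null(fid$windowed))
    vals <- vals * residual_correction_vector(fid$schedule)
  if (!is.null(params$effective_points)) {
    if (params$effective_points > length(vals))
      stop("`effective_points` exceeds the number of recorded increments",
           call. = FALSE)
    vals <- vals[seq_len(params$effective_points)]
  }
  n <- length(vals)
  if (params$apodization == "squared-cosine")
    vals <- vals * cos(pi * (0:(n - 1)) / (2 * n))^2
  vals[1] <- vals[1] * params$first_point_scale
  nfft <- 2L * params$zero_fill_factor * n
  padded <- c(vals, rep(0 + 0i, nfft - n))
  spec <- stats::fft(padded)
  half <- nfft %/% 2L
  spec <- spec[c((half + 1L):nfft, 1L:half)]
  dt <- fid$schedule$rows$t1_s[2] - fid$schedule$rows$t1_s[1]
  axis_hz <- ((0:(nfft - 1)) - half) / (nfft * dt)
  structure(list(intensity = Re(spec), axis_hz = axis_hz,
                 axis_ppm = axis_hz / params$spectrometer_freq_mhz,
                 meta = list(schedule_mode = fid$schedule$mode,
                             n_time_points = n, dwell_s = dt,
                             processing = params)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %.1f Hz/bin, %s acquisition\n",
              length(x$intensity), x$axis_hz[2] - x$axis_hz[1],
              x$meta$schedule_mode))
  invisible(x)
}

.window_idx <- function(spectrum, window_hz) {
  stopifnot(inherits(spectrum, "nmr_spectrum"), length(window_hz) == 2L)
  idx <- which(spectrum$axis_hz >= min(window_hz) &
               spectrum$axis_hz <= max(window_hz))
  if (length(idx) < 3L)
    stop("window contains fewer than 3 spectral points", call. = FALSE)
  idx
}

#' Full width at half maximum of the tallest peak in a window
#'
#' Locates the maximum inside the frequency window and finds the two
#' half-maximum crossings by linear interpolation between bins. The window
#' must bracket the peak: intensities at both window edges must lie below
#' half the maximum, otherwise an error is raised.
#'
#' @param spectrum an `nmr_spectrum`.
#' @param window_hz length-2 numeric, frequency interval in Hz.
#' @return FWHM in Hz.
#' @export
measure_fwhm <- function(spectrum, window_hz) {
  idx <- .window_idx(spectrum, window_hz)
  y <- spectrum$intensity[idx]
  x <- spectrum$axis_hz[idx]
  i <- which.max(y)
  if (i == 1L || i == length(y))
    stop("no interior maximum inside the window", call. = FALSE)
  half <- y[i] / 2
  if (y[1] >= half || y[length(y)] >= half)
    stop("half height is not bracketed inside the window; widen it",
         call. = FALSE)
  l <- max(which(y[1:i] < half))
  r <- i - 1L + min(which(y[i:length(y)] < half))
  xl <- x[l] + (half - y[l]) / (y[l + 1] - y[l]) * (x[l + 1] - x[l])
  xr <- x[r - 1] + (half - y[r - 1]) / (y[r] - y[r - 1]) * (x[r] - x[r - 1])
  xr - xl
}

# interior local maxima (strict on the left, non-strict on the right so a
# flat-topped pair counts once) above a relative threshold
.local_maxima <- function(y, rel_threshold) {
  n <- length(y)
  if (n < 3L) return(integer())
  thr <- rel_threshold * max(y)
  i <- 2:(n - 1)
  i[y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] > thr]
}

#' Count resolved components in a window
#'
#' Number of interior local maxima above `rel_threshold` times the window
#' maximum — e.g. 1 for a decoupled singlet, 2 for a residual doublet, and
#' 2 or more for the glycine artifact of an SR schedule applied to an
#' uncoupled spin.
#'
#' @inheritParams measure_fwhm
#' @param rel_threshold fraction of the window maximum below which local
#'   maxima are ignored.
#' @return Integer count.
#' @export
count_components <- function(spectrum, window_hz, rel_threshold = 0.1) {
  idx <- .window_idx(spectrum, window_hz)
  length(.local_maxima(spectrum$intensity[idx], rel_threshold))
}

#' Estimate a doublet splitting
#'
#' Frequency separation of the two tallest resolved components in the
#' window; with linear (bin-level) peak positions the expected accuracy is
#' one digital-resolution bin.
#'
#' @inheritParams count_components
#' @return Splitting in Hz.
#' @export
estimate_splitting <- function(spectrum, window_hz, rel_threshold = 0.2) {
  idx <- .window_idx(spectrum, window_hz)
  y <- spectrum$intensity[idx]
  peaks <- .local_maxima(y, rel_threshold)
  if (length(peaks) < 2L)
    stop("fewer than two components found in the window", call. = FALSE)
  top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  abs(diff(spectrum$axis_hz[idx][top2]))
}

#' Digital resolution of a spectrum
#'
#' @param spectrum an `nmr_spectrum`.
#' @return Width of one frequency bin, Hz.
#' @export
spectral_bin_hz <- function(spectrum) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  spectrum$axis_hz[2] - spectrum$axis_hz[1]
}
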