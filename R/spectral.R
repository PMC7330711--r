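# Frequency-domain zero-phase filtering and analytic-signal construction.
#
# Filters are applied multiplicatively in the Fourier domain with
# raised-cosine transition bands, which is exactly zero phase and remains
# well conditioned for narrow bands near DC where polynomial IIR designs
# lose precision. The price is a circular edge transient, handled by an
# explicit transient margin that downstream windowing skips.

# Raised-cosine band-pass gain at (nonnegative) frequencies f.
# Passband [f_low, f_high], cosine ramps of width `taper` on both sides;
# the lower ramp is clipped at 0 Hz.
.bp_gain <- function(f, f_low, f_high, taper) {
  lo0 <- max(f_low - taper, 0)
  g <- numeric(length(f))
  g[f >= f_low & f <= f_high] <- 1
  if (f_low > lo0) {
    i <- f > lo0 & f < f_low
    g[i] <- 0.5 * (1 - cos(pi * (f[i] - lo0) / (f_low - lo0)))
  }
  i <- f > f_high & f < f_high + taper
  g[i] <- 0.5 * (1 + cos(pi * (f[i] - f_high) / taper))
  g
}

# Apply a frequency-domain gain (defined on 0..Nyquist) to the columns of a
# T x k real matrix; gain is mirrored onto negative frequencies so the
# output is real.
.fft_apply <- function(x, fs, gain_fun) {
  n <- nrow(x)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)                      # fold onto [0, fs/2]
  g <- gain_fun(f)
  X <- stats::mvfft(x)
  Re(stats::mvfft(X * g, inverse = TRUE)) / n
}

# Transient margin (samples) for a raised-cosine transition of width
# `taper` Hz: the impulse-response energy is concentrated within ~1/taper
# seconds of the origin; twice that is excluded on each edge.
.transient_samples <- function(fs, taper) as.integer(ceiling(2 / taper * fs))

#' Zero-phase band-pass filter
#'
#' Filters every ROI of a [roi_timeseries()] into one frequency band with a
#' zero-phase frequency-domain filter (raised-cosine transitions of width
#' `taper` Hz). The returned series carries a `transient` attribute: the
#' number of samples at each edge contaminated by the filter edge response,
#' which window construction must skip (see [make_windows()]).
#'
#' @param ts A [roi_timeseries()].
#' @param band A [band_spec()] or canonical band name.
#' @param taper Transition-band width in Hz (default 0.5).
#' @return A [roi_timeseries()] of identical shape with attributes
#'   `band` (the [band_spec()]) and `transient` (samples per edge).
#' @export
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(2 * 1000), 2), fs = 250)
#' xb <- bandpass(ts, "alpha")
#' attr(xb, "transient")
bandpass <- function(ts, band, taper = 0.5) {
  stopifnot(inherits(ts, "roi_timeseries"))
  band <- as_band_spec(band)
  nyq <- ts$fs / 2
  if (band$f_high + taper >= nyq) {
    stop("band '", band$name, "' (upper edge ", band$f_high, " Hz + taper ",
         taper, " Hz) requires fs > ", 2 * (band$f_high + taper),
         " Hz; fs is ", ts$fs, call. = FALSE)
  }
  margin <- .transient_samples(ts$fs, taper)
  if (ncol(ts$data) <= 2L * margin) {
    stop("recording of ", ncol(ts$data), " samples is shorter than twice the ",
         "filter transient margin (", margin, " samples per edge)",
         call. = FALSE)
  }
  y <- .fft_apply(t(ts$data), ts$fs,
                  function(f) .bp_gain(f, band$f_low, band$f_high, taper))
  out <- roi_timeseries(t(y), fs = ts$fs, labels = ts$labels,
                        subject_id = ts$subject_id, group = ts$group)
  attr(out, "band") <- band
  attr(out, "transient") <- margin
  out
}

#' Analytic signal via the Hilbert transform
#'
#' Extends each (already band-limited) real ROI series `x(t)` to its complex
#' analytic signal `X(t) = x(t) + i H[x](t)` using the standard FFT
#' construction (zeroing negative frequencies, doubling positive ones). The
#' modulus `|X|` is the power envelope.
#'
#' @param ts_banded A band-limited [roi_timeseries()], typically the output
#'   of [bandpass()].
#' @return An object of class `analytic_signal`: list with complex matrix
#'   `data` (n_rois x n_samples), `fs`, `labels`, `band`, `transient`,
#'   `subject_id`, `group`.
#' @export
analytic <- function(ts_banded) {
  stopifnot(inherits(ts_banded, "roi_timeseries"))
  x <- t(ts_banded$data)                    # time in rows for mvfft
  n <- nrow(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[2L:((n + 1L) / 2L)] <- 2
  }
  Z <- stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
  structure(list(data = t(Z), fs = ts_banded$fs, labels = ts_banded$labels,
                 band = attr(ts_banded, "band"),
                 transient = attr(ts_banded, "transient") %||% 0L,
                 subject_id = ts_banded$subject_id, group = ts_banded$group),
            class = "analytic_signal")
}

#' @export
print.analytic_signal <- function(x, ...) {
  bn <- if (is.null(x$band)) "?" else x$band$name
  cat(sprintf("<analytic_signal> %d ROIs x %d samples @ %g Hz, band %s\n",
              nrow(x$data), ncol(x$data), x$fs, bn))
  invisible(x)
}

#' Fused band-pass + analytic signal
#'
#' Computes `analytic(bandpass(ts, band, taper))` with a single pair of
#' FFTs by applying the band gain and the analytic-signal weights in one
#' frequency-domain pass; the result is identical (to rounding) to the
#' two-step composition and carries the same `transient` margin.
#'
#' @inheritParams bandpass
#' @return An `analytic_signal` (see [analytic()]).
#' @export
analytic_band <- function(ts, band, taper = 0.5) {
  stopifnot(inherits(ts, "roi_timeseries"))
  band <- as_band_spec(band)
  if (band$f_high + taper >= ts$fs / 2) {
    stop("band '", band$name, "' (upper edge ", band$f_high, " Hz + taper ",
         taper, " Hz) requires fs > ", 2 * (band$f_high + taper),
         " Hz; fs is ", ts$fs, call. = FALSE)
  }
  margin <- .transient_samples(ts$fs, taper)
  x <- t(ts$data)
  n <- nrow(x)
  if (n <= 2L * margin) {
    stop("recording of ", n, " samples is shorter than twice the filter ",
         "transient margin (", margin, " samples per edge)", call. = FALSE)
  }
  f <- (seq_len(n) - 1L) / n * ts$fs
  g <- .bp_gain(pmin(f, ts$fs - f), band$f_low, band$f_high, taper)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[2L:((n + 1L) / 2L)] <- 2
  }
  Z <- stats::mvfft(stats::mvfft(x) * (g * h), inverse = TRUE) / n
  structure(list(data = t(Z), fs = ts$fs, labels = ts$labels, band = band,
                 transient = margin, subject_id = ts$subject_id,
                 group = ts$group),
            class = "analytic_signal")
}

#' Sliding-window scheme
#'
#' @param window_s Window length in seconds (default 30).
#' @param stride_fraction Stride as a fraction of the window (default 1/6,
#'   i.e. 5 s for the default window).
#' @return An object of class `window_scheme`.
#' @export
window_scheme <- function(window_s = 30, stride_fraction = 1 / 6) {
  stopifnot(window_s > 0, stride_fraction > 0, stride_fraction <= 1)
  structure(list(window_s = window_s, stride_fraction = stride_fraction),
            class = "window_scheme")
}

#' Build sliding-window sample intervals
#'
#' Deterministic, 0-based, half-open intervals `[start, stop)` fully inside
#' `[offset, n_samples - offset)`. The window count is
#' `floor((n_usable - window) / stride) + 1`. For a 7-minute recording at
#' 1000 Hz with the default 30 s / 5 s scheme and no offset this yields 79
#' windows.
#'
#' @param n_samples Total number of samples in the recording.
#' @param fs Sampling rate (Hz).
#' @param scheme A [window_scheme()].
#' @param offset Samples to skip at each edge (e.g. the `transient`
#'   attribute of [bandpass()] output). Default 0.
#' @return A data frame with integer columns `start`, `stop` (0-based,
#'   half-open).
#' @export
#' @examples
#' nrow(make_windows(420000, 1000))  # 79
make_windows <- function(n_samples, fs, scheme = window_scheme(), offset = 0L) {
  stopifnot(inherits(scheme, "window_scheme"))
  offset <- as.integer(offset)
  wlen <- as.integer(round(scheme$window_s * fs))
  stride <- max(1L, as.integer(round(wlen * scheme$stride_fraction)))
  usable <- n_samples - 2L * offset
  if (usable < wlen) {
    stop("recording too short for windowing: ", usable,
         " usable samples after trimming, but one ", scheme$window_s,
         " s window needs ", wlen, " samples", call. = FALSE)
  }
  nw <- (usable - wlen) %/% stride + 1L
  start <- offset + (seq_len(nw) - 1L) * stride
  data.frame(start = start, stop = start + wlen)
}
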