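# Band decomposition: zero-phase FIR bandpass filtering followed by the
# analytic signal (FFT Hilbert transform) to obtain instantaneous phase and
# amplitude.

#' Frequency band specification
#'
#' @param center_hz band center in Hz.
#' @param bandwidth_hz full bandwidth in Hz. Defaults to 2 Hz for phase bands
#'   and, for amplitude bands, to twice the modulating frequency supplied via
#'   `phase_center_hz`.
#' @param role `"phase"` or `"amplitude"` — which quantity the band is
#'   extracted for.
#' @param phase_center_hz for `role = "amplitude"`, the modulating (phase)
#'   frequency used to derive the default bandwidth.
#' @return an object of class `pcfc_band_spec` with fields `center_hz`,
#'   `bandwidth_hz`, `role`.
#' @export
#' @examples
#' band_spec(13, role = "phase")
#' band_spec(150, role = "amplitude", phase_center_hz = 13)
band_spec <- function(center_hz, bandwidth_hz = NULL,
                      role = c("phase", "amplitude"),
                      phase_center_hz = NULL) {
  role <- match.arg(role)
  check_number(center_hz, "center_hz", lower = 1e-9)
  if (is.null(bandwidth_hz)) {
    bandwidth_hz <- if (role == "phase") {
      2
    } else {
      if (is.null(phase_center_hz)) {
        abort(paste("amplitude bands need `bandwidth_hz` or",
                    "`phase_center_hz` to derive the default bandwidth."),
              class = "pcfc_invalid_band")
      }
      2 * phase_center_hz
    }
  }
  check_number(bandwidth_hz, "bandwidth_hz", lower = 1e-9)
  if (center_hz - bandwidth_hz / 2 <= 0) {
    abort("band must lie strictly above 0 Hz.", class = "pcfc_invalid_band")
  }
  structure(list(center_hz = center_hz, bandwidth_hz = bandwidth_hz,
                 role = role),
            class = "pcfc_band_spec")
}

#' @export
print.pcfc_band_spec <- function(x, ...) {
  cat(sprintf("<pcfc_band_spec> %s band %g-%g Hz\n", x$role,
              x$center_hz - x$bandwidth_hz / 2,
              x$center_hz + x$bandwidth_hz / 2))
  invisible(x)
}

# Windowed-sinc (Hamming) FIR order: 3 cycles of the lower band edge,
# rounded up to even so the filter has integer group delay.
fir_order <- function(sampling_rate_hz, lower_edge_hz) {
  ord <- ceiling(3 * sampling_rate_hz / lower_edge_hz)
  if (ord %% 2 == 1) ord <- ord + 1
  ord
}

# Number of samples dropped from each record end after forward-backward
# filtering: one filter length (order + 1).
filter_margin <- function(sampling_rate_hz, band) {
  fir_order(sampling_rate_hz, band$center_hz - band$bandwidth_hz / 2) + 1L
}

#' Zero-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) FIR bandpass applied forward and backward
#' (`signal::filtfilt`), giving zero group delay. The filter order is
#' `3 * sampling_rate_hz / lower_band_edge`, rounded up to even.
#'
#' @param x numeric series.
#' @param band a [band_spec()].
#' @param sampling_rate_hz sampling rate in Hz.
#' @return filtered numeric series, same length as `x`. One filter length at
#'   each end is contaminated by edge effects; downstream coupling statistics
#'   exclude it (see [decompose()]).
#' @export
#' @examples
#' fs <- 500
#' x <- sin(2 * pi * 13 * seq(0, 4, by = 1 / fs))
#' y <- bandpass_zero_phase(x, band_spec(13, role = "phase"), fs)
bandpass_zero_phase <- function(x, band, sampling_rate_hz) {
  stopifnot(inherits(band, "pcfc_band_spec"))
  check_numeric_vector(x, "x", min_length = 2L)
  check_number(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  lo <- band$center_hz - band$bandwidth_hz / 2
  hi <- band$center_hz + band$bandwidth_hz / 2
  nyq <- sampling_rate_hz / 2
  if (lo <= 0 || hi >= nyq) {
    abort(sprintf("band [%g, %g] Hz must lie inside (0, %g) Hz.", lo, hi, nyq),
          class = "pcfc_invalid_band")
  }
  ord <- fir_order(sampling_rate_hz, lo)
  if (length(x) < 3 * (ord + 1)) {
    abort(sprintf(paste("record too short for this band: need at least 3",
                        "filter lengths (%d samples), got %d."),
                  3 * (ord + 1), length(x)),
          class = "pcfc_insufficient_data")
  }
  b <- signal::fir1(ord, c(lo, hi) / nyq, type = "pass")
  signal::filtfilt(as.numeric(b), 1, x)
}

# Analytic signal via the FFT Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude in a band
#'
#' Bandpasses `x` with [bandpass_zero_phase()] and takes the analytic signal:
#' phase is its angle (cosine convention: phase 0 at the positive peak),
#' amplitude its magnitude.
#'
#' @inheritParams bandpass_zero_phase
#' @return a tibble of class `pcfc_decomposition` with columns `sample`,
#'   `phase_rad` (in `[-pi, pi)`) and `amplitude` (non-negative), plus
#'   attributes `band`, `sampling_rate_hz` and `valid_range` — the inclusive
#'   sample interval unaffected by filter edge artifacts (one filter length
#'   trimmed at each end).
#' @export
#' @examples
#' fs <- 500
#' x <- sin(2 * pi * 13 * seq(0, 4, by = 1 / fs))
#' d <- decompose(x, band_spec(13, role = "phase"), fs)
decompose <- function(x, band, sampling_rate_hz) {
  xf <- bandpass_zero_phase(x, band, sampling_rate_hz)
  a <- analytic_signal(xf)
  ph <- Arg(a)
  ph[ph >= pi] <- -pi  # wrap the single boundary angle into [-pi, pi)
  margin <- filter_margin(sampling_rate_hz, band)
  out <- tibble::tibble(sample = seq_along(x), phase_rad = ph,
                        amplitude = Mod(a))
  attr(out, "band") <- band
  attr(out, "sampling_rate_hz") <- sampling_rate_hz
  attr(out, "valid_range") <- c(margin + 1L, length(x) - margin)
  class(out) <- c("pcfc_decomposition", class(out))
  out
}

#' @export
print.pcfc_decomposition <- function(x, ...) {
  b <- attr(x, "band")
  vr <- attr(x, "valid_range")
  cat(sprintf("<pcfc_decomposition> %s band %g Hz (bw %g), valid %d..%d\n",
              b$role, b$center_hz, b$bandwidth_hz, vr[1], vr[2]))
  NextMethod()
}
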