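# Paired-signal simulators: two validation datasets in which a low-frequency
# rhythm in channel x modulates high-frequency amplitude in channel y, either
# confounded by simultaneous same-frequency phase coupling (dataset 1) or
# genuinely cross-regional with the coupling mechanisms separated in time
# (dataset 2). Sinusoidal and LFP-like waveform variants.

#' Simulation specification
#'
#' Bundles every parameter of the paired-signal generators. Records are built
#' from three equal-length segments; within each segment, each "seed role"
#' (the two low-frequency oscillators) draws a fresh frequency
#' \eqn{f_l \sim N(\mu, \sigma^2)} and a time offset
#' \eqn{\tau \sim N(0, 1/f_l)}.
#'
#' @param duration_s record duration in seconds (default 30).
#' @param sampling_rate_hz sampling rate in Hz (default 1000); must exceed
#'   twice `f_high_hz`.
#' @param f_low_mean_hz mean of the modulating frequency draw (default 13).
#' @param f_low_sd_hz standard deviation of the modulating frequency draw
#'   (default 1).
#' @param f_high_hz modulated carrier frequency in Hz (default 150).
#' @param mod_depth modulation depth `k` applied to the high-frequency term
#'   (default 1).
#' @param phase_offset_rad constant phase offset between the two channels'
#'   low-frequency components (default `pi/4`).
#' @param noise_sd standard deviation of the additive background (default 1).
#'   For the sinusoidal waveform this is i.i.d. Gaussian noise; for the
#'   LFP-like waveform it scales the unit-RMS background of
#'   [lfp_background()].
#' @param waveform `"sinusoid"` or `"lfp_like"`.
#' @param white_power_fraction for `waveform = "lfp_like"`, the fraction of
#'   background power carried by Gaussian white noise, the remainder by the
#'   aperiodic 1/f component (default 0.5).
#' @param n_lfp_components number of sinusoids summed into the aperiodic
#'   background (default 1000).
#' @param seed integer seed for reproducible draws, or `NULL` to use the
#'   current RNG state.
#'
#' @return an object of class `pcfc_sim_spec`.
#' @seealso [simulate_dataset1()], [simulate_dataset2()], [lfp_background()]
#' @export
#' @examples
#' spec <- sim_spec(duration_s = 10, seed = 1)
#' sig <- simulate_dataset2(spec)
sim_spec <- function(duration_s = 30,
                     sampling_rate_hz = 1000,
                     f_low_mean_hz = 13,
                     f_low_sd_hz = 1,
                     f_high_hz = 150,
                     mod_depth = 1,
                     phase_offset_rad = pi / 4,
                     noise_sd = 1,
                     waveform = c("sinusoid", "lfp_like"),
                     white_power_fraction = 0.5,
                     n_lfp_components = 1000,
                     seed = NULL) {
  waveform <- match.arg(waveform)
  check_number(duration_s, "duration_s", lower = 1e-9)
  check_number(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  check_number(f_high_hz, "f_high_hz", lower = 1e-9)
  if (sampling_rate_hz <= 2 * f_high_hz) {
    abort("`sampling_rate_hz` must exceed twice `f_high_hz` (Nyquist).",
          class = "pcfc_invalid_spec")
  }
  check_number(f_low_mean_hz, "f_low_mean_hz", lower = 1e-9)
  check_number(f_low_sd_hz, "f_low_sd_hz", lower = 0)
  check_number(mod_depth, "mod_depth", lower = 0)
  check_number(phase_offset_rad, "phase_offset_rad")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(white_power_fraction, "white_power_fraction", lower = 0,
               upper = 1)
  check_number(n_lfp_components, "n_lfp_components", lower = 1)
  if (!is.null(seed)) check_number(seed, "seed")
  structure(
    list(duration_s = duration_s,
         sampling_rate_hz = sampling_rate_hz,
         f_low_mean_hz = f_low_mean_hz,
         f_low_sd_hz = f_low_sd_hz,
         f_high_hz = f_high_hz,
         mod_depth = mod_depth,
         phase_offset_rad = phase_offset_rad,
         noise_sd = noise_sd,
         waveform = waveform,
         white_power_fraction = white_power_fraction,
         n_lfp_components = as.integer(n_lfp_components),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "pcfc_sim_spec"
  )
}

#' @export
print.pcfc_sim_spec <- function(x, ...) {
  cat("<pcfc_sim_spec>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  }
  invisible(x)
}

# Raw aperiodic + white background, unit RMS; caller handles seeding.
lfp_background_raw <- function(n, fs, white_power_fraction, n_components) {
  t <- (0:(n - 1)) / fs
  f <- runif(n_components, 1, 200)
  a <- 1 / f
  ph <- runif(n_components, 0, 2 * pi)
  ap <- numeric(n)
  for (i in seq_len(n_components)) {
    ap <- ap + a[i] * sin(2 * pi * f[i] * t + ph[i])
  }
  ap <- ap / sqrt(mean(ap^2)) * sqrt(1 - white_power_fraction)
  bg <- ap + rnorm(n, 0, sqrt(white_power_fraction))
  bg / sqrt(mean(bg^2))
}

#' LFP-like background series
#'
#' Sum of `n_lfp_components` sinusoids with frequencies drawn uniformly from
#' 1--200 Hz, amplitudes inversely proportional to frequency, and independent
#' uniform phases, plus Gaussian white noise; the composite is normalized to
#' unit root-mean-square. In LFP-like datasets this background replaces the
#' pure white noise term, scaled by `noise_sd`.
#'
#' @param spec a [sim_spec()] with `waveform = "lfp_like"`.
#' @return a tibble with columns `time_s` and `value`; RMS of `value` is 1.
#' @export
#' @examples
#' bg <- lfp_background(sim_spec(duration_s = 2, waveform = "lfp_like",
#'                               seed = 1))
#' sqrt(mean(bg$value^2))
lfp_background <- function(spec) {
  stopifnot(inherits(spec, "pcfc_sim_spec"))
  if (spec$waveform != "lfp_like") {
    abort("`lfp_background()` requires a spec with waveform = \"lfp_like\".",
          class = "pcfc_invalid_spec")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- round(spec$duration_s * spec$sampling_rate_hz)
  v <- lfp_background_raw(n, spec$sampling_rate_hz,
                          spec$white_power_fraction, spec$n_lfp_components)
  tibble::tibble(time_s = (0:(n - 1)) / spec$sampling_rate_hz, value = v)
}

# Shared generator core for both datasets.
simulate_dataset <- function(spec, dataset) {
  stopifnot(inherits(spec, "pcfc_sim_spec"), dataset %in% c(1L, 2L))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  fs <- spec$sampling_rate_hz
  n <- round(spec$duration_s * fs)
  t <- (0:(n - 1)) / fs
  T_ <- spec$duration_s
  segs <- list(t < T_ / 3, t >= T_ / 3 & t < 2 * T_ / 3, t >= 2 * T_ / 3)
  k <- spec$mod_depth
  phi <- spec$phase_offset_rad
  draw <- function() {
    f <- rnorm(1, spec$f_low_mean_hz, spec$f_low_sd_hz)
    list(f = f, tau = rnorm(1, 0, 1 / f))
  }
  hi <- function(tt) sin(2 * pi * spec$f_high_hz * tt)
  lw <- function(tt, d, ph = 0) sin(2 * pi * d$f * (tt + d$tau) + ph)
  x <- numeric(n)
  y <- numeric(n)
  draws <- vector("list", 3)
  for (g in 1:3) {
    d1 <- draw()
    d2 <- draw()
    draws[[g]] <- tibble::tibble(segment = g, role = c(1L, 2L),
                                 f_hz = c(d1$f, d2$f),
                                 tau_s = c(d1$tau, d2$tau))
    s <- segs[[g]]
    tt <- t[s]
    if (dataset == 1L) {
      # Confounded: in segment 2, x-y phase coupling and focal CFC in y
      # happen simultaneously.
      if (g == 1L) { x[s] <- lw(tt, d1); y[s] <- lw(tt, d2) + k * hi(tt) }
      if (g == 2L) { x[s] <- lw(tt, d1)
                     y[s] <- lw(tt, d1, phi) + k * lw(tt, d1, phi) * hi(tt) }
      if (g == 3L) { x[s] <- lw(tt, d2); y[s] <- lw(tt, d1) + k * hi(tt) }
    } else {
      # Genuine cross-regional CFC (segment 1), phase coupling (segment 2)
      # and focal CFC (segment 3) occupy non-overlapping thirds.
      if (g == 1L) { x[s] <- lw(tt, d1)
                     y[s] <- lw(tt, d2, phi) + k * lw(tt, d1, phi) * hi(tt) }
      if (g == 2L) { x[s] <- lw(tt, d1); y[s] <- lw(tt, d1) + k * hi(tt) }
      if (g == 3L) { x[s] <- lw(tt, d1)
                     y[s] <- lw(tt, d2, phi) + k * lw(tt, d2, phi) * hi(tt) }
    }
  }
  if (spec$waveform == "sinusoid") {
    x <- x + rnorm(n, 0, spec$noise_sd)
    y <- y + rnorm(n, 0, spec$noise_sd)
  } else {
    x <- x + spec$noise_sd *
      lfp_background_raw(n, fs, spec$white_power_fraction,
                         spec$n_lfp_components)
    y <- y + spec$noise_sd *
      lfp_background_raw(n, fs, spec$white_power_fraction,
                         spec$n_lfp_components)
  }
  out <- tibble::tibble(time_s = t, x = x, y = y)
  attr(out, "sampling_rate_hz") <- fs
  attr(out, "segment_boundaries") <- c(sum(segs[[1]]),
                                       sum(segs[[1]]) + sum(segs[[2]]))
  attr(out, "truth") <- if (dataset == 1L) "dataset1_confounded" else
    "dataset2_true"
  attr(out, "segment_draws") <- dplyr::bind_rows(draws)
  attr(out, "spec") <- spec
  class(out) <- c("pcfc_signals", class(out))
  out
}

#' Simulate the confounded paired dataset (dataset 1)
#'
#' Channel y always carries a high-frequency component; in the middle third of
#' the record, x and y are phase-coupled at the shared low frequency at the
#' same time as y's own low-frequency phase modulates y's high-frequency
#' amplitude. The apparent cross-regional phase-amplitude coupling between
#' x's phase and y's amplitude is therefore entirely attributable to the
#' local (within-y) coupling routed through the same-frequency phase link —
#' the textbook back-door path.
#'
#' @param spec a [sim_spec()].
#' @return a `pcfc_signals` tibble with columns `time_s`, `x`, `y` and
#'   attributes `sampling_rate_hz`, `segment_boundaries` (last sample index of
#'   segments 1 and 2), `truth`, `spec`, and `segment_draws` (tibble of the
#'   per-segment frequency/offset draws for each oscillator role).
#' @export
#' @examples
#' sig <- simulate_dataset1(sim_spec(duration_s = 6, seed = 1))
simulate_dataset1 <- function(spec) simulate_dataset(spec, 1L)

#' Simulate the genuinely coupled paired dataset (dataset 2)
#'
#' The three coupling mechanisms are separated in time: genuine cross-regional
#' phase-amplitude coupling from x's phase to y's amplitude (first third),
#' same-frequency x-y phase coupling (middle third), and focal within-y
#' coupling (final third). Because phase coupling and cross-regional CFC never
#' overlap, the back-door path is inactive and the cross-regional coupling is
#' real.
#'
#' @inheritParams simulate_dataset1
#' @return a `pcfc_signals` tibble; see [simulate_dataset1()].
#' @export
#' @examples
#' sig <- simulate_dataset2(sim_spec(duration_s = 6, seed = 1))
simulate_dataset2 <- function(spec) simulate_dataset(spec, 2L)

#' @export
print.pcfc_signals <- function(x, ...) {
  cat(sprintf("<pcfc_signals> %s, %d samples @ %g Hz\n",
              attr(x, "truth"), nrow(x), attr(x, "sampling_rate_hz")))
  NextMethod()
}
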