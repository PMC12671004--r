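# Simulators: structure, seeding, segment plan, envelope content.

test_that("paired signals have matching lengths and exact third boundaries", {
  spec <- sim_spec(duration_s = 9, sampling_rate_hz = 600, seed = 3)
  for (sig in list(simulate_dataset1(spec), simulate_dataset2(spec))) {
    expect_equal(nrow(sig), 9 * 600)
    expect_equal(length(sig$x), length(sig$y))
    sb <- attr(sig, "segment_boundaries")
    expect_equal(sb, c(1800L, 3600L))
    expect_equal(attr(sig, "sampling_rate_hz"), 600)
  }
})

test_that("truth labels follow the constructor contract", {
  spec <- sim_spec(duration_s = 3, sampling_rate_hz = 400, seed = 1)
  expect_identical(attr(simulate_dataset1(spec), "truth"),
                   "dataset1_confounded")
  expect_identical(attr(simulate_dataset2(spec), "truth"), "dataset2_true")
})

test_that("same seed reproduces, different seeds differ", {
  a <- simulate_dataset2(sim_spec(duration_s = 2, sampling_rate_hz = 500,
                                  seed = 11))
  b <- simulate_dataset2(sim_spec(duration_s = 2, sampling_rate_hz = 500,
                                  seed = 11))
  c <- simulate_dataset2(sim_spec(duration_s = 2, sampling_rate_hz = 500,
                                  seed = 12))
  expect_identical(a$y, b$y)
  expect_false(isTRUE(all.equal(a$y, c$y)))
})

test_that("spec validation rejects impossible parameters", {
  expect_error(sim_spec(duration_s = -1), class = "pcfc_error")
  expect_error(sim_spec(sampling_rate_hz = 250, f_high_hz = 150),
               class = "pcfc_invalid_spec")
  expect_error(sim_spec(mod_depth = -0.1), class = "pcfc_error")
  expect_error(sim_spec(noise_sd = -1), class = "pcfc_error")
})

test_that("per-segment oscillator draws are recorded and plausible", {
  draws <- purrr::map_dfr(1:40, function(s) {
    attr(simulate_dataset1(sim_spec(duration_s = 0.3,
                                    sampling_rate_hz = 400, seed = s)),
         "segment_draws")
  })
  expect_equal(nrow(draws), 40 * 6)
  # f ~ N(13, 1): moments of 240 pooled draws
  expect_lt(abs(mean(draws$f_hz) - 13), 0.35)
  expect_lt(abs(sd(draws$f_hz) - 1), 0.3)
  # fresh draws per segment: within a record, segments differ
  one <- attr(simulate_dataset1(sim_spec(duration_s = 0.3,
                                         sampling_rate_hz = 400, seed = 5)),
              "segment_draws")
  expect_gt(length(unique(one$f_hz)), 3)
})

test_that("k = 0 removes all high-frequency content from y", {
  spec <- sim_spec(duration_s = 4, sampling_rate_hz = 1000, mod_depth = 0,
                   noise_sd = 0, seed = 2)
  sig <- simulate_dataset1(spec)
  hf <- bandpass_zero_phase(sig$y, band_spec(150, 26, role = "amplitude"),
                            1000)
  # segment joins at samples ~1334 and ~2667 produce broadband transients
  # even in a noise-free record; test away from joins and edges
  away <- c(500:1200, 1500:2500, 2800:3500)
  expect_lt(max(abs(hf[away])), 1e-4)
})

test_that("dataset-2 middle segment phase-locks x and y at the shared draw", {
  spec <- sim_spec(duration_s = 9, sampling_rate_hz = 1000, noise_sd = 0,
                   seed = 4)
  sig <- simulate_dataset2(spec)
  d <- attr(sig, "segment_draws")
  f <- d$f_hz[d$segment == 2 & d$role == 1]
  seg <- 3001:6000
  band <- band_spec(f, 2, role = "phase")
  px <- decompose(sig$x[seg], band, 1000)
  py <- decompose(sig$y[seg], band, 1000)
  vr <- attr(px, "valid_range")
  keep <- vr[1]:vr[2]
  dphi <- Arg(exp(1i * (py$phase_rad[keep] - px$phase_rad[keep])))
  # dataset 2, segment 2: y carries x's low-frequency component with no
  # offset, so the phase difference is constant at ~0
  expect_lt(sd(dphi), 0.05)
  expect_lt(abs(mean(dphi)), 0.05)
})

test_that("dataset-1 middle segment locks with the configured offset", {
  spec <- sim_spec(duration_s = 9, sampling_rate_hz = 1000, noise_sd = 0,
                   phase_offset_rad = pi / 4, seed = 6)
  sig <- simulate_dataset1(spec)
  d <- attr(sig, "segment_draws")
  f <- d$f_hz[d$segment == 2 & d$role == 1]
  seg <- 3001:6000
  band <- band_spec(f, 2, role = "phase")
  px <- decompose(sig$x[seg], band, 1000)
  py <- decompose(sig$y[seg], band, 1000)
  vr <- attr(px, "valid_range")
  keep <- vr[1]:vr[2]
  dphi <- Arg(exp(1i * (py$phase_rad[keep] - px$phase_rad[keep])))
  expect_lt(sd(dphi), 0.1)
  expect_lt(abs(mean(dphi) - pi / 4), 0.1)
})

test_that("dataset-2 final-segment envelope follows the local modulator", {
  spec <- sim_spec(duration_s = 9, sampling_rate_hz = 1000, noise_sd = 0,
                   seed = 8)
  sig <- simulate_dataset2(spec)
  d <- attr(sig, "segment_draws")
  f2 <- d$f_hz[d$segment == 3 & d$role == 2]
  tau2 <- d$tau_s[d$segment == 3 & d$role == 2]
  seg <- 6001:9000
  t <- sig$time_s[seg]
  # rectification + lowpass envelope oracle on the high-frequency part
  hf <- bandpass_zero_phase(sig$y[seg], band_spec(150, 26,
                                                  role = "amplitude"), 1000)
  env <- as.numeric(stats::filter(abs(hf), rep(1 / 21, 21)))
  keep <- 600:2400
  # the modulated term is k * m(t) * carrier with m(t) = sin(2 pi f (t+tau)
  # + phi); its envelope is |m(t)| (the modulator's sign flips the carrier
  # phase instead of the envelope)
  modulator <- sin(2 * pi * f2 * (t + tau2) + spec$phase_offset_rad)
  expect_gt(cor(env[keep], abs(modulator)[keep]), 0.95)
  expect_lt(abs(cor(env[keep], modulator[keep])), 0.5)
})

test_that("LFP background is unit-RMS, 1/f-sloped, and seed-stable", {
  spec <- sim_spec(duration_s = 4, sampling_rate_hz = 1000,
                   waveform = "lfp_like", seed = 9)
  bg <- lfp_background(spec)
  expect_equal(sqrt(mean(bg$value^2)), 1, tolerance = 1e-9)
  # periodogram slope on log-log axes over 2-100 Hz is negative
  n <- nrow(bg)
  pw <- Mod(fft(bg$value))^2 / n
  freq <- (0:(n - 1)) * 1000 / n
  sel <- freq >= 2 & freq <= 100
  fit <- lm(log(pw[sel]) ~ log(freq[sel]))
  expect_lt(coef(fit)[2], -1)
  bg2 <- lfp_background(spec)
  expect_identical(bg$value, bg2$value)
  bg3 <- lfp_background(sim_spec(duration_s = 4, sampling_rate_hz = 1000,
                                 waveform = "lfp_like", seed = 10))
  expect_false(isTRUE(all.equal(bg$value, bg3$value)))
})

test_that("lfp_background requires the lfp_like waveform", {
  expect_error(lfp_background(sim_spec(seed = 1)),
               class = "pcfc_invalid_spec")
})

test_that("segment-local ground truth: focal CFC lives in segment 3", {
  # MI(phi_y, A_y) on segment 3 of dataset 2 beats its surrogate null;
  # on segment 1 it does not (no local coupling there).
  spec <- sim_spec(duration_s = 18, sampling_rate_hz = 1000, seed = 13)
  sig <- simulate_dataset2(spec)
  seg_p <- function(idx, seed) {
    y <- sig$y[idx]
    d_ph <- decompose(y, band_spec(13, 2, role = "phase"), 1000)
    d_am <- decompose(y, band_spec(150, 26, role = "amplitude"), 1000)
    vr <- attr(d_ph, "valid_range")
    keep <- vr[1]:vr[2]
    by <- bin_phases(d_ph$phase_rad[keep], 18)
    amp <- d_am$amplitude[keep]
    cfg <- surrogate_config(n_surrogates = 99, min_shift_s = 1, seed = seed)
    null <- vapply(1:99, function(dr) {
      suppressWarnings(modulation_index(
        time_shift_surrogate(amp, cfg, dr, 1000), by, 18)$value)
    }, numeric(1))
    obs <- suppressWarnings(modulation_index(amp, by, 18)$value)
    permutation_pvalue(obs, null)
  }
  expect_lte(seg_p(12001:18000, seed = 21), 0.05)
  expect_gt(seg_p(1:6000, seed = 22), 0.05)
})
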