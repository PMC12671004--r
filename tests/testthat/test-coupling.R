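# MI / PMI metrics and their oracles.

test_that("bin edges follow the half-open convention", {
  b <- phase_binning(18)
  expect_equal(bin_phases(-pi, b), 1L)
  expect_equal(bin_phases(pi * (1 - 1e-9), b), 18L)
  # 0 sits at the lower edge of the 10th of 18 bins
  expect_equal(bin_phases(0, b), 10L)
  expect_equal(bin_phases(-1e-12, b), 9L)
  expect_error(bin_phases(pi, b), class = "pcfc_contract_violation")
  expect_error(bin_phases(-3.2, b), class = "pcfc_contract_violation")
})

test_that("uniform phases fill bins evenly", {
  set.seed(1)
  n <- 90000
  bins <- bin_phases(runif_phase(n), 18)
  counts <- tabulate(bins, 18)
  expected <- n / 18
  sd4 <- 4 * sqrt(n * (1 / 18) * (17 / 18))
  expect_true(all(abs(counts - expected) < sd4))
})

test_that("MI endpoints are exact", {
  # uniform profile: constant amplitude in every bin
  expect_equal(modulation_index(rep(2.5, 180), rep(1:18, 10), 18)$value, 0)
  # point mass: all amplitude in one bin
  amp <- c(5, rep(0, 17))
  mi1 <- modulation_index(amp, 1:18, 18)
  expect_equal(mi1$value, 1)
})

test_that("MI matches the direct KL oracle on the [4,2,2,2] example", {
  amp <- c(4, 2, 2, 2)
  res <- modulation_index(amp, 1:4, 4)
  p <- c(0.4, 0.2, 0.2, 0.2)
  expect_equal(as.numeric(res$profile), p)
  kl <- sum(p * log(p / 0.25))
  expect_equal(res$value, kl / log(4))
  expect_equal(res$value, oracle_mi(amp, 1:4, 4))
})

test_that("MI is log-base invariant by construction", {
  set.seed(2)
  amp <- rexp(5000)
  bins <- bin_phases(runif_phase(5000), 18)
  res <- modulation_index(amp, bins, 18)
  p <- as.numeric(res$profile)
  h2 <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(res$value, (log2(18) - h2) / log2(18), tolerance = 1e-12)
})

test_that("empty bins warn and contribute zero mass; all-zero errors", {
  expect_warning(res <- modulation_index(c(1, 1), c(1L, 2L), 4),
                 class = "pcfc_empty_bins")
  expect_equal(as.numeric(res$detail$raw_mean[3:4]), c(0, 0))
  expect_error(modulation_index(rep(0, 10), rep(1:5, 2), 5),
               class = "pcfc_undefined_index")
})

test_that("MI and PMI are invariant to amplitude scaling", {
  set.seed(3)
  n <- 20000
  phx <- runif_phase(n)
  phy <- runif_phase(n)
  amp <- 1 + 0.4 * cos(phx) + 0.1 * rexp(n)
  m1 <- modulation_index(amp, bin_phases(phx, 18), 18)$value
  m2 <- modulation_index(amp * 37.5, bin_phases(phx, 18), 18)$value
  expect_equal(m1, m2, tolerance = 1e-12)
  p1 <- quiet_pmi(amp, phx, phy, 18)$value
  p2 <- quiet_pmi(amp * 37.5, phx, phy, 18)$value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("MI is invariant under consistent bin rotation", {
  set.seed(4)
  n <- 10000
  bins <- bin_phases(runif_phase(n), 18)
  amp <- 1 + 0.3 * cos(2 * pi * bins / 18) + 0.05 * rexp(n)
  m1 <- modulation_index(amp, bins, 18)$value
  rotated <- ((bins + 4L) %% 18L) + 1L
  m2 <- modulation_index(amp, rotated, 18)$value
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("joint table is diagonal under perfect locking, flat otherwise", {
  set.seed(5)
  bins <- sample(1:6, 3000, replace = TRUE)
  jt <- joint_mean_amplitude(rexp(3000), bins, bins, 6)
  offdiag <- jt$joint_counts[row(jt$joint_counts) != col(jt$joint_counts)]
  expect_true(all(offdiag == 0))
  bx <- sample(1:6, 6000, replace = TRUE)
  by <- sample(1:6, 6000, replace = TRUE)
  jt2 <- joint_mean_amplitude(rep(3.5, 6000), bx, by, 6)
  expect_true(all(abs(jt2$joint_means[jt2$joint_counts > 0] - 3.5) < 1e-12))
  expect_equal(sum(jt2$joint_counts), 6000)
  expect_equal(sum(jt2$phase_y_marginal), 1)
})

test_that("joint table matches hand enumeration on a 9-sample example", {
  amp <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  bx <- c(1, 1, 1, 2, 2, 3, 3, 3, 3)
  by <- c(1, 2, 1, 3, 3, 2, 2, 1, 2)
  jt <- joint_mean_amplitude(amp, bx, by, 3)
  expect_equal(jt$joint_means[1, 1], mean(c(1, 3)))
  expect_equal(jt$joint_means[1, 2], 2)
  expect_true(is.na(jt$joint_means[1, 3]))
  expect_equal(jt$joint_means[2, 3], mean(c(4, 5)))
  expect_equal(jt$joint_means[3, 1], 8)
  expect_equal(jt$joint_means[3, 2], mean(c(6, 7, 9)))
  expect_equal(jt$joint_counts[3, 2], 3L)
  expect_equal(jt$phase_y_marginal, c(3, 4, 2) / 9)
})

test_that("PMI equals the hand-evaluated back-door sum on an N=2 toy", {
  # joint samples over (x-bin, y-bin) with deterministic amplitudes
  centers <- c(-pi / 2, pi / 2)
  bx <- c(1, 1, 1, 2, 2, 2, 1, 2)
  by <- c(1, 2, 1, 1, 2, 2, 2, 1)
  amp <- c(2, 6, 2, 1, 3, 3, 6, 1)  # amp depends only on y-bin: 2 or 6 / 1 or 3
  res <- quiet_pmi(amp, centers[bx], centers[by], 2)
  pr_y <- c(4 / 8, 4 / 8)
  # mean amp per (i, j): (1,1)=2 (1,2)=6 (2,1)=1 (2,2)=3
  q <- c(pr_y[1] * 2 + pr_y[2] * 6, pr_y[1] * 1 + pr_y[2] * 3)
  p_adj <- q / sum(q)
  expect_equal(as.numeric(res$profile), p_adj)
  h <- -sum(p_adj * log(p_adj))
  expect_equal(res$value, (log(2) - h) / log(2))
})

test_that("PMI approximately equals MI when the confounder is disconnected", {
  set.seed(6)
  n <- 100000
  phx <- runif_phase(n)
  phy <- runif_phase(n)  # independent of phx; amp independent of phy
  amp <- 1 + 0.4 * cos(phx) + 0.2 * rexp(n)
  mi <- modulation_index(amp, bin_phases(phx, 18), 18)$value
  pmi <- quiet_pmi(amp, phx, phy, 18)$value
  expect_gt(mi, 0.001)
  expect_lt(abs(pmi - mi) / mi, 0.1)
})

test_that("PMI collapses on a pure fork/chain where MI stays large", {
  # 30 s noise-free construction: y's local phase drives A throughout;
  # x is phase-locked to y only in the middle third (same-frequency
  # coupling) and independent elsewhere — mirroring the confounded dataset.
  fs <- 1000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  n <- length(t)
  phy <- ((2 * pi * 13 * t + pi) %% (2 * pi)) - pi
  phx <- phy
  third <- n %/% 3
  out1 <- 1:third
  out3 <- (2 * third + 1):n
  phx[out1] <- ((2 * pi * 11.6 * t[out1] + pi) %% (2 * pi)) - pi
  phx[out3] <- ((2 * pi * 14.3 * t[out3] + 1.1 + pi) %% (2 * pi)) - pi
  amp <- 1 + 0.8 * cos(phy)
  mi <- modulation_index(amp, bin_phases(phx, 18), 18)$value
  pmi <- quiet_pmi(amp, phx, phy, 18)$value
  expect_gt(mi, 1e-3)
  expect_lt(pmi, 0.05 * mi)
})

test_that("sampled PMI converges to the analytic back-door value", {
  # discrete toy: Pr(y-bin) non-uniform, x|y a mixture of copy and uniform,
  # amplitude a deterministic function of (x-bin, y-bin)
  set.seed(7)
  n_bins <- 6
  n <- 100000
  pr_y <- c(0.3, 0.25, 0.15, 0.12, 0.1, 0.08)
  g <- function(i, j) 1 + 0.5 * cos(2 * pi * i / n_bins) +
    0.3 * sin(2 * pi * j / n_bins)
  yb <- sample(n_bins, n, replace = TRUE, prob = pr_y)
  copy <- runif(n) < 0.5
  xb <- ifelse(copy, yb, sample(n_bins, n, replace = TRUE))
  amp <- g(xb, yb)
  centers <- -pi + (1:n_bins - 0.5) * 2 * pi / n_bins
  sampled <- quiet_pmi(amp, centers[xb], centers[yb], n_bins)$value
  # analytic back-door: q[i] = sum_j pr_y[j] g(i, j)
  q <- vapply(1:n_bins, function(i) sum(pr_y * g(i, 1:n_bins)), numeric(1))
  p_adj <- q / sum(q)
  analytic <- (log(n_bins) + sum(p_adj * log(p_adj))) / log(n_bins)
  expect_lt(abs(sampled - analytic) / analytic, 0.02)
})

test_that("PMI errors with the joint-count table when a row is empty", {
  centers <- c(-pi / 2, pi / 2)
  err <- tryCatch(
    quiet_pmi(c(1, 2, 3), centers[c(1, 1, 1)], centers[c(1, 2, 1)], 2),
    error = function(e) e
  )
  expect_s3_class(err, "pcfc_undefined_pmi")
  expect_true(is.matrix(err$joint_counts))
  expect_equal(sum(err$joint_counts[2, ]), 0)
})

test_that("coupling values stay in [0, 1] across random inputs", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(200:2000, 1)
    phx <- runif_phase(n)
    phy <- if (i %% 2) phx + rnorm(n, 0, 0.2) else runif_phase(n)
    phy <- ((phy + pi) %% (2 * pi)) - pi
    amp <- rexp(n) * (1 + 0.5 * cos(phx))
    mi <- modulation_index(amp, bin_phases(phx, 12), 12)$value
    pmi <- tryCatch(quiet_pmi(amp, phx, phy, 12)$value,
                    error = function(e) NA_real_)
    expect_gte(mi, 0)
    expect_lte(mi, 1)
    if (!is.na(pmi)) {
      expect_gte(pmi, 0)
      expect_lte(pmi, 1)
    }
  }
})

test_that("tidy and glance return the documented shapes", {
  set.seed(9)
  res <- modulation_index(rexp(1000), bin_phases(runif_phase(1000), 18), 18)
  td <- tidy(res)
  expect_equal(nrow(td), 18)
  expect_named(td, c("bin", "phase_center_rad", "p"))
  expect_equal(sum(td$p), 1, tolerance = 1e-12)
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$kind, "MI")
})
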