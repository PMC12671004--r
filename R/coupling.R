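# Phase-amplitude coupling metrics: the Kullback-Leibler modulation index
# (MI) and the back-door-adjusted partial modulation index (PMI), which
# removes the confounding contribution of local same-frequency phase coupling
# from cross-regional coupling estimates.

#' Equal-width phase binning
#'
#' Partitions `[-pi, pi)` into `n_bins` half-open bins of width `2*pi/n_bins`.
#'
#' @param n_bins number of bins (default 18).
#' @return an object of class `pcfc_phase_binning` with fields `n_bins` and
#'   `edges` (length `n_bins + 1`).
#' @export
#' @examples
#' phase_binning(18)
phase_binning <- function(n_bins = 18) {
  check_number(n_bins, "n_bins", lower = 2)
  n_bins <- as.integer(n_bins)
  structure(list(n_bins = n_bins,
                 edges = seq(-pi, pi, length.out = n_bins + 1L)),
            class = "pcfc_phase_binning")
}

#' @export
print.pcfc_phase_binning <- function(x, ...) {
  cat(sprintf("<pcfc_phase_binning> %d bins of width %.4f rad\n",
              x$n_bins, 2 * pi / x$n_bins))
  invisible(x)
}

#' Assign phases to bins
#'
#' Deterministically maps each phase to the half-open bin
#' `[edge_i, edge_{i+1})` containing it. Bin indices are 1-based: `-pi` maps
#' to bin 1 and phases just below `pi` to bin `n_bins`.
#'
#' @param phase_rad numeric phases in `[-pi, pi)`.
#' @param binning a [phase_binning()] or a plain bin count.
#' @return integer vector of bin indices in `1..n_bins`.
#' @export
#' @examples
#' bin_phases(c(-pi, 0, pi - 1e-9), phase_binning(18))
bin_phases <- function(phase_rad, binning = phase_binning()) {
  if (is.numeric(binning) && length(binning) == 1L) {
    binning <- phase_binning(binning)
  }
  stopifnot(inherits(binning, "pcfc_phase_binning"))
  check_numeric_vector(phase_rad, "phase_rad")
  if (any(!is.finite(phase_rad)) || any(phase_rad < -pi) ||
      any(phase_rad >= pi)) {
    abort("`phase_rad` must be finite and lie in [-pi, pi).",
          class = "pcfc_contract_violation")
  }
  n <- binning$n_bins
  b <- floor((phase_rad + pi) / (2 * pi / n)) + 1L
  b[b > n] <- n  # guard against floating-point roundoff at the top edge
  as.integer(b)
}

# Normalized entropy-based index from a non-negative bin profile.
mi_from_profile <- function(p) {
  n <- length(p)
  total <- sum(p)
  if (total <= 0) {
    abort("all-zero amplitude profile: the index is undefined.",
          class = "pcfc_undefined_index")
  }
  p <- p / total
  nz <- p[p > 0]
  h <- -sum(nz * log(nz))
  max((log(n) - h) / log(n), 0)
}

new_coupling_result <- function(value, kind, n_bins, profile, detail,
                                n_samples, phase_freq_hz = NA_real_,
                                amp_freq_hz = NA_real_) {
  structure(list(value = value, kind = kind, n_bins = n_bins,
                 profile = profile, detail = detail, n_samples = n_samples,
                 phase_freq_hz = phase_freq_hz, amp_freq_hz = amp_freq_hz),
            class = "pcfc_coupling")
}

#' @export
print.pcfc_coupling <- function(x, ...) {
  cat(sprintf("<pcfc_coupling> %s = %.6g (%d bins, %d samples)\n",
              x$kind, x$value, x$n_bins, x$n_samples))
  invisible(x)
}

#' Amplitude distribution over phase bins
#'
#' Mean amplitude per phase bin, normalized to a probability-like profile.
#'
#' @param amplitude numeric amplitude series.
#' @param phase_bins integer bin indices (1-based), aligned with `amplitude`.
#' @param n_bins number of phase bins.
#' @return a tibble with columns `bin`, `count`, `raw_mean`, `p`; `p` sums
#'   to 1.
#' @export
#' @examples
#' amplitude_distribution(c(4, 2, 2, 2), 1:4, 4)
amplitude_distribution <- function(amplitude, phase_bins, n_bins) {
  check_numeric_vector(amplitude, "amplitude")
  n_bins <- as.integer(check_number(n_bins, "n_bins", lower = 2))
  if (length(phase_bins) != length(amplitude)) {
    abort("`amplitude` and `phase_bins` must have the same length.",
          class = "pcfc_contract_violation")
  }
  phase_bins <- as.integer(phase_bins)
  counts <- tabulate(phase_bins, n_bins)
  sums <- as.numeric(rowsum(amplitude, factor(phase_bins, levels = 1:n_bins),
                            reorder = TRUE))
  sums[is.na(sums)] <- 0
  raw_mean <- ifelse(counts > 0, sums / pmax(counts, 1L), 0)
  if (any(counts == 0)) {
    warn(sprintf("%d of %d phase bins are empty; their mean amplitude is 0.",
                 sum(counts == 0), n_bins),
         class = "pcfc_empty_bins")
  }
  total <- sum(raw_mean)
  tibble::tibble(bin = 1:n_bins, count = counts, raw_mean = raw_mean,
                 p = if (total > 0) raw_mean / total else rep(NA_real_,
                                                              n_bins))
}

#' Modulation index
#'
#' The Kullback-Leibler modulation index: the normalized divergence between
#' the amplitude-by-phase-bin profile `P` and the uniform distribution,
#' `MI = (log N - H(P)) / log N`, with `H` the Shannon entropy (natural log).
#' `MI = 0` for a uniform profile and 1 when all amplitude mass falls in one
#' bin.
#'
#' @inheritParams amplitude_distribution
#' @param phase_freq_hz,amp_freq_hz optional frequency labels carried into
#'   the result.
#' @return a `pcfc_coupling` object; `$value` is the MI in `[0, 1]`,
#'   `$profile` the normalized profile `P`, `$detail` the bin-level tibble.
#' @seealso [partial_modulation_index()]
#' @export
#' @examples
#' modulation_index(c(4, 2, 2, 2), 1:4, 4)$value
modulation_index <- function(amplitude, phase_bins, n_bins,
                             phase_freq_hz = NA_real_,
                             amp_freq_hz = NA_real_) {
  if (all(amplitude == 0)) {
    abort("all amplitudes are zero: MI is undefined.",
          class = "pcfc_undefined_index")
  }
  dist <- amplitude_distribution(amplitude, phase_bins, n_bins)
  value <- mi_from_profile(dist$raw_mean)
  new_coupling_result(value, "MI", as.integer(n_bins), dist$p, dist,
                      length(amplitude), phase_freq_hz, amp_freq_hz)
}

#' Joint mean amplitude table
#'
#' Mean target amplitude for each joint outcome of (source phase bin, local
#' phase bin), together with the local phase marginal — the ingredients of
#' the back-door adjustment.
#'
#' @param amplitude numeric amplitude series of the target channel.
#' @param bins_x integer source-phase bin indices, aligned with `amplitude`.
#' @param bins_y integer local (target) phase bin indices.
#' @param n_bins number of phase bins.
#' @return a list of class `pcfc_joint_table` with `joint_means` and
#'   `joint_counts` (`n_bins` x `n_bins` matrices, rows = source bins `i`,
#'   columns = local bins `j`; empty cells have mean `NA`), and
#'   `phase_y_marginal` (length-`n_bins` probability vector).
#' @export
#' @examples
#' joint_mean_amplitude(rep(1, 6), rep(1:2, 3), rep(1:3, 2), 3)
joint_mean_amplitude <- function(amplitude, bins_x, bins_y, n_bins) {
  check_numeric_vector(amplitude, "amplitude")
  n_bins <- as.integer(check_number(n_bins, "n_bins", lower = 2))
  if (length(bins_x) != length(amplitude) ||
      length(bins_y) != length(amplitude)) {
    abort("`amplitude`, `bins_x` and `bins_y` must be aligned.",
          class = "pcfc_contract_violation")
  }
  bins_x <- as.integer(bins_x)
  bins_y <- as.integer(bins_y)
  idx <- (bins_x - 1L) * n_bins + bins_y
  counts <- matrix(tabulate(idx, n_bins * n_bins), n_bins, n_bins,
                   byrow = TRUE)
  sums <- matrix(0, n_bins, n_bins)
  agg <- rowsum(amplitude, idx)
  sums[matrix(c((as.integer(rownames(agg)) - 1L) %/% n_bins + 1L,
                (as.integer(rownames(agg)) - 1L) %% n_bins + 1L),
              ncol = 2)] <- as.numeric(agg)
  means <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  structure(list(joint_means = means, joint_counts = counts,
                 phase_y_marginal = tabulate(bins_y, n_bins) /
                   length(bins_y)),
            class = "pcfc_joint_table")
}

#' Partial modulation index
#'
#' The back-door-adjusted modulation index. The local phase of the target
#' channel at the modulating frequency acts as a confounder when the two
#' regions are also phase-coupled at that frequency; PMI adjusts for it by
#' replacing the plain per-bin mean amplitude with the adjustment-formula
#' profile
#' \deqn{q[i] = \sum_j \Pr(\phi_y[j]) \langle A \rangle[i, j],}
#' i.e. the expected target amplitude if the source phase were set to bin `i`
#' while the local phase kept its marginal distribution. `q` is renormalized
#' to a probability vector before the Kullback-Leibler step, so
#' `PMI` lies in `[0, 1]` like MI. Empty joint cells are excluded, with the
#' local-phase marginal renormalized over the observed cells of each row (a
#' warning reports how many cells were empty).
#'
#' @param amplitude numeric amplitude series of the target channel.
#' @param phase_x source-channel phases in radians (`[-pi, pi)`), aligned
#'   with `amplitude`.
#' @param phase_y local (target-channel) phases in radians at the same
#'   modulating frequency.
#' @param n_bins number of phase bins (default 18).
#' @inheritParams modulation_index
#' @return a `pcfc_coupling` object with `$kind = "PMI"`; `$detail` holds the
#'   [joint_mean_amplitude()] table.
#' @export
#' @examples
#' set.seed(1)
#' ph_x <- runif(5000, -pi, pi * (1 - 1e-9))
#' ph_y <- runif(5000, -pi, pi * (1 - 1e-9))
#' amp <- 1 + 0.5 * cos(ph_x)
#' partial_modulation_index(amp, ph_x, ph_y, 18)$value
partial_modulation_index <- function(amplitude, phase_x, phase_y,
                                     n_bins = 18,
                                     phase_freq_hz = NA_real_,
                                     amp_freq_hz = NA_real_) {
  binning <- phase_binning(n_bins)
  bins_x <- bin_phases(phase_x, binning)
  bins_y <- bin_phases(phase_y, binning)
  jt <- joint_mean_amplitude(amplitude, bins_x, bins_y, binning$n_bins)
  value <- pmi_from_joint(jt)
  profile <- attr(value, "profile")
  new_coupling_result(as.numeric(value), "PMI", binning$n_bins, profile,
                      jt, length(amplitude), phase_freq_hz, amp_freq_hz)
}

# Back-door adjusted profile and index from a joint table.
pmi_from_joint <- function(jt) {
  counts <- jt$joint_counts
  means <- jt$joint_means
  n <- nrow(counts)
  empty_rows <- rowSums(counts > 0) == 0
  if (any(empty_rows)) {
    cnd <- rlang::error_cnd(class = "pcfc_undefined_pmi",
                            message = sprintf(
                              paste("source-phase bin(s) %s have no samples",
                                    "in any joint cell; PMI is undefined",
                                    "(insufficient joint support)."),
                              paste(which(empty_rows), collapse = ", ")),
                            joint_counts = counts)
    rlang::cnd_signal(cnd)
  }
  n_empty <- sum(counts == 0)
  if (n_empty > 0) {
    warn(sprintf(paste("%d of %d joint phase cells are empty; the local-",
                       "phase marginal was renormalized over observed",
                       "cells."), n_empty, length(counts)),
         class = "pcfc_empty_cells")
  }
  w <- matrix(jt$phase_y_marginal, n, n, byrow = TRUE)
  w[counts == 0] <- 0
  w <- w / rowSums(w)
  m0 <- means
  m0[counts == 0] <- 0
  q <- rowSums(w * m0)
  value <- mi_from_profile(q)
  attr(value, "profile") <- q / sum(q)
  value
}
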