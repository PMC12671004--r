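# Comodulograms: MI or PMI over a (phase frequency x amplitude frequency)
# grid with shared time-shift surrogate draws, uncorrected permutation
# p-values, and cluster-based correction.

# Vectorized MI over all circular shifts of the amplitude series.
# bx: phase bins (1..n_bins); shifts: integer sample shifts (0 = observed).
mi_all_shifts <- function(bx, n_bins, amplitude, shifts) {
  s <- shift_group_sums(amplitude, bx, n_bins, as.integer(shifts))
  cnt <- tabulate(bx, n_bins)
  p <- s / ifelse(cnt > 0, cnt, 1)
  p <- sweep(p, 2, colSums(p), "/")
  lg <- ifelse(p > 0, log(p), 0)
  pmax((log(n_bins) + colSums(p * lg)) / log(n_bins), 0)
}

# Vectorized PMI over all circular shifts. The joint-cell weights depend only
# on the (unshifted) phase bins, so all surrogate draws share one weighting.
pmi_all_shifts <- function(bx, by, n_bins, amplitude, shifts) {
  idx <- (bx - 1L) * n_bins + by
  cnt <- tabulate(idx, n_bins * n_bins)
  cnt_m <- matrix(cnt, n_bins, n_bins, byrow = TRUE)
  if (any(rowSums(cnt_m) == 0)) {
    abort("a source-phase bin has no samples; PMI is undefined.",
          class = "pcfc_undefined_pmi")
  }
  s <- shift_group_sums(amplitude, idx, n_bins * n_bins, as.integer(shifts))
  pr_j <- tabulate(by, n_bins) / length(by)
  w <- matrix(pr_j, n_bins, n_bins, byrow = TRUE)
  w[cnt_m == 0] <- 0
  w <- w / rowSums(w)
  k <- matrix(0, n_bins, n_bins)
  nz <- cnt_m > 0
  k[nz] <- w[nz] / cnt_m[nz]
  ks <- s * as.vector(t(k))  # flat in the same (i-1)*n_bins + j order as idx
  q <- rowsum(ks, rep(seq_len(n_bins), each = n_bins))
  q <- sweep(q, 2, colSums(q), "/")
  lg <- ifelse(q > 0, log(q), 0)
  pmax((log(n_bins) + colSums(q * lg)) / log(n_bins), 0)
}

# Observed + surrogate coupling values for one grid cell. Returns a vector:
# first element observed, rest surrogates.
cell_coupling_values <- function(x, y, sampling_rate_hz, phase_freq_hz,
                                 amp_freq_hz, kind, n_bins, u,
                                 min_shift_s, phase_bandwidth_hz = 2) {
  pband <- band_spec(phase_freq_hz, phase_bandwidth_hz, role = "phase")
  aband <- band_spec(amp_freq_hz, role = "amplitude",
                     phase_center_hz = phase_freq_hz)
  margin <- max(filter_margin(sampling_rate_hz, pband),
                filter_margin(sampling_rate_hz, aband))
  ph_x <- Arg(analytic_signal(bandpass_zero_phase(x, pband,
                                                  sampling_rate_hz)))
  amp <- Mod(analytic_signal(bandpass_zero_phase(y, aband,
                                                 sampling_rate_hz)))
  keep <- (margin + 1L):(length(x) - margin)
  ph_x <- ph_x[keep]
  ph_x[ph_x >= pi] <- -pi
  bx <- bin_phases(ph_x, n_bins)
  a <- amp[keep]
  n <- length(a)
  min_shift <- round(min_shift_s * sampling_rate_hz)
  if (n <= 2 * min_shift) {
    abort("record too short for the requested surrogate shifts.",
          class = "pcfc_insufficient_data")
  }
  shifts <- c(0L, as.integer(floor(min_shift + u * (n - 2 * min_shift))))
  if (kind == "mi") {
    mi_all_shifts(bx, n_bins, a, shifts)
  } else {
    ph_y <- Arg(analytic_signal(bandpass_zero_phase(y, pband,
                                                    sampling_rate_hz)))
    ph_y <- ph_y[keep]
    ph_y[ph_y >= pi] <- -pi
    by <- bin_phases(ph_y, n_bins)
    pmi_all_shifts(bx, by, n_bins, a, shifts)
  }
}

resolve_signals <- function(signals, sampling_rate_hz = NULL) {
  if (inherits(signals, "pcfc_signals")) {
    fs <- attr(signals, "sampling_rate_hz")
  } else {
    fs <- sampling_rate_hz
  }
  if (is.null(fs)) {
    abort(paste("`sampling_rate_hz` must be given when `signals` is not a",
                "pcfc_signals object."), class = "pcfc_contract_violation")
  }
  if (!is.data.frame(signals) || !all(c("x", "y") %in% names(signals))) {
    abort("`signals` must be a data frame with columns `x` and `y`.",
          class = "pcfc_contract_violation")
  }
  list(x = signals$x, y = signals$y, fs = fs)
}

#' Comodulogram with surrogate statistics
#'
#' Computes MI or PMI at every (phase frequency, amplitude frequency) pair of
#' a grid. Per cell: zero-phase FIR decomposition, coupling value, and a null
#' distribution from circular time-shift surrogates of the amplitude series.
#' Surrogate draws are shared across cells (one shift per draw), which makes
#' the max-statistic cluster correction of [cluster_correct()] valid. For
#' `kind = "pmi"`, the confounding local phase is the y-channel phase
#' extracted at the same modulating frequency and bandwidth as the x-channel
#' phase.
#'
#' @param signals a `pcfc_signals` tibble from the simulators, or any data
#'   frame with numeric columns `x` and `y`.
#' @param phase_freqs phase (modulating) frequency grid in Hz.
#' @param amp_freqs amplitude (modulated) frequency grid in Hz.
#' @param kind `"mi"` or `"pmi"`.
#' @param n_bins number of phase bins (default 18).
#' @param config a [surrogate_config()].
#' @param sampling_rate_hz sampling rate; taken from `signals` when it is a
#'   `pcfc_signals` object.
#' @param phase_bandwidth_hz bandwidth of the phase bands (default 2 Hz); the
#'   amplitude bandwidth is twice the phase frequency.
#' @return a tibble of class `pcfc_comodulogram` with one row per grid cell:
#'   `phase_hz`, `amp_hz`, `value`, `p` (uncorrected), `p_cluster`
#'   (cluster-corrected; 1 outside clusters), `significant` (surviving
#'   cluster membership). Attributes: `kind`, `n_bins`, `config`, `clusters`,
#'   `null_max_mass`.
#' @export
#' @examples
#' \donttest{
#' sig <- simulate_dataset2(sim_spec(duration_s = 10, seed = 1))
#' cm <- comodulogram(sig, 13, 150, kind = "pmi",
#'                    config = surrogate_config(50, seed = 1))
#' }
comodulogram <- function(signals, phase_freqs, amp_freqs,
                         kind = c("mi", "pmi"), n_bins = 18,
                         config = surrogate_config(),
                         sampling_rate_hz = NULL, phase_bandwidth_hz = 2) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "pcfc_surrogate_config"))
  check_numeric_vector(phase_freqs, "phase_freqs")
  check_numeric_vector(amp_freqs, "amp_freqs")
  sg <- resolve_signals(signals, sampling_rate_hz)
  n_bins <- as.integer(check_number(n_bins, "n_bins", lower = 2))
  u <- surrogate_uniforms(config)
  np <- length(phase_freqs)
  na <- length(amp_freqs)
  observed <- matrix(0, np, na)
  surr <- array(0, c(config$n_surrogates, np, na))
  for (ii in seq_len(np)) {
    for (jj in seq_len(na)) {
      vals <- cell_coupling_values(sg$x, sg$y, sg$fs, phase_freqs[ii],
                                   amp_freqs[jj], kind, n_bins, u,
                                   config$min_shift_s, phase_bandwidth_hz)
      observed[ii, jj] <- vals[1]
      surr[, ii, jj] <- vals[-1]
    }
  }
  p_matrix <- matrix(0, np, na)
  for (ii in seq_len(np)) {
    for (jj in seq_len(na)) {
      p_matrix[ii, jj] <- permutation_pvalue(observed[ii, jj],
                                             surr[, ii, jj])
    }
  }
  cc <- cluster_correct(observed, p_matrix, surr, config)
  out <- tidyr::expand_grid(phase_hz = phase_freqs, amp_hz = amp_freqs)
  cell_i <- match(out$phase_hz, phase_freqs)
  cell_j <- match(out$amp_hz, amp_freqs)
  out$value <- observed[cbind(cell_i, cell_j)]
  out$p <- p_matrix[cbind(cell_i, cell_j)]
  out$p_cluster <- cc$p_cluster[cbind(cell_i, cell_j)]
  out$significant <- cc$mask[cbind(cell_i, cell_j)]
  attr(out, "kind") <- toupper(kind)
  attr(out, "n_bins") <- n_bins
  attr(out, "config") <- config
  attr(out, "clusters") <- cc$clusters
  attr(out, "null_max_mass") <- cc$null_max_mass
  attr(out, "sampling_rate_hz") <- sg$fs
  class(out) <- c("pcfc_comodulogram", class(out))
  out
}

#' @export
print.pcfc_comodulogram <- function(x, ...) {
  cat(sprintf("<pcfc_comodulogram> %s, %d cells, %d significant\n",
              attr(x, "kind"), nrow(x), sum(x$significant)))
  NextMethod()
}

#' Cluster-corrected p-value at the grid cell nearest a frequency pair
#'
#' @param cm a [comodulogram()] result.
#' @param phase_hz,amp_hz target frequencies.
#' @return the `p_cluster` value of the nearest grid cell.
#' @export
p_at <- function(cm, phase_hz = 13, amp_hz = 150) {
  stopifnot(inherits(cm, "pcfc_comodulogram"))
  i <- which.min(abs(cm$phase_hz - phase_hz) / max(cm$phase_hz) +
                   abs(cm$amp_hz - amp_hz) / max(cm$amp_hz))
  cm$p_cluster[i]
}
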