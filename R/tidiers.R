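# broom-style tidiers.

#' Tidy a coupling result
#'
#' @param x a `pcfc_coupling` object from [modulation_index()] or
#'   [partial_modulation_index()].
#' @param ... unused.
#' @return a tibble with one row per phase bin: `bin`, `phase_center_rad`,
#'   `p` (the normalized — for PMI, back-door-adjusted — amplitude profile).
#' @export
tidy.pcfc_coupling <- function(x, ...) {
  n <- x$n_bins
  centers <- -pi + (seq_len(n) - 0.5) * 2 * pi / n
  tibble::tibble(bin = seq_len(n), phase_center_rad = centers,
                 p = as.numeric(x$profile))
}

#' Glance at a coupling result
#'
#' @inheritParams tidy.pcfc_coupling
#' @return a one-row tibble: `kind`, `value`, `n_bins`, `n_samples`,
#'   `phase_freq_hz`, `amp_freq_hz`.
#' @export
glance.pcfc_coupling <- function(x, ...) {
  tibble::tibble(kind = x$kind, value = x$value, n_bins = x$n_bins,
                 n_samples = x$n_samples, phase_freq_hz = x$phase_freq_hz,
                 amp_freq_hz = x$amp_freq_hz)
}

#' Tidy an MVAR fit
#'
#' @param x a [fit_mvar()] result.
#' @param ... unused.
#' @return a tibble with one row per coefficient: `to`, `from`, `lag`,
#'   `estimate`, `std_error`.
#' @export
tidy.pcfc_mvar <- function(x, ...) {
  chans <- c("x", "y")
  out <- tidyr::expand_grid(lag = seq_len(x$order), to = chans,
                            from = chans)
  out$estimate <- purrr::pmap_dbl(out, function(lag, to, from) {
    x$coeffs[match(to, chans), match(from, chans), lag]
  })
  out$std_error <- purrr::pmap_dbl(out[1:3], function(lag, to, from) {
    x$coef_se[match(to, chans), match(from, chans), lag]
  })
  dplyr::select(out, "to", "from", "lag", "estimate", "std_error")
}

#' Glance at an MVAR fit
#'
#' @inheritParams tidy.pcfc_mvar
#' @return a one-row tibble: `order`, `n_obs`, `aic`.
#' @export
glance.pcfc_mvar <- function(x, ...) {
  tibble::tibble(order = x$order, n_obs = x$n_obs,
                 aic = min(x$aic_path))
}

#' Glance at a transfer-entropy result
#'
#' @param x a [transfer_entropy()] result.
#' @param ... unused.
#' @return a one-row tibble: `direction`, `te_bits`, `baseline_bits`,
#'   `n_bins`, `lag_samples`, `n_states_occupied`.
#' @export
glance.pcfc_te <- function(x, ...) {
  tibble::tibble(direction = x$direction, te_bits = x$te_bits,
                 baseline_bits = x$baseline_bits, n_bins = x$n_bins,
                 lag_samples = x$lag_samples,
                 n_states_occupied = x$n_states_occupied)
}

#' Glance at a comodulogram
#'
#' @param x a [comodulogram()] result.
#' @param ... unused.
#' @return a one-row tibble: `kind`, `n_cells`, `n_significant`,
#'   `n_clusters`, `min_p_cluster`.
#' @export
glance.pcfc_comodulogram <- function(x, ...) {
  cl <- attr(x, "clusters")
  tibble::tibble(kind = attr(x, "kind"), n_cells = nrow(x),
                 n_significant = sum(x$significant),
                 n_clusters = nrow(cl),
                 min_p_cluster = min(x$p_cluster))
}
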