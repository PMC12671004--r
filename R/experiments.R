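# Scripted experiments: the headline MI/PMI contrast on both datasets and
# Monte-Carlo sensitivity sweeps over noise level, record duration, and
# phase-bin count.

#' MI/PMI contrast experiment
#'
#' Computes the four comodulograms (MI and PMI on dataset 1 and dataset 2)
#' for one simulation specification and summarizes whether each shows a
#' significant cluster at the grid cell nearest the target frequency pair.
#'
#' @param spec a [sim_spec()].
#' @param phase_freqs,amp_freqs frequency grids (defaults bracket the
#'   13 Hz / 150 Hz target).
#' @param n_bins number of phase bins (default 18).
#' @param config a [surrogate_config()].
#' @param target_phase_hz,target_amp_hz frequency pair summarized (13, 150).
#' @return an object of class `pcfc_contrast`: a list with `comodulograms`
#'   (named `mi_dataset1`, `pmi_dataset1`, `mi_dataset2`, `pmi_dataset2`)
#'   and `summary` (tibble: `kind`, `dataset`, `p_cluster`, `significant`).
#' @export
run_contrast_experiment <- function(spec,
                                    phase_freqs = c(11, 12, 13, 14, 15),
                                    amp_freqs = c(120, 135, 150, 165, 180),
                                    n_bins = 18,
                                    config = surrogate_config(),
                                    target_phase_hz = 13,
                                    target_amp_hz = 150) {
  stopifnot(inherits(spec, "pcfc_sim_spec"))
  sigs <- list(dataset1 = simulate_dataset1(spec),
               dataset2 = simulate_dataset2(spec))
  grid <- tidyr::expand_grid(kind = c("mi", "pmi"),
                             dataset = c("dataset1", "dataset2"))
  cms <- purrr::pmap(grid, function(kind, dataset) {
    comodulogram(sigs[[dataset]], phase_freqs, amp_freqs, kind = kind,
                 n_bins = n_bins, config = config)
  })
  names(cms) <- paste(grid$kind, grid$dataset, sep = "_")
  summary <- dplyr::mutate(
    grid,
    p_cluster = purrr::map_dbl(cms, p_at, phase_hz = target_phase_hz,
                               amp_hz = target_amp_hz),
    significant = .data$p_cluster <= config$alpha
  )
  structure(list(comodulograms = cms, summary = summary,
                 spec = spec, config = config),
            class = "pcfc_contrast")
}

#' @export
print.pcfc_contrast <- function(x, ...) {
  cat("<pcfc_contrast>\n")
  print(x$summary)
  invisible(x)
}

#' Sweep specification
#'
#' @param variable which parameter is swept: `"noise_sd"`, `"duration_s"` or
#'   `"n_bins"`.
#' @param grid values of the swept variable.
#' @param n_repeats Monte-Carlo repetitions per grid point (default 50).
#' @param base a [sim_spec()] providing all other parameters; its `seed` is
#'   ignored — the sweep is driven by `seed`.
#' @param seed master seed making the whole sweep reproducible.
#' @param n_surrogates surrogates per repeat (default 200, the reduced
#'   sweep-scale setting).
#' @param alpha per-cell significance level (default 0.05).
#' @param n_bins phase bins used when `variable` is not `"n_bins"`.
#' @param target_phase_hz,target_amp_hz the frequency pair tested.
#' @return an object of class `pcfc_sweep_spec`.
#' @export
sweep_spec <- function(variable = c("noise_sd", "duration_s", "n_bins"),
                       grid, n_repeats = 50, base = sim_spec(), seed = 1,
                       n_surrogates = 200, alpha = 0.05, n_bins = 18,
                       target_phase_hz = 13, target_amp_hz = 150) {
  variable <- match.arg(variable)
  check_numeric_vector(grid, "grid")
  check_number(n_repeats, "n_repeats", lower = 1)
  stopifnot(inherits(base, "pcfc_sim_spec"))
  check_number(seed, "seed")
  check_number(n_surrogates, "n_surrogates", lower = 1)
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  structure(list(variable = variable, grid = grid,
                 n_repeats = as.integer(n_repeats), base = base,
                 seed = as.integer(seed),
                 n_surrogates = as.integer(n_surrogates), alpha = alpha,
                 n_bins = as.integer(n_bins),
                 target_phase_hz = target_phase_hz,
                 target_amp_hz = target_amp_hz),
            class = "pcfc_sweep_spec")
}

# One repeat: PMI permutation p at the target cell for one dataset.
sweep_cell_p <- function(sig, sweep, n_bins) {
  u <- runif(sweep$n_surrogates)
  vals <- cell_coupling_values(sig$x, sig$y, attr(sig, "sampling_rate_hz"),
                               sweep$target_phase_hz, sweep$target_amp_hz,
                               "pmi", n_bins, u, min_shift_s = 1)
  list(p = permutation_pvalue(vals[1], vals[-1]), value = vals[1])
}

#' Run a Monte-Carlo sensitivity sweep
#'
#' For each grid value, repeatedly simulates both datasets, computes the PMI
#' permutation p-value at the target (phase, amplitude) cell, and aggregates
#' detection (dataset 2 significant) and false-alarm (dataset 1 significant)
#' rates with binomial confidence intervals. A grid point "qualifies" when
#' the dataset-2 detection rate is at least 0.8 and the dataset-1 false-alarm
#' rate is at most `alpha` plus the one-sided 95% binomial tolerance
#' `1.645 * sqrt(alpha * (1 - alpha) / n_repeats)`.
#'
#' @param sweep a [sweep_spec()].
#' @return a tibble of class `pcfc_sweep` with one row per grid value:
#'   `value`, `pmi_true_mean`, `pmi_true_sd`, `pmi_confounded_mean`,
#'   `pmi_confounded_sd`, `detection_rate`, `false_alarm_rate`, 95% CI
#'   bounds for both rates, `snr_db` (noise sweeps; `NA` otherwise) and
#'   `qualifies`. Attributes: `sweep`, `fa_tolerance`.
#' @export
run_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "pcfc_sweep_spec"))
  set.seed(sweep$seed)
  base <- sweep$base
  rows <- purrr::map_dfr(sweep$grid, function(g) {
    spec_args <- unclass(base)
    spec_args$seed <- NULL
    if (sweep$variable %in% c("noise_sd", "duration_s")) {
      spec_args[[sweep$variable]] <- g
    }
    spec <- do.call(sim_spec, c(spec_args, list(seed = NULL)))
    n_bins <- if (sweep$variable == "n_bins") as.integer(g) else
      sweep$n_bins
    reps <- purrr::map_dfr(seq_len(sweep$n_repeats), function(r) {
      s1 <- simulate_dataset1(spec)
      s2 <- simulate_dataset2(spec)
      r1 <- sweep_cell_p(s1, sweep, n_bins)
      r2 <- sweep_cell_p(s2, sweep, n_bins)
      snr <- if (sweep$variable == "noise_sd" && g > 0) {
        10 * log10(max(mean(s2$y^2) - g^2, 1e-12) / g^2)
      } else NA_real_
      tibble::tibble(p1 = r1$p, p2 = r2$p, v1 = r1$value, v2 = r2$value,
                     snr_db = snr)
    })
    n <- sweep$n_repeats
    det <- mean(reps$p2 <= sweep$alpha)
    fa <- mean(reps$p1 <= sweep$alpha)
    ci <- function(r) 1.96 * sqrt(r * (1 - r) / n)
    tibble::tibble(value = g,
                   pmi_true_mean = mean(reps$v2),
                   pmi_true_sd = sd(reps$v2),
                   pmi_confounded_mean = mean(reps$v1),
                   pmi_confounded_sd = sd(reps$v1),
                   detection_rate = det,
                   detection_ci_lo = max(det - ci(det), 0),
                   detection_ci_hi = min(det + ci(det), 1),
                   false_alarm_rate = fa,
                   false_alarm_ci_lo = max(fa - ci(fa), 0),
                   false_alarm_ci_hi = min(fa + ci(fa), 1),
                   snr_db = mean(reps$snr_db))
  })
  tol <- 1.645 * sqrt(sweep$alpha * (1 - sweep$alpha) / sweep$n_repeats)
  rows$qualifies <- rows$detection_rate >= 0.8 &
    rows$false_alarm_rate <= sweep$alpha + tol
  attr(rows, "sweep") <- sweep
  attr(rows, "fa_tolerance") <- tol
  class(rows) <- c("pcfc_sweep", class(rows))
  rows
}

#' @export
print.pcfc_sweep <- function(x, ...) {
  cat(sprintf("<pcfc_sweep> %s over {%s}, %d repeats\n",
              attr(x, "sweep")$variable,
              paste(attr(x, "sweep")$grid, collapse = ", "),
              attr(x, "sweep")$n_repeats))
  NextMethod()
}

#' Smallest qualifying duration of a duration sweep
#'
#' @param result a [run_sweep()] result for `variable = "duration_s"`.
#' @return the smallest grid duration whose point qualifies (detection at
#'   least 0.8, false alarms within tolerance), or `NA` if none does.
#' @export
min_qualifying_duration <- function(result) {
  stopifnot(inherits(result, "pcfc_sweep"))
  q <- result$value[result$qualifies]
  if (length(q) == 0) NA_real_ else min(q)
}

#' Largest qualifying bin count of a bin-count sweep
#'
#' @param result a [run_sweep()] result for `variable = "n_bins"`.
#' @return the largest grid bin count whose point qualifies, or `NA` if none
#'   does.
#' @export
max_qualifying_bins <- function(result) {
  stopifnot(inherits(result, "pcfc_sweep"))
  q <- result$value[result$qualifies]
  if (length(q) == 0) NA_real_ else max(q)
}
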