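# Null-distribution machinery: circular time-shift surrogates of the
# amplitude series, permutation p-values, and two-dimensional cluster-based
# correction for multiple comparisons across a frequency grid.

#' Surrogate/permutation configuration
#'
#' @param n_surrogates number of surrogate draws (default 1000).
#' @param min_shift_s minimum circular shift in seconds (default 1); shifts
#'   are drawn uniformly from `[min_shift, length - min_shift]` samples.
#' @param seed integer seed for the surrogate draws, or `NULL` to use the
#'   current RNG state.
#' @param alpha significance level for surviving clusters (default 0.05).
#' @param cluster_alpha cluster-forming threshold on uncorrected p-values
#'   (default 0.05).
#' @return an object of class `pcfc_surrogate_config`.
#' @export
#' @examples
#' surrogate_config(n_surrogates = 200, seed = 1)
surrogate_config <- function(n_surrogates = 1000, min_shift_s = 1,
                             seed = NULL, alpha = 0.05,
                             cluster_alpha = 0.05) {
  check_number(n_surrogates, "n_surrogates", lower = 1)
  check_number(min_shift_s, "min_shift_s", lower = 0)
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  check_number(cluster_alpha, "cluster_alpha", lower = 1e-12,
               upper = 1 - 1e-12)
  if (!is.null(seed)) check_number(seed, "seed")
  structure(list(n_surrogates = as.integer(n_surrogates),
                 min_shift_s = min_shift_s,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 alpha = alpha, cluster_alpha = cluster_alpha),
            class = "pcfc_surrogate_config")
}

#' @export
print.pcfc_surrogate_config <- function(x, ...) {
  cat(sprintf(paste0("<pcfc_surrogate_config> %d draws, min shift %g s, ",
                     "alpha %g, cluster alpha %g\n"),
              x$n_surrogates, x$min_shift_s, x$alpha, x$cluster_alpha))
  invisible(x)
}

# Uniform draws for all surrogate shifts, optionally seeded without
# disturbing the caller's RNG stream.
surrogate_uniforms <- function(config) {
  if (is.null(config$seed)) return(runif(config$n_surrogates))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(config$seed)
  runif(config$n_surrogates)
}

# Shift offsets in samples for a series of length n.
surrogate_shifts <- function(n, config, sampling_rate_hz) {
  min_shift <- round(config$min_shift_s * sampling_rate_hz)
  if (n <= 2 * min_shift) {
    abort(sprintf(paste("series too short for surrogate shifts: need more",
                        "than %d samples, got %d."), 2 * min_shift, n),
          class = "pcfc_insufficient_data")
  }
  u <- surrogate_uniforms(config)
  as.integer(floor(min_shift + u * (n - 2 * min_shift)))
}

#' Time-shift surrogate of an amplitude series
#'
#' Circularly shifts the amplitude series by a random offset of at least
#' `min_shift_s` seconds, destroying its alignment with the phase series
#' while preserving the amplitude value distribution and autocorrelation.
#'
#' @param amplitude numeric amplitude series.
#' @param config a [surrogate_config()].
#' @param draw which surrogate draw to return (1-based).
#' @param sampling_rate_hz sampling rate in Hz.
#' @return the shifted amplitude series (same multiset of values).
#' @export
#' @examples
#' time_shift_surrogate(sin(1:100), surrogate_config(10, min_shift_s = 0.01,
#'                                                   seed = 1), 1, 1000)
time_shift_surrogate <- function(amplitude, config, draw, sampling_rate_hz) {
  stopifnot(inherits(config, "pcfc_surrogate_config"))
  check_numeric_vector(amplitude, "amplitude", min_length = 2L)
  check_number(draw, "draw", lower = 1, upper = config$n_surrogates)
  n <- length(amplitude)
  sh <- surrogate_shifts(n, config, sampling_rate_hz)[as.integer(draw)]
  amplitude[((seq_len(n) - 1L + sh) %% n) + 1L]
}

#' Permutation p-value
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n)` — the add-one permutation
#' p-value, never exactly zero.
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of the statistic under the null.
#' @return p-value in `(0, 1]`.
#' @export
#' @examples
#' permutation_pvalue(2, runif(1000))
permutation_pvalue <- function(observed, null_values) {
  check_number(observed, "observed")
  check_numeric_vector(null_values, "null_values")
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

# 4-connected component labelling of a logical matrix.
label_components4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        queue <- list(c(i, j))
        lab[i, j] <- cur
        while (length(queue)) {
          cell <- queue[[1]]
          queue <- queue[-1]
          for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
            a <- cell[1] + d[1]
            b <- cell[2] + d[2]
            if (a >= 1L && a <= nrow(mask) && b >= 1L && b <= ncol(mask) &&
                mask[a, b] && lab[a, b] == 0L) {
              lab[a, b] <- cur
              queue <- c(queue, list(c(a, b)))
            }
          }
        }
      }
    }
  }
  lab
}

#' Cluster-based correction over a 2-D frequency grid
#'
#' Implements max-statistic cluster correction: cells with uncorrected
#' permutation `p < cluster_alpha` are grouped into 4-connected clusters whose
#' mass is the sum of observed coupling values; the null distribution of the
#' maximum cluster mass is built by applying the identical procedure to each
#' surrogate draw (ranking it against all draws). A cluster's corrected
#' p-value is the add-one permutation p-value of its mass against that null,
#' and it survives when that p-value is at most `alpha`.
#'
#' Surrogate draws must be shared across grid cells (the same time shift
#' applied at every cell of a draw) for the max-statistic null to be valid;
#' [comodulogram()] constructs its draws that way.
#'
#' @param observed numeric matrix of observed coupling values.
#' @param p_matrix matrix of uncorrected permutation p-values (same shape).
#' @param surrogates array of surrogate coupling values with dimensions
#'   `(n_surrogates, nrow(observed), ncol(observed))`.
#' @param config a [surrogate_config()].
#' @return a list with `mask` (logical matrix of surviving-cluster cells),
#'   `p_cluster` (matrix of corrected cluster p-values; 1 outside clusters),
#'   `clusters` (tibble: `cluster`, `n_cells`, `mass`, `p`), and
#'   `null_max_mass` (the max-mass null distribution).
#' @export
cluster_correct <- function(observed, p_matrix, surrogates, config) {
  stopifnot(inherits(config, "pcfc_surrogate_config"))
  if (!is.matrix(observed) || !is.matrix(p_matrix) ||
      !all(dim(observed) == dim(p_matrix))) {
    abort("`observed` and `p_matrix` must be matrices of the same shape.",
          class = "pcfc_contract_violation")
  }
  dims <- dim(surrogates)
  if (length(dims) != 3L || dims[2] != nrow(observed) ||
      dims[3] != ncol(observed)) {
    abort(paste("`surrogates` must be an array of shape",
                "(n_surrogates, nrow(observed), ncol(observed))."),
          class = "pcfc_contract_violation")
  }
  n_surr <- dims[1]
  nr <- nrow(observed)
  nc <- ncol(observed)
  # Per-draw p-values by ranking each draw against all draws, per cell.
  null_max_mass <- numeric(n_surr)
  rank_ge <- matrix(0L, n_surr, nr * nc)
  for (cell in seq_len(nr * nc)) {
    i <- (cell - 1L) %% nr + 1L
    j <- (cell - 1L) %/% nr + 1L
    v <- surrogates[, i, j]
    rank_ge[, cell] <- n_surr + 1L - rank(v, ties.method = "min")
  }
  for (s in seq_len(n_surr)) {
    p_s <- matrix((1 + rank_ge[s, ]) / (1 + n_surr), nr, nc)
    lab <- label_components4(p_s < config$cluster_alpha)
    if (max(lab) == 0L) {
      null_max_mass[s] <- 0
    } else {
      vals <- matrix(surrogates[s, , ], nr, nc)
      null_max_mass[s] <- max(tapply(vals[lab > 0], lab[lab > 0], sum))
    }
  }
  lab_obs <- label_components4(p_matrix < config$cluster_alpha)
  p_cluster <- matrix(1, nr, nc)
  clusters <- tibble::tibble(cluster = integer(), n_cells = integer(),
                             mass = numeric(), p = numeric())
  if (max(lab_obs) > 0L) {
    for (cl in seq_len(max(lab_obs))) {
      mass <- sum(observed[lab_obs == cl])
      p_cl <- permutation_pvalue(mass, null_max_mass)
      p_cluster[lab_obs == cl] <- p_cl
      clusters <- dplyr::bind_rows(clusters,
                                   tibble::tibble(cluster = cl,
                                                  n_cells =
                                                    sum(lab_obs == cl),
                                                  mass = mass, p = p_cl))
    }
  }
  list(mask = p_cluster <= config$alpha & lab_obs > 0L,
       p_cluster = p_cluster, clusters = clusters,
       null_max_mass = null_max_mass)
}
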