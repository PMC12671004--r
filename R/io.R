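# Plain-text readers and writers for paired signals and comodulograms.

#' Write paired signals to delimited text
#'
#' Writes a two-column (`x`, `y`) tab-delimited file with a header line, and
#' a sidecar metadata file at `<path>.meta` recording the sampling rate and,
#' when available, the truth label and the full simulation specification.
#'
#' @param signals a `pcfc_signals` tibble (or data frame with `x`, `y`).
#' @param path output file path.
#' @param sampling_rate_hz required when `signals` carries no sampling-rate
#'   attribute.
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path, sampling_rate_hz = NULL) {
  sg <- resolve_signals(signals, sampling_rate_hz)
  utils::write.table(data.frame(x = sg$x, y = sg$y), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- c(sprintf("sampling_rate_hz: %.10g", sg$fs))
  if (!is.null(attr(signals, "truth"))) {
    meta <- c(meta, sprintf("truth: %s", attr(signals, "truth")))
  }
  spec <- attr(signals, "spec")
  if (!is.null(spec)) {
    for (nm in names(spec)) {
      meta <- c(meta, sprintf("spec.%s: %s", nm,
                              if (is.null(spec[[nm]])) "NULL" else
                                format(spec[[nm]])))
    }
  }
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read paired signals from delimited text
#'
#' Reads a file written by [write_signals()] (or any delimited text with
#' `x` and `y` columns). The sampling rate is taken from the `<path>.meta`
#' sidecar when present, else from `sampling_rate_hz`.
#'
#' @param path input file path.
#' @param sampling_rate_hz fallback sampling rate in Hz.
#' @return a `pcfc_signals` tibble with columns `time_s`, `x`, `y`.
#' @export
read_signals <- function(path, sampling_rate_hz = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("x", "y") %in% names(df))) {
    abort("file must contain `x` and `y` columns.",
          class = "pcfc_contract_violation")
  }
  fs <- sampling_rate_hz
  truth <- NULL
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    meta <- readLines(meta_path)
    fs_line <- grep("^sampling_rate_hz:", meta, value = TRUE)
    if (length(fs_line)) fs <- as.numeric(sub("^sampling_rate_hz: *", "",
                                              fs_line[1]))
    truth_line <- grep("^truth:", meta, value = TRUE)
    if (length(truth_line)) truth <- sub("^truth: *", "", truth_line[1])
  }
  if (is.null(fs) || !is.finite(fs)) {
    abort("no sampling rate: supply `sampling_rate_hz` or a sidecar file.",
          class = "pcfc_contract_violation")
  }
  out <- tibble::tibble(time_s = (seq_len(nrow(df)) - 1) / fs,
                        x = df$x, y = df$y)
  attr(out, "sampling_rate_hz") <- fs
  if (!is.null(truth)) attr(out, "truth") <- truth
  class(out) <- c("pcfc_signals", class(out))
  out
}

#' Write a comodulogram to delimited text
#'
#' Long-format tab-delimited table with columns `phase_hz`, `amp_hz`,
#' `value`, `p`, `p_cluster`, `significant`.
#'
#' @param cm a [comodulogram()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_comodulogram <- function(cm, path) {
  stopifnot(inherits(cm, "pcfc_comodulogram"))
  utils::write.table(as.data.frame(cm), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
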