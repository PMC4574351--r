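#' Read and write length-trace tables
#'
#' The exchange format is tab-delimited with header
#' `cell_id  mt_id  time_s  length_um`, one row per sample; a file may hold
#' many traces.
#'
#' @param traces list of `length_trace` objects (or one)
#' @param path file path
#' @return `write_traces` returns the path invisibly; `read_traces` a list
#'   of `length_trace` data.frames, one per `cell_id`/`mt_id` pair
#' @export
write_traces <- function(traces, path) {
  if (is.data.frame(traces)) traces <- list(traces)
  write_tsv(do.call(rbind, lapply(traces, as.data.frame)), path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- read_tsv(path)
  need <- c("cell_id", "mt_id", "time_s", "length_um")
  if (!all(need %in% names(df))) {
    stop("trace table must have columns ", paste(need, collapse = ", "))
  }
  if (any(df$length_um < 0)) stop("negative lengths in trace table")
  split_by <- interaction(df$cell_id, df$mt_id, drop = TRUE)
  lapply(split(df, split_by), function(tr) {
    tr <- tr[order(tr$time_s), ]
    rownames(tr) <- NULL
    dts <- diff(tr$time_s)
    if (length(dts) < 3) stop("trace has fewer than 4 samples")
    if (any(dts <= 0)) stop("times must be strictly increasing")
    structure(tr, dt = dts[1], class = c("length_trace", "data.frame"))
  })
}

#' Read and write GTPase titration tables
#'
#' Tab-delimited `substrate_uM  rate_uM_per_min` (rate mode) or
#' `substrate_uM  a621` (absorbance mode); standard series are
#' `pi_uM  a621`.
#'
#' @param series data.frame to write
#' @param path file path
#' @export
write_titration <- function(series, path) write_tsv(as.data.frame(series), path)

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  df <- read_tsv(path)
  if (!"substrate_uM" %in% names(df)) stop("missing substrate_uM column")
  class(df) <- c("titration_series", "data.frame")
  df
}

#' @rdname write_titration
#' @export
read_standard_series <- function(path) {
  df <- read_tsv(path)
  if (!all(c("pi_uM", "a621") %in% names(df))) {
    stop("standard series must have columns pi_uM, a621")
  }
  class(df) <- c("standard_series", "data.frame")
  df
}

#' Read a subunit mass table
#'
#' Two-column tab-delimited `name  mass_da`.
#'
#' @param path file path
#' @return data.frame `name`, `mass_da`
#' @export
read_subunits <- function(path) {
  df <- read_tsv(path)
  if (!all(c("name", "mass_da") %in% names(df))) {
    stop("subunit table must have columns name, mass_da")
  }
  df
}

#' Write or read a ground-truth sidecar
#'
#' Structured text (YAML) record of the parameters a synthetic data set was
#' generated from, for recovery-test harnesses.
#'
#' @param truth a list of ground-truth parameters (e.g. a [kinetic_truth()]
#'   or the `adjusted` element of [calibrate_generator()])
#' @param path file path
#' @export
write_ground_truth <- function(truth, path) {
  clean <- rapply(unclass(truth), unclass, how = "replace")
  writeLines(yaml::as.yaml(clean), path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) yaml::read_yaml(path)
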