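# Recording file format: delimited text (CSV with header "time,ap,si" or
# "ap,si") plus a JSON sidecar ("<path>.json") holding the sampling rate,
# provenance, seed, events and method parameters.

sidecar_path <- function(path) paste0(path, ".json")

#' Read a dual-axis recording from a delimited text file
#'
#' Expects a CSV with header columns `ap` and `si` (and optionally `time`);
#' the sampling rate comes from the JSON sidecar written by
#' [write_recording()], or from the `f_s` argument, which takes precedence.
#' A present `time` column must be uniformly spaced at `1/f_s` within one
#' part in 1e6.
#'
#' @param path Path to the CSV file.
#' @param f_s Optional sampling rate override (Hz).
#' @return A `swacc_recording` (without ground truth) with fields `data`,
#'   `f_s`, `events` (if recorded in the sidecar), `meta`.
#' @export
read_recording <- function(path, f_s = NULL) {
  abort_if(!file.exists(path), sprintf("file '%s' does not exist.", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("ap", "si"))
    abort_if(!col %in% names(data),
             sprintf("recording is missing the '%s' channel column.", col))
  abort_if(nrow(data) == 0L, "recording contains no samples.")
  abort_if(anyNA(data$ap) || anyNA(data$si),
           "recording contains missing (NA/NaN) samples.")
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (is.null(f_s)) f_s <- meta$f_s
  abort_if(is.null(f_s),
           "sampling rate not found: provide `f_s` or a sidecar with an f_s field.")
  check_scalar_number(f_s, "f_s", min = .Machine$double.eps)
  if ("time" %in% names(data) && nrow(data) > 1L) {
    dt <- diff(data$time)
    abort_if(any(abs(dt - 1 / f_s) > (1 / f_s) * 1e-6),
             "time column is not uniformly spaced at 1/f_s.")
  } else if (!"time" %in% names(data)) {
    data$time <- (seq_len(nrow(data)) - 1L) / f_s
  }
  events <- NULL
  if (!is.null(meta$events) && length(meta$events))
    events <- tibble::as_tibble(meta$events)
  structure(
    list(data = tibble::as_tibble(data[c("time", "ap", "si")]),
         truth = NULL, events = events, f_s = f_s,
         snr_db = meta$snr_db, realized_snr_db = meta$realized_snr_db,
         config = NULL, meta = meta),
    class = "swacc_recording")
}

#' Write a dual-axis recording and its metadata sidecar
#'
#' Writes the samples as full-precision CSV (`time`, `ap`, `si`) and a JSON
#' sidecar `<path>.json` with the sampling rate, seed, events, realized
#' SNR, generator configuration, package version and the invoking command
#' line.
#'
#' @param recording A `swacc_recording`, or a data frame with `ap`, `si`
#'   (and optionally `time`) columns.
#' @param path Output CSV path.
#' @param f_s Sampling rate, required when `recording` is a plain data
#'   frame without one.
#' @param extra Optional named list merged into the sidecar (e.g. method
#'   parameters).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, f_s = NULL, extra = list()) {
  if (inherits(recording, "swacc_recording")) {
    data <- recording$data
    f_s <- recording$f_s
    meta <- list(f_s = f_s, seed = recording$seed, snr_db = recording$snr_db,
                 realized_snr_db = as.list(recording$realized_snr_db),
                 events = if (!is.null(recording$events))
                   as.list(recording$events),
                 config = recording$config[!vapply(recording$config, is.null,
                                                   logical(1))])
  } else {
    abort_if(!is.data.frame(recording) ||
               !all(c("ap", "si") %in% names(recording)),
             "`recording` must have 'ap' and 'si' columns.")
    abort_if(is.null(f_s), "`f_s` is required for plain data frames.")
    data <- tibble::as_tibble(recording)
    if (!"time" %in% names(data))
      data$time <- (seq_len(nrow(data)) - 1L) / f_s
    data <- data[c("time", "ap", "si")]
    meta <- list(f_s = f_s)
  }
  meta$package_version <- as.character(utils::packageVersion("splinetrend"))
  meta$command <- paste(commandArgs(), collapse = " ")
  meta <- utils::modifyList(meta, extra)
  readr::write_csv(data, path, progress = FALSE)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
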