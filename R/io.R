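#' Write a recording to a plain-text container
#'
#' The container is a directory holding `voltage.csv` (channels x time, one
#' row per channel, no header) and `meta.json` with `sampling_rate_hz`,
#' `units`, `provenance`, and the layout (`n_rows`, `n_cols`, `pitch_um`,
#' per-channel `row`, `col`, `x_um`, `y_um`).  Round trips preserve 15
#' significant digits (CSV decimal serialisation).
#'
#' @param rec a [voltage_recording()].
#' @param path container directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "voltage_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.table::as.data.table(rec$voltage),
                     file.path(path, "voltage.csv"),
                     col.names = FALSE)
  lay <- rec$layout
  meta <- list(sampling_rate_hz = rec$sampling_rate, units = "uV",
               provenance = rec$provenance,
               layout = list(n_rows = lay$n_rows, n_cols = lay$n_cols,
                             pitch_um = lay$pitch, row = lay$row,
                             col = lay$col, x_um = lay$x_um, y_um = lay$y_um))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from a plain-text container
#'
#' Validates the schema: missing files or metadata keys raise an error
#' naming the missing piece; a channel count inconsistent with the layout is
#' a validation error.
#'
#' @param path container directory written by [write_recording()].
#' @return a [voltage_recording()].
#' @export
read_recording <- function(path) {
  vfile <- file.path(path, "voltage.csv")
  mfile <- file.path(path, "meta.json")
  if (!file.exists(vfile)) stop("schema error: missing voltage.csv")
  if (!file.exists(mfile)) stop("schema error: missing meta.json")
  meta <- jsonlite::read_json(mfile, simplifyVector = TRUE)
  for (key in c("sampling_rate_hz", "units", "layout"))
    if (is.null(meta[[key]])) stop("schema error: missing key '", key, "'")
  for (key in c("n_rows", "n_cols", "pitch_um"))
    if (is.null(meta$layout[[key]]))
      stop("schema error: missing layout key '", key, "'")
  v <- as.matrix(data.table::fread(vfile, header = FALSE))
  dimnames(v) <- NULL
  lay <- electrode_layout(meta$layout$n_rows, meta$layout$n_cols,
                          meta$layout$pitch_um)
  if (nrow(v) != lay$n_channels)
    stop("validation error: channel count (", nrow(v),
         ") does not match layout (", lay$n_channels, ")")
  voltage_recording(v, meta$sampling_rate_hz, lay,
                    provenance = meta$provenance)
}

#' Write ground truth or a wave table to CSV / JSON
#'
#' @param x data.frame (ground truth or the table from [detect_waves()]).
#' @param path output file; `.json` extension selects JSON, anything else
#'   CSV.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  else data.table::fwrite(x, path)
  invisible(path)
}

#' Read an event table written by [write_event_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_event_table <- function(path) {
  if (grepl("\\.json$", path))
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  else as.data.frame(data.table::fread(path))
}
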