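## Plain-text interchange: voltage frames as CSV with a JSON sidecar,
## ventilator logs, breath tables and 0/1 mask rasters as CSV.

#' Write / read a voltage series (CSV + JSON sidecar)
#'
#' @param series a \linkS4class{VoltageSeries}.
#' @param prefix file path prefix; writes \code{<prefix>.csv} and
#'   \code{<prefix>.json}.
#' @return the prefix, invisibly.
#' @export
writeVoltageSeries <- function(series, prefix) {
  fr <- series@frames
  colnames(fr) <- sprintf("ch%03d", seq_len(ncol(fr)))
  write.csv(fr, paste0(prefix, ".csv"), row.names = FALSE)
  meta <- series@metadata
  meta$frame_rate <- series@frameRate
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeVoltageSeries
#' @export
readVoltageSeries <- function(prefix) {
  fr <- as.matrix(read.csv(paste0(prefix, ".csv")))
  meta <- jsonlite::fromJSON(paste0(prefix, ".json"))
  fps <- meta$frame_rate
  meta$frame_rate <- NULL
  new("VoltageSeries", frames = unname(fr), frameRate = fps, metadata = meta)
}

#' Write / read a ventilator log
#'
#' @param log data.frame with step_label, stage, mode, PEEP, P_plat and
#'   optional PaO2, PaCO2, C_vent columns.
#' @param path CSV file path.
#' @export
writeVentilatorLog <- function(log, path) {
  write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVentilatorLog
#' @export
readVentilatorLog <- function(path) {
  log <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("step_label", "stage", "mode", "PEEP", "P_plat")
  if (!all(need %in% names(log)))
    stop("ventilator log must contain columns: ", paste(need, collapse = ", "))
  log
}

#' Write / read a breath table
#'
#' @param table a breath table from \code{\link{detectBreaths}} (or a
#'   manually corrected copy with the same columns).
#' @param path CSV file path.
#' @export
writeBreathTable <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBreathTable
#' @export
readBreathTable <- function(path) {
  bt <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("insp_frame", "exp_frame") %in% names(bt)))
    stop("breath table needs insp_frame and exp_frame columns")
  if (any(bt$insp_frame >= bt$exp_frame))
    stop("each breath needs insp_frame < exp_frame")
  class(bt) <- c("BreathTable", "data.frame")
  bt
}

#' Write a 0/1 mask raster as CSV
#'
#' @param mask logical matrix.
#' @param path CSV file path.
#' @param meta optional list written as a JSON sidecar.
#' @export
writeMaskCsv <- function(mask, path, meta = NULL) {
  write.table(matrix(as.integer(mask), nrow(mask), ncol(mask)),
              path, sep = ",", row.names = FALSE, col.names = FALSE)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a numeric raster (e.g. a compliance or F map) as CSV
#'
#' @param raster numeric matrix (NA allowed).
#' @param path CSV file path.
#' @export
writeRasterCsv <- function(raster, path) {
  write.table(raster, path, sep = ",", row.names = FALSE, col.names = FALSE,
              na = "")
  invisible(path)
}
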