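#' Read a recording from CSV tables
#'
#' The trace table has one row per unit: first column `unit_id`, remaining
#' columns the per-frame fluorescence values. The optional positions table
#' has columns `unit_id`, `x`, `y`.
#'
#' @param traces_csv Path to the trace CSV.
#' @param positions_csv Path to the positions CSV, or `NULL` for a
#'   recording without positions (distance analyses will then refuse to
#'   run).
#' @param fps Frames per second of the recording.
#' @param name Recording label; defaults to the trace file stem.
#' @return A [recording()].
#' @export
read_table <- function(traces_csv, positions_csv = NULL, fps,
                       name = NULL) {
  if (!file.exists(traces_csv)) stop("no such file: ", traces_csv)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("'fps' must be a single positive number")
  nf <- utils::count.fields(traces_csv, sep = ",")
  if (length(unique(nf)) != 1L)
    stop("ragged rows in ", traces_csv, ": rows have ",
         paste(unique(nf), collapse = ", "), " fields")
  df <- utils::read.csv(traces_csv, check.names = FALSE)
  if (ncol(df) < 3L) stop("trace table needs unit_id plus >= 2 frames")
  ids <- as.integer(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  pos <- NULL
  if (!is.null(positions_csv)) {
    if (!file.exists(positions_csv)) stop("no such file: ", positions_csv)
    pdf <- utils::read.csv(positions_csv)
    if (!all(c("unit_id", "x", "y") %in% names(pdf)))
      stop("positions table needs columns unit_id, x, y")
    pos <- neuron_positions(pdf$unit_id, pdf$x, pdf$y)
  }
  if (is.null(name))
    name <- tools::file_path_sans_ext(basename(traces_csv))
  recording(trace_matrix(mat, fps, ids), positions = pos, name = name)
}

#' Write a recording to CSV tables
#'
#' Inverse of [read_table()]. Values are written with 17 significant
#' digits so the round trip reproduces doubles bit-for-bit.
#'
#' @param rec A [recording()].
#' @param traces_csv Output path for the trace table.
#' @param positions_csv Output path for the positions table (only written
#'   when the recording has positions).
#' @return `traces_csv`, invisibly.
#' @export
write_table <- function(rec, traces_csv, positions_csv = NULL) {
  stopifnot(inherits(rec, "recording"))
  mat <- unclass(rec$traces)
  chr <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat))
  out <- cbind(unit_id = as.character(unit_ids(rec)), chr)
  colnames(out) <- c("unit_id", sprintf("f%d", seq_len(ncol(mat)) - 1L))
  utils::write.table(out, traces_csv, sep = ",", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(positions_csv) && !is.null(rec$positions)) {
    p <- rec$positions
    pout <- data.frame(unit_id = p$unit_id, x = sprintf("%.17g", p$x),
                       y = sprintf("%.17g", p$y))
    utils::write.table(pout, positions_csv, sep = ",", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(traces_csv)
}

#' Write a spreadsheet report with CSV mirrors
#'
#' Writes one workbook with one sheet per table, and mirrors every table
#' as a CSV file next to the workbook (named `<stem>_<sheet>.csv`).
#'
#' @param tables Named list of rectangular data frames.
#' @param path Output `.xlsx` path.
#' @return Invisible character vector: the workbook path followed by the
#'   mirror CSV paths.
#' @export
#'
#' @examples
#' \donttest{
#' tf <- tempfile(fileext = ".xlsx")
#' write_report(list(metrics = data.frame(name = "nsd", value = 12.5)), tf)
#' read_xlsx_sheet(tf, "metrics")
#' }
write_report <- function(tables, path) {
  if (length(tables) == 0L) stop("nothing to write")
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("every table must be named")
  tables <- lapply(tables, as.data.frame)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  xlsx_write(tables, path)
  stem <- tools::file_path_sans_ext(path)
  mirrors <- character(length(tables))
  for (i in seq_along(tables)) {
    mirrors[i] <- sprintf("%s_%s.csv", stem,
                          sanitize_sheet_name(names(tables)[i]))
    utils::write.csv(tables[[i]], mirrors[i], row.names = FALSE)
  }
  invisible(c(path, mirrors))
}
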