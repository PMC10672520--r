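# Minimal zarr-v2 directory-store support (the layout CNMF extraction
# pipelines such as Minian emit): JSON array metadata, C- or F-order
# chunks, raw or zlib-compressed. Enough to round-trip trace matrices,
# footprints and positions without further dependencies.

zarr_dtype <- function(dtype) {
  m <- regmatches(dtype, regexec("^[<>|]?([a-z])([0-9]+)$", dtype))[[1]]
  if (length(m) == 0L) stop("unsupported zarr dtype: ", dtype)
  kind <- m[2]; bytes <- as.integer(m[3])
  if (kind == "f") list(what = "double", size = bytes, signed = TRUE)
  else if (kind == "i") list(what = "integer", size = bytes, signed = TRUE)
  else if (kind == "u") list(what = "integer", size = bytes, signed = FALSE)
  else stop("unsupported zarr dtype: ", dtype)
}

# read one zarr array (any rank) into an R array, R (col-major) layout
zarr_read_array <- function(dir) {
  meta_path <- file.path(dir, ".zarray")
  if (!file.exists(meta_path)) stop("not a zarr array: ", dir)
  meta <- jsonlite::fromJSON(meta_path)
  shape <- as.integer(meta$shape)
  chunks <- as.integer(meta$chunks)
  dt <- zarr_dtype(meta$dtype)
  comp_id <- if (is.null(meta$compressor)) NULL else meta$compressor$id
  if (!is.null(comp_id) && comp_id != "zlib")
    stop(sprintf("unsupported zarr compressor '%s' (only zlib/raw)", comp_id))
  if (!is.null(meta$filters) && length(meta$filters) > 0)
    stop("zarr filters are not supported")
  order_c <- identical(meta$order, "C")
  fill <- if (is.null(meta$fill_value)) 0 else meta$fill_value
  sep <- if (!is.null(meta$dimension_separator)) meta$dimension_separator
         else "."
  rank <- length(shape)
  fill <- if (dt$what == "double") as.numeric(fill) else as.integer(fill)
  out <- array(fill, dim = shape)
  grid <- lapply(seq_len(rank), function(d)
    seq_len(ceiling(shape[d] / chunks[d])) - 1L)
  for (cell in split(as.matrix(expand.grid(grid)),
                     seq_len(prod(vapply(grid, length, integer(1)))))) {
    cfile <- file.path(dir, paste(cell, collapse = sep))
    if (!file.exists(cfile)) next   # missing chunk = fill_value
    bytes <- readBin(cfile, "raw", file.info(cfile)$size)
    if (identical(comp_id, "zlib"))
      bytes <- memDecompress(bytes, type = "gzip")
    vals <- readBin(bytes, dt$what, n = prod(chunks), size = dt$size,
                    signed = dt$signed, endian = "little")
    ch <- if (order_c) aperm(array(vals, dim = rev(chunks)), rev(seq_len(rank)))
          else array(vals, dim = chunks)
    idx <- lapply(seq_len(rank), function(d) {
      lo <- cell[d] * chunks[d] + 1L
      lo:min(lo + chunks[d] - 1L, shape[d])
    })
    keep <- lapply(seq_len(rank), function(d) seq_along(idx[[d]]))
    out[matrix_index(idx)] <- ch[matrix_index(keep)]
  }
  out
}

# cartesian index matrix for `[` with a list of per-dim indices
matrix_index <- function(idx) as.matrix(expand.grid(idx))

# write one R array as a single-chunk zlib-compressed zarr array
zarr_write_array <- function(x, dir, dtype = "<f8") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  dt <- zarr_dtype(dtype)
  meta <- list(zarr_format = 2L, shape = as.integer(shape),
               chunks = as.integer(shape), dtype = dtype,
               compressor = list(id = "zlib", level = 6L),
               fill_value = 0, filters = NULL, order = "C")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null"),
             file.path(dir, ".zarray"))
  vals <- if (length(shape) > 1L)
    as.vector(aperm(x, rev(seq_along(shape)))) else as.vector(x)
  payload <- writeBin(if (dt$what == "double") as.numeric(vals)
                      else as.integer(vals),
                      raw(), size = dt$size, endian = "little")
  writeBin(memCompress(payload, type = "gzip"),
           file.path(dir, paste(rep("0", length(shape)), collapse = ".")))
  invisible(dir)
}

#' Read a recording from a labeled-array (zarr) store
#'
#' Reads the conventional CNMF output layout: a zarr-v2 group directory
#' with a 2-D trace array (units x frames, default name `"C"`) and
#' optionally a 3-D footprint array (units x height x width, default name
#' `"A"`). When footprints are present, unit positions are their
#' intensity-weighted centroids (x along width, y along height, 0-based
#' pixels); footprints themselves are discarded — point centroids are the
#' canonical position representation downstream. A 2-D `position` array
#' (units x \[x, y\]) and a 1-D `unit_id` array are also honoured when
#' present. NetCDF containers are not supported; convert upstream output
#' to zarr or CSV.
#'
#' @param path Store directory.
#' @param trace_var Name of the trace array.
#' @param footprint_var Name of the footprint array (skipped when absent).
#' @param fps Frames per second (not stored in the array layout).
#' @param nan `"reject"` (default) fails when traces contain NaN, listing
#'   the offending units; `"interpolate"` linearly fills interior gaps of
#'   at most `max_gap` frames.
#' @param max_gap Longest NaN gap the interpolation is willing to fill.
#' @param name Recording label; defaults to the store directory name.
#' @return A [recording()].
#' @export
read_labeled_store <- function(path, trace_var = "C", footprint_var = "A",
                               fps = 20, nan = c("reject", "interpolate"),
                               max_gap = 5L, name = NULL) {
  nan <- match.arg(nan)
  if (!dir.exists(path)) {
    if (file.exists(path) && grepl("\\.(nc|netcdf)$", path,
                                   ignore.case = TRUE))
      stop("NetCDF stores are not supported; convert to zarr or CSV")
    stop("no such store: ", path)
  }
  tdir <- file.path(path, trace_var)
  if (!file.exists(file.path(tdir, ".zarray")))
    stop(sprintf("store variable '%s' not found in %s", trace_var, path))
  traces <- zarr_read_array(tdir)
  if (length(dim(traces)) != 2L)
    stop(sprintf("store variable '%s' must be 2-D (unit x frame)",
                 trace_var))
  ids <- if (file.exists(file.path(path, "unit_id", ".zarray")))
    as.integer(zarr_read_array(file.path(path, "unit_id")))
  else seq_len(nrow(traces)) - 1L
  if (anyNA(traces)) {
    if (nan == "reject") {
      bad <- ids[apply(traces, 1L, anyNA)]
      stop("NaN frames in units: ", paste(bad, collapse = ", "),
           " (use nan = 'interpolate' for isolated gaps)")
    }
    traces <- t(apply(traces, 1L, interpolate_gaps, max_gap = max_gap))
  }
  pos <- NULL
  if (!is.null(footprint_var) &&
      file.exists(file.path(path, footprint_var, ".zarray"))) {
    A <- zarr_read_array(file.path(path, footprint_var))
    if (length(dim(A)) != 3L)
      stop(sprintf("store variable '%s' must be 3-D (unit x height x width)",
                   footprint_var))
    pos <- footprint_centroids(A, ids)
  } else if (file.exists(file.path(path, "position", ".zarray"))) {
    P <- zarr_read_array(file.path(path, "position"))
    pos <- neuron_positions(ids, P[, 1], P[, 2])
  }
  if (is.null(name)) name <- basename(normalizePath(path))
  recording(trace_matrix(traces, fps, ids), positions = pos, name = name)
}

# intensity-weighted centroids of unit x height x width footprints
footprint_centroids <- function(A, ids) {
  nu <- dim(A)[1]
  xs <- numeric(nu); ys <- numeric(nu)
  wcol <- seq_len(dim(A)[3]) - 1L  # x: width index, 0-based pixels
  hrow <- seq_len(dim(A)[2]) - 1L  # y: height index
  for (i in seq_len(nu)) {
    f <- A[i, , ]
    tot <- sum(f)
    if (tot <= 0) stop(sprintf("unit %d has an empty footprint", ids[i]))
    xs[i] <- sum(t(f) * wcol) / tot
    ys[i] <- sum(f * hrow) / tot
  }
  neuron_positions(ids, xs, ys)
}

interpolate_gaps <- function(x, max_gap = 5L) {
  if (!anyNA(x)) return(x)
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (g in which(r$values)) {
    if (r$lengths[g] > max_gap)
      stop(sprintf("NaN gap of %d frames exceeds max_gap = %d",
                   r$lengths[g], max_gap))
    lo <- starts[g] - 1L; hi <- ends[g] + 1L
    if (lo < 1L || hi > length(x))
      stop("NaN gap touches the recording edge; cannot interpolate")
    x[starts[g]:ends[g]] <- x[lo] +
      (x[hi] - x[lo]) * (seq_len(r$lengths[g])) / (r$lengths[g] + 1L)
  }
  x
}

#' Write a recording as a labeled-array (zarr) store
#'
#' Inverse of [read_labeled_store()] for the arrays this package uses:
#' writes `C` (traces, float64), `unit_id`, and `position` (x, y) when the
#' recording has positions, as single-chunk zlib-compressed zarr-v2
#' arrays.
#'
#' @param rec A [recording()].
#' @param path Store directory to create.
#' @return `path`, invisibly.
#' @export
write_labeled_store <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  writeLines('{"zarr_format":2}', file.path(path, ".zgroup"))
  zarr_write_array(unclass(rec$traces), file.path(path, "C"), "<f8")
  zarr_write_array(unit_ids(rec), file.path(path, "unit_id"), "<i4")
  if (!is.null(rec$positions))
    zarr_write_array(cbind(rec$positions$x, rec$positions$y),
                     file.path(path, "position"), "<f8")
  invisible(path)
}
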