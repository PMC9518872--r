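#' Read a 4D BOLD image series
#'
#' Reads an ANALYZE 7.5 (`.hdr`/`.img`) or NIfTI-1 (`.nii`/`.nii.gz`) file
#' and attaches the repetition time. Header scaling (scl_slope/scl_inter) is
#' applied on read; both byte orders are supported. ANALYZE carries no
#' orientation, so the voxel grid is taken as stored and never re-oriented:
#' any mask or parcellation supplied later must share the same grid.
#'
#' @param path Path to the image file (`.nii`, `.nii.gz`, or the `.hdr` of an
#'   ANALYZE/NIfTI pair).
#' @param tr Repetition time in seconds (> 0). Frame `i` (0-based) is
#'   assigned acquisition time `i * tr`.
#' @return An object of class `image4d`: a list with `data` (4D array),
#'   `voxel_size` (mm, length 3), `tr` (s), `n_frames`, and `template` (the
#'   source header, reused verbatim when maps are written back out).
#' @export
read_image_4d <- function(path, tr) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("tr must be a single positive number (seconds)")
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4L) stop("expected 4D series, got ", length(dm), "D image")
  if (dm[4] < 2L) stop("expected 4D series with >= 2 frames")
  pd <- RNifti::pixdim(img)
  vox <- abs(pd[1:3])
  if (any(!is.finite(vox)) || any(vox <= 0)) stop("corrupt header: non-positive voxel sizes")
  image4d(as.array(img), voxel_size = vox, tr = tr, template = img)
}

#' Construct an in-memory 4D image volume
#'
#' @param data 4D numeric array (x, y, z, frame).
#' @param voxel_size Voxel edge lengths in mm (length 3).
#' @param tr Repetition time in seconds.
#' @param template Optional source image header carried through to writers.
#' @return An `image4d` object.
#' @export
image4d <- function(data, voxel_size = c(1, 1, 1), tr = 1, template = NULL) {
  if (length(dim(data)) != 4L) stop("expected 4D series")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0), tr > 0)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 tr = as.numeric(tr), n_frames = dim(data)[4],
                 template = template),
            class = "image4d")
}

#' @export
print.image4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image4d> %dx%dx%d voxels x %d frames, voxel %s mm, TR %.3g s\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_size, 3), collapse = "x"), x$tr))
  invisible(x)
}

#' Read a raw CO2 trace
#'
#' Accepts a plain-text/CSV capnogram: either two columns (time in seconds,
#' CO2 partial pressure in mmHg) or a single column of pressures with the
#' sampling rate given as `fs`. Delimiters may be comma, tab, semicolon or
#' whitespace; decimal separator is ".". Lines starting with `#` are skipped.
#'
#' @param path Path to the trace file.
#' @param fs Sampling rate in Hz, required for single-column files.
#' @return A `co2_trace`: list with `t` (s, strictly increasing), `p`
#'   (mmHg) and `fs_native` (Hz).
#' @export
read_co2_trace <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("CO2 trace file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("CO2 trace must contain at least 2 samples")
  fields <- strsplit(lines, "[,;\t ]+")
  ncols <- lengths(fields)
  if (any(ncols != ncols[1])) stop("inconsistent column count in CO2 trace")
  vals <- suppressWarnings(vapply(fields, function(f) as.numeric(f), numeric(ncols[1])))
  if (anyNA(vals)) stop("non-numeric entries in CO2 trace")
  if (ncols[1] == 1L) {
    if (is.null(fs)) stop("single-column CO2 trace requires a sampling rate (fs)")
    p <- as.numeric(vals)
    t <- (seq_along(p) - 1) / fs
  } else if (ncols[1] == 2L) {
    t <- vals[1, ]
    p <- vals[2, ]
    if (any(diff(t) <= 0)) stop("CO2 trace time axis must be strictly increasing")
    fs <- 1 / median(diff(t))
  } else {
    stop("CO2 trace must have 1 or 2 columns, got ", ncols[1])
  }
  co2_trace(t, p, fs)
}

#' Construct a CO2 trace object
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param p CO2 partial pressures in mmHg.
#' @param fs_native Native sampling rate in Hz.
#' @return A `co2_trace` object.
#' @export
co2_trace <- function(t, p, fs_native) {
  if (length(t) != length(p)) stop("t and p must have equal length")
  if (length(t) < 2L) stop("CO2 trace must contain at least 2 samples")
  if (any(diff(t) <= 0)) stop("CO2 trace time axis must be strictly increasing")
  if (any(!is.finite(p))) stop("CO2 trace pressures must be finite")
  if (!is.finite(fs_native) || fs_native < 1 || fs_native > 1000)
    stop("fs_native must lie in [1, 1000] Hz")
  structure(list(t = as.numeric(t), p = as.numeric(p),
                 fs_native = as.numeric(fs_native)),
            class = "co2_trace")
}

#' @export
print.co2_trace <- function(x, ...) {
  cat(sprintf("<co2_trace> %d samples, %.1f s @ %.3g Hz, range %.1f-%.1f mmHg\n",
              length(x$p), diff(range(x$t)), x$fs_native, min(x$p), max(x$p)))
  invisible(x)
}

#' Read rigid-body motion parameters
#'
#' Reads a whitespace- or comma-delimited text file with six numeric columns
#' (3 translations in mm, 3 rotations in rad), one row per BOLD frame, as
#' produced by standard realignment tools.
#'
#' @param path Path to the motion parameter file.
#' @return A numeric matrix of class `motion_params` (N x 6).
#' @export
read_motion_params <- function(path) {
  if (!file.exists(path)) stop("motion parameter file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- tryCatch(read.table(path, sep = sep, header = FALSE,
                             colClasses = "numeric", comment.char = "#"),
                  error = function(e) stop("non-numeric entries in motion file: ",
                                           conditionMessage(e)))
  if (ncol(tab) != 6L)
    stop("motion parameter file must have 6 columns, got ", ncol(tab))
  m <- as.matrix(tab)
  dimnames(m) <- list(NULL, c("tx_mm", "ty_mm", "tz_mm", "rx_rad", "ry_rad", "rz_rad"))
  class(m) <- c("motion_params", class(m))
  m
}

write_motion_params <- function(motion, path) {
  write.table(format(unclass(motion), digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "  ", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a 3D map as NIfTI with source geometry
#'
#' @param map 3D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param template Optional source image (or `image4d`) providing geometry.
#' @return The path, invisibly.
#' @export
write_map <- function(map, path, template = NULL) {
  if (inherits(template, "image4d")) template <- template$template
  img <- if (is.null(template)) RNifti::asNifti(map)
         else RNifti::asNifti(map, reference = template)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write pipeline outputs and a manifest
#'
#' Writes CVR/shift maps as NIfTI (source geometry), tables as CSV, JSON
#' blocks as JSON and reports as plain text, and returns a manifest
#' data.frame (also saved as `manifest.json`).
#'
#' @param out_dir Output directory, created if missing.
#' @param maps Named list of 3D arrays (written as `<name>.nii.gz`).
#' @param tables Named list of data.frames (written as `<name>.csv`).
#' @param json Named list of lists (written as `<name>.json`).
#' @param reports Named list of character vectors (written as `<name>.txt`).
#' @param template Optional source image for map geometry.
#' @return Data frame with columns `name`, `type`, `file`.
#' @export
write_outputs <- function(out_dir, maps = list(), tables = list(),
                          json = list(), reports = list(), template = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2L) != 0L) stop("output directory not writable: ", out_dir)
  rows <- list()
  add <- function(name, type, file) rows[[length(rows) + 1L]] <<-
    data.frame(name = name, type = type, file = file, stringsAsFactors = FALSE)
  for (nm in names(maps)) {
    f <- file.path(out_dir, paste0(nm, ".nii.gz"))
    write_map(maps[[nm]], f, template)
    add(nm, "map", basename(f))
  }
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], f, row.names = FALSE)
    add(nm, "table", basename(f))
  }
  for (nm in names(json)) {
    f <- file.path(out_dir, paste0(nm, ".json"))
    jsonlite::write_json(json[[nm]], f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add(nm, "json", basename(f))
  }
  for (nm in names(reports)) {
    f <- file.path(out_dir, paste0(nm, ".txt"))
    writeLines(reports[[nm]], f)
    add(nm, "report", basename(f))
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
              else data.frame(name = character(), type = character(), file = character())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  manifest
}
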