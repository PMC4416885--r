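#' Read a hyperspectral cube from an ENVI-style file pair
#'
#' Reads the single supported on-disk dialect: a text header (`<path>.hdr`)
#' describing a band-sequential (BSQ) raster of 32-bit little-endian floats
#' (`data type = 4`) stored in `<path>`. Files whose wavelength list is
#' descending (a common instrument convention) are reordered so the in-memory
#' axis is always ascending, with spectra reversed consistently.
#'
#' @param path path to the binary raster; the header is `<path>.hdr`.
#' @return a [spectral_cube()].
#' @export
read_cube <- function(path) {
  hdr <- read_envi_header(envi_header_path(path))
  for (f in c("samples", "lines", "bands", "interleave", "data type", "wavelength"))
    if (is.null(hdr[[f]]))
      stop("ENVI header missing required field `", f, "`", call. = FALSE)
  if (tolower(hdr$interleave) != "bsq")
    stop("unsupported interleave `", hdr$interleave, "`; only bsq is supported",
         call. = FALSE)
  if (as.integer(hdr[["data type"]]) != 4L)
    stop("unsupported data type `", hdr[["data type"]],
         "`; only 4 (32-bit float) is supported", call. = FALSE)
  ns <- as.integer(hdr$samples); nl <- as.integer(hdr$lines); nb <- as.integer(hdr$bands)
  wl <- hdr$wavelength
  if (length(wl) != nb)
    stop("header declares ", nb, " bands but lists ", length(wl),
         " wavelength entries", call. = FALSE)
  n <- ns * nl * nb
  if (file.size(path) != 4 * n)
    stop("raster size (", file.size(path), " bytes) does not match header dims (",
         4 * n, " bytes expected)", call. = FALSE)
  raw <- readBin(path, "numeric", n = n, size = 4L, endian = "little")
  # BSQ: band-major, within a band samples (cols) vary fastest then lines (rows)
  x <- array(raw, dim = c(ns, nl, nb))     # [col, row, band]
  x <- aperm(x, c(2, 1, 3))                # [row, col, band]
  if (is.unsorted(wl)) {
    if (is.unsorted(rev(wl)))
      stop("wavelength list is neither ascending nor descending", call. = FALSE)
    wl <- rev(wl)
    x <- x[, , rev(seq_len(nb)), drop = FALSE]
  }
  pitch <- if (!is.null(hdr[["pixel size um"]])) as.numeric(hdr[["pixel size um"]]) else 6.25
  prov <- if (!is.null(hdr$description)) as.character(hdr$description) else character()
  spectral_cube(x, wavenumber_axis(values = wl), pitch,
                c(prov, paste0("read_cube: ", path)))
}

#' Write a hyperspectral cube as an ENVI-style file pair
#'
#' Writes the cube bit-exactly (after the lossless float32 representation) as
#' a BSQ raster of 32-bit little-endian floats plus a text header recording
#' dimensions, interleave, data type, the wavelength list in cm^-1 and the
#' custom key `pixel size um`.
#'
#' @param cube a [spectral_cube()].
#' @param path output path for the binary raster; the header is written to
#'   `<path>.hdr`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (!all(is.finite(cube$data)))
    stop("cube contains non-finite values; refusing to write", call. = FALSE)
  d <- dim(cube$data)
  wl <- as.numeric(cube$axis)
  hdr <- c(
    "ENVI",
    "description = {irheart spectral cube}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    paste0("pixel size um = ", format(cube$pixel_pitch, digits = 17)),
    paste0("wavelength units = cm-1"),
    paste0("wavelength = {", paste(format(wl, digits = 17, trim = TRUE),
                                   collapse = ", "), "}")
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  x <- aperm(cube$data, c(2, 1, 3))  # [col, row, band] -> BSQ order on disk
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
  writeLines(hdr, envi_header_path(path))
  invisible(path)
}

envi_header_path <- function(path) paste0(path, ".hdr")

# Minimal parser for the supported header dialect: `key = value` lines,
# brace-delimited lists allowed to span lines.
read_envi_header <- function(hdr_path) {
  if (!file.exists(hdr_path))
    stop("ENVI header not found: ", hdr_path, call. = FALSE)
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  out <- list()
  # tokenize on key = value with value possibly a multi-line {...} block
  pat <- "(?m)^\\s*([A-Za-z][A-Za-z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) stop("malformed ENVI header: no key = value entries", call. = FALSE)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    eq <- regexpr("=", piece, fixed = TRUE)
    key <- trimws(substr(piece, 1L, eq - 1L))
    val <- trimws(substr(piece, eq + 1L, nchar(piece)))
    if (startsWith(val, "{")) {
      val <- gsub("^\\{|\\}$", "", val)
      val <- suppressWarnings(as.numeric(trimws(strsplit(val, ",")[[1]])))
      if (anyNA(val)) val <- NULL  # non-numeric list (e.g. description) dropped
    }
    out[[tolower(key)]] <- val
  }
  # description kept as text if present
  dm <- regmatches(txt, regexpr("description\\s*=\\s*\\{[^}]*\\}", txt))
  if (length(dm)) out$description <- gsub("^.*\\{|\\}$", "", dm)
  out
}

#' Read / write a label raster
#'
#' Label rasters pair a cube with per-pixel integer class codes
#' (0 = unlabeled/unclassified, 1 = Myocardium, 2 = Endocardium,
#' 3 = Fibrosis-Endocardium, 4 = Fibrosis-Myocardium, 5 = Lymphocytes).
#' On disk they are single-band ENVI rasters of unsigned bytes
#' (`data type = 1`).
#'
#' @param labels integer matrix with codes in 0..5.
#' @param path raster path (header at `<path>.hdr`).
#' @return `read_label_raster`: the integer label matrix;
#'   `write_label_raster`: `path`, invisibly.
#' @export
write_label_raster <- function(labels, path) {
  labels <- validate_labels(labels)
  hdr <- c("ENVI",
           paste0("samples = ", ncol(labels)),
           paste0("lines = ", nrow(labels)),
           "bands = 1",
           "header offset = 0",
           "data type = 1",
           "interleave = bsq",
           "byte order = 0")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(t(labels)), con)
  writeLines(hdr, envi_header_path(path))
  invisible(path)
}

#' @rdname write_label_raster
#' @export
read_label_raster <- function(path) {
  hdr <- read_envi_header(envi_header_path(path))
  ns <- as.integer(hdr$samples); nl <- as.integer(hdr$lines)
  if (as.integer(hdr$bands) != 1L || as.integer(hdr[["data type"]]) != 1L)
    stop("label raster must be single-band unsigned bytes", call. = FALSE)
  if (file.size(path) != ns * nl)
    stop("label raster size does not match header dims", call. = FALSE)
  raw <- readBin(path, "raw", n = ns * nl)
  validate_labels(matrix(as.integer(raw), nrow = nl, ncol = ns, byrow = TRUE))
}

validate_labels <- function(labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L) || any(labels > 5L))
    stop("label codes must be integers in 0..5", call. = FALSE)
  labels
}

#' Histologic class codes and names
#'
#' @return named integer vector mapping class names to codes 1..5.
#' @export
class_codes <- function() {
  c(Myocardium = 1L, Endocardium = 2L, `Fibrosis-Endocardium` = 3L,
    `Fibrosis-Myocardium` = 4L, Lymphocytes = 5L)
}

class_name <- function(code) {
  nm <- c("Unclassified", names(class_codes()))
  nm[code + 1L]
}
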