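#' Hyperspectral absorbance cube
#'
#' The pipeline's central object: a rows x cols x bands array of absorbance
#' (absorbance units, AU) with a [wavenumber_axis()] and a pixel pitch in
#' micrometres (6.25 um for full-resolution imaging, 25 um for the coarse
#' mode).
#'
#' @param data numeric array `[rows, cols, bands]`, all values finite.
#' @param axis a [wavenumber_axis()]; its length must equal `dim(data)[3]`.
#' @param pixel_pitch pixel size in um (> 0).
#' @param provenance free-text provenance notes (character vector).
#' @return an object of class `spectral_cube` (a list with elements `data`,
#'   `axis`, `pixel_pitch`, `provenance`).
#' @export
spectral_cube <- function(data, axis, pixel_pitch = 6.25, provenance = character()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a rows x cols x bands array", call. = FALSE)
  if (!inherits(axis, "wavenumber_axis")) axis <- wavenumber_axis(values = axis)
  if (dim(data)[3] != length(axis))
    stop("bands dimension (", dim(data)[3], ") does not match axis length (",
         length(axis), ")", call. = FALSE)
  if (!all(is.finite(data)))
    stop("cube contains non-finite absorbance values", call. = FALSE)
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L || pixel_pitch <= 0)
    stop("`pixel_pitch` must be a single positive number (um)", call. = FALSE)
  structure(list(data = data, axis = axis, pixel_pitch = pixel_pitch,
                 provenance = as.character(provenance)),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  v <- as.numeric(x$axis)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%.6g-%.6g cm^-1), %.4g um pitch\n",
              d[1], d[2], d[3], v[1], v[length(v)], x$pixel_pitch))
  if (length(x$provenance)) cat("provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

# pixels-by-bands matrix view (row index runs over rows fastest, matching
# R's array flattening); used by the vectorized preprocessing/metric code.
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}

matrix_cube <- function(mat, template) {
  d <- dim(template$data)
  spectral_cube(array(mat, dim = d), template$axis, template$pixel_pitch,
                template$provenance)
}

#' Truncate a cube to a wavenumber range
#'
#' Keeps only the bands inside the closed interval `[lo, hi]`, mirroring the
#' truncation applied to raw interferometer output for storage.
#'
#' @param cube a [spectral_cube()].
#' @param lo,hi range bounds in cm^-1, `lo < hi`.
#' @return a [spectral_cube()] restricted to the requested bands.
#' @export
truncate_range <- function(cube, lo, hi) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (!(lo < hi)) stop("`lo` must be < `hi`", call. = FALSE)
  v <- as.numeric(cube$axis)
  idx <- which(v >= lo - 1e-9 & v <= hi + 1e-9)
  if (length(idx) < 2L)
    stop("range [", lo, ", ", hi, "] does not intersect the axis (",
         v[1], "-", v[length(v)], " cm^-1)", call. = FALSE)
  spectral_cube(cube$data[, , idx, drop = FALSE],
                wavenumber_axis(values = v[idx]),
                cube$pixel_pitch, cube$provenance)
}

#' Spatially bin a cube
#'
#' Replaces each `factor` x `factor` block of pixels by its unweighted mean
#' spectrum and multiplies the pixel pitch accordingly — the software analog
#' of acquiring at a coarser pixel size (6.25 um binned 4x gives 25 um).
#' Trailing rows/columns that do not fill a block are dropped (recorded in
#' provenance). Binning operates on raw absorbance; any mask is re-derived
#' afterwards.
#'
#' @param cube a [spectral_cube()].
#' @param factor integer binning factor >= 1.
#' @return the binned [spectral_cube()].
#' @export
bin_pixels <- function(cube, factor) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be a single integer >= 1", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(cube)
  d <- dim(cube$data)
  nr <- d[1] %/% factor; nc <- d[2] %/% factor
  if (nr < 1L || nc < 1L)
    stop("cube smaller than one ", factor, "x", factor, " block", call. = FALSE)
  dropped <- c(d[1] - nr * factor, d[2] - nc * factor)
  x <- cube$data[seq_len(nr * factor), seq_len(nc * factor), , drop = FALSE]
  # average factor x factor blocks band by band via dimension folding
  dim(x) <- c(factor, nr, factor, nc, d[3])
  out <- apply(x, c(2, 4, 5), mean)
  prov <- cube$provenance
  if (any(dropped > 0))
    prov <- c(prov, sprintf("bin_pixels: dropped %d trailing rows, %d trailing cols",
                            dropped[1], dropped[2]))
  prov <- c(prov, sprintf("bin_pixels: factor %d", factor))
  spectral_cube(out, cube$axis, cube$pixel_pitch * factor, prov)
}

#' Stitch cube tiles into a mosaic
#'
#' Reassembles separately acquired rectangular regions into one composite
#' image. The mosaic is sized to the tiles' bounding box; pixels covered by
#' no tile are zero-filled (and flagged in provenance) so the downstream
#' amide-I mask removes them; where tiles overlap, the last tile wins.
#'
#' @param tiles a list; each element a list with components `cube`
#'   (a [spectral_cube()]), `row_offset`, `col_offset` (0-based, >= 0).
#' @return the stitched [spectral_cube()].
#' @export
stitch_tiles <- function(tiles) {
  if (!length(tiles)) stop("no tiles to stitch", call. = FALSE)
  cubes <- lapply(tiles, `[[`, "cube")
  ax <- cubes[[1]]$axis; pitch <- cubes[[1]]$pixel_pitch
  for (cb in cubes) {
    if (!isTRUE(all.equal(as.numeric(cb$axis), as.numeric(ax), tolerance = 0)))
      stop("tiles have incompatible wavenumber axes", call. = FALSE)
    if (cb$pixel_pitch != pitch)
      stop("tiles have incompatible pixel pitch", call. = FALSE)
  }
  ro <- vapply(tiles, function(t) as.integer(t$row_offset), integer(1))
  co <- vapply(tiles, function(t) as.integer(t$col_offset), integer(1))
  if (any(ro < 0) || any(co < 0)) stop("offsets must be non-negative", call. = FALSE)
  nr <- max(mapply(function(cb, o) o + dim(cb$data)[1], cubes, ro))
  nc <- max(mapply(function(cb, o) o + dim(cb$data)[2], cubes, co))
  out <- array(0, dim = c(nr, nc, length(ax)))
  covered <- matrix(FALSE, nr, nc)
  for (i in seq_along(tiles)) {
    d <- dim(cubes[[i]]$data)
    rr <- ro[i] + seq_len(d[1]); cc <- co[i] + seq_len(d[2])
    out[rr, cc, ] <- cubes[[i]]$data
    covered[rr, cc] <- TRUE
  }
  prov <- sprintf("stitch_tiles: %d tiles, %d x %d mosaic", length(tiles), nr, nc)
  if (!all(covered))
    prov <- c(prov, sprintf("stitch_tiles: %d uncovered pixels zero-filled",
                            sum(!covered)))
  spectral_cube(out, ax, pitch, c(cubes[[1]]$provenance, prov))
}
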