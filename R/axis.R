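#' Wavenumber axis
#'
#' A uniformly spaced, strictly increasing wavenumber grid in cm^-1. The
#' mid-infrared storage range used throughout is 800-4000 cm^-1 with a
#' 2 cm^-1 step (4 cm^-1 instrument resolution); cubes are always held with
#' an ascending axis in memory even when a file stores bands in descending
#' order.
#'
#' @param lo,hi range endpoints in cm^-1 (inclusive); must lie in
#'   \[800, 4000\].
#' @param step grid step in cm^-1 (default 2).
#' @param values alternatively, an explicit vector of wavenumbers; `lo`,
#'   `hi`, `step` are then ignored.
#' @return an object of class `wavenumber_axis`: a numeric vector of
#'   wavenumbers with a `step` attribute.
#' @examples
#' ax <- wavenumber_axis(800, 4000)
#' length(ax)  # 1601 bands
#' @export
wavenumber_axis <- function(lo = 800, hi = 4000, step = 2, values = NULL) {
  if (is.null(values)) {
    stopifnot(is.numeric(lo), is.numeric(hi), lo < hi, step > 0)
    values <- seq(lo, hi, by = step)
  } else {
    values <- as.numeric(values)
  }
  validate_axis(values)
  structure(values, step = diff(values[1:2]), class = "wavenumber_axis")
}

validate_axis <- function(values) {
  if (length(values) < 2L)
    stop("wavenumber axis needs at least 2 bands", call. = FALSE)
  d <- diff(values)
  if (any(d <= 0))
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  if (max(d) - min(d) > 1e-9)
    stop("wavenumber axis must be uniformly spaced (tolerance 1e-9 cm^-1)",
         call. = FALSE)
  if (values[1] < 800 - 1e-9 || values[length(values)] > 4000 + 1e-9)
    stop("wavenumber axis must lie within [800, 4000] cm^-1", call. = FALSE)
  invisible(values)
}

axis_step <- function(axis) {
  s <- attr(axis, "step")
  if (is.null(s)) s <- diff(as.numeric(axis)[1:2])
  s
}

#' Index of the band nearest a named wavenumber
#'
#' Named wavenumbers (1652, 1543, 1236, ...) are resolved to the nearest
#' stored band; no interpolation is done, the 2 cm^-1 step being far below
#' the bands' widths.
#'
#' @param axis a [wavenumber_axis()].
#' @param wn target wavenumber(s) in cm^-1.
#' @return integer index (vectorized over `wn`).
#' @export
nearest_band <- function(axis, wn) {
  v <- as.numeric(axis)
  if (any(wn < v[1] - axis_step(axis) / 2 | wn > v[length(v)] + axis_step(axis) / 2))
    stop("wavenumber ", paste(wn, collapse = ", "),
         " outside axis range [", v[1], ", ", v[length(v)], "]", call. = FALSE)
  idx <- round((wn - v[1]) / axis_step(axis)) + 1L
  pmin(pmax(as.integer(idx), 1L), length(v))
}

# indices of bands inside the closed interval [lo, hi]
band_window <- function(axis, lo, hi) {
  v <- as.numeric(axis)
  idx <- which(v >= lo - 1e-9 & v <= hi + 1e-9)
  if (length(idx) == 0L)
    stop("no bands in [", lo, ", ", hi, "] cm^-1", call. = FALSE)
  idx
}

#' @export
print.wavenumber_axis <- function(x, ...) {
  v <- as.numeric(x)
  cat(sprintf("<wavenumber_axis> %d bands, %.6g-%.6g cm^-1, step %.6g cm^-1\n",
              length(v), v[1], v[length(v)], axis_step(x)))
  invisible(x)
}
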