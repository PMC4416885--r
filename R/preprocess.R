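#' Mask pixels without protein-characteristic amide I absorbance
#'
#' All cells and extracellular matrix in cardiac tissue contain protein, so
#' pixels whose raw absorbance at the band nearest 1652 cm^-1 falls below the
#' threshold carry no tissue and are excluded from all downstream analysis.
#' The mask is computed on raw absorbance, before normalization (normalizing
#' first would destroy the thickness signal the threshold uses); the
#' comparison is inclusive (>= threshold).
#'
#' @param cube a [spectral_cube()], raw (not normalized).
#' @param threshold minimum acceptable absorbance in AU (default 0.30, about
#'   10-fold above the acquisition peak-to-peak noise).
#' @return a `pixel_mask`: list with logical matrix `keep` and the
#'   `threshold` used.
#' @export
amide_mask <- function(cube, threshold = 0.30) {
  stopifnot(inherits(cube, "spectral_cube"))
  v <- as.numeric(cube$axis)
  if (v[1] > 1652 || v[length(v)] < 1652)
    stop("axis lacks the fingerprint region: 1652 cm^-1 not covered", call. = FALSE)
  i <- nearest_band(cube$axis, 1652)
  keep <- cube$data[, , i] >= threshold
  structure(list(keep = keep, threshold = threshold), class = "pixel_mask")
}

#' Default two-point baseline anchors
#'
#' One anchor pair spanning the fingerprint region and one spanning the
#' amide A region. The anchors are fixed for all spectra in a run and are
#' recorded in the run configuration.
#'
#' @return a list of `c(left, right)` anchor pairs in cm^-1.
#' @export
default_anchors <- function() list(c(900, 1800), c(2800, 3600))

validate_anchors <- function(anchors, axis) {
  if (!is.list(anchors) || !length(anchors))
    stop("anchors must be a non-empty list of c(left, right) pairs", call. = FALSE)
  iv <- t(vapply(anchors, function(p) {
    if (length(p) != 2 || !(p[1] < p[2]))
      stop("each anchor pair must satisfy left < right", call. = FALSE)
    nearest_band(axis, p)  # errors if outside axis
    as.numeric(p)
  }, numeric(2)))
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
    stop("anchor pairs overlap", call. = FALSE)
  anchors[o]
}

# matrix version: pixels x bands
baseline_correct_mat <- function(mat, axis, anchors = default_anchors()) {
  anchors <- validate_anchors(anchors, axis)
  v <- as.numeric(axis)
  for (p in anchors) {
    il <- nearest_band(axis, p[1]); ir <- nearest_band(axis, p[2])
    idx <- il:ir
    al <- mat[, il]; ar <- mat[, ir]
    w <- (v[idx] - v[il]) / (v[ir] - v[il])
    mat[, idx] <- mat[, idx, drop = FALSE] -
      (outer(al, 1 - w) + outer(ar, w))
  }
  mat
}

#' Two-point linear baseline correction
#'
#' For each anchor pair, the straight line through the spectrum's values at
#' the two anchors is subtracted over the closed interval between them; the
#' corrected value at both anchors is exactly zero and bands outside all
#' pairs are unchanged. The operation is idempotent per anchor pair and
#' removes any linear baseline drift exactly.
#'
#' @param spectrum numeric absorbance spectrum (or a [spectral_cube()], in
#'   which case every pixel is corrected).
#' @param axis the spectrum's [wavenumber_axis()] (ignored for cubes).
#' @param anchors list of `c(left, right)` pairs, see [default_anchors()].
#' @return the corrected spectrum (or cube).
#' @export
baseline_correct <- function(spectrum, axis = NULL, anchors = default_anchors()) {
  if (inherits(spectrum, "spectral_cube")) {
    mat <- baseline_correct_mat(cube_matrix(spectrum), spectrum$axis, anchors)
    return(matrix_cube(mat, spectrum))
  }
  stopifnot(!is.null(axis))
  drop(baseline_correct_mat(matrix(spectrum, nrow = 1), axis, anchors))
}

#' Normalize a spectrum to its amide I peak
#'
#' Divides a baseline-corrected spectrum by its amide I peak height (windowed
#' maximum around 1652 cm^-1, see [peak_height()]) so the result has height
#' 1.0 at amide I. This removes section-thickness variation: every ratio
#' metric becomes exactly invariant to scaling of the input. Spectra whose
#' amide I height is not positive cannot be normalized and are flagged
#' (`NA` spectrum) so the pixel is carried as unclassified rather than
#' dropped from the raster geometry.
#'
#' @param spectrum numeric baseline-corrected spectrum.
#' @param axis its [wavenumber_axis()].
#' @return the normalized spectrum, or all-`NA` if amide I height <= 0.
#' @export
normalize_amide1 <- function(spectrum, axis) {
  h <- peak_height(spectrum, axis, 1652)
  if (!is.finite(h) || h <= 0) return(rep(NA_real_, length(spectrum)))
  spectrum / h
}

#' Preprocess a cube: mask, baseline, amide I normalization
#'
#' The standard preprocessing chain: compute the amide-I mask on raw
#' absorbance, two-point baseline correction, then per-pixel amide I
#' normalization. Pixels failing normalization (non-positive amide I after
#' correction) are flagged and removed from the mask but kept in the raster.
#'
#' @param cube a raw [spectral_cube()].
#' @param threshold amide-I mask threshold in AU (default 0.30).
#' @param anchors baseline anchor pairs (default [default_anchors()]).
#' @return list with `cube` (corrected, normalized; flagged pixels `NA`-free
#'   but excluded from `mask`), `mask` (a `pixel_mask`), and
#'   `n_norm_failed` (count of pixels that failed normalization).
#' @export
preprocess_cube <- function(cube, threshold = 0.30, anchors = default_anchors()) {
  mask <- amide_mask(cube, threshold)
  mat <- baseline_correct_mat(cube_matrix(cube), cube$axis, anchors)
  win <- peak_window(cube$axis, 1652)
  h <- row_max(mat, win)
  ok <- is.finite(h) & h > 0
  mat[ok, ] <- mat[ok, , drop = FALSE] / h[ok]
  failed <- as.vector(mask$keep) & !ok
  keep <- matrix(as.vector(mask$keep) & ok, nrow(mask$keep), ncol(mask$keep))
  list(cube = matrix_cube(mat, cube),
       mask = structure(list(keep = keep, threshold = threshold),
                        class = "pixel_mask"),
       n_norm_failed = sum(failed))
}

#' Residual-paraffin quality-control score
#'
#' Mean over kept pixels of the paraffin CH-bending band height at
#' 1464 cm^-1, measured above a local chord anchored at 1452 and 1476 cm^-1
#' (so the overlapping 1452 cm^-1 tissue band is removed), clipped at zero,
#' and divided by the amide I height. De-paraffinized tissue scores near
#' zero; residual paraffin raises the score monotonically. A QC number, not
#' a gate.
#'
#' @param cube a raw [spectral_cube()].
#' @param mask a `pixel_mask` (default: [amide_mask()] of the cube).
#' @param anchors baseline anchors used for the amide I denominator.
#' @return the scalar score (unitless ratio).
#' @export
paraffin_residual_score <- function(cube, mask = amide_mask(cube),
                                    anchors = default_anchors()) {
  v <- as.numeric(cube$axis)
  if (v[1] > 1464 || v[length(v)] < 1476)
    stop("axis lacks the paraffin band region (1464 cm^-1)", call. = FALSE)
  keep <- as.vector(mask$keep)
  if (!any(keep)) stop("empty mask: paraffin score undefined", call. = FALSE)
  mat <- cube_matrix(cube)[keep, , drop = FALSE]
  il <- nearest_band(cube$axis, 1452); ir <- nearest_band(cube$axis, 1476)
  ic <- nearest_band(cube$axis, 1464)
  w <- (v[ic] - v[il]) / (v[ir] - v[il])
  chord <- mat[, il] * (1 - w) + mat[, ir] * w
  num <- pmax(mat[, ic] - chord, 0)
  corr <- baseline_correct_mat(mat, cube$axis, anchors)
  den <- row_max(corr, peak_window(cube$axis, 1652))
  mean(num[den > 0] / den[den > 0])
}
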