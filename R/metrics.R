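# ---- shared low-level helpers ---------------------------------------------

# band indices of the +/- half_window around a named peak position
peak_window <- function(axis, center, half_window = 6) {
  v <- as.numeric(axis)
  if (center - half_window < v[1] - 1e-9 ||
      center + half_window > v[length(v)] + 1e-9)
    stop("peak window [", center - half_window, ", ", center + half_window,
         "] outside axis range", call. = FALSE)
  band_window(axis, center - half_window, center + half_window)
}

# row-wise max over a set of columns (vectorized over pixels)
row_max <- function(mat, cols) {
  out <- mat[, cols[1]]
  for (j in cols[-1]) out <- pmax(out, mat[, j])
  out
}

# trapezoid weights for a uniform grid of n points with step h
trapz_weights <- function(n, h) {
  w <- rep(h, n); w[c(1, n)] <- h / 2
  w
}

# absorbance above the chord joining the interval endpoints, pixels x bands
above_chord <- function(mat, axis, left, right) {
  v <- as.numeric(axis)
  idx <- band_window(axis, left, right)
  il <- idx[1]; ir <- idx[length(idx)]
  w <- (v[idx] - v[il]) / (v[ir] - v[il])
  mat[, idx, drop = FALSE] - (outer(mat[, il], 1 - w) + outer(mat[, ir], w))
}

as_row <- function(spectrum) matrix(as.numeric(spectrum), nrow = 1)

# ---- single-spectrum metric primitives ------------------------------------

#' Peak height
#'
#' Maximum baseline-corrected absorbance within `+/- half_window` of the
#' named peak position. The windowed maximum (rather than a fixed-band
#' lookup) tolerates calibration jitter of a band or two.
#'
#' @param spectrum numeric baseline-corrected spectrum.
#' @param axis its [wavenumber_axis()].
#' @param center peak position in cm^-1.
#' @param half_window half-width of the search window in cm^-1 (default 6).
#' @return the peak height in AU.
#' @export
peak_height <- function(spectrum, axis, center, half_window = 6) {
  max(spectrum[peak_window(axis, center, half_window)])
}

#' Peak height ratio
#'
#' `peak_height(p1) / peak_height(p2)`. Exactly invariant under scaling of
#' the spectrum, hence independent of section thickness and instrument
#' response. Undefined (NA) when the denominator height is below `eps`.
#'
#' @inheritParams peak_height
#' @param p1,p2 numerator and denominator peak positions in cm^-1.
#' @param eps smallest usable denominator (default 1e-6 AU).
#' @return the ratio, or `NA` if undefined.
#' @export
peak_height_ratio <- function(spectrum, axis, p1, p2, half_window = 6,
                              eps = 1e-6) {
  den <- peak_height(spectrum, axis, p2, half_window)
  if (!is.finite(den) || den <= eps) return(NA_real_)
  peak_height(spectrum, axis, p1, half_window) / den
}

#' Band area above a local baseline
#'
#' Trapezoidal integral over `[left, right]` of the absorbance above the
#' straight line joining the spectrum's values at the interval endpoints.
#' A spectrum that is linear over the interval therefore has zero area.
#'
#' @inheritParams peak_height
#' @param left,right integration bounds in cm^-1, `left < right`.
#' @return the area in AU cm^-1.
#' @export
band_area <- function(spectrum, axis, left, right) {
  stopifnot(left < right)
  ac <- above_chord(as_row(spectrum), axis, left, right)
  drop(ac %*% trapz_weights(ncol(ac), axis_step(axis)))
}

#' Peak area to height ratio
#'
#' `band_area(area_left, area_right) / peak_height(peak)`; units cm^-1.
#'
#' @inheritParams band_area
#' @param area_left,area_right area bounds in cm^-1.
#' @param peak peak position for the height denominator in cm^-1.
#' @param eps smallest usable denominator height.
#' @return the ratio in cm^-1, or `NA` if undefined.
#' @export
area_to_height_ratio <- function(spectrum, axis, area_left, area_right, peak,
                                 eps = 1e-6) {
  den <- peak_height(spectrum, axis, peak)
  if (!is.finite(den) || den <= eps) return(NA_real_)
  band_area(spectrum, axis, area_left, area_right) / den
}

#' Peak area to area ratio
#'
#' `band_area(l1, r1) / band_area(l2, r2)`.
#'
#' @inheritParams band_area
#' @param l1,r1,l2,r2 numerator and denominator area bounds in cm^-1.
#' @param eps smallest usable denominator area.
#' @return the ratio, or `NA` if undefined.
#' @export
area_to_area_ratio <- function(spectrum, axis, l1, r1, l2, r2, eps = 1e-6) {
  den <- band_area(spectrum, axis, l2, r2)
  if (!is.finite(den) || abs(den) <= eps) return(NA_real_)
  band_area(spectrum, axis, l1, r1) / den
}

#' Center of gravity of a band interval
#'
#' Absorbance-weighted mean wavenumber over `[left, right]`:
#' `sum(v * A') / sum(A')` where `A'` is the absorbance above the chord
#' joining the values at `anchor_left`/`anchor_right` (defaulting to the
#' interval endpoints), clipped at zero so the weighted mean stays
#' well-defined. Always lies within `[left, right]`.
#'
#' @inheritParams band_area
#' @param anchor_left,anchor_right chord anchors for the local baseline
#'   (default: `left`, `right`).
#' @param eps smallest usable total weight.
#' @return the center of gravity in cm^-1, or `NA` if the total weight is
#'   not positive.
#' @export
center_of_gravity <- function(spectrum, axis, left, right,
                              anchor_left = left, anchor_right = right,
                              eps = 1e-6) {
  stopifnot(left < right, anchor_left < anchor_right)
  ac <- above_chord(as_row(spectrum), axis, anchor_left, anchor_right)
  v_anchor <- as.numeric(axis)[band_window(axis, anchor_left, anchor_right)]
  inside <- v_anchor >= left - 1e-9 & v_anchor <= right + 1e-9
  if (!any(inside))
    stop("no bands in CG interval [", left, ", ", right, "]", call. = FALSE)
  a <- pmax(drop(ac)[inside], 0)
  tot <- sum(a)
  if (!is.finite(tot) || tot <= eps) return(NA_real_)
  sum(v_anchor[inside] * a) / tot
}

# ---- metric library --------------------------------------------------------

#' Define a spectral metric
#'
#' One recipe from the four metric families, with its kind-specific
#' wavenumber parameters:
#' * `peak_height_ratio`: `params = c(peak1, peak2)`
#' * `area_to_height_ratio`: `params = c(area_left, area_right, peak)`
#' * `area_to_area_ratio`: `params = c(left1, right1, left2, right2)`
#' * `center_of_gravity`: `params = c(left, right, cg1, cg2)` — by default
#'   the CG is computed over `[cg1, cg2]` with the local chord anchored at
#'   `[left, right]`; see the `cog_mode` argument of [compute_features()]
#'   for the alternative normalized reading.
#'
#' @param name stable unique identifier.
#' @param kind one of the four family names above.
#' @param params numeric wavenumber parameters in cm^-1, all within
#'   \[800, 4000\].
#' @return a `metric_definition` object.
#' @export
metric_definition <- function(name, kind, params) {
  kinds <- c(peak_height_ratio = 2L, area_to_height_ratio = 3L,
             area_to_area_ratio = 4L, center_of_gravity = 4L)
  if (!kind %in% names(kinds)) stop("unknown metric kind: ", kind, call. = FALSE)
  params <- as.numeric(params)
  if (length(params) != kinds[[kind]])
    stop(kind, " takes ", kinds[[kind]], " parameters", call. = FALSE)
  if (any(params < 800 - 1e-9 | params > 4000 + 1e-9))
    stop("metric wavenumbers must lie in [800, 4000] cm^-1", call. = FALSE)
  structure(list(name = as.character(name), kind = kind, params = params),
            class = "metric_definition")
}

#' The published spectral-metric library
#'
#' The 27 metric definitions found useful to differentiate the five
#' histologic classes: 21 peak height ratios, 3 peak-area-to-height ratios
#' and 3 centers of gravity. With `expand = TRUE`, height ratios of every
#' annotated fingerprint/amide band to amide I are appended (a step toward
#' the full 217-parameter metric space, whose complete list is not
#' published).
#'
#' @param expand also generate band/amide-I height ratios (default FALSE).
#' @return a list of [metric_definition()] objects with unique names.
#' @export
default_metric_library <- function(expand = FALSE) {
  phr <- list(
    c(1389, 1236), c(3315, 1236), c(1204, 1236),
    c(1027, 1065), c(1163, 1236), c(1239, 1652),
    c(1239, 1543), c(1163, 1065), c(1236, 1543),
    c(1389, 1452), c(1452, 1543), c(1236, 3300),
    c(1239, 3300), c(1389, 1652), c(1389, 3300),
    c(1389, 1065), c(1452, 1236), c(1027, 1543),
    c(1405, 1236), c(1155, 1452), c(1032, 1236))
  ahr <- list(c(1482, 1594, 1652), c(1424, 1480, 1546), c(1184, 1300, 1652))
  cog <- list(c(1184, 1302, 1188, 1216), c(1482, 1726, 1482, 1594),
              c(984, 1144, 1016, 1048))
  defs <- c(
    lapply(phr, function(p) metric_definition(
      sprintf("phr_%d_%d", p[1], p[2]), "peak_height_ratio", p)),
    lapply(ahr, function(p) metric_definition(
      sprintf("ahr_%d_%d_%d", p[1], p[2], p[3]), "area_to_height_ratio", p)),
    lapply(cog, function(p) metric_definition(
      sprintf("cog_%d_%d_%d_%d", p[1], p[2], p[3], p[4]),
      "center_of_gravity", p)))
  if (expand) {
    bands <- c(1027, 1032, 1065, 1155, 1163, 1204, 1236, 1239, 1389, 1405,
               1452, 1543, 3300, 3315)
    extra <- lapply(bands, function(b) metric_definition(
      sprintf("phr_%d_1652", b), "peak_height_ratio", c(b, 1652)))
    have <- vapply(defs, `[[`, character(1), "name")
    extra <- extra[!vapply(extra, `[[`, character(1), "name") %in% have]
    defs <- c(defs, extra)
  }
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  if (anyDuplicated(names(defs))) stop("duplicate metric names", call. = FALSE)
  defs
}

#' Write / read a metric library as JSON
#'
#' @param defs a list of [metric_definition()] objects.
#' @param path JSON file path.
#' @return `read_metric_library`: the metric list.
#' @export
write_metric_library <- function(defs, path) {
  payload <- lapply(unname(defs), function(d)
    list(name = d$name, kind = d$kind, params = d$params))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_metric_library
#' @export
read_metric_library <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  defs <- lapply(payload, function(d)
    metric_definition(d$name, d$kind, unlist(d$params)))
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  defs
}

# ---- vectorized per-pixel evaluation ---------------------------------------

# evaluate one metric on a pixels x bands matrix of preprocessed spectra
eval_metric_mat <- function(mat, axis, def, half_window = 6, eps = 1e-6,
                            cog_mode = c("window", "normalized")) {
  cog_mode <- match.arg(cog_mode)
  p <- def$params
  h <- axis_step(axis)
  switch(def$kind,
    peak_height_ratio = {
      num <- row_max(mat, peak_window(axis, p[1], half_window))
      den <- row_max(mat, peak_window(axis, p[2], half_window))
      ifelse(is.finite(den) & den > eps, num / den, NA_real_)
    },
    area_to_height_ratio = {
      ac <- above_chord(mat, axis, p[1], p[2])
      num <- drop(ac %*% trapz_weights(ncol(ac), h))
      den <- row_max(mat, peak_window(axis, p[3], half_window))
      ifelse(is.finite(den) & den > eps, num / den, NA_real_)
    },
    area_to_area_ratio = {
      ac1 <- above_chord(mat, axis, p[1], p[2])
      ac2 <- above_chord(mat, axis, p[3], p[4])
      num <- drop(ac1 %*% trapz_weights(ncol(ac1), h))
      den <- drop(ac2 %*% trapz_weights(ncol(ac2), h))
      ifelse(is.finite(den) & abs(den) > eps, num / den, NA_real_)
    },
    center_of_gravity = {
      if (cog_mode == "window") {
        ac <- pmax(above_chord(mat, axis, p[1], p[2]), 0)
        v <- as.numeric(axis)[band_window(axis, p[1], p[2])]
        inside <- v >= p[3] - 1e-9 & v <= p[4] + 1e-9
        tot <- rowSums(ac[, inside, drop = FALSE])
        cg <- (ac[, inside, drop = FALSE] %*% v[inside]) / tot
        ifelse(is.finite(tot) & tot > eps, drop(cg), NA_real_)
      } else {
        # CG over the full [left, right]; cg1/cg2 map the value to [0, 1]
        ac <- pmax(above_chord(mat, axis, p[1], p[2]), 0)
        v <- as.numeric(axis)[band_window(axis, p[1], p[2])]
        tot <- rowSums(ac)
        cg <- drop(ac %*% v) / tot
        out <- (cg - p[3]) / (p[4] - p[3])
        ifelse(is.finite(tot) & tot > eps, out, NA_real_)
      }
    },
    stop("unknown metric kind: ", def$kind, call. = FALSE))
}

#' Compute the metric library on every kept pixel
#'
#' Evaluates each metric definition per pixel of a preprocessed
#' (baseline-corrected, amide-I-normalized) cube. Masked pixels carry `NA`
#' for every metric; individual metrics that are undefined for a pixel
#' (vanishing denominators, non-positive CG weight) are `NA` and are later
#' dropped from that pixel's likelihood product.
#'
#' @param cube a preprocessed [spectral_cube()].
#' @param mask a `pixel_mask`.
#' @param defs a metric library, e.g. [default_metric_library()].
#' @param half_window peak search half-window in cm^-1 (default 6).
#' @param cog_mode `"window"` (default: CG over `[cg1, cg2]`, chord anchored
#'   at `[left, right]`) or `"normalized"` (CG over `[left, right]` mapped
#'   linearly so `cg1 -> 0`, `cg2 -> 1`).
#' @return a `feature_image`: list with `values` (rows x cols x n_metrics
#'   array), `metric_names`, and `mask`.
#' @export
compute_features <- function(cube, mask, defs, half_window = 6,
                             cog_mode = c("window", "normalized")) {
  stopifnot(inherits(cube, "spectral_cube"))
  cog_mode <- match.arg(cog_mode)
  if (!length(defs)) stop("empty metric library", call. = FALSE)
  d <- dim(cube$data)
  if (!all(dim(mask$keep) == d[1:2]))
    stop("mask shape does not match cube", call. = FALSE)
  keep <- as.vector(mask$keep)
  mat <- cube_matrix(cube)[keep, , drop = FALSE]
  vals <- matrix(NA_real_, d[1] * d[2], length(defs))
  for (k in seq_along(defs))
    vals[keep, k] <- eval_metric_mat(mat, cube$axis, defs[[k]],
                                     half_window = half_window,
                                     cog_mode = cog_mode)
  structure(list(values = array(vals, dim = c(d[1], d[2], length(defs))),
                 metric_names = vapply(defs, `[[`, character(1), "name"),
                 mask = mask),
            class = "feature_image")
}

# features as (n_kept_or_all pixels) x metrics matrix
feature_matrix <- function(features, kept_only = FALSE) {
  d <- dim(features$values)
  m <- matrix(features$values, d[1] * d[2], d[3])
  colnames(m) <- features$metric_names
  if (kept_only) m[as.vector(features$mask$keep), , drop = FALSE] else m
}
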