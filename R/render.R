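#' Default class palette
#'
#' Distinct saturated colors for the five histologic classes, black for
#' unclassified and white for background, as RGB triples in 0..255.
#'
#' @return named list mapping codes "0".."5" (and "background") to RGB
#'   triples.
#' @export
default_palette <- function() {
  pal <- list(
    `0` = c(0, 0, 0),        # unclassified: black
    `1` = c(214, 39, 40),    # myocardium: red
    `2` = c(148, 103, 189),  # endocardium: purple
    `3` = c(44, 160, 44),    # fibrosis-endocardium: green
    `4` = c(255, 127, 14),   # fibrosis-myocardium: orange
    `5` = c(31, 119, 180),   # lymphocytes: blue
    background = c(255, 255, 255))
  key <- vapply(pal, paste, character(1), collapse = ",")
  if (anyDuplicated(key)) stop("palette colors must be unique", call. = FALSE)
  pal
}

#' Grayscale single-band contrast image
#'
#' Baseline-corrected absorbance at the band nearest the requested
#' wavenumber, linearly stretched so the 1st percentile of kept pixels maps
#' to 0 and the 99th to 255 (then clipped); masked pixels are 0. The
#' 1236 cm^-1 band gives strong contrast between collagen-rich (fibrosis,
#' endocardium) and muscle regions.
#'
#' @param cube a raw [spectral_cube()].
#' @param band wavenumber in cm^-1 (default 1236).
#' @param mask a `pixel_mask` (default [amide_mask()]).
#' @param anchors baseline anchors.
#' @return numeric matrix of gray levels in 0..255.
#' @export
band_image <- function(cube, band = 1236, mask = amide_mask(cube),
                       anchors = default_anchors()) {
  v <- as.numeric(cube$axis)
  if (band < v[1] || band > v[length(v)])
    stop("band ", band, " cm^-1 outside axis range", call. = FALSE)
  mat <- baseline_correct_mat(cube_matrix(cube), cube$axis, anchors)
  x <- mat[, nearest_band(cube$axis, band)]
  keep <- as.vector(mask$keep)
  q <- stats::quantile(x[keep], c(0.01, 0.99), names = FALSE, type = 7)
  if (q[2] <= q[1]) q[2] <- q[1] + 1e-12
  g <- pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1) * 255
  g[!keep] <- 0
  matrix(g, nrow(mask$keep), ncol(mask$keep))
}

#' Pseudo-color rendering of a class map
#'
#' Per-pixel palette lookup producing an RGB array; the legend (code, class
#' name, color) is returned as an attribute and written alongside the PNG by
#' [run_pipeline()].
#'
#' @param pred class map matrix (codes 0..5).
#' @param palette a palette from [default_palette()].
#' @return rows x cols x 3 numeric array in \[0, 1\], with a `legend`
#'   attribute (data frame of code, class, hex color).
#' @export
class_image <- function(pred, palette = default_palette()) {
  pred <- validate_labels(pred)
  codes <- sort(unique(as.vector(pred)))
  missing <- setdiff(as.character(codes), names(palette))
  if (length(missing))
    stop("palette lacks colors for code(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  img <- array(0, dim = c(nrow(pred), ncol(pred), 3))
  for (cc in codes) {
    rgb_ <- palette[[as.character(cc)]] / 255
    sel <- pred == cc
    for (k in 1:3) {
      plane <- img[, , k]
      plane[sel] <- rgb_[k]
      img[, , k] <- plane
    }
  }
  legend <- data.frame(
    code = 0:5, class = class_name(0:5),
    color = vapply(as.character(0:5), function(k)
      grDevices::rgb(palette[[k]][1], palette[[k]][2], palette[[k]][3],
                     maxColorValue = 255), character(1)))
  attr(img, "legend") <- legend
  img
}

#' Recover class codes from a rendered image
#'
#' Inverse palette lookup; exact round trip of [class_image()].
#'
#' @param img rows x cols x 3 array in \[0, 1\].
#' @param palette the palette used to render.
#' @return integer class-map matrix.
#' @export
image_to_codes <- function(img, palette = default_palette()) {
  key <- apply(round(img * 255), c(1, 2), paste, collapse = ",")
  lut <- vapply(palette[as.character(0:5)], paste, character(1), collapse = ",")
  out <- matrix(NA_integer_, nrow(key), ncol(key))
  for (cc in 0:5) out[key == lut[cc + 1]] <- cc
  if (anyNA(out)) stop("image contains colors outside the palette", call. = FALSE)
  out
}

write_gray_png <- function(gray, path) {
  png::writePNG(gray / 255, path)
  invisible(path)
}

write_rgb_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
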