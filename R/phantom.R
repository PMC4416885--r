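#' Built-in spectral models for the five histologic classes
#'
#' Each class is modeled as a sum of Gaussian (optionally Lorentzian) bands
#' at the annotated positions of cardiac tissue mid-IR spectra, with heights
#' relative to the amide I anchor (1652 cm^-1, height 1.0). The relative
#' heights are simulator constants chosen so the discriminative orderings
#' observed in tissue hold: the amide III / collagen region (1204, 1236,
#' 1239 cm^-1) is elevated in both fibrosis classes and in endocardium
#' relative to healthy myocardium; the glycogen band (1027/1032 cm^-1) is
#' elevated in myocardium and depressed at sites of fibrosis; and lymphocytes
#' are separable from muscle at 1236 cm^-1. Fingerprint bands default to
#' 25 cm^-1 FWHM, the broad amide A band to 120 cm^-1. The paraffin band at
#' 1464 cm^-1 is present in the band set with height 0 (see
#' [paraffin_contaminate()]).
#'
#' @return a named list of five `class_spectral_model` objects (one per class
#'   code 1..5), each a list with `class_code`, `class_name` and a `peaks`
#'   data frame (`center`, `height`, `fwhm`, `shape`).
#' @export
default_class_library <- function() {
  bands <- c(1027, 1065, 1155, 1163, 1204, 1236, 1389, 1405, 1452, 1464,
             1543, 1652, 3300)
  h <- rbind(
    Myocardium             = c(0.28, 0.10, 0.08, 0.09, 0.05, 0.10, 0.12, 0.10, 0.22, 0, 0.55, 1.0, 0.35),
    Endocardium            = c(0.14, 0.12, 0.10, 0.12, 0.16, 0.26, 0.14, 0.11, 0.26, 0, 0.52, 1.0, 0.33),
    `Fibrosis-Endocardium` = c(0.08, 0.14, 0.13, 0.16, 0.28, 0.40, 0.16, 0.12, 0.30, 0, 0.50, 1.0, 0.30),
    `Fibrosis-Myocardium`  = c(0.10, 0.13, 0.12, 0.14, 0.22, 0.34, 0.15, 0.12, 0.28, 0, 0.51, 1.0, 0.31),
    Lymphocytes            = c(0.18, 0.20, 0.11, 0.13, 0.08, 0.18, 0.13, 0.10, 0.24, 0, 0.58, 1.0, 0.38)
  )
  fwhm <- ifelse(bands >= 2800, 120, 25)
  codes <- class_codes()
  out <- lapply(names(codes), function(nm) {
    class_spectral_model(codes[[nm]], data.frame(
      center = bands, height = h[nm, ], fwhm = fwhm, shape = "gaussian",
      stringsAsFactors = FALSE))
  })
  names(out) <- names(codes)
  out
}

#' Construct a class spectral model
#'
#' @param class_code integer class code 1..5.
#' @param peaks data frame with columns `center` (cm^-1), `height` (AU
#'   relative to amide I), `fwhm` (cm^-1) and `shape`
#'   (`"gaussian"` or `"lorentzian"`). Must contain the amide I anchor at
#'   1652 cm^-1 with height 1.0 and an amide II band near 1543 cm^-1.
#' @return a `class_spectral_model` object.
#' @export
class_spectral_model <- function(class_code, peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("center", "height", "fwhm", "shape") %in% names(peaks)))
  if (any(peaks$height < 0)) stop("peak heights must be >= 0", call. = FALSE)
  if (any(peaks$fwhm <= 0)) stop("peak FWHM must be > 0", call. = FALSE)
  if (!any(abs(peaks$center - 1652) < 1e-9 & abs(peaks$height - 1.0) < 1e-9))
    stop("model must contain the amide I anchor: center 1652 cm^-1, height 1.0",
         call. = FALSE)
  if (!any(abs(peaks$center - 1543) < 10))
    stop("model must contain an amide II band near 1543 cm^-1", call. = FALSE)
  if (!all(peaks$shape %in% c("gaussian", "lorentzian")))
    stop("peak shape must be gaussian or lorentzian", call. = FALSE)
  structure(list(class_code = as.integer(class_code),
                 class_name = class_name(as.integer(class_code)),
                 peaks = peaks),
            class = "class_spectral_model")
}

#' Write / read a class library as JSON
#'
#' @param library a named list of [class_spectral_model()] objects.
#' @param path JSON file path.
#' @return `read_class_library`: the class library list.
#' @export
write_class_library <- function(library, path) {
  payload <- lapply(library, function(m)
    list(class_code = m$class_code, class_name = m$class_name, peaks = m$peaks))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_class_library
#' @export
read_class_library <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(payload, function(m)
    class_spectral_model(m$class_code, as.data.frame(m$peaks)))
  names(out) <- vapply(out, `[[`, character(1), "class_name")
  out
}

# analytic peak sum of a class model on an axis
model_spectrum <- function(model, axis) {
  v <- as.numeric(axis)
  s <- numeric(length(v))
  for (i in seq_len(nrow(model$peaks))) {
    p <- model$peaks[i, ]
    if (p$height == 0) next
    s <- s + peak_profile(v, p$center, p$height, p$fwhm, p$shape)
  }
  s
}

peak_profile <- function(v, center, height, fwhm, shape) {
  if (shape == "gaussian") {
    height * exp(-4 * log(2) * ((v - center) / fwhm)^2)
  } else {
    height / (1 + (2 * (v - center) / fwhm)^2)
  }
}

#' Default noise level for a target signal-to-noise ratio
#'
#' The acquisition SNR is specified as amide I peak height divided by the
#' peak-to-peak (max minus min) noise in the signal-free 1800-2000 cm^-1
#' window. For i.i.d. Gaussian noise over the ~101 bands of that window the
#' expected peak-to-peak is about 5 standard deviations, so the per-band
#' noise SD is set to `1 / (snr * pp_factor)` with `pp_factor = 7`, placing
#' the 5th percentile of the measured ratio safely above the target.
#'
#' @param snr target SNR (default 500).
#' @param pp_factor assumed peak-to-peak-to-SD factor (default 7).
#' @return per-band noise standard deviation in AU.
#' @export
noise_sd_for_snr <- function(snr = 500, pp_factor = 7) {
  stopifnot(snr > 0, pp_factor > 0)
  1 / (snr * pp_factor)
}

#' Synthesize one spectrum from a class model
#'
#' spectrum = thickness x (sum of the model's peaks) + linear baseline +
#' i.i.d. Gaussian noise. The baseline is
#' `baseline_intercept + baseline_slope * (wavenumber - min(axis))`.
#' Randomness comes from R's global RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param model a [class_spectral_model()].
#' @param axis a [wavenumber_axis()].
#' @param thickness multiplicative section-thickness scale (default 1).
#' @param baseline_slope AU per cm^-1 (default 0).
#' @param baseline_intercept AU (default 0).
#' @param noise_sd per-band Gaussian noise SD in AU
#'   (default [noise_sd_for_snr()] at SNR 500).
#' @return numeric absorbance spectrum along `axis`.
#' @export
synth_spectrum <- function(model, axis, thickness = 1, baseline_slope = 0,
                           baseline_intercept = 0,
                           noise_sd = noise_sd_for_snr(500)) {
  stopifnot(noise_sd >= 0)
  v <- as.numeric(axis)
  s <- thickness * model_spectrum(model, axis) +
    baseline_intercept + baseline_slope * (v - v[1])
  if (noise_sd > 0) s <- s + stats::rnorm(length(v), sd = noise_sd)
  s
}

#' Phantom specification
#'
#' Parameters of the synthetic biopsy phantom. Defaults are the study
#' conditions the generator emulates: 6.25 um pixels, acquisition SNR 500:1,
#' +/-30% section-thickness variation, mild linear baseline drift, boundary
#' mixing on, no residual paraffin.
#'
#' @param layout `"layered_biopsy"` (endocardium band, fibrosis layer,
#'   myocardium bulk with fibrotic patches and lymphocyte foci),
#'   `"checkerboard"`, or `"custom"` with `labels` supplied.
#' @param rows,cols raster size in pixels.
#' @param pixel_pitch um per pixel (default 6.25).
#' @param snr target acquisition SNR (default 500).
#' @param thickness_range multiplicative thickness interval
#'   (default `c(0.7, 1.3)`).
#' @param baseline_slope_sd SD of per-pixel linear baseline slope,
#'   AU per cm^-1 (default 2e-5, i.e. drift up to a few percent of amide I
#'   across the stored range).
#' @param paraffin_residual height in AU of a residual paraffin band at
#'   1464 cm^-1 (default 0: de-paraffinized tissue).
#' @param boundary_mixing mix spectra at class interfaces (default TRUE).
#' @param n_fibrosis number of elliptical fibrosis-myocardium patches.
#' @param n_foci,focus_radius lymphocyte foci count and radius in pixels.
#' @param background_margin width in pixels of the non-tissue frame.
#' @param seed integer RNG seed; equal specs give bit-identical phantoms.
#' @param labels optional custom label matrix (codes 0..5) for
#'   `layout = "custom"`.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(layout = "layered_biopsy", rows = 200, cols = 200,
                         pixel_pitch = 6.25, snr = 500,
                         thickness_range = c(0.7, 1.3),
                         baseline_slope_sd = 2e-5, paraffin_residual = 0,
                         boundary_mixing = TRUE, n_fibrosis = 2,
                         n_foci = 3, focus_radius = 5,
                         background_margin = 3, seed = 1, labels = NULL) {
  stopifnot(layout %in% c("layered_biopsy", "checkerboard", "custom"),
            rows >= 1, cols >= 1, snr > 0,
            length(thickness_range) == 2, all(thickness_range > 0),
            thickness_range[1] <= thickness_range[2],
            baseline_slope_sd >= 0, paraffin_residual >= 0)
  if (layout == "custom" && is.null(labels))
    stop("layout = \"custom\" requires `labels`", call. = FALSE)
  structure(list(layout = layout, rows = as.integer(rows), cols = as.integer(cols),
                 pixel_pitch = pixel_pitch, snr = snr,
                 thickness_range = thickness_range,
                 baseline_slope_sd = baseline_slope_sd,
                 paraffin_residual = paraffin_residual,
                 boundary_mixing = isTRUE(boundary_mixing),
                 n_fibrosis = as.integer(n_fibrosis),
                 n_foci = as.integer(n_foci), focus_radius = focus_radius,
                 background_margin = as.integer(background_margin),
                 seed = as.integer(seed), labels = labels),
            class = "phantom_spec")
}

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# ---- layout construction -------------------------------------------------

layout_labels <- function(spec) {
  if (spec$layout == "custom") return(validate_labels(spec$labels))
  nr <- spec$rows; nc <- spec$cols
  lab <- matrix(0L, nr, nc)
  m <- spec$background_margin
  r0 <- m + 1L; r1 <- nr - m; c0 <- m + 1L; c1 <- nc - m
  if (r1 - r0 < 6L || c1 - c0 < 6L)
    stop("layout larger than raster: tissue region too small after margins",
         call. = FALSE)
  if (spec$layout == "checkerboard") {
    blk <- max(4L, min(r1 - r0, c1 - c0) %/% 5L)
    for (r in r0:r1) for (cc in c0:c1)
      lab[r, cc] <- ((((r - r0) %/% blk) + ((cc - c0) %/% blk)) %% 5L) + 1L
    return(lab)
  }
  tis_rows <- r1 - r0 + 1L
  endo_h <- max(2L, round(0.10 * tis_rows))
  fibe_h <- max(2L, round(0.10 * tis_rows))
  lab[r0:r1, c0:c1] <- 1L                                  # myocardium bulk
  lab[r0:(r0 + endo_h - 1L), c0:c1] <- 2L                  # endocardium band
  lab[(r0 + endo_h):(r0 + endo_h + fibe_h - 1L), c0:c1] <- 3L
  myo_r <- (r0 + endo_h + fibe_h):r1
  # elliptical fibrosis-myocardium patches
  if (spec$n_fibrosis > 0) {
    a <- max(3, round(0.08 * tis_rows)); b <- max(4, round(0.12 * (c1 - c0)))
    for (i in seq_len(spec$n_fibrosis)) {
      rc <- sample(myo_r[myo_r > min(myo_r) + a & myo_r < max(myo_r) - a], 1)
      cc <- sample((c0 + b):(c1 - b), 1)
      rr <- outer(seq_len(nr) - rc, rep(1, nc))
      cs <- outer(rep(1, nr), seq_len(nc) - cc)
      ell <- (rr / a)^2 + (cs / b)^2 <= 1
      lab[ell & lab == 1L] <- 4L
    }
  }
  # circular lymphocyte foci inside the myocardium
  if (spec$n_foci > 0) {
    rad <- spec$focus_radius
    centers <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(centers) < spec$n_foci && tries < 1000L) {
      tries <- tries + 1L
      rc <- sample(myo_r[myo_r > min(myo_r) + rad & myo_r < max(myo_r) - rad], 1)
      cc <- sample((c0 + rad):(c1 - rad), 1)
      if (lab[rc, cc] != 1L) next
      # keep foci disjoint so the truth has the requested component count;
      # on small rasters where disjoint placement is infeasible, fall back
      # to allowing contact after enough failed attempts
      if (tries < 600L && nrow(centers) &&
          any(sqrt((centers[, 1] - rc)^2 +
                   (centers[, 2] - cc)^2) <= 2 * rad + 2)) next
      rr <- outer(seq_len(nr) - rc, rep(1, nc))
      cs <- outer(rep(1, nr), seq_len(nc) - cc)
      lab[rr^2 + cs^2 <= rad^2] <- 5L
      centers <- rbind(centers, c(rc, cc))
    }
    if (nrow(centers) < spec$n_foci)
      stop("layout larger than raster: could not place ", spec$n_foci,
           " disjoint lymphocyte foci", call. = FALSE)
  }
  lab
}

# For each tissue pixel on a class interface, the most common differing
# 8-neighbour class (0 = none). Background does not mix.
boundary_partner <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  partner <- matrix(0L, nr, nc)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  neigh <- array(0L, dim = c(nr, nc, nrow(shifts)))
  for (k in seq_len(nrow(shifts))) {
    dr <- shifts$dr[k]; dc <- shifts$dc[k]
    src_r <- seq_len(nr) + dr; src_c <- seq_len(nc) + dc
    ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
    neigh[ok_r, ok_c, k] <- lab[src_r[ok_r], src_c[ok_c]]
  }
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    own <- lab[r, cc]
    if (own == 0L) next
    nb <- neigh[r, cc, ]
    nb <- nb[nb != 0L & nb != own]
    if (length(nb)) {
      tb <- tabulate(nb, 5L)
      partner[r, cc] <- which.max(tb)
    }
  }
  partner
}

#' Generate a synthetic biopsy phantom
#'
#' Builds an absorbance cube plus ground truth from a [phantom_spec()] and a
#' class library. The layered-biopsy layout places an endocardium band along
#' the top edge, a fibrosis-endocardium layer beneath it, a myocardium bulk
#' with elliptical fibrosis patches and circular lymphocyte foci (emulating
#' foci of infiltrate), all inside a non-tissue frame whose near-zero
#' absorbance the amide-I mask removes. With `boundary_mixing` on, pixels at
#' class interfaces are convex mixtures of the two adjacent class spectra
#' (linear Beer-Lambert additivity) with the dominant-class fraction drawn
#' uniformly from \[0.5, 1\] and recorded in the truth.
#'
#' @param spec a [phantom_spec()].
#' @param library a class library as from [default_class_library()]; must
#'   cover every class used by the layout.
#' @return a list with `cube` (a [spectral_cube()]) and `truth` (a list with
#'   `labels`, the dominant-class raster, and `mixing_fraction`, the
#'   dominant-class fraction per pixel, 1 wherever no mixing occurred).
#' @export
synth_phantom <- function(spec, library = default_class_library()) {
  stopifnot(inherits(spec, "phantom_spec"))
  axis <- wavenumber_axis(800, 4000, 2)
  with_preserved_seed(spec$seed, {
    lab <- layout_labels(spec)
    used <- setdiff(sort(unique(as.integer(lab))), 0L)
    lib_codes <- vapply(library, `[[`, integer(1), "class_code")
    if (!all(used %in% lib_codes))
      stop("class library does not cover classes ",
           paste(setdiff(used, lib_codes), collapse = ", "), call. = FALSE)
    means <- t(vapply(library[order(lib_codes)], model_spectrum,
                      numeric(length(axis)), axis = axis))  # 5 x bands
    if (spec$paraffin_residual > 0)
      means <- means + rep(peak_profile(as.numeric(axis), 1464,
                                        spec$paraffin_residual, 12, "gaussian"),
                           each = nrow(means))
    npix <- spec$rows * spec$cols
    labv <- as.integer(lab)
    tissue <- labv > 0L
    frac <- rep(1, npix)
    W <- matrix(0, npix, 5L)
    W[cbind(which(tissue), labv[tissue])] <- 1
    if (spec$boundary_mixing) {
      partner <- as.integer(boundary_partner(lab))
      mixed <- which(tissue & partner > 0L)
      if (length(mixed)) {
        f <- stats::runif(length(mixed), 0.5, 1)
        frac[mixed] <- f
        W[cbind(mixed, labv[mixed])] <- f
        W[cbind(mixed, partner[mixed])] <- 1 - f
      }
    }
    thick <- rep(0, npix)
    thick[tissue] <- stats::runif(sum(tissue), spec$thickness_range[1],
                                  spec$thickness_range[2])
    slope <- stats::rnorm(npix, sd = spec$baseline_slope_sd)
    mat <- (thick * W) %*% means
    mat <- mat + outer(slope, as.numeric(axis) - 800)
    mat <- mat + matrix(stats::rnorm(npix * length(axis),
                                     sd = noise_sd_for_snr(spec$snr)),
                        npix, length(axis))
    cube <- spectral_cube(array(mat, dim = c(spec$rows, spec$cols, length(axis))),
                          axis, spec$pixel_pitch,
                          sprintf("synth_phantom: layout %s, seed %d",
                                  spec$layout, spec$seed))
    list(cube = cube,
         truth = list(labels = lab,
                      mixing_fraction = matrix(frac, spec$rows, spec$cols)))
  })
}

#' Add residual paraffin to a cube
#'
#' Adds a Gaussian band at 1464 cm^-1 (CH bending of paraffin) of the given
#' height to every tissue pixel (pixels passing the default amide-I mask),
#' modeling incomplete de-paraffinization. The default FWHM of 12 cm^-1 is
#' narrower than the tissue fingerprint bands: crystalline paraffin bending
#' bands are sharp, which is also what lets the residual-paraffin QC score
#' separate paraffin from the overlapping 1452 cm^-1 tissue band.
#'
#' @param cube a [spectral_cube()].
#' @param height band height in AU (>= 0); 0 returns the cube unchanged.
#' @param fwhm band FWHM in cm^-1.
#' @return the contaminated [spectral_cube()].
#' @export
paraffin_contaminate <- function(cube, height, fwhm = 12) {
  stopifnot(inherits(cube, "spectral_cube"), height >= 0)
  if (height == 0) return(cube)
  band <- peak_profile(as.numeric(cube$axis), 1464, height, fwhm, "gaussian")
  keep <- as.vector(amide_mask(cube)$keep)
  mat <- cube_matrix(cube)
  mat[keep, ] <- mat[keep, , drop = FALSE] + rep(band, each = sum(keep))
  out <- matrix_cube(mat, cube)
  out$provenance <- c(out$provenance,
                      sprintf("paraffin_contaminate: height %.4g AU", height))
  out
}

#' Write / read a phantom specification as YAML
#'
#' @param spec a [phantom_spec()].
#' @param path YAML file path.
#' @return `read_phantom_spec`: the [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec)[!vapply(unclass(spec), is.null, logical(1))], path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  do.call(phantom_spec, yaml::read_yaml(path))
}
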