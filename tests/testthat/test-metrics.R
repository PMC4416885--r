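test_that("peak height has closed-form behaviour on constructed spectra", {
  ax <- wavenumber_axis()
  v <- as.numeric(ax)
  g <- 0.4 * exp(-4 * log(2) * ((v - 1236) / 25)^2)
  expect_equal(peak_height(g, ax, 1236), 0.4, tolerance = 1e-6)
  expect_equal(peak_height(rep(0, length(v)), ax, 1236), 0)
  # tolerates calibration jitter of +/- 2 bands
  g_shift <- 0.4 * exp(-4 * log(2) * ((v - 1240) / 25)^2)
  expect_equal(peak_height(g_shift, ax, 1236), 0.4, tolerance = 1e-6)
  # two overlapping Gaussians: equals brute-force max over window bands
  s2 <- g + 0.3 * exp(-4 * log(2) * ((v - 1250) / 20)^2)
  expect_equal(peak_height(s2, ax, 1236), oracle_peak_height(s2, v, 1236))
  expect_error(peak_height(g, ax, 4000), "outside")
})

test_that("band area matches geometry and quadrature", {
  ax <- wavenumber_axis()
  v <- as.numeric(ax)
  # triangle of base 40 and height 0.6 on zero baseline: area = b*h/2
  tri <- pmax(0, 0.6 * (1 - abs(v - 1300) / 20))
  expect_equal(band_area(tri, ax, 1260, 1340), 40 * 0.6 / 2, tolerance = 0.01)
  # linear segment -> 0 (local-baseline subtraction)
  expect_equal(band_area(0.2 + 0.001 * v, ax, 1000, 1200), 0, tolerance = 1e-12)
  # Gaussian over wide bounds ~ height * fwhm * 1.0645
  g <- 0.5 * exp(-4 * log(2) * ((v - 1500) / 30)^2)
  expect_equal(band_area(g, ax, 1350, 1650), 0.5 * 30 * 1.0645, tolerance = 0.01)
})

test_that("ratio and CG metrics agree with arithmetic on simple inputs", {
  ax <- wavenumber_axis()
  v <- as.numeric(ax)
  g1 <- 0.4 * exp(-4 * log(2) * ((v - 1236) / 25)^2)
  amide <- 1.0 * exp(-4 * log(2) * ((v - 1652) / 25)^2)
  s <- g1 + amide
  expect_equal(peak_height_ratio(s, ax, 1236, 1652), 0.4, tolerance = 1e-3)
  expect_true(is.na(peak_height_ratio(g1, ax, 1236, 3300)))  # denominator ~ 0
  # area 10 / height 1 -> 10 cm^-1 (rectangle above chord on flat zero)
  expect_equal(area_to_height_ratio(s, ax, 1602, 1702, 1652) /
                 band_area(s, ax, 1602, 1702), 1, tolerance = 1e-9)
  # identical regions -> area ratio 1; scaled numerator -> 3
  expect_equal(area_to_area_ratio(s, ax, 1200, 1280, 1200, 1280), 1)
  s3 <- s + 2 * g1
  expect_equal(area_to_area_ratio(s3, ax, 1200, 1280, 1200, 1280), 1)
  expect_equal(band_area(s3, ax, 1200, 1280) / band_area(s, ax, 1200, 1280), 3,
               tolerance = 1e-9)
  # symmetric Gaussian at 1030 over [984, 1144] -> CG at its center
  g30 <- exp(-4 * log(2) * ((v - 1030) / 25)^2)
  expect_equal(center_of_gravity(g30, ax, 984, 1144), 1030, tolerance = 1)
  # uniform weight over [a, b] -> midpoint
  u <- as.numeric(v >= 1000 & v <= 1100)
  expect_equal(center_of_gravity(u, ax, 990, 1110), 1050, tolerance = 1)
  # CG always inside [left, right]
  set.seed(5)
  for (k in 1:20) {
    s_r <- random_spectrum(ax)
    cg <- center_of_gravity(s_r, ax, 984, 1144)
    if (!is.na(cg)) expect_true(cg >= 984 && cg <= 1144)
  }
})

test_that("every metric matches its brute-force oracle on random spectra", {
  set.seed(99)
  ax <- wavenumber_axis()
  v <- as.numeric(ax)
  rel <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
  for (k in 1:200) {
    s <- random_spectrum(ax)
    o_h <- oracle_peak_height(s, v, 1236)
    expect_lt(rel(peak_height(s, ax, 1236), o_h), 1e-9)
    o_r <- oracle_peak_height(s, v, 1239) / oracle_peak_height(s, v, 1652)
    expect_lt(rel(peak_height_ratio(s, ax, 1239, 1652), o_r), 1e-9)
    o_a <- oracle_band_area(s, v, 1482, 1594)
    expect_lt(rel(band_area(s, ax, 1482, 1594), o_a), 1e-9)
    o_ah <- o_a / oracle_peak_height(s, v, 1652)
    expect_lt(rel(area_to_height_ratio(s, ax, 1482, 1594, 1652), o_ah), 1e-9)
    o_aa <- oracle_band_area(s, v, 1184, 1300) / oracle_band_area(s, v, 984, 1144)
    expect_lt(rel(area_to_area_ratio(s, ax, 1184, 1300, 984, 1144), o_aa), 1e-9)
    o_cg <- oracle_cog(s, v, 1016, 1048, 984, 1144)
    got <- center_of_gravity(s, ax, 1016, 1048, 984, 1144)
    if (is.na(o_cg)) expect_true(is.na(got)) else expect_lt(rel(got, o_cg), 1e-9)
  }
})

test_that("the published metric library has 27 valid, uniquely named entries", {
  defs <- default_metric_library()
  expect_length(defs, 27)
  kinds <- vapply(defs, `[[`, character(1), "kind")
  expect_equal(unname(table(kinds)[c("peak_height_ratio", "area_to_height_ratio",
                                     "center_of_gravity")]), c(21L, 3L, 3L),
               ignore_attr = TRUE)
  expect_false(anyDuplicated(names(defs)) > 0)
  for (d in defs) expect_true(all(d$params >= 800 & d$params <= 4000))
  # expanded library appends band / amide-I ratios
  expect_gt(length(default_metric_library(expand = TRUE)), 27)
  # JSON round trip
  path <- file.path(tempdir(), "defs.json")
  write_metric_library(defs, path)
  back <- read_metric_library(path)
  expect_equal(lapply(back, unclass), lapply(defs, unclass))
  expect_error(metric_definition("x", "peak_height_ratio", c(1236)), "2 parameters")
  expect_error(metric_definition("x", "no_such_kind", c(1, 2)), "unknown")
})

test_that("compute_features is consistent with single-spectrum metrics", {
  ph <- synth_phantom(phantom_spec(rows = 24, cols = 24, seed = 13,
                                   boundary_mixing = FALSE, snr = Inf,
                                   baseline_slope_sd = 0, n_foci = 1,
                                   n_fibrosis = 1))
  pp <- preprocess_cube(ph$cube)
  defs <- default_metric_library()
  fe <- compute_features(pp$cube, pp$mask, defs)
  # masked pixels carry the NA sentinel; kept pixels all finite or flagged
  fm <- irheart:::feature_matrix(fe)
  expect_true(all(is.na(fm[!as.vector(pp$mask$keep), ])))
  # noiseless pure-class phantom: identical feature vector within a class
  for (cc in c(1, 5)) {
    rows <- fm[as.vector(ph$truth$labels == cc & pp$mask$keep), , drop = FALSE]
    expect_lt(max(apply(rows, 2, function(x) diff(range(x)))), 1e-9)
  }
  # per-pixel values match the single-spectrum operations exactly
  px <- which(ph$truth$labels == 4 & pp$mask$keep, arr.ind = TRUE)[1, ]
  s <- pp$cube$data[px[1], px[2], ]
  ax <- pp$cube$axis
  expect_equal(fe$values[px[1], px[2], which(names(defs) == "phr_1239_1652")],
               peak_height_ratio(s, ax, 1239, 1652))
  expect_equal(fe$values[px[1], px[2], which(names(defs) == "ahr_1482_1594_1652")],
               area_to_height_ratio(s, ax, 1482, 1594, 1652))
  expect_equal(fe$values[px[1], px[2], which(names(defs) == "cog_984_1144_1016_1048")],
               center_of_gravity(s, ax, 1016, 1048, 984, 1144))
  expect_error(compute_features(pp$cube, pp$mask, list()), "empty")
})

test_that("both CG interpretations are available", {
  ph <- synth_phantom(phantom_spec(rows = 16, cols = 16, seed = 2, n_foci = 0,
                                   n_fibrosis = 0))
  pp <- preprocess_cube(ph$cube)
  defs <- default_metric_library()[25:27]
  a <- compute_features(pp$cube, pp$mask, defs, cog_mode = "window")
  b <- compute_features(pp$cube, pp$mask, defs, cog_mode = "normalized")
  ka <- a$values[, , 3][pp$mask$keep]
  kb <- b$values[, , 3][pp$mask$keep]
  expect_true(all(ka >= 1016 - 1e-9 & ka <= 1048 + 1e-9))  # window: in [cg1, cg2]
  expect_true(all(kb > -2 & kb < 3))                       # normalized: unit scale
})
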