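# build a small feature_image directly from a matrix of metric values
fake_features <- function(m, metric_names = colnames(m)) {
  nr <- nrow(m)
  structure(list(
    values = array(m, dim = c(nr, 1, ncol(m))),
    metric_names = metric_names,
    mask = structure(list(keep = matrix(TRUE, nr, 1), threshold = 0.3),
                     class = "pixel_mask")),
    class = "feature_image")
}

test_that("metric scoring reproduces exhaustive AUC and boundary cases", {
  set.seed(14)
  # perfectly separated metric: auc 1, min_error 0
  x <- c(rnorm(30, 10), rnorm(30, -10))
  lab <- matrix(c(rep(5L, 30), rep(1L, 30)), ncol = 1)
  fe <- fake_features(matrix(x, ncol = 1, dimnames = list(NULL, "m1")))
  sc <- score_metrics(fe, lab)
  expect_equal(sc$auc[sc$class_code == 5], 1.0)
  expect_equal(sc$min_error[sc$class_code == 5], 0.0)
  # identical distributions: auc ~ 0.5
  x0 <- rnorm(1000)
  lab0 <- matrix(rep(c(1L, 2L), each = 500), ncol = 1)
  sc0 <- score_metrics(fake_features(matrix(x0, ncol = 1,
                                            dimnames = list(NULL, "m1"))), lab0)
  expect_lt(abs(sc0$auc[1] - 0.5), 0.05)
  # 20-point hand-made sample equals the exhaustive pairwise-comparison oracle
  xh <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3, 2, 3, 8, 4)
  yh <- rep(c(TRUE, FALSE), 10)
  scored <- irheart:::rank_auc(xh, yh)
  expect_equal(scored, oracle_auc(xh, yh), tolerance = 1e-12)
  # orientation: min_error <= 0.5 and auc >= 0.5 always
  expect_true(all(sc0$auc >= 0.5 - 1e-12))
  expect_true(all(sc0$min_error <= 0.5 + 1e-12))
})

test_that("metric selection is deterministic with documented tie-breaks", {
  scores <- data.frame(
    metric_name = rep(c("a", "b", "c"), 2),
    class_code = rep(1:2, each = 3),
    auc = c(0.9, 0.9, 0.7, 0.6, 0.95, 0.6),
    min_error = c(0.2, 0.1, 0.3, 0.4, 0.05, 0.4))
  # class 1: tie on auc broken by lower min_error -> "b"; class 2 -> "b"
  expect_equal(select_metrics(scores, 1), "b")
  # all equal: name order decides, stable across calls
  eq <- data.frame(metric_name = c("z", "y", "x"), class_code = 1,
                   auc = 0.8, min_error = 0.1)
  expect_equal(select_metrics(eq, 2), c("x", "y"))
  expect_warning(sel <- select_metrics(eq, 10), "capped")
  expect_equal(sort(sel), c("x", "y", "z"))
})

test_that("fit recovers generator parameters and is order-invariant", {
  set.seed(15)
  n <- 500
  mu <- c(0, 3, -2, 6, 10); sd_ <- c(1, 1.5, 0.5, 2, 1)
  x <- unlist(lapply(1:5, function(cc) rnorm(n, mu[cc], sd_[cc])))
  x2 <- x + rnorm(5 * n, 0, 4)  # second, weaker metric
  lab <- matrix(rep(1:5, each = n), ncol = 1)
  fe <- fake_features(matrix(c(x, x2), ncol = 2,
                             dimnames = list(NULL, c("m1", "m2"))))
  defs <- list(m1 = metric_definition("m1", "peak_height_ratio", c(1236, 1652)),
               m2 = metric_definition("m2", "peak_height_ratio", c(1204, 1652)))
  m <- ir_bayes(fe, lab, metric_library = defs, k_per_class = 2)
  mus <- coef(m)[, "m1"]
  for (cc in 1:5) {
    se <- sd_[cc] / sqrt(n)
    expect_lt(abs(mus[cc] - mu[cc]), 3 * se)
    expect_lt(abs(m$params[[cc]]$sd[["m1"]] - sd_[cc]), 3 * sd_[cc] / sqrt(n))
  }
  # permuting training pixels yields the identical model
  perm <- sample(5 * n)
  fe_p <- fake_features(matrix(c(x[perm], x2[perm]), ncol = 2,
                               dimnames = list(NULL, c("m1", "m2"))))
  m_p <- ir_bayes(fe_p, matrix(lab[perm], ncol = 1), metric_library = defs,
                  k_per_class = 2)
  expect_equal(m_p$params, m$params, tolerance = 1e-12)
  expect_equal(m_p$weights, m$weights, tolerance = 1e-12)
  # duplicated training set: identical model (deterministic fit)
  m_d <- ir_bayes(fake_features(matrix(c(x, x, x2, x2), ncol = 2,
                                       dimnames = list(NULL, c("m1", "m2")))),
                  matrix(rep(lab, 2), ncol = 1), metric_library = defs,
                  k_per_class = 2)
  expect_equal(m_d$params[[1]]$mean, m$params[[1]]$mean, tolerance = 1e-12)
  # absent class errors by name
  expect_error(ir_bayes(fe, matrix(pmin(lab, 4L), ncol = 1),
                        metric_library = defs), "Lymphocytes")
})

test_that("model round-trips through JSON serialization", {
  set.seed(16)
  lab <- matrix(rep(1:5, each = 60), ncol = 1)
  x <- rnorm(300, rep(1:5, each = 60))
  fe <- fake_features(matrix(x, ncol = 1, dimnames = list(NULL, "m1")))
  defs <- list(m1 = metric_definition("m1", "peak_height_ratio", c(1236, 1652)))
  m <- ir_bayes(fe, lab, metric_library = defs, k_per_class = 1)
  path <- file.path(tempdir(), "model.json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$params, m$params, tolerance = 0)
  expect_equal(back$weights, m$weights, tolerance = 0)
  expect_equal(back$priors, m$priors, tolerance = 0)
  expect_identical(back$selected, m$selected)
  post1 <- posterior_map(fe, m)
  post2 <- posterior_map(fe, back)
  expect_identical(post1, post2)
})

test_that("posteriors follow Bayes' rule and normalize", {
  # uniform priors, one metric, equal likelihoods -> 0.2 per class
  defs <- list(m1 = metric_definition("m1", "peak_height_ratio", c(1236, 1652)))
  m <- list(classes = 1:5, class_names = names(class_codes()),
            priors = rep(0.2, 5), likelihood = "gaussian",
            params = lapply(1:5, function(cc)
              list(mean = c(m1 = 0), sd = c(m1 = 1))),
            selected = "m1", weights = c(m1 = 1), posterior_threshold = 0.5,
            metric_library = defs)
  class(m) <- "ir_bayes"
  fe <- fake_features(matrix(0.7, 1, 1, dimnames = list(NULL, "m1")))
  post <- posterior_map(fe, m)
  expect_equal(as.vector(post[1, 1, ]), rep(0.2, 5), tolerance = 1e-12)
  # 3-class, 2-metric hand example matches longhand Bayes computation
  mus <- list(c(0, 1), c(2, -1), c(1, 3))
  sds <- list(c(1, 2), c(0.5, 1), c(2, 0.5))
  m2 <- m
  m2$priors <- c(0.5, 0.3, 0.2, 0, 0)
  m2$params <- c(lapply(1:3, function(cc)
    list(mean = c(m1 = mus[[cc]][1], m2 = mus[[cc]][2]),
         sd = c(m1 = sds[[cc]][1], m2 = sds[[cc]][2]))),
    lapply(4:5, function(cc) list(mean = c(m1 = 0, m2 = 0),
                                  sd = c(m1 = 1e-6, m2 = 1e-6))))
  m2$selected <- c("m1", "m2")
  m2$weights <- c(m1 = 1.4, m2 = 0.6)
  obs <- c(0.8, 1.9)
  fe2 <- fake_features(matrix(obs, 1, 2, dimnames = list(NULL, c("m1", "m2"))))
  post2 <- posterior_map(fe2, m2)
  hand <- vapply(1:3, function(cc)
    m2$priors[cc] * dnorm(obs[1], mus[[cc]][1], sds[[cc]][1])^1.4 *
      dnorm(obs[2], mus[[cc]][2], sds[[cc]][2])^0.6, numeric(1))
  expect_equal(as.vector(post2[1, 1, 1:3]), hand / sum(hand), tolerance = 1e-9)
  # posteriors sum to 1 on every kept pixel
  set.seed(17)
  feR <- fake_features(matrix(rnorm(200), 100, 2,
                              dimnames = list(NULL, c("m1", "m2"))))
  postR <- posterior_map(feR, m2)
  sums <- apply(matrix(postR, 100, 5), 1, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # undefined metrics drop from the product; all-undefined -> unclassified
  feN <- fake_features(matrix(c(0.8, NA, NA, NA), 2, 2,
                              dimnames = list(NULL, c("m1", "m2"))))
  postN <- posterior_map(feN, m2)
  expect_false(anyNA(postN[1, 1, ]))
  expect_true(all(is.na(postN[2, 1, ])))
  pred <- classify_map(postN, feN$mask, m2)
  expect_equal(pred[2, 1], 0L)
})

test_that("classification threshold and tie rules behave as documented", {
  mask <- structure(list(keep = matrix(TRUE, 3, 1)), class = "pixel_mask")
  model <- list(posterior_threshold = 0.5)
  post <- array(c(0.9, 0.3, 0.4,   0.025, 0.3, 0.4,  0.025, 0.2, 0.1,
                  0.025, 0.1, 0.05, 0.025, 0.1, 0.05), dim = c(3, 1, 5))
  pred <- classify_map(post, mask, model)
  expect_equal(pred[1, 1], 1L)   # 0.9 >= 0.5
  expect_equal(pred[2, 1], 0L)   # max 0.3 < 0.5 -> unclassified
  expect_equal(pred[3, 1], 0L)   # tie 0.4/0.4 below threshold
  model0 <- list(posterior_threshold = 0)
  pred0 <- classify_map(post, mask, model0)
  expect_true(all(pred0 > 0L))   # threshold 0: no unclassified kept pixels
  expect_equal(pred0[3, 1], 1L)  # argmax tie broken by lowest class code
  # lowering the threshold never decreases the number of classified pixels
  counts <- vapply(c(0.9, 0.5, 0.25, 0), function(th)
    sum(classify_map(post, mask, list(posterior_threshold = th)) > 0L),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("noiseless unmixed phantom is classified perfectly; noisy one nearly so", {
  ph0 <- synth_phantom(phantom_spec(rows = 40, cols = 40, seed = 19,
                                    boundary_mixing = FALSE, snr = Inf,
                                    baseline_slope_sd = 0))
  pp0 <- preprocess_cube(ph0$cube)
  defs <- default_metric_library()
  fe0 <- compute_features(pp0$cube, pp0$mask, defs)
  m0 <- ir_bayes(fe0, ph0$truth$labels, metric_library = defs)
  pred0 <- predict(m0, fe0)
  lab0 <- ph0$truth$labels
  expect_equal(mean((pred0 == lab0)[pp0$mask$keep & lab0 > 0]), 1.0)
  # stochastic recovery at SNR 500: >= 99% accuracy on pure pixels
  ph <- tiny_phantom(seed = 20)
  pp <- preprocess_cube(ph$cube)
  fe <- compute_features(pp$cube, pp$mask, defs)
  m <- ir_bayes(fe, ph$truth$labels, metric_library = defs)
  pred <- predict(m, fe)
  pure <- pp$mask$keep & ph$truth$labels > 0 & ph$truth$mixing_fraction == 1
  expect_gte(mean((pred == ph$truth$labels)[pure]), 0.99)
  # phantom-trained selection includes an amide III (1236/1239) metric
  expect_true(any(grepl("123[69]", m$selected)))
  # histogram likelihood variant trains and predicts sanely on pure pixels
  mh <- ir_bayes(fe, ph$truth$labels, metric_library = defs,
                 likelihood = "histogram")
  predh <- predict(mh, fe)
  expect_gte(mean((predh == ph$truth$labels)[pure]), 0.95)
})
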