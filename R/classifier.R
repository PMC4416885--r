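# ---- metric scoring and selection ------------------------------------------

# Mann-Whitney AUC of scores x for binary truth y (TRUE = positive),
# tie-corrected via midranks.
rank_auc <- function(x, y) {
  ok <- is.finite(x)
  x <- x[ok]; y <- y[ok]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(x)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# minimum achievable overall error over all thresholds of rule x >= t,
# orientation fixed by the caller
min_threshold_error <- function(x, y) {
  ok <- is.finite(x)
  x <- x[ok]; y <- y[ok]
  n <- length(x); n1 <- sum(y); n0 <- n - n1
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  # rule: x >= t -> positive. Cutting after sorted index i predicts items
  # 1..i negative: FN = fn[i], FP = n0 - tn[i]. Cuts inside a tie group are
  # not realizable thresholds and are excluded.
  fn <- cumsum(ys)
  tn <- seq_len(n) - fn
  realizable <- c(xs[-1] > xs[-n], TRUE)
  err <- c(n0, (fn + n0 - tn)[realizable])
  min(err) / n
}

#' Score metrics by one-vs-rest class separability
#'
#' For every (metric, class) pair, computes the one-vs-rest area under the
#' ROC curve by the rank (Mann-Whitney) statistic and the minimum achievable
#' classification error over all thresholds. Orientation is chosen per pair
#' so that AUC >= 0.5.
#'
#' @param features a `feature_image` from [compute_features()].
#' @param truth a label matrix (codes 0..5; 0 = unlabeled).
#' @param min_pixels minimum labeled pixels a class needs to be scored
#'   (default 20); classes below it are skipped with a warning.
#' @return a data frame with columns `metric_name`, `class_code`, `auc`,
#'   `min_error`.
#' @export
score_metrics <- function(features, truth, min_pixels = 20) {
  truth <- validate_labels(truth)
  m <- feature_matrix(features)
  keep <- as.vector(features$mask$keep) & as.vector(truth) > 0L
  m <- m[keep, , drop = FALSE]
  lab <- as.vector(truth)[keep]
  present <- sort(unique(lab))
  counts <- tabulate(lab, 5L)
  scored <- present[counts[present] >= min_pixels]
  if (length(scored) < 2L)
    stop("need >= 2 classes with >= ", min_pixels, " labeled pixels", call. = FALSE)
  if (length(scored) < length(present))
    warning("skipping classes with < ", min_pixels, " pixels: ",
            paste(class_name(setdiff(present, scored)), collapse = ", "))
  out <- expand.grid(metric_name = colnames(m), class_code = scored,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$auc <- NA_real_; out$min_error <- NA_real_
  for (i in seq_len(nrow(out))) {
    x <- m[, out$metric_name[i]]
    y <- lab == out$class_code[i]
    a <- rank_auc(x, y)
    if (!is.finite(a)) next
    flip <- a < 0.5
    out$auc[i] <- if (flip) 1 - a else a
    out$min_error[i] <- min_threshold_error(if (flip) -x else x, y)
  }
  out
}

#' Select the top discriminative metrics per class
#'
#' Takes the union over classes of each class's top `k_per_class` metrics by
#' AUC; ties broken by lower minimum error, then by name order, so the
#' selection is deterministic.
#'
#' @param scores data frame from [score_metrics()].
#' @param k_per_class metrics retained per class (>= 1); capped at the
#'   library size with a warning.
#' @return character vector of selected metric names.
#' @export
select_metrics <- function(scores, k_per_class = 5) {
  stopifnot(k_per_class >= 1)
  n_metrics <- length(unique(scores$metric_name))
  if (k_per_class > n_metrics) {
    warning("k_per_class exceeds library size; capped at ", n_metrics)
    k_per_class <- n_metrics
  }
  sel <- character()
  for (cc in sort(unique(scores$class_code))) {
    s <- scores[scores$class_code == cc & is.finite(scores$auc), ]
    s <- s[order(-s$auc, s$min_error, s$metric_name), ]
    sel <- union(sel, utils::head(s$metric_name, k_per_class))
  }
  sort(sel)
}

# ---- the fitted model -------------------------------------------------------

#' Fit the weighted naive-Bayes tissue classifier
#'
#' Trains the per-pixel Bayesian classifier on labeled feature images. Each
#' selected metric contributes an independent univariate likelihood per class
#' (Gaussian by default: location = class mean, spread = class SD floored at
#' 1e-6; optionally a Laplace-smoothed 64-bin histogram density). Metrics are
#' selected by one-vs-rest AUC ([score_metrics()], [select_metrics()]) and
#' enter the posterior product with exponent weights
#' `w = max(AUC - 0.5, 0)` (the metric's best AUC over classes), normalized
#' to mean 1 — metrics that separate classes better count more, realizing
#' the differential weighting of metric parameters. Priors are uniform by
#' default: class abundances in a biopsy are not population-representative.
#'
#' @param features a `feature_image` from [compute_features()], computed on a
#'   preprocessed cube.
#' @param truth label matrix (codes 0..5; 0 = unlabeled) marking training
#'   pixels.
#' @param metric_library the metric definitions the features were computed
#'   with (stored in the model so prediction can recompute them).
#' @param k_per_class metrics retained per class (default 5).
#' @param priors per-class prior probabilities (default uniform over the five
#'   classes); must sum to 1.
#' @param likelihood `"gaussian"` (default) or `"histogram"`.
#' @param weights `"auc"` (default) or `"uniform"` (all exponents 1).
#' @param posterior_threshold minimum posterior for a pixel to be assigned a
#'   class; below it the pixel is left unclassified (default 0.5).
#' @param n_bins histogram bins when `likelihood = "histogram"`.
#' @return an object of class `ir_bayes` with `print`, `summary`, `coef` and
#'   `predict` methods.
#' @seealso [predict.ir_bayes()], [write_model()], [read_model()]
#' @export
ir_bayes <- function(features, truth, metric_library = default_metric_library(),
                     k_per_class = 5, priors = NULL,
                     likelihood = c("gaussian", "histogram"),
                     weights = c("auc", "uniform"),
                     posterior_threshold = 0.5, n_bins = 64) {
  likelihood <- match.arg(likelihood)
  weights <- match.arg(weights)
  truth <- validate_labels(truth)
  classes <- 1:5
  counts <- tabulate(as.vector(truth)[as.vector(features$mask$keep) &
                                        as.vector(truth) > 0L], 5L)
  if (any(counts == 0L))
    stop("training error: class(es) absent from labeled kept pixels: ",
         paste(class_name(which(counts == 0L)), collapse = ", "), call. = FALSE)
  if (is.null(priors)) priors <- rep(1 / 5, 5)
  if (abs(sum(priors) - 1) > 1e-9 || any(priors < 0))
    stop("priors must be non-negative and sum to 1", call. = FALSE)
  scores <- score_metrics(features, truth)
  selected <- select_metrics(scores, k_per_class)
  best_auc <- vapply(selected, function(nm)
    max(scores$auc[scores$metric_name == nm], na.rm = TRUE), numeric(1))
  w <- if (weights == "auc") pmax(best_auc - 0.5, 0) else rep(1, length(selected))
  if (weights == "auc") {
    if (mean(w) <= 0) stop("no metric has AUC > 0.5; cannot weight", call. = FALSE)
    w <- w / mean(w)
  }
  names(w) <- selected

  m <- feature_matrix(features)
  keep <- as.vector(features$mask$keep) & as.vector(truth) > 0L
  m <- m[keep, selected, drop = FALSE]
  lab <- as.vector(truth)[keep]
  lik <- vector("list", 5L)
  for (cc in classes) {
    mc <- m[lab == cc, , drop = FALSE]
    if (likelihood == "gaussian") {
      mu <- apply(mc, 2, function(x) mean(x[is.finite(x)]))
      sd_ <- apply(mc, 2, function(x) stats::sd(x[is.finite(x)]))
      sd_[!is.finite(sd_) | sd_ < 1e-6] <- 1e-6
      lik[[cc]] <- list(mean = mu, sd = sd_)
    } else {
      lik[[cc]] <- lapply(selected, function(nm) {
        x <- mc[, nm]; x <- x[is.finite(x)]
        rng <- range(m[, nm][is.finite(m[, nm])])
        if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
        br <- seq(rng[1], rng[2], length.out = n_bins + 1)
        cnt <- tabulate(findInterval(x, br, all.inside = TRUE), n_bins)
        dens <- (cnt + 1) / (sum(cnt) + n_bins) / diff(br)[1]  # Laplace-smoothed
        list(breaks = br, density = dens)
      })
      names(lik[[cc]]) <- selected
    }
  }
  structure(list(classes = classes, class_names = names(class_codes()),
                 priors = priors, likelihood = likelihood,
                 params = lik, selected = selected, weights = w,
                 posterior_threshold = posterior_threshold,
                 metric_library = metric_library[selected],
                 scores = scores, n_train = counts,
                 schema_version = 1L),
            class = "ir_bayes")
}

#' @export
print.ir_bayes <- function(x, ...) {
  cat("Weighted naive-Bayes FT-IR tissue classifier\n")
  cat(sprintf("  classes: %s\n", paste(x$class_names, collapse = ", ")))
  cat(sprintf("  likelihood: %s; %d selected metrics; posterior threshold %.2f\n",
              x$likelihood, length(x$selected), x$posterior_threshold))
  cat(sprintf("  training pixels per class: %s\n",
              paste(x$n_train, collapse = ", ")))
  invisible(x)
}

#' @export
summary.ir_bayes <- function(object, ...) {
  cat("Selected metrics (weight = normalized max AUC excess over 0.5):\n")
  best <- vapply(object$selected, function(nm)
    max(object$scores$auc[object$scores$metric_name == nm], na.rm = TRUE),
    numeric(1))
  df <- data.frame(metric = object$selected, best_auc = round(best, 4),
                   weight = round(object$weights, 4), row.names = NULL)
  print(df)
  invisible(df)
}

#' @export
coef.ir_bayes <- function(object, ...) {
  if (object$likelihood != "gaussian")
    stop("coef is defined for the Gaussian likelihood only", call. = FALSE)
  mu <- t(vapply(object$params, `[[`, numeric(length(object$selected)), "mean"))
  rownames(mu) <- object$class_names
  colnames(mu) <- object$selected
  mu
}

# ---- posterior and classification -------------------------------------------

#' Per-pixel class posteriors
#'
#' Computes, for every kept pixel, posteriors proportional to
#' `prior * prod_m likelihood_m ^ w_m` over the model's selected metrics,
#' in the log domain, normalized to sum to 1. Metrics undefined for a pixel
#' are dropped from that pixel's product; pixels with no defined metric get
#' an undefined posterior (all `NA`) and fall to unclassified.
#'
#' @param features a `feature_image` computed with the model's metric
#'   library.
#' @param model an [ir_bayes()] model.
#' @return rows x cols x 5 array of posterior probabilities (`NA` on masked
#'   or all-undefined pixels).
#' @export
posterior_map <- function(features, model) {
  stopifnot(inherits(model, "ir_bayes"))
  if (!all(model$selected %in% features$metric_names))
    stop("features lack selected metrics: ",
         paste(setdiff(model$selected, features$metric_names), collapse = ", "),
         call. = FALSE)
  d <- dim(features$values)
  m <- feature_matrix(features)[, model$selected, drop = FALSE]
  keep <- as.vector(features$mask$keep)
  mk <- m[keep, , drop = FALSE]
  logp <- matrix(rep(log(model$priors), each = nrow(mk)), nrow(mk), 5L)
  any_defined <- rep(FALSE, nrow(mk))
  for (j in seq_along(model$selected)) {
    nm <- model$selected[j]
    x <- mk[, j]
    ok <- is.finite(x)
    any_defined <- any_defined | ok
    for (cc in model$classes) {
      ll <- if (model$likelihood == "gaussian") {
        p <- model$params[[cc]]
        stats::dnorm(x[ok], p$mean[[nm]], p$sd[[nm]], log = TRUE)
      } else {
        p <- model$params[[cc]][[nm]]
        i <- findInterval(x[ok], p$breaks, all.inside = TRUE)
        log(p$density[i])
      }
      logp[ok, cc] <- logp[ok, cc] + model$weights[[nm]] * ll
    }
  }
  # normalize in log domain
  mx <- apply(logp, 1, max)
  post <- exp(logp - mx)
  post <- post / rowSums(post)
  post[!any_defined, ] <- NA_real_
  out <- matrix(NA_real_, d[1] * d[2], 5L)
  out[keep, ] <- post
  array(out, dim = c(d[1], d[2], 5L))
}

#' Classify pixels from posteriors
#'
#' Assigns each kept pixel the argmax-posterior class if the maximum
#' posterior reaches the model's threshold, else code 0 (unclassified);
#' masked or undefined-posterior pixels are always 0. Argmax ties are broken
#' by the lowest class code.
#'
#' @param posteriors array from [posterior_map()].
#' @param mask the `pixel_mask`.
#' @param model an [ir_bayes()] model (supplies `posterior_threshold`).
#' @return an integer class-map matrix (codes 0..5).
#' @export
classify_map <- function(posteriors, mask, model) {
  d <- dim(posteriors)
  p <- matrix(posteriors, d[1] * d[2], d[3])
  lab <- rep(0L, nrow(p))
  ok <- as.vector(mask$keep) & apply(p, 1, function(r) all(is.finite(r)))
  if (any(ok)) {
    pm <- p[ok, , drop = FALSE]
    amax <- max.col(pm, ties.method = "first")  # lowest code wins ties
    mx <- pm[cbind(seq_len(nrow(pm)), amax)]
    lab[ok] <- ifelse(mx >= model$posterior_threshold, amax, 0L)
  }
  matrix(as.integer(lab), d[1], d[2])
}

#' Predict method for ir_bayes models
#'
#' @param object an [ir_bayes()] model.
#' @param features a `feature_image` (from [compute_features()] with the
#'   model's metric library), or a preprocessed [spectral_cube()] plus
#'   `mask`, in which case features are computed internally.
#' @param type `"class"` for a class map (default) or `"posterior"` for the
#'   rows x cols x 5 posterior array.
#' @param mask required when `features` is a cube.
#' @param ... unused.
#' @return class-map matrix or posterior array.
#' @export
predict.ir_bayes <- function(object, features, type = c("class", "posterior"),
                             mask = NULL, ...) {
  type <- match.arg(type)
  if (inherits(features, "spectral_cube")) {
    if (is.null(mask)) stop("supply `mask` when predicting from a cube", call. = FALSE)
    features <- compute_features(features, mask, object$metric_library)
  }
  post <- posterior_map(features, object)
  if (type == "posterior") return(post)
  classify_map(post, features$mask, object)
}

# ---- serialization ----------------------------------------------------------

#' Serialize / deserialize an ir_bayes model as JSON
#'
#' The JSON schema is versioned; numeric values are written at full precision
#' so a round trip reproduces the model exactly.
#'
#' @param model an [ir_bayes()] model.
#' @param path JSON file path.
#' @return `read_model`: the restored model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ir_bayes"))
  payload <- unclass(model)
  payload$metric_library <- lapply(unname(payload$metric_library), function(d)
    list(name = d$name, kind = d$kind, params = d$params))
  # atomic-vector names do not survive JSON; store per-metric values as objects
  if (model$likelihood == "gaussian")
    payload$params <- lapply(payload$params, function(cl)
      list(mean = as.list(cl$mean), sd = as.list(cl$sd)))
  payload$weights <- as.list(payload$weights)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  defs <- lapply(p$metric_library, function(d)
    metric_definition(d$name, d$kind, unlist(d$params)))
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  lik <- lapply(p$params, function(cl) {
    if (p$likelihood == "gaussian")
      list(mean = unlist(cl$mean), sd = unlist(cl$sd))
    else lapply(cl, function(h) list(breaks = unlist(h$breaks),
                                     density = unlist(h$density)))
  })
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  scores <- data.frame(
    metric_name = vapply(p$scores, function(r) r$metric_name, character(1)),
    class_code = vapply(p$scores, function(r) as.integer(r$class_code), integer(1)),
    auc = vapply(p$scores, function(r) num_or_na(r$auc), numeric(1)),
    min_error = vapply(p$scores, function(r) num_or_na(r$min_error), numeric(1)))
  w <- unlist(p$weights)
  structure(list(classes = as.integer(unlist(p$classes)),
                 class_names = as.character(unlist(p$class_names)),
                 priors = as.numeric(unlist(p$priors)),
                 likelihood = p$likelihood,
                 params = lik, selected = as.character(unlist(p$selected)),
                 weights = stats::setNames(as.numeric(w), names(w)),
                 posterior_threshold = as.numeric(p$posterior_threshold),
                 metric_library = defs,
                 scores = scores,
                 n_train = as.integer(unlist(p$n_train)),
                 schema_version = as.integer(p$schema_version)),
            class = "ir_bayes")
}
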