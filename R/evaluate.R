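#' One-vs-rest ROC curve from class posteriors
#'
#' Sweeps a threshold over the class-`c` posterior of every kept,
#' ground-truth-labeled pixel, yielding the (Pfa, Pd) curve from (0,0) to
#' (1,1) and its trapezoidal AUC. Labeled pixels whose posterior is
#' undefined (unclassified by the missing-metric rule) stay in the sweep
#' with score -Inf, so they count as misses / true negatives at every
#' threshold — keeping Pd honest about the unclassified mechanism. At most
#' one curve point is kept per unique score.
#'
#' @param posteriors posterior array from [posterior_map()].
#' @param class_code class treated as positive (1..5).
#' @param truth label matrix (codes 0..5; 0 = unlabeled, excluded).
#' @param mask a `pixel_mask`.
#' @return an object of class `roc_curve`: list with `points` (data frame of
#'   `pfa`, `pd`), `auc`, `class_code`.
#' @export
roc_one_vs_rest <- function(posteriors, class_code, truth, mask) {
  truth <- validate_labels(truth)
  d <- dim(posteriors)
  score <- matrix(posteriors, d[1] * d[2], d[3])[, class_code]
  keep <- as.vector(mask$keep) & as.vector(truth) > 0L
  score <- score[keep]
  score[!is.finite(score)] <- -Inf
  y <- as.vector(truth)[keep] == class_code
  P <- sum(y); N <- sum(!y)
  if (P == 0 || N == 0)
    stop("one-sided truth: class ", class_name(class_code),
         " needs both positives and negatives", call. = FALSE)
  o <- order(score, decreasing = TRUE)
  ys <- y[o]; ss <- score[o]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  last <- c(ss[-1] != ss[-length(ss)], TRUE)  # one point per unique score
  pd <- c(0, tp[last] / P)
  pfa <- c(0, fp[last] / N)
  if (pd[length(pd)] != 1 || pfa[length(pfa)] != 1) {
    pd <- c(pd, 1); pfa <- c(pfa, 1)
  }
  auc <- sum(diff(pfa) * (pd[-1] + pd[-length(pd)]) / 2)
  structure(list(points = data.frame(pfa = pfa, pd = pd), auc = auc,
                 class_code = as.integer(class_code)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> class %s: %d points, AUC %.4f\n",
              class_name(x$class_code), nrow(x$points), x$auc))
  invisible(x)
}

#' Plot method for ROC curves
#'
#' @param x a `roc_curve`.
#' @param ... passed to [plot.default()].
#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$points$pfa, x$points$pd, type = "l",
       xlab = "Probability of false alarm", ylab = "Probability of detection",
       main = sprintf("%s (AUC %.3f)", class_name(x$class_code), x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Probability of detection at a fixed false-alarm rate
#'
#' Linearly interpolates the ROC curve at the target Pfa — the study's
#' headline operating point is Pd at 10% Pfa.
#'
#' @param curve a `roc_curve`.
#' @param pfa_target false-alarm probability in \[0, 1\] (default 0.10).
#' @return the interpolated Pd.
#' @export
pd_at_pfa <- function(curve, pfa_target = 0.10) {
  stopifnot(inherits(curve, "roc_curve"), pfa_target >= 0, pfa_target <= 1)
  p <- curve$points
  # the curve is a non-decreasing step/polyline; take the max pd at ties
  stats::approx(p$pfa, p$pd, xout = pfa_target, ties = max, rule = 2)$y
}

#' Column-normalized confusion table
#'
#' Tallies predicted class (rows, including Unclassified as row 0) against
#' ground truth (columns, classes 1..5) over kept, truth-labeled pixels, and
#' normalizes each truth column to percent (each column sums to 100).
#'
#' @param pred predicted class map (codes 0..5).
#' @param truth label matrix (codes 0..5; 0 = unlabeled, excluded).
#' @param mask a `pixel_mask`.
#' @return a `confusion_table`: list with `percent` and `counts` matrices
#'   (6 predicted rows x up-to-5 truth columns).
#' @export
confusion <- function(pred, truth, mask) {
  pred <- validate_labels(pred); truth <- validate_labels(truth)
  keep <- as.vector(mask$keep) & as.vector(truth) > 0L
  if (!any(keep)) stop("no kept, labeled pixels to tally", call. = FALSE)
  p <- as.vector(pred)[keep]; t_ <- as.vector(truth)[keep]
  present <- sort(unique(t_))
  counts <- matrix(0L, 6L, length(present),
                   dimnames = list(predicted = class_name(0:5),
                                   truth = class_name(present)))
  for (j in seq_along(present))
    counts[, j] <- tabulate(p[t_ == present[j]] + 1L, 6L)
  percent <- sweep(counts, 2, colSums(counts), "/") * 100
  structure(list(percent = percent, counts = counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, digits = 2, ...) {
  cat("Confusion table (column-normalized %, truth in columns):\n")
  print(round(x$percent, digits))
  invisible(x)
}

# 8-connected components of a logical matrix; returns integer labels (0 = bg)
connected_components8 <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  idx <- which(bw)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1L || rr > nr || c2 < 1L || c2 > nc) next
        j <- (c2 - 1L) * nr + rr
        if (bw[j] && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# any TRUE pixel of a 8-adjacent to a TRUE pixel of b
any_adjacent8 <- function(a, b) {
  nr <- nrow(a); nc <- ncol(a)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ra <- max(1, 1 + dr):min(nr, nr + dr)
    rb <- max(1, 1 - dr):min(nr, nr - dr)
    ca <- max(1, 1 + dc):min(nc, nc + dc)
    cb <- max(1, 1 - dc):min(nc, nc - dc)
    if (any(a[ra, ca] & b[rb, cb])) return(TRUE)
  }
  FALSE
}

#' Sample-level rejection call from a classified map
#'
#' Quantifies lymphocyte infiltration: total lymphocyte pixel count, number
#' of foci (8-connected lymphocyte components of at least `min_size` pixels),
#' and whether any lymphocyte pixel encroaches on the myocardium (is
#' 8-adjacent to a myocardium pixel). The sample is called positive
#' (rejected) when the lymphocyte burden exceeds `negligible_frac` of the
#' tissue pixels *and* lymphocytes encroach on myocardium; grade-0 samples
#' show negligible, non-encroaching lymphocyte pixels and are called
#' negative.
#'
#' @param pred classified map (codes 0..5); tissue pixels are those with a
#'   class assigned (code > 0).
#' @param min_size minimum focus size in pixels (default 4).
#' @param negligible_frac negligible lymphocyte burden as a fraction of
#'   tissue pixels (default 0.001).
#' @return a `rejection_report`: list with `lymphocyte_pixels`,
#'   `lymphocyte_foci`, `encroaching`, `call` (`"positive"`/`"negative"`),
#'   plus the thresholds used.
#' @export
rejection_report <- function(pred, min_size = 4, negligible_frac = 0.001) {
  pred <- validate_labels(pred)
  lymph <- pred == 5L
  myo <- pred == 1L
  n_lymph <- sum(lymph)
  comp <- connected_components8(lymph)
  sizes <- tabulate(comp[comp > 0L])
  n_foci <- sum(sizes >= min_size)
  encroaching <- n_lymph > 0 && any_adjacent8(lymph, myo)
  n_tissue <- sum(pred > 0L)
  burden_threshold <- negligible_frac * n_tissue
  call_ <- if (n_lymph > burden_threshold && encroaching) "positive" else "negative"
  structure(list(lymphocyte_pixels = n_lymph, lymphocyte_foci = n_foci,
                 encroaching = encroaching, call = call_,
                 min_size = min_size, negligible_frac = negligible_frac,
                 tissue_pixels = n_tissue),
            class = "rejection_report")
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("Rejection call: %s\n", toupper(x$call)))
  cat(sprintf("  lymphocyte pixels: %d (%.3f%% of %d tissue pixels)\n",
              x$lymphocyte_pixels,
              100 * x$lymphocyte_pixels / max(x$tissue_pixels, 1),
              x$tissue_pixels))
  cat(sprintf("  foci (>= %d px, 8-connected): %d; encroaching on myocardium: %s\n",
              x$min_size, x$lymphocyte_foci, x$encroaching))
  invisible(x)
}
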