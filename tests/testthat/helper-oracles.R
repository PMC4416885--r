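# Independent brute-force oracles for the spectral metrics and ROC analysis.
# These deliberately use plain loops / direct summation, never the package's
# vectorized code paths.

oracle_peak_height <- function(s, v, center, hw = 6) {
  best <- -Inf
  for (i in seq_along(v))
    if (v[i] >= center - hw - 1e-9 && v[i] <= center + hw + 1e-9 && s[i] > best)
      best <- s[i]
  best
}

oracle_chord_corrected <- function(s, v, left, right) {
  idx <- which(v >= left - 1e-9 & v <= right + 1e-9)
  il <- idx[1]; ir <- idx[length(idx)]
  slope <- (s[ir] - s[il]) / (v[ir] - v[il])
  list(idx = idx, corrected = s[idx] - (s[il] + slope * (v[idx] - v[il])))
}

oracle_band_area <- function(s, v, left, right) {
  cc <- oracle_chord_corrected(s, v, left, right)
  a <- cc$corrected
  tot <- 0
  for (i in seq_len(length(a) - 1))
    tot <- tot + (a[i] + a[i + 1]) / 2 * (v[cc$idx[i + 1]] - v[cc$idx[i]])
  tot
}

oracle_cog <- function(s, v, left, right, anchor_left = left, anchor_right = right) {
  cc <- oracle_chord_corrected(s, v, anchor_left, anchor_right)
  vv <- v[cc$idx]
  inside <- vv >= left - 1e-9 & vv <= right + 1e-9
  a <- pmax(cc$corrected[inside], 0)
  if (sum(a) <= 1e-6) return(NA_real_)
  num <- 0
  for (i in seq_along(a)) num <- num + vv[inside][i] * a[i]
  num / sum(a)
}

# AUC by exhaustive pairwise comparison (ties count 1/2)
oracle_auc <- function(x, y) {
  pos <- x[y]; neg <- x[!y]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# ROC by exhaustive threshold enumeration (rule: score >= t -> positive)
oracle_roc <- function(score, y) {
  ts <- sort(unique(score), decreasing = TRUE)
  pd <- pfa <- numeric(length(ts))
  for (i in seq_along(ts)) {
    pred <- score >= ts[i]
    pd[i] <- sum(pred & y) / sum(y)
    pfa[i] <- sum(pred & !y) / sum(!y)
  }
  data.frame(pfa = c(0, pfa), pd = c(0, pd))
}

# small random synthetic spectrum: a handful of Gaussian bands + drift +
# noise. An amide I band (1652) and a carbohydrate-region band (1030) are
# always present so that the standard metric denominators stay well-defined.
random_spectrum <- function(axis) {
  v <- as.numeric(axis)
  n_pk <- sample(3:8, 1)
  s <- exp(-4 * log(2) * ((v - 1652) / 40)^2) +
    0.4 * exp(-4 * log(2) * ((v - 1030) / 35)^2)
  for (k in seq_len(n_pk)) {
    c0 <- runif(1, 950, 3400); h <- runif(1, 0.05, 1); fw <- runif(1, 15, 80)
    s <- s + h * exp(-4 * log(2) * ((v - c0) / fw)^2)
  }
  s + runif(1, -1e-4, 1e-4) * (v - v[1]) + rnorm(length(v), sd = 1e-3)
}

# small fast phantom for tests
tiny_phantom <- function(seed = 3, rows = 48, cols = 48, ...) {
  synth_phantom(phantom_spec(rows = rows, cols = cols, seed = seed, ...))
}
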