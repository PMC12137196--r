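# Independent brute-force oracles and small fixtures shared across tests.
# Everything here is written from definitions (plain loops, explicit DFT
# sums), deliberately not reusing the package's vectorised code paths.

# From-definition 36-feature oracle for one window (matrix n x 3).
# Static = truncated centred running mean computed with an explicit loop
# (12 before, current, 11 after at width 24), matching summarize_window's
# within-window convention.
oracle_features <- function(acc, fs = 8, width = 24L) {
  n <- nrow(acc)
  back <- width %/% 2L
  fwd <- width - back - 1L
  static <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    lo <- max(1L, i - back)
    hi <- min(n, i + fwd)
    for (a in 1:3) static[i, a] <- mean(acc[lo:hi, a])
  }
  dba <- acc - static
  odba_s <- numeric(n)
  mag <- numeric(n)
  for (i in seq_len(n)) {
    odba_s[i] <- abs(dba[i, 1]) + abs(dba[i, 2]) + abs(dba[i, 3])
    mag[i] <- sqrt(acc[i, 1]^2 + acc[i, 2]^2 + acc[i, 3]^2)
  }
  moments <- function(v) {
    mu <- sum(v) / n
    m2 <- sum((v - mu)^2) / n
    m3 <- sum((v - mu)^3) / n
    m4 <- sum((v - mu)^4) / n
    list(mean = mu,
         std = sqrt(sum((v - mu)^2) / (n - 1)),
         max = max(v), min = min(v),
         kurt = if (m2 > 0) m4 / m2^2 else 0,
         skew = if (m2 > 0) m3 / m2^1.5 else 0)
  }
  corr <- function(u, v) {
    cu <- u - mean(u); cv <- v - mean(v)
    den <- sqrt(sum(cu^2) * sum(cv^2))
    if (den > 0) sum(cu * cv) / den else 0
  }
  dps <- function(v) {
    v <- v - mean(v)
    if (all(v == 0)) return(0)
    kmax <- n %/% 2L
    dens <- numeric(kmax)
    for (k in seq_len(kmax)) {
      re <- 0; im <- 0
      for (j in seq_len(n)) {
        ang <- -2 * pi * (j - 1) * k / n
        re <- re + v[j] * cos(ang)
        im <- im + v[j] * sin(ang)
      }
      p <- (re^2 + im^2) / (n * fs)
      dens[k] <- if (k == kmax && n %% 2L == 0L) p else 2 * p
    }
    max(dens)
  }
  ch <- list(x = acc[, 1], y = acc[, 2], z = acc[, 3], mag = mag)
  mom <- lapply(ch, moments)
  out <- c(
    vapply(mom, `[[`, numeric(1), "mean"),
    vapply(mom, `[[`, numeric(1), "std"),
    vapply(mom, `[[`, numeric(1), "max"),
    vapply(mom, `[[`, numeric(1), "min"),
    vapply(mom, `[[`, numeric(1), "kurt"),
    vapply(mom, `[[`, numeric(1), "skew"),
    corr(ch$x, ch$y), corr(ch$x, ch$z), corr(ch$y, ch$z),
    mean(dba[, 1]), mean(dba[, 2]), mean(dba[, 3]),
    sum(odba_s), mean(odba_s),
    vapply(ch, dps, numeric(1))
  )
  stats::setNames(out, feature_names())
}

# Run-length-encoding bout oracle over one contiguous label sequence.
oracle_bouts <- function(lab, behavior) {
  r <- rle(lab == behavior)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start_i = starts[r$values], n = r$lengths[r$values])
}

# From-definition one-vs-rest metrics oracle for a square count matrix.
oracle_metrics <- function(cm) {
  total <- sum(cm)
  k <- nrow(cm)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    tn <- total - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (den > 0) (tp * tn - fp * fn) / den else NA_real_
    out[[i]] <- c(TP = tp, FP = fp, TN = tn, FN = fn,
                  precision = prec, recall = rec, mcc = mcc)
  }
  list(per_class = do.call(rbind, out),
       overall_error = 1 - sum(diag(cm)) / total)
}

# The published captive-bear confusion matrix (observed rows, predicted
# columns, class order feeding/resting/running/walking).
published_confusion <- function() {
  matrix(c(3826, 195, 0, 104,
           103, 6640, 0, 15,
           0, 0, 145, 3,
           154, 5, 1, 1688),
         nrow = 4, byrow = TRUE,
         dimnames = list(observed = bear_behaviors(),
                         predicted = bear_behaviors()))
}

# Random complete 24-sample window fixture.
random_window <- function(seed) {
  set.seed(seed)
  base <- matrix(rnorm(72, sd = runif(1, 0.01, 0.5)), ncol = 3)
  sweep(base, 2, c(0, runif(1, -0.5, 0.5), runif(1, 0.5, 1)), "+")
}

# Single-behaviour accelerometry fixture: one bout of the given behaviour.
single_behavior_series <- function(behavior, duration_s, seed) {
  params <- default_behavior_params()
  dwell <- params
  dwell$mean_dwell_s <- 1e9
  sched <- simulate_schedule(duration_s, params = dwell, seed = seed,
                             start_behavior = behavior)
  simulate_accel(sched, params = params, seed = seed + 1000L)
}

# Labelled feature sets for classifier tests: n_per_class complete windows
# of each behaviour, generated with default simulator parameters.
labelled_feature_set <- function(n_per_class, seed) {
  dur <- n_per_class * 3 + 6
  out <- lapply(seq_along(bear_behaviors()), function(i) {
    b <- bear_behaviors()[i]
    f <- compute_features(single_behavior_series(b, dur, seed + 17L * i))
    f <- f[seq_len(min(n_per_class, nrow(f))), , drop = FALSE]
    f$label <- b
    f
  })
  do.call(rbind, out)
}
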