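# Independent oracles used to validate the package's estimators. These are
# deliberately brute-force and share no code with the implementation.

# Grid-search SSE oracle for the segmented IVIM fit: for each (f, d_p) on a
# dense grid the optimal s0 is the closed-form linear least-squares scale,
# so only two dimensions are searched.
oracle_segmented_sse <- function(signal, b, d_t,
                                 f_grid = seq(0, 0.7, by = 0.002),
                                 dp_grid = exp(seq(log(3e-3), log(0.5),
                                                   length.out = 300))) {
  best <- Inf
  for (dp in dp_grid) {
    e_p <- exp(-b * dp)
    e_t <- exp(-b * d_t)
    for (f in f_grid) {
      m <- f * e_p + (1 - f) * e_t
      s0 <- sum(m * signal) / sum(m^2)
      sse <- sum((s0 * m - signal)^2)
      if (sse < best) best <- sse
    }
  }
  best
}

# Exhaustive Youden search: every observed value as a threshold (plus
# +/-Inf), both directions; returns the maximal J.
oracle_max_youden <- function(values, labels) {
  cand <- c(-Inf, sort(unique(values)), Inf)
  best <- -Inf
  for (cut in cand) {
    for (ge in c(TRUE, FALSE)) {
      pos <- if (ge) values >= cut else values < cut
      sens <- sum(pos & labels == 1) / sum(labels == 1)
      spec <- sum(!pos & labels == 0) / sum(labels == 0)
      best <- max(best, sens + spec - 1)
    }
  }
  best
}

# Concordant-pair AUC: fraction of (positive, negative) pairs ranked
# correctly, ties counting one half.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Hand product-limit estimator over the event times.
oracle_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ts <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# Two-group log-rank statistic from first principles (O - E)^2 / V.
oracle_logrank_chi2 <- function(times, events, group) {
  g <- as.integer(as.factor(group))
  ts <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# A small noiseless phantom used by several files.
make_test_phantom <- function(noise_sigma = 0, seed = 1L, ...) {
  generate_phantom(phantom_spec(noise_sigma = noise_sigma, seed = seed, ...))
}
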