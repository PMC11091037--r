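# Independent brute-force oracles, written as literal transcriptions of the
# defining formulas (plain loops, no reuse of package internals).

oracle_feature_vector <- function(w, n_bins = 10, k_max = 8) {
  N <- length(w)
  mu <- sum(w) / N
  v0 <- sum((w - mu)^2) / (N - 1)

  # wavelet entropy over normalized squared coefficients
  p <- w^2 / sum(w^2)
  we <- 0
  for (pe in p) if (pe > 0) we <- we - pe * log2(pe)

  # zero crossings: strict sign alternation, zeros skipped
  s <- c()
  for (x in w) if (x > 0) s <- c(s, 1) else if (x < 0) s <- c(s, -1)
  zc <- 0
  if (length(s) >= 2)
    for (i in 1:(length(s) - 1)) if (s[i] != s[i + 1]) zc <- zc + 1

  # Hjorth via first differences
  d1 <- numeric(N - 1)
  for (i in 1:(N - 1)) d1[i] <- w[i + 1] - w[i]
  m1 <- sum(d1) / length(d1)
  v1 <- sum((d1 - m1)^2) / (length(d1) - 1)
  d2 <- numeric(length(d1) - 1)
  for (i in 1:(length(d1) - 1)) d2[i] <- d1[i + 1] - d1[i]
  m2 <- sum(d2) / length(d2)
  v2 <- sum((d2 - m2)^2) / (length(d2) - 1)
  mob <- sqrt(v1 / v0)
  comp <- sqrt(v2 / v1) / mob

  # Shannon entropy from an equal-width histogram over [min, max]
  lo <- min(w); hi <- max(w)
  if (hi == lo) {
    se <- 0
  } else {
    counts <- integer(n_bins)
    width <- (hi - lo) / n_bins
    for (x in w) {
      b <- floor((x - lo) / width) + 1
      if (b > n_bins) b <- n_bins
      if (b < 1) b <- 1
      counts[b] <- counts[b] + 1
    }
    se <- 0
    for (c in counts) if (c > 0) {
      q <- c / N
      se <- se - q * log2(q)
    }
  }

  # Higuchi mean curve length and log-log slope
  lk <- numeric(k_max)
  for (k in 1:k_max) {
    lms <- numeric(k)
    for (m in 1:k) {
      jmax <- floor((N - m) / k)
      tot <- 0
      for (j in 1:jmax)
        tot <- tot + abs(w[m + j * k] - w[m + (j - 1) * k])
      lms[m] <- tot * (N - 1) / (jmax * k) / k
    }
    lk[k] <- sum(lms) / k
  }
  xs <- log(1 / (1:k_max)); ys <- log(lk)
  fd <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)

  c(mean = mu,
    wavelet_entropy = we,
    mean_abs = abs(mu),
    std = sqrt(v0),
    hjorth_activity = v0,
    hjorth_mobility = mob,
    hjorth_complexity = comp,
    zero_crossing = zc,
    higuchi_fd = fd,
    band_power = sum(w^2) / N,
    shannon_entropy = se,
    differential_entropy = 0.5 * log(2 * pi * v0),
    amplitude_max = max(w))
}

# sliding-window count by explicit enumeration of start offsets
oracle_window_count <- function(n_samples, wl_n, step_n) {
  cnt <- 0
  start <- 0
  while (start + wl_n <= n_samples) {
    cnt <- cnt + 1
    start <- start + step_n
  }
  cnt
}

# direct double-sum Morlet CWT (correlation form)
oracle_cwt <- function(x, scales) {
  psi <- function(t) ifelse(abs(t) <= 8, cos(5 * t) * exp(-t^2 / 2), 0)
  n <- length(x)
  out <- matrix(0, nrow = length(scales), ncol = n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    for (tau in 1:n)
      for (m in 1:n)
        out[si, tau] <- out[si, tau] +
          x[m] * psi(((m - 1) - (tau - 1)) / s) / sqrt(s)
  }
  out
}

# small helper: a fast synthetic set for pipeline tests
small_synth_set <- function(n_per_class = 6, seed = 7, ...) {
  generate_dataset(synth_config(n_trials_per_class = n_per_class,
                                seed = seed, ...))
}

fast_era_config <- function(...) {
  era_config(subbands = "high_alpha", n_groups = 4,
             window = window_spec(3, 2), seed = 5, ...)
}
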