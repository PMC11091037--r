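test_that("basic statistics match hand-computed values", {
  b <- basic_stats(c(1, 2, 3, 4))
  expect_equal(b$mean, 2.5)
  expect_equal(b$std, sd(c(1, 2, 3, 4)))
  expect_equal(b$band_power, 7.5)
  expect_equal(b$amplitude_max, 4)
  expect_equal(basic_stats(c(1, -1, 1, -1))$zero_crossings, 3L)
  # zeros neither terminate nor start a crossing
  expect_equal(basic_stats(c(1, 0, -1, 0, 1))$zero_crossings, 2L)
  s <- basic_stats(c(-3, -1, -2))
  expect_equal(s$mean, -2)
  expect_equal(s$mean_abs, 2)       # |mean|, absolute value outside the sum
  expect_equal(s$amplitude_max, -1) # plain max, not max |w|
  v <- basic_stats(c(-3, -1, -2),
                   feature_options(mean_abs_variant = "mean_of_abs",
                                   amplitude_abs = TRUE))
  expect_equal(v$mean_abs, 2)
  expect_equal(v$amplitude_max, 3)
  expect_error(basic_stats(1), "too short")
})

test_that("Hjorth parameters follow their closed forms", {
  expect_error(hjorth(rep(2, 50)), "degenerate")
  set.seed(21)
  w <- rnorm(1e4)
  h <- hjorth(w)
  expect_lt(abs(h$activity - 1), 0.05)
  # first-difference mobility of a sampled sine: 2 sin(pi f / fs)
  fs <- 128
  for (f in c(5, 10, 20)) {
    n <- 0:(fs * 8 - 1)
    hs <- hjorth(sin(2 * pi * f * n / fs))
    expect_lt(abs(hs$mobility - 2 * sin(pi * f / fs)) /
                (2 * sin(pi * f / fs)), 0.01)
  }
})

test_that("entropies match their closed forms", {
  e <- entropies(c(1, 1, 1, 1))
  expect_equal(e$wavelet_entropy, 2)   # uniform energy over 4 samples
  expect_equal(e$shannon_entropy, 0)   # point mass in one bin
  # sigma^2 = 1/(2*pi) makes the printed differential entropy exactly 0
  w <- c(-1, 1) * sqrt(1 / (2 * pi) / 2)
  expect_equal(entropies(w)$differential_entropy, 0)
  # the Gaussian variant adds 1/2
  expect_equal(entropies(w, feature_options(de_standard = TRUE))$differential_entropy,
               0.5)
  expect_error(entropies(c(0, 0, 0)), "all-zero")
})

test_that("Higuchi dimension is ~1 on a ramp and ~2 on white noise", {
  expect_lt(abs(higuchi_fd(1:1000, 8) - 1), 0.05)
  set.seed(22)
  expect_lt(abs(higuchi_fd(rnorm(1000), 8) - 2), 0.15)
  expect_error(higuchi_fd(1:100, 1), "k_max")
  expect_error(higuchi_fd(1:10, 8), "too short")
})

test_that("all 13 features match the brute-force oracle on random windows", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(40:400, 1)
    w <- rnorm(n, sd = 10^runif(1, -2, 2)) + runif(1, -5, 5)
    got <- feature_vector(w)
    want <- oracle_feature_vector(w)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1)), 1e-9,
              label = paste("rep", rep))
  }
})

test_that("features transform as expected under amplitude scaling", {
  set.seed(24)
  w <- rnorm(400)
  a <- 3.7
  f1 <- feature_vector(w)
  f2 <- feature_vector(a * w)
  lin <- c("mean", "mean_abs", "std", "amplitude_max")
  inv <- c("hjorth_mobility", "hjorth_complexity", "zero_crossing",
           "higuchi_fd", "wavelet_entropy", "shannon_entropy")
  quad <- c("band_power", "hjorth_activity")
  expect_equal(f2[lin], a * f1[lin], tolerance = 1e-9)
  expect_equal(f2[inv], f1[inv], tolerance = 1e-9)
  expect_equal(f2[quad], a^2 * f1[quad], tolerance = 1e-9)
  expect_equal(unname(f2["differential_entropy"] - f1["differential_entropy"]),
               log(a), tolerance = 1e-9)
})

test_that("feature rows assemble channel-major with 13 x scales x channels", {
  set.seed(25)
  mk <- function(scales) {
    out <- lapply(scales, function(s) rnorm(64))
    names(out) <- scales
    out
  }
  meta <- data.frame(subject_id = "S01", trial_id = "T01", window_index = 1,
                     period_group = 1, sub_band = "high_alpha",
                     class_label = "LAHV")
  r3x2 <- assemble_feature_row(list(O1 = mk(8:10), O2 = mk(8:10)), meta)
  expect_equal(ncol(r3x2$values), 78)
  r6x2 <- assemble_feature_row(list(O1 = mk(8:13), O2 = mk(8:13)), meta)
  expect_equal(ncol(r6x2$values), 156)
  w <- mk(8)
  r1x1 <- assemble_feature_row(list(O1 = w), meta)
  expect_equal(ncol(r1x1$values), 13)
  expect_equal(unname(r1x1$values[1, ]), unname(feature_vector(w[["8"]])))
  expect_equal(r1x1$column_meta$feature_id, 1:13)
  # ragged windows are rejected
  bad <- list(O1 = mk(8:10), O2 = list(`8` = rnorm(64), `9` = rnorm(32),
                                       `10` = rnorm(64)))
  expect_error(assemble_feature_row(bad, meta), "ragged")
})

test_that("extract_features produces the documented table shape", {
  rs <- small_synth_set(3, seed = 31)
  grp <- period_boundaries(4, 128, 3, 63)
  labels <- quadrant_label(rs$ratings$valence, rs$ratings$arousal)
  tab <- extract_features(rs, "high_alpha", grp, 4, window_spec(3, 2),
                          class_labels = labels)
  expect_equal(ncol(tab$values), 78)
  n_win <- window_count(1920, window_spec(3, 2), 128)
  expect_equal(nrow(tab$values), length(rs) * n_win)
  expect_setequal(unique(tab$row_meta$class_label), c("LAHV", "LALV"))
  expect_true(all(tab$row_meta$period_group == 4))
  # matrix fast path agrees with the per-row assembler
  rec <- bandpass_filter(rs$recordings[[1]])
  rec <- select_channels(rec, c("O1", "O2"))
  cw <- lapply(1:2, function(i) cwt_morlet(rec$samples[i, ], 8:13, 128))
  names(cw) <- c("O1", "O2")
  sl <- lapply(cw, function(x) slice_period(slice_subband(x, "high_alpha"),
                                            grp, 4))
  w1 <- lapply(sl, function(x) {
    out <- lapply(1:3, function(i) x$coeffs[i, 1:384])
    names(out) <- 8:10
    out
  })
  row1 <- assemble_feature_row(w1, tab$row_meta[1, ])
  expect_equal(unname(row1$values[1, ]), unname(tab$values[1, ]),
               tolerance = 1e-12)
})
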