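test_that("recording enforces shape, finiteness and baseline alignment", {
  m <- matrix(rnorm(2 * 128), nrow = 2)
  r <- recording(m, fs = 128, channel_names = c("O1", "O2"), baseline_s = 0.5)
  expect_identical(r$channel_names, c("O1", "O2"))
  expect_error(recording(m, 128, "O1"), "channel_names")
  expect_error(recording(cbind(m[, -1], NA), 128, c("O1", "O2")), "finite")
  expect_error(recording(m, 128, c("O1", "O2"), baseline_s = 0.013),
               "integer number of samples")
})

test_that("recording_set validates parallel ratings and shared layout", {
  r1 <- recording(matrix(rnorm(256), 2), 128, c("O1", "O2"))
  r2 <- recording(matrix(rnorm(256), 2), 128, c("O1", "O2"))
  rs <- recording_set(list(r1, r2), data.frame(valence = c(7, 3),
                                               arousal = c(3, 3)))
  expect_length(rs, 2)
  expect_error(recording_set(list(r1), data.frame(valence = c(7, 3),
                                                  arousal = c(3, 3))),
               "same length")
  expect_error(recording_set(list(r1), data.frame(valence = 11, arousal = 3)),
               "\\[1, 9\\]")
  r3 <- recording(matrix(rnorm(256), 2), 128, c("C3", "C4"))
  expect_error(recording_set(list(r1, r3),
                             data.frame(valence = c(7, 3), arousal = c(3, 3))),
               "channel names")
})

test_that("container round-trips a DEAP-shaped recording set losslessly", {
  set.seed(42)
  n_tr <- 4; n_ch <- 32; n_sm <- 8064
  recs <- lapply(seq_len(n_tr), function(i)
    recording(matrix(rnorm(n_ch * n_sm), n_ch), fs = 128,
              channel_names = deap_channels(), baseline_s = 3,
              subject_id = "S01", trial_id = sprintf("T%02d", i)))
  rs <- recording_set(recs, data.frame(valence = c(7, 3, 8, 2),
                                       arousal = c(3, 3, 2, 4)))
  path <- tempfile(fileext = ".rds")
  write_recording_set(rs, path)
  rs2 <- load_recording_set(path)
  expect_length(rs2, n_tr)
  for (i in seq_len(n_tr)) {
    expect_identical(rs2$recordings[[i]]$samples, rs$recordings[[i]]$samples)
    expect_equal(ncol(rs2$recordings[[i]]$samples) /
                   rs2$recordings[[i]]$fs, 63)
  }
  expect_equal(rs2$ratings, rs$ratings)
  unlink(path)
})

test_that("empty containers and malformed containers are handled", {
  path <- tempfile(fileext = ".rds")
  write_recording_set(recording_set(list(),
                                    data.frame(valence = numeric(0),
                                               arousal = numeric(0))), path)
  rs <- load_recording_set(path)
  expect_length(rs, 0)
  saveRDS(list(data = array(0, c(2, 2, 4))), path)
  expect_error(load_recording_set(path), "'data' and 'labels'")
  saveRDS(list(data = array(0, c(2, 2, 4)), labels = matrix(5, 3, 4)), path)
  expect_error(load_recording_set(path), "do not match trials")
  unlink(path)
})

test_that("feature-table CSV round-trips within 1e-9 and flags bad headers", {
  set.seed(1)
  n_row <- 10
  cm <- expand.grid(feature_id = 1:13, scale = 8:10,
                    channel = c("O1", "O2"), stringsAsFactors = FALSE)
  cm <- cm[order(match(cm$channel, c("O1", "O2")), cm$scale, cm$feature_id), ]
  tab <- feature_table(matrix(rnorm(n_row * 78) * 10^runif(n_row * 78, -3, 3),
                              n_row),
                       cm,
                       data.frame(subject_id = "S01",
                                  trial_id = sprintf("T%02d", seq_len(n_row)),
                                  window_index = seq_len(n_row),
                                  period_group = 4, sub_band = "high_alpha",
                                  class_label = "LAHV"))
  expect_equal(ncol(tab$values), 13 * 3 * 2)
  path <- tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  tab2 <- read_feature_table(path)
  expect_equal(dim(tab2$values), dim(tab$values))
  expect_lt(max(abs(tab2$values - tab$values) /
                  pmax(abs(tab$values), 1e-300)), 1e-9)
  expect_equal(tab2$column_meta$feature_id, tab$column_meta$feature_id)
  expect_equal(tab2$column_meta$scale, tab$column_meta$scale)
  expect_equal(tab2$row_meta$window_index, tab$row_meta$window_index)

  # corrupt one header: drop the feature id
  lines <- readLines(path)
  lines[1] <- sub("O1.s8.F1\"", "O1.s8\"", lines[1])
  writeLines(lines, path)
  expect_error(read_feature_table(path), "malformed feature column")
  unlink(path)
})

test_that("feature_table rejects missing values and meta mismatches", {
  cm <- data.frame(feature_id = 1:13, scale = 8, channel = "O1")
  expect_error(feature_table(matrix(c(1:12, NA), 1), cm,
                             data.frame(subject_id = "S01")),
               "missing or non-finite")
  expect_error(feature_table(matrix(1:13, 1), cm[1:5, ],
                             data.frame(subject_id = "S01")),
               "column_meta")
})
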