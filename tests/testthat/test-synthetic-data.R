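test_that("planted feature tables have the declared shape and ground truth", {
  tab <- sim_feature_table(planted_spec(100, 4, 10, 5, 85, effect_size = 1.5, seed = 1))
  expect_equal(nrow(tab$data), 100)
  expect_equal(ncol(tab$data), 101)        # 100 features + label
  expect_length(tab$informative, 10)
  expect_length(tab$redundant, 5)
  expect_length(tab$noise, 85)
  # labels balanced within one sample
  counts <- table(tab$data$label)
  expect_lte(max(counts) - min(counts), 1)
})

test_that("degenerate planted specs are rejected", {
  expect_error(planted_spec(100, 4, 10, effect_size = 0), "effect_size")
  expect_error(planted_spec(100, 1, 10), "n_classes")
  expect_error(planted_spec(6, 4, 10), "at least 2 samples")
  expect_error(planted_spec(100, 4, 10, redundancy_corr = 0), "redundancy_corr")
})

test_that("generation is deterministic in the spec seed", {
  a <- sim_feature_table(planted_spec(60, 3, 4, 2, 6, effect_size = 1, seed = 7))
  b <- sim_feature_table(planted_spec(60, 3, 4, 2, 6, effect_size = 1, seed = 7))
  c <- sim_feature_table(planted_spec(60, 3, 4, 2, 6, effect_size = 1, seed = 8))
  expect_identical(a, b)
  expect_false(identical(a$data, c$data))
})

test_that("redundant columns correlate with their informative source as specified", {
  tab <- sim_feature_table(planted_spec(200, 3, 5, 5, 0, effect_size = 1,
                                        redundancy_corr = 0.9, seed = 2))
  for (j in seq_along(tab$redundant)) {
    r <- cor(tab$data[[tab$redundant[j]]], tab$data[[tab$source[j]]])
    expect_gte(r, 0.9 - 1e-10)
  }
})

test_that("informative columns beat noise columns for a held-out classifier", {
  # direct oracle: run the classifier on each column set over 10 seeds
  wins <- 0L
  for (s in 1:10) {
    tab <- sim_feature_table(planted_spec(120, 4, 10, 0, 10, effect_size = 1.5, seed = s))
    y <- tab$data$label
    tr <- local({ set.seed(s); unlist(lapply(split(seq_along(y), y),
                                             function(ix) sample(ix, round(0.7 * length(ix))))) })
    acc_on <- function(cols) {
      x <- as.matrix(tab$data[, cols, drop = FALSE])
      pred <- class::knn(x[tr, ], x[-tr, ], y[tr], k = 1)
      mean(pred == y[-tr])
    }
    if (acc_on(tab$informative) > acc_on(tab$noise)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("synthetic recordings match their closed-form construction", {
  rec <- demo_recording(seed = 3, fs = 50, duration = 10)
  expect_equal(nrow(rec$data), 2 * 500)    # two classes x fs * duration
  still <- rec$data[rec$labels == "still", ]
  # stationary class: accelerometer mean ~ gravity * orientation, var ~ noise_sd^2
  expect_equal(mean(still$az), 9.80665, tolerance = 0.01)
  expect_equal(mean(still$ax), 0, tolerance = 0.05)
  expect_equal(var(still$az), 0.1^2, tolerance = 0.3)
  # dynamic class: dominant DFT frequency of a gyro channel inside the band
  walk <- rec$data[rec$labels == "walk", ]
  spec <- Mod(fft(walk$gz - mean(walk$gz)))
  ks <- seq_len(floor(nrow(walk) / 2))
  fdom <- ks[which.max(spec[ks + 1])] * 50 / nrow(walk)
  expect_gte(fdom, 1.5)
  expect_lte(fdom, 2.5)
})

test_that("recording specs reject bands at or above Nyquist and non-unit orientations", {
  cls <- data.frame(label = "a", f_lo = 1, f_hi = 30, amplitude = 1,
                    ox = 0, oy = 0, oz = 1, noise_sd = 0.1)
  expect_error(recording_spec(50, 5, cls), "Nyquist")
  cls$f_hi <- 5; cls$oz <- 2
  expect_error(recording_spec(50, 5, cls), "unit norm")
})
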