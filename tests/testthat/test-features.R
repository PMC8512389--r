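test_that("time-domain features match hand-computed oracles", {
  v <- time_features(c(1, -1, 1, -1))
  expect_equal(v[["mean"]], 0)
  expect_equal(v[["rms"]], 1)
  # three sign changes, each |delta sgn| = 2: 6 / (2 * 4)
  expect_equal(v[["zcr"]], 0.75)

  w <- time_features(c(1, 2, 3, 4))
  expect_equal(w[["median"]], 2.5)
  # (n+1)-term interpolation rule: q1 at the 1.25th term, q3 at the 3.75th
  expect_equal(w[["iqr"]], (3 + 0.75 * 1) - (1 + 0.25 * 1))
  expect_equal(w[["iqr"]],
               diff(unname(quantile(c(1, 2, 3, 4), c(0.25, 0.75), type = 6))))
  expect_equal(w[["sra"]], mean(sqrt(1:4))^2)
})

test_that("constant windows hit every degenerate-case convention", {
  v <- time_features(rep(3, 8))
  expect_equal(v[["mean"]], 3)
  expect_equal(v[["variance"]], 0)
  expect_equal(v[["zcr"]], 0)
  expect_equal(v[["p2p"]], 0)
  expect_equal(v[["skewness"]], 0)
  expect_equal(v[["kurtosis"]], 0)
  z <- time_features(rep(0, 8))
  expect_true(all(is.finite(z)))
  expect_equal(unname(z[c("impulse_factor", "margin_factor",
                          "shape_factor", "crest_factor")]), rep(0, 4))
})

test_that("frequency features satisfy Parseval and locate sinusoid frequencies", {
  fs <- 32
  n <- 64
  # all-zero window: everything zero
  z <- freq_features(rep(0, n), fs)
  expect_true(all(z == 0))
  # on-bin sinusoid: frequency center within one bin, entropy <= 1 bit
  f0 <- 4 * fs / n
  x <- sin(2 * pi * f0 * (0:(n - 1)) / fs)
  v <- freq_features(x, fs)
  expect_lte(abs(v[["freq_center"]] - f0), fs / n)
  expect_lte(v[["entropy"]], 1)
  expect_equal(v[["top1_freq"]], f0)
  # Parseval: sum x^2 = (1/N) sum |X_k|^2 (brute-force DFT sum)
  set.seed(1)
  for (i in 1:5) {
    y <- rnorm(n)
    k <- 0:(n - 1)
    X <- vapply(k, function(kk) sum(y * exp(-2i * pi * kk * k / n)), complex(1))
    expect_equal(freq_features(y, fs)[["energy"]], sum(Mod(X)^2) / n,
                 tolerance = 1e-8)
  }
})

test_that("pair features recover exact correlation cases", {
  a <- c(1, 2, 3, 5)
  expect_equal(unname(pair_features(a, a)), c(1, 0))
  expect_equal(pair_features(a, -a)[["correlation"]], -1)
  # hand evaluation of the product-moment formula
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  num <- 3 * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((3 * sum(x^2) - sum(x)^2) * (3 * sum(y^2) - sum(y)^2))
  expect_equal(pair_features(x, y)[["correlation"]], num / den)
  expect_equal(pair_features(rep(1, 4), rnorm(4))[["correlation"]], 0)
})

test_that("features scale as their definitions require", {
  set.seed(42)
  x <- rnorm(64)
  base <- time_features(x)
  scaled <- time_features(5 * x)
  for (f in c("mean", "sd", "rms", "abs_mean", "p2p", "iqr"))
    expect_equal(scaled[[f]], 5 * base[[f]], tolerance = 1e-12)
  for (f in c("skewness", "kurtosis", "shape_factor", "crest_factor", "zcr"))
    expect_equal(scaled[[f]], base[[f]], tolerance = 1e-12)
  y <- rnorm(64)
  expect_equal(pair_features(5 * x, 2 * y)[["correlation"]],
               pair_features(x, y)[["correlation"]], tolerance = 1e-12)
})

test_that("the default catalogue yields 26 columns per channel on 12-channel data", {
  # 12-channel recording: four synthetic tri-axial sensors
  set.seed(9)
  n <- 256
  dat <- as.data.frame(matrix(rnorm(n * 12), n, 12))
  names(dat) <- as.vector(outer(c("x", "y", "z"), c("acc", "lin", "gyr", "mag"),
                                function(a, s) paste0(s, a)))
  rec <- new_recording(cbind(t = (0:(n - 1)) / 50, dat), fs = 50)
  tab <- extract_features(rec, window_spec(2.56, 0.5, fs = 50))
  single_cols <- grep("^(correlation|cosine_distance)__", names(tab),
                      invert = TRUE, value = TRUE)
  expect_equal(length(single_cols), 26 * 12)
  # pair features within each 3-axis group: 2 features x 4 sensors x 3 pairs
  expect_equal(ncol(tab) - length(single_cols), 2 * 4 * 3)
})

test_that("feature matrix layout is deterministic and label-aware", {
  rec <- demo_recording(seed = 2, fs = 50, duration = 6)
  ws <- window_spec(2.56, 0.5, fs = 50)
  tab1 <- extract_features(rec, ws)
  tab2 <- extract_features(rec, ws)
  expect_identical(tab1, tab2)
  expect_equal(names(tab1)[ncol(tab1)], "label")
  expect_s3_class(tab1$label, "factor")
  # catalogue order governs column order, not channel insertion order
  rec_shuf <- rec
  perm <- c("gz", "ax", "gy", "az", "gx", "ay")
  rec_shuf$data <- rec$data[, c("t", perm)]
  tab3 <- extract_features(rec_shuf, ws)
  expect_setequal(names(tab3), names(tab1))
  first_feat <- default_single_features()[1]
  expect_equal(grep(paste0("^", first_feat, "__"), names(tab3)),
               seq_along(perm))  # first catalogue feature still leads
  # empty segmentation: zero rows, full header
  tiny <- new_recording(rec$data[1:10, ], fs = 50)
  tab0 <- extract_features(tiny, ws)
  expect_equal(nrow(tab0), 0)
  expect_setequal(names(tab0), setdiff(names(tab1), "label"))
})

test_that("feature tables round-trip through CSV and ARFF", {
  rec <- demo_recording(seed = 5, fs = 50, duration = 6)
  tab <- extract_features(rec, window_spec(2.56, 0.5, fs = 50))
  csv <- tempfile(fileext = ".csv")
  arff <- tempfile(fileext = ".arff")
  write_table(tab, csv)
  write_table(tab, arff)
  back_csv <- read_table(csv)
  back_arff <- read_table(arff)
  expect_equal(as.character(back_csv$label), as.character(tab$label))
  num <- setdiff(names(tab), "label")
  expect_equal(as.matrix(back_csv[num]), as.matrix(tab[num]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(as.matrix(back_arff[num]), as.matrix(tab[num]), tolerance = 1e-6,
               ignore_attr = TRUE)
})
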