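test_that("subsampling keeps every k-th sample from the first", {
  x <- seq_len(100)
  y <- subsample(x, 10)
  expect_equal(length(y), 20)
  expect_equal(y, x[seq(1, 100, by = 5)])
  expect_equal(subsample(x, 50), x)
  expect_equal(length(subsample(seq_len(101), 10)), 21)
  m <- matrix(seq_len(20), nrow = 2)
  expect_equal(dim(subsample(m, 10)), c(2, 2))
  expect_error(subsample(x, 7), "divisor")
})

test_that("segmentation yields floor((span-window)/step)+1 fully-contained windows", {
  sig <- matrix(rnorm(2 * 600), nrow = 2,
                dimnames = list(c("LF_x", "RF_x"), NULL))
  ann <- data.frame(start_s = c(0, 10.5), end_s = c(10, 11.5),
                    label = c("working_trot", "halt"),
                    side = "none", velocity = c(3.8, 0),
                    stride_duration = c(0.8, NA))
  rec <- equigait:::new_recording(sig, 50, subject_profile("s", 1.7), ann)
  expect_length(segment(rec, 2, 2), 5)      # 10 s span only; 1 s span dropped
  expect_length(segment(rec, 2, 0.5), 17)
  w <- segment(rec, 2, 2)[[1]]
  expect_equal(w$label, "working_trot")
  expect_equal(w$truth_velocity, 3.8)
  expect_equal(ncol(w$signal), 100)
  rec$annotations <- ann[2, ]               # only the 1 s span remains
  expect_warning(out <- segment(rec, 2, 2), "long enough")
  expect_length(out, 0)
  expect_error(segment(rec, -1, 1), "must be > 0")
})

test_that("window indices reconstruct exactly from the window number", {
  sig <- matrix(seq_len(500), nrow = 1, dimnames = list("LF_x", NULL))
  ann <- data.frame(start_s = 0, end_s = 10, label = "halt", side = "none",
                    velocity = 0, stride_duration = NA)
  rec <- equigait:::new_recording(sig, 50, subject_profile("s", 1.7), ann)
  ws <- segment(rec, 1, 0.4)
  for (j in seq_along(ws)) {
    i0 <- round((j - 1) * 0.4 * 50) + 1
    expect_equal(unname(ws[[j]]$signal[1, ]), as.numeric(sig[1, i0:(i0 + 49)]))
  }
})

test_that("handcrafted features match their definitions", {
  rate <- 50
  tt <- (0:99) / rate
  const <- matrix(5, nrow = 1, ncol = 100)
  f <- extract_features(const, sampling_rate = rate)
  expect_equal(unname(f), c(5, 0, 0, 2))  # mean, var, p2p, mci = duration
  # sine of amplitude A: peak-to-peak 2A, mean-crossing interval P/2
  # (phase offset so no sample sits exactly on the mean)
  A <- 3; P <- 0.5
  sine <- matrix(A * sin(2 * pi * tt / P + 0.3), nrow = 1)
  f2 <- extract_features(sine, sampling_rate = rate)
  expect_equal(unname(f2[3]), 2 * A, tolerance = 0.01)
  # brute-force crossing count over k full cycles
  xc <- sine[1, ] - mean(sine[1, ])
  s <- sign(xc); s <- s[s != 0]
  crossings <- sum(diff(s) != 0)
  expect_equal(unname(f2[4]), 2 / crossings)      # duration / crossings
  expect_equal(unname(f2[4]), P / 2, tolerance = 0.05)
  expect_error(extract_features(matrix(1, 1, 1), sampling_rate = rate),
               "at least 2 samples")
})

test_that("autocorrelation equals the O(n^2) oracle and is 1 at lag zero", {
  set.seed(21)
  x <- rnorm(200) + sin((1:200) / 5)
  r <- autocorrelation(x, sampling_rate = 50)
  expect_equal(r$acf[1], 1)
  expect_equal(max(r$acf), 1)
  expect_equal(r$acf, acf_oracle(x), tolerance = 1e-9)
  expect_equal(r$lags[2], 1 / 50)
  # white noise has no substantial off-zero peak
  set.seed(22)
  wn <- autocorrelation(rnorm(1000), sampling_rate = 50)
  expect_lt(max(wn$acf[-1]), 0.2)
  expect_error(autocorrelation(rep(1, 50), 50), "zero-variance")
})

test_that("stride duration is the highest in-band autocorrelation peak", {
  rate <- 50
  tt <- (0:299) / rate
  sine <- sin(2 * pi * 1.25 * tt)     # 1.25 Hz -> 0.8 s period
  dt <- estimate_stride_duration(sine, sampling_rate = rate)
  expect_equal(as.numeric(dt), 0.8)
  expect_equal(attr(dt, "step_frequency"), 1.25)
  expect_error(estimate_stride_duration(rnorm(100) * 0 + (1:100) * 1e-12,
                                        sampling_rate = rate),
               class = "eg_aperiodic")
})

test_that("stride length follows L = v * dT", {
  expect_equal(round(stride_length(1.30, 1.12), 2), 1.46)  # pony working walk
  expect_equal(round(stride_length(1.88, 1.19), 2), 2.24)  # horse extended walk
  expect_equal(round(stride_length(3.41, 0.64), 2), 2.18)  # horse collected canter
  expect_equal(stride_length(0, 1), 0)
  expect_error(stride_length(1, 0), "> 0")
  m <- stride_metrics(3.8, 0.8)
  expect_equal(m$step_frequency, 1.25)
  expect_equal(m$stride_length, 3.04)
})
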