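test_that("group velocity profiles follow the height and speed rules", {
  expect_equal(assign_group(1.32), "pony")
  expect_equal(assign_group(1.48), "pony")                 # boundary inclusive
  expect_equal(assign_group(1.71, 1.65), "fast_horse")
  expect_equal(assign_group(1.71, 1.59), "slow_horse")
  expect_equal(assign_group(1.60, 1.6), "fast_horse")      # >= 1.6 is fast
  expect_error(assign_group(1.71), "min_collected_walk_speed")
  expect_error(assign_group(0), "> 0")
})

test_that("two tight classes give a near-midpoint boundary", {
  set.seed(41)
  n <- 40
  # identical residuals in both classes -> equal covariances, so the QDA
  # boundary reduces to the linear-discriminant midpoint near v = 4.35
  hdev <- rnorm(n, 0, 1e-3); vdev <- rnorm(n, 0, 0.01)
  s <- data.frame(h = 1.7 + rep(hdev, 2),
                  v = c(3.4 + vdev, 5.3 + vdev),
                  pace = rep(c("collected", "extended"), each = n))
  m <- fit_pace_qda(s, "canter")
  expect_equal(predict_pace(m, 1.7, 4.30)$pace, "collected")
  expect_equal(predict_pace(m, 1.7, 4.40)$pace, "extended")
  expect_error(fit_pace_qda(s[s$pace == "collected", ], "canter"),
               "at least two")
  expect_error(predict_pace(list(), 1.7, 4), "not a fitted")
})

test_that("posteriors match a brute-force Gaussian computation", {
  set.seed(42)
  s <- sample_pace_dataset("canter", 40)
  m <- fit_pace_qda(s, "canter")
  X <- cbind(h = runif(100, 1.3, 1.85), v = runif(100, 3, 5.5))
  pred <- predict_pace(m, X[, 1], X[, 2])
  oracle <- qda_posterior_oracle(m$models$all, X)
  expect_equal(unname(as.matrix(pred[, m$models$all$classes])),
               unname(oracle), tolerance = 1e-9)
})

test_that("posteriors agree with an independent QDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(43)
  s <- sample_pace_dataset("canter", 40)
  m <- fit_pace_qda(s, "canter")
  ref <- MASS::qda(pace ~ h + v, data = s,
                   prior = rep(1 / 3, 3))
  X <- data.frame(h = runif(50, 1.3, 1.85), v = runif(50, 3, 5.5))
  ours <- predict_pace(m, X$h, X$v)
  theirs <- predict(ref, X)
  expect_equal(as.character(ours$pace), as.character(theirs$class))
  expect_equal(unname(as.matrix(ours[, m$models$all$classes])),
               unname(theirs$posterior[, m$models$all$classes]),
               tolerance = 1e-6)
})

test_that("exact posterior ties resolve to the earliest pace", {
  # two classes mirrored about v = 4 (equal covariances, cov(h,v) = 0);
  # the midpoint is an exact posterior tie
  s <- data.frame(h = rep(c(1.69, 1.71, 1.70), 2),
                  v = c(3.9, 3.9, 3.8, 4.1, 4.1, 4.2),
                  pace = rep(c("collected", "working"), each = 3))
  m <- fit_pace_qda(s, "trot")
  p <- predict_pace(m, 1.70, 4.0)
  expect_equal(p$pace, "collected")
  expect_equal(p$collected, p$working, tolerance = 1e-9)
})

test_that("sample at a class mean is assigned to that class", {
  set.seed(44)
  s <- sample_pace_dataset("canter", 30)
  m <- fit_pace_qda(s, "canter")
  for (p in c("collected", "working", "extended")) {
    mu <- m$models$all$fits[[p]]$mean
    expect_equal(predict_pace(m, mu[1], mu[2])$pace, p)
  }
})

test_that("singular covariances are ridge-regularized with a warning", {
  s <- data.frame(h = rep(1.7, 8), v = c(rep(3.4, 4), rep(5.3, 4)),
                  pace = rep(c("collected", "extended"), each = 4))
  w <- capture_warnings(m <- fit_pace_qda(s, "canter"))
  expect_true(any(grepl("ridge", w)))  # one warning per singular class
  expect_equal(predict_pace(m, 1.7, 3.41)$pace, "collected")
})

test_that("pony walk paces need the group profile and classify cleanly", {
  set.seed(42)
  s <- sample_pace_dataset("walk", 20)
  n <- nrow(s)
  tr <- sample(n, round(0.66 * n)); te <- setdiff(seq_len(n), tr)
  m <- fit_pace_qda(s[tr, ], "walk")
  expect_error(predict_pace(m, s$h[te], s$v[te]), "group")
  pred <- predict_pace(m, s$h[te], s$v[te], group = s$group[te])
  acc <- tapply(pred$pace == s$pace[te], s$group[te], mean)
  expect_equal(unname(acc[["pony"]]), 1.0)
  expect_equal(unname(acc[["slow_horse"]]), 1.0)
  expect_gte(unname(acc[["fast_horse"]]), 0.85)
  # the study-style walk samples carry coherent group labels
  expect_setequal(unique(s$group), c("pony", "slow_horse", "fast_horse"))
})

test_that("trot paces classify at the level the published bands allow", {
  set.seed(45)
  s <- sample_pace_dataset("trot", 40)
  n <- nrow(s)
  tr <- sample(n, round(0.66 * n)); te <- setdiff(seq_len(n), tr)
  m <- fit_pace_qda(s[tr, ], "trot")
  pred <- predict_pace(m, s$h[te], s$v[te])$pace
  # the pony collected/working bands overlap, and pony extended speeds
  # overlap horse working speeds, capping the pooled trot accuracy below
  # the clean canter separation
  expect_gte(mean(pred == s$pace[te]), 0.85)
})

test_that("pace models serialize to readable text", {
  set.seed(46)
  s <- sample_pace_dataset("canter", 10)
  m <- fit_pace_qda(s, "canter")
  path <- tempfile(fileext = ".tsv")
  write_pace_model(m, path)
  txt <- readLines(path)
  expect_true(any(grepl("^gait\tcanter", txt)))
  expect_true(any(grepl("class\tcollected", txt)))
  unlink(path)
})
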