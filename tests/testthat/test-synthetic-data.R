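test_that("pace velocities are drawn uniformly within mean +/- 1 SD", {
  set.seed(1)
  v <- sample_pace_velocity("walk", "collected", "pony", n = 500)
  expect_true(all(v >= 1.18 & v <= 1.22))
  # Monte-Carlo mean of many draws recovers the population mean
  set.seed(2)
  v2 <- sample_pace_velocity("canter", "working", "horse", n = 10000)
  expect_equal(mean(v2), 4.03, tolerance = 0.01 / 4.03)
  # determinism under an identical RNG state
  set.seed(3); a <- sample_pace_velocity("trot", "extended", "pony")
  set.seed(3); b <- sample_pace_velocity("trot", "extended", "pony")
  expect_identical(a, b)
  expect_error(sample_pace_velocity("walk", "collected", "icelandic"),
               "no locomotion")
})

test_that("stride duration is coupled to the drawn velocity", {
  # a draw at the row mean velocity has the row mean stride duration
  expect_equal(stride_duration_for("trot", "working", "horse", 3.80), 0.80)
  # faster draws have shorter strides
  expect_lt(stride_duration_for("walk", "working", "horse", 1.85),
            stride_duration_for("walk", "working", "horse", 1.65))
})

test_that("halt windows are noise only and arguments are validated", {
  set.seed(1)
  w <- synthesize_window("halt", noise_sd = 0.3, duration_s = 20)
  expect_true(all(apply(w$signal, 1, var) <= 1.1 * 0.3^2))
  expect_equal(mean(apply(w$signal, 1, var)), 0.3^2, tolerance = 0.05)
  expect_equal(w$truth_velocity, 0)
  expect_error(synthesize_window("halt", duration_s = -1), "duration")
  expect_error(synthesize_window("halt", noise_sd = -0.1), "noise_sd")
  expect_error(synthesize_window("levade"), "unknown activity")
})

test_that("generated windows carry the intended stride periodicity", {
  # working trot horse at the row mean velocity recovers the row duration
  set.seed(5)
  w <- synthesize_window("working_trot", velocity = 3.80,
                         horse_type = "horse", duration_s = 2)
  dt <- estimate_stride_duration(w$signal[1, ], sampling_rate = 50)
  expect_equal(as.numeric(dt), 0.80, tolerance = 1 / 50 / 0.80)
  # property: recovery within one sample period across the full table
  set.seed(6)
  tab <- locomotion_params()
  for (i in seq_len(nrow(tab))) {
    for (rep in 1:2) {
      v <- sample_pace_velocity(tab$gait[i], tab$pace[i], tab$horse_type[i])
      dur <- if (tab$gait[i] == "walk") 4 else 2
      w <- synthesize_window(paste0(tab$pace[i], "_", tab$gait[i]),
                             velocity = v, horse_type = tab$horse_type[i],
                             duration_s = dur)
      est <- estimate_stride_duration(w$signal[1, ], sampling_rate = 50)
      expect_lt(abs(as.numeric(est) - w$stride_duration), 1 / 50 + 1e-9)
    }
  }
})

test_that("impact amplitude increases with pace at fixed gait and type", {
  set.seed(7)
  peak <- function(pace, gait, ht) {
    v <- locomotion_row(gait, pace, ht)$mean_velocity
    w <- synthesize_window(paste0(pace, "_", gait), velocity = v,
                           horse_type = ht, noise_sd = 0)
    max(w$signal[1, ])
  }
  for (gait in c("walk", "trot", "canter")) {
    for (ht in c("pony", "horse")) {
      p <- vapply(c("collected", "working", "extended"), peak, numeric(1),
                  gait = gait, ht = ht)
      expect_true(all(diff(p) > 0))
    }
  }
})

test_that("sided movements mirror exactly under a left/right sensor swap", {
  swap_lr <- function(sig) sig[c(4:6, 1:3), ]
  for (case in c("working_canter", "shoulder_in_trot", "pirouette_walk")) {
    set.seed(11)
    wl <- synthesize_window(activity_spec(case, side = "left"),
                            noise_sd = 0)
    set.seed(11)
    wr <- synthesize_window(activity_spec(case, side = "right"),
                            noise_sd = 0)
    expect_equal(unname(swap_lr(wl$signal)), unname(wr$signal),
                 tolerance = 1e-12)
  }
})

test_that("piaffe stays on the spot relative to passage", {
  set.seed(12)
  v_pi <- mean(replicate(10, var(synthesize_window("piaffe")$signal[2, ])))
  v_pa <- mean(replicate(10, var(synthesize_window("passage")$signal[2, ])))
  expect_lt(v_pi, 0.3 * v_pa)
})

test_that("jump windows contain a single high-magnitude transient", {
  set.seed(13)
  wj <- synthesize_window(activity_spec("jump", side = "left",
                                        discipline = "jumping"),
                          velocity = 4.0, noise_sd = 0)
  wc <- synthesize_window(activity_spec("working_canter", side = "left"),
                          velocity = 4.0, noise_sd = 0)
  # the transient raises the peak well above the canter impact peaks
  expect_gt(max(wj$signal[1, ]) - max(wc$signal[1, ]), 5)
  # and it is a single event: only one 0.5 s neighborhood reaches the top
  top <- which(wj$signal[1, ] > max(wc$signal[1, ]) + 5)
  expect_lt(diff(range(top)), 0.5 * 50)
})

test_that("dataset generation honors the config and is seed-deterministic", {
  cfg <- generator_config("jumping", n_per_class = 3)
  ds <- generate_dataset(cfg, seed = 9)
  labs <- vapply(ds$windows, function(w) w$label, character(1))
  expect_setequal(labs, activity_catalog("jumping")$label)
  expect_true(all(table(labs) == 3))
  # zero-count classes are absent without error
  cfg0 <- generator_config("jumping",
                           activities = c(walk = 2, trot = 2, jump = 0))
  labs0 <- vapply(generate_dataset(cfg0, seed = 9)$windows,
                  function(w) w$label, character(1))
  expect_setequal(labs0, c("walk", "trot"))
  # unknown activities are rejected
  expect_error(generator_config("jumping", activities = c(piaffe = 5)),
               "not in the jumping inventory")
  # byte-identical reruns
  ds2 <- generate_dataset(cfg, seed = 9)
  expect_identical(ds$windows[[1]]$signal, ds2$windows[[1]]$signal)
  expect_identical(lapply(ds$recordings, `[[`, "annotations"),
                   lapply(ds2$recordings, `[[`, "annotations"))
  # ground-truth velocity is stored per window
  expect_true(all(vapply(ds$windows, function(w)
    is.finite(w$truth_velocity), logical(1))))
})
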