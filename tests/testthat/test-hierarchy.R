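test_that("the dressage hierarchy wires the phases and blocks as published", {
  h <- build_dressage_hierarchy()
  expect_equal(h$root, "phase1")
  expect_setequal(h$nodes$phase1$classes, c("halt", "walk", "trot", "canter"))
  expect_setequal(h$nodes$block1$classes, c("pirouette_walk", "other_walk"))
  expect_setequal(h$nodes$block8$classes,
                  c("flying_change", "pirouette_canter",
                    "lateral_canter_movements_and_paces"))
  expect_setequal(h$nodes$block9$classes,
                  c("canter_paces", "shoulder_in_canter",
                    "haunches_in_canter", "half_pass_canter"))
  # per-node window settings
  ws <- vapply(h$nodes, `[[`, numeric(1), "window_s")
  expect_equal(unname(ws[c("phase1", "walk_side", "trot_side", "canter_side",
                           "block1", "block2", "block3", "block4", "block5",
                           "block6", "block7", "block8", "block9")]),
               c(2, 4, 1, 2, 2.4, 1.2, 0.64, 0.8, 0.5, 2, 0.8, 2, 0.64))
  expect_equal(h$nodes$block6$step_s, 0.5)   # the sliding-window stage
  # every dressage label reaches a leaf and pace hooks exist per gait
  expect_setequal(names(h$nodes$phase1$assign),
                  activity_catalog("dressage")$label)
  expect_equal(h$nodes$block2$pace_classes, "walk_paces")
  expect_equal(h$nodes$block4$pace_classes, "trot_paces")
  expect_equal(h$nodes$block9$pace_classes, "canter_paces")
})

test_that("the jumping model is a single 6-class node at 2 s / 10 Hz", {
  h <- build_jumping_model()
  node <- h$nodes$jumping
  expect_length(node$classes, 6)
  expect_equal(node$window_s * node$sampling_rate, 20)  # samples per window
  expect_equal(node$sampling_rate, 10)
})

test_that("overall accuracy weights per-class accuracies by proportion", {
  expect_equal(overall_accuracy(c(a = 1, b = 0.5), c(a = 0.8, b = 0.2)), 0.9)
  expect_equal(overall_accuracy(c(a = 0.6, b = 0.8), c(a = 1, b = 1)), 0.7)
  expect_equal(overall_accuracy(c(a = 0.37), c(a = 5)), 0.37)
  expect_error(overall_accuracy(c(a = 1), c(b = 1)), "same classes")
})

test_that("side context is inherited from the last trot-pace span", {
  spans <- data.frame(
    label = c("trot_paces", "haunches_in_trot"),
    side_estimate = c("left", NA), stringsAsFactors = FALSE)
  expect_equal(inject_side(spans), c("unknown", "left"))
  spans2 <- data.frame(label = "haunches_in_trot", side_estimate = NA)
  expect_equal(inject_side(spans2), "unknown")
  spans3 <- data.frame(
    label = c("trot_paces", "walk_paces", "shoulder_in_trot"),
    side_estimate = c("right", NA, NA), stringsAsFactors = FALSE)
  expect_equal(inject_side(spans3), c("unknown", "unknown", "right"))
})

test_that("streams cascade through the hierarchy to the right leaves", {
  hier <- build_dressage_hierarchy()
  # halt gets as many windows as the trot family so the tiny phase-1 run
  # is class-balanced
  acts <- c(halt = 32, collected_trot = 16, working_trot = 16,
            passage = 16, piaffe = 16)
  cfg <- generator_config("dressage", activities = acts, span_s = 6,
                          window_s = 2)
  ds <- generate_dataset(cfg, seed = 51)
  models <- list()
  for (nd in c("phase1", "block4", "block5", "trot_side")) {
    models[[nd]] <- train_node(hier, nd, ds$recordings, seed = 51,
                               conv_filters = c(8, 16), dense = 16,
                               batch_size = 16, epochs = 60)
  }
  res <- do.call(rbind, lapply(ds$recordings, classify_stream,
                               hierarchy = hier, models = models))
  # halt stops at phase 1, piaffe descends trot -> variations -> piaffe,
  # trot paces stop at the pace superclass and carry a side estimate
  expect_equal(unique(res$label[res$truth == "halt"]), "halt")
  expect_gte(mean(res$label[res$truth == "piaffe"] == "piaffe"), 0.8)
  tp <- res$truth %in% c("collected_trot", "working_trot")
  expect_gte(mean(res$label[tp] == "trot_paces"), 0.9)
  expect_true(all(res$is_pace[res$label == "trot_paces"]))
  expect_true(all(res$side_estimate[tp & res$label == "trot_paces"]
                  %in% c("left", "right")))
  # a gait is always assigned before any pace label
  expect_true(all(!res$is_pace | !is.na(res$gait)))
  # a missing node model is an error naming the node
  expect_error(classify_stream(hier, ds$recordings[[1]],
                               models[c("phase1", "block4")]),
               "block5")
})
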