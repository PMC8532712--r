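# ---- multi-phase classification hierarchy ------------------------------

hierarchy_node <- function(name, classes, window_s, step_s = NULL,
                           sampling_rate = 50, children = character(0),
                           assign = character(0),
                           pace_classes = character(0),
                           label_source = c("label", "side")) {
  structure(list(name = name, classes = classes, window_s = window_s,
                 step_s = step_s, sampling_rate = sampling_rate,
                 children = children, assign = assign,
                 pace_classes = pace_classes,
                 label_source = match.arg(label_source)),
            class = "eg_node")
}

#' @export
print.eg_node <- function(x, ...) {
  cat(sprintf("<eg_node> %s [%g s%s @ %g Hz]: %s\n", x$name, x$window_s,
              if (!is.null(x$step_s)) sprintf(", sliding %g s", x$step_s) else "",
              x$sampling_rate, paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Build the multi-phase dressage classification hierarchy
#'
#' Phase 1 routes every window to halt/walk/trot/canter. Phase 2 holds the
#' per-gait side classifiers. Phase 3 refines each gait through its blocks:
#' walk into pirouette vs other walk (block 1), lateral walk movements vs
#' walk paces (block 2), the individual lateral walk movements (block 3);
#' trot into paces / variations / lateral movements (block 4), passage vs
#' piaffe (block 5), shoulder-in vs haunches-in vs side movements (block 6,
#' sliding window), leg yield vs half pass (block 7); canter into flying
#' change / pirouette / lateral movements and paces (block 8) and its
#' refinement (block 9). Pace superclasses are handed to phase 4 (the
#' velocity + QDA pace models). Per-node window sizes follow the optimal
#' settings of each stage.
#'
#' @return object of class `eg_hierarchy` (named node list + root).
#' @export
build_dressage_hierarchy <- function() {
  cat <- activity_catalog("dressage")
  lab <- cat$label
  gait_of <- stats::setNames(cat$gait, lab)
  category_of <- stats::setNames(cat$category, lab)

  walk <- lab[gait_of == "walk"]
  trot <- lab[gait_of == "trot"]
  canter <- lab[gait_of == "canter"]

  nodes <- list()
  nodes$phase1 <- hierarchy_node(
    "phase1", c("halt", "walk", "trot", "canter"), window_s = 2,
    children = c(walk = "block1", trot = "block4", canter = "block8"),
    assign = stats::setNames(gait_of, lab))

  nodes$walk_side <- hierarchy_node(
    "walk_side", c("left", "right"), window_s = 4,
    assign = stats::setNames(rep("walk", length(walk)), walk),
    label_source = "side")
  nodes$trot_side <- hierarchy_node(
    "trot_side", c("left", "right"), window_s = 1,
    assign = stats::setNames(rep("trot", length(trot)), trot),
    label_source = "side")
  nodes$canter_side <- hierarchy_node(
    "canter_side", c("left", "right"), window_s = 2,
    assign = stats::setNames(rep("canter", length(canter)), canter),
    label_source = "side")

  nodes$block1 <- hierarchy_node(
    "block1", c("pirouette_walk", "other_walk"), window_s = 2.4,
    children = c(other_walk = "block2"),
    assign = stats::setNames(
      ifelse(category_of[walk] == "pirouette", "pirouette_walk", "other_walk"),
      walk))
  ow <- walk[category_of[walk] != "pirouette"]
  nodes$block2 <- hierarchy_node(
    "block2", c("lateral_walk_movements", "walk_paces"), window_s = 1.2,
    children = c(lateral_walk_movements = "block3"),
    assign = stats::setNames(
      ifelse(category_of[ow] == "lateral", "lateral_walk_movements",
             "walk_paces"), ow),
    pace_classes = "walk_paces")
  lw <- ow[category_of[ow] == "lateral"]
  nodes$block3 <- hierarchy_node(
    "block3", sort(lw), window_s = 0.64,
    assign = stats::setNames(lw, lw))

  nodes$block4 <- hierarchy_node(
    "block4", c("trot_paces", "variations_on_the_trot_gait",
                "lateral_trot_movements"), window_s = 0.8,
    children = c(variations_on_the_trot_gait = "block5",
                 lateral_trot_movements = "block6"),
    assign = stats::setNames(
      ifelse(category_of[trot] == "pace", "trot_paces",
             ifelse(category_of[trot] == "variation",
                    "variations_on_the_trot_gait", "lateral_trot_movements")),
      trot),
    pace_classes = "trot_paces")
  nodes$block5 <- hierarchy_node(
    "block5", c("passage", "piaffe"), window_s = 0.5,
    assign = c(passage = "passage", piaffe = "piaffe"))
  lt <- trot[category_of[trot] == "lateral"]
  nodes$block6 <- hierarchy_node(
    "block6", c("shoulder_in_trot", "haunches_in_trot", "side_movements_trot"),
    window_s = 2, step_s = 0.5,
    children = c(side_movements_trot = "block7"),
    assign = stats::setNames(
      ifelse(lt %in% c("leg_yield_trot", "half_pass_trot"),
             "side_movements_trot", lt), lt))
  nodes$block7 <- hierarchy_node(
    "block7", c("leg_yield_trot", "half_pass_trot"), window_s = 0.8,
    assign = c(leg_yield_trot = "leg_yield_trot",
               half_pass_trot = "half_pass_trot"))

  nodes$block8 <- hierarchy_node(
    "block8", c("flying_change", "pirouette_canter",
                "lateral_canter_movements_and_paces"), window_s = 2,
    children = c(lateral_canter_movements_and_paces = "block9"),
    assign = stats::setNames(
      ifelse(category_of[canter] == "flying_change", "flying_change",
             ifelse(category_of[canter] == "pirouette", "pirouette_canter",
                    "lateral_canter_movements_and_paces")), canter))
  lc <- canter[category_of[canter] %in% c("lateral", "pace")]
  nodes$block9 <- hierarchy_node(
    "block9", c("canter_paces", "shoulder_in_canter", "haunches_in_canter",
                "half_pass_canter"), window_s = 0.64,
    assign = stats::setNames(
      ifelse(category_of[lc] == "pace", "canter_paces", lc), lc),
    pace_classes = "canter_paces")

  structure(list(nodes = nodes, root = "phase1", discipline = "dressage"),
            class = "eg_hierarchy")
}

#' Build the single-phase jumping model
#'
#' One classifier node over the six jumping classes (walk, trot, left canter,
#' right canter, jump, flying change), 2 s windows sub-sampled to 10 Hz.
#'
#' @return an `eg_hierarchy` with one node.
#' @export
build_jumping_model <- function() {
  labs <- activity_catalog("jumping")$label
  node <- hierarchy_node("jumping", labs, window_s = 2, sampling_rate = 10,
                         assign = stats::setNames(labs, labs))
  structure(list(nodes = list(jumping = node), root = "jumping",
                 discipline = "jumping"),
            class = "eg_hierarchy")
}

#' @export
print.eg_hierarchy <- function(x, ...) {
  cat(sprintf("<eg_hierarchy> %s, %d nodes (root %s)\n", x$discipline,
              length(x$nodes), x$root))
  for (nd in x$nodes) print(nd)
  invisible(x)
}

# windows for one node from a list of recordings: re-segments the raw stream
# at the node's window size/rate and maps fine labels to node classes
node_windows <- function(node, recordings) {
  out <- list()
  for (rec in recordings) {
    r <- rec
    if (node$sampling_rate < rec$sampling_rate) {
      r$signal <- subsample(rec$signal, node$sampling_rate, rec$sampling_rate)
      r$sampling_rate <- node$sampling_rate
    }
    keep <- r$annotations$label %in% names(node$assign)
    if (!any(keep)) next
    r$annotations <- r$annotations[keep, , drop = FALSE]
    ws <- suppressWarnings(segment(r, node$window_s,
                                   node$step_s %||% node$window_s))
    for (w in ws) {
      w$node_class <- if (node$label_source == "side") w$side
                      else unname(node$assign[[w$label]])
      if (w$node_class %in% node$classes) out[[length(out) + 1L]] <- w
    }
  }
  out
}

#' Train the classifier of one hierarchy node
#'
#' Re-segments the recordings at the node's window size (and sampling rate),
#' maps fine labels to the node's classes (or to the window side for side
#' nodes), and trains the hybrid CNN with a stratified held-out split.
#'
#' @param hierarchy an `eg_hierarchy`.
#' @param node_name node to train.
#' @param recordings list of `eg_recording` (e.g. from [generate_dataset()]).
#' @param split_fraction,seed see [train_classifier()].
#' @param ... overrides forwarded to [classifier_config()] (e.g. smaller
#'   `conv_filters` or `epochs`).
#' @return the [train_classifier()] result, with the node name attached.
#' @export
train_node <- function(hierarchy, node_name, recordings,
                       split_fraction = 0.66, seed = 1, ...) {
  node <- hierarchy$nodes[[node_name]]
  if (is.null(node)) stop("unknown node '", node_name, "'")
  ws <- node_windows(node, recordings)
  if (length(ws) == 0) stop("no training windows for node '", node_name, "'")
  arr <- windows_to_arrays(ws)
  labels <- vapply(ws, function(w) w$node_class, character(1))
  cfg <- classifier_config(n_classes = length(unique(labels)),
                           n_channels = dim(arr$x)[2],
                           n_samples = dim(arr$x)[1],
                           n_features = ncol(arr$features), seed = seed, ...)
  fit <- train_classifier(build_classifier(cfg), arr$x, arr$features, labels,
                          split_fraction = split_fraction, seed = seed)
  fit$node <- node_name
  fit
}

majority_vote <- function(labels, classes) {
  tab <- table(factor(labels, classes))
  classes[which.max(tab)]
}

#' Classify an annotated recording through the hierarchy
#'
#' Each annotated span is cascaded through the hierarchy: at every node the
#' span is re-segmented at that node's window size (and sub-sampled to its
#' rate), every window is classified, the span-level decision is the majority
#' vote, and the cascade descends into the voted child until a leaf. Spans
#' voted into a pace superclass are flagged for phase-4 pace classification.
#' When a fitted `trot_side` model is supplied, trot-pace spans also receive
#' a side estimate (the source for [inject_side()]).
#'
#' @param hierarchy an `eg_hierarchy`.
#' @param recording an `eg_recording`.
#' @param models named list of fitted node models (`train_node()` results or
#'   bare `eg_cnn` models), keyed by node name.
#' @return data.frame with one row per span: start_s, end_s, truth, label,
#'   gait, is_pace, side_estimate.
#' @export
classify_stream <- function(hierarchy, recording, models) {
  ann <- recording$annotations
  get_model <- function(name) {
    m <- models[[name]]
    if (is.null(m)) stop("no fitted model for node '", name, "'")
    if (inherits(m, "eg_cnn")) m else m$model
  }
  span_votes <- function(node, span_rec) {
    r <- span_rec
    if (node$sampling_rate < span_rec$sampling_rate) {
      r$signal <- subsample(span_rec$signal, node$sampling_rate,
                            span_rec$sampling_rate)
      r$sampling_rate <- node$sampling_rate
    }
    ws <- suppressWarnings(segment(r, node$window_s,
                                   node$step_s %||% node$window_s))
    if (length(ws) == 0) return(NA_character_)
    arr <- windows_to_arrays(ws)
    pred <- predict(get_model(node$name), arr$x, arr$features)
    majority_vote(pred$label, get_model(node$name)$classes)
  }
  out <- list()
  for (i in seq_len(nrow(ann))) {
    i0 <- round(ann$start_s[i] * recording$sampling_rate) + 1
    i1 <- round(ann$end_s[i] * recording$sampling_rate)
    span_rec <- new_recording(
      recording$signal[, i0:i1, drop = FALSE], recording$sampling_rate,
      recording$subject,
      data.frame(start_s = 0, end_s = ann$end_s[i] - ann$start_s[i],
                 label = ann$label[i], side = ann$side[i],
                 velocity = ann$velocity[i],
                 stride_duration = ann$stride_duration[i],
                 stringsAsFactors = FALSE))
    node <- hierarchy$nodes[[hierarchy$root]]
    gait <- NA_character_
    repeat {
      vote <- span_votes(node, span_rec)
      if (node$name == hierarchy$root && hierarchy$discipline == "dressage") {
        gait <- vote
      }
      if (is.na(vote) || !vote %in% names(node$children)) break
      node <- hierarchy$nodes[[node$children[[vote]]]]
    }
    is_pace <- !is.na(vote) && vote %in% node$pace_classes
    side_est <- NA_character_
    if (is_pace && identical(vote, "trot_paces") &&
        "trot_side" %in% names(models)) {
      side_est <- span_votes(hierarchy$nodes$trot_side, span_rec)
    }
    out[[i]] <- data.frame(start_s = ann$start_s[i], end_s = ann$end_s[i],
                           truth = ann$label[i], label = vote, gait = gait,
                           is_pace = is_pace, side_estimate = side_est,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Inherit side context for shoulder-in / haunches-in spans
#'
#' Shoulder-in and haunches-in are ridden on the hand the horse was already
#' on, so their side is inherited from the side estimate of the most recent
#' preceding trot-pace span (across any intervening spans); "unknown" when no
#' trot-pace span precedes.
#'
#' @param spans data.frame in span order with columns `label` and
#'   `side_estimate` (as produced by [classify_stream()]).
#' @return character vector of side context per span ("left", "right",
#'   "unknown").
#' @export
inject_side <- function(spans) {
  trot_pace_labels <- c("trot_paces", "collected_trot", "working_trot",
                        "extended_trot")
  needs_side <- function(lbl) grepl("^(shoulder_in|haunches_in)", lbl)
  current <- "unknown"
  out <- character(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    if (spans$label[i] %in% trot_pace_labels &&
        !is.na(spans$side_estimate[i]) &&
        spans$side_estimate[i] %in% c("left", "right")) {
      current <- spans$side_estimate[i]
    }
    out[i] <- if (needs_side(spans$label[i])) current else "unknown"
  }
  out
}
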