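#' Confusion matrix with per-class and overall accuracy
#'
#' Rows are true labels, columns predictions. Overall accuracy is the trace
#' divided by the total count; per-class accuracy is the diagonal divided by
#' the row sum.
#'
#' @param truth true labels.
#' @param predicted predicted labels (same length).
#' @param classes optional fixed class set; labels outside it are an error.
#' @return object of class `eg_confusion` with `counts`, `per_class_accuracy`
#'   and `overall_accuracy`.
#' @export
confusion <- function(truth, predicted, classes = NULL) {
  if (length(truth) == 0) stop("empty label vectors")
  if (length(truth) != length(predicted)) stop("length mismatch")
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) stop("labels outside class set: ", paste(bad, collapse = ", "))
  counts <- table(factor(truth, classes), factor(predicted, classes))
  counts <- matrix(counts, nrow = length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  per_class <- diag(counts) / rowSums(counts)
  structure(list(counts = counts,
                 per_class_accuracy = per_class,
                 overall_accuracy = sum(diag(counts)) / sum(counts)),
            class = "eg_confusion")
}

#' @export
print.eg_confusion <- function(x, ...) {
  cat(sprintf("<eg_confusion> overall accuracy %.2f%%\n",
              100 * x$overall_accuracy))
  print(x$counts)
  invisible(x)
}

#' Write a confusion matrix as delimited text
#'
#' @param cm an `eg_confusion`.
#' @param path output file (tab-delimited, row names are true labels).
#' @export
write_confusion <- function(cm, path) {
  utils::write.table(cm$counts, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Regression error metrics
#'
#' RMSE is the square root of the mean squared difference between truth and
#' estimate; R-squared is 1 - SS_res/SS_tot.
#'
#' @param truth observed values.
#' @param estimate model estimates (same, nonzero length).
#' @return list with `rmse` and `r2`.
#' @export
regression_metrics <- function(truth, estimate) {
  if (length(truth) == 0 || length(truth) != length(estimate)) {
    stop("truth and estimate must have equal, nonzero length")
  }
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) stop("R-squared undefined for zero-variance truth")
  ss_res <- sum((truth - estimate)^2)
  list(rmse = sqrt(mean((truth - estimate)^2)), r2 = 1 - ss_res / ss_tot)
}

#' Proportion-weighted overall accuracy
#'
#' Overall accuracy over a set of classes as the sum of per-class accuracies
#' weighted by the class proportions observed in the dataset; proportions are
#' renormalized over the evaluated classes.
#'
#' @param accuracies named per-class accuracies in [0, 1].
#' @param proportions named class proportions (any positive scale).
#' @return weighted overall accuracy.
#' @export
overall_accuracy <- function(accuracies, proportions) {
  if (is.null(names(accuracies)) || is.null(names(proportions)) ||
      !setequal(names(accuracies), names(proportions))) {
    stop("accuracies and proportions must be named over the same classes")
  }
  p <- proportions[names(accuracies)]
  p <- p / sum(p)
  sum(p * accuracies)
}

#' Per-group locomotion summary
#'
#' Mean and standard deviation of velocity, stride duration and stride length
#' per (horse type, gait, pace), in the layout of the locomotion-parameter
#' table. Groups without data are omitted with a warning.
#'
#' @param metrics data.frame with columns horse_type, gait, pace, velocity,
#'   stride_duration (stride_length is computed when absent).
#' @return data.frame of group means and SDs.
#' @export
locomotion_summary <- function(metrics) {
  need <- c("horse_type", "gait", "pace", "velocity", "stride_duration")
  if (!all(need %in% names(metrics))) {
    stop("metrics must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(metrics) == 0) stop("no metrics to summarize")
  if (!"stride_length" %in% names(metrics)) {
    metrics$stride_length <- stride_length(metrics$velocity,
                                           metrics$stride_duration)
  }
  key <- interaction(metrics$horse_type, metrics$gait, metrics$pace, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    m <- metrics[key == k, ]
    data.frame(horse_type = m$horse_type[1], gait = m$gait[1], pace = m$pace[1],
               n = nrow(m),
               mean_velocity = mean(m$velocity),
               sd_velocity = stats::sd(m$velocity),
               mean_stride_duration = mean(m$stride_duration),
               sd_stride_duration = stats::sd(m$stride_duration),
               mean_stride_length = mean(m$stride_length),
               sd_stride_length = stats::sd(m$stride_length),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$sd_velocity[is.na(out$sd_velocity)] <- 0
  out$sd_stride_duration[is.na(out$sd_stride_duration)] <- 0
  out$sd_stride_length[is.na(out$sd_stride_length)] <- 0
  grid <- locomotion_params()
  grid <- grid[grid$horse_type %in% unique(metrics$horse_type), ]
  missing <- !paste(grid$horse_type, grid$gait, grid$pace) %in%
    paste(out$horse_type, out$gait, out$pace)
  if (any(missing)) {
    warning(sum(missing), " locomotion group(s) without data omitted")
  }
  out
}

#' @rdname locomotion_summary
#' @param summary a locomotion summary data.frame.
#' @param path output file (tab-delimited).
#' @export
write_locomotion_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot helpers (require ggplot2)
#'
#' `plot_confusion` draws a confusion heatmap, `plot_velocity_fit` a
#' truth-versus-estimate scatter with the identity line, and
#' `plot_pace_regions` the (height, velocity) samples colored by pace with
#' the QDA decision regions shaded underneath.
#'
#' @param cm an `eg_confusion`.
#' @return a ggplot object.
#' @export
plot_confusion <- function(cm) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- as.data.frame(as.table(cm$counts))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(predicted, truth, fill = n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::theme_minimal()
}

#' @rdname plot_confusion
#' @param truth,estimate velocities, m/s.
#' @export
plot_velocity_fit <- function(truth, estimate) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- data.frame(estimate = estimate, truth = truth)
  ggplot2::ggplot(df, ggplot2::aes(estimate, truth)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "estimated velocity (m/s)", y = "true velocity (m/s)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_confusion
#' @param model an `eg_pace_model` (pooled, i.e. trot/canter).
#' @param samples data.frame with h, v, pace.
#' @export
plot_pace_regions <- function(model, samples) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  if (model$by_group) stop("decision-region plot expects a pooled model")
  hs <- seq(min(samples$h) - 0.05, max(samples$h) + 0.05, length.out = 80)
  vs <- seq(min(samples$v) - 0.3, max(samples$v) + 0.3, length.out = 80)
  grid <- expand.grid(h = hs, v = vs)
  grid$pace <- predict_pace(model, grid$h, grid$v)$pace
  ggplot2::ggplot() +
    ggplot2::geom_tile(data = grid,
                       ggplot2::aes(h, v, fill = pace),
                       alpha = 0.25) +
    ggplot2::geom_point(data = samples,
                        ggplot2::aes(h, v, color = pace)) +
    ggplot2::labs(x = "height at withers (m)", y = "velocity (m/s)") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("predicted", "truth", "n", "estimate", "pace",
                         "h", "v"))
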