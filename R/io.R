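# ---- delimited-text interchange ----------------------------------------

#' Write / read a recording as delimited text
#'
#' The signal file is comma-delimited with a header: `time_s` followed by one
#' `<sensor>_<axis>` column per channel (e.g. LF_x, LF_y, LF_z, RF_x, ...).
#' Annotations go to a separate tab-delimited file via [write_annotations()].
#'
#' @param recording an `eg_recording`.
#' @param path output signal file.
#' @param annotations_path optional; when given, annotations are written too.
#' @export
write_recording <- function(recording, path, annotations_path = NULL) {
  n <- ncol(recording$signal)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$sampling_rate)
  sig <- t(recording$signal)
  colnames(sig) <- rownames(recording$signal)
  df <- cbind(df, as.data.frame(sig))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(annotations_path)) {
    write_annotations(recording$annotations, annotations_path)
  }
  invisible(path)
}

#' @rdname write_recording
#' @param subject a [subject_profile()] to attach to the recording.
#' @return `read_recording` returns an `eg_recording`.
#' @export
read_recording <- function(path, annotations_path = NULL, subject = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s") stop("first column must be time_s")
  rate <- round(1 / stats::median(diff(df$time_s)))
  sig <- t(as.matrix(df[, -1, drop = FALSE]))
  ann <- if (!is.null(annotations_path)) read_annotations(annotations_path)
         else data.frame(start_s = numeric(0), end_s = numeric(0),
                         label = character(0), side = character(0),
                         velocity = numeric(0), stride_duration = numeric(0))
  if (is.null(subject)) subject <- subject_profile("unknown", 1.70, "dressage")
  new_recording(sig, rate, subject, ann)
}

#' Write / read interval annotations (ELAN-export style)
#'
#' Tab-delimited without a header: start (s), end (s), label. With
#' `extras = TRUE` three more columns (side, velocity, stride_duration) are
#' appended, which [read_annotations()] picks up by column count.
#'
#' @param annotations data.frame with start_s, end_s, label (and optionally
#'   side, velocity, stride_duration).
#' @param path output file.
#' @param extras write the generator's side/velocity/stride columns too.
#' @export
write_annotations <- function(annotations, path, extras = TRUE) {
  cols <- c("start_s", "end_s", "label")
  if (extras && all(c("side", "velocity", "stride_duration") %in%
                    names(annotations))) {
    cols <- c(cols, "side", "velocity", "stride_duration")
  }
  utils::write.table(annotations[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @return `read_annotations` returns a data.frame with start_s, end_s,
#'   label, side, velocity, stride_duration (the last three NA when the file
#'   has only the three ELAN columns).
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) == 3) {
    names(df) <- c("start_s", "end_s", "label")
    df$side <- "none"; df$velocity <- NA_real_; df$stride_duration <- NA_real_
  } else if (ncol(df) == 6) {
    names(df) <- c("start_s", "end_s", "label", "side", "velocity",
                   "stride_duration")
  } else {
    stop("expected 3 or 6 tab-delimited columns, got ", ncol(df))
  }
  df
}

#' Write / read a generator configuration as a key-value text file
#'
#' One `key = value` pair per line. Keys: discipline, sampling_rate,
#' window_s, step_s, span_s, noise_sd, lateral_ratio, sensors (comma
#' separated) and counts (comma-separated `label:count` pairs).
#'
#' @param config an [generator_config()].
#' @param path file path.
#' @export
write_generator_config <- function(config, path) {
  lines <- c(
    paste("discipline =", config$discipline),
    paste("sensors =", paste(config$sensors, collapse = ",")),
    paste("sampling_rate =", config$sampling_rate),
    paste("window_s =", config$window_s),
    paste("step_s =", config$step_s),
    paste("span_s =", config$span_s),
    paste("noise_sd =", config$noise_sd),
    paste("lateral_ratio =", config$lateral_ratio),
    paste("counts =", paste(sprintf("%s:%d", names(config$activities),
                                    config$activities), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @return `read_generator_config` returns an `eg_config`.
#' @export
read_generator_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), character(1)))
  get <- function(k, default = NULL) if (k %in% keys) vals[match(k, keys)] else default
  counts <- NULL
  if (!is.null(get("counts"))) {
    pairs <- strsplit(strsplit(get("counts"), ",")[[1]], ":")
    counts <- stats::setNames(as.integer(vapply(pairs, `[`, character(1), 2)),
                              trimws(vapply(pairs, `[`, character(1), 1)))
  }
  generator_config(
    discipline = get("discipline", "dressage"),
    activities = counts,
    sensors = strsplit(get("sensors", "LF,RF"), ",")[[1]],
    sampling_rate = as.numeric(get("sampling_rate", "50")),
    window_s = as.numeric(get("window_s", "2")),
    step_s = as.numeric(get("step_s", get("window_s", "2"))),
    span_s = as.numeric(get("span_s", get("window_s", "2"))),
    noise_sd = as.numeric(get("noise_sd", "0.3")),
    lateral_ratio = as.numeric(get("lateral_ratio", "1.3")))
}
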