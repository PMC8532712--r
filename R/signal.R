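#' Sub-sample a 50 Hz signal to a divisor rate
#'
#' Keeps every (rate/target_rate)-th sample starting at the first one, e.g.
#' 50 -> 10 Hz keeps samples 1, 6, 11, ...
#'
#' @param signal numeric vector, or a channels x samples matrix.
#' @param target_rate target sampling rate in Hz; must divide `rate`.
#' @param rate original sampling rate in Hz (default 50).
#' @return signal of the same shape family at the target rate.
#' @export
subsample <- function(signal, target_rate, rate = 50) {
  if (target_rate <= 0 || rate %% target_rate != 0) {
    stop("target_rate must be a positive divisor of ", rate, " Hz")
  }
  step <- rate / target_rate
  if (is.matrix(signal)) {
    signal[, seq(1, ncol(signal), by = step), drop = FALSE]
  } else {
    signal[seq(1, length(signal), by = step)]
  }
}

#' Cut an annotated recording into fixed-size labeled windows
#'
#' Fixed-size (optionally overlapping) sliding windows are taken within each
#' annotation span. A window is kept only when it lies entirely inside a
#' single annotation; windows straddling boundaries or unlabeled spans are
#' dropped, so an annotation of length `span` yields
#' `floor((span - window_s)/step_s) + 1` windows.
#'
#' @param recording an `eg_recording` (see [generate_dataset()] /
#'   [read_recording()]).
#' @param window_s window duration, seconds.
#' @param step_s hop between window starts, seconds (defaults to `window_s`,
#'   i.e. non-overlapping).
#' @return list of `eg_window` objects (possibly empty, with a warning when
#'   no annotation can hold a single window).
#' @export
segment <- function(recording, window_s, step_s = window_s) {
  stopifnot(inherits(recording, "eg_recording"))
  if (window_s <= 0 || step_s <= 0) stop("window_s and step_s must be > 0")
  rate <- recording$sampling_rate
  n_win <- round(window_s * rate)
  ann <- recording$annotations
  out <- list()
  for (i in seq_len(nrow(ann))) {
    span <- ann$end_s[i] - ann$start_s[i]
    k <- floor((span - window_s) / step_s + 1e-9) + 1
    if (k < 1) next
    for (j in seq_len(k)) {
      t0 <- ann$start_s[i] + (j - 1) * step_s
      i0 <- round(t0 * rate) + 1
      sig <- recording$signal[, i0:(i0 + n_win - 1), drop = FALSE]
      out[[length(out) + 1L]] <- new_window(
        signal = sig, sampling_rate = rate, label = ann$label[i],
        side = ann$side[i], subject_id = recording$subject$subject_id,
        height = recording$subject$height_withers,
        horse_type = recording$subject$horse_type,
        truth_velocity = ann$velocity[i],
        stride_duration = ann$stride_duration[i])
    }
  }
  if (length(out) == 0L) {
    warning("no annotation span is long enough for a ", window_s, " s window")
  }
  out
}

new_window <- function(signal, sampling_rate, label, side = "none",
                       subject_id = NA_character_, height = NA_real_,
                       horse_type = NA_character_,
                       truth_velocity = NA_real_,
                       stride_duration = NA_real_) {
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 duration_s = ncol(signal) / sampling_rate,
                 label = label, side = side, subject_id = subject_id,
                 height = height, horse_type = horse_type,
                 truth_velocity = truth_velocity,
                 stride_duration = stride_duration),
            class = "eg_window")
}

#' @export
print.eg_window <- function(x, ...) {
  cat(sprintf("<eg_window> %s (%s)  %d ch x %d samples @ %g Hz\n",
              x$label, x$side, nrow(x$signal), ncol(x$signal),
              x$sampling_rate))
  invisible(x)
}

#' Handcrafted global features of a window
#'
#' Per channel: mean, variance, peak-to-peak amplitude and the mean time
#' interval between consecutive crossings of the signal mean (window duration
#' when the mean-centered signal never changes sign). These summarize the
#' global form of the window and are fused with the convolutional features.
#'
#' @param window an `eg_window`, or a channels x samples matrix with
#'   `sampling_rate` supplied.
#' @param sampling_rate required when `window` is a bare matrix.
#' @return named numeric vector of length 4 x channels.
#' @export
extract_features <- function(window, sampling_rate = NULL) {
  if (inherits(window, "eg_window")) {
    sig <- window$signal; rate <- window$sampling_rate
  } else {
    sig <- window; rate <- sampling_rate
    if (is.null(rate)) stop("sampling_rate required for a bare matrix")
  }
  if (!is.matrix(sig) || ncol(sig) < 2L) {
    stop("window must have at least 2 samples per channel")
  }
  dur <- ncol(sig) / rate
  ch <- rownames(sig)
  if (is.null(ch)) ch <- paste0("ch", seq_len(nrow(sig)))
  feats <- lapply(seq_len(nrow(sig)), function(i) {
    x <- sig[i, ]
    xc <- x - mean(x)
    s <- sign(xc)
    s <- s[s != 0]
    crossings <- if (length(s) > 1) sum(diff(s) != 0) else 0L
    mci <- if (crossings == 0) dur else dur / crossings
    v <- c(mean(x), stats::var(x), diff(range(x)), mci)
    names(v) <- paste0(ch[i], c("_mean", "_var", "_p2p", "_mci"))
    v
  })
  unlist(feats)
}

#' Normalized autocorrelation of a signal
#'
#' Biased normalized estimator (divisor n at every lag), so the value at lag
#' zero is 1 and is the maximum; larger lags are naturally tapered, which
#' stabilizes peak picking on short windows.
#'
#' @param x numeric vector (typically the downward x-axis acceleration).
#' @param sampling_rate Hz, used to express lags in seconds.
#' @param lag_max_s largest lag to compute, seconds (default: whole window).
#' @return object of class `eg_acf` with fields `acf` and `lags` (seconds).
#' @export
autocorrelation <- function(x, sampling_rate, lag_max_s = NULL) {
  if (length(x) < 2L) stop("need at least 2 samples")
  if (stats::var(x) == 0) {
    stop("autocorrelation undefined for a zero-variance signal")
  }
  lag_max <- if (is.null(lag_max_s)) length(x) - 1L
             else min(length(x) - 1L, round(lag_max_s * sampling_rate))
  r <- stats::acf(x, lag.max = lag_max, type = "correlation",
                  plot = FALSE, demean = TRUE)$acf[, 1, 1]
  structure(list(acf = as.numeric(r),
                 lags = (seq_along(r) - 1) / sampling_rate,
                 sampling_rate = sampling_rate),
            class = "eg_acf")
}

#' Stride duration from the autocorrelation function
#'
#' The stride duration is the lag of the highest local maximum of the
#' autocorrelation of the downward (x) acceleration, searched over a band
#' covering equine stride durations (0.2 s to 2.5 s by default). The step
#' frequency is its inverse.
#'
#' @param acf_result an `eg_acf` from [autocorrelation()], or a numeric
#'   signal (then `sampling_rate` must be given and the ACF is computed).
#' @param sampling_rate Hz; only needed when passing a raw signal.
#' @param band search band for the peak, seconds.
#' @return stride duration in seconds, with attribute `step_frequency` (Hz)
#'   and `peak` (ACF value at the peak).
#' @export
estimate_stride_duration <- function(acf_result, sampling_rate = NULL,
                                     band = c(0.2, 2.5)) {
  if (!inherits(acf_result, "eg_acf")) {
    if (is.null(sampling_rate)) stop("sampling_rate required for raw signal")
    acf_result <- autocorrelation(acf_result, sampling_rate)
  }
  r <- acf_result$acf
  lags <- acf_result$lags
  n <- length(r)
  if (n < 3L) stop_aperiodic()
  i <- 2:(n - 1)
  is_peak <- r[i] > r[i - 1] & r[i] >= r[i + 1]
  in_band <- lags[i] >= band[1] & lags[i] <= band[2]
  cand <- i[is_peak & in_band]
  if (length(cand) == 0L) stop_aperiodic()
  best <- cand[which.max(r[cand])]
  dt <- lags[best]
  structure(dt, step_frequency = 1 / dt, peak = r[best])
}

stop_aperiodic <- function() {
  stop(structure(class = c("eg_aperiodic", "error", "condition"),
                 list(message = "no stride periodicity found in search band",
                      call = sys.call(-1))))
}

#' Stride length from velocity and stride duration
#'
#' L = v * dT: a horse moving at velocity v covers one stride length per
#' stride duration.
#'
#' @param v velocity, m/s (>= 0).
#' @param dT stride duration, s (> 0).
#' @return stride length, m.
#' @export
stride_length <- function(v, dT) {
  if (any(v < 0)) stop("velocity must be >= 0")
  if (any(dT <= 0)) stop("stride duration must be > 0")
  v * dT
}

#' Stride mechanics for one window
#'
#' Combines a velocity with an estimated stride duration into the full set of
#' stride metrics: duration, step frequency f = 1/dT, velocity, and stride
#' length L = v * dT.
#'
#' @param v velocity, m/s.
#' @param dT stride duration, s.
#' @return list with stride_duration, step_frequency, velocity, stride_length.
#' @export
stride_metrics <- function(v, dT) {
  L <- stride_length(v, dT)
  list(stride_duration = dT, step_frequency = 1 / dT, velocity = v,
       stride_length = L)
}
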