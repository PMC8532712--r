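GRAVITY <- 9.80665

# fixed waveform constants of the generator (see the methods vignette for
# the rationale behind each value)
sig_constants <- function() {
  list(
    v_ref = 1.6,            # m/s giving ~1 g impact peaks (typical walk)
    sigma_frac = 0.04,      # impact pulse width as fraction of stride
    sigma_min = 0.02,       # s; keeps pulses resolvable after 50->10 Hz
    bleed_front = 0.12,     # contralateral foreleg impact bleed-through
    bleed_hind_same = 0.20, # ipsilateral hindleg bleed-through
    bleed_hind_diag = 0.15, # diagonal hindleg bleed-through
    lead_ratio = 1.30,      # canter lead foreleg impact ratio
    hand_ratio = 1.12,      # mild asymmetry of paces toward the hand
    y_frac = 0.50,          # forward-axis oscillation amp rel. to impact amp
    y_harm = 0.40,          # second harmonic fraction on the forward axis
    z_osc = 0.30,           # lateral oscillation fraction of the z offset
    z_pace = 0.30,          # m/s^2 lateral offset toward the hand (paces)
    z_lead = 0.80,          # m/s^2 lateral offset on the canter lead side
    z_offsets = c(shoulder_in = 1.5, haunches_in = 2.5, half_pass = 3.5,
                  leg_yield = 3.5, pirouette = 5.0),
    pirouette_off_ratio = 0.7, # outside-sensor share of the pirouette offset
    jump_amp = 4.5,         # jump transient peak, in g
    jump_sigma = 0.10,      # s
    piaffe_v = c(0.15, 0.30),   # forward velocity band, m/s
    passage_v = c(1.40, 1.70),  # forward velocity band, m/s
    piaffe_dT = c(1.00, 1.10),  # cadence band shared by piaffe/passage, s
    piaffe_v_impact = 2.0       # impact energy scale for piaffe/passage
  )
}

#' Draw a velocity for a gait/pace/horse-type combination
#'
#' Velocities are drawn uniformly within mean +/- 1 SD of the matching
#' locomotion-parameter row, so that pace classes have disjoint supports
#' wherever the population bands do not overlap.
#'
#' @inheritParams locomotion_row
#' @param n number of draws.
#' @return numeric vector of velocities, m/s. Reproducible under `set.seed()`.
#' @export
sample_pace_velocity <- function(gait, pace, horse_type, n = 1) {
  row <- locomotion_row(gait, pace, horse_type)
  stats::runif(n, row$mean_velocity - row$sd_velocity,
               row$mean_velocity + row$sd_velocity)
}

#' Stride duration implied by a drawn velocity
#'
#' Within a locomotion-parameter row the stride duration is coupled
#' deterministically to the velocity: a draw at the row's mean velocity has
#' the row's mean stride duration, and faster draws have shorter strides
#' (dT = mean_dT - sd_dT * (v - mean_v)/sd_v). This keeps windows internally
#' consistent and makes the autocorrelation channel informative about
#' velocity.
#'
#' @inheritParams locomotion_row
#' @param velocity m/s.
#' @return stride duration, s.
#' @export
stride_duration_for <- function(gait, pace, horse_type, velocity) {
  row <- locomotion_row(gait, pace, horse_type)
  z <- (velocity - row$mean_velocity) / row$sd_velocity
  dt <- row$mean_stride_duration - row$sd_stride_duration * z
  pmax(dt, 0.2)
}

# footfall phase (fraction of the stride cycle) of each leg; the pattern is
# anchored on the lead/reference side so that swapping the left and right
# sensors maps a left-sided pattern exactly onto its right-sided counterpart
footfall_phases <- function(gait, lead = "left") {
  ph <- switch(gait,
    # lateral walk sequence starting at the reference foreleg
    walk = c(LF = 0.00, RH = 0.25, RF = 0.50, LH = 0.75),
    # diagonal pairs; reference foreleg with its diagonal hind at 0
    trot = c(LF = 0.00, RH = 0.00, RF = 0.50, LH = 0.50),
    # 3-beat; the lead-side foreleg lands last
    canter = c(LF = 2 / 3, RF = 1 / 3, LH = 1 / 3, RH = 0),
    stop("no footfall pattern for gait '", gait, "'"))
  if (identical(lead, "right")) {
    ph <- ph[c("RF", "LF", "RH", "LH")]
    names(ph) <- c("LF", "RF", "LH", "RH")
  }
  ph[c("LF", "RF", "LH", "RH")]
}

# impact bleed-through weight from a source leg into a sensor's signal
bleed_weight <- function(sensor, leg, k) {
  if (sensor == leg) return(1)
  s_front <- substr(sensor, 2, 2) == "F"
  l_front <- substr(leg, 2, 2) == "F"
  s_side <- substr(sensor, 1, 1)
  l_side <- substr(leg, 1, 1)
  if (s_front == l_front) return(k$bleed_front)          # other leg, same girdle
  if (s_side == l_side) return(k$bleed_hind_same)        # same side
  k$bleed_hind_diag                                      # diagonal
}

# sum of Gaussian impact pulses at phase*dT + m*dT + t0 over the window
pulse_train <- function(t, phase, dT, sigma, t0) {
  m <- seq(floor((t[1] - t0) / dT) - 1, ceiling((t[length(t)] - t0) / dT) + 1)
  centers <- (m + phase) * dT + t0
  out <- numeric(length(t))
  for (ctr in centers) out <- out + exp(-0.5 * ((t - ctr) / sigma)^2)
  out
}

# deterministic periodic part of one locomotion pattern (no noise, no
# transients); returns channels x samples matrix for the requested sensors
gait_pattern <- function(t, gait, lead, v_impact, v_forward, dT, t0,
                         sensors, side, category, lateral_ratio, k) {
  phases <- footfall_phases(gait, lead)
  A <- GRAVITY * v_impact / k$v_ref
  sigma <- max(k$sigma_frac * dT, k$sigma_min)
  amp_leg <- c(LF = A, RF = A, LH = A, RH = A)
  if (gait == "canter") {
    lead_fore <- if (identical(lead, "right")) "RF" else "LF"
    amp_leg[lead_fore] <- amp_leg[lead_fore] * k$lead_ratio
  }
  base_cat <- if (category %in% c("lateral", "pirouette")) "lateral" else category
  if (side %in% c("left", "right")) {
    side_legs <- if (side == "left") c("LF", "LH") else c("RF", "RH")
    ratio <- switch(base_cat, lateral = lateral_ratio, k$hand_ratio)
    amp_leg[side_legs] <- amp_leg[side_legs] * ratio
  }
  zoff <- c(LF = 0, RF = 0, LH = 0, RH = 0)
  if (side %in% c("left", "right")) {
    side_sensors <- if (side == "left") c("LF", "LH") else c("RF", "RH")
    off_sensors <- setdiff(c("LF", "RF", "LH", "RH"), side_sensors)
    zo <- switch(category,
                 lateral = k$z_offsets[[sub("_(walk|trot|canter)$", "",
                                            attr(category, "label") %||% "half_pass")]],
                 pirouette = k$z_offsets[["pirouette"]],
                 flying_change = k$z_lead,
                 pace = if (gait == "canter") k$z_lead else k$z_pace,
                 k$z_pace)
    zoff[side_sensors] <- zo
    if (category == "pirouette") zoff[off_sensors] <- zo * k$pirouette_off_ratio
  }
  amp_y <- k$y_frac * GRAVITY * v_forward / k$v_ref
  out <- matrix(0, nrow = 3 * length(sensors), ncol = length(t))
  rn <- character(3 * length(sensors))
  for (si in seq_along(sensors)) {
    s <- sensors[si]
    x <- numeric(length(t))
    for (leg in names(phases)) {
      w <- bleed_weight(s, leg, k)
      x <- x + w * amp_leg[[leg]] * pulse_train(t, phases[[leg]], dT, sigma, t0)
    }
    ph <- phases[[s]]
    y <- amp_y * (sin(2 * pi * ((t - t0) / dT - ph)) +
                    k$y_harm * sin(4 * pi * ((t - t0) / dT - ph)))
    z <- zoff[[s]] * (1 + k$z_osc * sin(2 * pi * ((t - t0) / dT - ph)))
    rows <- (si - 1) * 3 + 1:3
    out[rows[1], ] <- GRAVITY + x
    out[rows[2], ] <- y
    out[rows[3], ] <- z
    rn[rows] <- paste0(s, c("_x", "_y", "_z"))
  }
  rownames(out) <- rn
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesize one labeled accelerometer window
#'
#' Generates per-sensor tri-axial acceleration for a single activity as a sum
#' of Gaussian-windowed impact pulses placed at the gait's footfall phases
#' (walk 4-beat, trot 2-beat diagonal pairs, canter 3-beat with the lead-side
#' foreleg carrying the largest impact), plus a forward-axis oscillation whose
#' amplitude grows with velocity, lateral-axis offsets for sided movements, a
#' high-magnitude transient for jumps, a mid-window lead swap for flying
#' changes, and pure noise for halt. Impact peak amplitude scales linearly
#' with velocity (about 1 g at walk). Axis convention per sensor: x toward
#' the ground, y forward, z into the leg.
#'
#' @param activity an activity label or an [activity_spec()].
#' @param subject optional [subject_profile()]; supplies horse type and height.
#' @param velocity forward velocity in m/s; drawn from the locomotion table
#'   via [sample_pace_velocity()] when `NULL`.
#' @param sampling_rate Hz.
#' @param duration_s window length in seconds; should cover at least one
#'   stride for periodic activities.
#' @param noise_sd Gaussian noise sd added to every channel, m/s^2.
#' @param sensors ordered subset of c("LF","RF","LH","RH").
#' @param horse_type used when no subject is given.
#' @param lateral_ratio impact amplitude ratio applied on the side of a
#'   lateral movement.
#' @return an `eg_window` with `truth_velocity` and `stride_duration` fields.
#' @export
synthesize_window <- function(activity, subject = NULL, velocity = NULL,
                              sampling_rate = 50, duration_s = 2,
                              noise_sd = 0.3, sensors = c("LF", "RF"),
                              horse_type = "horse", lateral_ratio = 1.3) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!all(sensors %in% c("LF", "RF", "LH", "RH"))) stop("unknown sensor id")
  spec <- if (is.character(activity)) activity_spec(activity) else activity
  if (!is.null(subject)) horse_type <- subject$horse_type
  height <- if (!is.null(subject)) subject$height_withers else NA_real_
  k <- sig_constants()
  n <- round(duration_s * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  nc <- 3 * length(sensors)
  ch_names <- as.vector(t(outer(sensors, c("_x", "_y", "_z"), paste0)))

  label <- spec$label
  side <- spec$side
  gait <- spec$gait
  category <- spec$category

  if (gait == "halt") {
    sig <- matrix(stats::rnorm(nc * n, sd = noise_sd), nrow = nc)
    sig[grep("_x$", ch_names), ] <- sig[grep("_x$", ch_names), ] + GRAVITY
    rownames(sig) <- ch_names
    return(new_window(sig, sampling_rate, label, side,
                      subject_id = subject$subject_id %||% NA_character_,
                      height = height, horse_type = horse_type,
                      truth_velocity = 0, stride_duration = NA_real_))
  }

  if (label %in% c("piaffe", "passage")) {
    vband <- if (label == "piaffe") k$piaffe_v else k$passage_v
    v_forward <- velocity %||% stats::runif(1, vband[1], vband[2])
    dT <- stats::runif(1, k$piaffe_dT[1], k$piaffe_dT[2])
    v_impact <- k$piaffe_v_impact
  } else {
    v_forward <- velocity %||% sample_pace_velocity(gait, spec$pace, horse_type)
    dT <- stride_duration_for(gait, spec$pace, horse_type, v_forward)
    v_impact <- v_forward
  }

  t0 <- stats::runif(1, 0, dT)
  lead <- if (side %in% c("left", "right")) side else
    sample(c("left", "right"), 1)

  # attach movement identity so gait_pattern can pick the z offset
  cat_tagged <- category
  attr(cat_tagged, "label") <- label

  if (category == "flying_change") {
    old_lead <- if (lead == "left") "right" else "left"
    s1 <- gait_pattern(t, gait, old_lead, v_impact, v_forward, dT, t0,
                       sensors, old_lead, "pace", lateral_ratio, k)
    s2 <- gait_pattern(t, gait, lead, v_impact, v_forward, dT, t0,
                       sensors, lead, "pace", lateral_ratio, k)
    t_switch <- stats::runif(1, 0.4, 0.6) * duration_s
    mask <- t < t_switch
    sig <- s1 * rep(mask, each = nrow(s1)) + s2 * rep(!mask, each = nrow(s2))
  } else {
    sig <- gait_pattern(t, gait, lead, v_impact, v_forward, dT, t0,
                        sensors, side, cat_tagged, lateral_ratio, k)
  }

  if (category == "jump") {
    t_jump <- stats::runif(1, 0.3, 0.7) * duration_s
    pulse <- exp(-0.5 * ((t - t_jump) / k$jump_sigma)^2)
    sig[grep("_x$", ch_names), ] <-
      sig[grep("_x$", ch_names), ] +
      rep(k$jump_amp * GRAVITY * pulse, each = length(sensors))
    sig[grep("_y$", ch_names), ] <-
      sig[grep("_y$", ch_names), ] +
      rep(2 * GRAVITY * pulse, each = length(sensors))
  }

  sig <- sig + matrix(stats::rnorm(nc * n, sd = noise_sd), nrow = nc)
  rownames(sig) <- ch_names
  new_window(sig, sampling_rate, label, side,
             subject_id = subject$subject_id %||% NA_character_,
             height = height, horse_type = horse_type,
             truth_velocity = v_forward, stride_duration = dT)
}

#' Generator configuration
#'
#' @param discipline "dressage" or "jumping"; selects the activity inventory
#'   and the subjects.
#' @param activities named integer vector of window counts per activity label;
#'   defaults to `n_per_class` for every label of the discipline. Labels must
#'   belong to the discipline's catalog; classes with count 0 are omitted.
#' @param n_per_class default count used when `activities` is NULL.
#' @param sensors ordered subset of c("LF","RF","LH","RH").
#' @param sampling_rate Hz.
#' @param window_s window duration, s.
#' @param step_s window hop, s.
#' @param span_s duration of each annotated activity span, s (>= window_s);
#'   longer spans allow re-segmentation at other window sizes.
#' @param noise_sd channel noise sd, m/s^2.
#' @param lateral_ratio see [synthesize_window()].
#' @return list of class `eg_config`.
#' @export
generator_config <- function(discipline = c("dressage", "jumping"),
                             activities = NULL, n_per_class = 20,
                             sensors = c("LF", "RF"), sampling_rate = 50,
                             window_s = 2, step_s = window_s,
                             span_s = window_s, noise_sd = 0.3,
                             lateral_ratio = 1.3) {
  discipline <- match.arg(discipline)
  cat <- activity_catalog(discipline)
  if (is.null(activities)) {
    activities <- stats::setNames(rep(n_per_class, nrow(cat)), cat$label)
  }
  bad <- setdiff(names(activities), cat$label)
  if (length(bad)) {
    stop("activities not in the ", discipline, " inventory: ",
         paste(bad, collapse = ", "))
  }
  if (span_s < window_s) stop("span_s must be >= window_s")
  structure(list(discipline = discipline,
                 activities = activities[activities > 0],
                 sensors = sensors, sampling_rate = sampling_rate,
                 window_s = window_s, step_s = step_s, span_s = span_s,
                 noise_sd = noise_sd, lateral_ratio = lateral_ratio),
            class = "eg_config")
}

#' Generate a labeled synthetic dataset
#'
#' Produces per-subject recordings (continuous multi-sensor signals with
#' non-overlapping annotation spans) and the labeled windows segmented from
#' them, with per-window ground-truth velocity and stride duration. Output is
#' fully reproducible from (config, seed).
#'
#' @param config an [generator_config()].
#' @param seed integer seed.
#' @return list of class `eg_dataset` with elements `recordings` (list of
#'   `eg_recording`) and `windows` (list of `eg_window`).
#' @export
generate_dataset <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "eg_config"))
  set.seed(seed)
  roster <- subject_roster()
  roster <- roster[roster$discipline == config$discipline, ]
  subjects <- lapply(seq_len(nrow(roster)), function(i) {
    subject_profile(roster$subject_id[i], roster$height_withers[i],
                    roster$discipline[i], roster$level[i],
                    roster$min_collected_walk_speed[i])
  })
  names(subjects) <- roster$subject_id

  per_span <- floor((config$span_s - config$window_s) / config$step_s + 1e-9) + 1
  streams <- stats::setNames(vector("list", length(subjects)), names(subjects))
  anns <- stats::setNames(vector("list", length(subjects)), names(subjects))

  for (label in names(config$activities)) {
    count <- config$activities[[label]]
    n_spans <- ceiling(count / per_span)
    cat_row <- activity_catalog(config$discipline)
    sided <- cat_row$sided[cat_row$label == label]
    for (sp in seq_len(n_spans)) {
      subj <- subjects[[sample(length(subjects), 1)]]
      side <- if (label == "left_canter") "left"
              else if (label == "right_canter") "right"
              else if (sided) sample(c("left", "right"), 1)
              else "none"
      w <- synthesize_window(activity_spec(label, side, config$discipline),
                             subject = subj, sampling_rate = config$sampling_rate,
                             duration_s = config$span_s,
                             noise_sd = config$noise_sd,
                             sensors = config$sensors,
                             lateral_ratio = config$lateral_ratio)
      id <- subj$subject_id
      streams[[id]] <- c(streams[[id]], list(w$signal))
      anns[[id]] <- c(anns[[id]], list(
        data.frame(label = label, side = side,
                   velocity = w$truth_velocity,
                   stride_duration = w$stride_duration,
                   dur = config$span_s, stringsAsFactors = FALSE)))
    }
  }

  recordings <- list()
  for (id in names(streams)) {
    if (is.null(streams[[id]])) next
    sig <- do.call(cbind, streams[[id]])
    a <- do.call(rbind, anns[[id]])
    a$end_s <- cumsum(a$dur)
    a$start_s <- a$end_s - a$dur
    a <- a[, c("start_s", "end_s", "label", "side", "velocity",
               "stride_duration")]
    recordings[[id]] <- new_recording(sig, config$sampling_rate,
                                      subjects[[id]], a)
  }

  windows <- unlist(lapply(recordings, segment,
                           window_s = config$window_s,
                           step_s = config$step_s), recursive = FALSE)
  # trim any per-class overshoot from span packing to the requested counts
  labs <- vapply(windows, function(w) w$label, character(1))
  keep <- logical(length(windows))
  for (label in names(config$activities)) {
    idx <- which(labs == label)
    keep[idx[seq_len(min(length(idx), config$activities[[label]]))]] <- TRUE
  }
  windows <- windows[keep]
  structure(list(recordings = recordings, windows = windows,
                 config = config, seed = seed),
            class = "eg_dataset")
}

new_recording <- function(signal, sampling_rate, subject, annotations) {
  stopifnot(is.matrix(signal))
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 subject = subject, annotations = annotations),
            class = "eg_recording")
}

#' @export
print.eg_recording <- function(x, ...) {
  cat(sprintf("<eg_recording> %s: %d ch x %d samples @ %g Hz, %d annotations\n",
              x$subject$subject_id, nrow(x$signal), ncol(x$signal),
              x$sampling_rate, nrow(x$annotations)))
  invisible(x)
}

#' @export
print.eg_dataset <- function(x, ...) {
  cat(sprintf("<eg_dataset> %d recordings, %d windows (%s)\n",
              length(x$recordings), length(x$windows), x$config$discipline))
  invisible(x)
}

#' Draw (height, velocity) pace samples for decision-region fitting
#'
#' For trot and canter, velocities are drawn i.i.d. uniformly within
#' mean +/- 1 SD of the locomotion table and heights uniformly within the
#' pony (1.32-1.46 m) and horse (1.66-1.82 m) study ranges. For walk, where
#' population pace bands overlap, samples are generated per subject from the
#' study-style roster: each subject carries a fixed offset z within the band
#' (for horses derived from its minimum collected-walk speed, for ponies
#' drawn once), its pace velocities are mean + z * sd plus a small
#' within-subject jitter, and the subject's group velocity profile (pony /
#' slow horse / fast horse) is recorded.
#'
#' @param gait "walk", "trot" or "canter".
#' @param n_per_class samples per (pace x horse type) for trot/canter, or per
#'   (pace x group) for walk.
#' @return data.frame with columns h, v, pace, horse_type, group, subject_id.
#' @export
sample_pace_dataset <- function(gait, n_per_class = 50) {
  paces <- c("collected", "working", "extended")
  if (gait %in% c("trot", "canter")) {
    out <- list()
    for (ht in c("pony", "horse")) {
      hr <- if (ht == "pony") c(1.32, 1.46) else c(1.66, 1.82)
      for (p in paces) {
        v <- sample_pace_velocity(gait, p, ht, n_per_class)
        h <- stats::runif(n_per_class, hr[1], hr[2])
        out[[length(out) + 1L]] <- data.frame(
          h = h, v = v, pace = p, horse_type = ht,
          group = ifelse(ht == "pony", "pony", NA_character_),
          subject_id = NA_character_, stringsAsFactors = FALSE)
      }
    }
    return(do.call(rbind, out))
  }
  if (gait != "walk") stop("gait must be walk, trot or canter")
  roster <- subject_roster()
  roster <- roster[roster$discipline == "dressage", ]
  tab <- locomotion_params()
  out <- list()
  for (i in seq_len(nrow(roster))) {
    ht <- if (roster$height_withers[i] <= 1.48) "pony" else "horse"
    mcw <- roster$min_collected_walk_speed[i]
    z <- if (ht == "horse") (mcw - 1.50) / 0.13 else stats::runif(1, -1, 1)
    group <- assign_group(roster$height_withers[i], mcw)
    for (p in paces) {
      row <- tab[tab$gait == "walk" & tab$pace == p & tab$horse_type == ht, ]
      v <- row$mean_velocity + z * row$sd_velocity +
        stats::runif(n_per_class, -0.15, 0.15) * row$sd_velocity
      out[[length(out) + 1L]] <- data.frame(
        h = roster$height_withers[i], v = v, pace = p, horse_type = ht,
        group = group, subject_id = roster$subject_id[i],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
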