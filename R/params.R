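#' Locomotion parameters per horse type, gait and pace
#'
#' Population means and spreads of velocity (m/s), stride duration (s) and
#' stride length (m) for ponies (height at withers <= 1.48 m) and horses,
#' for the collected, working and extended variants of walk, trot and canter.
#' These values parameterize the synthetic-data generator and the pace
#' decision regions.
#'
#' @return A data.frame with one row per (horse_type, gait, pace) and columns
#'   `mean_velocity`, `sd_velocity`, `mean_stride_duration`,
#'   `sd_stride_duration`, `mean_stride_length`, `sd_stride_length`.
#' @export
locomotion_params <- function() {
  g <- function(horse_type, gait, pace, v, dt, L) {
    data.frame(horse_type = horse_type, gait = gait, pace = pace,
               mean_velocity = v[1], sd_velocity = v[2],
               mean_stride_duration = dt[1], sd_stride_duration = dt[2],
               mean_stride_length = L[1], sd_stride_length = L[2],
               stringsAsFactors = FALSE)
  }
  rbind(
    g("pony",  "walk",   "collected", c(1.20, 0.02), c(1.32, 0.34), c(1.60, 0.43)),
    g("pony",  "walk",   "working",   c(1.30, 0.04), c(1.12, 0.10), c(1.46, 0.14)),
    g("pony",  "walk",   "extended",  c(1.37, 0.04), c(1.08, 0.08), c(1.48, 0.16)),
    g("pony",  "trot",   "collected", c(2.73, 0.05), c(0.71, 0.04), c(1.95, 0.14)),
    g("pony",  "trot",   "working",   c(2.93, 0.19), c(0.69, 0.03), c(2.03, 0.22)),
    g("pony",  "trot",   "extended",  c(4.21, 0.37), c(0.69, 0.05), c(2.89, 0.10)),
    g("pony",  "canter", "collected", c(3.27, 0.15), c(0.57, 0.03), c(1.87, 0.17)),
    g("pony",  "canter", "working",   c(3.83, 0.26), c(0.57, 0.03), c(2.20, 0.27)),
    g("pony",  "canter", "extended",  c(4.72, 0.16), c(0.57, 0.02), c(2.67, 0.21)),
    g("horse", "walk",   "collected", c(1.50, 0.13), c(1.30, 0.21), c(1.94, 0.34)),
    g("horse", "walk",   "working",   c(1.75, 0.10), c(1.26, 0.25), c(2.20, 0.41)),
    g("horse", "walk",   "extended",  c(1.88, 0.07), c(1.19, 0.05), c(2.24, 0.15)),
    g("horse", "trot",   "collected", c(3.46, 0.16), c(0.82, 0.02), c(2.85, 0.16)),
    g("horse", "trot",   "working",   c(3.80, 0.15), c(0.80, 0.01), c(3.05, 0.14)),
    g("horse", "trot",   "extended",  c(4.64, 0.12), c(0.78, 0.03), c(3.60, 0.18)),
    g("horse", "canter", "collected", c(3.41, 0.14), c(0.64, 0.02), c(2.18, 0.11)),
    g("horse", "canter", "working",   c(4.03, 0.16), c(0.64, 0.01), c(2.57, 0.09)),
    g("horse", "canter", "extended",  c(5.28, 0.14), c(0.62, 0.01), c(3.26, 0.09))
  )
}

#' Look up one locomotion-parameter row
#'
#' @param gait one of "walk", "trot", "canter".
#' @param pace one of "collected", "working", "extended" ("normal" is accepted
#'   as a synonym of "working").
#' @param horse_type "pony" or "horse".
#' @return single-row data.frame from [locomotion_params()].
#' @export
locomotion_row <- function(gait, pace, horse_type) {
  pace <- if (identical(pace, "normal")) "working" else pace
  tab <- locomotion_params()
  row <- tab[tab$gait == gait & tab$pace == pace & tab$horse_type == horse_type, ]
  if (nrow(row) != 1L) {
    stop("no locomotion parameters for gait='", gait, "', pace='", pace,
         "', horse_type='", horse_type, "'")
  }
  row
}

#' Study-style subject roster
#'
#' A synthetic roster of 14 subjects mirroring the heights at withers,
#' disciplines and levels of the study population (11 dressage subjects,
#' two of them ponies, and 3 jumping subjects). The minimum collected-walk
#' speed column (used to assign horses to a group velocity profile) is not
#' published per subject and is filled with synthetic plausible values
#' inside the horse collected-walk band; it is `NA` for ponies, whose group
#' is determined by height alone.
#'
#' @return data.frame of [subject_profile()] rows.
#' @export
subject_roster <- function() {
  heights <- c(1.71, 1.68, 1.68, 1.73, 1.73, 1.80, 1.82, 1.66, 1.46, 1.32,
               1.66, 1.76, 1.71, 1.75)
  discipline <- c(rep("dressage", 11), rep("jumping", 3))
  level <- c("Intermediair", "Intermediair", "Advanced Medium",
             "Advanced Medium", "Intermediair", "Grand Prix", "Grand Prix",
             "Preliminary", "Medium", "Medium", "Grand Prix",
             "1.30 m", "1.50 m", "1.10 m")
  # synthetic: spread across the slow (< 1.6 m/s) / fast (>= 1.6 m/s) split
  mcw <- c(1.62, 1.48, 1.55, 1.63, 1.44, 1.68, 1.70, 1.41, NA, NA, 1.50,
           1.52, 1.61, 1.47)
  do.call(rbind, lapply(seq_along(heights), function(i) {
    as.data.frame(subject_profile(sprintf("S%02d", i), heights[i],
                                  discipline[i], level[i], mcw[i]),
                  stringsAsFactors = FALSE)
  }))
}

#' Build a subject profile
#'
#' @param subject_id identifier.
#' @param height_withers height at withers in meters (> 0). A subject with
#'   height <= 1.48 m is a pony.
#' @param discipline "dressage" or "jumping".
#' @param level free-text training level.
#' @param min_collected_walk_speed minimum speed at collected walk in m/s,
#'   used to split horses into slow/fast group velocity profiles; optional.
#' @return named list with `horse_type` derived from the height.
#' @export
subject_profile <- function(subject_id, height_withers,
                            discipline = c("dressage", "jumping"),
                            level = "", min_collected_walk_speed = NA_real_) {
  discipline <- match.arg(discipline)
  if (!is.numeric(height_withers) || height_withers <= 0) {
    stop("height_withers must be a positive number (meters)")
  }
  list(subject_id = as.character(subject_id),
       height_withers = as.numeric(height_withers),
       discipline = discipline,
       level = as.character(level),
       horse_type = if (height_withers <= 1.48) "pony" else "horse",
       min_collected_walk_speed = as.numeric(min_collected_walk_speed))
}

#' Catalog of classifiable training activities
#'
#' The 25 dressage activities and 6 jumping activities, with the gait each is
#' ridden in, the pace variant used by the generator, the movement category,
#' whether the movement has a side (bend direction or canter lead), and the
#' observed dataset proportion used to weight overall accuracies.
#'
#' @param discipline "dressage", "jumping", or "all".
#' @return data.frame with columns label, discipline, gait, pace, category,
#'   sided, proportion, samples.
#' @export
activity_catalog <- function(discipline = c("all", "dressage", "jumping")) {
  discipline <- match.arg(discipline)
  a <- function(label, gait, pace, category, sided, proportion, samples) {
    data.frame(label = label, gait = gait, pace = pace, category = category,
               sided = sided, proportion = proportion, samples = samples,
               stringsAsFactors = FALSE)
  }
  dres <- rbind(
    a("halt",               "halt",   NA,          "halt",          FALSE,  7.56, 16175),
    a("collected_walk",     "walk",   "collected", "pace",          TRUE,   3.70,  7912),
    a("working_walk",       "walk",   "working",   "pace",          TRUE,  22.70, 48565),
    a("extended_walk",      "walk",   "extended",  "pace",          TRUE,   4.69, 10035),
    a("shoulder_in_walk",   "walk",   "collected", "lateral",       TRUE,   0.63,  1343),
    a("haunches_in_walk",   "walk",   "collected", "lateral",       TRUE,   0.29,   623),
    a("half_pass_walk",     "walk",   "collected", "lateral",       TRUE,   0.75,  1606),
    a("pirouette_walk",     "walk",   "collected", "pirouette",     TRUE,   1.24,  2652),
    a("collected_trot",     "trot",   "collected", "pace",          TRUE,   2.78,  5947),
    a("working_trot",       "trot",   "working",   "pace",          TRUE,  15.56, 33281),
    a("extended_trot",      "trot",   "extended",  "pace",          TRUE,   1.43,  3059),
    a("passage",            "trot",   NA,          "variation",     FALSE,  2.30,  4927),
    a("piaffe",             "trot",   NA,          "variation",     FALSE,  0.56,  1197),
    a("shoulder_in_trot",   "trot",   "collected", "lateral",       TRUE,   2.96,  6325),
    a("haunches_in_trot",   "trot",   "collected", "lateral",       TRUE,   2.46,  5269),
    a("leg_yield_trot",     "trot",   "working",   "lateral",       TRUE,   1.32,  2814),
    a("half_pass_trot",     "trot",   "collected", "lateral",       TRUE,   2.72,  5829),
    a("collected_canter",   "canter", "collected", "pace",          TRUE,   3.19,  6818),
    a("working_canter",     "canter", "working",   "pace",          TRUE,  14.22, 30421),
    a("extended_canter",    "canter", "extended",  "pace",          TRUE,   1.88,  4012),
    a("flying_change",      "canter", "working",   "flying_change", TRUE,   2.06,  4404),
    a("shoulder_in_canter", "canter", "collected", "lateral",       TRUE,   0.63,  1337),
    a("haunches_in_canter", "canter", "collected", "lateral",       TRUE,   0.68,  1447),
    a("half_pass_canter",   "canter", "collected", "lateral",       TRUE,   1.25,  2666),
    a("pirouette_canter",   "canter", "collected", "pirouette",     TRUE,   2.46,  5254)
  )
  dres$discipline <- "dressage"
  jump <- rbind(
    a("walk",          "walk",   "working", "pace",          FALSE, 29.56, 46835),
    a("trot",          "trot",   "working", "pace",          FALSE, 24.98, 39581),
    a("left_canter",   "canter", "working", "pace",          TRUE,  20.07, 31800),
    a("right_canter",  "canter", "working", "pace",          TRUE,  18.36, 29091),
    a("flying_change", "canter", "working", "flying_change", TRUE,   0.32,   503),
    a("jump",          "canter", "working", "jump",          TRUE,   6.70, 10611)
  )
  jump$discipline <- "jumping"
  out <- rbind(dres, jump)
  out <- out[, c("label", "discipline", "gait", "pace", "category", "sided",
                 "proportion", "samples")]
  switch(discipline,
         all = out,
         dressage = out[out$discipline == "dressage", ],
         jumping = out[out$discipline == "jumping", ])
}

#' Build an activity specification
#'
#' @param label an activity label from [activity_catalog()].
#' @param side "left", "right" or "none"; only sided movements may carry a
#'   side. For the fixed-lead jumping classes `left_canter`/`right_canter`
#'   the side is implied by the label.
#' @param discipline catalog to look the label up in.
#' @return list with label, gait, pace, category, side.
#' @export
activity_spec <- function(label, side = "none",
                          discipline = c("all", "dressage", "jumping")) {
  cat <- activity_catalog(match.arg(discipline))
  row <- cat[cat$label == label, ][1, ]
  if (is.na(row$label)) stop("unknown activity label '", label, "'")
  if (label == "left_canter") side <- "left"
  if (label == "right_canter") side <- "right"
  if (!side %in% c("left", "right", "none")) stop("invalid side '", side, "'")
  if (side != "none" && !row$sided) {
    stop("activity '", label, "' does not take a side")
  }
  list(label = row$label, gait = row$gait, pace = row$pace,
       category = row$category, side = side, discipline = row$discipline)
}

# superclass labels per specialization mode for the dressage label set
mode_table <- function() {
  cat <- activity_catalog("dressage")
  lab <- cat$label
  m1 <- ifelse(cat$gait == "halt", "halt", paste0(cat$gait, "_superclass"))
  m2 <- ifelse(cat$gait == "halt", "halt",
               paste0(cat$gait, "_superclass_with_side"))
  m3 <- character(length(lab))
  m4 <- character(length(lab))
  for (i in seq_along(lab)) {
    g <- cat$gait[i]; cg <- cat$category[i]
    if (g == "halt") { m3[i] <- "halt"; m4[i] <- "halt"; next }
    m3[i] <- switch(cg,
      pace = paste0(g, "_paces"),
      lateral = , pirouette = , variation = , flying_change = ,
      jump = paste0(g, "_movements"))
    m4[i] <- switch(cg,
      pace = paste0(g, "_paces"),
      lateral = paste0(g, "_lateral_movements"),
      pirouette = paste0("pirouette_", g),
      variation = "variations_on_the_trot_gait",
      flying_change = "flying_change")
  }
  data.frame(label = lab, mode1 = m1, mode2 = m2, mode3 = m3, mode4 = m4,
             mode5 = lab, stringsAsFactors = FALSE)
}

#' Map a fine dressage label to its superclass at a specialization mode
#'
#' Mode 1 keeps halt plus the gait superclasses; mode 2 keeps the gait
#' superclasses annotated with side; mode 3 separates paces from movements
#' within each gait; mode 4 further separates lateral movements, pirouettes,
#' gait variations and flying change; mode 5 is the full fine label set.
#'
#' @param label fine dressage label(s).
#' @param mode integer 1..5.
#' @return character vector of superclass labels.
#' @export
map_to_mode <- function(label, mode) {
  if (!is.numeric(mode) || length(mode) != 1L || !mode %in% 1:5) {
    stop("mode must be a single integer in 1..5")
  }
  tab <- mode_table()
  idx <- match(label, tab$label)
  if (anyNA(idx)) {
    stop("unknown dressage label(s): ",
         paste(label[is.na(idx)], collapse = ", "))
  }
  tab[[paste0("mode", mode)]][idx]
}
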