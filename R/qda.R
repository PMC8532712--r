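# ---- phase 4: pace discrimination on (height, velocity) ----------------

PACE_LEVELS <- c("collected", "working", "extended")

#' Assign a subject to a group velocity profile
#'
#' Three groups are used for walk-pace discrimination: ponies (height at
#' withers <= 1.48 m), slow horses, and fast horses (minimum speed at
#' collected walk >= 1.6 m/s).
#'
#' @param h height at withers, m (> 0).
#' @param min_collected_walk_speed minimum collected-walk speed, m/s;
#'   required for non-ponies.
#' @return "pony", "slow_horse" or "fast_horse".
#' @export
assign_group <- function(h, min_collected_walk_speed = NA_real_) {
  if (!is.numeric(h) || h <= 0) stop("height must be > 0")
  if (h <= 1.48) return("pony")
  if (is.na(min_collected_walk_speed)) {
    stop("min_collected_walk_speed is required to assign a horse ",
         "(> 1.48 m) to a group velocity profile")
  }
  if (min_collected_walk_speed >= 1.6) "fast_horse" else "slow_horse"
}

# quadratic discriminant fit on a feature matrix; uniform priors
qda_fit <- function(X, y, ridge = 1e-8) {
  classes <- PACE_LEVELS[PACE_LEVELS %in% unique(y)]
  if (length(classes) == 0) classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least two pace classes")
  fits <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    if (nrow(Xi) < 3) stop("fewer than 3 samples for pace class '", cl, "'")
    S <- stats::cov(Xi)
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok || det(S) < 1e-12) {
      warning("singular covariance for class '", cl,
              "'; adding ridge regularization")
      S <- S + diag(max(ridge, 1e-6 * mean(diag(S))), ncol(X))
    }
    Sinv <- solve(S)
    list(mean = colMeans(Xi), cov = S, inv = Sinv,
         logdet = determinant(S, logarithm = TRUE)$modulus[1])
  })
  names(fits) <- classes
  structure(list(classes = classes, fits = fits,
                 priors = stats::setNames(rep(1 / length(classes),
                                              length(classes)), classes)),
            class = "eg_qda")
}

# log posterior (up to a constant) per class for rows of X
qda_log_posterior <- function(model, X) {
  lp <- vapply(model$classes, function(cl) {
    f <- model$fits[[cl]]
    d <- sweep(X, 2, f$mean, "-")
    q <- rowSums((d %*% f$inv) * d)
    -0.5 * f$logdet - 0.5 * q + log(model$priors[[cl]])
  }, numeric(nrow(X)))
  matrix(lp, nrow = nrow(X), dimnames = list(NULL, model$classes))
}

#' Fit the QDA pace model for a gait
#'
#' Quadratic discriminant analysis on the two features (height at withers h,
#' velocity v) over the pace classes collected / working / extended, with
#' uniform priors. For trot and canter a single model is fitted over all
#' samples; for walk, where velocities of different horses overlap, one model
#' is fitted per group velocity profile (pony, slow horse, fast horse).
#'
#' @param samples data.frame with columns `h`, `v`, `pace`, and `group` for
#'   walk (see [sample_pace_dataset()]).
#' @param gait "walk", "trot" or "canter".
#' @return object of class `eg_pace_model`.
#' @export
fit_pace_qda <- function(samples, gait = c("canter", "trot", "walk")) {
  gait <- match.arg(gait)
  stopifnot(all(c("h", "v") %in% names(samples)))
  X <- as.matrix(samples[, c("h", "v")])
  if (gait != "walk") {
    m <- qda_fit(X, samples$pace)
    return(structure(list(gait = gait, by_group = FALSE, models = list(all = m)),
                     class = "eg_pace_model"))
  }
  if (!"group" %in% names(samples)) {
    stop("walk pace samples need a 'group' column (group velocity profile)")
  }
  groups <- unique(samples$group)
  models <- lapply(groups, function(g) {
    idx <- samples$group == g
    qda_fit(X[idx, , drop = FALSE], samples$pace[idx])
  })
  names(models) <- groups
  structure(list(gait = gait, by_group = TRUE, models = models),
            class = "eg_pace_model")
}

#' Predict pace from height and velocity
#'
#' Maximum-posterior class under the fitted quadratic discriminant model;
#' exact posterior ties resolve to the earlier pace in the order collected,
#' working, extended.
#'
#' @param model an `eg_pace_model` from [fit_pace_qda()].
#' @param h height(s) at withers, m.
#' @param v velocity(ies), m/s.
#' @param group group velocity profile per sample; required for walk models.
#' @return data.frame with `pace` and posterior probabilities per class.
#' @export
predict_pace <- function(model, h, v, group = NULL) {
  if (!inherits(model, "eg_pace_model")) stop("model is not a fitted pace model")
  X <- cbind(h = h, v = v)
  if (!model$by_group) {
    return(qda_predict_one(model$models$all, X))
  }
  if (is.null(group)) stop("walk pace prediction needs the group profile")
  group <- rep_len(group, nrow(X))
  out <- vector("list", nrow(X))
  for (g in unique(group)) {
    m <- model$models[[g]]
    if (is.null(m)) stop("no fitted walk model for group '", g, "'")
    idx <- which(group == g)
    out[idx] <- split(qda_predict_one(m, X[idx, , drop = FALSE]),
                      seq_along(idx))
  }
  do.call(rbind, out)
}

qda_predict_one <- function(m, X) {
  lp <- qda_log_posterior(m, X)
  post <- exp(lp - apply(lp, 1, max))
  post <- post / rowSums(post)
  j <- apply(post, 1, function(r) which(r >= max(r) - 1e-12)[1])
  res <- data.frame(pace = m$classes[j], stringsAsFactors = FALSE)
  cbind(res, as.data.frame(post))
}

#' @export
print.eg_pace_model <- function(x, ...) {
  cat(sprintf("<eg_pace_model> gait %s, %s\n", x$gait,
              if (x$by_group) paste0("per-group models: ",
                                     paste(names(x$models), collapse = ", "))
              else "pooled model"))
  invisible(x)
}

#' Write pace-model parameters as readable text
#'
#' Class means, covariance matrices and priors per (group, pace class),
#' tab-delimited for inspection.
#'
#' @param model an `eg_pace_model`.
#' @param path output file.
#' @export
write_pace_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("gait\t%s", model$gait), con)
  for (g in names(model$models)) {
    m <- model$models[[g]]
    for (cl in m$classes) {
      f <- m$fits[[cl]]
      writeLines(sprintf("group\t%s\tclass\t%s\tprior\t%.10g", g, cl,
                         m$priors[[cl]]), con)
      writeLines(sprintf("mean\t%.10g\t%.10g", f$mean[1], f$mean[2]), con)
      writeLines(sprintf("cov\t%.10g\t%.10g", f$cov[1, 1], f$cov[1, 2]), con)
      writeLines(sprintf("cov\t%.10g\t%.10g", f$cov[2, 1], f$cov[2, 2]), con)
    }
  }
  invisible(path)
}
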