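# ---- hybrid convolutional network -------------------------------------
#
# A small 1-D convolutional classifier/regressor over raw accelerometer
# windows, whose pooled convolutional features are fused with handcrafted
# global features before the dense layers. Implemented as plain matrix
# algebra (im2col) so training is fast on a single CPU and bit-reproducible
# under set.seed().

#' Hybrid CNN configuration
#'
#' Two convolutional layers (ReLU, the first followed by zero-padding back to
#' the input length), segment pooling (the maximum and the mean of each
#' feature map over each temporal segment; the mean is robust to the sampling
#' phase of short impact transients), flattening, fusion with z-scored global
#' features, one dense ReLU layer and a softmax (classification) or linear
#' (regression) output. Dropout (default probability 0.55) is applied to the
#' pooled convolutional features during training.
#'
#' @param n_classes number of output classes (>= 2), or 0 for regression.
#' @param n_channels input channels.
#' @param n_samples samples per window.
#' @param n_features fused global features per window.
#' @param conv_filters filters of the two convolutional layers.
#' @param kernel kernel width, samples.
#' @param dense dense layer width.
#' @param dropout dropout probability on the pooled convolutional features.
#' @param pool_segments number of temporal segments for max-pooling.
#' @param lr,batch_size,epochs,patience,val_fraction optimizer settings
#'   (adaptive-moment optimizer; early stopping on validation loss).
#' @param min_loss validation loss at which training is considered converged
#'   and stops (mean cross-entropy for classification, standardized MSE for
#'   regression).
#' @param seed seed for weight initialization.
#' @return list of class `eg_cnn_config`.
#' @export
classifier_config <- function(n_classes, n_channels, n_samples, n_features,
                              conv_filters = c(32, 64), kernel = 5,
                              dense = 64, dropout = 0.55, pool_segments = 4,
                              lr = 1e-3, batch_size = 32, epochs = 100,
                              patience = 8, val_fraction = 0.15,
                              min_loss = 1e-3, seed = 1) {
  task <- if (n_classes == 0) "regression" else "classification"
  if (task == "classification" && n_classes < 2) {
    stop("n_classes must be >= 2 for classification")
  }
  if (n_channels < 1 || n_samples < 2 * kernel || n_features < 0) {
    stop("non-positive or inconsistent input dimensions")
  }
  if (length(conv_filters) != 2 || any(conv_filters < 1)) {
    stop("conv_filters must give two positive layer widths")
  }
  if (pool_segments < 1 || pool_segments > n_samples - kernel + 1) {
    stop("pool_segments out of range")
  }
  structure(list(task = task, n_classes = n_classes, n_channels = n_channels,
                 n_samples = n_samples, n_features = n_features,
                 conv_filters = conv_filters, kernel = kernel, dense = dense,
                 dropout = dropout, pool_segments = pool_segments, lr = lr,
                 batch_size = batch_size, epochs = epochs, patience = patience,
                 val_fraction = val_fraction, min_loss = min_loss,
                 seed = seed),
            class = "eg_cnn_config")
}

#' Velocity regressor configuration
#'
#' The velocity model uses the same network as the activity classifier with a
#' linear output optimized for mean squared error. Its eight input channels
#' are the two legs' tri-axial accelerations plus the autocorrelation of the
#' x-axis (downward) acceleration of each leg; the height at withers is the
#' only fused feature. Unlike the classifier, the regressor defaults to no
#' dropout: multiplicative dropout noise on the pooled amplitude features
#' directly limits the precision of a continuous velocity readout, while the
#' early-stopped small network needs no extra regularization for this task.
#' The regression defaults also allow more epochs and a longer early-stopping
#' patience, since the validation MSE is noisier than a validation
#' cross-entropy.
#'
#' @param n_samples samples per window.
#' @param dropout,epochs,patience optimizer settings; see
#'   [classifier_config()].
#' @param ... further overrides passed to [classifier_config()].
#' @return an `eg_cnn_config` with task "regression".
#' @export
velocity_config <- function(n_samples, dropout = 0, epochs = 150,
                            patience = 15, ...) {
  classifier_config(n_classes = 0, n_channels = 8, n_samples = n_samples,
                    n_features = 1, dropout = dropout, epochs = epochs,
                    patience = patience, ...)
}

#' Build an (untrained) hybrid CNN
#'
#' @param config an [classifier_config()] or [velocity_config()].
#' @param channel_scale per-channel input scaling; defaults to 1/g for
#'   acceleration channels so raw inputs are in g units.
#' @return model of class `eg_cnn`.
#' @export
build_classifier <- function(config, channel_scale = NULL) {
  stopifnot(inherits(config, "eg_cnn_config"))
  K <- config$kernel; C <- config$n_channels
  F1 <- config$conv_filters[1]; F2 <- config$conv_filters[2]
  S <- config$pool_segments
  n_out <- if (config$task == "regression") 1L else config$n_classes
  n_hidden_in <- 2 * S * F2 + config$n_features
  set.seed(config$seed)
  he <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan)), nr, nc)
  params <- list(
    W1 = he(K * C, F1, K * C), b1 = numeric(F1),
    W2 = he(K * F1, F2, K * F1), b2 = numeric(F2),
    Wd = he(n_hidden_in, config$dense, n_hidden_in), bd = numeric(config$dense),
    Wo = he(config$dense, n_out, config$dense), bo = numeric(n_out))
  if (is.null(channel_scale)) channel_scale <- rep(1 / GRAVITY, C)
  structure(list(config = config, params = params,
                 channel_scale = channel_scale,
                 feat_mu = numeric(config$n_features),
                 feat_sd = rep(1, config$n_features),
                 y_mu = 0, y_sd = 1, classes = NULL, trained = FALSE),
            class = "eg_cnn")
}

#' @export
print.eg_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<eg_cnn> %s: %d ch x %d samples + %d features -> ",
                     "conv(%d,%d; k=%d) -> pool(%d) -> dense(%d) -> %s",
                     " [dropout %.2f]%s\n"),
              cfg$task, cfg$n_channels, cfg$n_samples, cfg$n_features,
              cfg$conv_filters[1], cfg$conv_filters[2], cfg$kernel,
              cfg$pool_segments, cfg$dense,
              if (cfg$task == "regression") "linear(1)"
              else sprintf("softmax(%d)", cfg$n_classes),
              cfg$dropout, if (x$trained) " trained" else ""))
  invisible(x)
}

im2col <- function(A, K) {
  d <- dim(A); T1 <- d[1] - K + 1
  M <- matrix(0, T1 * d[2], K * d[3])
  for (cc in seq_len(d[3])) {
    for (kk in seq_len(K)) {
      M[, (cc - 1) * K + kk] <- as.vector(A[kk:(kk + T1 - 1), , cc])
    }
  }
  M
}

col2im <- function(dM, Tlen, B, C, K) {
  dA <- array(0, c(Tlen, B, C)); T1 <- Tlen - K + 1
  for (cc in seq_len(C)) {
    for (kk in seq_len(K)) {
      dA[kk:(kk + T1 - 1), , cc] <- dA[kk:(kk + T1 - 1), , cc] +
        matrix(dM[, (cc - 1) * K + kk], T1, B)
    }
  }
  dA
}

pool_bounds <- function(T2, S) {
  edges <- floor(seq(0, T2, length.out = S + 1))
  cbind(lo = edges[-(S + 1)] + 1, hi = edges[-1])
}

# forward pass over a batch; x: (T, C, B) already channel-scaled
cnn_forward <- function(model, x, feat, training = FALSE) {
  cfg <- model$config; p <- model$params
  K <- cfg$kernel; Tlen <- cfg$n_samples; S <- cfg$pool_segments
  F1 <- cfg$conv_filters[1]; F2 <- cfg$conv_filters[2]
  B <- dim(x)[3]
  A0 <- aperm(x, c(1, 3, 2))                       # (T, B, C)
  M1 <- im2col(A0, K)
  Z1 <- sweep(M1 %*% p$W1, 2, p$b1, "+")
  R1 <- pmax(Z1, 0)
  T1 <- Tlen - K + 1
  pl <- (K - 1) %/% 2
  A1 <- array(0, c(Tlen, B, F1))                   # zero-padding after conv1
  A1[(pl + 1):(pl + T1), , ] <- array(R1, c(T1, B, F1))
  M2 <- im2col(A1, K)
  Z2 <- sweep(M2 %*% p$W2, 2, p$b2, "+")
  R2 <- pmax(Z2, 0)
  T2 <- Tlen - K + 1
  A2 <- array(R2, c(T2, B, F2))
  bounds <- pool_bounds(T2, S)
  Pf <- matrix(0, B, 2 * S * F2)   # per segment: max then mean, per filter
  argmax <- matrix(0L, B * F2, S)
  for (s in seq_len(S)) {
    sl <- A2[bounds[s, 1]:bounds[s, 2], , , drop = FALSE]
    m <- matrix(sl, dim(sl)[1], B * F2)
    j <- max.col(t(m), ties.method = "first")
    vals <- m[cbind(j, seq_len(ncol(m)))]
    Pf[, (seq_len(F2) - 1) * 2 * S + s] <- matrix(vals, B, F2)
    Pf[, (seq_len(F2) - 1) * 2 * S + S + s] <- matrix(colMeans(m), B, F2)
    argmax[, s] <- bounds[s, 1] - 1L + j
  }
  mask <- NULL
  Pd <- Pf
  if (training && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    mask <- matrix(stats::rbinom(length(Pf), 1, keep) / keep, nrow(Pf))
    Pd <- Pf * mask
  }
  fs <- if (cfg$n_features > 0) {
    sweep(sweep(feat, 2, model$feat_mu, "-"), 2, model$feat_sd, "/")
  } else {
    matrix(0, B, 0)
  }
  Hin <- cbind(Pd, fs)
  Zd <- sweep(Hin %*% p$Wd, 2, p$bd, "+")
  Rd <- pmax(Zd, 0)
  Zo <- sweep(Rd %*% p$Wo, 2, p$bo, "+")
  out <- if (cfg$task == "classification") {
    e <- exp(Zo - apply(Zo, 1, max))
    e / rowSums(e)
  } else {
    Zo
  }
  list(out = out, cache = list(M1 = M1, R1 = R1, M2 = M2, R2 = R2,
                               argmax = argmax, bounds = bounds, mask = mask,
                               Hin = Hin, Zd = Zd, Rd = Rd, B = B))
}

# gradient of the loss w.r.t. parameters; dZo already includes the 1/B factor
cnn_backward <- function(model, cache, dZo) {
  cfg <- model$config; p <- model$params
  K <- cfg$kernel; Tlen <- cfg$n_samples; S <- cfg$pool_segments
  F1 <- cfg$conv_filters[1]; F2 <- cfg$conv_filters[2]
  B <- cache$B; T1 <- Tlen - K + 1; T2 <- Tlen - K + 1
  pl <- (K - 1) %/% 2
  g <- list()
  g$Wo <- crossprod(cache$Rd, dZo); g$bo <- colSums(dZo)
  dRd <- dZo %*% t(p$Wo)
  dZd <- dRd * (cache$Zd > 0)
  g$Wd <- crossprod(cache$Hin, dZd); g$bd <- colSums(dZd)
  dHin <- dZd %*% t(p$Wd)
  dPd <- dHin[, seq_len(2 * S * F2), drop = FALSE]
  if (!is.null(cache$mask)) dPd <- dPd * cache$mask
  dR2 <- matrix(0, T2 * B, F2)
  bvec <- rep(seq_len(B), F2)
  fvec <- rep(seq_len(F2), each = B)
  for (s in seq_len(S)) {
    rows <- (bvec - 1L) * T2 + cache$argmax[, s]
    idx <- rows + (fvec - 1L) * (T2 * B)
    dR2[idx] <- dR2[idx] + as.vector(dPd[, (seq_len(F2) - 1) * 2 * S + s])
    # mean-pool gradient spreads evenly over the segment
    lo <- cache$bounds[s, 1]; hi <- cache$bounds[s, 2]
    dmean <- dPd[, (seq_len(F2) - 1) * 2 * S + S + s, drop = FALSE] /
      (hi - lo + 1)
    for (tt in lo:hi) {
      ridx <- (bvec - 1L) * T2 + tt + (fvec - 1L) * (T2 * B)
      dR2[ridx] <- dR2[ridx] + as.vector(dmean)
    }
  }
  dZ2 <- dR2 * (cache$R2 > 0)
  g$W2 <- crossprod(cache$M2, dZ2); g$b2 <- colSums(dZ2)
  dM2 <- dZ2 %*% t(p$W2)
  dA1 <- col2im(dM2, Tlen, B, F1, K)
  dR1 <- matrix(dA1[(pl + 1):(pl + T1), , ], T1 * B, F1)
  dZ1 <- dR1 * (cache$R1 > 0)
  g$W1 <- crossprod(cache$M1, dZ1); g$b1 <- colSums(dZ1)
  g
}

scale_channels <- function(x, scale) {
  d <- dim(x)
  x * array(rep(rep(scale, each = d[1]), d[3]), d)
}

adam_init <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# core training loop on a prepared training set; y integer classes or numeric
cnn_fit <- function(model, x, feat, y, seed) {
  cfg <- model$config
  set.seed(seed)
  N <- dim(x)[3]
  x <- scale_channels(x, model$channel_scale)
  if (cfg$n_features > 0) {
    model$feat_mu <- colMeans(feat)
    sdv <- apply(feat, 2, stats::sd)
    model$feat_sd <- ifelse(is.na(sdv) | sdv < 1e-12, 1, sdv)
  }
  if (cfg$task == "regression") {
    model$y_mu <- mean(y); model$y_sd <- max(stats::sd(y), 1e-12)
    ys <- (y - model$y_mu) / model$y_sd
  } else {
    ys <- as.integer(y)
  }
  n_val <- max(2L, round(cfg$val_fraction * N))
  val_idx <- sample(N, n_val)
  tr_idx <- setdiff(seq_len(N), val_idx)
  xv <- x[, , val_idx, drop = FALSE]; fv <- feat[val_idx, , drop = FALSE]
  yv <- ys[val_idx]
  st <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0)
  stall <- 0
  loss_of <- function(out, yy) {
    if (cfg$task == "classification") {
      -mean(log(pmax(out[cbind(seq_along(yy), yy)], 1e-12)))
    } else {
      mean((out[, 1] - yy)^2)
    }
  }
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    bs <- min(cfg$batch_size, length(ord))
    starts <- seq(1, length(ord), by = bs)
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + bs - 1, length(ord))]
      xb <- x[, , idx, drop = FALSE]
      fb <- feat[idx, , drop = FALSE]
      yb <- ys[idx]
      fw <- cnn_forward(model, xb, fb, training = TRUE)
      B <- length(idx)
      dZo <- if (cfg$task == "classification") {
        Y <- matrix(0, B, cfg$n_classes)
        Y[cbind(seq_len(B), yb)] <- 1
        (fw$out - Y) / B
      } else {
        matrix(2 * (fw$out[, 1] - yb) / B, B, 1)
      }
      gr <- cnn_backward(model, fw$cache, dZo)
      upd <- adam_step(model$params, gr, st, cfg$lr)
      model$params <- upd$params; st <- upd$state
    }
    vout <- cnn_forward(model, xv, fv, training = FALSE)$out
    vloss <- loss_of(vout, yv)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = model$params, epoch = epoch)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= cfg$patience) break
    }
    if (vloss < cfg$min_loss) break
  }
  model$params <- best$params
  model$trained <- TRUE
  model$val_loss <- best$loss
  model$epochs_run <- best$epoch
  model
}

#' Train the hybrid CNN classifier with a stratified held-out split
#'
#' Splits the windows into disjoint training (default 66%) and test (34%)
#' sets stratified by class, fits the network on the training set (with an
#' internal validation split for early stopping), and reports held-out
#' accuracy and the confusion matrix. Fully reproducible given the seed.
#'
#' @param model an untrained [build_classifier()] model.
#' @param x array (samples x channels x windows) of raw windows, m/s^2.
#' @param features matrix (windows x features) of global features.
#' @param labels factor or character vector of window labels.
#' @param split_fraction fraction used for training.
#' @param seed integer seed controlling split, shuffling and dropout.
#' @return list with elements model, accuracy, confusion, predicted,
#'   test_idx.
#' @export
train_classifier <- function(model, x, features, labels,
                             split_fraction = 0.66, seed = 1) {
  stopifnot(inherits(model, "eg_cnn"),
            model$config$task == "classification")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (length(classes) != model$config$n_classes) {
    stop("model expects ", model$config$n_classes, " classes, got ",
         length(classes))
  }
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("class with fewer than 2 windows: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  set.seed(seed)
  tr <- unlist(lapply(classes, function(cl) {
    idx <- which(labels == cl)
    sample(idx, max(1L, round(split_fraction * length(idx))))
  }))
  te <- setdiff(seq_along(labels), tr)
  model$classes <- classes
  y <- match(labels, classes)
  model <- cnn_fit(model, x[, , tr, drop = FALSE],
                   features[tr, , drop = FALSE], y[tr], seed = seed)
  pred <- predict(model, x[, , te, drop = FALSE],
                  features[te, , drop = FALSE])
  cm <- confusion(labels[te], pred$label, classes = classes)
  list(model = model, accuracy = cm$overall_accuracy, confusion = cm,
       predicted = pred, test_idx = te)
}

#' Predict activity labels (or velocities) for windows
#'
#' @param object a trained `eg_cnn`.
#' @param x array (samples x channels x windows).
#' @param features matrix (windows x features).
#' @param ... unused.
#' @return for classifiers, a data.frame with `label`, `prob` (probability of
#'   the chosen label; ties go to the lowest class index) and the full
#'   posterior matrix as attribute "posterior"; for regressors, a numeric
#'   vector of velocities (m/s).
#' @export
predict.eg_cnn <- function(object, x, features, ...) {
  cfg <- object$config
  if (!object$trained) stop("model is not trained")
  if (dim(x)[1] != cfg$n_samples || dim(x)[2] != cfg$n_channels) {
    stop("input shape (", dim(x)[1], " x ", dim(x)[2],
         ") does not match model (", cfg$n_samples, " x ", cfg$n_channels, ")")
  }
  if (nrow(features) != dim(x)[3]) stop("features/windows count mismatch")
  xs <- scale_channels(x, object$channel_scale)
  out <- cnn_forward(object, xs, features, training = FALSE)$out
  if (cfg$task == "regression") {
    return(out[, 1] * object$y_sd + object$y_mu)
  }
  j <- apply(out, 1, which.max)
  res <- data.frame(label = object$classes[j],
                    prob = out[cbind(seq_len(nrow(out)), j)],
                    stringsAsFactors = FALSE)
  colnames(out) <- object$classes
  attr(res, "posterior") <- out
  res
}

#' Build velocity-regressor inputs from windows
#'
#' Stacks the six acceleration channels with the autocorrelation function of
#' each leg's x-axis acceleration (lag 0 .. window length - 1, so the two
#' autocorrelation channels are length-matched to the raw window), and
#' collects the height feature and ground-truth velocities.
#'
#' @param windows list of `eg_window` with two front sensors.
#' @return list with `x` (samples x 8 x windows), `height` (m), `velocity`
#'   (m/s), `gait` per window.
#' @export
velocity_inputs <- function(windows) {
  stopifnot(length(windows) > 0)
  n <- ncol(windows[[1]]$signal)
  cat <- activity_catalog("all")
  x <- array(0, c(n, 8, length(windows)))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    sig <- w$signal
    if (nrow(sig) < 6) stop("velocity model needs two tri-axial sensors")
    xl <- autocorrelation(sig[1, ], w$sampling_rate)$acf
    xr <- autocorrelation(sig[4, ], w$sampling_rate)$acf
    x[, 1:6, i] <- t(sig[1:6, ])
    x[, 7, i] <- xl[seq_len(n)]
    x[, 8, i] <- xr[seq_len(n)]
  }
  list(x = x,
       height = vapply(windows, function(w) w$height, numeric(1)),
       velocity = vapply(windows, function(w) w$truth_velocity, numeric(1)),
       gait = cat$gait[match(vapply(windows, function(w) w$label,
                                    character(1)), cat$label)])
}

#' Train the velocity regressor for one gait
#'
#' Fits the hybrid network (8 signal channels + height feature, mean squared
#' error objective) on a random held-out split and reports held-out RMSE and
#' R-squared. One regressor is trained per gait; see
#' [train_velocity_models()].
#'
#' @param x array (samples x 8 x windows) from [velocity_inputs()].
#' @param height height at withers per window, m.
#' @param velocity ground-truth velocity per window, m/s.
#' @param config optional [velocity_config()]; defaults to the window size.
#' @param split_fraction training fraction.
#' @param seed integer seed.
#' @return list with model, rmse, r2, predicted, truth, test_idx.
#' @export
train_velocity_regressor <- function(x, height, velocity, config = NULL,
                                     split_fraction = 0.66, seed = 1) {
  n <- dim(x)[3]
  if (n < 20) stop("need at least 20 windows to train a velocity regressor")
  if (is.null(config)) config <- velocity_config(n_samples = dim(x)[1],
                                                 seed = seed)
  scale <- c(rep(1 / GRAVITY, 6), 1, 1)  # ACF channels are already unit scale
  model <- build_classifier(config, channel_scale = scale)
  set.seed(seed)
  tr <- sample(n, max(1L, round(split_fraction * n)))
  te <- setdiff(seq_len(n), tr)
  feat <- matrix(height, ncol = 1)
  model <- cnn_fit(model, x[, , tr, drop = FALSE],
                   feat[tr, , drop = FALSE], velocity[tr], seed = seed)
  pred <- predict(model, x[, , te, drop = FALSE], feat[te, , drop = FALSE])
  met <- regression_metrics(velocity[te], pred)
  list(model = model, rmse = met$rmse, r2 = met$r2, predicted = pred,
       truth = velocity[te], test_idx = te)
}

#' Train per-gait velocity regressors
#'
#' @param windows list of `eg_window` covering one or more gaits; each gait
#'   needs at least 20 windows.
#' @param ... passed to [train_velocity_regressor()].
#' @return named list of per-gait fits (walk/trot/canter as present).
#' @export
train_velocity_models <- function(windows, ...) {
  inp <- velocity_inputs(windows)
  gaits <- setdiff(unique(inp$gait), "halt")
  out <- list()
  for (g in gaits) {
    idx <- which(inp$gait == g)
    if (length(idx) < 20) {
      stop("fewer than 20 windows for gait '", g, "'")
    }
    out[[g]] <- train_velocity_regressor(inp$x[, , idx, drop = FALSE],
                                         inp$height[idx],
                                         inp$velocity[idx], ...)
  }
  out
}

#' Convert a list of windows to model inputs
#'
#' @param windows list of `eg_window`.
#' @param features compute handcrafted global features per window.
#' @return list with `x` (samples x channels x windows), `features`,
#'   `labels`, `sides`, `velocity`, `height`.
#' @export
windows_to_arrays <- function(windows, features = TRUE) {
  stopifnot(length(windows) > 0)
  n <- ncol(windows[[1]]$signal)
  C <- nrow(windows[[1]]$signal)
  x <- array(0, c(n, C, length(windows)))
  for (i in seq_along(windows)) x[, , i] <- t(windows[[i]]$signal)
  f <- if (features) {
    t(vapply(windows, extract_features, numeric(4 * C)))
  } else {
    matrix(0, length(windows), 0)
  }
  list(x = x, features = f,
       labels = vapply(windows, function(w) w$label, character(1)),
       sides = vapply(windows, function(w) w$side, character(1)),
       velocity = vapply(windows, function(w) w$truth_velocity, numeric(1)),
       height = vapply(windows, function(w) w$height, numeric(1)))
}

#' Save / load a fitted hybrid CNN as plain text
#'
#' The model directory holds the configuration and scalers in DCF text files
#' and each weight array as a text matrix written with 17 significant digits,
#' so reloading reproduces predictions bit-exactly.
#'
#' @param model a trained `eg_cnn`.
#' @param dir directory to create.
#' @export
save_cnn <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  meta <- c(lapply(cfg, function(v) paste(v, collapse = ",")),
            list(channel_scale = paste(fmt17(model$channel_scale), collapse = ","),
                 feat_mu = paste(fmt17(model$feat_mu), collapse = ","),
                 feat_sd = paste(fmt17(model$feat_sd), collapse = ","),
                 y_mu = fmt17(model$y_mu), y_sd = fmt17(model$y_sd),
                 classes = paste(model$classes, collapse = ","),
                 trained = model$trained))
  write.dcf(as.data.frame(meta, stringsAsFactors = FALSE),
            file.path(dir, "model.dcf"))
  for (nm in names(model$params)) {
    w <- model$params[[nm]]
    utils::write.table(fmt17(as.matrix(w)), file.path(dir, paste0(nm, ".txt")),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

fmt17 <- function(x) formatC(x, digits = 17, format = "e")

#' @rdname save_cnn
#' @param dir model directory written by [save_cnn()].
#' @return the restored `eg_cnn`.
#' @export
load_cnn <- function(dir) {
  meta <- as.list(read.dcf(file.path(dir, "model.dcf"))[1, ])
  num <- function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ",")[[1]])
  }
  cfg <- classifier_config(
    n_classes = as.integer(meta$n_classes),
    n_channels = as.integer(meta$n_channels),
    n_samples = as.integer(meta$n_samples),
    n_features = as.integer(meta$n_features),
    conv_filters = as.integer(num(meta$conv_filters)),
    kernel = as.integer(meta$kernel), dense = as.integer(meta$dense),
    dropout = as.numeric(meta$dropout),
    pool_segments = as.integer(meta$pool_segments),
    lr = as.numeric(meta$lr), batch_size = as.integer(meta$batch_size),
    epochs = as.integer(meta$epochs), patience = as.integer(meta$patience),
    val_fraction = as.numeric(meta$val_fraction),
    min_loss = as.numeric(meta$min_loss %||% 1e-3),
    seed = as.integer(meta$seed))
  model <- build_classifier(cfg, channel_scale = num(meta$channel_scale))
  model$feat_mu <- num(meta$feat_mu)
  model$feat_sd <- num(meta$feat_sd)
  model$y_mu <- as.numeric(meta$y_mu)
  model$y_sd <- as.numeric(meta$y_sd)
  if (nzchar(meta$classes)) {
    model$classes <- strsplit(meta$classes, ",")[[1]]
  }
  for (nm in names(model$params)) {
    w <- as.matrix(utils::read.table(file.path(dir, paste0(nm, ".txt"))))
    dimnames(w) <- NULL
    if (is.null(dim(model$params[[nm]]))) w <- as.numeric(w)
    model$params[[nm]] <- w
  }
  model$trained <- as.logical(meta$trained)
  model
}
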