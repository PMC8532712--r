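# shared helpers for building small fixtures in code

# a reduced classifier configuration that trains in seconds
small_cfg <- function(n_classes, x, features, seed = 1, ...) {
  args <- list(n_classes = n_classes, n_channels = dim(x)[2],
               n_samples = dim(x)[1], n_features = ncol(features),
               conv_filters = c(8, 16), dense = 16, batch_size = 16,
               epochs = 40, seed = seed)
  do.call(classifier_config, utils::modifyList(args, list(...)))
}

# windows for a named count vector of dressage activities
gen_windows <- function(acts, seed = 1, ...) {
  generate_dataset(generator_config("dressage", activities = acts, ...),
                   seed = seed)$windows
}

# direct O(n^2) autocorrelation oracle (biased normalized estimator)
acf_oracle <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  vapply(0:(n - 1), function(l) {
    sum(xc[1:(n - l)] * xc[(1 + l):n]) / denom
  }, numeric(1))
}

# brute-force Gaussian posterior for a fitted two-feature QDA
qda_posterior_oracle <- function(model, X) {
  dens <- vapply(model$classes, function(cl) {
    f <- model$fits[[cl]]
    det2 <- f$cov[1, 1] * f$cov[2, 2] - f$cov[1, 2] * f$cov[2, 1]
    inv <- matrix(c(f$cov[2, 2], -f$cov[2, 1], -f$cov[1, 2], f$cov[1, 1]),
                  2, 2) / det2
    apply(X, 1, function(x) {
      d <- x - f$mean
      exp(-0.5 * (d %*% inv %*% d)) / (2 * pi * sqrt(det2)) *
        model$priors[[cl]]
    })
  }, numeric(nrow(X)))
  dens <- matrix(dens, nrow = nrow(X))
  dens / rowSums(dens)
}
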