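# Independent oracles used across test files. Each deliberately takes a
# different computational route from the implementation it checks.

# Exhaustive UFS oracle: recomputes all pairwise correlations and all
# candidate multiple-R2 values (via lm()) at every step.
oracle_ufs <- function(x, r2_max) {
  p <- ncol(x)
  cm <- abs(cor(x))
  diag(cm) <- Inf
  best <- c(1L, 2L); best_val <- Inf
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      if (cm[i, j] < best_val) { best_val <- cm[i, j]; best <- c(i, j) }
    }
  }
  sel <- best
  repeat {
    rem <- setdiff(seq_len(p), sel)
    if (length(rem) == 0L) return(list(selected = sel, reason = "exhausted"))
    r2 <- vapply(rem, function(j) {
      summary(lm(x[, j] ~ x[, sel]))$r.squared
    }, numeric(1))
    k <- which.min(r2)
    if (r2[k] >= r2_max) {
      return(list(selected = sel, reason = "r2_max_reached"))
    }
    sel <- c(sel, rem[k])
  }
}

# Closed-form Bayesian ridge with grouped priors: MAP weights via direct
# solve, effective parameters from the posterior covariance, and the EXACT
# log marginal likelihood via the n x n marginal covariance (a different
# identity from the package's Laplace expression, which is exact for
# linear models).
oracle_bayes_ridge <- function(x, y, alpha, beta) {
  xd <- cbind(x, 1)
  a0 <- diag(alpha)
  sigma <- solve(beta * crossprod(xd) + a0)
  w_map <- drop(beta * sigma %*% crossprod(xd, y))
  gamma <- 1 - alpha * diag(sigma)
  e_w <- 0.5 * w_map^2
  alpha_new <- gamma / (2 * e_w)
  resid <- y - drop(xd %*% w_map)
  beta_new <- (length(y) - sum(gamma)) / sum(resid^2)
  cmar <- diag(length(y)) / beta + xd %*% solve(a0) %*% t(xd)
  log_ev <- -0.5 * drop(crossprod(y, solve(cmar, y))) -
    0.5 * as.numeric(determinant(cmar)$modulus) -
    length(y) / 2 * log(2 * pi)
  list(w = w_map, gamma = gamma, alpha_new = alpha_new,
       beta_new = beta_new, log_evidence = log_ev)
}

# Noise-free generator configuration with a single shared class line, so
# the truth is exactly linear in the log Kow descriptor.
noise_free_linear_config <- function(seed = 1L, slope = 0.42, intercept = 1.07) {
  generator_config(
    class_slopes = c(uncharged = slope, positive = slope,
                     negative = slope, zwitterion = slope),
    class_intercepts = c(uncharged = intercept, positive = intercept,
                         negative = intercept, zwitterion = intercept),
    nonlinearity_amplitude = 0, compound_noise_sd = 0,
    replicate_spread_target = 0, seed = seed
  )
}

# Noise-free config keeping the default class-specific truth.
noise_free_class_config <- function(seed = 1L) {
  generator_config(nonlinearity_amplitude = 0, compound_noise_sd = 0,
                   replicate_spread_target = 0, seed = seed)
}

random_bnn_arch <- function(p = 5L, h = 3L) {
  bnn_architecture(p, h)
}

bnn_n_weights <- function(arch) sorbkd:::bnn_groups(arch)$n_weights
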