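# Bayesian-regularised multilayer perceptrons under the evidence
# framework, with automatic relevance determination (ARD).
#
# Architecture: inputs -> one tanh hidden layer -> single linear output.
# Weight vector packing (n_hidden = h, n_inputs = p):
#   [ W1 (h x p, stacked by input column) | b1 (h) | v (h) | b2 (1) ]
# ARD weight groups: one group per input (that input's fan-out column of
# W1), one group for the hidden biases, one for the hidden->output
# weights, one for the output bias.
#
# A linear architecture (n_hidden = 0: direct input->output map, one
# group per input weight plus a bias group) is provided as a test hook:
# in that mode the evidence framework coincides exactly with closed-form
# Bayesian ridge regression.

#' Network architecture for a Bayesian regression perceptron
#'
#' @param n_inputs Number of input nodes (descriptors).
#' @param n_hidden Hidden-layer size; 2-5 are the sizes typically scanned.
#'   `n_hidden = 0` requests the linear (no hidden layer) architecture, a
#'   testing hook whose evidence framework has an exact Bayesian
#'   linear-regression counterpart.
#' @param input_names Optional descriptor names (used by ARD rankings).
#' @return An object of class `kd_bnn_architecture`.
#' @export
bnn_architecture <- function(n_inputs, n_hidden = 2L, input_names = NULL) {
  check_count(n_inputs, "n_inputs")
  if (!is.numeric(n_hidden) || n_hidden < 0 || n_hidden != round(n_hidden)) {
    abort("`n_hidden` must be a non-negative integer.",
          class = "sorbkd_config_error")
  }
  if (is.null(input_names)) input_names <- sprintf("x%02d", seq_len(n_inputs))
  if (length(input_names) != n_inputs) {
    abort("`input_names` must have length `n_inputs`.",
          class = "sorbkd_config_error")
  }
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden),
                 input_names = input_names),
            class = "kd_bnn_architecture")
}

# Number of weights and ARD group index list for an architecture.
bnn_groups <- function(arch) {
  p <- arch$n_inputs
  h <- arch$n_hidden
  if (h == 0L) {
    nw <- p + 1L
    groups <- c(lapply(seq_len(p), identity), list(p + 1L))
    names(groups) <- c(arch$input_names, "output_bias")
  } else {
    nw <- h * p + h + h + 1L
    groups <- lapply(seq_len(p), function(i) ((i - 1L) * h + 1L):(i * h))
    groups <- c(groups,
                list(h * p + seq_len(h)),            # hidden biases
                list(h * p + h + seq_len(h)),        # hidden -> output
                list(nw))                            # output bias
    names(groups) <- c(arch$input_names, "hidden_bias", "output_weights",
                       "output_bias")
  }
  list(n_weights = nw, groups = groups)
}

bnn_unpack <- function(arch, w) {
  p <- arch$n_inputs; h <- arch$n_hidden
  if (h == 0L) {
    return(list(w1 = matrix(w[seq_len(p)], 1L, p), b2 = w[p + 1L]))
  }
  list(
    w1 = matrix(w[seq_len(h * p)], h, p),   # column i = fan-out of input i
    b1 = w[h * p + seq_len(h)],
    v = w[h * p + h + seq_len(h)],
    b2 = w[h * p + 2L * h + 1L]
  )
}

#' Forward pass of a Bayesian network
#'
#' Computes `yhat = b2 + sum_j v_j tanh(b1_j + sum_i w_ij x_i)` (or the
#' direct linear map for the linear architecture). Predictions are on the
#' centred-target scale used internally; add the model's `y_center` (the
#' `predict()` method does this) for original-scale output.
#'
#' @param arch A `kd_bnn_architecture`.
#' @param w Packed weight vector.
#' @param x Input matrix (rows = cases, columns = inputs).
#' @return Numeric vector of network outputs.
#' @export
bnn_forward <- function(arch, w, x) {
  x <- as.matrix(x)
  if (ncol(x) != arch$n_inputs) {
    abort(sprintf("Input has %d columns; architecture expects %d.",
                  ncol(x), arch$n_inputs),
          class = "sorbkd_input_error")
  }
  wp <- bnn_unpack(arch, w)
  if (arch$n_hidden == 0L) {
    return(drop(x %*% wp$w1[1L, ] + wp$b2))
  }
  a <- sweep(x %*% t(wp$w1), 2, wp$b1, "+")   # n x h pre-activations
  hmat <- tanh(a)
  drop(hmat %*% wp$v + wp$b2)
}

#' Regularized error and exact gradient
#'
#' `E_total = beta E_D + sum_g alpha_g E_W(g)` with
#' `E_D = 0.5 sum (y - yhat)^2` and `E_W(g) = 0.5 sum_{w in g} w^2`.
#' The gradient is exact (back-propagation for the data term).
#'
#' @param arch Architecture.
#' @param w Packed weights.
#' @param x,y Training inputs and (centred) targets.
#' @param alpha Per-group prior precisions (length = number of groups).
#' @param beta Noise precision.
#' @return List with `value`, `gradient`, `e_d`, `e_w` (per group).
#' @export
bnn_error <- function(arch, w, x, y, alpha, beta) {
  x <- as.matrix(x)
  gi <- bnn_groups(arch)
  if (length(alpha) != length(gi$groups)) {
    abort(sprintf("`alpha` must have %d entries (one per weight group).",
                  length(gi$groups)),
          class = "sorbkd_input_error")
  }
  wp <- bnn_unpack(arch, w)
  n <- nrow(x)
  if (arch$n_hidden == 0L) {
    yhat <- drop(x %*% wp$w1[1L, ] + wp$b2)
    r <- yhat - y
    g_w1 <- drop(crossprod(x, r))
    grad_data <- c(g_w1, sum(r))
  } else {
    a <- sweep(x %*% t(wp$w1), 2, wp$b1, "+")
    hmat <- tanh(a)
    yhat <- drop(hmat %*% wp$v + wp$b2)
    r <- yhat - y
    dh <- 1 - hmat^2
    delta <- (r %o% wp$v) * dh            # n x h
    g_w1 <- crossprod(delta, x)           # h x p
    grad_data <- c(as.numeric(g_w1), colSums(delta),
                   drop(crossprod(hmat, r)), sum(r))
  }
  e_d <- 0.5 * sum(r^2)
  alpha_expanded <- numeric(gi$n_weights)
  e_w <- numeric(length(gi$groups))
  for (g in seq_along(gi$groups)) {
    idx <- gi$groups[[g]]
    alpha_expanded[idx] <- alpha[g]
    e_w[g] <- 0.5 * sum(w[idx]^2)
  }
  value <- beta * e_d + sum(alpha * e_w)
  gradient <- beta * grad_data + alpha_expanded * w
  list(value = value, gradient = gradient, e_d = e_d,
       e_w = setNames(e_w, names(gi$groups)))
}

# Per-case Jacobian d yhat / d w (n x n_weights), for the Gauss-Newton
# Hessian of the data term.
bnn_jacobian <- function(arch, w, x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (arch$n_hidden == 0L) {
    return(cbind(x, rep(1, n)))
  }
  wp <- bnn_unpack(arch, w)
  a <- sweep(x %*% t(wp$w1), 2, wp$b1, "+")
  hmat <- tanh(a)
  dh <- 1 - hmat^2
  vdh <- sweep(dh, 2, wp$v, "*")          # n x h: v_j (1 - h_j^2)
  h_dim <- arch$n_hidden
  p <- arch$n_inputs
  jw1 <- matrix(0, n, h_dim * p)
  for (i in seq_len(p)) {
    jw1[, ((i - 1L) * h_dim + 1L):(i * h_dim)] <- vdh * x[, i]
  }
  cbind(jw1, vdh, hmat, rep(1, n))
}

# Regularized Gauss-Newton Hessian A = beta J'J + diag(alpha by group),
# with its eigendecomposition (floored at eig_floor).
bnn_hessian <- function(arch, w, x, alpha, beta, eig_floor = 1e-10) {
  gi <- bnn_groups(arch)
  jac <- bnn_jacobian(arch, w, x)
  alpha_expanded <- numeric(gi$n_weights)
  for (g in seq_along(gi$groups)) alpha_expanded[gi$groups[[g]]] <- alpha[g]
  a_mat <- beta * crossprod(jac) + diag(alpha_expanded, gi$n_weights)
  eig <- eigen(a_mat, symmetric = TRUE)
  floored <- any(eig$values < eig_floor)
  vals <- pmax(eig$values, eig_floor)
  list(a = a_mat, vectors = eig$vectors, values = vals, floored = floored)
}

#' Deterministic MAP training of a network at fixed hyperparameters
#'
#' Minimizes the regularized error with a quasi-Newton (BFGS) optimizer
#' using the exact gradient, with a fixed iteration cap; deterministic
#' given the starting weights. The final error never exceeds the initial
#' error.
#'
#' @param arch Architecture.
#' @param w Starting weights.
#' @param x,y Training data (targets centred).
#' @param alpha,beta Hyperparameters.
#' @param max_iter Inner iteration cap (default 100).
#' @return List with `w`, `value`, `initial_value`, `converged`.
#' @export
bnn_train_map <- function(arch, w, x, y, alpha, beta, max_iter = 100L) {
  fn <- function(wv) {
    v <- bnn_error(arch, wv, x, y, alpha, beta)$value
    if (!is.finite(v)) {
      abort("Non-finite error during optimization; check inputs and hyperparameters.",
            class = "sorbkd_numeric_error")
    }
    v
  }
  gr <- function(wv) bnn_error(arch, wv, x, y, alpha, beta)$gradient
  initial <- fn(w)
  res <- optim(w, fn, gr, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-12))
  # optim never returns a worse point than it was given
  out_w <- if (res$value <= initial) res$par else w
  list(w = out_w, value = min(res$value, initial), initial_value = initial,
       converged = res$convergence == 0L)
}

#' Evidence-framework hyperparameter re-estimation
#'
#' At a (local) minimum of the regularized error, computes the
#' Gauss-Newton Hessian `A = beta J'J + diag(alpha)`, the effective
#' parameter counts `gamma_g = |g| - alpha_g trace_g(A^-1)` and the
#' MacKay updates `alpha_g <- gamma_g / (2 E_W(g))`,
#' `beta <- (N - sum gamma) / (2 E_D)`. Updates are clamped to
#' `[1e-8, 1e8]` (alpha) and a `1e-8` floor (beta); near-singular
#' Hessian directions are eigenvalue-floored and flagged.
#'
#' @param arch Architecture.
#' @param w Weights at the MAP point.
#' @param x,y Training data (targets centred).
#' @param alpha,beta Current hyperparameters.
#' @return List with `alpha`, `beta`, `gamma` (per group, clamped to
#'   `[0, |g|]`), `gamma_raw` (before clamping), `group_sizes`,
#'   `floored`.
#' @export
bnn_update_hyperparams <- function(arch, w, x, y, alpha, beta) {
  gi <- bnn_groups(arch)
  err <- bnn_error(arch, w, x, y, alpha, beta)
  hess <- bnn_hessian(arch, w, x, alpha, beta)
  inv_diag <- drop((hess$vectors^2) %*% (1 / hess$values))
  n <- nrow(as.matrix(x))
  gamma_raw <- numeric(length(gi$groups))
  gamma <- numeric(length(gi$groups))
  alpha_new <- numeric(length(gi$groups))
  for (g in seq_along(gi$groups)) {
    idx <- gi$groups[[g]]
    gamma_raw[g] <- length(idx) - alpha[g] * sum(inv_diag[idx])
    gamma[g] <- min(max(gamma_raw[g], 0), length(idx))
    ew <- max(err$e_w[g], 1e-300)
    alpha_new[g] <- min(max(gamma[g] / (2 * ew), 1e-8), 1e8)
  }
  beta_new <- max((n - sum(gamma)) / (2 * max(err$e_d, 1e-300)), 1e-8)
  list(alpha = setNames(alpha_new, names(gi$groups)), beta = beta_new,
       gamma = setNames(gamma, names(gi$groups)),
       gamma_raw = setNames(gamma_raw, names(gi$groups)),
       group_sizes = lengths(gi$groups),
       floored = hess$floored)
}

#' Log evidence (Gaussian approximation) of a trained network
#'
#' `log ev = -beta E_D - sum_g alpha_g E_W(g) - 0.5 log det A
#'  + 0.5 sum_g |g| log alpha_g + (N/2) log beta - (N/2) log 2 pi`,
#' with the determinant computed from eigenvalues floored at 1e-10.
#' For the linear architecture this equals the exact log marginal
#' likelihood of the corresponding Bayesian linear model.
#'
#' @param arch Architecture.
#' @param w MAP weights.
#' @param x,y Training data (targets centred).
#' @param alpha,beta Hyperparameters.
#' @return Scalar log evidence.
#' @export
bnn_evidence <- function(arch, w, x, y, alpha, beta) {
  gi <- bnn_groups(arch)
  err <- bnn_error(arch, w, x, y, alpha, beta)
  hess <- bnn_hessian(arch, w, x, alpha, beta)
  n <- nrow(as.matrix(x))
  group_sizes <- lengths(gi$groups)
  -beta * err$e_d - sum(alpha * err$e_w) -
    0.5 * sum(log(hess$values)) +
    0.5 * sum(group_sizes * log(alpha)) +
    (n / 2) * log(beta) - (n / 2) * log(2 * pi)
}

#' Train one Bayesian network under the evidence framework
#'
#' From a seeded Gaussian initialization (sd `1/sqrt(fan-in)`), performs
#' a MAP fit at the initial hyperparameters, then `outer_loops`
#' alternations of hyperparameter re-estimation and MAP refitting, and
#' records the final log evidence, effective parameter counts and a
#' per-iteration trace. Inputs are expected standardized; targets are
#' centred internally and the centre stored on the model.
#'
#' @param x Standardized input matrix.
#' @param y Targets (original scale; centred internally).
#' @param arch A `kd_bnn_architecture` (or `n_hidden`, in which case the
#'   architecture is built from the data).
#' @param seed Integer seed for the weight initialization.
#' @param outer_loops Number of re-estimation cycles (default 8).
#' @param alpha_init,beta_init Initial hyperparameters.
#' @param max_iter Inner optimizer iteration cap per MAP fit.
#' @return An object of class `kd_bnn`.
#' @export
bnn_train <- function(x, y, arch = 2L, seed = 1L, outer_loops = 8L,
                      alpha_init = 0.01, beta_init = 1, max_iter = 100L) {
  xy <- check_matrix_xy(x, y)
  x <- xy$x; y_raw <- xy$y
  if (!inherits(arch, "kd_bnn_architecture")) {
    arch <- bnn_architecture(ncol(x), n_hidden = arch,
                             input_names = colnames(x) %||%
                               sprintf("x%02d", seq_len(ncol(x))))
  }
  gi <- bnn_groups(arch)
  y_center <- mean(y_raw)
  y <- y_raw - y_center

  w0 <- withr::with_seed(as.integer(seed) %% 2147483629L, {
    p <- arch$n_inputs; h <- arch$n_hidden
    if (h == 0L) {
      c(rnorm(p, 0, 1 / sqrt(p + 1)), rnorm(1, 0, 1 / sqrt(p + 1)))
    } else {
      c(rnorm(h * p, 0, 1 / sqrt(p + 1)),   # W1
        rnorm(h, 0, 1 / sqrt(p + 1)),       # b1
        rnorm(h, 0, 1 / sqrt(h + 1)),       # v
        rnorm(1, 0, 1 / sqrt(h + 1)))       # b2
    }
  })

  alpha <- setNames(rep(alpha_init, length(gi$groups)), names(gi$groups))
  beta <- beta_init
  trace <- list()
  fit <- bnn_train_map(arch, w0, x, y, alpha, beta, max_iter = max_iter)
  w <- fit$w
  gamma <- setNames(rep(NA_real_, length(gi$groups)), names(gi$groups))
  if (outer_loops > 0L) {
    for (l in seq_len(outer_loops)) {
      upd <- bnn_update_hyperparams(arch, w, x, y, alpha, beta)
      alpha <- upd$alpha
      beta <- upd$beta
      gamma <- upd$gamma
      fit <- bnn_train_map(arch, w, x, y, alpha, beta, max_iter = max_iter)
      w <- fit$w
      err <- bnn_error(arch, w, x, y, alpha, beta)
      trace[[l]] <- tibble::tibble(
        outer = l, e_total = err$value, e_d = err$e_d,
        sum_gamma = sum(gamma), beta = beta,
        alpha_min = min(alpha), alpha_max = max(alpha),
        gamma_raw_min = min(upd$gamma_raw),
        gamma_raw_excess = max(upd$gamma_raw - upd$group_sizes),
        hessian_floored = upd$floored
      )
    }
  }
  log_ev <- bnn_evidence(arch, w, x, y, alpha, beta)

  structure(
    list(n_inputs = arch$n_inputs, n_hidden = arch$n_hidden,
         input_names = arch$input_names,
         w = w, alpha = alpha, beta = beta, gamma = gamma,
         y_center = y_center, log_evidence = log_ev,
         seed = as.integer(seed), outer_loops = as.integer(outer_loops),
         trace = if (length(trace)) dplyr::bind_rows(trace) else NULL),
    class = "kd_bnn"
  )
}

bnn_arch_of <- function(model) {
  bnn_architecture(model$n_inputs, model$n_hidden, model$input_names)
}

#' @export
predict.kd_bnn <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) {
    as.matrix(newdata[, object$input_names, drop = FALSE])
  } else {
    m <- as.matrix(newdata)
    if (!is.null(colnames(m)) && all(object$input_names %in% colnames(m))) {
      m[, object$input_names, drop = FALSE]
    } else m
  }
  bnn_forward(bnn_arch_of(object), object$w, x) + object$y_center
}

#' @export
print.kd_bnn <- function(x, ...) {
  cat(sprintf("Bayesian network: %d inputs, %d hidden tanh unit(s); log evidence %.2f\n",
              x$n_inputs, x$n_hidden, x$log_evidence))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.kd_bnn <- function(x, ...) {
  tibble::tibble(n_inputs = x$n_inputs, n_hidden = x$n_hidden,
                 log_evidence = x$log_evidence, beta = x$beta,
                 sum_gamma = sum(x$gamma))
}

#' @exportS3Method generics::tidy
tidy.kd_bnn <- function(x, ...) {
  tibble::tibble(term = names(x$alpha),
                 alpha = unname(x$alpha),
                 gamma = unname(x$gamma))
}
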