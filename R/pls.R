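#' Partial least squares regression by NIPALS
#'
#' Single-response NIPALS: predictors are autoscaled (mean 0, sd 1) and
#' the response centred (not scaled) using training statistics; the
#' predictor matrix is deflated after each component. The sign of each
#' x-weight vector is fixed so its largest-magnitude element is positive,
#' making loadings and rankings reproducible. Regression coefficients are
#' back-transformed to the original descriptor scale.
#'
#' @param x Numeric matrix of predictors (columns named).
#' @param y Numeric response.
#' @param n_components Number of latent components; must not exceed the
#'   rank of the scaled predictor matrix.
#' @return An object of class `kd_pls` with x-weights `w`, x-loadings
#'   `p`, y-loadings `q`, scores variance, centering/scaling vectors,
#'   original-scale `coefficients` and `intercept`, and the fraction of
#'   X-variance explained per component (`x_variance`).
#' @export
fit_pls <- function(x, y, n_components) {
  xy <- check_matrix_xy(x, y)
  x <- xy$x; y <- xy$y
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  if (sd(y) <= 0) {
    abort("Response has zero variance.", class = "sorbkd_input_error")
  }
  check_count(n_components, "n_components")

  x_mean <- colMeans(x)
  x_sd <- apply(x, 2, sd)
  if (any(x_sd <= 0)) {
    abort(sprintf("Zero-variance predictor(s): %s.",
                  paste(colnames(x)[x_sd <= 0], collapse = ", ")),
          class = "sorbkd_input_error")
  }
  y_mean <- mean(y)
  xs <- sweep(sweep(x, 2, x_mean, "-"), 2, x_sd, "/")
  ys <- y - y_mean

  rank_x <- qr(xs)$rank
  if (n_components > rank_x) {
    abort(sprintf("Requested %d components but the scaled predictor matrix has rank %d.",
                  n_components, rank_x),
          class = "sorbkd_input_error")
  }

  p_dim <- ncol(x)
  ss_x_total <- sum(xs^2)
  W <- matrix(0, p_dim, n_components, dimnames = list(colnames(x), NULL))
  P <- matrix(0, p_dim, n_components, dimnames = list(colnames(x), NULL))
  Q <- numeric(n_components)
  xvar <- numeric(n_components)
  xa <- xs
  ya <- ys
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(xa, ya))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) {
      abort(sprintf("Component %d is degenerate (no remaining covariance); achievable components: %d.",
                    a, a - 1L),
            class = "sorbkd_input_error")
    }
    w <- w / wn
    if (w[which.max(abs(w))] < 0) w <- -w
    t_a <- drop(xa %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(xa, t_a)) / tt
    q_a <- sum(ya * t_a) / tt
    xa <- xa - tcrossprod(t_a, p_a)
    ya <- ya - q_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    Q[a] <- q_a
    xvar[a] <- tt * sum(p_a^2) / ss_x_total
  }

  # coefficients in scaled space: B = W (P'W)^-1 Q
  b_scaled <- drop(W %*% solve(crossprod(P, W), Q))
  coefficients <- b_scaled / x_sd
  intercept <- y_mean - sum(coefficients * x_mean)

  structure(
    list(n_components = as.integer(n_components),
         w = W, p = P, q = Q,
         x_mean = x_mean, x_sd = x_sd, y_mean = y_mean,
         coefficients = setNames(coefficients, colnames(x)),
         intercept = intercept,
         x_variance = xvar,
         descriptor_names = colnames(x)),
    class = "kd_pls"
  )
}

#' @export
predict.kd_pls <- function(object, newdata, ...) {
  if (!is.null(object$standardizer) && is.data.frame(newdata)) {
    newdata <- apply_standardizer(object$standardizer,
                                  as.matrix(newdata[, object$descriptor_names,
                                                    drop = FALSE]))
  }
  x <- if (is.data.frame(newdata)) {
    as.matrix(newdata[, object$descriptor_names, drop = FALSE])
  } else {
    m <- as.matrix(newdata)
    if (!is.null(colnames(m)) &&
        all(object$descriptor_names %in% colnames(m))) {
      m[, object$descriptor_names, drop = FALSE]
    } else m
  }
  drop(object$intercept + x %*% object$coefficients)
}

#' @export
print.kd_pls <- function(x, ...) {
  cat(sprintf("PLS model: %d component(s) on %d descriptors (X-variance %.2f)\n",
              x$n_components, length(x$coefficients), sum(x$x_variance)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kd_pls <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @exportS3Method generics::glance
glance.kd_pls <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 n_descriptors = length(x$coefficients),
                 x_variance = sum(x$x_variance))
}

# Sequential predictions for 1..A components from one NIPALS run, used by
# leave-one-out component selection.
pls_predict_upto <- function(model, x, max_comp) {
  x <- as.matrix(x)[, model$descriptor_names, drop = FALSE]
  xs <- sweep(sweep(x, 2, model$x_mean, "-"), 2, model$x_sd, "/")
  out <- matrix(0, nrow(x), max_comp)
  pw <- crossprod(model$p, model$w)
  for (k in seq_len(max_comp)) {
    bk <- drop(model$w[, seq_len(k), drop = FALSE] %*%
                 solve(pw[seq_len(k), seq_len(k), drop = FALSE],
                       model$q[seq_len(k)]))
    out[, k] <- model$y_mean + xs %*% bk
  }
  out
}

#' Select the number of PLS components by leave-one-out cross-validation
#'
#' For each candidate component count k the model is refit n times with
#' one row held out (centring and scaling recomputed inside each fold)
#' and the held-out rows predicted; `r2_cv(k) = 1 - PRESS(k)/SST`. The k
#' maximizing `r2_cv` is returned, smallest k on ties.
#'
#' @param x Predictor matrix.
#' @param y Response.
#' @param max_comp Maximum component count scanned (silently capped at the
#'   achievable rank of each training fold).
#' @return A list with `n_components`, `r2_cv` (at the chosen k) and
#'   `r2_cv_all` (vector over k).
#' @export
select_ncomp_loo <- function(x, y, max_comp) {
  xy <- check_matrix_xy(x, y)
  x <- xy$x; y <- xy$y
  n <- nrow(x)
  if (n < 5L) abort("Need n >= 5.", class = "sorbkd_input_error")
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  max_comp <- min(max_comp, ncol(x), n - 2L)
  preds <- matrix(NA_real_, n, max_comp)
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]
    keep <- apply(xt, 2, sd) > 0
    a_i <- min(max_comp, qr(scale(xt[, keep, drop = FALSE]))$rank)
    fit <- fit_pls(xt[, keep, drop = FALSE], y[-i], a_i)
    pr <- pls_predict_upto(fit, x[i, keep, drop = FALSE], a_i)
    preds[i, seq_len(a_i)] <- pr
    if (a_i < max_comp) preds[i, seq.int(a_i + 1L, max_comp)] <- pr[a_i]
  }
  sst <- sum((y - mean(y))^2)
  press <- colSums((preds - y)^2)
  r2_cv <- 1 - press / sst
  k <- which.max(r2_cv)  # which.max returns the first (smallest k) on ties
  list(n_components = k, r2_cv = r2_cv[k], r2_cv_all = r2_cv)
}

#' Rank descriptors by their PLS loadings across models
#'
#' For each of the first `k_components` components, descriptors are
#' ranked by the mean absolute loading across the supplied models
#' (absolute value taken before averaging so sign-flipped components
#' agree), in descending order.
#'
#' @param models List of `kd_pls` models sharing descriptor names.
#' @param k_components Number of leading components to rank (default 3);
#'   models with fewer components contribute what they have, with a
#'   warning.
#' @return A tibble with columns `component`, `rank`, `term`,
#'   `mean_abs_loading`.
#' @export
pls_loading_ranking <- function(models, k_components = 3L) {
  if (length(models) == 0L) {
    abort("Need at least one model.", class = "sorbkd_input_error")
  }
  nms <- models[[1]]$descriptor_names
  for (m in models) {
    if (!identical(m$descriptor_names, nms)) {
      abort("All models must share descriptor names.",
            class = "sorbkd_input_error")
    }
  }
  avail <- vapply(models, function(m) as.numeric(m$n_components), numeric(1))
  if (any(avail < k_components)) {
    warn(sprintf("Some models have fewer than %d components; using what is available.",
                 k_components))
  }
  out <- list()
  for (comp in seq_len(k_components)) {
    contrib <- vapply(models, function(m) {
      if (m$n_components >= comp) abs(m$p[, comp]) else rep(NA_real_, length(nms))
    }, numeric(length(nms)))
    mean_abs <- rowMeans(contrib, na.rm = TRUE)
    ord <- order(-mean_abs, nms)
    out[[comp]] <- tibble::tibble(
      component = comp, rank = seq_along(nms),
      term = nms[ord], mean_abs_loading = mean_abs[ord]
    )
  }
  dplyr::bind_rows(out)
}
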