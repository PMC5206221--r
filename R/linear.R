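#' Univariate linear model of log Kd on a single predictor
#'
#' Ordinary least squares with intercept, the classic
#' `log Kd = a + b log Kow` sorption model. Accepts either two numeric
#' vectors or a descriptor table plus column names.
#'
#' @param x Numeric predictor vector, or a descriptor table.
#' @param y Numeric response vector; ignored when `x` is a data frame.
#' @param predictor,response Column names used when `x` is a data frame
#'   (defaults `"log_kow"` and `"log_kd"`).
#' @param charge_class Label stored on the model (a charge class or
#'   `"combined"`).
#' @return An object of class `kd_univariate` with fields `intercept`,
#'   `slope`, `r2`, `n`, `predictor_name`, `charge_class`.
#' @export
fit_univariate <- function(x, y = NULL, predictor = "log_kow",
                           response = "log_kd", charge_class = "combined") {
  if (is.data.frame(x)) {
    y <- x[[response]]
    x <- x[[predictor]]
  } else {
    predictor <- predictor %||% "x"
  }
  if (length(x) < 3L) {
    abort("Univariate fit needs at least 3 observations.",
          class = "sorbkd_input_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite.", class = "sorbkd_input_error")
  }
  if (sd(x) <= 0) {
    abort("Predictor has zero variance.", class = "sorbkd_input_error")
  }
  fit <- lm.fit(cbind(1, x), y)
  b <- unname(fit$coefficients)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= 0) 0 else max(0, min(1, 1 - sum(fit$residuals^2) / sst))
  structure(
    list(intercept = b[1], slope = b[2], r2 = r2, n = length(y),
         predictor_name = predictor, charge_class = charge_class),
    class = "kd_univariate"
  )
}

#' @export
predict.kd_univariate <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata[[object$predictor_name]] else newdata
  object$intercept + object$slope * x
}

#' @export
print.kd_univariate <- function(x, ...) {
  cat(sprintf("Univariate Kd model (%s): log_kd = %.4f + %.4f * %s  (R2 = %.3f, n = %d)\n",
              x$charge_class, x$intercept, x$slope, x$predictor_name, x$r2, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kd_univariate <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$predictor_name),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.kd_univariate <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n,
                 charge_class = x$charge_class,
                 predictor = x$predictor_name)
}

#' Leverage diagnostics with single-pass removal and refit
#'
#' Fits an OLS model with intercept, computes the hat-matrix diagonal,
#' flags rows with leverage above `multiplier * p / n` (p = number of
#' parameters including the intercept), removes them once, and refits on
#' the survivors.
#'
#' @param x Numeric predictor matrix (columns = variables, no intercept
#'   column).
#' @param y Numeric response.
#' @param multiplier Threshold multiplier (default 3).
#' @return An object of class `kd_leverage`: a list with `leverage`
#'   (tibble of row, h, flagged), `threshold`, `flagged` (row indices),
#'   `coefficients` / `coefficients_refit` (named, intercept first), `n`,
#'   `p`.
#' @export
leverage_filter_refit <- function(x, y, multiplier = 3) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  xy <- check_matrix_xy(x, y)
  x <- xy$x; y <- xy$y
  n <- nrow(x)
  p <- ncol(x) + 1L
  if (n <= p) {
    abort("Need more rows than model parameters.", class = "sorbkd_input_error")
  }
  xd <- cbind(`(Intercept)` = 1, x)
  qr_x <- qr(xd)
  if (qr_x$rank < p) {
    abort("Design matrix is rank deficient.", class = "sorbkd_input_error")
  }
  q <- qr.Q(qr_x)
  h <- rowSums(q^2)
  threshold <- multiplier * p / n
  flagged <- which(h > threshold)
  if (length(flagged) == n) {
    abort("Every row exceeds the leverage threshold (degenerate design).",
          class = "sorbkd_input_error")
  }
  fit_all <- lm.fit(xd, y)
  keep <- setdiff(seq_len(n), flagged)
  fit_refit <- lm.fit(xd[keep, , drop = FALSE], y[keep])
  structure(
    list(
      leverage = tibble::tibble(row = seq_len(n), h = h,
                                flagged = seq_len(n) %in% flagged),
      threshold = threshold,
      flagged = flagged,
      coefficients = fit_all$coefficients,
      coefficients_refit = fit_refit$coefficients,
      n = n, p = p
    ),
    class = "kd_leverage"
  )
}

#' @exportS3Method generics::tidy
tidy.kd_leverage <- function(x, ...) x$leverage

#' Regression fit statistics
#'
#' Computes the standard QSPR reporting set: R2, adjusted R2, PRESS-based
#' predicted R2, mean unsigned error (MUE) and the residual standard
#' deviation s.
#'
#' @param y_true Observed values.
#' @param y_pred Model predictions for the same rows.
#' @param n_params Number of fitted parameters p (excluding the
#'   intercept); adjusted statistics use n - p - 1 denominators.
#' @param press Optional PRESS statistic (sum of squared leave-one-out
#'   residuals of the same model family); when supplied, `r2_pred`
#'   is `1 - PRESS/SST`.
#' @return One-row tibble: `r2`, `r2_adj`, `r2_pred`, `mue`, `s`, `n`,
#'   `n_params`, `df_ok`. When `n <= n_params + 1` the adjusted statistics
#'   are undefined: they are returned as `NA` with `df_ok = FALSE` and a
#'   warning.
#' @export
fit_metrics <- function(y_true, y_pred, n_params, press = NULL) {
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have equal length.",
          class = "sorbkd_input_error")
  }
  n <- length(y_true)
  err <- y_true - y_pred
  sst <- sum((y_true - mean(y_true))^2)
  sse <- sum(err^2)
  r2 <- if (sst <= 0) ifelse(sse <= 1e-24, 1, 0) else 1 - sse / sst
  mue <- mean(abs(err))
  df_ok <- n > n_params + 1
  if (!df_ok) {
    warn("n <= n_params + 1: adjusted and residual-sd statistics are undefined.")
  }
  r2_adj <- if (df_ok && sst > 0) 1 - (1 - r2) * (n - 1) / (n - n_params - 1) else NA_real_
  s <- if (df_ok) sqrt(sse / (n - n_params - 1)) else NA_real_
  r2_pred <- if (!is.null(press) && sst > 0) 1 - press / sst else NA_real_
  tibble::tibble(r2 = r2, r2_adj = r2_adj, r2_pred = r2_pred,
                 mue = mue, s = s, n = n, n_params = n_params, df_ok = df_ok)
}

# PRESS of an OLS fit via the closed-form leave-one-out identity
# e_i / (1 - h_ii) for a fixed design (no re-selection per fold).
ols_press <- function(xd, y) {
  fit <- lm.fit(xd, y)
  q <- qr.Q(qr(xd))
  h <- rowSums(q^2)
  sum((fit$residuals / (1 - h))^2)
}

#' Forward-backward stepwise regression on partial t-test p-values
#'
#' Classic stepwise selection: at each step the candidate whose
#' coefficient (when added to the current model) has the smallest p-value
#' enters if that p-value is below `alpha_enter`; after each addition any
#' included variable whose p-value exceeds `alpha_remove` is removed
#' (largest first). Terminates when no move is possible. Ties are broken
#' by the smallest column index. Perfectly collinear candidates (NA
#' coefficient) are treated as p-value 1.
#'
#' @param x Numeric matrix of candidate predictors.
#' @param y Numeric response.
#' @param alpha_enter,alpha_remove Entry / removal p-value thresholds
#'   (defaults 0.15 / 0.15, with `alpha_remove >= alpha_enter`).
#' @return An object of class `kd_stepwise`: list with `selected`
#'   (ordered names), `coefficients` (intercept first), `metrics`
#'   (a [fit_metrics()] row whose `r2_pred` uses fixed-set PRESS - an
#'   optimistic convention since selection is not repeated per fold),
#'   `trace` (tibble of add/remove moves).
#' @export
stepwise_regression <- function(x, y, alpha_enter = 0.15, alpha_remove = 0.15) {
  xy <- check_matrix_xy(x, y)
  x <- xy$x; y <- xy$y
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  n <- nrow(x)
  if (n <= 2L) abort("Need n > 2.", class = "sorbkd_input_error")
  if (alpha_remove < alpha_enter) {
    abort("`alpha_remove` must be >= `alpha_enter`.",
          class = "sorbkd_config_error")
  }

  coef_pvals <- function(cols) {
    xd <- cbind(1, x[, cols, drop = FALSE])
    fit <- lm.fit(xd, y)
    k <- fit$rank
    dfres <- n - k
    if (dfres <= 0) return(rep(1, length(cols)))
    coefs <- fit$coefficients
    sigma2 <- sum(fit$residuals^2) / dfres
    r <- fit$qr
    keep_piv <- r$pivot[seq_len(k)]
    xtxinv_diag <- rep(NA_real_, ncol(xd))
    rinv <- backsolve(qr.R(r)[seq_len(k), seq_len(k), drop = FALSE],
                      diag(k))
    xtxinv_diag[keep_piv] <- rowSums(rinv^2)
    se <- sqrt(sigma2 * xtxinv_diag)
    tval <- coefs / se
    pv <- 2 * pt(abs(tval), dfres, lower.tail = FALSE)
    pv[is.na(pv)] <- 1
    pv[-1]  # drop intercept
  }

  selected <- integer(0)
  moves <- list()
  repeat {
    moved <- FALSE
    remaining <- setdiff(seq_len(ncol(x)), selected)
    if (length(remaining) > 0L) {
      entry_p <- vapply(remaining, function(j) {
        pv <- coef_pvals(c(selected, j))
        pv[length(pv)]
      }, numeric(1))
      k <- which.min(entry_p)
      if (entry_p[k] < alpha_enter) {
        selected <- c(selected, remaining[k])
        moves[[length(moves) + 1L]] <-
          tibble::tibble(step = length(moves) + 1L, action = "add",
                         term = colnames(x)[remaining[k]],
                         p_value = entry_p[k])
        moved <- TRUE
        # backward sweep
        repeat {
          if (length(selected) == 0L) break
          pv <- coef_pvals(selected)
          worst <- which.max(pv)
          if (pv[worst] > alpha_remove) {
            moves[[length(moves) + 1L]] <-
              tibble::tibble(step = length(moves) + 1L, action = "remove",
                             term = colnames(x)[selected[worst]],
                             p_value = pv[worst])
            selected <- selected[-worst]
          } else break
        }
      }
    }
    if (!moved) break
  }

  sel_names <- colnames(x)[selected]
  xd <- cbind(`(Intercept)` = 1, x[, selected, drop = FALSE])
  fit <- lm.fit(xd, y)
  press <- ols_press(xd, y)
  metrics <- fit_metrics(y, xd %*% fit$coefficients, length(selected),
                         press = press)
  structure(
    list(selected = sel_names,
         coefficients = fit$coefficients,
         metrics = metrics,
         trace = if (length(moves)) dplyr::bind_rows(moves) else
           tibble::tibble(step = integer(), action = character(),
                          term = character(), p_value = numeric()),
         alpha_enter = alpha_enter, alpha_remove = alpha_remove),
    class = "kd_stepwise"
  )
}

#' @export
predict.kd_stepwise <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) {
    as.matrix(newdata[, object$selected, drop = FALSE])
  } else {
    as.matrix(newdata)[, object$selected, drop = FALSE]
  }
  drop(cbind(1, x) %*% object$coefficients)
}

#' @exportS3Method generics::tidy
tidy.kd_stepwise <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @exportS3Method generics::glance
glance.kd_stepwise <- function(x, ...) {
  dplyr::mutate(x$metrics, n_selected = length(x$selected))
}

#' @export
print.kd_stepwise <- function(x, ...) {
  cat(sprintf("Stepwise model: %d term(s) selected (R2 = %.3f, R2_pred = %.3f)\n",
              length(x$selected), x$metrics$r2, x$metrics$r2_pred))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
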