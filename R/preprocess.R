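#' Coefficient-of-variation filter for descriptor columns
#'
#' Removes descriptor columns whose coefficient of variation
#' (standard deviation divided by the absolute mean) falls below
#' `threshold`. Columns with a mean indistinguishable from zero are kept
#' (their CV is effectively infinite) unless their standard deviation is
#' also ~0, in which case they are removed as constants.
#'
#' @param data A descriptor table (reserved columns are never filtered) or
#'   a plain numeric data frame / matrix, in which case all columns are
#'   candidates.
#' @param threshold CV threshold (default 0.05).
#' @return A list with `data` (the filtered table, same type as the input)
#'   and `removed` (character vector of removed column names).
#' @export
cv_filter <- function(data, threshold = 0.05) {
  if (is.matrix(data)) {
    res <- cv_filter(as.data.frame(data), threshold)
    return(list(data = as.matrix(res$data), removed = res$removed))
  }
  if (nrow(data) == 0L) {
    abort("`data` must be nonempty.", class = "sorbkd_input_error")
  }
  cand <- descriptor_names(data)
  cand <- cand[vapply(data[cand], is.numeric, logical(1))]
  removed <- character(0)
  tol <- sqrt(.Machine$double.eps)
  for (nm in cand) {
    x <- data[[nm]]
    m <- mean(x)
    s <- sd(x)
    if (is.na(s)) s <- 0
    if (abs(m) < tol) {
      if (s < tol) removed <- c(removed, nm)  # constant at ~0
      next                                    # CV treated as infinite
    }
    if (abs(s / m) < threshold) removed <- c(removed, nm)
  }
  list(data = data[, setdiff(names(data), removed), drop = FALSE],
       removed = removed)
}

# Multiple R2 of candidate column y on selected columns (with intercept).
multiple_r2 <- function(xsel, y) {
  fit <- lm.fit(cbind(`(Intercept)` = 1, xsel), y)
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) return(1)
  res <- fit$residuals
  max(0, min(1, 1 - sum(res^2) / sst))
}

#' Unsupervised forward selection of descriptors
#'
#' Selects a subset of columns with minimal multiple correlation:
#' the first two selected variables are the pair with the smallest
#' absolute pairwise correlation; at every later stage the candidate whose
#' squared multiple correlation (R2 of its regression, with intercept, on
#' the selected set) is smallest is added, provided that R2 is below
#' `r2_max`. Selection stops when no candidate qualifies
#' (`stop_reason = "r2_max_reached"`) or all columns are selected
#' (`"exhausted"`). Ties are broken by the smallest column index.
#'
#' @param x Numeric matrix or data frame of candidate columns (>= 2
#'   columns, each with nonzero variance).
#' @param r2_max Maximum admissible multiple R2 (default 0.99).
#' @return An object of class `kd_ufs_report`: a list with `selected`
#'   (ordered names), `r2_at_selection` (for the first two entries, their
#'   squared pairwise correlation; thereafter the candidate's multiple R2
#'   with the previously selected set), `rejected` (names never selected)
#'   and `stop_reason`.
#' @export
ufs_select <- function(x, r2_max = 0.99) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  p <- ncol(x)
  if (p < 2L) {
    abort("UFS needs at least two columns.", class = "sorbkd_input_error")
  }
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(p))
  sds <- apply(x, 2, sd)
  if (any(sds <= 0)) {
    abort(sprintf("Zero-variance column(s): %s. Apply cv_filter() first.",
                  paste(colnames(x)[sds <= 0], collapse = ", ")),
          class = "sorbkd_input_error")
  }

  cm <- abs(cor(x))
  diag(cm) <- Inf
  # smallest |correlation| pair; ties -> smallest (i, j)
  best <- c(1L, 2L)
  best_val <- Inf
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      if (cm[i, j] < best_val) {
        best_val <- cm[i, j]
        best <- c(i, j)
      }
    }
  }
  selected <- best
  r2_at <- rep(best_val^2, 2L)

  repeat {
    remaining <- setdiff(seq_len(p), selected)
    if (length(remaining) == 0L) {
      reason <- "exhausted"
      break
    }
    r2s <- vapply(remaining, function(j) {
      multiple_r2(x[, selected, drop = FALSE], x[, j])
    }, numeric(1))
    k <- which.min(r2s)  # ties: first = smallest column index
    if (r2s[k] >= r2_max) {
      reason <- "r2_max_reached"
      break
    }
    selected <- c(selected, remaining[k])
    r2_at <- c(r2_at, r2s[k])
  }

  structure(
    list(selected = colnames(x)[selected],
         r2_at_selection = r2_at,
         rejected = colnames(x)[setdiff(seq_len(p), selected)],
         r2_max = r2_max,
         stop_reason = reason),
    class = "kd_ufs_report"
  )
}

#' @export
print.kd_ufs_report <- function(x, ...) {
  cat(sprintf("Unsupervised forward selection: %d selected, %d rejected (%s)\n",
              length(x$selected), length(x$rejected), x$stop_reason))
  cat("Selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kd_ufs_report <- function(x, ...) {
  tibble::tibble(term = x$selected,
                 order = seq_along(x$selected),
                 r2_at_selection = x$r2_at_selection)
}

#' Learn column means and standard deviations on training data
#'
#' @param x Numeric matrix or data frame of training descriptors; all
#'   columns must have positive standard deviation.
#' @return An object of class `kd_standardizer` holding the training
#'   means and standard deviations.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  if (any(sds <= 0)) {
    abort(sprintf(
      "Zero-variance column(s): %s. Remove them (cv_filter()) before standardizing.",
      paste(colnames(x)[sds <= 0], collapse = ", ")),
      class = "sorbkd_input_error")
  }
  structure(list(mean = mu, sd = sds, names = colnames(x)),
            class = "kd_standardizer")
}

#' Apply (or invert) a trained standardizer
#'
#' Transforms columns with the training means and standard deviations
#' only; data from another distribution will not end up centred.
#'
#' @param standardizer A [fit_standardizer()] object.
#' @param x Matrix with the same columns as the training data.
#' @param invert If `TRUE`, maps standardized values back to the original
#'   scale.
#' @return Transformed matrix.
#' @export
apply_standardizer <- function(standardizer, x, invert = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(colnames(x)) && !is.null(standardizer$names)) {
    if (!identical(colnames(x), standardizer$names)) {
      if (!all(standardizer$names %in% colnames(x))) {
        abort("`x` lacks columns the standardizer was trained on.",
              class = "sorbkd_input_error")
      }
      x <- x[, standardizer$names, drop = FALSE]
    }
  }
  if (ncol(x) != length(standardizer$mean)) {
    abort("Column count does not match the standardizer.",
          class = "sorbkd_input_error")
  }
  if (invert) {
    sweep(sweep(x, 2, standardizer$sd, "*"), 2, standardizer$mean, "+")
  } else {
    sweep(sweep(x, 2, standardizer$mean, "-"), 2, standardizer$sd, "/")
  }
}

#' Reduce a descriptor table: CV filter then unsupervised forward selection
#'
#' Convenience wrapper applying [cv_filter()] followed by [ufs_select()] to
#' the descriptor columns of a table, as done before multivariate
#' modelling.
#'
#' @param data A descriptor table.
#' @param cv_threshold CV threshold.
#' @param ufs_r2_max UFS multiple-R2 cap.
#' @return A list with `data` (table restricted to the selected
#'   descriptors), `removed_by_cv`, and `ufs` (the `kd_ufs_report`).
#' @export
reduce_descriptors <- function(data, cv_threshold = 0.05, ufs_r2_max = 0.99) {
  cvres <- cv_filter(data, cv_threshold)
  desc <- descriptor_names(cvres$data)
  if (length(desc) < 2L) {
    abort("Fewer than two descriptors survive the CV filter.",
          class = "sorbkd_input_error")
  }
  ufs <- ufs_select(descriptor_matrix(cvres$data), ufs_r2_max)
  keep <- c(intersect(names(cvres$data), kd_reserved_cols()), ufs$selected)
  list(data = cvres$data[, keep, drop = FALSE],
       removed_by_cv = cvres$removed,
       ufs = ufs)
}
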