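#' Random train/test split plan
#'
#' Draws `n_splits` independent test sets of `n_test` rows by uniform
#' sampling without replacement (independent across splits, so test sets
#' may overlap between splits, not within). With `level = "compound"`,
#' whole compounds are assigned to the test side and the nearest
#' achievable test size is used (flagged when it differs from `n_test`).
#'
#' @param n_total Total number of measurement rows.
#' @param n_test Test rows per split (default 60).
#' @param n_splits Number of splits (default 5).
#' @param level `"measurement"` (default; replicates of one compound may
#'   straddle train and test) or `"compound"`.
#' @param seed Seed; split s uses a derived substream.
#' @param compound_ids Required for compound-level splits: vector of
#'   length `n_total`.
#' @return An object of class `kd_split_plan`: list with `test_indices`
#'   (list of integer vectors), `n_total`, `n_test`, `n_splits`, `level`,
#'   `seed`, `exact` (logical per split).
#' @export
make_splits <- function(n_total, n_test = 60L, n_splits = 5L,
                        level = c("measurement", "compound"),
                        seed = 1L, compound_ids = NULL) {
  level <- match.arg(level)
  check_count(n_total, "n_total")
  check_count(n_test, "n_test")
  check_count(n_splits, "n_splits")
  if (n_test >= n_total) {
    abort("`n_test` must be smaller than `n_total`.",
          class = "sorbkd_config_error")
  }
  if (level == "compound" && (is.null(compound_ids) ||
                              length(compound_ids) != n_total)) {
    abort("Compound-level splits need `compound_ids` of length `n_total`.",
          class = "sorbkd_config_error")
  }
  test_indices <- vector("list", n_splits)
  exact <- logical(n_splits)
  for (s in seq_len(n_splits)) {
    split_seed <- kd_substream(seed, "split", s)
    if (level == "measurement") {
      test_indices[[s]] <- withr::with_seed(split_seed,
                                            sort(sample.int(n_total, n_test)))
      exact[s] <- TRUE
    } else {
      test_indices[[s]] <- withr::with_seed(split_seed, {
        cmp <- unique(compound_ids)
        cmp <- sample(cmp)  # random order
        counts <- vapply(cmp, function(cc) sum(compound_ids == cc), integer(1))
        csum <- cumsum(counts)
        ncmp <- which.min(abs(csum - n_test))
        sort(which(compound_ids %in% cmp[seq_len(ncmp)]))
      })
      exact[s] <- length(test_indices[[s]]) == n_test
      if (!exact[s]) {
        warn(sprintf("Split %d: compound-level test set has %d rows (requested %d).",
                     s, length(test_indices[[s]]), n_test))
      }
    }
  }
  structure(list(test_indices = test_indices, n_total = as.integer(n_total),
                 n_test = as.integer(n_test), n_splits = as.integer(n_splits),
                 level = level, seed = as.integer(seed), exact = exact),
            class = "kd_split_plan")
}

#' @export
print.kd_split_plan <- function(x, ...) {
  cat(sprintf("Split plan: %d splits of %d total rows, %d test rows each (%s level)\n",
              x$n_splits, x$n_total, x$n_test, x$level))
  invisible(x)
}

# ---- univariate experiment --------------------------------------------------

#' Charge-class univariate study
#'
#' Fits `log Kd = a + b x` (x = `log_kow` by default) for each charge
#' class with at least 3 measurements and for the combined dataset, each
#' with leverage diagnostics and a single-pass high-leverage refit.
#'
#' @param data A descriptor table.
#' @param predictor Predictor column (`"log_kow"` or `"log_dow_74"`).
#' @param leverage_multiplier Threshold multiplier for the hat diagonal.
#' @return An object of class `kd_univariate_experiment`: `summary` (one
#'   tibble row per model: class, n, intercept, slope, r2, plus the
#'   leverage-refit variants and removal counts), `models`,
#'   `leverage`, and the data (for plotting).
#' @export
run_univariate_experiment <- function(data, predictor = "log_kow",
                                      leverage_multiplier = 3) {
  groups <- c(kd_charge_classes(), "combined")
  rows <- list()
  models <- list()
  leverage <- list()
  for (gc in groups) {
    sub <- if (gc == "combined") data else
      data[data$charge_class == gc, , drop = FALSE]
    if (nrow(sub) < 3L) {
      warn(sprintf("Charge class '%s' has fewer than 3 measurements; skipped.", gc))
      next
    }
    m <- fit_univariate(sub, predictor = predictor, charge_class = gc)
    lev <- leverage_filter_refit(matrix(sub[[predictor]], ncol = 1,
                                        dimnames = list(NULL, predictor)),
                                 sub$log_kd, multiplier = leverage_multiplier)
    keep <- setdiff(seq_len(nrow(sub)), lev$flagged)
    refit_r2 <- fit_univariate(sub[[predictor]][keep], sub$log_kd[keep],
                               predictor = predictor, charge_class = gc)
    models[[gc]] <- m
    leverage[[gc]] <- lev
    rows[[gc]] <- tibble::tibble(
      charge_class = gc, n = m$n,
      intercept = m$intercept, slope = m$slope, r2 = m$r2,
      n_removed = length(lev$flagged),
      intercept_refit = refit_r2$intercept, slope_refit = refit_r2$slope,
      r2_refit = refit_r2$r2
    )
  }
  structure(
    list(summary = dplyr::bind_rows(rows), models = models,
         leverage = leverage, predictor = predictor, data = data),
    class = "kd_univariate_experiment"
  )
}

#' @export
print.kd_univariate_experiment <- function(x, ...) {
  cat(sprintf("Univariate log Kd ~ %s models by charge class:\n", x$predictor))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kd_univariate_experiment <- function(x, ...) x$summary

# ---- experiment report container -------------------------------------------

new_experiment_report <- function(splits_tbl, method, models = NULL,
                                  meta = list()) {
  structure(list(splits = splits_tbl, method = method, models = models,
                 meta = meta),
            class = "kd_experiment_report")
}

#' Summarize an experiment report with mean and sd rows
#'
#' @param object A `kd_experiment_report`.
#' @param ... Unused.
#' @return Tibble of the per-split rows plus `mean` / `sd` rows
#'   (recomputed from the per-split rows) in a `statistic` column.
#' @export
summary.kd_experiment_report <- function(object, ...) {
  tbl <- object$splits
  group_cols <- intersect("n_hidden", names(tbl))
  num_cols <- setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))],
                      c("split", group_cols))
  per <- dplyr::mutate(tbl, statistic = "split")
  agg <- tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(num_cols),
                                   list(mean = mean, sd = sd)),
                     .groups = "drop")
  mean_rows <- agg |>
    dplyr::select(dplyr::all_of(group_cols),
                  dplyr::ends_with("_mean")) |>
    dplyr::rename_with(~ sub("_mean$", "", .x)) |>
    dplyr::mutate(statistic = "mean")
  sd_rows <- agg |>
    dplyr::select(dplyr::all_of(group_cols), dplyr::ends_with("_sd")) |>
    dplyr::rename_with(~ sub("_sd$", "", .x)) |>
    dplyr::mutate(statistic = "sd")
  dplyr::bind_rows(per, mean_rows, sd_rows)
}

#' @export
print.kd_experiment_report <- function(x, ...) {
  cat(sprintf("%s experiment over %d split(s):\n", x$method,
              length(unique(x$splits$split))))
  print(summary(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kd_experiment_report <- function(x, ...) x$splits

#' @exportS3Method generics::glance
glance.kd_experiment_report <- function(x, ...) {
  s <- summary(x)
  dplyr::filter(s, .data$statistic == "mean")
}

# Shared per-split preprocessing: optional reduction fit on training rows
# only, then train-statistics standardization.
split_design <- function(data, test_idx, reduce, cv_threshold, ufs_r2_max,
                         global_reduction) {
  train <- data[-test_idx, , drop = FALSE]
  test <- data[test_idx, , drop = FALSE]
  if (reduce) {
    red <- reduce_descriptors(if (global_reduction) data else train,
                              cv_threshold, ufs_r2_max)
    sel <- red$ufs$selected
  } else {
    sel <- descriptor_names(data)
  }
  xtr <- as.matrix(train[, sel, drop = FALSE])
  xte <- as.matrix(test[, sel, drop = FALSE])
  std <- fit_standardizer(xtr)
  list(
    x_train = apply_standardizer(std, xtr),
    x_test = apply_standardizer(std, xte),
    y_train = train$log_kd, y_test = test$log_kd,
    selected = sel, standardizer = std
  )
}

#' Combined-class PLS experiment over a split plan
#'
#' For each split: descriptor reduction (CV filter + UFS) and
#' standardization are fit on the training rows only (set
#' `global_reduction = TRUE` to reduce once on the full table), the
#' component count is chosen by leave-one-out cross-validation on the
#' training set, and training/test MUE and R2 are reported together with
#' the cumulative fraction of X-variance carried by the selected
#' components.
#'
#' @param data A descriptor table.
#' @param splits A [make_splits()] plan.
#' @param max_comp Maximum components scanned.
#' @param reduce Apply CV filter + UFS (default TRUE).
#' @param cv_threshold,ufs_r2_max Reduction parameters.
#' @param global_reduction Reduce once on the full table instead of per
#'   training split (reproduces protocols that fixed the descriptor set
#'   up front, at the cost of mild test-set leakage).
#' @return A `kd_experiment_report` whose per-split rows carry
#'   `n_components`, `variance`, `mue_train`, `mue_test`, `r2_train`,
#'   `r2_cv`, `r2_test`.
#' @export
run_pls_experiment <- function(data, splits, max_comp = 10L, reduce = TRUE,
                               cv_threshold = 0.05, ufs_r2_max = 0.99,
                               global_reduction = FALSE) {
  rows <- list()
  models <- list()
  for (s in seq_len(splits$n_splits)) {
    d <- split_design(data, splits$test_indices[[s]], reduce,
                      cv_threshold, ufs_r2_max, global_reduction)
    sel <- select_ncomp_loo(d$x_train, d$y_train, max_comp)
    fit <- fit_pls(d$x_train, d$y_train, sel$n_components)
    pr_tr <- predict(fit, d$x_train)
    pr_te <- predict(fit, d$x_test)
    m_tr <- fit_metrics(d$y_train, pr_tr, sel$n_components)
    m_te <- fit_metrics(d$y_test, pr_te, sel$n_components)
    models[[s]] <- fit
    rows[[s]] <- tibble::tibble(
      split = s, n_components = sel$n_components,
      variance = sum(fit$x_variance),
      mue_train = m_tr$mue, mue_test = m_te$mue,
      r2_train = m_tr$r2, r2_cv = sel$r2_cv, r2_test = m_te$r2
    )
  }
  new_experiment_report(dplyr::bind_rows(rows), "PLS", models,
                        meta = list(max_comp = max_comp, reduce = reduce,
                                    global_reduction = global_reduction))
}

#' Combined-class ANN committee experiment over a split plan
#'
#' For each split and hidden-node count: descriptor reduction and
#' standardization are fit on the training rows, a committee of
#' `n_networks` Bayesian networks is trained with the best `k` (by log
#' evidence) retained, and committee-mean MUE/R2 on training and test
#' rows are reported.
#'
#' @param data A descriptor table.
#' @param splits A [make_splits()] plan.
#' @param hidden_range Hidden-node counts to scan (default 2:5).
#' @param n_networks,k Committee parameters (defaults 100 and 10).
#' @param seed Master seed for member initializations.
#' @param reduce,cv_threshold,ufs_r2_max,global_reduction As in
#'   [run_pls_experiment()].
#' @param ... Passed to [bnn_train()] (e.g. `outer_loops`).
#' @return A `kd_experiment_report` with one block of per-split rows per
#'   hidden-node count (`n_hidden`, `mue_train`, `mue_test`, `r2_train`,
#'   `r2_test`).
#' @export
run_ann_experiment <- function(data, splits, hidden_range = 2:5,
                               n_networks = 100L, k = 10L, seed = 1L,
                               reduce = TRUE, cv_threshold = 0.05,
                               ufs_r2_max = 0.99, global_reduction = FALSE,
                               ...) {
  rows <- list()
  models <- list()
  for (s in seq_len(splits$n_splits)) {
    d <- split_design(data, splits$test_indices[[s]], reduce,
                      cv_threshold, ufs_r2_max, global_reduction)
    for (h in hidden_range) {
      cmt <- train_committee(d$x_train, d$y_train, arch = h,
                             n_networks = n_networks, k = k,
                             seed = kd_substream(seed, "committee", s * 1000 + h),
                             ...)
      pr_tr <- predict_committee(cmt, d$x_train)
      pr_te <- predict_committee(cmt, d$x_test)
      m_tr <- fit_metrics(d$y_train, pr_tr, 0L)
      m_te <- fit_metrics(d$y_test, pr_te, 0L)
      models[[sprintf("split%d_h%d", s, h)]] <- cmt
      rows[[length(rows) + 1L]] <- tibble::tibble(
        split = s, n_hidden = as.integer(h),
        mue_train = m_tr$mue, mue_test = m_te$mue,
        r2_train = m_tr$r2, r2_test = m_te$r2
      )
    }
  }
  tbl <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$n_hidden, .data$split)
  new_experiment_report(tbl, "ANN committee", models,
                        meta = list(n_networks = n_networks, k = k,
                                    seed = seed))
}

#' Production PLS and ANN models on the full dataset
#'
#' Trains final models on every measurement (no held-out data), following
#' the same protocol as the split experiments: reduction, train-statistics
#' standardization, LOO component selection for PLS, and an
#' evidence-selected committee for the ANN. Reported metrics are
#' in-sample fit statistics, not predictive estimates.
#'
#' @param data A descriptor table.
#' @param n_hidden Hidden-node count of the production committee
#'   (default 2).
#' @param n_networks,k Committee parameters.
#' @param max_comp Maximum PLS components scanned.
#' @param cv_threshold,ufs_r2_max Reduction parameters.
#' @param seed Master seed.
#' @param ... Passed to [bnn_train()].
#' @return A list of class `kd_production_models`: `pls`, `committee`
#'   (both with stored standardizer where relevant), `metrics` (tibble of
#'   in-sample R2/MUE per method, flagged `in_sample = TRUE`), `selected`
#'   descriptor names.
#' @export
train_production_models <- function(data, n_hidden = 2L, n_networks = 100L,
                                    k = 10L, max_comp = 10L,
                                    cv_threshold = 0.05, ufs_r2_max = 0.99,
                                    seed = 1L, ...) {
  red <- reduce_descriptors(data, cv_threshold, ufs_r2_max)
  sel <- red$ufs$selected
  xmat <- as.matrix(data[, sel, drop = FALSE])
  std <- fit_standardizer(xmat)
  xs <- apply_standardizer(std, xmat)
  y <- data$log_kd

  ncomp <- select_ncomp_loo(xs, y, max_comp)
  pls <- fit_pls(xs, y, ncomp$n_components)
  pls$standardizer <- std
  pr_pls <- predict(pls, xs)

  cmt <- train_committee(xs, y, arch = as.integer(n_hidden),
                         n_networks = n_networks, k = k,
                         seed = kd_substream(seed, "production", 0L),
                         standardizer = NULL, ...)
  cmt$standardizer <- std
  pr_ann <- predict_committee(cmt, xmat)

  metrics <- dplyr::bind_rows(
    dplyr::mutate(fit_metrics(y, pr_pls, ncomp$n_components),
                  method = "PLS", in_sample = TRUE),
    dplyr::mutate(fit_metrics(y, pr_ann, 0L),
                  method = "ANN committee", in_sample = TRUE)
  )
  structure(list(pls = pls, committee = cmt, metrics = metrics,
                 selected = sel, standardizer = std,
                 ncomp = ncomp$n_components),
            class = "kd_production_models")
}

#' @export
print.kd_production_models <- function(x, ...) {
  cat("Production models on the full dataset (in-sample fit statistics):\n")
  print(dplyr::select(x$metrics, "method", "r2", "mue", "in_sample"))
  invisible(x)
}
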