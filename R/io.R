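#' Read a descriptor table from CSV
#'
#' Loads a comma-separated descriptor table (UTF-8, header mandatory). The
#' reserved columns `compound_id`, `charge_class`, `log_kow` and `log_kd`
#' are required; `smiles`, `log_dow_74`, `experimental_ph` and `study_id`
#' are optional. Every other column is treated as a numeric molecular
#' descriptor. Rows with missing `log_kd` are dropped (with a message);
#' missing descriptor cells are handled per `missing_policy`.
#'
#' @param path Path to a CSV file.
#' @param missing_policy One of `"error"` (fail on any missing descriptor
#'   cell, reporting row and column), `"drop_row"` (drop rows containing
#'   missing descriptor values) or `"drop_column"` (drop descriptor columns
#'   containing missing values).
#' @return A tibble descriptor table.
#' @export
read_descriptor_table <- function(path,
                                  missing_policy = c("error", "drop_row", "drop_column")) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "sorbkd_io_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  required <- c("compound_id", "charge_class", "log_kow", "log_kd")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Descriptor table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "sorbkd_format_error")
  }
  bad_class <- setdiff(unique(data$charge_class), kd_charge_classes())
  if (length(bad_class) > 0L) {
    abort(sprintf("Unknown charge_class value(s): %s",
                  paste(bad_class, collapse = ", ")),
          class = "sorbkd_format_error")
  }

  n_missing_kd <- sum(!is.finite(data$log_kd))
  if (n_missing_kd > 0L) {
    inform(sprintf("Dropped %d row(s) with missing log_kd.", n_missing_kd))
    data <- data[is.finite(data$log_kd), , drop = FALSE]
  }

  desc <- descriptor_names(data)
  for (nm in desc) {
    if (!is.numeric(data[[nm]])) {
      suppressWarnings(num <- as.numeric(data[[nm]]))
      if (missing_policy == "error" && anyNA(num) && !anyNA(data[[nm]])) {
        abort(sprintf("Non-numeric descriptor value in column '%s' (row %d).",
                      nm, which(is.na(num))[1]),
              class = "sorbkd_parse_error")
      }
      data[[nm]] <- num
    }
  }

  if (length(desc) > 0L) {
    na_mat <- is.na(as.matrix(data[, desc, drop = FALSE]))
    if (any(na_mat)) {
      if (missing_policy == "error") {
        hit <- which(na_mat, arr.ind = TRUE)[1, ]
        abort(sprintf("Missing descriptor value at row %d, column '%s'.",
                      hit[["row"]], desc[hit[["col"]]]),
              class = "sorbkd_parse_error")
      } else if (missing_policy == "drop_row") {
        keep <- rowSums(na_mat) == 0L
        inform(sprintf("Dropped %d row(s) with missing descriptor values.",
                       sum(!keep)))
        data <- data[keep, , drop = FALSE]
      } else {
        bad <- desc[colSums(na_mat) > 0L]
        inform(sprintf("Dropped %d descriptor column(s) with missing values: %s",
                       length(bad), paste(bad, collapse = ", ")))
        data <- data[, setdiff(names(data), bad), drop = FALSE]
      }
    }
  }
  tibble::as_tibble(data)
}

#' Write a descriptor table to CSV
#'
#' @param data A descriptor table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

# ---- model serialization ----------------------------------------------------

kd_model_kind <- function(model) {
  if (inherits(model, "kd_univariate")) "univariate"
  else if (inherits(model, "kd_pls")) "pls"
  else if (inherits(model, "kd_bnn")) "bnn"
  else if (inherits(model, "kd_committee")) "committee"
  else NA_character_
}

#' Serialize a fitted model to JSON
#'
#' Supports univariate models, PLS models, single Bayesian networks and
#' committees. `read_model(write_model(m, path))` reproduces predictions
#' exactly (numbers are written at full double precision).
#'
#' @param model A fitted sorbkd model object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  kind <- kd_model_kind(model)
  if (is.na(kind)) {
    abort("Unknown model kind: cannot serialize.",
          class = "sorbkd_serialization_error")
  }
  payload <- list(kind = kind, model = unclass_model(model))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

unclass_model <- function(model) {
  if (inherits(model, "kd_committee")) {
    out <- unclass(model)
    out$members <- lapply(out$members, unclass_model)
    out$evidence <- as.list(out$evidence)
    if (!is.null(out$standardizer)) {
      out$standardizer <- unclass(out$standardizer)
    }
    return(out)
  }
  out <- unclass(model)
  if (!is.null(out$standardizer)) out$standardizer <- unclass(out$standardizer)
  # matrices -> list of rows with dimnames kept separately
  for (nm in names(out)) {
    if (is.matrix(out[[nm]])) {
      out[[nm]] <- list(
        .matrix = TRUE, dim = dim(out[[nm]]),
        dimnames = dimnames(out[[nm]]), values = as.numeric(out[[nm]])
      )
    }
  }
  out
}

reclass_model <- function(x, kind) {
  restore <- function(out) {
    for (nm in names(out)) {
      el <- out[[nm]]
      if (is.list(el) && isTRUE(el$.matrix)) {
        m <- matrix(unlist(el$values), nrow = el$dim[[1]], ncol = el$dim[[2]])
        if (!is.null(el$dimnames)) {
          dimnames(m) <- lapply(el$dimnames, function(d) unlist(d) %||% NULL)
        }
        out[[nm]] <- m
      } else if (is.list(el) && length(el) > 0 &&
                 all(vapply(el, is.numeric, logical(1))) &&
                 all(lengths(el) == 1L)) {
        out[[nm]] <- unlist(el)
      }
    }
    out
  }
  cls <- switch(kind,
    univariate = "kd_univariate", pls = "kd_pls",
    bnn = "kd_bnn", committee = "kd_committee",
    abort(sprintf("Unknown model kind '%s' in file.", kind),
          class = "sorbkd_serialization_error")
  )
  if (kind == "committee") {
    x$members <- lapply(x$members, function(m) {
      structure(restore(m), class = "kd_bnn")
    })
    x$evidence <- tibble::as_tibble(lapply(x$evidence, unlist))
    if (!is.null(x$standardizer)) {
      x$standardizer <- structure(
        lapply(x$standardizer, unlist), class = "kd_standardizer")
    }
    return(structure(x, class = cls))
  }
  out <- restore(x)
  if (!is.null(out$standardizer)) {
    out$standardizer <- structure(lapply(out$standardizer, unlist),
                                  class = "kd_standardizer")
  }
  structure(out, class = cls)
}

#' Read a serialized model from JSON
#'
#' @param path Path written by [write_model()].
#' @return The fitted model object.
#' @export
read_model <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                        simplifyDataFrame = FALSE),
    error = function(e) {
      abort(sprintf("Cannot read model file '%s': %s", path,
                    conditionMessage(e)),
            class = "sorbkd_io_error")
    }
  )
  if (!is.list(payload) || is.null(payload$kind) || is.null(payload$model)) {
    abort(sprintf("File '%s' is not a serialized sorbkd model.", path),
          class = "sorbkd_serialization_error")
  }
  reclass_model(payload$model, payload$kind)
}

# ---- run configuration ------------------------------------------------------

#' Pipeline run configuration
#'
#' Bundles the tunable parameters of the modelling pipeline with their
#' defaults: a CV-filter threshold of 0.05, a UFS multiple-correlation cap
#' of 0.99, five random 60-measurement test sets, 2-5 hidden nodes, 100
#' networks per committee with the best 10 (by log evidence) retained,
#' stepwise entry/removal alphas of 0.15, and a leverage threshold of
#' 3 p / n.
#'
#' @param cv_threshold Coefficient-of-variation threshold below which
#'   descriptors are removed.
#' @param ufs_r2_max Maximum multiple R2 a candidate may have with the
#'   already-selected set in unsupervised forward selection.
#' @param n_test Test-set size per split.
#' @param n_splits Number of independent train/test splits.
#' @param hidden_nodes Integer vector of hidden-layer sizes to scan.
#' @param n_networks Networks trained per committee.
#' @param committee_size Members retained per committee (by log evidence).
#' @param alpha_enter,alpha_remove Stepwise entry/removal p-value cutoffs.
#' @param leverage_multiplier Rows with hat value above
#'   `leverage_multiplier * p / n` are flagged.
#' @param max_components Maximum PLS components scanned.
#' @param master_seed Master seed; all randomness flows from it through
#'   named substreams.
#' @return An object of class `kd_run_config`.
#' @export
run_config <- function(cv_threshold = 0.05,
                       ufs_r2_max = 0.99,
                       n_test = 60L,
                       n_splits = 5L,
                       hidden_nodes = 2:5,
                       n_networks = 100L,
                       committee_size = 10L,
                       alpha_enter = 0.15,
                       alpha_remove = 0.15,
                       leverage_multiplier = 3,
                       max_components = 10L,
                       master_seed = 1L) {
  if (!is.numeric(cv_threshold) || cv_threshold <= 0) {
    abort("`cv_threshold` must be > 0.", class = "sorbkd_config_error")
  }
  if (!is.numeric(ufs_r2_max) || ufs_r2_max <= 0 || ufs_r2_max >= 1) {
    abort("`ufs_r2_max` must be in (0, 1).", class = "sorbkd_config_error")
  }
  check_count(n_test, "n_test")
  check_count(n_splits, "n_splits")
  check_count(n_networks, "n_networks")
  check_count(committee_size, "committee_size")
  check_count(max_components, "max_components")
  if (committee_size > n_networks) {
    abort("`committee_size` cannot exceed `n_networks`.",
          class = "sorbkd_config_error")
  }
  if (any(hidden_nodes < 1)) {
    abort("`hidden_nodes` must be positive.", class = "sorbkd_config_error")
  }
  for (a in c(alpha_enter, alpha_remove)) {
    if (!is.numeric(a) || a <= 0 || a >= 1) {
      abort("Stepwise alphas must be in (0, 1).", class = "sorbkd_config_error")
    }
  }
  structure(
    list(cv_threshold = cv_threshold, ufs_r2_max = ufs_r2_max,
         n_test = as.integer(n_test), n_splits = as.integer(n_splits),
         hidden_nodes = as.integer(hidden_nodes),
         n_networks = as.integer(n_networks),
         committee_size = as.integer(committee_size),
         alpha_enter = alpha_enter, alpha_remove = alpha_remove,
         leverage_multiplier = leverage_multiplier,
         max_components = as.integer(max_components),
         master_seed = as.integer(master_seed)),
    class = "kd_run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' The file holds a flat key set mirroring the arguments of
#' [run_config()]; keys not present keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `kd_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "sorbkd_io_error")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "sorbkd_config_error")
  }
  do.call(run_config, vals)
}
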