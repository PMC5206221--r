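# Internal helpers shared across modules.

# Reserved (non-descriptor) column names of a descriptor table.
kd_reserved_cols <- function() {
  c("compound_id", "smiles", "charge_class", "log_kow", "log_dow_74",
    "log_kd", "experimental_ph", "study_id")
}

kd_charge_classes <- function() {
  c("uncharged", "positive", "negative", "zwitterion")
}

#' Names of the descriptor columns of a descriptor table
#'
#' Every column that is not one of the reserved metadata columns
#' (`compound_id`, `smiles`, `charge_class`, `log_kow`, `log_dow_74`,
#' `log_kd`, `experimental_ph`, `study_id`) is treated as a numeric
#' molecular descriptor.
#'
#' @param data A descriptor table (data frame).
#' @return Character vector of descriptor column names.
#' @export
descriptor_names <- function(data) {
  setdiff(names(data), kd_reserved_cols())
}

#' Extract the descriptor matrix of a descriptor table
#'
#' @param data A descriptor table.
#' @return Numeric matrix (measurements x descriptors) with column names.
#' @export
descriptor_matrix <- function(data) {
  nm <- descriptor_names(data)
  if (length(nm) == 0L) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  as.matrix(data[, nm, drop = FALSE])
}

# Deterministic sub-seed derived from a master seed and a stream name.
# Keeps results < 2^31 so they are valid R integer seeds.
kd_substream <- function(master_seed, name, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(as.character(name))) {
    h <- (h * 31 + ch) %% 1000003
  }
  as.integer((abs(as.numeric(master_seed)) * 2654435 + h * 97 + index) %% 2147483629)
}

# Validate a positive scalar count.
check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x)) {
    abort(sprintf("`%s` must be a single positive integer.", field),
          class = "sorbkd_config_error")
  }
  invisible(as.integer(x))
}

check_matrix_xy <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) {
    abort("`x` and `y` must have matching row counts.",
          class = "sorbkd_input_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite.", class = "sorbkd_input_error")
  }
  list(x = x, y = y)
}
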