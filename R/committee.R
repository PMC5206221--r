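#' Train a committee of Bayesian networks and keep the best by evidence
#'
#' Trains `n_networks` networks that differ only in their weight
#' initialization seed, ranks them by log evidence, and retains the top
#' `k` as the committee (ties broken by seed order). Members that fail to
#' train are logged and excluded; an error is raised only if fewer than
#' `k` members survive.
#'
#' @param x Standardized input matrix.
#' @param y Targets.
#' @param arch Architecture (or hidden-node count).
#' @param n_networks Number of networks trained (default 100).
#' @param k Committee size retained (default 10).
#' @param seed Master seed; member seeds are derived substreams.
#' @param standardizer Optional `kd_standardizer` stored on the committee
#'   and applied by `predict()`.
#' @param ... Passed to [bnn_train()] (e.g. `outer_loops`, `max_iter`).
#' @return An object of class `kd_committee`: `members` (the selected
#'   models, best first), `evidence` (tibble over all trained networks),
#'   `k`, `standardizer`.
#' @export
train_committee <- function(x, y, arch = 2L, n_networks = 100L, k = 10L,
                            seed = 1L, standardizer = NULL, ...) {
  check_count(n_networks, "n_networks")
  check_count(k, "k")
  if (k > n_networks) {
    abort("`k` cannot exceed `n_networks`.", class = "sorbkd_config_error")
  }
  models <- vector("list", n_networks)
  ok <- logical(n_networks)
  for (m in seq_len(n_networks)) {
    member_seed <- kd_substream(seed, "init", m)
    models[[m]] <- tryCatch(
      bnn_train(x, y, arch = arch, seed = member_seed, ...),
      error = function(e) {
        warn(sprintf("Committee member %d failed to train: %s", m,
                     conditionMessage(e)))
        NULL
      }
    )
    ok[m] <- !is.null(models[[m]])
  }
  if (sum(ok) < k) {
    abort(sprintf("Only %d of %d members trained; cannot form a committee of %d.",
                  sum(ok), n_networks, k),
          class = "sorbkd_training_error")
  }
  ev <- vapply(models, function(m) if (is.null(m)) -Inf else m$log_evidence,
               numeric(1))
  ord <- order(-ev, seq_len(n_networks))     # ties broken by seed order
  sel <- ord[seq_len(k)]
  evidence <- tibble::tibble(
    member = seq_len(n_networks),
    seed = vapply(seq_len(n_networks), function(m) kd_substream(seed, "init", m),
                  integer(1)),
    log_evidence = ev,
    trained = ok,
    selected = seq_len(n_networks) %in% sel
  )
  structure(
    list(members = models[sel], evidence = evidence, k = as.integer(k),
         standardizer = standardizer),
    class = "kd_committee"
  )
}

#' Committee prediction: mean over members, with spread
#'
#' @param committee A `kd_committee`.
#' @param x Input matrix or descriptor table. If the committee stores a
#'   standardizer it is applied first; otherwise `x` must already be
#'   standardized the way the members were trained.
#' @param spread If `TRUE`, return a tibble with per-point member
#'   min/max alongside the mean.
#' @return Numeric vector of committee-mean predictions, or a tibble
#'   (`.pred`, `.pred_lo`, `.pred_hi`) when `spread = TRUE`.
#' @export
predict_committee <- function(committee, x, spread = FALSE) {
  if (!inherits(committee, "kd_committee") || length(committee$members) == 0L) {
    abort("`committee` must be a non-empty kd_committee.",
          class = "sorbkd_input_error")
  }
  if (is.data.frame(x)) {
    nms <- committee$members[[1]]$input_names
    x <- as.matrix(x[, nms, drop = FALSE])
  }
  if (!is.null(committee$standardizer)) {
    x <- apply_standardizer(committee$standardizer, x)
  }
  preds <- vapply(committee$members, function(m) {
    bnn_forward(bnn_arch_of(m), m$w, x) + m$y_center
  }, numeric(nrow(as.matrix(x))))
  preds <- matrix(preds, nrow = nrow(as.matrix(x)))
  mean_pred <- rowMeans(preds)
  if (!spread) return(mean_pred)
  tibble::tibble(.pred = mean_pred,
                 .pred_lo = apply(preds, 1, min),
                 .pred_hi = apply(preds, 1, max))
}

#' @export
predict.kd_committee <- function(object, newdata, spread = FALSE, ...) {
  predict_committee(object, newdata, spread = spread)
}

#' @export
print.kd_committee <- function(x, ...) {
  cat(sprintf("Committee: %d of %d networks (%d hidden units), log evidence %.2f to %.2f\n",
              x$k, nrow(x$evidence), x$members[[1]]$n_hidden,
              min(vapply(x$members, `[[`, numeric(1), "log_evidence")),
              max(vapply(x$members, `[[`, numeric(1), "log_evidence"))))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.kd_committee <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_networks = nrow(x$evidence),
    n_hidden = x$members[[1]]$n_hidden,
    best_log_evidence = max(x$evidence$log_evidence)
  )
}

#' Descriptor relevance ranking by automatic relevance determination
#'
#' Within each committee member, inputs are ranked by ascending ARD prior
#' precision alpha (small alpha = weakly decayed = large weights = most
#' relevant); the final order is by mean rank across members, ties broken
#' by descriptor name.
#'
#' @param committee A `kd_committee` (or a single `kd_bnn`).
#' @return A tibble with `rank`, `term`, `mean_rank`, `mean_alpha`,
#'   ordered most relevant first; also classed `kd_ard_ranking` for
#'   plotting.
#' @export
ard_ranking <- function(committee) {
  members <- if (inherits(committee, "kd_bnn")) list(committee)
             else committee$members
  if (length(members) == 0L) {
    abort("Empty committee.", class = "sorbkd_input_error")
  }
  nms <- members[[1]]$input_names
  per_member_rank <- vapply(members, function(m) {
    a <- m$alpha[nms]
    rk <- numeric(length(nms))
    rk[order(a, nms)] <- seq_along(nms)
    rk
  }, numeric(length(nms)))
  per_member_alpha <- vapply(members, function(m) unname(m$alpha[nms]),
                             numeric(length(nms)))
  mean_rank <- rowMeans(matrix(per_member_rank, nrow = length(nms)))
  mean_alpha <- rowMeans(matrix(per_member_alpha, nrow = length(nms)))
  ord <- order(mean_rank, nms)
  out <- tibble::tibble(rank = seq_along(nms), term = nms[ord],
                        mean_rank = mean_rank[ord],
                        mean_alpha = mean_alpha[ord])
  class(out) <- c("kd_ard_ranking", class(out))
  out
}
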