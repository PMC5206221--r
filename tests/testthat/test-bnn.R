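test_that("forward pass obeys tanh-network algebra", {
  arch <- bnn_architecture(3, 2)
  nw <- bnn_n_weights(arch)
  x <- matrix(rnorm(12), 4, 3)

  # all-zero weights: output equals the output bias
  w <- rep(0, nw)
  w[nw] <- 0.7
  expect_equal(bnn_forward(arch, w, x), rep(0.7, 4))

  # single input / single hidden unit tanh limits
  a1 <- bnn_architecture(1, 1)
  w1 <- c(1, 0, 1, 0)  # w=1, b1=0, v=1, b2=0
  expect_equal(bnn_forward(a1, w1, matrix(0)), 0)
  expect_equal(bnn_forward(a1, w1, matrix(50)), 1, tolerance = 1e-12)
  expect_equal(bnn_forward(a1, w1, matrix(-50)), -1, tolerance = 1e-12)

  expect_error(bnn_forward(arch, w, matrix(rnorm(8), 4, 2)), "expects 3")
})

test_that("small-weight networks agree with their linearization to third order", {
  set.seed(40)
  p <- 4; h <- 3
  arch <- bnn_architecture(p, h)
  w1 <- matrix(rnorm(h * p), h, p)
  b1 <- rnorm(h)
  v <- rnorm(h)
  b2 <- rnorm(1)
  x <- matrix(rnorm(20 * p), 20, p)
  # scale the first layer: tanh(eps a) = eps a + O(eps^3), so the gap to
  # the identity-activation network shrinks cubically
  lin_err <- function(eps) {
    w <- c(as.numeric(eps * w1), eps * b1, v, b2)
    a <- sweep(x %*% t(eps * w1), 2, eps * b1, "+")
    linear <- drop(a %*% v + b2)
    max(abs(bnn_forward(arch, w, x) - linear))
  }
  e1 <- lin_err(1e-2)
  e2 <- lin_err(5e-3)
  expect_gt(e1 / e2, 6)  # cubic scaling: halving eps shrinks error ~8x
})

test_that("regularized error decomposes exactly and its gradient is exact", {
  set.seed(41)
  arch <- bnn_architecture(5, 3)
  gi <- sorbkd:::bnn_groups(arch)
  w <- rnorm(gi$n_weights, 0, 0.5)
  x <- matrix(rnorm(20 * 5), 20, 5)
  y <- rnorm(20)
  alpha <- runif(length(gi$groups), 0.1, 2)
  beta <- 1.7

  e <- bnn_error(arch, w, x, y, alpha, beta)
  # zero weights, centred targets: E_W = 0, E_D = 0.5 sum y^2
  yc <- y - mean(y)
  e0 <- bnn_error(arch, rep(0, gi$n_weights), x, yc, alpha, beta)
  expect_equal(sum(e0$e_w), 0)
  expect_equal(e0$e_d, 0.5 * sum(yc^2))

  # doubling one alpha raises the objective by exactly alpha_g E_W(g)
  alpha2 <- alpha
  alpha2[3] <- 2 * alpha[3]
  e2 <- bnn_error(arch, w, x, y, alpha2, beta)
  expect_equal(e2$value - e$value, alpha[3] * e$e_w[[3]], tolerance = 1e-12)

  # central finite differences
  fd <- vapply(seq_along(w), function(k) {
    h <- 1e-6
    wp <- w; wm <- w
    wp[k] <- wp[k] + h; wm[k] <- wm[k] - h
    (bnn_error(arch, wp, x, y, alpha, beta)$value -
       bnn_error(arch, wm, x, y, alpha, beta)$value) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(e$gradient - fd) / pmax(abs(fd), 1e-8)), 1e-5)
})

test_that("MAP training never increases the error and respects stationary starts", {
  set.seed(42)
  arch <- bnn_architecture(3, 2)
  gi <- sorbkd:::bnn_groups(arch)
  x <- matrix(rnorm(50 * 3), 50, 3)
  y <- drop(tanh(x[, 1]) + 0.5 * x[, 2]) + rnorm(50, 0, 0.1)
  y <- y - mean(y)
  alpha <- rep(0.01, length(gi$groups)); beta <- 10

  fit <- bnn_train_map(arch, rnorm(gi$n_weights, 0, 0.3), x, y, alpha, beta)
  expect_lte(fit$value, fit$initial_value)
  # training reaches below the noise level on this easy problem
  resid <- y - bnn_forward(arch, fit$w, x)
  expect_lt(mean(abs(resid)), 0.15)

  # restart from the optimum: no meaningful movement
  again <- bnn_train_map(arch, fit$w, x, y, alpha, beta)
  expect_lt(abs(again$value - fit$value), 1e-8)
})

test_that("hyperparameter re-estimation respects the gamma bounds and limits", {
  set.seed(43)
  arch <- bnn_architecture(4, 2)
  gi <- sorbkd:::bnn_groups(arch)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- drop(x %*% c(1, -0.5, 0, 0)) + rnorm(60, 0, 0.3)
  y <- y - mean(y)
  alpha <- rep(0.1, length(gi$groups)); beta <- 5
  fit <- bnn_train_map(arch, rnorm(gi$n_weights, 0, 0.3), x, y, alpha, beta)
  upd <- bnn_update_hyperparams(arch, fit$w, x, y, alpha, beta)
  sizes <- lengths(gi$groups)
  expect_true(all(upd$gamma_raw >= -1e-8))
  expect_true(all(upd$gamma_raw <= sizes + 1e-8))
  expect_true(all(upd$alpha > 0) && upd$beta > 0)

  # enormous alpha on a group with bounded curvature forces gamma -> 0
  alpha_big <- alpha
  alpha_big[1] <- 1e8
  fit_b <- bnn_train_map(arch, fit$w, x, y, alpha_big, beta)
  upd_b <- bnn_update_hyperparams(arch, fit_b$w, x, y, alpha_big, beta)
  expect_lt(upd_b$gamma[[1]], 1e-3)
})

test_that("the evidence framework matches closed-form Bayesian ridge in linear mode", {
  set.seed(44)
  n <- 20; p <- 3
  x <- matrix(rnorm(n * p), n, p)
  y <- drop(x %*% c(1, -0.5, 0.3)) + rnorm(n, 0, 0.3)
  y <- y - mean(y)
  arch <- bnn_architecture(p, 0)  # linear test hook
  alpha <- c(0.5, 0.8, 1.2, 2.0)
  beta <- 4

  fit <- bnn_train_map(arch, rep(0, p + 1), x, y, alpha, beta, max_iter = 500)
  oracle <- oracle_bayes_ridge(x, y, alpha, beta)
  expect_equal(fit$w, oracle$w, tolerance = 1e-6)

  upd <- bnn_update_hyperparams(arch, fit$w, x, y, alpha, beta)
  expect_equal(unname(upd$gamma), oracle$gamma, tolerance = 1e-5)
  expect_equal(unname(upd$alpha), pmin(pmax(oracle$alpha_new, 1e-8), 1e8),
               tolerance = 1e-5)
  expect_equal(upd$beta, oracle$beta_new, tolerance = 1e-5)

  ev <- bnn_evidence(arch, fit$w, x, y, alpha, beta)
  expect_equal(ev, oracle$log_evidence, tolerance = 1e-5)
})

test_that("the log evidence equals its term-level decomposition", {
  set.seed(45)
  arch <- bnn_architecture(3, 2)
  gi <- sorbkd:::bnn_groups(arch)
  w <- rnorm(gi$n_weights, 0, 0.4)
  x <- matrix(rnorm(30 * 3), 30, 3)
  y <- rnorm(30); y <- y - mean(y)
  alpha <- runif(length(gi$groups), 0.05, 1); beta <- 2
  ev <- bnn_evidence(arch, w, x, y, alpha, beta)
  err <- bnn_error(arch, w, x, y, alpha, beta)
  hess <- sorbkd:::bnn_hessian(arch, w, x, alpha, beta)
  manual <- -beta * err$e_d - sum(alpha * err$e_w) -
    0.5 * sum(log(hess$values)) +
    0.5 * sum(lengths(gi$groups) * log(alpha)) +
    (30 / 2) * log(beta) - (30 / 2) * log(2 * pi)
  expect_equal(ev, manual, tolerance = 1e-12)
  # the beta-dependent normalization term moves the evidence as expected
  ev2 <- bnn_evidence(arch, w, x, y, alpha, 2 * beta)
  err_term <- -2 * beta * err$e_d + beta * err$e_d
  hess2 <- sorbkd:::bnn_hessian(arch, w, x, alpha, 2 * beta)
  expect_equal(ev2 - ev,
               err_term + (30 / 2) * log(2) -
                 0.5 * (sum(log(hess2$values)) - sum(log(hess$values))),
               tolerance = 1e-10)
})

test_that("training is deterministic and outer_loops = 0 is the plain MAP fit", {
  set.seed(46)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- drop(tanh(x[, 1])) + rnorm(40, 0, 0.2)
  m1 <- bnn_train(x, y, arch = 2, seed = 99, outer_loops = 3)
  m2 <- bnn_train(x, y, arch = 2, seed = 99, outer_loops = 3)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$log_evidence, m2$log_evidence)

  m0 <- bnn_train(x, y, arch = 2, seed = 99, outer_loops = 0,
                  alpha_init = 0.02, beta_init = 3)
  expect_true(all(m0$alpha == 0.02))
  expect_equal(m0$beta, 3)
  # at the returned weights the MAP objective is stationary
  arch <- bnn_architecture(3, 2)
  g <- bnn_error(arch, m0$w, x, y - m0$y_center, m0$alpha, m0$beta)$gradient
  expect_lt(max(abs(g)), 1e-3)
})

test_that("ARD drives noise-input precisions above the signal input's", {
  wins <- vapply(1:6, function(s) {
    set.seed(700 + s)
    n <- 100
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, c("sig", paste0("noise", 1:4))))
    y <- tanh(1.5 * x[, "sig"]) + rnorm(n, 0, 0.2)
    m <- bnn_train(x, y, arch = 2, seed = s, outer_loops = 6)
    median(m$alpha[paste0("noise", 1:4)]) > m$alpha[["sig"]]
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("committees select by evidence and average their members", {
  set.seed(47)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- drop(tanh(x[, 1]) - 0.5 * x[, 2]) + rnorm(60, 0, 0.2)
  cmt <- train_committee(x, y, arch = 2, n_networks = 6, k = 3, seed = 5,
                         outer_loops = 3)
  ev <- cmt$evidence
  expect_gte(min(ev$log_evidence[ev$selected]),
             max(ev$log_evidence[!ev$selected]))
  expect_length(cmt$members, 3)

  probe <- matrix(rnorm(15 * 3), 15, 3)
  pred <- predict_committee(cmt, probe)
  hand <- rowMeans(vapply(cmt$members, function(m) predict(m, probe),
                          numeric(15)))
  expect_equal(pred, hand, tolerance = 1e-12)

  sp <- predict_committee(cmt, probe, spread = TRUE)
  expect_true(all(sp$.pred >= sp$.pred_lo - 1e-12 &
                    sp$.pred <= sp$.pred_hi + 1e-12))

  # member order does not change the mean
  perm <- cmt
  perm$members <- rev(cmt$members)
  expect_equal(predict_committee(perm, probe), pred, tolerance = 1e-12)

  solo <- train_committee(x, y, arch = 2, n_networks = 1, k = 1, seed = 5,
                          outer_loops = 2)
  expect_equal(predict_committee(solo, probe),
               predict(solo$members[[1]], probe), tolerance = 1e-12)
})

test_that("ARD rankings order by alpha with name tie-breaks", {
  mk <- function(alpha_inputs) {
    structure(list(
      n_inputs = 3L, n_hidden = 2L,
      input_names = c("d1", "d2", "d3"),
      alpha = c(d1 = alpha_inputs[1], d2 = alpha_inputs[2],
                d3 = alpha_inputs[3],
                hidden_bias = 1, output_weights = 1, output_bias = 1),
      w = rep(0, 13), beta = 1, gamma = NULL, y_center = 0,
      log_evidence = 0), class = "kd_bnn")
  }
  rk <- ard_ranking(mk(c(0.1, 10, 1)))
  expect_equal(rk$term, c("d1", "d3", "d2"))

  # two members with reversed rankings tie; names break the tie
  cmt <- structure(list(members = list(mk(c(0.1, 10, 1)), mk(c(10, 0.1, 1))),
                        k = 2L), class = "kd_committee")
  rk2 <- ard_ranking(cmt)
  expect_equal(rk2$mean_rank, rep(2, 3))
  expect_equal(rk2$term, c("d1", "d2", "d3"))
})
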