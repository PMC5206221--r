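test_that("PLS reduces to least squares in the appropriate limits", {
  set.seed(30)
  n <- 60; p <- 5
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- drop(x %*% runif(p, -1, 1)) + rnorm(n, 0, 0.4)

  # full rank: PLS = OLS
  full <- fit_pls(x, y, p)
  ols <- lm.fit(cbind(1, x), y)
  expect_lt(max(abs(predict(full, x) - drop(cbind(1, x) %*% ols$coefficients))),
            1e-8)

  # single predictor, one component = simple OLS
  one <- fit_pls(x[, 1, drop = FALSE], y, 1)
  ols1 <- lm.fit(cbind(1, x[, 1]), y)
  expect_lt(max(abs(predict(one, x[, 1, drop = FALSE]) -
                      drop(cbind(1, x[, 1]) %*% ols1$coefficients))), 1e-10)
})

test_that("first NIPALS weight matches the eigen-oracle up to sign", {
  set.seed(31)
  x <- matrix(rnorm(50 * 6), 50, 6)
  y <- rnorm(50)
  fit <- fit_pls(x, y, 2)
  xs <- scale(x)
  yc <- y - mean(y)
  m <- crossprod(xs, yc) %*% t(crossprod(xs, yc))
  ev <- eigen(m, symmetric = TRUE)$vectors[, 1]
  w1 <- fit$w[, 1]
  expect_lt(min(max(abs(w1 - ev)), max(abs(w1 + ev))), 1e-8)
})

test_that("PLS predictions are invariant to predictor column permutation", {
  set.seed(32)
  x <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- drop(x %*% runif(6)) + rnorm(80, 0, 0.3)
  fit <- fit_pls(x, y, 3)
  perm <- sample(6)
  fit_p <- fit_pls(x[, perm], y, 3)
  expect_equal(predict(fit_p, x[, perm]), predict(fit, x), tolerance = 1e-10)
})

test_that("degenerate PLS inputs raise informative errors", {
  x <- matrix(rnorm(30 * 3), 30, 3)
  expect_error(fit_pls(x, rep(1, 30), 1), "zero variance")
  xr <- cbind(x, x[, 1] + x[, 2])  # rank 3
  expect_error(fit_pls(xr, rnorm(30), 4), "rank 3")
})

test_that("LOO component selection recovers a two-factor structure", {
  hits <- vapply(1:20, function(s) {
    set.seed(400 + s)
    n <- 120
    t1 <- rnorm(n); t2 <- rnorm(n)
    loadings <- matrix(rnorm(2 * 8), 2, 8)
    x <- cbind(t1, t2) %*% loadings   # exactly two latent factors
    y <- 2 * t1 - t2 + rnorm(n, 0, 0.3)
    select_ncomp_loo(x, y, 5)$n_components == 2L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("LOO selection on pure noise yields no predictive components", {
  r2s <- vapply(1:5, function(s) {
    set.seed(500 + s)
    x <- matrix(rnorm(60 * 6), 60, 6)
    sel <- select_ncomp_loo(x, rnorm(60), 4)
    max(sel$r2_cv_all)
  }, numeric(1))
  expect_lt(mean(r2s), 0.05)

  set.seed(33)
  x <- matrix(rnorm(40 * 3), 40, 3)
  expect_equal(select_ncomp_loo(x, rnorm(40), 1)$n_components, 1L)
})

test_that("loading rankings sort by absolute loading and ignore sign flips", {
  set.seed(34)
  x <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("d1", "d2", "d3")))
  y <- rnorm(50)
  fit <- fit_pls(x, y, 1)
  fake <- fit
  fake$p <- matrix(c(0.9, 0.1, -0.5), 3, 1, dimnames = list(c("d1", "d2", "d3")))
  rk <- pls_loading_ranking(list(fake), k_components = 1)
  expect_equal(rk$term, c("d1", "d3", "d2"))

  flipped <- fake
  flipped$p <- -fake$p
  rk2 <- pls_loading_ranking(list(fake, flipped), k_components = 1)
  expect_equal(rk2$term, rk$term)
})

test_that("loading rankings surface the generator's signal columns", {
  hits <- vapply(1:5, function(s) {
    g <- generate_dataset(generator_config(seed = 600 + s))
    sp <- make_splits(nrow(g$data), 60, 3, seed = s)
    models <- lapply(sp$test_indices, function(idx) {
      train <- g$data[-idx, ]
      xmat <- descriptor_matrix(train)
      fit_pls(xmat, train$log_kd, 3)
    })
    rk <- pls_loading_ranking(models, k_components = 1)
    rk$term[1] %in% c(g$truth$signal_columns,
                      names(g$truth$redundant_columns))
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
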