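test_that("CV filter removes low-variation columns and keeps zero-mean ones", {
  set.seed(10)
  tbl <- tibble::tibble(
    constant = rep(5, 50),
    stable = rnorm(50, mean = 10, sd = 1),     # CV = 0.1, kept
    drifting = rnorm(50, mean = 100, sd = 1),  # CV = 0.01, removed
    centred = rnorm(50, mean = 0, sd = 1),     # |mean| ~ 0, kept
    zero = rep(0, 50)                          # constant at zero, removed
  )
  res <- cv_filter(tbl, 0.05)
  expect_true(all(c("constant", "drifting", "zero") %in% res$removed))
  expect_true(all(c("stable", "centred") %in% names(res$data)))
})

test_that("CV filter agrees with direct sd/mean recomputation", {
  set.seed(11)
  for (rep in 1:5) {
    x <- matrix(rnorm(40 * 5, mean = sample(c(0, 1, 20), 5, TRUE)), 40, 5)
    colnames(x) <- paste0("c", 1:5)
    res <- cv_filter(x, 0.05)
    manual <- colnames(x)[abs(apply(x, 2, sd) / colMeans(x)) < 0.05 &
                            abs(colMeans(x)) > 1e-8]
    expect_setequal(res$removed, manual)
  }
})

test_that("UFS selects orthogonal pairs and rejects exact sums", {
  set.seed(12)
  n <- 200
  a <- rnorm(n); b <- rnorm(n)
  res <- ufs_select(cbind(a = a, b = b), 0.99)
  expect_setequal(res$selected, c("a", "b"))
  expect_equal(res$stop_reason, "exhausted")

  x <- cbind(a = a, b = b, ab = a + b)
  res2 <- ufs_select(x, 0.99)
  expect_setequal(res2$selected, c("a", "b"))
  expect_equal(res2$rejected, "ab")
  expect_equal(res2$stop_reason, "r2_max_reached")
  # confirm by direct regression that the rejected column is collinear
  expect_gt(suppressWarnings(summary(lm(x[, "ab"] ~ a + b))$r.squared), 0.99)
})

test_that("UFS matches the exhaustive oracle on small random matrices", {
  set.seed(13)
  for (rep in 1:10) {
    p <- sample(3:8, 1)
    x <- matrix(rnorm(100 * p), 100, p)
    if (rep %% 2 == 0) x[, p] <- x[, 1] - x[, 2] + rnorm(100, 0, 0.05)
    colnames(x) <- sprintf("V%d", seq_len(p))
    mine <- ufs_select(x, 0.9)
    oracle <- oracle_ufs(x, 0.9)
    expect_identical(match(mine$selected, colnames(x)), oracle$selected)
    expect_identical(mine$stop_reason, oracle$reason)
  }
})

test_that("UFS selection set is invariant to column permutation without ties", {
  set.seed(14)
  x <- matrix(rnorm(150 * 6), 150, 6)
  colnames(x) <- sprintf("V%d", 1:6)
  base <- ufs_select(x, 0.95)
  perm <- sample(6)
  shuffled <- ufs_select(x[, perm], 0.95)
  expect_setequal(base$selected, shuffled$selected)
})

test_that("standardizer centres training data and reuses train statistics", {
  set.seed(15)
  x <- matrix(rnorm(80 * 4, mean = 3, sd = 2), 80, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  std <- fit_standardizer(x)
  z <- apply_standardizer(std, x)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4), tolerance = 1e-10)
  # round trip
  expect_equal(apply_standardizer(std, z, invert = TRUE), x, tolerance = 1e-12)
  # shifted test data keeps its shift
  shifted <- x + 5
  expect_gt(min(abs(colMeans(apply_standardizer(std, shifted)))), 1)
  # zero-variance columns are refused with advice
  bad <- cbind(x, fixed = rep(1, 80))
  expect_error(fit_standardizer(bad), "cv_filter")
})

test_that("reduction eliminates exactly the generator's redundant dimensions", {
  # Each redundant column adds one near-dependent dimension. UFS keeps a
  # maximal non-collinear set, so the number of rejected columns equals
  # the redundancy count, and every rejected column is reproducible from
  # the selected set (occasionally a redundant column stands in for one
  # of its generating parents, which carries the same information).
  for (s in c(16, 20)) {
    g <- generate_dataset(generator_config(seed = s))
    red <- reduce_descriptors(g$data, cv_threshold = 0.05, ufs_r2_max = 0.95)
    n_red <- length(g$truth$redundant_columns)
    expect_length(red$ufs$rejected, n_red)
    xsel <- as.matrix(g$data[, red$ufs$selected, drop = FALSE])
    for (nm in red$ufs$rejected) {
      expect_gte(summary(lm(g$data[[nm]] ~ xsel))$r.squared, 0.95)
    }
    # rejected columns are all tied to the redundancy structure: either a
    # redundant column or one of its generating parents
    parents <- unique(unlist(lapply(g$truth$redundant_columns, `[[`, "parents")))
    expect_true(all(red$ufs$rejected %in%
                      c(names(g$truth$redundant_columns), parents)))
  }
})
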