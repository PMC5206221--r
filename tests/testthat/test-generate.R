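test_that("default generator reproduces the study's dataset structure", {
  g <- generate_dataset(generator_config(seed = 3))
  expect_equal(nrow(g$data), 297L)
  expect_equal(length(unique(g$data$compound_id)), 148L)
  counts <- table(g$data$charge_class)
  expect_equal(unname(counts[c("uncharged", "positive", "negative", "zwitterion")]),
               unname(as.table(c(92L, 105L, 76L, 24L))))
  # replicated compounds exist and the exact log Kow descriptor is present
  expect_gt(sum(table(g$data$compound_id) >= 2), 0)
  expect_equal(g$data$d_logkow, g$data$log_kow)
  expect_equal(length(descriptor_names(g$data)), 25L)
})

test_that("generation is bit-identical under the same seed", {
  a <- generate_dataset(generator_config(seed = 17))
  b <- generate_dataset(generator_config(seed = 17))
  expect_identical(a$data, b$data)
  c <- generate_dataset(generator_config(seed = 18))
  expect_false(identical(a$data$log_kd, c$data$log_kd))
})

test_that("noise-free data sit exactly on the class lines", {
  g <- generate_dataset(noise_free_class_config(seed = 5))
  cfg <- generator_config()
  expected <- cfg$class_intercepts[g$data$charge_class] +
    cfg$class_slopes[g$data$charge_class] * g$data$log_kow
  expect_equal(g$data$log_kd, unname(expected), tolerance = 1e-12)
  # per-class univariate fits recover the configured truth
  for (cc in c("uncharged", "positive")) {
    sub <- g$data[g$data$charge_class == cc, ]
    m <- fit_univariate(sub)
    expect_equal(m$slope, unname(cfg$class_slopes[cc]), tolerance = 1e-10)
    expect_equal(m$intercept, unname(cfg$class_intercepts[cc]), tolerance = 1e-10)
  }
})

test_that("redundant columns are reproduced by their recorded combinations", {
  g <- generate_dataset(generator_config(seed = 9))
  cmp <- g$data[!duplicated(g$data$compound_id), ]
  for (nm in names(g$truth$redundant_columns)) {
    info <- g$truth$redundant_columns[[nm]]
    reconstructed <- as.matrix(cmp[, info$parents, drop = FALSE]) %*%
      info$coefficients
    resid <- cmp[[nm]] - drop(reconstructed)
    expect_lt(sd(resid), 5 * info$noise_sd)
  }
})

test_that("replicate range statistic matches hand arithmetic and an oracle loop", {
  tbl <- tibble::tibble(
    compound_id = c("a", "a", "a", "b", "b", "c"),
    log_kd = c(1.0, 1.5, 2.0, 0.0, 0.8, 5)
  )
  st <- replicate_range_statistic(tbl)
  expect_equal(st$mean_range, 0.9)
  expect_equal(st$median_range, 0.9)

  singles <- tibble::tibble(compound_id = letters[1:4], log_kd = rnorm(4))
  st0 <- replicate_range_statistic(singles)
  expect_equal(c(st0$mean_range, st0$median_range), c(0, 0))

  g <- generate_dataset(generator_config(seed = 21))
  st2 <- replicate_range_statistic(g$data)
  # brute-force per-compound max - min
  ids <- unique(g$data$compound_id)
  r <- c()
  for (id in ids) {
    v <- g$data$log_kd[g$data$compound_id == id]
    if (length(v) >= 2) r <- c(r, max(v) - min(v))
  }
  expect_equal(st2$mean_range, mean(r))
  expect_equal(st2$median_range, median(r))
})

test_that("replicate noise is calibrated to the configured spread target", {
  ranges <- vapply(1:5, function(s) {
    replicate_range_statistic(generate_dataset(generator_config(seed = s))$data)$mean_range
  }, numeric(1))
  expect_lt(abs(mean(ranges) - 0.91), 0.15)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(generator_config(n_redundant = 25, n_descriptors = 25),
               "n_redundant")
  expect_error(
    generator_config(class_compound_counts = c(uncharged = 40, positive = 60,
                                               negative = 28, zwitterion = 16)),
    "class_compound_counts")
  expect_error(generator_config(replicate_spread_target = -1),
               "replicate_spread_target")
  expect_error(generate_dataset(list(n_compounds = 10)), "generator_config")
})
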