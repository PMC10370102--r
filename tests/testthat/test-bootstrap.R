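test_that("percentile intervals interpolate empirical quantiles", {
  ci <- percentile_ci(1:100, 0.9)
  expect_equal(unname(ci), c(5.95, 95.05))
  expect_equal(unname(percentile_ci(rep(3.2, 10), 0.95)), c(3.2, 3.2))
  # level -> 1 approaches the sample range
  ci99 <- percentile_ci(1:100, 0.999)
  expect_equal(unname(ci99), c(1.0495, 99.9505))
  expect_error(percentile_ci(numeric(0)), "no replicates")
  # widening the level never shrinks the interval
  set.seed(31)
  x <- rnorm(200)
  c80 <- percentile_ci(x, 0.8)
  c95 <- percentile_ci(x, 0.95)
  expect_lte(c95[["lo"]], c80[["lo"]])
  expect_gte(c95[["hi"]], c80[["hi"]])
})

test_that("bootstrap machinery resamples, summarizes, and reproduces", {
  set.seed(32)
  reads <- tibble::tibble(read_id = sprintf("r%03d", 1:60), value = rnorm(60, 5))
  mean_fitter <- function(r) c(mu = mean(r$value))
  bs <- bootstrap_fit(reads, mean_fitter, n_boot = 50, ci_level = 0.9, seed = 7)
  expect_equal(nrow(bs$replicates), 50L)
  expect_equal(bs$ci$estimate, mean(reads$value))
  expect_lte(bs$ci$conf.low, bs$ci$median)
  expect_gte(bs$ci$conf.high, bs$ci$median)
  bs2 <- bootstrap_fit(reads, mean_fitter, n_boot = 50, ci_level = 0.9, seed = 7)
  expect_identical(bs$replicates, bs2$replicates)

  # n_boot = 1: interval degenerates to the single replicate
  b1 <- bootstrap_fit(reads, mean_fitter, n_boot = 1, seed = 3)
  expect_equal(b1$ci$conf.low, b1$ci$conf.high)

  # failing replicates are skipped with a warning and counted
  flaky_n <- 0
  flaky <- function(r) {
    flaky_n <<- flaky_n + 1
    if (flaky_n == 2) stop("boom")
    c(mu = mean(r$value))
  }
  expect_warning(
    bf <- bootstrap_fit(reads, flaky, n_boot = 4, seed = 5),
    "failed"
  )
  expect_equal(bf$n_failed, 1L)
  expect_equal(nrow(bf$replicates), 3L)
})

test_that("percentile intervals achieve near-nominal coverage for a mean", {
  set.seed(33)
  n <- 40
  n_exp <- 120
  covered <- 0
  for (i in seq_len(n_exp)) {
    reads <- tibble::tibble(value = rnorm(n, 2, 1))
    bs <- bootstrap_fit(reads, function(r) c(mu = mean(r$value)),
      n_boot = 120, ci_level = 0.9, seed = 1000 + i
    )
    if (bs$ci$conf.low <= 2 && bs$ci$conf.high >= 2) covered <- covered + 1
  }
  # 90% nominal; allow 4 binomial SDs (sd ~ 2.7%)
  expect_gt(covered / n_exp, 0.9 - 4 * sqrt(0.9 * 0.1 / n_exp))
})

test_that("the bootstrap plot exposes replicate spread and point estimates", {
  reads <- tibble::tibble(value = rnorm(30))
  bs <- bootstrap_fit(reads, function(r) {
    c(a = mean(r$value), b = stats::sd(r$value))
  }, n_boot = 10, seed = 2)
  p <- autoplot(bs, truth = c(a = 0, b = 1))
  expect_s3_class(p, "ggplot")
  td <- tidy(bs)
  expect_named(td, c("term", "estimate", "conf.low", "conf.high", "median"))
})
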