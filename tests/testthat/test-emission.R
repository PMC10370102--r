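test_that("emission densities follow the count-k normal model", {
  p <- seq_params(mu = 6000, sigma = 900, bg_mu = 0, bg_sigma = 350)
  expect_equal(emission_density(0, 0, p), 1 / (350 * sqrt(2 * pi)))
  expect_equal(
    emission_density(6000, 1, p),
    1 / (sqrt(350^2 + 900^2) * sqrt(2 * pi))
  )
  expect_error(emission_density(0, -1, p), "non-negative")
  # integrates to one over intensity
  for (k in 0:2) {
    int <- stats::integrate(function(y) emission_density(y, k, p),
      -2e4, 4e4,
      rel.tol = 1e-10
    )
    expect_equal(int$value, 1, tolerance = 1e-8)
  }
})

test_that("channel fitting recovers a normal peak from its mode and width", {
  set.seed(11)
  x <- rnorm(50000, 6000, 800)
  fit <- fit_channel_distribution(x)
  expect_lt(abs(fit$mu - 6000) / 6000, 0.02)
  expect_lt(abs(fit$sigma - 800) / 800, 0.10)

  expect_error(fit_channel_distribution(rnorm(50)), "at least 100")
  expect_error(fit_channel_distribution(rep(5, 1000)), "degenerate")
})

test_that("channel fitting picks the dominant mode of a mixture", {
  set.seed(12)
  x <- c(rnorm(20000, 6000, 700), rnorm(2000, 11000, 700))
  fit <- fit_channel_distribution(x)
  expect_lt(abs(fit$mu - 6000), 500)
})

test_that("channel fitting is scale-equivariant", {
  set.seed(13)
  x <- rnorm(20000, 6000, 800)
  f1 <- fit_channel_distribution(x)
  f2 <- fit_channel_distribution(3.5 * x)
  expect_equal(f2$mu / f1$mu, 3.5, tolerance = 1e-6)
  expect_equal(f2$sigma / f1$sigma, 3.5, tolerance = 1e-6)
})

test_that("read filtering removes whole reads with out-of-range values", {
  des <- peptide_design(1, n_cycles = 1)
  mk <- function(id, v0, v1) {
    tibble::tibble(read_id = id, ch0_t0 = v0, ch0_t1 = v1)
  }
  reads <- dplyr::bind_rows(
    mk("a", 100, 200), mk("b", 3500, 100), # 3500 in the forbidden gap
    mk("c", 250, 250), mk("d", 100, 4500), # 4500 in the forbidden gap
    mk("e", 5000, 300)
  )
  filt <- intensity_filter(list(c(-1000, 3000), c(4800, 10000)))
  out <- filter_reads(reads, filt, des)
  expect_equal(out$n_removed, 2L)
  expect_equal(out$kept$read_id, c("a", "c", "e"))

  # closed intervals: exact boundary values are kept
  bnd <- mk("f", 3000, 4800)
  expect_equal(filter_reads(bnd, filt, des)$n_removed, 0L)

  # empty filter admits everything
  expect_equal(filter_reads(reads, intensity_filter(NULL), des)$n_removed, 0L)

  # idempotence
  again <- filter_reads(out$kept, filt, des)
  expect_equal(again$n_removed, 0L)
  expect_identical(again$kept, out$kept)

  expect_error(
    filter_reads(reads, intensity_filter(NULL, NULL), des),
    "more channels"
  )
  expect_error(intensity_filter(list(c(0, 10), c(5, 20))), "non-overlapping")
})
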