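test_that("error-free simulation gives the deterministic staircase", {
  des <- two_label_design(6)
  p <- seq_params(
    edman_failure = 0, detach = 0, initial_block = 0, cyclic_block = 0,
    dye_loss = 0, dud = 0, mu = 6000, sigma = 1e-6, bg_mu = 0, bg_sigma = 1e-6
  )
  sim <- simulate_reads(des, p, 50, seed = 1)
  # labels at 2 and 4: counts 2,2,1,1,0,0,0 across timepoints 0..6
  expected <- c(2, 2, 1, 1, 0, 0, 0)
  for (t in 0:6) {
    expect_true(all(sim$truth[[paste0("ch0_t", t)]] == expected[t + 1]))
  }
})

test_that("all-dark fraction matches the dud-rate binomial", {
  des <- two_label_design(3)
  p <- seq_params(dud = 0.3, initial_block = 0)
  sim <- simulate_reads(des, p, 100000, seed = 2, keep_invisible = TRUE)
  dark0 <- mean(sim$truth$ch0_t0 == 0)
  se <- sqrt(0.09 * 0.91 / 100000)
  expect_lt(abs(dark0 - 0.09), 3 * se)
  # initial counts follow Binomial(2, 0.7)
  for (k in 0:2) {
    pk <- dbinom(k, 2, 0.7)
    expect_lt(
      abs(mean(sim$truth$ch0_t0 == k) - pk),
      3 * sqrt(pk * (1 - pk) / 100000) + 1e-9
    )
  }
})

test_that("mean intensity tracks the fluorophore count", {
  des <- two_label_design(2)
  p <- typical_params()
  sim <- simulate_reads(des, p, 40000, seed = 3)
  for (k in 1:2) {
    sel <- sim$truth$ch0_t0 == k
    m <- mean(sim$reads$ch0_t0[sel])
    sd_k <- sqrt(p$bg_sigma^2 + k * p$sigma[1]^2)
    expect_lt(abs(m - k * p$mu[1]), 3 * sd_k / sqrt(sum(sel)))
  }
})

test_that("the same seed reproduces the simulation exactly", {
  des <- two_label_design(4)
  p <- typical_params()
  s1 <- simulate_reads(des, p, 500, seed = 42)
  s2 <- simulate_reads(des, p, 500, seed = 42)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_reads(des, p, 500, seed = 43)
  expect_false(identical(s1$reads, s3$reads))
})

test_that("last-visible-cycle frequencies follow the closed-form distribution", {
  # single label at position 2; only Edman failure and blocking active
  des <- peptide_design(2, n_cycles = 12)
  p <- seq_params(
    edman_failure = 0.15, detach = 0, initial_block = 0.1, cyclic_block = 0.05,
    dye_loss = 0, dud = 0
  )
  n <- 100000
  sim <- simulate_reads(des, p, n, seed = 8)
  counts <- as.matrix(sim$truth[, paste0("ch0_t", 0:12)])
  removed_at <- apply(counts, 1, function(x) {
    w <- which(x == 0)
    if (length(w)) w[1] - 1L else NA_integer_
  })
  kap <- kappa_distribution(r = 2, e = 0.15, b = 0.1, c = 0.05, i_max = 8)
  for (j in seq_len(6)) {
    freq <- mean(!is.na(removed_at) & removed_at == kap$cycle[j])
    pk <- kap$kappa[j]
    expect_lt(abs(freq - pk), 3 * sqrt(pk * (1 - pk) / n))
  }
})

test_that("dye-track reduction inverts noiseless emission", {
  des <- two_label_design(5)
  p_gen <- seq_params(
    edman_failure = 0.1, detach = 0.05, initial_block = 0.05,
    cyclic_block = 0.02, dye_loss = 0.06, dud = 0.1,
    mu = 6000, sigma = 1e-6, bg_mu = 0, bg_sigma = 1e-6
  )
  sim <- simulate_reads(des, p_gen, 300, seed = 4)
  p_reduce <- typical_params()
  tracks <- reduce_to_dyetrack(sim$reads, p_reduce, des)
  expect_equal(
    as.matrix(tracks[, -1]),
    as.matrix(sim$truth[, -1]),
    ignore_attr = TRUE
  )
})

test_that("reduction maps count means exactly and breaks ties downward", {
  des <- peptide_design(c(2, 4), n_cycles = 1)
  p <- typical_params()
  for (k in 0:2) {
    y <- p$bg_mu + k * (p$mu[1] - p$bg_mu)
    arr <- array(y, dim = c(1, 2, 1))
    tr <- reduce_to_dyetrack(arr, p, des)
    expect_true(all(as.matrix(tr[, -1]) == k))
  }
  # at an exact density crossover the smaller count wins
  g <- function(y) emission_density(y, 0, p) - emission_density(y, 1, p)
  cross <- uniroot(g, c(p$bg_mu, p$mu[1]), tol = 1e-14)$root
  arr <- array(cross, dim = c(1, 2, 1))
  expect_true(all(as.matrix(reduce_to_dyetrack(arr, p, des)[, -1]) %in% 0L))
})

test_that("dye-track histograms count exact track multiplicity", {
  des <- peptide_design(1, n_cycles = 1)
  t1 <- tibble::tibble(read_id = "x", ch0_t0 = 1L, ch0_t1 = 0L)
  tracks <- dplyr::bind_rows(t1, t1, t1, dplyr::mutate(t1, ch0_t1 = 1L))
  h <- dyetrack_histogram(tracks, des)
  expect_equal(sort(h$count), c(1L, 3L))
  expect_equal(sum(h$count), 4L)
  expect_equal(nrow(dyetrack_histogram(t1[0, ], des)), 0L)
  # round trip: expanding the histogram reproduces the multiset of keys
  keys <- rep(h$track, h$count)
  expect_setequal(
    keys,
    paste(tracks$ch0_t0, tracks$ch0_t1, sep = ",")
  )
})
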