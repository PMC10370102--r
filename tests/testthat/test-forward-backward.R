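test_that("a deterministic model yields the closed-form log-likelihood", {
  des <- peptide_design(1, n_cycles = 1)
  p <- seq_params(
    edman_failure = 0, detach = 0, initial_block = 0, cyclic_block = 0,
    dye_loss = 0, dud = 0, mu = 6000, sigma = 900, bg_mu = 0, bg_sigma = 350
  )
  # single possible path: k = 1 at t0, removed at cycle 1
  read <- array(c(6000, 0), dim = c(1, 2, 1))
  fb <- forward_backward(read, des, p)
  expect_equal(
    fb$loglik,
    dnorm(6000, 6000, sqrt(350^2 + 900^2), log = TRUE) +
      dnorm(0, 0, 350, log = TRUE),
    tolerance = 1e-7 # likelihood evaluation clamps exact-zero rates to 1e-9
  )
})

test_that("forward log-likelihood matches exhaustive path enumeration", {
  des1 <- peptide_design(1, n_cycles = 2)
  p1 <- seq_params(
    edman_failure = 0.1, detach = 0.02, initial_block = 0, cyclic_block = 0,
    dye_loss = 0.05, dud = 0
  )
  set.seed(5)
  sim1 <- simulate_reads(des1, p1, 4, seed = 5)
  arr1 <- fluorfit:::reads_as_array(sim1$reads, des1)
  fb1 <- forward_backward(sim1$reads, des1, p1)
  for (i in 1:4) {
    expect_equal(
      fb1$loglik[i],
      oracle_path_loglik(matrix(arr1[i, , ], ncol = 1), des1, p1),
      tolerance = 1e-10
    )
  }

  # two labels, blocking and duds active, three cycles
  des2 <- peptide_design(c(1, 3), n_cycles = 3)
  p2 <- seq_params(
    edman_failure = 0.15, detach = 0.06, initial_block = 0.1,
    cyclic_block = 0.08, dye_loss = 0.07, dud = 0.2
  )
  sim2 <- simulate_reads(des2, p2, 3, seed = 9)
  arr2 <- fluorfit:::reads_as_array(sim2$reads, des2)
  fb2 <- forward_backward(sim2$reads, des2, p2)
  for (i in 1:3) {
    ll_oracle <- oracle_path_loglik(
      matrix(arr2[i, , ], ncol = 1), des2, p2
    )
    expect_equal(fb2$loglik[i], ll_oracle, tolerance = 1e-10)
  }
})

test_that("posteriors at every sub-step sum to one and xi is consistent", {
  des <- two_label_design(3)
  p <- typical_params()
  sim <- simulate_reads(des, p, 6, seed = 3)
  fb <- forward_backward(sim$reads, des, p, want_xi = TRUE)
  for (post in fb$posteriors) {
    expect_lt(max(abs(rowSums(post) - 1)), 1e-9)
  }
  # pairwise sub-transition posteriors: each read's xi sums to one, and its
  # row/column sums reproduce the boundary marginals
  for (nm in names(fb$xi)) {
    j <- match(nm, fb$sub_steps) # boundary after the sub-transition
    for (i in 1:6) {
      x <- fb$xi[[nm]][i, , ]
      expect_lt(abs(sum(x) - 1), 1e-9)
      expect_lt(max(abs(colSums(x) - fb$posteriors[[j]][i, ])), 1e-9)
      expect_lt(max(abs(rowSums(x) - fb$posteriors[[j - 1L]][i, ])), 1e-9)
    }
  }
})

test_that("log-likelihood is finite for wild but finite intensities", {
  des <- two_label_design(3)
  p <- typical_params()
  fb <- forward_backward(
    array(c(1e7, -1e7, 0, 0), dim = c(1, 4, 1)), des, p
  )
  expect_true(is.finite(fb$loglik))
})

test_that("reads with the wrong shape are rejected", {
  des <- two_label_design(3)
  bad <- tibble::tibble(read_id = "r1", ch0_t0 = 1, ch0_t1 = 2)
  expect_error(forward_backward(bad, des, typical_params()), "missing column")
})
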