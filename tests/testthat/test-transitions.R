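test_that("every factor row is stochastic for random valid parameters", {
  set.seed(42)
  for (rep in 1:5) {
    des <- if (rep %% 2) two_label_design(4) else peptide_design(list(2, c(1, 3)), 3)
    sp <- build_state_space(des)
    p <- seq_params(
      edman_failure = runif(1, 0, 0.4), detach = runif(1, 0, 0.4),
      initial_block = runif(1, 0, 0.4), cyclic_block = runif(1, 0, 0.4),
      dye_loss = runif(des$n_channels, 0, 0.4),
      dud = runif(des$n_channels, 0, 0.4),
      mu = rep(6000, des$n_channels), sigma = rep(900, des$n_channels)
    )
    fs <- transition_factors(p, sp, 1)
    for (f in fs) {
      expect_lt(max(abs(Matrix::rowSums(f$matrix) - 1)), 1e-12)
    }
  }
})

test_that("with all rates zero only the Edman factor moves mass", {
  des <- two_label_design(4)
  sp <- build_state_space(des)
  p <- seq_params(
    edman_failure = 0, detach = 0, initial_block = 0, cyclic_block = 0,
    dye_loss = 0, dud = 0
  )
  fs <- transition_factors(p, sp, 1)
  I <- Matrix::Diagonal(sp$n_states)
  for (f in fs) {
    if (f$name == "edman") {
      # every unblocked state advances n deterministically (the count may
      # split when some of the merged state's labels are already dark)
      M <- as.matrix(f$matrix)
      for (s in which(!sp$blocked & !sp$detached & sp$n < des$n_cycles)) {
        tgt <- which(M[s, ] > 0)
        expect_true(all(sp$n[tgt] == sp$n[s] + 1L))
        expect_equal(sum(M[s, tgt]), 1)
        full <- all(sp$k[s, ] == sp$remaining[, sp$n[s] + 1L])
        if (full) expect_length(tgt, 1L)
      }
    } else {
      expect_lt(max(abs(f$matrix - I)), 1e-15)
    }
  }
  expect_error(transition_factors(p, sp, 0), "cycle_index")
  expect_error(transition_factors(p, sp, 5), "cycle_index")
})

test_that("the product of a cycle's factors equals the enumerated cycle matrix", {
  set.seed(7)
  for (des in list(peptide_design(3, 3), two_label_design(4))) {
    sp <- build_state_space(des)
    p <- seq_params(
      edman_failure = 0.12, detach = 0.07, initial_block = 0.04,
      cyclic_block = 0.09, dye_loss = 0.06, dud = 0.1
    )
    prod_mat <- as.matrix(fluorfit:::factor_product(transition_factors(p, sp, 1)))
    oracle <- oracle_cycle_matrix(p, sp)
    expect_lt(max(abs(prod_mat - oracle)), 1e-12)
  }
})

test_that("initial distribution follows independent binomial dud thinning", {
  des <- two_label_design(3)
  sp <- build_state_space(des)
  p0 <- seq_params(dud = 0, initial_block = 0)
  pi0 <- initial_distribution(p0, sp)
  full <- fluorfit:::state_index(sp, 0L, 2L, FALSE)
  expect_equal(pi0[full], 1)
  expect_equal(sum(pi0), 1)

  p <- seq_params(dud = 0.2, initial_block = 0)
  pi1 <- initial_distribution(p, sp)
  k_of <- function(k) fluorfit:::state_index(sp, 0L, k, FALSE)
  expect_equal(pi1[k_of(2L)], 0.64)
  expect_equal(pi1[k_of(1L)], 0.32)
  expect_equal(pi1[k_of(0L)], 0.04)

  pi2 <- initial_distribution(p, sp, condition_on_visible = TRUE)
  expect_equal(pi2[k_of(2L)], 0.64 / 0.96)
  expect_equal(pi2[k_of(1L)], 0.32 / 0.96)
  expect_equal(pi2[k_of(0L)], 0)
  expect_lt(abs(sum(pi2) - 1), 1e-12)

  # blocking splits every count's mass by the initial block rate
  pb <- seq_params(dud = 0.2, initial_block = 0.3)
  pi3 <- initial_distribution(pb, sp)
  expect_equal(pi3[k_of(2L)], 0.64 * 0.7)
  expect_equal(pi3[fluorfit:::state_index(sp, 0L, 2L, TRUE)], 0.64 * 0.3)
})
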