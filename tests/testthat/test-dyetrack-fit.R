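test_that("the RMSE objective follows the union-key count formula", {
  # hand example: data {A:3, B:1}, rescaled simulation {A:1, C:2}
  h_data <- tibble::tibble(track = c("A", "B"), count = c(3L, 1L))
  h_sim <- tibble::tibble(track = c("A", "C"), count = c(1L, 2L))
  expect_equal(fluorfit:::hist_rmse(h_data, h_sim, scale = 1), sqrt(3))
  # invariant to key order
  expect_equal(
    fluorfit:::hist_rmse(h_data[2:1, ], h_sim[2:1, ], scale = 1), sqrt(3)
  )
})

test_that("the objective vanishes when data and simulation share a pipeline", {
  des <- two_label_design(4)
  p <- typical_params()
  sim <- simulate_reads(des, p, 2000, seed = 21)
  tracks <- reduce_to_dyetrack(sim$reads, p, des)
  h <- dyetrack_histogram(tracks, des)
  theta <- fluorfit:::rates_as_vector(p)
  val <- rmse_objective(theta, h, des, p,
    n_data = 2000, n_sim = 2000, seed = 21
  )
  expect_equal(val, 0)
  # and is deterministic under a fixed seed
  v1 <- rmse_objective(theta, h, des, p, n_data = 2000, n_sim = 500, seed = 3)
  v2 <- rmse_objective(theta, h, des, p, n_data = 2000, n_sim = 500, seed = 3)
  expect_identical(v1, v2)
  expect_error(
    rmse_objective(theta * 0 + 0.9, h, des, p, n_data = 2000, n_sim = 10),
    "out of bounds"
  )
})

test_that("the cached-noise objective path reproduces the reference exactly", {
  des <- two_label_design(6)
  fx <- typical_params()
  # high dud rate so the invisible-redraw branch is exercised
  p <- fluorfit:::rates_from_vector(fx, c(
    edman_failure = 0.08, detach = 0.04, initial_block = 0.06,
    cyclic_block = 0.03, dye_loss_ch0 = 0.05, dud_ch0 = 0.25
  ))
  bank <- fluorfit:::make_sim_bank(des, 4000, 17)
  khat <- fluorfit:::make_khat_cache(des, fx, bank)
  rem <- matrix(vapply(0:des$n_cycles, function(n) {
    fluorfit:::labels_remaining(des, 1L, n)
  }, integer(1)), nrow = 1)
  poschan <- vapply(seq_len(des$n_cycles), function(pp) {
    fluorfit:::channel_at_position(des, pp)
  }, integer(1))
  M_fast <- fluorfit:::banked_tracks_fast(
    bank, p, fx, des, khat, rem, poschan, rem[, 1]
  )
  core <- fluorfit:::simulate_core(des, p, 4000, FALSE, bank = bank, emit = FALSE)
  M_ref <- fluorfit:::banked_tracks(core, khat, fx, des)
  expect_identical(M_fast, M_ref)
  expect_gt(length(core$redrawn), 0)

  # and the banked simulation itself is bit-identical to live sampling
  set.seed(17)
  live <- fluorfit:::simulate_core(des, p, 4000, FALSE)
  banked <- fluorfit:::simulate_core(des, p, 4000, FALSE, bank = bank, emit = TRUE)
  expect_identical(live$truth, banked$truth)
  expect_equal(live$intens, banked$intens)
})

test_that("coordinate trisection finds convex and two-basin optima", {
  r1 <- direct_search(function(x) (x - 0.3)^2, 0, 1, max_evals = 100)
  expect_lt(abs(r1$par - 0.3), 0.02)
  expect_lte(r1$n_evals, 100)

  # two basins, global at (0.2, 0.7)
  f2 <- function(x) {
    -0.8 * exp(-sum((x - c(0.2, 0.7))^2) / 0.02) -
      0.5 * exp(-sum((x - c(0.8, 0.2))^2) / 0.02)
  }
  r2 <- direct_search(f2, c(0, 0), c(1, 1), max_evals = 300, min_step = 1e-4)
  expect_lt(sqrt(sum((r2$par - c(0.2, 0.7))^2)), 0.1)

  # a budget of one evaluation returns the box center
  r3 <- direct_search(function(x) sum(x^2), c(0, 0), c(1, 1), max_evals = 1)
  expect_equal(r3$par, c(0.5, 0.5))
  expect_equal(r3$n_evals, 1L)

  expect_error(
    direct_search(function(x) NaN, 0, 1, max_evals = 10),
    "non-finite"
  )
})

test_that("coordinate descent solves separable quadratics to high accuracy", {
  f <- function(x) sum((x - c(0.4, 0.1))^2)
  r <- powell_minimize(f, c(0.9, 0.9), 0, 1, tol = 1e-10, line_tol = 1e-6)
  expect_lt(max(abs(r$par - c(0.4, 0.1))), 1e-4)
  expect_true(r$converged)

  # starting at the optimum returns promptly
  r0 <- powell_minimize(f, c(0.4, 0.1), 0, 1, tol = 1e-8, line_tol = 1e-6)
  expect_equal(r0$n_sweeps, 1L)
  expect_lt(max(abs(r0$par - c(0.4, 0.1))), 1e-4)

  # bounded Rosenbrock: moves toward the (1, 1) corner optimum
  fr <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  rr <- powell_minimize(fr, c(0.2, 0.8), 0, 1, tol = 1e-10, max_sweeps = 60,
    line_tol = 1e-6
  )
  expect_lt(fr(rr$par), fr(c(0.2, 0.8)) / 100)
  expect_true(all(rr$par >= 0 & rr$par <= 1))
})

test_that("dye-track fitting recovers rates on a small simulated dataset", {
  des <- two_label_design(8)
  truth <- typical_params()
  sim <- simulate_reads(des, truth, 4000, seed = 23)
  fit <- fit_dyetrack(sim$reads, des,
    fixed_params = seq_params(),
    n_sim = 8000, direct_evals = 150, max_sweeps = 4, seed = 24
  )
  err <- abs(
    fluorfit:::rates_as_vector(fit$params) - fluorfit:::rates_as_vector(truth)
  )
  expect_lt(max(err), 0.05) # 4,000 reads: sampling noise dominates
  # the refined optimum is no worse than the global-search point
  expect_lte(fit$rmse, fit$rmse_direct)
})

test_that("single-label fits pin the unidentifiable rates", {
  des <- peptide_design(2, n_cycles = 6)
  truth <- seq_params(
    edman_failure = 0.08, detach = 0, initial_block = 0.1, cyclic_block = 0,
    dye_loss = 0.05, dud = 0
  )
  sim <- simulate_reads(des, truth, 2000, seed = 25)
  fit <- fit_dyetrack(sim$reads, des,
    fixed_params = seq_params(),
    n_sim = 4000, direct_evals = 80, max_sweeps = 3, seed = 26
  )
  v <- fluorfit:::rates_as_vector(fit$params)
  expect_equal(unname(v["detach"]), 0)
  expect_equal(unname(v["cyclic_block"]), 0)
  expect_equal(unname(v["dud_ch0"]), 0)

  # degenerate single-track histogram still terminates
  one <- sim$reads[1, ]
  fit1 <- fit_dyetrack(one, des,
    fixed_params = seq_params(), n_sim = 200,
    direct_evals = 20, max_sweeps = 1, refine_bracket = 0, seed = 27
  )
  expect_s3_class(fit1, "fluorfit_fit")
})
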