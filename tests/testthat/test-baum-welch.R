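test_that("m_step maps sufficient statistics to rates", {
  p <- typical_params()
  nm <- fluorfit:::rate_param_names(1)
  stats <- stats::setNames(rep(list(c(n = 200, x = 0)), 6), nm)
  stats$detach <- c(n = 200, x = 10)
  out <- m_step(stats, p)
  expect_equal(out$detach, 0.05)
  expect_equal(out$edman_failure, 0)

  pinned <- m_step(stats, p, constraints = c(detach = 0))
  expect_equal(pinned$detach, 0)

  stats$detach <- c(n = 0, x = 0)
  expect_error(m_step(stats, p), "non-identifiable")
})

test_that("dud correction counts the expected censored reads", {
  des <- two_label_design(3)
  p <- typical_params()
  p$dud <- 0.3
  corr <- dud_bias_correction(1000, des, p)
  expect_equal(corr$all_dud_prob, 0.09)
  expect_equal(corr$missing_reads, 1000 * 0.09 / 0.91)
  expect_equal(
    corr$pseudo$dud_ch0,
    c(n = 2 * 1000 * 0.09 / 0.91, x = 2 * 1000 * 0.09 / 0.91)
  )

  p$dud <- 0
  expect_equal(dud_bias_correction(1000, des, p)$missing_reads, 0)
})

test_that("a direct x of 0.2 gives 250 missing-read equivalents", {
  # single-label-per-"channel" pair of channels so the joint all-dud
  # probability is exactly the product of the per-channel dud rates
  des <- peptide_design(list(1, 2), n_cycles = 2)
  p <- seq_params(
    dud = c(0.4, 0.5), dye_loss = c(0, 0), mu = c(6000, 6000),
    sigma = c(900, 900)
  )
  corr <- dud_bias_correction(1000, des, p)
  expect_equal(corr$all_dud_prob, 0.2)
  expect_equal(corr$missing_reads, 250)
})

test_that("dud correction matches N x / (1 - x) for a two-label design", {
  des <- two_label_design(3)
  p <- typical_params()
  p$dud <- 0.2
  corr <- dud_bias_correction(1000, des, p)
  expect_equal(corr$all_dud_prob, 0.04)
  expect_equal(corr$missing_reads, 1000 * 0.04 / 0.96)
})

test_that("single-fluorophore designs pin the unidentifiable rates", {
  pins <- identifiability_constraints(peptide_design(3, 10))
  expect_mapequal(
    pins, c(detach = 0, cyclic_block = 0, dud_ch0 = 0)
  )
  expect_length(identifiability_constraints(two_label_design(10)), 0L)
  expect_length(
    identifiability_constraints(peptide_design(list(c(1, 2, 5)), 10)), 0L
  )
})

test_that("error-free reads produce (almost) no error events", {
  des <- two_label_design(5)
  p0 <- seq_params(
    edman_failure = 0, detach = 0, initial_block = 0, cyclic_block = 0,
    dye_loss = 0, dud = 0
  )
  sim <- simulate_reads(des, p0, 200, seed = 6)
  st <- accumulate_sufficient_stats(sim$reads, des, p0)
  for (nm in names(st)) {
    expect_lt(st[[nm]]["x"] / max(st[[nm]]["n"], 1), 1e-6)
  }
})

test_that("with vanishing noise the E-step counts dye losses exactly", {
  # labels beyond the last cycle so Edman never removes one: every count
  # drop on a truth track is a dye loss, giving a complete-data oracle
  des <- peptide_design(c(10, 12), n_cycles = 6)
  p <- seq_params(
    edman_failure = 0, detach = 0, initial_block = 0, cyclic_block = 0,
    dye_loss = 0.15, dud = 0,
    mu = 6000, sigma = 1, bg_mu = 0, bg_sigma = 1
  )
  sim <- simulate_reads(des, p, 400, seed = 10)
  st <- accumulate_sufficient_stats(sim$reads, des, p)

  counts <- as.matrix(sim$truth[, paste0("ch0_t", 0:6)])
  n_hand <- sum(counts[, 1:6]) # fluorophore-cycles at risk
  x_hand <- sum(counts[, 1:6] - counts[, 2:7]) # losses
  expect_equal(st$dye_loss_ch0[["n"]], n_hand, tolerance = 1e-6)
  expect_equal(st$dye_loss_ch0[["x"]], x_hand, tolerance = 1e-6)
  expect_equal(
    st$dye_loss_ch0[["x"]] / st$dye_loss_ch0[["n"]],
    x_hand / n_hand,
    tolerance = 1e-8
  )
})

test_that("sufficient statistics are additive across reads", {
  des <- two_label_design(4)
  p <- typical_params()
  sim <- simulate_reads(des, p, 20, seed = 12)
  st_all <- accumulate_sufficient_stats(sim$reads, des, p)
  st_a <- accumulate_sufficient_stats(sim$reads[1:8, ], des, p)
  st_b <- accumulate_sufficient_stats(sim$reads[9:20, ], des, p)
  for (nm in names(st_all)) {
    expect_equal(
      st_all[[nm]],
      st_a[[nm]] + st_b[[nm]],
      tolerance = 1e-8
    )
  }
})

test_that("EM increases the observed-data log-likelihood monotonically", {
  des <- two_label_design(8)
  p <- typical_params()
  sim <- simulate_reads(des, p, 3000, seed = 14)
  fit <- fit_baum_welch(sim$reads, des,
    init = seq_params(), n_starts = 1,
    max_iter = 40, tol = 1e-8, loglik_tol = 1e-12
  )
  dll <- diff(fit$loglik_trace)
  expect_true(all(dll > -1e-8 * (abs(fit$loglik) + 1)))
})

test_that("starting at the truth the M-step barely moves", {
  des <- two_label_design(8)
  p <- typical_params()
  sim <- simulate_reads(des, p, 20000, seed = 15)
  st <- accumulate_sufficient_stats(sim$reads, des, p)
  corr <- dud_bias_correction(20000, des, p)
  st <- fluorfit:::add_stats(st, corr$pseudo)
  upd <- m_step(st, p)
  v0 <- fluorfit:::rates_as_vector(p)
  v1 <- fluorfit:::rates_as_vector(upd)
  # each parameter's one-step move stays within Monte-Carlo scale
  expect_lt(max(abs(v1 - v0)), 0.01)
})

test_that("a single-read dataset converges without error", {
  des <- two_label_design(4)
  p <- typical_params()
  sim <- simulate_reads(des, p, 1, seed = 16)
  fit <- fit_baum_welch(sim$reads, des,
    init = p, n_starts = 1, max_iter = 15
  )
  expect_s3_class(fit, "fluorfit_fit")
  expect_true(all(is.finite(fluorfit:::rates_as_vector(fit$params))))
})

test_that("tidy and glance expose estimates and fit metadata", {
  des <- two_label_design(4)
  p <- typical_params()
  sim <- simulate_reads(des, p, 300, seed = 17)
  fit <- fit_baum_welch(sim$reads, des, init = p, n_starts = 1, max_iter = 5)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "pinned"))
  expect_equal(nrow(td), 6L)
  gl <- glance(fit)
  expect_equal(gl$method, "baum_welch")
  expect_equal(gl$n_reads, 300L)
})
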