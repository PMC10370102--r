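# Modified Baum-Welch: EM over the factored HMM in which the M-step computes
# weighted MLEs of the tied physical parameters (one rate per error
# mechanism) instead of independent per-transition probabilities, interleaved
# with the iterative censoring correction for invisible all-dud peptides.

#' Identifiability constraints for a peptide design
#'
#' With a single fluorophore, several parameters cannot be identified from
#' reads: dye loss and detachment are visibly equivalent (either way the only
#' spot goes dark), no all-dud peptide is ever observed so the dud rate
#' carries no data, and the initial/cyclic blocking rates trade off freely
#' against the Edman failure rate (only the product `e(1-c)` enters the
#' observable last-cycle distribution; see [kappa_distribution()]). Such
#' designs therefore pin the detachment, dud, and cyclic blocking rates to
#' zero. Designs with two or more fluorophores leave all six rates free.
#'
#' @param design A [peptide_design()].
#' @return A named numeric vector of pinned parameter values (possibly
#'   empty), usable as the `constraints` argument of the fitters.
#' @examples
#' identifiability_constraints(peptide_design(3, 10)) # one label: 3 pins
#' identifiability_constraints(peptide_design(c(2, 4), 10)) # none
#' @export
identifiability_constraints <- function(design) {
  stopifnot(inherits(design, "peptide_design"))
  if (sum(lengths(design$labels_by_channel)) > 1L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  pins <- c(detach = 0, cyclic_block = 0)
  for (ch in seq_len(design$n_channels) - 1L) {
    pins[paste0("dud_ch", ch)] <- 0
  }
  pins
}

#' Pseudo-observations correcting dud-rate censoring
#'
#' Peptides whose fluorophores are all dud never appear as reads, so a naive
#' dud-rate MLE from visible reads is biased low. Under the current dud
#' estimates the probability that a peptide is invisible is
#' `x = prod(dud_ch ^ L_ch)`; `N * x / (1 - x)` then estimates the number of
#' censored reads, and each is counted as a peptide with every label dud.
#' The correction is recomputed from the updated dud rates at every EM
#' iteration.
#'
#' @param n_reads Number of observed (visible) reads `N`.
#' @param design A [peptide_design()].
#' @param params Current [seq_params()] (only the dud rates are used).
#' @return A list with `all_dud_prob` (`x`), `missing_reads`
#'   (`N * x / (1 - x)`), and `pseudo` — per channel, the trial and event
#'   counts to add to that channel's dud sufficient statistics.
#' @export
dud_bias_correction <- function(n_reads, design, params) {
  L <- vapply(
    seq_len(design$n_channels),
    function(ch) labels_remaining(design, ch, 0L), integer(1)
  )
  x <- prod(params$dud^L)
  if (x >= 1) stop("all-dud probability must be < 1", call. = FALSE)
  missing <- n_reads * x / (1 - x)
  pseudo <- lapply(seq_len(design$n_channels), function(ch) {
    c(n = L[ch] * missing, x = L[ch] * missing)
  })
  names(pseudo) <- paste0("dud_ch", seq_len(design$n_channels) - 1L)
  list(all_dud_prob = x, missing_reads = missing, pseudo = pseudo)
}

#' M-step: weighted MLEs of the tied rates
#'
#' Each free rate is the ratio `x / n` of its expected event count to its
#' expected trial count; pinned parameters take their constraint value.
#' Intensity-model parameters are held fixed throughout fitting.
#'
#' @param stats Named list of `c(n = , x = )` sufficient statistics, as from
#'   [accumulate_sufficient_stats()].
#' @param params Current [seq_params()] (supplies fixed intensity model).
#' @param constraints Named numeric vector of pinned rates.
#' @return An updated [seq_params()].
#' @export
m_step <- function(stats, params, constraints = NULL) {
  est <- rates_as_vector(params)
  for (nm in names(stats)) {
    if (!is.null(constraints) && nm %in% names(constraints)) {
      est[nm] <- constraints[[nm]]
      next
    }
    n <- stats[[nm]]["n"]
    x <- stats[[nm]]["x"]
    if (n <= 0) {
      stop(
        "parameter '", nm, "' has no expected trials: ",
        "non-identifiable configuration (consider pinning it)",
        call. = FALSE
      )
    }
    est[nm] <- min(max(x / n, 0), 1 - 1e-12)
  }
  rates_from_vector(params, est)
}

add_stats <- function(stats, extra) {
  for (nm in names(extra)) {
    stats[[nm]]["n"] <- stats[[nm]]["n"] + extra[[nm]]["n"]
    stats[[nm]]["x"] <- stats[[nm]]["x"] + extra[[nm]]["x"]
  }
  stats
}

#' Fit sequencing parameters by modified Baum-Welch
#'
#' Iterates expectation-maximization on the factored fluorosequencing HMM:
#' the E-step runs a scaled forward/backward pass per read and accumulates,
#' for each tied physical parameter, the expected number of Bernoulli trials
#' and events across all sub-transitions; the M-step sets each free rate to
#' its weighted MLE `x / n`. The dud-censoring correction
#' ([dud_bias_correction()]) injects the expected number of invisible
#' all-dud peptides into the dud statistics at every iteration. Intensity
#' parameters (`mu`, `sigma`, `bg_mu`, `bg_sigma`) are held fixed.
#'
#' Iteration stops when the maximum relative parameter change drops below
#' `tol`, when the observed-data log-likelihood gain drops below
#' `loglik_tol`, or at `max_iter` — whichever happens first. Multiple
#' jittered starts guard against poor initialization: each start runs a few
#' burn-in iterations and the best log-likelihood continues to convergence.
#'
#' @param reads Wide reads tibble or intensity array.
#' @param design A [peptide_design()].
#' @param init Initial [seq_params()]; its intensity model is used as-is.
#'   Rate entries are the EM starting point.
#' @param constraints Named vector of pinned rates; defaults to
#'   [identifiability_constraints()] of the design.
#' @param dud_correction Apply the censoring correction? (Disable only to
#'   demonstrate the bias.)
#' @param condition_on_visible Condition the HMM on reads being visible
#'   (default `TRUE`; real reads are visible by construction).
#' @param tol Convergence threshold on the maximum relative rate change.
#' @param loglik_tol Convergence threshold on the relative log-likelihood
#'   gain.
#' @param max_iter Iteration cap.
#' @param n_starts Number of jittered starts.
#' @param burn_iter Burn-in EM iterations per extra start.
#' @param seed Seed for the start jitter.
#' @return An object of class `fluorfit_fit` with elements `params`
#'   (estimates), `loglik`, `loglik_trace`, `n_iterations`, `converged`,
#'   `constraints`, `method = "baum_welch"`, `n_reads`, and `settings`.
#' @examples
#' des <- peptide_design(c(2, 4), n_cycles = 10)
#' truth <- seq_params(dye_loss = 0.04, dud = 0.07)
#' sim <- simulate_reads(des, truth, 2000, seed = 1)
#' fit <- fit_baum_welch(sim$reads, des, init = seq_params(), n_starts = 1)
#' tidy(fit)
#' @export
fit_baum_welch <- function(reads, design, init = seq_params(),
                           constraints = identifiability_constraints(design),
                           dud_correction = TRUE, condition_on_visible = TRUE,
                           tol = 1e-6, loglik_tol = 1e-9, max_iter = 1000,
                           n_starts = 3, burn_iter = 8, seed = 1) {
  validate_seq_params(init)
  arr <- reads_as_array(reads, design)
  N <- dim(arr)[1]
  if (N < 1L) stop("need at least one read", call. = FALSE)
  space <- build_state_space(design)
  cache <- build_emission_cache(arr, design, init, space)

  pins <- constraints
  start_params <- function(jitter_seed) {
    p <- init
    if (!is.null(jitter_seed)) {
      v <- rates_as_vector(p)
      with_seed(jitter_seed, {
        v <- pmin(pmax(v * stats::runif(length(v), 0.4, 1.8), 1e-4), 0.4)
      })
      p <- rates_from_vector(p, v)
    }
    if (length(pins)) p <- rates_from_vector(p, unlist(pins))
    p
  }

  em_iterate <- function(params, iters, tol, loglik_tol) {
    trace <- numeric(0)
    converged <- FALSE
    it <- 0L
    repeat {
      it <- it + 1L
      pass <- hmm_pass(arr, design, params,
        condition_on_visible = condition_on_visible,
        space = space, cache = cache
      )
      ll <- sum(pass$loglik)
      if (!is.finite(ll)) {
        bad <- which(!is.finite(pass$loglik))[1]
        stop("non-finite log-likelihood at read ", bad, call. = FALSE)
      }
      trace <- c(trace, ll)
      stats <- stats_from_pass(pass)
      if (dud_correction && condition_on_visible) {
        corr <- dud_bias_correction(N, design, params)
        stats <- add_stats(stats, corr$pseudo)
      }
      new_params <- m_step(stats, params, pins)
      old_v <- rates_as_vector(params)
      new_v <- rates_as_vector(new_params)
      rel <- max(abs(new_v - old_v) / pmax(abs(old_v), 1e-3))
      ll_gain <- if (length(trace) >= 2L) {
        (trace[it] - trace[it - 1L]) / (abs(trace[it]) + 1)
      } else {
        Inf
      }
      params <- new_params
      if (rel < tol || abs(ll_gain) < loglik_tol) {
        converged <- TRUE
        break
      }
      if (it >= iters) break
    }
    list(params = params, trace = trace, converged = converged, iters = it)
  }

  # burn in each start briefly, continue the best
  starts <- list(start_params(NULL))
  if (n_starts > 1L) {
    for (k in seq_len(n_starts - 1L)) {
      starts[[k + 1L]] <- start_params(seed + k)
    }
  }
  best <- NULL
  if (length(starts) > 1L) {
    burns <- lapply(starts, function(p) em_iterate(p, burn_iter, tol, loglik_tol))
    lls <- vapply(burns, function(b) b$trace[length(b$trace)], numeric(1))
    best <- burns[[which.max(lls)]]
  } else {
    best <- em_iterate(starts[[1]], burn_iter, tol, loglik_tol)
  }
  run <- if (best$converged) {
    best
  } else {
    cont <- em_iterate(best$params, max_iter - best$iters, tol, loglik_tol)
    list(
      params = cont$params, trace = c(best$trace, cont$trace),
      converged = cont$converged, iters = best$iters + cont$iters
    )
  }

  structure(
    list(
      params = run$params,
      loglik = run$trace[length(run$trace)],
      loglik_trace = run$trace,
      n_iterations = run$iters,
      converged = run$converged,
      constraints = pins,
      method = "baum_welch",
      n_reads = N,
      design = design,
      settings = list(
        dud_correction = dud_correction,
        condition_on_visible = condition_on_visible,
        tol = tol, loglik_tol = loglik_tol, max_iter = max_iter,
        n_starts = n_starts, burn_iter = burn_iter, seed = seed
      )
    ),
    class = c("fluorfit_bw", "fluorfit_fit")
  )
}

#' @export
print.fluorfit_fit <- function(x, ...) {
  cat("<fluorfit_fit> method: ", x$method, ", ", x$n_reads, " reads\n", sep = "")
  obj <- if (!is.null(x$loglik)) {
    sprintf("log-likelihood %.4f", x$loglik)
  } else {
    sprintf("RMSE %.4f", x$rmse)
  }
  cat(
    "  ", obj, " after ", x$n_iterations, " iterations (converged: ",
    x$converged, ")\n",
    sep = ""
  )
  v <- rates_as_vector(x$params)
  for (nm in names(v)) {
    pin <- if (nm %in% names(x$constraints)) " [pinned]" else ""
    cat(sprintf("  %-15s %.5f%s\n", nm, v[nm], pin))
  }
  invisible(x)
}
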