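# Scaled forward/backward over the factored HMM.
#
# Each imaging timestep is expanded into sub-steps, one per transition-matrix
# factor (blocking, detachment, per-channel dye loss, Edman), with emissions
# applied at every timepoint. Scaling at each emission keeps the pass
# underflow-safe; with that scaling, alpha * beta at any sub-step boundary is
# the exact state posterior and rows sum to one.
#
# The tied-parameter M-step needs only low-dimensional functionals of the
# posteriors (expected event counts per factor). Each factor changes exactly
# one state coordinate, so those functionals are computable from the state
# marginals at the two boundaries of the factor -- no pairwise posteriors are
# required. The engine therefore aggregates column sums of the marginals
# over reads, chunk by chunk, which keeps memory flat in the read count.

# Convert a wide reads tibble/data.frame (read_id + ch{c}_t{t} columns) to a
# numeric array N x (T+1) x C.
reads_as_array <- function(reads, design) {
  Tn <- design$n_cycles
  C <- design$n_channels
  if (is.array(reads) && length(dim(reads)) == 3L) {
    stopifnot(dim(reads)[2] == Tn + 1L, dim(reads)[3] == C)
    return(reads)
  }
  stopifnot(is.data.frame(reads))
  arr <- array(NA_real_, dim = c(nrow(reads), Tn + 1L, C))
  for (ch in seq_len(C) - 1L) {
    for (t in 0:Tn) {
      col <- paste0("ch", ch, "_t", t)
      if (!col %in% names(reads)) {
        stop("reads are missing column '", col, "'", call. = FALSE)
      }
      arr[, t + 1L, ch + 1L] <- as.numeric(reads[[col]])
    }
  }
  if (any(!is.finite(arr))) stop("reads contain non-finite intensities", call. = FALSE)
  dimnames(arr) <- list(
    if ("read_id" %in% names(reads)) as.character(reads$read_id) else NULL,
    NULL, NULL
  )
  arr
}

# Distinct per-channel count combinations present in the state space, and
# the map state -> combination column. Emissions depend on the counts only.
kcombo_map <- function(space) {
  key <- apply(space$k, 1, paste, collapse = ",")
  u <- unique(key)
  list(combos = space$k[match(u, key), , drop = FALSE], index = match(key, u))
}

# Per-timepoint emission densities for every count combination:
# Dens[[t+1]] is N x K with joint (over channels) normal densities, floored
# away from zero so extreme outliers keep the log-likelihood finite.
build_emission_cache <- function(arr, design, params, space) {
  km <- kcombo_map(space)
  Tn <- design$n_cycles
  C <- design$n_channels
  K <- nrow(km$combos)
  dens <- vector("list", Tn + 1L)
  for (t in 0:Tn) {
    D <- matrix(1, nrow = dim(arr)[1], ncol = K)
    for (ch in seq_len(C)) {
      y <- arr[, t + 1L, ch]
      for (kk in seq_len(K)) {
        k <- km$combos[kk, ch]
        D[, kk] <- D[, kk] * stats::dnorm(
          y,
          mean = params$bg_mu + k * (params$mu[ch] - params$bg_mu),
          sd = sqrt(params$bg_sigma^2 + k * params$sigma[ch]^2)
        )
      }
    }
    dens[[t + 1L]] <- pmax(D, 1e-300)
  }
  list(dens = dens, kindex = km$index, n_reads = dim(arr)[1])
}

# Ordered operation list for a full pass: pre-sequencing initial-block
# factor, emission at t = 0, then per cycle the transition factors followed
# by that cycle's emission.
build_ops <- function(params, space, order = c("cyclic_block", "detach", "dye_loss", "edman")) {
  design <- space$design
  cl <- params
  cl$edman_failure <- clamp_rate(cl$edman_failure)
  cl$detach <- clamp_rate(cl$detach)
  cl$initial_block <- clamp_rate(cl$initial_block)
  cl$cyclic_block <- clamp_rate(cl$cyclic_block)
  cl$dye_loss <- clamp_rate(cl$dye_loss)
  cl$dud <- clamp_rate(cl$dud)
  ops <- list(list(
    type = "factor", name = "initial_block", param = "initial_block",
    channel = NA_integer_, M = factor_block(space, cl$initial_block)
  ))
  ops[[2]] <- list(type = "emission", t = 0L)
  cyc <- transition_factors(cl, space, 1L, order = order)
  for (t in seq_len(design$n_cycles)) {
    for (f in cyc) {
      ops[[length(ops) + 1L]] <- list(
        type = "factor", name = f$name, param = f$param, channel = f$channel,
        M = f$matrix
      )
    }
    ops[[length(ops) + 1L]] <- list(type = "emission", t = t)
  }
  attr(ops, "clamped_params") <- cl
  ops
}

# Core pass. detail = "stats": aggregated boundary marginals + sufficient
# statistics; detail = "posteriors": per-read marginals at every sub-step
# boundary (and optionally pairwise sub-transition posteriors), for small
# inputs and contract checks.
hmm_pass <- function(arr, design, params, condition_on_visible = TRUE,
                     space = NULL, cache = NULL, chunk_size = 1024L,
                     detail = c("stats", "posteriors"), want_xi = FALSE,
                     order = c("cyclic_block", "detach", "dye_loss", "edman")) {
  detail <- match.arg(detail)
  if (is.null(space)) space <- build_state_space(design)
  if (is.null(cache)) cache <- build_emission_cache(arr, design, params, space)
  ops <- build_ops(params, space, order = order)
  cl <- attr(ops, "clamped_params")
  S <- space$n_states
  N <- dim(arr)[1]
  pi0 <- initial_counts_vector(cl, space, condition_on_visible)
  csc <- function(M) list(i = M@i, p = M@p, x = M@x, nc = ncol(M))
  fM <- lapply(ops, function(op) if (op$type == "factor") csc(op$M) else NULL)
  tM <- lapply(ops, function(op) if (op$type == "factor") csc(Matrix::t(op$M)) else NULL)
  n_bound <- length(ops) + 1L

  loglik <- numeric(N)
  margsum <- vector("list", n_bound)
  for (j in seq_len(n_bound)) margsum[[j]] <- numeric(S)
  per_read <- NULL
  xi <- NULL
  if (detail == "posteriors") {
    chunk_size <- N
    if (want_xi && N * S * S > 5e6) {
      stop("pairwise sub-transition posteriors are only kept for small inputs",
        call. = FALSE
      )
    }
  }

  if (detail == "stats") {
    # fully compiled path: chunked forward/backward with aggregate marginals
    em_t <- vapply(ops, function(op) {
      if (op$type == "emission") op$t else -1L
    }, integer(1))
    res <- hmm_estep_cpp(
      pi0, fM, tM, em_t, cache$dens, cache$kindex, N,
      as.integer(min(chunk_size, N))
    )
    return(list(
      ops = ops, space = space, loglik = res$loglik,
      margsum = lapply(seq_len(n_bound), function(j) res$margsum[, j]),
      per_read = NULL, xi = NULL, n_reads = N,
      condition_on_visible = condition_on_visible
    ))
  }

  starts <- seq(1L, N, by = chunk_size)
  for (cs in starts) {
    ce <- min(cs + chunk_size - 1L, N)
    idx <- cs:ce
    n <- length(idx)
    A <- matrix(pi0, nrow = n, ncol = S, byrow = TRUE)
    Astore <- vector("list", n_bound)
    Astore[[1]] <- A
    scales <- vector("list", length(ops))
    ll <- numeric(n)
    for (oi in seq_along(ops)) {
      op <- ops[[oi]]
      if (op$type == "factor") {
        m <- fM[[oi]]
        A <- dense_sparse_prod(A, m$i, m$p, m$x, m$nc)
      } else {
        D <- cache$dens[[op$t + 1L]]
        if (n < nrow(D)) D <- D[idx, , drop = FALSE]
        es <- emission_scale(A, D, cache$kindex)
        A <- es$A
        ll <- ll + log(es$scale)
        scales[[oi]] <- es$scale
      }
      Astore[[oi + 1L]] <- A
    }
    loglik[idx] <- ll

    B <- matrix(1, nrow = n, ncol = S)
    Bstore <- if (detail == "posteriors") vector("list", n_bound) else NULL
    if (!is.null(Bstore)) Bstore[[n_bound]] <- B
    margsum[[n_bound]] <- margsum[[n_bound]] + colsums_prod(Astore[[n_bound]], B)
    for (oi in rev(seq_along(ops))) {
      op <- ops[[oi]]
      if (op$type == "factor") {
        m <- tM[[oi]]
        B <- dense_sparse_prod(B, m$i, m$p, m$x, m$nc)
      } else {
        D <- cache$dens[[op$t + 1L]]
        if (n < nrow(D)) D <- D[idx, , drop = FALSE]
        B <- emission_divide(B, D, cache$kindex, scales[[oi]])
      }
      margsum[[oi]] <- margsum[[oi]] + colsums_prod(Astore[[oi]], B)
      if (!is.null(Bstore)) Bstore[[oi]] <- B
    }

    if (detail == "posteriors") {
      per_read <- lapply(seq_len(n_bound), function(j) Astore[[j]] * Bstore[[j]])
      if (want_xi) {
        xi <- vector("list", length(ops))
        for (oi in seq_along(ops)) {
          if (ops[[oi]]$type != "factor") next
          M <- as.matrix(ops[[oi]]$M)
          xi[[oi]] <- array(0, dim = c(n, S, S))
          for (i in seq_len(n)) {
            xi[[oi]][i, , ] <- outer(Astore[[oi]][i, ], Bstore[[oi + 1L]][i, ]) * M
          }
        }
      }
    }
  }

  list(
    ops = ops, space = space, loglik = loglik, margsum = margsum,
    per_read = per_read, xi = xi, n_reads = N,
    condition_on_visible = condition_on_visible
  )
}

# Human-readable labels for the sub-step boundaries of a pass.
boundary_labels <- function(ops) {
  lab <- character(length(ops) + 1L)
  lab[1] <- "t0_start"
  cyc <- 0L
  for (oi in seq_along(ops)) {
    op <- ops[[oi]]
    if (op$type == "emission") {
      cyc <- op$t
      lab[oi + 1L] <- paste0("post_emission_t", op$t)
    } else {
      nm <- if (!is.na(op$channel)) paste0(op$name, "_ch", op$channel - 1L) else op$name
      lab[oi + 1L] <- paste0("post_", nm, "_cycle", cyc + 1L)
    }
  }
  lab
}

#' Forward/backward pass over the factored fluorosequencing HMM
#'
#' Runs the scaled forward and backward recursions factor-by-factor and
#' returns per-read log-likelihoods together with the posterior probability
#' of every state at every sub-step boundary (and, optionally, the pairwise
#' posteriors of every sub-transition).
#'
#' @param reads A wide reads tibble (columns `read_id`, `ch{c}_t{t}`) or a
#'   numeric array `N x (n_cycles+1) x n_channels`.
#' @param design A [peptide_design()].
#' @param params A [seq_params()].
#' @param condition_on_visible Condition the initial distribution on the
#'   peptide being visible (at least one working fluorophore)? Real reads are
#'   visible by construction, so this defaults to `TRUE`.
#' @param want_xi Also return pairwise sub-transition posteriors (small
#'   inputs only)?
#' @return A list with `loglik` (per read), `posteriors` (named list over
#'   sub-step boundaries of reads x states matrices, each row summing to 1),
#'   `sub_steps` (boundary labels), and `xi` (if requested, a named list over
#'   factor sub-transitions of reads x states x states arrays).
#' @examples
#' des <- peptide_design(1, n_cycles = 2)
#' prm <- seq_params(dye_loss = 0.05, dud = 0)
#' sim <- simulate_reads(des, prm, n_reads = 5, seed = 1)
#' fb <- forward_backward(sim$reads, des, prm)
#' fb$loglik
#' @export
forward_backward <- function(reads, design, params, condition_on_visible = TRUE,
                             want_xi = FALSE) {
  validate_seq_params(params)
  arr <- reads_as_array(reads, design)
  res <- hmm_pass(arr, design, params,
    condition_on_visible = condition_on_visible,
    detail = "posteriors", want_xi = want_xi
  )
  lab <- boundary_labels(res$ops)
  posteriors <- stats::setNames(res$per_read, lab)
  out <- list(
    loglik = res$loglik, posteriors = posteriors, sub_steps = lab,
    space = res$space
  )
  if (want_xi) {
    keep <- !vapply(res$xi, is.null, logical(1))
    out$xi <- stats::setNames(res$xi[keep], lab[-1][keep])
  }
  out
}

# Sufficient statistics (expected trials n and events x per tied parameter)
# from the aggregated boundary marginals of a pass. Tiny negative values from
# floating-point cancellation are floored at zero.
stats_from_pass <- function(pass) {
  space <- pass$space
  ops <- pass$ops
  S <- space$n_states
  att <- !space$detached
  unb <- att & !space$blocked
  blk <- space$blocked
  nvec <- space$n
  Tn <- space$design$n_cycles
  C <- ncol(space$k)
  L <- space$remaining[, 1]
  N <- pass$n_reads

  nm <- rate_param_names(C)
  stats <- stats::setNames(
    rep(list(c(n = 0, x = 0)), length(nm)), nm
  )
  add <- function(key, dn, dx) {
    stats[[key]]["n"] <<- stats[[key]]["n"] + dn
    stats[[key]]["x"] <<- stats[[key]]["x"] + max(dx, 0)
  }

  # dud rates: expected dark labels at the very first sub-step boundary
  m0 <- pass$margsum[[1]]
  for (ch in seq_len(C)) {
    Ek <- sum(m0 * space$k[, ch])
    add(paste0("dud_ch", ch - 1L), N * L[ch], N * L[ch] - Ek)
  }

  for (oi in seq_along(ops)) {
    op <- ops[[oi]]
    if (op$type != "factor") next
    mpre <- pass$margsum[[oi]]
    mpost <- pass$margsum[[oi + 1L]]
    if (op$name == "initial_block") {
      add("initial_block", N, sum(mpost[blk & att]))
    } else if (op$name == "cyclic_block") {
      add(
        "cyclic_block", sum(mpre[unb]),
        sum(mpost[blk & att]) - sum(mpre[blk & att])
      )
    } else if (op$name == "detach") {
      di <- space$detached_index
      add("detach", sum(mpre[att]), mpost[di] - mpre[di])
    } else if (op$name == "dye_loss") {
      kch <- space$k[, op$channel]
      pre <- sum(mpre * kch)
      add(op$param, pre, pre - sum(mpost * kch))
    } else if (op$name == "edman") {
      elig <- unb & nvec < Tn
      trials <- sum(mpre[elig])
      adv <- sum(mpost * nvec) - sum(mpre * nvec)
      add("edman_failure", trials, trials - adv)
    }
  }
  stats
}

#' Expected sufficient statistics for the tied sequencing parameters
#'
#' Maps forward/backward posteriors to the weighted trial/event counts the
#' M-step consumes: for each tied rate, `n` is the expected number of
#' Bernoulli trials (e.g. fluorophore-cycles at risk of dye loss) and `x` the
#' expected number of events (e.g. fluorophores lost), both weighted by the
#' posterior probabilities and summed over reads.
#'
#' @inheritParams forward_backward
#' @return A named list, one element per rate parameter, each a vector
#'   `c(n = , x = )`.
#' @export
accumulate_sufficient_stats <- function(reads, design, params,
                                        condition_on_visible = TRUE) {
  validate_seq_params(params)
  arr <- reads_as_array(reads, design)
  pass <- hmm_pass(arr, design, params,
    condition_on_visible = condition_on_visible, detail = "stats"
  )
  stats_from_pass(pass)
}
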