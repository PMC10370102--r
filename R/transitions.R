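# Sparse row-stochastic factors of the per-cycle transition matrix, one per
# error mechanism. Factoring the cycle transition into sub-transitions
# isolates each error type, which is what lets the M-step estimate the tied
# physical parameters directly.

sparse_from_triplets <- function(i, j, x, S) {
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(S, S))
}

# Blocking factor: unblocked attached states cross to their blocked twin with
# probability `prob`; blocked and detached states are fixed points. Used with
# prob = initial_block before cycle 1 and prob = cyclic_block per cycle.
factor_block <- function(space, prob) {
  S <- space$n_states
  src <- which(!space$blocked & !space$detached)
  fixed <- which(space$blocked | space$detached)
  i <- c(src, src, fixed)
  j <- c(src, space$twin[src], fixed)
  x <- c(rep(1 - prob, length(src)), rep(prob, length(src)), rep(1, length(fixed)))
  sparse_from_triplets(i, j, x, S)
}

# Detachment factor: every attached state (blocked or not) moves to the
# absorbing detached state with probability `prob`.
factor_detach <- function(space, prob) {
  S <- space$n_states
  att <- which(!space$detached)
  i <- c(att, att, S)
  j <- c(att, rep(space$detached_index, length(att)), S)
  x <- c(rep(1 - prob, length(att)), rep(prob, length(att)), 1)
  sparse_from_triplets(i, j, x, S)
}

# Dye-loss factor for one channel: each of the k attached fluorophores of
# that color survives the cycle independently with probability 1 - rate, so
# the count moves k -> j with Binomial(k, 1 - rate) mass.
factor_dye_loss <- function(space, rate, ch) {
  S <- space$n_states
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (s in seq_len(S)) {
    if (space$detached[s]) {
      ii <- c(ii, s); jj <- c(jj, s); xx <- c(xx, 1)
      next
    }
    k <- space$k[s, ch]
    if (k == 0L) {
      ii <- c(ii, s); jj <- c(jj, s); xx <- c(xx, 1)
      next
    }
    for (j in 0:k) {
      kt <- space$k[s, ]
      kt[ch] <- j
      tgt <- state_index(space, space$n[s], kt, space$blocked[s])
      ii <- c(ii, s); jj <- c(jj, tgt)
      xx <- c(xx, stats::dbinom(j, k, 1 - rate))
    }
  }
  sparse_from_triplets(ii, jj, xx, S)
}

# Edman factor: an unblocked attached state advances n -> n + 1 with
# probability 1 - e. If the removed residue (position n + 1) carries a label
# of channel ch, the channel's count decrements by one with probability
# k_ch / R_ch(n) -- of the R labels still attached, k are alive, and which
# ones are alive is exchangeable in the merged model, so the removed label is
# alive with probability k / R. Blocked and detached states are fixed points.
factor_edman <- function(space, e, design) {
  S <- space$n_states
  Tn <- design$n_cycles
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (s in seq_len(S)) {
    n <- space$n[s]
    if (space$detached[s] || space$blocked[s] || n >= Tn) {
      ii <- c(ii, s); jj <- c(jj, s); xx <- c(xx, 1)
      next
    }
    ii <- c(ii, s); jj <- c(jj, s); xx <- c(xx, e) # Edman failure: stay
    ch <- channel_at_position(design, n + 1L)
    k <- space$k[s, ]
    if (ch == 0L) {
      tgt <- state_index(space, n + 1L, k, FALSE)
      ii <- c(ii, s); jj <- c(jj, tgt); xx <- c(xx, 1 - e)
    } else {
      R <- space$remaining[ch, n + 1L] # labels with position > n
      w <- if (R > 0L) k[ch] / R else 0
      if (w > 0) {
        kd <- k
        kd[ch] <- kd[ch] - 1L
        tgt <- state_index(space, n + 1L, kd, FALSE)
        ii <- c(ii, s); jj <- c(jj, tgt); xx <- c(xx, (1 - e) * w)
      }
      if (w < 1) {
        tgt <- state_index(space, n + 1L, k, FALSE)
        ii <- c(ii, s); jj <- c(jj, tgt); xx <- c(xx, (1 - e) * (1 - w))
      }
    }
  }
  sparse_from_triplets(ii, jj, xx, S)
}

#' Transition-matrix factors for one Edman cycle
#'
#' Returns the ordered sparse factors whose product is the full one-cycle
#' transition matrix: N-terminal blocking, detachment, per-channel dye loss,
#' then Edman degradation. Each factor is row-stochastic and touches only the
#' states its error mechanism can connect.
#'
#' @param params A [seq_params()].
#' @param space A [build_state_space()] result.
#' @param cycle_index Cycle number in `1:n_cycles` (the factors are identical
#'   across cycles; the index is validated against the design's range).
#' @param order Character vector giving the sub-transition order within the
#'   cycle. The default places blocking first (a block acquired this cycle
#'   already gates this cycle's Edman step) and dye loss before imaging.
#' @return A list of class `transition_factor_set`; each element has fields
#'   `name`, `param` (the rate parameter(s) it depends on), `channel` (for
#'   dye loss) and `matrix` (sparse `dgCMatrix`).
#' @examples
#' des <- peptide_design(c(2, 4), n_cycles = 3)
#' fs <- transition_factors(seq_params(), build_state_space(des), 1)
#' vapply(fs, `[[`, "", "name")
#' @export
transition_factors <- function(params, space, cycle_index,
                               order = c("cyclic_block", "detach", "dye_loss", "edman")) {
  validate_seq_params(params)
  design <- space$design
  cycle_index <- as.integer(cycle_index)
  if (is.na(cycle_index) || cycle_index < 1L || cycle_index > design$n_cycles) {
    stop("cycle_index must be in [1, n_cycles]", call. = FALSE)
  }
  order <- match.arg(order, c("cyclic_block", "detach", "dye_loss", "edman"),
    several.ok = TRUE
  )
  out <- list()
  for (nm in order) {
    if (nm == "cyclic_block") {
      out[[length(out) + 1L]] <- list(
        name = "cyclic_block", param = "cyclic_block", channel = NA_integer_,
        matrix = factor_block(space, params$cyclic_block)
      )
    } else if (nm == "detach") {
      out[[length(out) + 1L]] <- list(
        name = "detach", param = "detach", channel = NA_integer_,
        matrix = factor_detach(space, params$detach)
      )
    } else if (nm == "dye_loss") {
      for (ch in seq_len(design$n_channels)) {
        out[[length(out) + 1L]] <- list(
          name = "dye_loss", param = paste0("dye_loss_ch", ch - 1L),
          channel = ch,
          matrix = factor_dye_loss(space, params$dye_loss[ch], ch)
        )
      }
    } else {
      out[[length(out) + 1L]] <- list(
        name = "edman", param = "edman_failure", channel = NA_integer_,
        matrix = factor_edman(space, params$edman_failure, design)
      )
    }
  }
  structure(out, class = "transition_factor_set")
}

# Product of a cycle's factors: the unfactored one-cycle transition matrix.
factor_product <- function(factors) {
  M <- factors[[1]]$matrix
  for (f in factors[-1]) M <- M %*% f$matrix
  M
}

# Pre-sequencing distribution over fluorophore counts (unblocked states at
# n = 0): per-channel counts are independent Binomial(L_ch, 1 - dud_ch).
# If conditioning on visibility, all-zero-count states get zero mass.
initial_counts_vector <- function(params, space, condition_on_visible = FALSE) {
  S <- space$n_states
  pi0 <- numeric(S)
  idx <- which(space$n == 0L & !space$blocked & !space$detached)
  L <- space$remaining[, 1]
  for (s in idx) {
    pr <- 1
    for (ch in seq_len(ncol(space$k))) {
      pr <- pr * stats::dbinom(space$k[s, ch], L[ch], 1 - params$dud[ch])
    }
    pi0[s] <- pr
  }
  if (condition_on_visible) {
    zero <- rowSums(space$k) == 0L
    pi0[zero] <- 0
    tot <- sum(pi0)
    if (tot <= 0) stop("no visible initial states under these dud rates", call. = FALSE)
    pi0 <- pi0 / tot
  }
  pi0
}

#' Initial state distribution
#'
#' Distribution over HMM states at the first imaging timepoint: mass sits
#' only on `n = 0` states, per-channel fluorophore counts are independent
#' binomials with success probability `1 - dud`, and the N-terminus is
#' blocked with probability `initial_block`. With
#' `condition_on_visible = TRUE`, states with zero fluorophores in every
#' channel (invisible peptides, which never appear as reads) get zero mass
#' and the vector is renormalized.
#'
#' @inheritParams transition_factors
#' @param condition_on_visible Drop all-dark states and renormalize?
#' @return A probability vector over the state space (sums to 1).
#' @export
initial_distribution <- function(params, space, condition_on_visible = FALSE) {
  validate_seq_params(params)
  pi0 <- initial_counts_vector(params, space, condition_on_visible)
  as.numeric(pi0 %*% factor_block(space, params$initial_block))
}
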