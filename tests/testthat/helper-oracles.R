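# Independent oracles for the HMM machinery, built by brute-force
# enumeration rather than matrix algebra so they share no code path with the
# implementation under test.

# One-cycle transition matrix by exhaustive enumeration of joint outcomes:
# for every source state, walk every combination of (cyclic block?, detach?,
# per-channel dye-loss counts, Edman success?, labeled-residue-alive?) with
# its probability and accumulate mass on the destination state.
oracle_cycle_matrix <- function(params, space) {
  design <- space$design
  S <- space$n_states
  C <- ncol(space$k)
  M <- matrix(0, S, S)
  det_i <- space$detached_index
  M[det_i, det_i] <- 1
  for (s in seq_len(S)) {
    if (space$detached[s]) next
    n <- space$n[s]
    k <- space$k[s, ]
    blk0 <- space$blocked[s]
    for (blk in unique(c(blk0, TRUE))) {
      p_blk <- if (blk0) {
        if (blk) 1 else 0
      } else if (blk) params$cyclic_block else 1 - params$cyclic_block
      if (p_blk == 0) next
      # detach
      M[s, det_i] <- M[s, det_i] + p_blk * params$detach
      p_stay <- p_blk * (1 - params$detach)
      # dye loss: enumerate surviving counts per channel
      surv_sets <- lapply(seq_len(C), function(ch) 0:k[ch])
      grid <- expand.grid(surv_sets)
      for (g in seq_len(nrow(grid))) {
        ks <- as.integer(grid[g, ])
        p_loss <- p_stay
        for (ch in seq_len(C)) {
          p_loss <- p_loss * dbinom(ks[ch], k[ch], 1 - params$dye_loss[ch])
        }
        if (p_loss == 0) next
        if (blk || n >= design$n_cycles) {
          tgt <- fluorfit:::state_index(space, n, ks, blk)
          M[s, tgt] <- M[s, tgt] + p_loss
          next
        }
        # Edman failure
        tgt <- fluorfit:::state_index(space, n, ks, blk)
        M[s, tgt] <- M[s, tgt] + p_loss * params$edman_failure
        # Edman success
        p_succ <- p_loss * (1 - params$edman_failure)
        ch_rm <- fluorfit:::channel_at_position(design, n + 1L)
        if (ch_rm == 0L) {
          tgt <- fluorfit:::state_index(space, n + 1L, ks, blk)
          M[s, tgt] <- M[s, tgt] + p_succ
        } else {
          R <- sum(design$labels_by_channel[[ch_rm]] > n)
          w <- if (R > 0) ks[ch_rm] / R else 0
          if (w > 0) {
            kd <- ks
            kd[ch_rm] <- kd[ch_rm] - 1L
            tgt <- fluorfit:::state_index(space, n + 1L, kd, blk)
            M[s, tgt] <- M[s, tgt] + p_succ * w
          }
          if (w < 1) {
            tgt <- fluorfit:::state_index(space, n + 1L, ks, blk)
            M[s, tgt] <- M[s, tgt] + p_succ * (1 - w)
          }
        }
      }
    }
  }
  M
}

# Emission density of one timepoint's intensities given a state, multiplying
# independent per-channel normals.
oracle_emission <- function(y, state_k, params) {
  d <- 1
  for (ch in seq_along(y)) {
    k <- state_k[ch]
    d <- d * dnorm(
      y[ch],
      mean = params$bg_mu + k * (params$mu[ch] - params$bg_mu),
      sd = sqrt(params$bg_sigma^2 + k * params$sigma[ch]^2)
    )
  }
  d
}

# Observed-data likelihood of one read by exhaustive summation over all
# state paths at timepoint boundaries (transitions from the enumeration
# oracle above, not from the package's factor product).
oracle_path_loglik <- function(read_mat, design, params,
                               condition_on_visible = TRUE) {
  space <- build_state_space(design)
  S <- space$n_states
  Tn <- design$n_cycles
  Mcyc <- oracle_cycle_matrix(params, space)
  pi0 <- numeric(S)
  idx0 <- which(space$n == 0L & !space$detached)
  L <- space$remaining[, 1]
  for (s in idx0) {
    pr <- 1
    for (ch in seq_len(ncol(space$k))) {
      pr <- pr * dbinom(space$k[s, ch], L[ch], 1 - params$dud[ch])
    }
    pr <- pr * if (space$blocked[s]) params$initial_block else 1 - params$initial_block
    pi0[s] <- pr
  }
  if (condition_on_visible) {
    pi0[rowSums(space$k) == 0L] <- 0
    pi0 <- pi0 / sum(pi0)
  }
  paths <- expand.grid(rep(list(seq_len(S)), Tn + 1L))
  total <- 0
  for (p in seq_len(nrow(paths))) {
    st <- as.integer(paths[p, ])
    pr <- pi0[st[1]] * oracle_emission(read_mat[1, ], space$k[st[1], ], params)
    if (pr == 0) next
    for (t in seq_len(Tn)) {
      pr <- pr * Mcyc[st[t], st[t + 1L]] *
        oracle_emission(read_mat[t + 1L, ], space$k[st[t + 1L], ], params)
      if (pr == 0) break
    }
    total <- total + pr
  }
  log(total)
}

# Shared small fixtures
two_label_design <- function(n_cycles = 10) peptide_design(c(2, 4), n_cycles)

typical_params <- function() {
  seq_params(
    edman_failure = 0.06, detach = 0.05, initial_block = 0.05,
    cyclic_block = 0.02, dye_loss = 0.04, dud = 0.07,
    mu = 6000, sigma = 900, bg_mu = 0, bg_sigma = 350
  )
}
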