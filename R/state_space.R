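#' Build the merged HMM state space for a peptide design
#'
#' States of the fluorosequencing HMM are merged by their observable
#' signature: the number of successful Edman cycles `n`, the per-channel
#' fluorophore counts `k`, and whether the N-terminus is blocked. Every
#' unblocked state has a blocked twin (blocking halts Edman chemistry but not
#' fluorescence), and a single absorbing "detached" state with zero signal
#' closes the space. Merging keeps the state count polynomial in the label
#' count instead of exponential.
#'
#' A channel's count `k` can never exceed the number of that channel's labels
#' still attached after `n` removals, so the allowed counts shrink as Edman
#' chemistry proceeds past labeled positions.
#'
#' @param design A [peptide_design()].
#' @return An object of class `state_space` with fields `n` (Edman counts),
#'   `k` (states x channels count matrix), `blocked`, `detached` (logical),
#'   `detached_index`, `n_states`, and `remaining` (channels x (n_cycles+1)
#'   matrix of attached label counts by Edman count). States are ordered by
#'   `n`, then counts, then blocked flag, with the detached state last.
#' @examples
#' sp <- build_state_space(peptide_design(1, n_cycles = 1))
#' sp$n_states # 7: 3 unblocked, 3 blocked twins, 1 detached
#' @export
build_state_space <- function(design) {
  stopifnot(inherits(design, "peptide_design"))
  C <- design$n_channels
  Tn <- design$n_cycles
  remaining <- vapply(
    0:Tn,
    function(n) vapply(seq_len(C), function(ch) labels_remaining(design, ch, n), integer(1)),
    integer(C)
  )
  remaining <- matrix(remaining, nrow = C) # C x (Tn+1)

  rows <- list()
  for (n in 0:Tn) {
    combos <- expand.grid(lapply(seq_len(C), function(ch) 0:remaining[ch, n + 1]))
    # expand.grid varies the first factor fastest; reorder so counts sort
    # lexicographically with channel 1 most significant
    combos <- as.matrix(combos[do.call(order, as.list(as.data.frame(combos))), , drop = FALSE])
    for (i in seq_len(nrow(combos))) {
      for (blk in 0:1) {
        rows[[length(rows) + 1L]] <- c(n, combos[i, ], blk)
      }
    }
  }
  mat <- do.call(rbind, rows)
  S <- nrow(mat) + 1L # + detached
  nvec <- c(mat[, 1], 0L)
  kmat <- rbind(mat[, 2:(1 + C), drop = FALSE], rep(0L, C))
  blocked <- c(mat[, 2 + C], 0L) == 1L
  detached <- c(rep(FALSE, nrow(mat)), TRUE)

  key <- paste(nvec, apply(kmat, 1, paste, collapse = ","), as.integer(blocked),
    sep = "|"
  )
  key[S] <- "detached"
  twin <- match(
    paste(nvec, apply(kmat, 1, paste, collapse = ","), 1L, sep = "|"), key
  )
  twin[blocked | detached] <- NA_integer_

  structure(
    list(
      n = as.integer(nvec), k = kmat, blocked = blocked, detached = detached,
      detached_index = S, n_states = S, key = key, twin = twin,
      remaining = remaining, design = design
    ),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space> ", x$n_states, " states (",
    sum(!x$blocked & !x$detached), " unblocked + ",
    sum(x$blocked), " blocked + 1 detached), ",
    ncol(x$k), " channel(s)\n",
    sep = ""
  )
  invisible(x)
}

# Integer index of state (n, k, blocked); detached via detached_index.
state_index <- function(space, n, k, blocked) {
  match(
    paste(n, paste(k, collapse = ","), as.integer(blocked), sep = "|"),
    space$key
  )
}

#' Serialize a state space (and optionally factors) to a JSON-ready list
#'
#' Intended for debugging model structure (`--dump-model` in the CLI).
#'
#' @param space A [build_state_space()] result.
#' @return A list of plain vectors describing each state.
#' @export
state_space_as_list <- function(space) {
  list(
    n_states = space$n_states,
    n_edman = space$n,
    counts = unname(apply(space$k, 1, as.list)),
    blocked = space$blocked,
    detached_index = space$detached_index
  )
}
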