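# Monte Carlo generative model of fluorosequencing reads. The simulator
# draws the merged-state chain directly (dud realization, initial block,
# then per cycle: cyclic block, detachment, per-channel dye loss, Edman with
# the exchangeable k/R label-removal rule), which is exactly the process the
# HMM describes, then adds normal intensity noise at every imaging timepoint.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

reads_colnames <- function(design) {
  unlist(lapply(seq_len(design$n_channels) - 1L, function(ch) {
    paste0("ch", ch, "_t", 0:design$n_cycles)
  }))
}

array_to_tibble <- function(arr, design, read_ids) {
  C <- design$n_channels
  Tn <- design$n_cycles
  out <- vector("list", C * (Tn + 1L))
  nms <- character(length(out))
  i <- 0L
  for (ch in seq_len(C) - 1L) {
    for (t in 0:Tn) {
      i <- i + 1L
      nms[i] <- paste0("ch", ch, "_t", t)
      out[[i]] <- arr[, t + 1L, ch + 1L]
    }
  }
  names(out) <- nms
  dplyr::bind_cols(tibble::tibble(read_id = read_ids), tibble::as_tibble(out))
}

#' Simulate fluorosequencing reads
#'
#' Draws `n_reads` peptide reads from the generative error model: duds and
#' initial blocking are realized before sequencing, then each Edman cycle
#' applies (in order) cyclic blocking, detachment, per-channel dye loss, and
#' the Edman step itself; noisy intensities are emitted at every imaging
#' timepoint (one before cycle 1, then one per cycle). Detached peptides keep
#' emitting background noise, matching a spot that has gone dark.
#'
#' Peptides whose fluorophores are all dud at the start never show up as
#' reads; by default such draws are redrawn so exactly `n_reads` visible
#' reads are returned, and the fraction of invisible draws is reported (it is
#' the quantity the dud-censoring correction estimates).
#'
#' @param design A [peptide_design()].
#' @param params A [seq_params()].
#' @param n_reads Number of reads to return.
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @param keep_invisible Keep all-dud peptides (with pure-background reads)
#'   instead of redrawing them?
#' @return A list of class `fluorseq_sim`: `reads` (wide tibble, columns
#'   `read_id` and `ch{c}_t{t}`), `truth` (same shape, integer true
#'   fluorophore counts at each timepoint), `invisible_fraction`, `params`,
#'   `design`, `seed`.
#' @examples
#' sim <- simulate_reads(peptide_design(c(2, 4), 10), seq_params(), 100, seed = 1)
#' sim$reads
#' @export
simulate_reads <- function(design, params, n_reads, seed = NULL,
                           keep_invisible = FALSE) {
  validate_seq_params(params)
  stopifnot(inherits(design, "peptide_design"), n_reads >= 1)
  n_reads <- as.integer(n_reads)
  core <- with_seed(seed, {
    simulate_core(design, params, n_reads, keep_invisible)
  })
  ids <- sprintf("r%06d", seq_len(n_reads))
  structure(
    list(
      reads = array_to_tibble(core$intens, design, ids),
      truth = array_to_tibble(core$truth, design, ids),
      invisible_fraction = core$n_invisible / (core$n_invisible + n_reads),
      params = params, design = design, seed = seed
    ),
    class = "fluorseq_sim"
  )
}

# RNG-consuming simulation core shared by simulate_reads() and the RMSE
# objective's internal fast path (which skips tibble construction).
# Pre-draw the whole parameter-independent random stream for n reads, plus
# the RNG state reached afterwards (needed to reproduce the redraws of
# invisible peptides bit-for-bit). Feeding the bank back into simulate_core
# gives output identical to drawing live under the same seed, while letting
# repeated objective evaluations skip all RNG work.
make_sim_bank <- function(design, n, seed) {
  C <- design$n_channels
  Tn <- design$n_cycles
  with_seed(seed, {
    u <- list()
    z <- list()
    for (ch in seq_len(C)) u[[length(u) + 1L]] <- stats::runif(n)
    u[[length(u) + 1L]] <- stats::runif(n) # initial block
    for (t in seq_len(Tn)) {
      u[[length(u) + 1L]] <- stats::runif(n) # cyclic block
      u[[length(u) + 1L]] <- stats::runif(n) # detach
      for (ch in seq_len(C)) u[[length(u) + 1L]] <- stats::runif(n) # dye loss
      u[[length(u) + 1L]] <- stats::runif(n) # edman advance
      u[[length(u) + 1L]] <- stats::runif(n) # label decrement
    }
    for (ch in seq_len(C)) {
      for (t in 0:(Tn)) z[[length(z) + 1L]] <- stats::rnorm(n)
    }
    list(u = u, z = z, n = n, state = get(".Random.seed", globalenv()))
  })
}

simulate_core <- function(design, params, n_reads, keep_invisible, bank = NULL,
                          emit = TRUE) {
  if (!is.null(bank)) {
    stopifnot(bank$n == n_reads)
    return(simulate_core_banked(
      design, params, n_reads, keep_invisible, bank,
      emit = emit
    ))
  }
  simulate_core_draws(
    design, params, n_reads, keep_invisible,
    draw_u = function() stats::runif(n_reads),
    draw_z = function() stats::rnorm(n_reads),
    emit = emit
  )
}

simulate_core_banked <- function(design, params, n_reads, keep_invisible, bank,
                                 emit = FALSE) {
  iu <- 0L
  iz <- 0L
  out <- simulate_core_draws(
    design, params, n_reads,
    keep_invisible = TRUE,
    draw_u = function() {
      iu <<- iu + 1L
      bank$u[[iu]]
    },
    draw_z = function() {
      iz <<- iz + 1L
      bank$z[[iz]]
    },
    emit = emit
  )
  out$redrawn <- integer(0)
  if (!keep_invisible) {
    inv <- which(rowSums(out$truth[, 1L, , drop = FALSE]) == 0L)
    if (length(inv)) {
      # reproduce the live redraw stream from the post-bank RNG state
      old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        get(".Random.seed", globalenv())
      } else {
        NULL
      }
      on.exit({
        if (is.null(old)) {
          rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", old, envir = globalenv())
        }
      })
      assign(".Random.seed", bank$state, envir = globalenv())
      redrawn <- integer(0)
      repeat {
        inv <- which(rowSums(out$truth[, 1L, , drop = FALSE]) == 0L)
        if (!length(inv)) break
        out$n_invisible <- out$n_invisible + length(inv)
        redo <- simulate_core(design, params, length(inv), keep_invisible = TRUE)
        out$truth[inv, , ] <- redo$truth
        if (is.null(out$intens)) {
          out$intens <- array(NA_real_, dim = dim(out$truth))
        }
        out$intens[inv, , ] <- redo$intens
        redrawn <- union(redrawn, inv)
      }
      out$redrawn <- redrawn
    }
  }
  out
}

simulate_core_draws <- function(design, params, n_reads, keep_invisible,
                                draw_u, draw_z, emit = TRUE) {
  C <- design$n_channels
  Tn <- design$n_cycles
  rem <- matrix(vapply(
    0:Tn,
    function(n) {
      vapply(seq_len(C), function(ch) labels_remaining(design, ch, n), integer(1))
    },
    integer(C)
  ), nrow = C)
  L <- rem[, 1]
  poschan <- vapply(seq_len(Tn), function(p) channel_at_position(design, p), integer(1))
  # All stochastic decisions draw a fixed number of uniforms/normals per read
  # regardless of the parameter values (inverse-CDF sampling), so the random
  # stream consumed is parameter-independent. Under a common seed the whole
  # simulation then varies smoothly with the rates — the property the RMSE
  # fitter's common-random-numbers objective relies on.
  N <- n_reads
  # inverse-CDF binomial draw: number of successes among `size` trials with
  # success probability q, from one uniform per element
  qbinom_u <- function(u, size, q) {
    out <- integer(length(u))
    for (kv in unique(size[size > 0L])) {
      idx <- which(size == kv)
      cdf <- stats::pbinom(0:(kv - 1L), kv, q)
      x <- integer(length(idx))
      for (j in seq_along(cdf)) x <- x + (u[idx] > cdf[j])
      out[idx] <- x
    }
    out
  }

  k <- matrix(0L, N, C)
  for (ch in seq_len(C)) {
    k[, ch] <- qbinom_u(draw_u(), rep(L[ch], N), 1 - params$dud[ch])
  }
  blocked <- draw_u() < params$initial_block
  detached <- rep(FALSE, N)
  nED <- integer(N)

  truth <- array(0L, dim = c(N, Tn + 1L, C))
  truth[, 1L, ] <- k
  for (t in seq_len(Tn)) {
    blocked <- blocked | (!detached & draw_u() < params$cyclic_block)
    newdet <- !detached & draw_u() < params$detach
    detached <- detached | newdet
    k[newdet, ] <- 0L
    for (ch in seq_len(C)) {
      k[, ch] <- qbinom_u(draw_u(), k[, ch], 1 - params$dye_loss[ch])
    }
    adv <- !blocked & !detached & draw_u() < 1 - params$edman_failure
    u_dec <- draw_u() # fixed-size draw keeps the stream aligned
    ia <- which(adv)
    if (length(ia)) {
      p <- nED[ia] + 1L
      chp <- poschan[p]
      lab <- which(chp > 0L)
      if (length(lab)) {
        il <- ia[lab]
        chl <- chp[lab]
        R <- rem[cbind(chl, nED[il] + 1L)]
        kv <- k[cbind(il, chl)]
        dec <- u_dec[il] < ifelse(R > 0L, kv / R, 0)
        k[cbind(il, chl)] <- kv - as.integer(dec)
      }
      nED[ia] <- nED[ia] + 1L
    }
    truth[, t + 1L, ] <- k
  }

  intens <- NULL
  if (emit) {
    intens <- array(0, dim = c(N, Tn + 1L, C))
    for (ch in seq_len(C)) {
      for (t in 0:Tn) {
        kt <- truth[, t + 1L, ch]
        intens[, t + 1L, ch] <- params$bg_mu + kt * (params$mu[ch] - params$bg_mu) +
          sqrt(params$bg_sigma^2 + kt * params$sigma[ch]^2) * draw_z()
      }
    }
  }

  # redraw invisible all-dud peptides last, so their (parameter-dependent)
  # extra draws never shift the main stream
  n_invisible <- 0L
  if (!keep_invisible) {
    repeat {
      inv <- which(rowSums(truth[, 1L, , drop = FALSE]) == 0L)
      if (!length(inv)) break
      n_invisible <- n_invisible + length(inv)
      redo <- simulate_core(design, params, length(inv), keep_invisible = TRUE)
      truth[inv, , ] <- redo$truth
      intens[inv, , ] <- redo$intens
    }
  }

  list(intens = intens, truth = truth, n_invisible = n_invisible)
}

#' @export
print.fluorseq_sim <- function(x, ...) {
  cat("<fluorseq_sim> ", nrow(x$reads), " reads, ",
    x$design$n_channels, " channel(s), ", x$design$n_cycles, " cycles",
    if (x$invisible_fraction > 0) {
      sprintf(" (invisible draw fraction %.3g)", x$invisible_fraction)
    } else {
      ""
    }, "\n",
    sep = ""
  )
  invisible(x)
}

#' Reduce reads to integer dye tracks
#'
#' Maps every intensity independently to the fluorophore count (between 0 and
#' the channel's label count) whose emission density is highest, breaking
#' exact ties toward the smaller count. This is the integer approximation of
#' a read used by the RMSE fitter.
#'
#' @param reads Wide reads tibble or intensity array.
#' @param params A [seq_params()] supplying the intensity model.
#' @param design A [peptide_design()].
#' @return A wide tibble of integer counts with the same column layout as the
#'   reads.
#' @export
reduce_to_dyetrack <- function(reads, params, design) {
  validate_seq_params(params)
  arr <- reads_as_array(reads, design)
  out <- reduce_core(arr, params, design)
  ids <- if (is.data.frame(reads) && "read_id" %in% names(reads)) {
    as.character(reads$read_id)
  } else {
    sprintf("r%06d", seq_len(dim(arr)[1]))
  }
  array_to_tibble(out, design, ids)
}

# Array-in, array-out reduction: every intensity maps to the count (0..kmax)
# with the largest log emission density, ties broken toward the smaller
# count (max.col "first" with counts in ascending order).
reduce_core <- function(arr, params, design) {
  out <- array(0L, dim = dim(arr))
  for (ch in seq_len(design$n_channels)) {
    kmax <- labels_remaining(design, ch, 0L)
    y <- as.vector(arr[, , ch])
    logd <- vapply(0:kmax, function(k) {
      v <- params$bg_sigma^2 + k * params$sigma[ch]^2
      m <- params$bg_mu + k * (params$mu[ch] - params$bg_mu)
      -(y - m)^2 / (2 * v) - 0.5 * log(v)
    }, numeric(length(y)))
    out[, , ch] <- array(
      max.col(logd, ties.method = "first") - 1L,
      dim = dim(arr)[1:2]
    )
  }
  out
}

#' Histogram of unique dye tracks
#'
#' Counts occurrences of each distinct integer dye track (exact equality of
#' the whole counts-by-timepoint matrix).
#'
#' @param tracks A wide tibble of integer counts as returned by
#'   [reduce_to_dyetrack()] (the `read_id` column is ignored), or a list of
#'   such tibbles' rows.
#' @param design A [peptide_design()].
#' @return A tibble with columns `track` (canonical string key, channel-major
#'   `ch{c}_t{t}` order) and `count`, sorted by decreasing count. Counts sum
#'   to the number of tracks.
#' @export
dyetrack_histogram <- function(tracks, design) {
  cols <- reads_colnames(design)
  if (nrow(tracks) == 0L) {
    return(tibble::tibble(track = character(0), count = integer(0)))
  }
  missing <- setdiff(cols, names(tracks))
  if (length(missing)) {
    stop("tracks are missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  key <- do.call(paste, c(unname(as.list(tracks[cols])), sep = ","))
  tb <- table(key)
  tibble::tibble(
    track = names(tb), count = as.integer(tb)
  ) |> dplyr::arrange(dplyr::desc(count), track)
}

# Fast internal histogram used by the RMSE objective: tracks encoded as
# base-B integers (exact while B^ncol stays within double precision),
# falling back to the string-keyed version otherwise. Key spaces match
# between calls with the same design, which is all the RMSE union needs.
dyetrack_histogram_fast <- function(tracks, design) {
  cols <- reads_colnames(design)
  m <- if (is.array(tracks) && length(dim(tracks)) == 3L) {
    # channel-major flattening matches reads_colnames order
    matrix(as.vector(tracks), nrow = dim(tracks)[1])
  } else if (is.matrix(tracks)) {
    tracks
  } else {
    as.matrix(tracks[cols])
  }
  kmax <- max(vapply(
    seq_len(design$n_channels),
    function(ch) labels_remaining(design, ch, 0L), integer(1)
  ))
  B <- kmax + 1
  if (B^length(cols) < 2^50) {
    key <- as.vector(m %*% B^(seq_along(cols) - 1))
    uk <- unique(key)
    tibble::tibble(track = uk, count = tabulate(match(key, uk), length(uk)))
  } else {
    dyetrack_histogram(
      if (is.matrix(m)) {
        tibble::as_tibble(stats::setNames(as.data.frame(m), cols))
      } else {
        tracks
      },
      design
    )
  }
}
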