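#' Sequencing parameter set
#'
#' Bundles the full parameter vector of the fluorosequencing error model:
#' four global per-cycle (or pre-sequencing) error rates, two per-channel
#' rates, and the per-channel intensity model held fixed during rate fitting.
#'
#' @param edman_failure Per-cycle probability that Edman removal of the
#'   N-terminal residue fails (the peptide stays at the same position).
#' @param detach Per-cycle probability that the whole peptide is lost from the
#'   flow-cell surface.
#' @param initial_block Probability that the N-terminus is chemically blocked
#'   before sequencing starts, preventing all Edman cleavage.
#' @param cyclic_block Per-cycle probability of acquiring an N-terminal block
#'   during sequencing.
#' @param dye_loss Numeric vector, one value per channel: per-cycle
#'   probability that each attached fluorophore of that color is destroyed
#'   (chemical destruction and photobleaching combined).
#' @param dud Numeric vector, one value per channel: probability that a
#'   fluorophore of that color is absent or dark from the start (the
#'   "missing fluorophore" or dud rate).
#' @param mu,sigma Numeric vectors, one value per channel: mean and standard
#'   deviation of the single-fluorophore intensity distribution.
#' @param bg_mu,bg_sigma Mean and standard deviation of the zero-fluorophore
#'   (background) intensity distribution.
#'
#' @details All rates must lie in `[0, 1)`. The emission model for a state
#' with `k` fluorophores in a channel is normal with mean
#' `bg_mu + k * (mu - bg_mu)` and standard deviation
#' `sqrt(bg_sigma^2 + k * sigma^2)`, i.e. the sum of `k` independent one-dye
#' signals on top of background.
#'
#' @return An object of class `seq_params`.
#' @examples
#' seq_params(
#'   edman_failure = 0.06, detach = 0.05, initial_block = 0.05,
#'   cyclic_block = 0.02, dye_loss = 0.04, dud = 0.07,
#'   mu = 6000, sigma = 900, bg_mu = 0, bg_sigma = 350
#' )
#' @export
seq_params <- function(edman_failure = 0.05, detach = 0.05, initial_block = 0.05,
                       cyclic_block = 0.05, dye_loss = 0.05, dud = 0.05,
                       mu = 6000, sigma = 900, bg_mu = 0, bg_sigma = 350) {
  n_channels <- max(length(dye_loss), length(dud), length(mu), length(sigma))
  dye_loss <- rep_len(dye_loss, n_channels)
  dud <- rep_len(dud, n_channels)
  mu <- rep_len(mu, n_channels)
  sigma <- rep_len(sigma, n_channels)
  p <- structure(
    list(
      edman_failure = edman_failure, detach = detach,
      initial_block = initial_block, cyclic_block = cyclic_block,
      dye_loss = dye_loss, dud = dud,
      mu = mu, sigma = sigma, bg_mu = bg_mu, bg_sigma = bg_sigma,
      n_channels = n_channels
    ),
    class = "seq_params"
  )
  validate_seq_params(p)
  p
}

validate_seq_params <- function(p) {
  stopifnot(inherits(p, "seq_params"))
  rates <- c(
    p$edman_failure, p$detach, p$initial_block, p$cyclic_block,
    p$dye_loss, p$dud
  )
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates >= 1)) {
    stop("all error rates must lie in [0, 1)", call. = FALSE)
  }
  if (any(p$sigma <= 0) || p$bg_sigma <= 0) {
    stop("sigma and bg_sigma must be positive", call. = FALSE)
  }
  if (any(p$mu <= p$bg_mu)) {
    stop("mu must exceed bg_mu in every channel", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.seq_params <- function(x, ...) {
  cat("<seq_params> ", x$n_channels, " channel(s)\n", sep = "")
  cat(sprintf(
    "  edman_failure %.4g  detach %.4g  initial_block %.4g  cyclic_block %.4g\n",
    x$edman_failure, x$detach, x$initial_block, x$cyclic_block
  ))
  for (ch in seq_len(x$n_channels)) {
    cat(sprintf(
      "  ch%d: dye_loss %.4g  dud %.4g  mu %.4g  sigma %.4g\n",
      ch - 1L, x$dye_loss[ch], x$dud[ch], x$mu[ch], x$sigma[ch]
    ))
  }
  cat(sprintf("  background: mu %.4g  sigma %.4g\n", x$bg_mu, x$bg_sigma))
  invisible(x)
}

# Names of the free rate parameters for a given channel count, in canonical
# order. Per-channel names carry a 0-based channel suffix.
rate_param_names <- function(n_channels) {
  c(
    "edman_failure", "detach", "initial_block", "cyclic_block",
    paste0("dye_loss_ch", seq_len(n_channels) - 1L),
    paste0("dud_ch", seq_len(n_channels) - 1L)
  )
}

# Flatten the rate parameters of a seq_params into a named vector.
rates_as_vector <- function(params) {
  stats::setNames(
    c(
      params$edman_failure, params$detach, params$initial_block,
      params$cyclic_block, params$dye_loss, params$dud
    ),
    rate_param_names(params$n_channels)
  )
}

# Replace rate parameters from a named vector (inverse of rates_as_vector).
rates_from_vector <- function(params, v) {
  nm <- names(v)
  for (i in seq_along(v)) {
    val <- unname(v[i])
    key <- nm[i]
    if (key %in% c("edman_failure", "detach", "initial_block", "cyclic_block")) {
      params[[key]] <- val
    } else if (grepl("^dye_loss_ch", key)) {
      params$dye_loss[as.integer(sub("^dye_loss_ch", "", key)) + 1L] <- val
    } else if (grepl("^dud_ch", key)) {
      params$dud[as.integer(sub("^dud_ch", "", key)) + 1L] <- val
    } else {
      stop("unknown rate parameter: ", key, call. = FALSE)
    }
  }
  validate_seq_params(params)
  params
}

# Rates exactly 0 or 1 make log-likelihoods degenerate; clamp inside
# likelihood evaluation only (reported estimates are never clamped).
clamp_rate <- function(x, eps = 1e-9) pmin(pmax(x, eps), 1 - eps)
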