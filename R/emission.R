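#' Emission density of an intensity under a fluorophore count
#'
#' Density of observing `intensity` in a channel when `count` fluorophores
#' are present: normal with mean `bg_mu + count * (mu - bg_mu)` and standard
#' deviation `sqrt(bg_sigma^2 + count * sigma^2)` (the sum of `count`
#' independent one-dye signals plus background).
#'
#' @param intensity Numeric vector of intensities.
#' @param count Non-negative fluorophore count (scalar or vector).
#' @param params A [seq_params()].
#' @param channel 0-based channel index.
#' @return Densities, strictly positive for finite intensities.
#' @examples
#' p <- seq_params(mu = 6000, sigma = 900, bg_mu = 0, bg_sigma = 350)
#' emission_density(6000, 1, p, channel = 0)
#' @export
emission_density <- function(intensity, count, params, channel = 0) {
  validate_seq_params(params)
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  ch <- as.integer(channel) + 1L
  stopifnot(ch >= 1L, ch <= params$n_channels)
  stats::dnorm(
    intensity,
    mean = params$bg_mu + count * (params$mu[ch] - params$bg_mu),
    sd = sqrt(params$bg_sigma^2 + count * params$sigma[ch]^2)
  )
}

#' Fit a channel's one-fluorophore intensity distribution
#'
#' Estimates `mu` as the mode of a kernel-smoothed histogram of
#' single-fluorophore intensities and `sigma` from the half-width at
#' half-maximum of the smoothed peak (`HWHM / sqrt(2 log 2)`), mirroring the
#' practice of fitting the peak max and half-width rather than moments --
#' robust to the heavy shoulders real intensity histograms show.
#'
#' @param one_count_intensities Numeric vector (>= 100 values) of intensities
#'   believed to come from single-fluorophore spots.
#' @param bw Kernel bandwidth passed to [stats::density()] (default
#'   `"nrd0"`).
#' @return A list with elements `mu` and `sigma`.
#' @examples
#' set.seed(1)
#' fit_channel_distribution(rnorm(5000, 6000, 800))
#' @export
fit_channel_distribution <- function(one_count_intensities, bw = "nrd0") {
  x <- one_count_intensities[is.finite(one_count_intensities)]
  if (length(x) < 100) {
    stop("need at least 100 intensity values to fit a channel distribution",
      call. = FALSE
    )
  }
  if (stats::sd(x) == 0) {
    stop("intensity histogram is degenerate (constant values)", call. = FALSE)
  }
  d <- stats::density(x, bw = bw, n = 2048)
  imax <- which.max(d$y)
  mu <- d$x[imax]
  half <- d$y[imax] / 2
  # walk outward from the peak to the half-maximum crossings
  right <- which(d$y[imax:length(d$y)] <= half)
  left <- which(rev(d$y[1:imax]) <= half)
  hw_r <- if (length(right)) d$x[imax + right[1] - 1L] - mu else NA_real_
  hw_l <- if (length(left)) mu - d$x[imax - left[1] + 1L] else NA_real_
  hwhm <- mean(c(hw_l, hw_r), na.rm = TRUE)
  if (!is.finite(hwhm) || hwhm <= 0) {
    stop("could not locate half-maximum crossings (flat histogram?)",
      call. = FALSE
    )
  }
  list(mu = mu, sigma = hwhm / sqrt(2 * log(2)))
}

#' Intensity filter specification
#'
#' A per-channel list of closed allowed intensity intervals used to remove
#' reads contaminated by non-fluorophore signals.
#'
#' @param ... One numeric matrix/list of intervals per channel. Each
#'   channel's spec is a list of `c(lo, hi)` pairs (or a 2-column matrix).
#'   Use `NULL` for a channel with no restriction.
#' @return An object of class `intensity_filter`.
#' @examples
#' intensity_filter(list(c(-2000, 3000), c(4500, 20000)))
#' @export
intensity_filter <- function(...) {
  chans <- list(...)
  norm <- lapply(chans, function(iv) {
    if (is.null(iv)) {
      return(NULL)
    }
    if (is.matrix(iv)) iv <- lapply(seq_len(nrow(iv)), function(i) iv[i, ])
    if (is.numeric(iv) && length(iv) == 2L) iv <- list(iv)
    m <- do.call(rbind, lapply(iv, function(p) {
      stopifnot(length(p) == 2L, p[1] <= p[2])
      as.numeric(p)
    }))
    m <- m[order(m[, 1]), , drop = FALSE]
    if (nrow(m) > 1L && any(m[-1, 1] <= m[-nrow(m), 2])) {
      stop("filter intervals must be non-overlapping", call. = FALSE)
    }
    m
  })
  structure(norm, class = "intensity_filter")
}

#' Remove reads with intensities outside the allowed ranges
#'
#' A read is removed if any single intensity, at any timepoint in any
#' channel, lies outside every allowed (closed) interval for that channel --
#' such values are most likely contaminants, and one contaminated value
#' invalidates the whole read. Channels without a filter spec admit all
#' values. Read order is preserved; the operation is idempotent.
#'
#' @param reads Wide reads tibble (see [simulate_reads()]).
#' @param filt An [intensity_filter()].
#' @param design A [peptide_design()] giving cycle/channel structure.
#' @return A list with `kept` (filtered tibble) and `n_removed`.
#' @export
filter_reads <- function(reads, filt, design) {
  stopifnot(inherits(filt, "intensity_filter"))
  if (length(filt) > design$n_channels) {
    stop("filter specifies more channels than the design has", call. = FALSE)
  }
  arr <- reads_as_array(reads, design)
  ok <- rep(TRUE, nrow(reads))
  for (ch in seq_along(filt)) {
    iv <- filt[[ch]]
    if (is.null(iv)) next
    vals <- arr[, , ch, drop = FALSE]
    allowed <- matrix(FALSE, nrow = dim(vals)[1], ncol = dim(vals)[2])
    for (r in seq_len(nrow(iv))) {
      allowed <- allowed | (vals[, , 1] >= iv[r, 1] & vals[, , 1] <= iv[r, 2])
    }
    ok <- ok & apply(allowed, 1, all)
  }
  list(kept = reads[ok, , drop = FALSE], n_removed = sum(!ok))
}
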