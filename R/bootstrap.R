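#' Percentile confidence interval from bootstrap replicates
#'
#' Empirical quantiles (linear interpolation) at `(1 - level) / 2` and
#' `1 - (1 - level) / 2`.
#'
#' @param replicates Numeric vector of replicate estimates.
#' @param level Central coverage level in (0, 1).
#' @return Named vector `c(lo = , hi = )` with `lo <= hi`.
#' @examples
#' percentile_ci(1:100, 0.9) # (5.95, 95.05)
#' @export
percentile_ci <- function(replicates, level = 0.95) {
  if (!length(replicates)) stop("no replicates", call. = FALSE)
  stopifnot(level > 0, level < 1)
  q <- stats::quantile(replicates,
    probs = c((1 - level) / 2, 1 - (1 - level) / 2),
    names = FALSE, type = 7
  )
  c(lo = q[1], hi = q[2])
}

fit_estimates <- function(fit) {
  if (inherits(fit, "fluorfit_fit")) {
    return(rates_as_vector(fit$params))
  }
  if (is.numeric(fit) && !is.null(names(fit))) {
    return(fit)
  }
  stop("fitter must return a fluorfit_fit or a named numeric vector",
    call. = FALSE
  )
}

#' Bootstrap a parameter fitter
#'
#' Resamples the reads with replacement (`n_boot` datasets of the original
#' size), refits each with the supplied fitter, and summarizes the replicate
#' estimates with percentile confidence intervals. Replicate `i` draws its
#' resampling indices from a stream seeded at `seed + i`, so replicates are
#' independent and individually reproducible; the fitter receives the
#' replicate index as a seed offset through its second argument if it
#' accepts one.
#'
#' @param reads Wide reads tibble.
#' @param fitter Function `(reads)` or `(reads, seed)` returning a fit object
#'   (class `fluorfit_fit`) or a named numeric vector of estimates. Warm-start
#'   replicate fits from the original-data estimate for speed.
#' @param n_boot Number of bootstrap replicates.
#' @param ci_level Central coverage of the percentile intervals.
#' @param seed Master seed for the resampling streams.
#' @param point Optional precomputed fit on the original data; if `NULL` the
#'   fitter is run on the original reads first.
#' @return An object of class `fluorfit_boot`: `replicates` (tibble with
#'   `replicate`, `term`, `estimate`), `ci` (tibble with `term`, `estimate`,
#'   `conf.low`, `conf.high`), `n_boot`, `n_failed`, `ci_level`, `seed`.
#' @export
bootstrap_fit <- function(reads, fitter, n_boot = 100, ci_level = 0.95,
                          seed = 1, point = NULL) {
  stopifnot(n_boot >= 1, nrow(reads) >= 1)
  N <- nrow(reads)
  if (is.null(point)) point <- fitter(reads)
  point_est <- fit_estimates(point)
  takes_seed <- length(formals(fitter)) >= 2L

  reps <- vector("list", n_boot)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- with_seed(seed + b, sample.int(N, N, replace = TRUE))
    rep_reads <- reads[idx, , drop = FALSE]
    est <- tryCatch(
      fit_estimates(
        if (takes_seed) fitter(rep_reads, seed + b) else fitter(rep_reads)
      ),
      error = function(e) {
        warning("replicate ", b, " failed: ", conditionMessage(e),
          call. = FALSE
        )
        NULL
      }
    )
    if (is.null(est)) {
      failed <- failed + 1L
      next
    }
    reps[[b]] <- tibble::tibble(
      replicate = b, term = names(est), estimate = unname(est)
    )
  }
  replicates <- dplyr::bind_rows(reps)
  if (!nrow(replicates)) stop("every bootstrap replicate failed", call. = FALSE)

  ci <- replicates |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      conf.low = percentile_ci(.data$estimate, ci_level)[["lo"]],
      conf.high = percentile_ci(.data$estimate, ci_level)[["hi"]],
      median = stats::median(.data$estimate),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      estimate = unname(point_est[.data$term]), .before = "conf.low"
    )

  structure(
    list(
      replicates = replicates, ci = ci, point = point,
      n_boot = n_boot, n_failed = failed, ci_level = ci_level, seed = seed
    ),
    class = "fluorfit_boot"
  )
}

#' @export
print.fluorfit_boot <- function(x, ...) {
  cat("<fluorfit_boot> ", x$n_boot - x$n_failed, " replicates",
    if (x$n_failed) paste0(" (", x$n_failed, " failed)") else "",
    ", ", 100 * x$ci_level, "% percentile CIs\n",
    sep = ""
  )
  print(x$ci)
  invisible(x)
}
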