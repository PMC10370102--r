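#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fluorosequencing parameter fit
#'
#' @param x A fit from [fit_baum_welch()] or [fit_dyetrack()].
#' @param ... Unused.
#' @return A tibble with one row per rate parameter: `term`, `estimate`, and
#'   `pinned` (was the parameter held by an identifiability constraint?).
#' @export
tidy.fluorfit_fit <- function(x, ...) {
  v <- rates_as_vector(x$params)
  tibble::tibble(
    term = names(v),
    estimate = unname(v),
    pinned = names(v) %in% names(x$constraints)
  )
}

#' One-row fit summary
#'
#' @param x A fit from [fit_baum_welch()] or [fit_dyetrack()].
#' @param ... Unused.
#' @return A one-row tibble: `method`, `objective` (log-likelihood or RMSE),
#'   `n_iterations`, `converged`, `n_reads`.
#' @export
glance.fluorfit_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    objective = if (!is.null(x$loglik)) x$loglik else x$rmse,
    n_iterations = x$n_iterations,
    converged = x$converged,
    n_reads = x$n_reads
  )
}

#' Tidy a bootstrap summary
#'
#' @param x A [bootstrap_fit()] result.
#' @param ... Unused.
#' @return The CI tibble: `term`, `estimate` (original data), `conf.low`,
#'   `conf.high`, `median` (of replicates).
#' @export
tidy.fluorfit_boot <- function(x, ...) x$ci

#' Box plot of bootstrap replicate estimates
#'
#' One box per rate parameter over the bootstrap replicates, with the
#' original-data estimate marked; optionally overlays known true values
#' (e.g. the generating rates of a simulation).
#'
#' @param object A [bootstrap_fit()] result.
#' @param truth Optional named vector of true rates to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fluorfit_boot <- function(object, truth = NULL, ...) {
  pt <- object$ci
  p <- ggplot2::ggplot(
    object$replicates,
    ggplot2::aes(x = .data$term, y = .data$estimate)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_point(
      data = pt, shape = 17, size = 2.5, colour = "red3"
    ) +
    ggplot2::labs(
      x = NULL, y = "estimated rate",
      title = "Bootstrap distribution of parameter estimates"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (!is.null(truth)) {
    td <- tibble::tibble(term = names(truth), estimate = unname(truth))
    p <- p + ggplot2::geom_point(
      data = td, shape = 95, size = 8, colour = "blue3"
    )
  }
  p
}

#' Plot the last-visible-cycle distribution
#'
#' @param kappa A [kappa_distribution()] tibble.
#' @return A ggplot bar chart of the probabilities by cycle.
#' @export
plot_kappa <- function(kappa) {
  ggplot2::ggplot(kappa, ggplot2::aes(x = .data$cycle, y = .data$kappa)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "last visible cycle", y = "probability",
      title = "Single-fluorophore removal-cycle distribution"
    ) +
    ggplot2::theme_minimal()
}
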