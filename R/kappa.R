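#' Last-visible-cycle distribution for a single-fluorophore peptide
#'
#' For a peptide whose only fluorophore sits at position `r`, the observable
#' data are fully summarized by the cycle at which the fluorophore is removed
#' (assuming no dye loss, detachment, or duds). The probability that this
#' last cycle is `r + i` -- i.e. that Edman chemistry needed `i` failures
#' before completing `r` successful removals, with no block acquired --
#' is
#' \deqn{\kappa_i = (1-b)\,\binom{i+r-1}{i}\,(1-e)^r\,e^i\,(1-c)^{r+i}}
#' where `e` is the Edman failure rate, `b` the initial block rate and `c`
#' the cyclic block rate. Successive terms satisfy
#' \eqn{\kappa_{i+1}/\kappa_i = e(1-c)(i+r)/(i+1)}, so only the product
#' `e(1-c)` is identifiable from the ratios: this is why the cyclic block
#' rate is pinned to zero when fitting single-fluorophore peptides.
#'
#' @param r 1-based position of the single labeled residue (>= 1).
#' @param e,b,c Edman failure, initial block, and cyclic block rates, each in
#'   `[0, 1)`.
#' @param i_max Largest number of Edman failures tabulated.
#' @return A tibble with columns `i`, `cycle` (`r + i`), and `kappa`. The
#'   probabilities need not sum to one: the remaining mass corresponds to
#'   peptides that are blocked (or still incomplete) forever.
#' @examples
#' kappa_distribution(r = 1, e = 0.1, b = 0, c = 0, i_max = 3)
#' @export
kappa_distribution <- function(r, e, b, c, i_max = 25) {
  r <- as.integer(r)
  if (is.na(r) || r < 1L) stop("r must be >= 1", call. = FALSE)
  rates <- c(e, b, c)
  if (any(rates < 0) || any(rates >= 1)) {
    stop("rates must lie in [0, 1)", call. = FALSE)
  }
  i <- 0:i_max
  kappa <- (1 - b) * choose(i + r - 1, i) * (1 - e)^r * e^i * (1 - c)^(r + i)
  tibble::tibble(i = i, cycle = r + i, kappa = kappa)
}
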