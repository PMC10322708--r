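#' Two-tailed z-test p-value
#'
#' Probability of a deviation at least as large as \code{|x - mu|} under a
#' normal reference with known standard deviation, \eqn{p = 2\Phi(-|x-\mu|/\sigma)}.
#' The reference s.d. is treated as known (no small-sample t correction), which
#' is how chromosome-level transcription calls are made throughout the package.
#'
#' @param x Observed value(s).
#' @param mu Reference mean.
#' @param sigma Reference standard deviation; must be positive.
#' @return Numeric vector of two-tailed p-values in (0, 1].
#' @examples
#' zTestTwoTailed(0.5, 0.5, 0.05)          # 1
#' zTestTwoTailed(0.5 + 1.959964 * 0.05, 0.5, 0.05)  # ~0.05
#' @export
zTestTwoTailed <- function(x, mu, sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("'sigma' must be positive and finite")
  }
  2 * stats::pnorm(-abs((x - mu) / sigma))
}

#' Bonferroni correction
#'
#' \code{min(1, p * nTests)}, vectorized over \code{p}.
#'
#' @param p Uncorrected p-value(s).
#' @param nTests Number of tests in the family (>= 1).
#' @return Corrected p-values, capped at 1.
#' @export
bonferroniCorrect <- function(p, nTests) {
  if (length(nTests) != 1L || !is.finite(nTests) || nTests < 1) {
    stop("'nTests' must be a single number >= 1")
  }
  pmin(1, p * nTests)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the probability-mass criterion: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability does
#' not exceed that of the observed table.
#'
#' @param tab 2x2 matrix of non-negative integer counts, or a length-4 vector
#'   (a, b, c, d) filled by row.
#' @return Single p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(matrix(c(5, 5, 5, 5), 2))   # 1
#' fisherExactTwoSided(matrix(c(3, 0, 0, 3), 2))   # 0.1
#' @export
fisherExactTwoSided <- function(tab) {
  if (is.vector(tab) && length(tab) == 4L) {
    tab <- matrix(tab, nrow = 2, byrow = TRUE)
  }
  if (!is.matrix(tab) || any(dim(tab) != 2L)) {
    stop("'tab' must be a 2x2 matrix or length-4 vector")
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers")
  }
  if (sum(tab) == 0) {
    stop("all-zero contingency table")
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Empirical p-value with add-one correction
#'
#' \code{(1 + nAsExtreme) / (1 + nPerm)}; never returns 0, so the attainable
#' floor is \code{1/(1 + nPerm)}.
#'
#' @param nAsExtreme Number of null statistics at least as extreme as observed.
#' @param nPerm Number of permutations.
#' @return Empirical p in (0, 1].
#' @export
empiricalP <- function(nAsExtreme, nPerm) {
  if (any(nPerm < 1) || any(nAsExtreme < 0) || any(nAsExtreme > nPerm)) {
    stop("need 0 <= nAsExtreme <= nPerm, nPerm >= 1")
  }
  (1 + nAsExtreme) / (1 + nPerm)
}
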