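#' Gene-specificity score
#'
#' Upper-tail hypergeometric probability of observing at least \code{ai}
#' of a gene's \code{Ai} associated metabolites inside a signature of
#' \code{S} metabolites drawn from a universe of \code{M} metabolites:
#' \deqn{s_i = \sum_{x = a_i}^{\min(A_i, S)}
#'   \frac{\binom{A_i}{x}\binom{M - A_i}{S - x}}{\binom{M}{S}}}
#' Smaller values indicate a more specific association between the gene
#' and the signature. The tail is evaluated through the hypergeometric
#' survival function, which works in log-space internally, so very
#' small scores do not underflow to zero for realistic model sizes.
#'
#' @param M universe size: total metabolites represented in the GEM
#'   (compartment-collapsed by default; see \code{\link{mapToGenes}}).
#' @param S signature metabolites resolved in that universe.
#' @param Ai metabolites associated with the gene.
#' @param ai associated metabolites that overlap the signature.
#' @return the score \eqn{s_i \in (0, 1]}. Vectorized over
#'   \code{Ai}/\code{ai}.
#' @examples
#' specificityScore(M = 10, S = 3, Ai = 2, ai = 2)  # 8/120
#' specificityScore(M = 50, S = 5, Ai = 4, ai = 0)  # 1: P(X >= 0)
#' @export
specificityScore <- function(M, S, Ai, ai) {
  n <- max(length(Ai), length(ai))
  Ai <- rep_len(Ai, n); ai <- rep_len(ai, n)
  if (any(M < 0 | S < 0 | S > M))
    stop("require 0 <= S <= M", call. = FALSE)
  if (any(Ai < 0 | Ai > M))
    stop("require 0 <= Ai <= M", call. = FALSE)
  if (any(ai < 0 | ai > pmin(Ai, S)))
    stop("require 0 <= ai <= min(Ai, S)", call. = FALSE)
  # P(X >= ai) with X ~ Hypergeom(M, Ai, S): white balls = the gene's
  # metabolites, draws = the signature
  ifelse(ai == 0, 1,
         phyper(ai - 1, m = Ai, n = M - Ai, k = S, lower.tail = FALSE))
}

#' Sigmoid weight of a specificity score
#'
#' Transforms a specificity score into a weight in (0, 1):
#' \deqn{w_i = \frac{1}{1 + e^{a \log_{10} s_i - b}}}
#' The weight decreases monotonically in \eqn{s_i}, approaching 1 as
#' \eqn{s_i \to 0} (highly specific genes) and its minimum at
#' \eqn{s_i = 1} (promiscuous genes). \code{b} sets the inflection
#' point: \eqn{w_i = 0.5} exactly at \eqn{s_i = 10^{b/a}}; \code{a}
#' controls the steepness.
#'
#' @param s specificity score(s) in (0, 1].
#' @param params a list from \code{\link{weightParams}} (fields
#'   \code{a}, \code{b}).
#' @return weights in (0, 1), same length as \code{s}.
#' @examples
#' sigmoidWeight(0.05)                      # 0.5 at the default half-point
#' sigmoidWeight(1, weightParams(a = 2, b = -2.6))
#' @export
sigmoidWeight <- function(s, params = weightParams()) {
  if (any(!is.finite(s)) || any(s <= 0) || any(s > 1))
    stop("specificity scores must lie in (0, 1]", call. = FALSE)
  1 / (1 + exp(params$a * log10(s) - params$b))
}

#' Sigmoid weight parameters
#'
#' The transformation has two free parameters: steepness \code{a > 0}
#' and offset \code{b} on the \eqn{a \cdot \log_{10} s} scale.
#' Alternatively the offset may be given as the half-point score
#' \code{halfPointS} (the score receiving weight 0.5), converted as
#' \code{b = a * log10(halfPointS)}. Defaults anchor the half-point at
#' a score of 0.05, i.e. \code{a = 2}, \code{b = 2 * log10(0.05)}
#' (about -2.602).
#'
#' @param a steepness, dimensionless, > 0.
#' @param b offset; ignored when \code{halfPointS} is given.
#' @param halfPointS optional half-point score in (0, 1].
#' @return list with elements \code{a} and \code{b}.
#' @export
weightParams <- function(a = 2, b = 2 * log10(0.05), halfPointS = NULL) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0)
    stop("'a' must be a positive scalar", call. = FALSE)
  if (!is.null(halfPointS)) {
    if (halfPointS <= 0 || halfPointS > 1)
      stop("'halfPointS' must lie in (0, 1]", call. = FALSE)
    b <- a * log10(halfPointS)
  }
  if (!is.numeric(b) || length(b) != 1L)
    stop("'b' must be a numeric scalar", call. = FALSE)
  list(a = a, b = b)
}
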