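#' Small-sample correction for information content
#'
#' The plug-in entropy of frequencies estimated from `n` sites is biased
#' low, which inflates apparent information. `small_sample_correction()`
#' returns the expected bias `e(n) = log2(k) - E[H_obs]` (in bits, per
#' position) under uniform sampling from a `k`-symbol alphabet, together
#' with the sampling standard deviation of the per-position information
#' estimate used to report "+/- x bits" on totals.
#'
#' For `n <= 12` the expectation is exact, computed from the multinomial
#' sampling distribution (the per-symbol terms of the entropy decompose
#' over Binomial(n, 1/k) marginals, so the exact value is available for
#' any alphabet size without enumerating outcomes). Above `n = 12` the
#' standard asymptotic approximation `(k - 1) / (2 ln2 n)` is used. The
#' standard deviation is computed exactly from the Binomial marginals and
#' trinomial pairwise joints for `n <= 1000`, and from the chi-square
#' limit `sqrt((k - 1)/2) / (n ln2)` above.
#'
#' @param n number of sites (>= 1).
#' @param alphabet_size number of symbols `k` (default 4).
#' @return A list with `e_bits` (expected per-position bias) and
#'   `sd_bits` (per-position sampling s.d. of the information estimate).
#' @examples
#' small_sample_correction(1)$e_bits   # 2: one site carries no information
#' small_sample_correction(1e9)$e_bits # ~0
#' @export
small_sample_correction <- function(n, alphabet_size = 4) {
  stopifnot(length(n) == 1L, is.finite(n) || is.infinite(n))
  if (n < 1) stop("n must be >= 1")
  k <- as.integer(alphabet_size)
  if (k < 2) stop("alphabet_size must be >= 2")
  if (is.infinite(n)) return(list(e_bits = 0, sd_bits = 0))
  n <- as.integer(round(n))
  if (n <= 12L) {
    e <- log2(k) - exact_mean_entropy(n, k)
  } else {
    e <- (k - 1) / (2 * log(2) * n)
  }
  sd <- if (n <= 1000L) sqrt(exact_var_entropy(n, k))
        else sqrt((k - 1) / 2) / (n * log(2))
  list(e_bits = e, sd_bits = sd)
}

# -x log2 x with 0 log 0 = 0, for count x out of n
.hterm <- function(x, n) {
  p <- x / n
  ifelse(x == 0, 0, -p * log2(p))
}

# E[H_obs] for counts ~ Multinomial(n, uniform over k symbols).
# H = sum_b h(n_b); by symmetry E[H] = k E[h(X)], X ~ Binomial(n, 1/k).
exact_mean_entropy <- function(n, k) {
  x <- 0:n
  k * sum(stats::dbinom(x, n, 1 / k) * .hterm(x, n))
}

# Var[H_obs] via the Binomial marginals and trinomial pairwise joints:
# Var = k Var(h(X)) + k(k-1) Cov(h(X), h(Y)), (X, Y) trinomial margins.
exact_var_entropy <- function(n, k) {
  x <- 0:n
  px <- stats::dbinom(x, n, 1 / k)
  h <- .hterm(x, n)
  Eh <- sum(px * h)
  Eh2 <- sum(px * h^2)
  # joint over x + y <= n with cell probs 1/k, 1/k, 1 - 2/k
  Ehh <- 0
  for (xi in 0:n) {
    yj <- 0:(n - xi)
    lp <- lgamma(n + 1) - lgamma(xi + 1) - lgamma(yj + 1) -
      lgamma(n - xi - yj + 1) +
      (xi + yj) * log(1 / k) + (n - xi - yj) * log(1 - 2 / k)
    Ehh <- Ehh + sum(exp(lp) * .hterm(xi, n) * .hterm(yj, n))
  }
  v <- k * (Eh2 - Eh^2) + k * (k - 1) * (Ehh - Eh^2)
  max(v, 0)
}

#' Information content (Rsequence) of a frequency matrix
#'
#' Per-position information is `log2(k) - H(l) - e(n)` where `H(l)` is the
#' Shannon entropy of the position's symbol frequencies (with
#' `0 log 0 = 0`) and `e(n)` the small-sample correction; the total over a
#' position range is the sum of per-position values. With the correction
#' applied the estimate may be negative.
#'
#' `apply_correction = "auto"` (the default) applies the correction when
#' the matrix carries a known site count and skips it for matrices of
#' unknown `n` (energy- or chromatogram-derived), matching standard
#' practice for energy logos.
#'
#' @param fm a [frequency_matrix()].
#' @param from,to position label interval to sum over (defaults: all
#'   positions).
#' @param apply_correction `TRUE`, `FALSE`, or `"auto"`.
#' @return A list: `total` (bits), `per_position` (named numeric, bits),
#'   `sd_total` and `sd_per_position` (sampling s.d., 0 when `n` is
#'   unknown or the correction is off), `correction_bits` (the e(n)
#'   applied, 0 if none).
#' @examples
#' fm <- frequency_matrix(rbind(c(.5, .5, 0, 0)), positions = 1)
#' information_content(fm)$total  # 1 bit
#' @export
information_content <- function(fm, from = NULL, to = NULL,
                                apply_correction = "auto") {
  stopifnot(inherits(fm, "freq_matrix"))
  if (is.null(from)) from <- min(fm$positions)
  if (is.null(to)) to <- max(fm$positions)
  if (from > to) stop("empty position range")
  fm <- subset_positions(fm, from, to)
  corr <- resolve_correction(apply_correction, fm$n)
  k <- length(fm$alphabet)
  H <- apply(fm$probs, 1L, function(p) sum(.hterm_p(p)))
  if (corr) {
    ssc <- small_sample_correction(fm$n, k)
    e <- ssc$e_bits
    sd_pos <- ssc$sd_bits
  } else {
    e <- 0
    sd_pos <- 0
  }
  per <- log2(k) - H - e
  names(per) <- as.character(fm$positions)
  list(total = sum(per),
       per_position = per,
       sd_per_position = rep(sd_pos, length(per)),
       sd_total = sqrt(length(per)) * sd_pos,
       correction_bits = e)
}

.hterm_p <- function(p) ifelse(p == 0, 0, -p * log2(p))

resolve_correction <- function(apply_correction, n) {
  if (identical(apply_correction, "auto")) return(!is.na(n))
  corr <- isTRUE(apply_correction)
  if (corr && is.na(n))
    stop("cannot apply the small-sample correction: site count n is unknown")
  corr
}

#' Letter-height table for sequence-logo rendering
#'
#' Heights are `f(b,l) * Rseq(l)`: each position's letters share the
#' position's information content in proportion to their frequencies, so
#' per-position heights sum to `Rseq(l)` and are non-negative whenever
#' `Rseq(l) >= 0`.
#'
#' @inheritParams information_content
#' @param blank_positions optional position labels to zero out (e.g.
#'   unrandomised positions left blank in a selection logo).
#' @return A data frame with columns `position`, `symbol`, `height`
#'   (bits).
#' @export
logo_table <- function(fm, apply_correction = "auto",
                       blank_positions = NULL) {
  ic <- information_content(fm, apply_correction = apply_correction)
  h <- fm$probs * ic$per_position
  out <- data.frame(position = rep(fm$positions, times = length(fm$alphabet)),
                    symbol = rep(fm$alphabet, each = length(fm$positions)),
                    height = as.vector(h),
                    stringsAsFactors = FALSE)
  if (!is.null(blank_positions))
    out$height[out$position %in% blank_positions] <- 0
  out[order(out$position, match(out$symbol, fm$alphabet)), , drop = FALSE]
}
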