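#' Individual-information (Ri) weight model
#'
#' Converts a frequency matrix into per-position log-ratio weights
#' `Riw(b,l) = log2(k) + log2 f'(b,l) - e(n)` (bits), where `f'` is the
#' pseudocount-regularised frequency and `e(n)` the small-sample
#' correction when applied. A site's individual information is the sum of
#' its per-position weights; sites scoring below 0 bits are predicted to
#' be bound non-specifically.
#'
#' With `pseudocount = 0`, symbols of probability zero receive a finite
#' floor weight of -50 bits rather than -Inf, keeping arithmetic finite
#' while preserving the ordering of sites.
#'
#' @param fm a [frequency_matrix()].
#' @param pseudocount smoothing added to each frequency before taking
#'   logs (default 0: energy-derived frequencies are never zero).
#' @param apply_correction `TRUE`, `FALSE` or `"auto"` (correction on
#'   only when `fm$n` is known).
#' @return An object of class `ri_model` with fields `alphabet`,
#'   `positions`, `weights` (bits), `correction_bits`.
#' @seealso [score_site()], [score_sites()]
#' @export
ri_weights <- function(fm, pseudocount = 0, apply_correction = "auto") {
  stopifnot(inherits(fm, "freq_matrix"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  corr <- resolve_correction(apply_correction, fm$n)
  k <- length(fm$alphabet)
  f <- (fm$probs + pseudocount) / (1 + k * pseudocount)
  e <- if (corr) small_sample_correction(fm$n, k)$e_bits else 0
  w <- log2(k) + log2(f) - e
  w[f == 0] <- -50
  structure(list(alphabet = fm$alphabet,
                 positions = fm$positions,
                 weights = w,
                 correction_bits = e),
            class = "ri_model")
}

#' @export
print.ri_model <- function(x, digits = 3, ...) {
  cat(sprintf("Ri weight model (bits): %d positions, e(n) = %.4g bits\n",
              length(x$positions), x$correction_bits))
  print(round(x$weights, digits))
  invisible(x)
}

#' Score sites by individual information
#'
#' `score_site()` returns the Ri (bits) of a single site under a weight
#' model: the sum over positions of the weight of the site's symbol.
#' `score_sites()` is the vectorised form; `ri_all_sites()` scores the
#' full `k^L` site universe (used for the 64-triplet comparisons).
#'
#' @param rm an [ri_weights()] model.
#' @param site,sites character; each site's length must equal the number
#'   of model positions.
#' @return `score_site`: a single numeric (bits). `score_sites` /
#'   `ri_all_sites`: a named numeric vector of Ri values.
#' @examples
#' fm <- frequency_matrix_from_sites(c("GCA", "GCA"), pseudocount = 0)
#' rm <- ri_weights(fm, apply_correction = FALSE)
#' score_site(rm, "GCA")  # 6 bits: 3 fully conserved DNA positions
#' @export
score_site <- function(rm, site) {
  score_sites(rm, site)[[1L]]
}

#' @rdname score_site
#' @export
score_sites <- function(rm, sites) {
  stopifnot(inherits(rm, "ri_model"))
  m <- split_sites(sites, rm$alphabet)
  if (ncol(m) != length(rm$positions))
    stop("site length ", ncol(m), " does not match model length ",
         length(rm$positions))
  idx <- matrix(match(m, rm$alphabet), nrow = nrow(m))
  ri <- vapply(seq_len(nrow(m)), function(i) {
    sum(rm$weights[cbind(seq_len(ncol(m)), idx[i, ])])
  }, numeric(1))
  names(ri) <- sites
  ri
}

#' @rdname score_site
#' @export
ri_all_sites <- function(rm) {
  stopifnot(inherits(rm, "ri_model"))
  score_sites(rm, enumerate_sites(rm$alphabet, length(rm$positions)))
}

#' Enumerate every sequence of a given length over an alphabet
#'
#' @param alphabet character vector of symbols.
#' @param length_out sequence length.
#' @return Character vector of all `k^L` sequences, first position
#'   varying slowest (lexicographic order).
#' @export
enumerate_sites <- function(alphabet, length_out) {
  g <- expand.grid(rev(replicate(length_out, alphabet, simplify = FALSE)),
                   stringsAsFactors = FALSE)
  apply(g[, rev(seq_len(length_out)), drop = FALSE], 1L, paste0,
        collapse = "")
}
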