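#' Per-position symbol frequency matrix
#'
#' The common currency of sequence logos, individual-information models and
#' motif comparison: for each position of an aligned site set, one
#' probability per symbol of the alphabet. Positions carry integer labels
#' (which may be negative, e.g. the -2..0 core of a binding site) and the
#' matrix records the effective number of sites `n` behind it (`NA` for
#' matrices derived from energies or chromatogram peak heights, where no
#' site count exists).
#'
#' @param probs numeric matrix, rows = positions, columns = alphabet
#'   symbols; each row must be a probability vector (non-negative, summing
#'   to 1 within 1e-9).
#' @param alphabet ordered character vector of unique symbols (>= 2).
#' @param positions strictly increasing integer position labels, one per
#'   row of `probs`.
#' @param n effective sample count behind the frequencies, or `NA` when
#'   unknown.
#' @param semi_quantitative flag carried in provenance for matrices built
#'   from chromatogram peak heights, which are biased by neighbouring
#'   bases and only semi-quantitative.
#' @return An object of class `freq_matrix`.
#' @seealso [frequency_matrix_from_sites()], [boltzmann_frequencies()],
#'   [information_content()]
#' @export
frequency_matrix <- function(probs, alphabet = dna_alphabet(),
                             positions = NULL, n = NA,
                             semi_quantitative = FALSE) {
  probs <- as.matrix(probs)
  if (is.null(positions)) positions <- seq_len(nrow(probs))
  validate_alphabet(alphabet)
  validate_positions(positions, nrow(probs))
  if (ncol(probs) != length(alphabet))
    stop("probs must have one column per alphabet symbol")
  if (any(!is.finite(probs)) || any(probs < 0))
    stop("probabilities must be finite and non-negative")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-9))
    stop("probabilities at position(s) ",
         paste(positions[abs(rs - 1) > 1e-9], collapse = ", "),
         " do not sum to 1")
  dimnames(probs) <- list(as.character(positions), alphabet)
  structure(list(alphabet = as.character(alphabet),
                 positions = as.integer(positions),
                 probs = probs,
                 n = if (is.na(n)) NA_real_ else as.numeric(n),
                 semi_quantitative = isTRUE(semi_quantitative)),
            class = "freq_matrix")
}

validate_alphabet <- function(alphabet) {
  if (length(alphabet) < 2L) stop("alphabet must have at least 2 symbols")
  if (anyDuplicated(alphabet)) stop("alphabet symbols must be unique")
  invisible(alphabet)
}

validate_positions <- function(positions, n_expected) {
  if (length(positions) != n_expected)
    stop("need one position label per matrix row")
  if (any(diff(positions) <= 0))
    stop("position labels must be strictly increasing")
  invisible(positions)
}

#' Build a frequency matrix from an aligned site list
#'
#' Tallies (optionally weighted) symbol counts per position and converts
#' them to probabilities with a Laplace-style pseudocount:
#' `f(b,l) = (pseudocount + count(b,l)) / (|alphabet| * pseudocount + N)`.
#' The default pseudocount `0.5/|alphabet|` regularises structural zeros
#' in count data; pass `pseudocount = 0` for raw frequencies.
#'
#' @param sites character vector of equal-length aligned sequences.
#' @param alphabet symbol alphabet (default DNA); sites must use only
#'   these symbols.
#' @param weights optional positive per-site counts (e.g. colony counts
#'   behind each distinct sequence); default 1 per site.
#' @param pseudocount non-negative smoothing count added per symbol.
#' @param positions optional integer labels for the site positions
#'   (default `1..L`).
#' @return A [frequency_matrix()] with `n = round(sum(weights))`.
#' @examples
#' frequency_matrix_from_sites(c("GCA", "GCA"), pseudocount = 0)
#' @export
frequency_matrix_from_sites <- function(sites, alphabet = dna_alphabet(),
                                        weights = NULL,
                                        pseudocount = 0.5 / length(alphabet),
                                        positions = NULL) {
  m <- split_sites(sites, alphabet)
  if (is.null(weights)) weights <- rep(1, length(sites))
  if (length(weights) != length(sites) || any(weights <= 0))
    stop("weights must be positive, one per site")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  counts <- vapply(seq_len(ncol(m)), function(l) {
    vapply(alphabet, function(b) sum(weights[m[, l] == b]), numeric(1))
  }, numeric(length(alphabet)))
  counts <- t(counts)  # rows = positions, cols = alphabet
  tot <- sum(weights)
  probs <- (counts + pseudocount) / (length(alphabet) * pseudocount + tot)
  frequency_matrix(probs, alphabet = alphabet, positions = positions,
                   n = round(tot))
}

#' @export
as.matrix.freq_matrix <- function(x, ...) x$probs

#' @export
print.freq_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Frequency matrix: %d positions x %d symbols (n = %s%s)\n",
              length(x$positions), length(x$alphabet),
              if (is.na(x$n)) "unknown" else format(x$n),
              if (x$semi_quantitative) ", semi-quantitative" else ""))
  print(round(x$probs, digits))
  invisible(x)
}

# Subset a frequency matrix to a position label interval [from, to].
subset_positions <- function(fm, from, to) {
  keep <- fm$positions >= from & fm$positions <= to
  if (!any(keep)) stop("no positions in range [", from, ", ", to, "]")
  frequency_matrix(fm$probs[keep, , drop = FALSE], alphabet = fm$alphabet,
                   positions = fm$positions[keep], n = fm$n,
                   semi_quantitative = fm$semi_quantitative)
}
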