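#' Per-position binding free-energy penalty matrix
#'
#' Each cell is the binding free-energy penalty ddG(b, l) in kJ/mol of
#' carrying symbol `b` at position `l` instead of the consensus symbol;
#' every position's minimum is anchored at 0 (the consensus base costs
#' nothing). The matrix carries the temperature at which the underlying
#' association constants were measured, used for Boltzmann conversion.
#'
#' @param ddg numeric matrix of penalties in kJ/mol, rows = positions,
#'   columns = alphabet symbols; finite, column minimum 0 per row within
#'   1e-9.
#' @param alphabet ordered character vector of unique symbols.
#' @param positions strictly increasing integer labels.
#' @param temperature_K measurement temperature in Kelvin.
#' @return An object of class `energy_matrix`.
#' @seealso [boltzmann_frequencies()], [energy_matrix_from_single_mutants()]
#' @export
energy_matrix <- function(ddg, alphabet = dna_alphabet(), positions = NULL,
                          temperature_K = 295) {
  ddg <- as.matrix(ddg)
  if (is.null(positions)) positions <- seq_len(nrow(ddg))
  validate_alphabet(alphabet)
  validate_positions(positions, nrow(ddg))
  if (ncol(ddg) != length(alphabet))
    stop("ddg must have one column per alphabet symbol")
  if (any(!is.finite(ddg))) stop("all ddG values must be finite")
  mins <- apply(ddg, 1L, min)
  if (any(abs(mins) > 1e-9))
    stop("every position must have minimum ddG = 0 (consensus anchored); ",
         "offending position(s): ",
         paste(positions[abs(mins) > 1e-9], collapse = ", "))
  dimnames(ddg) <- list(as.character(positions), alphabet)
  structure(list(alphabet = as.character(alphabet),
                 positions = as.integer(positions),
                 ddg = ddg,
                 temperature_K = as.numeric(temperature_K)),
            class = "energy_matrix")
}

#' @export
as.matrix.energy_matrix <- function(x, ...) x$ddg

#' @export
print.energy_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Energy matrix (kJ/mol, consensus = 0): %d positions, T = %g K\n",
              length(x$positions), x$temperature_K))
  print(round(x$ddg, digits))
  invisible(x)
}

#' Convert an energy matrix to frequencies by Boltzmann weighting
#'
#' Per position, `f(b,l) = exp(-beta ddG(b,l)) / sum_b' exp(-beta
#' ddG(b',l))`. The default inverse temperature `beta = 1/RT` (at the
#' matrix's own temperature, in kJ/mol) is the thermodynamic
#' conversion; energy-logo software differs in the scale it applies to
#' matrix values, so `beta` is exposed for calibrating against logos
#' produced under another unit convention. Strong penalties become rare
#' bases, a flat column becomes uniform, and larger `beta` sharpens the
#' logo.
#'
#' @param em an [energy_matrix()].
#' @param beta inverse temperature in (kJ/mol)^-1; `NULL` (default) uses
#'   `1 / thermal_energy(em$temperature_K)`.
#' @return A [frequency_matrix()] with `n = NA` (no site count exists for
#'   energy-derived frequencies, so the small-sample correction stays
#'   off downstream).
#' @examples
#' em <- energy_matrix(rbind(c(0, 1.7, 1.7, 1.7)), positions = 1)
#' boltzmann_frequencies(em)$probs  # ~ (0.4, 0.2, 0.2, 0.2) at 295 K
#' @export
boltzmann_frequencies <- function(em, beta = NULL) {
  stopifnot(inherits(em, "energy_matrix"))
  if (is.null(beta)) beta <- 1 / thermal_energy(em$temperature_K)
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0)
  w <- exp(-beta * em$ddg)
  probs <- w / rowSums(w)
  frequency_matrix(probs, alphabet = em$alphabet, positions = em$positions,
                   n = NA)
}
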