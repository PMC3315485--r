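#' Built-in alphabets and thermodynamic constants
#'
#' `dna_alphabet()` returns the four DNA bases in the conventional order;
#' `aa_alphabet()` the twenty amino acids in alphabetical one-letter order.
#' `thermal_energy()` returns RT in kJ/mol with R = 8.314e-3 kJ/(mol K);
#' the default temperature of 295 K is the temperature at which the
#' association constants this package was written to analyse were measured.
#'
#' @param temperature_K temperature in Kelvin.
#' @return A character vector of symbols, or a single numeric (kJ/mol).
#' @examples
#' thermal_energy()          # 2.4527 kJ/mol at 295 K
#' thermal_energy(298)
#' @name alphabets
NULL

#' @rdname alphabets
#' @export
dna_alphabet <- function() c("A", "C", "G", "T")

#' @rdname alphabets
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.GAS_CONSTANT_KJ <- 8.314e-3  # kJ / (mol K)

#' @rdname alphabets
#' @export
thermal_energy <- function(temperature_K = 295) {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1L,
            is.finite(temperature_K), temperature_K > 0)
  .GAS_CONSTANT_KJ * temperature_K
}

# Run an expression under a fixed seed without disturbing the caller's RNG
# stream. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Split equal-length sequences into a character matrix (rows = sequences),
# validating symbols against an alphabet. Errors name position and symbol.
split_sites <- function(sites, alphabet) {
  if (length(sites) == 0L) stop("no sites given")
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L)
    stop("ragged site lengths: ", paste(unique(lens), collapse = ", "))
  m <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  bad <- which(!(m %in% alphabet))
  if (length(bad)) {
    i <- bad[1L]
    row <- (i - 1L) %% nrow(m) + 1L
    col <- (i - 1L) %/% nrow(m) + 1L
    stop(sprintf("symbol '%s' at position %d of site '%s' is not in the alphabet",
                 m[row, col], col, sites[row]))
  }
  m
}
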