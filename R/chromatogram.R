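#' Pooled-sequencing chromatogram peak-height table
#'
#' Holds the per-position, per-base fluorescence peak heights from a
#' single Sanger read of a pooled site population (the output of a
#' binding-site selection competition), plus a record of which positions
#' were not randomised and therefore carry one fixed base. Relative peak
#' height tracks population base frequency only semi-quantitatively (it
#' is biased by neighbouring bases), and matrices derived from it carry
#' that flag.
#'
#' @param heights numeric matrix of non-negative peak heights, rows =
#'   positions, columns = alphabet symbols.
#' @param positions strictly increasing integer labels.
#' @param fixed named character vector mapping position label to the
#'   forced base at unrandomised positions (e.g. `c("-4" = "T")`).
#' @param alphabet base alphabet.
#' @return An object of class `chromatogram_table`.
#' @export
chromatogram_table <- function(heights, positions = NULL,
                               fixed = NULL, alphabet = dna_alphabet()) {
  heights <- as.matrix(heights)
  if (is.null(positions)) positions <- seq_len(nrow(heights))
  validate_alphabet(alphabet)
  validate_positions(positions, nrow(heights))
  if (ncol(heights) != length(alphabet))
    stop("heights must have one column per alphabet symbol")
  if (any(!is.finite(heights)) || any(heights < 0))
    stop("peak heights must be finite and non-negative")
  fixed_pos <- if (is.null(fixed)) integer(0) else as.integer(names(fixed))
  if (length(fixed_pos) && !all(fixed %in% alphabet))
    stop("fixed bases must be alphabet symbols")
  randomized <- setdiff(positions, fixed_pos)
  zero <- randomized[rowSums(heights)[match(randomized, positions)] <= 0]
  if (length(zero))
    stop("all peak heights are zero at randomized position(s): ",
         paste(zero, collapse = ", "))
  dimnames(heights) <- list(as.character(positions), alphabet)
  structure(list(positions = as.integer(positions),
                 heights = heights,
                 fixed = fixed,
                 alphabet = as.character(alphabet)),
            class = "chromatogram_table")
}

#' @export
print.chromatogram_table <- function(x, digits = 1, ...) {
  cat(sprintf("Chromatogram peak heights: %d positions (%d fixed)\n",
              length(x$positions), length(x$fixed)))
  print(round(x$heights, digits))
  invisible(x)
}

#' Population base frequencies from chromatogram peak heights
#'
#' At each randomised position the relative frequency of a base is its
#' peak height divided by the summed heights of all peaks at that
#' position; fixed (unrandomised) positions become probability-1 columns
#' for their forced base. The result has unknown `n` (a pooled read
#' carries no clone count) and is flagged semi-quantitative.
#'
#' @param ct a [chromatogram_table()].
#' @return A [frequency_matrix()].
#' @examples
#' ct <- chromatogram_table(rbind(c(30, 10, 40, 20)), positions = 1)
#' frequencies_from_peaks(ct)$probs  # 0.3 0.1 0.4 0.2
#' @export
frequencies_from_peaks <- function(ct) {
  stopifnot(inherits(ct, "chromatogram_table"))
  probs <- ct$heights / rowSums(ct$heights)
  if (length(ct$fixed)) {
    for (i in seq_along(ct$fixed)) {
      row <- match(as.integer(names(ct$fixed)[i]), ct$positions)
      probs[row, ] <- 0
      probs[row, ct$fixed[i]] <- 1
    }
  }
  frequency_matrix(probs, alphabet = ct$alphabet, positions = ct$positions,
                   n = NA, semi_quantitative = TRUE)
}

#' Selection logo from a pooled chromatogram
#'
#' Composes [frequencies_from_peaks()], [information_content()] and
#' [logo_table()]; unrandomised positions can be left blank in the
#' letter-height table, as is conventional when rendering selection
#' logos.
#'
#' @param ct a [chromatogram_table()].
#' @param blank_fixed zero the logo heights of fixed positions.
#' @param from,to optional position range for the reported information
#'   total (defaults: all positions).
#' @return A list: `frequencies` (the frequency matrix), `information`
#'   (see [information_content()]), `logo` (letter-height data frame).
#' @export
selection_logo <- function(ct, blank_fixed = TRUE, from = NULL, to = NULL) {
  fm <- frequencies_from_peaks(ct)
  ic <- information_content(fm, from = from, to = to,
                            apply_correction = FALSE)
  blank <- if (blank_fixed && length(ct$fixed))
    as.integer(names(ct$fixed)) else NULL
  list(frequencies = fm,
       information = ic,
       logo = logo_table(fm, apply_correction = FALSE,
                         blank_positions = blank))
}
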