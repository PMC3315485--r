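#' Quadrant overlap of predicted binding between two variants
#'
#' Given each variant's Ri score over the same site universe, sites are
#' assigned to four quadrants by the sign of each score relative to the
#' threshold (ties to specific): bound specifically by both
#' (`shared_specific`), by neither (`neither`), or by only one (`only_a`,
#' `only_b`). Also reports the squared Pearson correlation of the paired
#' scores across all sites.
#'
#' @param ri_a,ri_b named numeric Ri vectors (bits) over identical site
#'   sets.
#' @param threshold specificity threshold in bits (default 0).
#' @return An object of class `quadrant_summary` with the four site
#'   lists, `pearson_r2`, and `threshold`.
#' @export
overlap_quadrants <- function(ri_a, ri_b, threshold = 0) {
  if (is.null(names(ri_a)) || is.null(names(ri_b)))
    stop("ri vectors must be named by site")
  if (!setequal(names(ri_a), names(ri_b)))
    stop("site universes differ")
  ri_b <- ri_b[names(ri_a)]
  a <- ri_a >= threshold
  b <- ri_b >= threshold
  structure(list(shared_specific = names(ri_a)[a & b],
                 neither = names(ri_a)[!a & !b],
                 only_a = names(ri_a)[a & !b],
                 only_b = names(ri_a)[!a & b],
                 pearson_r2 = stats::cor(ri_a, ri_b)^2,
                 threshold = threshold),
            class = "quadrant_summary")
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat(sprintf(paste0("Quadrant overlap (threshold %g bits): ",
                     "shared %d, only A %d, only B %d, neither %d; ",
                     "r2 = %.3f\n"),
              x$threshold, length(x$shared_specific), length(x$only_a),
              length(x$only_b), length(x$neither), x$pearson_r2))
  invisible(x)
}

#' Reference-normalised relative expression
#'
#' The transcriptional output of each (variant, site) pair is the ratio
#' of reporter to factor transcript abundance, normalised so that a
#' chosen reference pair equals 1.
#'
#' @param records data frame with columns `variant_id`, `site`,
#'   `tet_abundance`, `mara_abundance` (both positive).
#' @param reference length-2 character vector `c(variant_id, site)` of
#'   the reference pair (must be present exactly once).
#' @return `records` with an added `relative_expression` column.
#' @export
relative_expression <- function(records, reference) {
  req <- c("variant_id", "site", "tet_abundance", "mara_abundance")
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "))
  if (any(records$tet_abundance <= 0) || any(records$mara_abundance <= 0))
    stop("abundances must be positive")
  ratio <- records$tet_abundance / records$mara_abundance
  iref <- which(records$variant_id == reference[1L] &
                  records$site == reference[2L])
  if (length(iref) != 1L)
    stop("reference (", reference[1L], ", ", reference[2L],
         ") must be present exactly once")
  records$relative_expression <- ratio / ratio[iref]
  records
}

#' Correlation between binding affinity and expression output
#'
#' Squared Pearson correlation between relative association constants
#' and relative expression over matched sites, optionally restricted to
#' a subset of sites. Defined as 0 (with a warning) when either variable
#' has zero variance.
#'
#' @param records data frame with `site` and `relative_expression`
#'   columns (see [relative_expression()]).
#' @param affinities named numeric vector: site -> relative Ka.
#' @param subset optional character vector of sites to use.
#' @return Squared Pearson correlation (r2).
#' @export
expression_affinity_correlation <- function(records, affinities,
                                            subset = NULL) {
  sites <- intersect(records$site, names(affinities))
  if (!is.null(subset)) sites <- intersect(sites, subset)
  if (length(sites) < 3L) stop("need at least 3 paired points")
  x <- affinities[sites]
  y <- records$relative_expression[match(sites, records$site)]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance in affinity or expression; r2 defined as 0")
    return(0)
  }
  stats::cor(x, y)^2
}
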