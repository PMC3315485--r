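#' Binding table: one protein variant's measured association constants
#'
#' Holds, for a single protein variant, the relative association constant
#' `Ka` measured against each site of an enumerated library (e.g. all 64
#' trinucleotide contexts of a binding site), plus the derived binding
#' free energy `dG = -RT ln Ka` at the measurement temperature. Ka values
#' are treated as relative (unitless): every downstream quantity of
#' interest is a ddG, which is invariant to a global rescaling of Ka.
#'
#' @param variant_id short variant label (e.g. "WQR").
#' @param sites character vector of equal-length site sequences, no
#'   duplicates.
#' @param ka positive association constants, one per site.
#' @param temperature_K measurement temperature in Kelvin.
#' @param alphabet site alphabet (default DNA).
#' @return An object of class `binding_table` with a `data` data frame
#'   (`site`, `ka`, `dg`).
#' @export
binding_table <- function(variant_id, sites, ka, temperature_K = 295,
                          alphabet = dna_alphabet()) {
  split_sites(sites, alphabet)  # validates lengths and symbols
  if (anyDuplicated(sites)) stop("duplicate sites in binding table")
  if (length(ka) != length(sites)) stop("need one ka per site")
  dg <- free_energy_from_association(ka, temperature_K)
  structure(list(variant_id = as.character(variant_id),
                 data = data.frame(site = as.character(sites),
                                   ka = as.numeric(ka),
                                   dg = dg,
                                   stringsAsFactors = FALSE),
                 temperature_K = as.numeric(temperature_K),
                 alphabet = as.character(alphabet)),
            class = "binding_table")
}

#' @export
print.binding_table <- function(x, ...) {
  cat(sprintf("Binding table '%s': %d sites, T = %g K\n", x$variant_id,
              nrow(x$data), x$temperature_K))
  cat(sprintf("  strongest site: %s (ka = %g)\n",
              x$data$site[which.max(x$data$ka)], max(x$data$ka)))
  invisible(x)
}

#' Binding free energy from an association constant
#'
#' `dG = -RT ln Ka` with R = 8.314e-3 kJ/(mol K). With relative
#' (unitless) Ka the absolute dG carries an arbitrary offset; differences
#' between sites (ddG) are offset-free.
#'
#' @param ka positive association constant(s).
#' @param temperature_K temperature in Kelvin (default 295).
#' @return Free energy in kJ/mol (vectorised).
#' @examples
#' free_energy_from_association(1)            # 0
#' free_energy_from_association(2) - free_energy_from_association(1)
#' # -RT ln 2 = -1.700 kJ/mol at 295 K
#' @export
free_energy_from_association <- function(ka, temperature_K = 295) {
  if (any(!is.finite(ka)) || any(ka <= 0))
    stop("ka must be finite and > 0")
  -thermal_energy(temperature_K) * log(ka)
}

#' Binding energies relative to the strongest site
#'
#' `ddG(s) = dG(s) - dG(s*)`, where `s*` is the highest-affinity site in
#' the table, so the strongest site has ddG = 0 and weaker binders have
#' ddG > 0. A tie for the strongest site is broken to the
#' lexicographically smallest site with a warning.
#'
#' @param bt a [binding_table()].
#' @return Named numeric vector of ddG (kJ/mol) over the table's sites,
#'   with attribute `consensus` = the strongest site.
#' @export
relative_binding_energies <- function(bt) {
  stopifnot(inherits(bt, "binding_table"))
  kamax <- max(bt$data$ka)
  best <- bt$data$site[bt$data$ka == kamax]
  if (length(best) > 1L) {
    best <- sort(best)[1L]
    warning("tie for strongest site; using lexicographically smallest: ",
            best)
  } else best <- best[1L]
  ddg <- bt$data$dg - bt$data$dg[bt$data$site == best]
  names(ddg) <- bt$data$site
  attr(ddg, "consensus") <- best
  ddg
}

#' Energy matrix from consensus and single-mutant energies
#'
#' Builds the per-position penalty matrix from the measured relative
#' binding energies of the consensus site and all of its single-symbol
#' mutants: cell (b, l) is `ddG(consensus with b at l) - ddG(consensus)`.
#' If some single mutant binds tighter than the nominated consensus, the
#' offending columns are re-anchored so the minimum is 0, with a warning
#' (the nominated consensus is then not the table's strongest site).
#'
#' @param ddg named numeric vector of relative binding energies (kJ/mol)
#'   containing at least the consensus and all its single mutants.
#' @param consensus the consensus site sequence.
#' @param alphabet site alphabet.
#' @param positions optional integer position labels (default `1..L`).
#' @param temperature_K temperature recorded on the output matrix.
#' @return An [energy_matrix()].
#' @export
energy_matrix_from_single_mutants <- function(ddg, consensus,
                                              alphabet = dna_alphabet(),
                                              positions = NULL,
                                              temperature_K = 295) {
  cons <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  L <- length(cons)
  if (!(consensus %in% names(ddg)))
    stop("consensus site '", consensus, "' missing from ddg")
  mat <- matrix(NA_real_, nrow = L, ncol = length(alphabet))
  missing_sites <- character(0)
  for (l in seq_len(L)) {
    for (bi in seq_along(alphabet)) {
      mut <- cons
      mut[l] <- alphabet[bi]
      site <- paste0(mut, collapse = "")
      if (site %in% names(ddg)) {
        mat[l, bi] <- ddg[[site]] - ddg[[consensus]]
      } else missing_sites <- c(missing_sites, site)
    }
  }
  if (length(missing_sites))
    stop("missing single-mutant site(s): ",
         paste(unique(missing_sites), collapse = ", "))
  mins <- apply(mat, 1L, min)
  if (any(mins < -1e-9)) {
    warning("single mutant(s) bind tighter than the nominated consensus '",
            consensus, "'; re-anchoring column(s) ",
            paste(which(mins < -1e-9), collapse = ", "),
            " so the strongest base is 0")
  }
  mat <- sweep(mat, 1L, pmin(mins, 0), "-")
  energy_matrix(mat, alphabet = alphabet, positions = positions,
                temperature_K = temperature_K)
}

#' Predicted binding energy under the independent-additive model
#'
#' Sums the matrix penalty of each site symbol: the prediction that every
#' position contributes independently and additively to binding energy.
#'
#' @param em an [energy_matrix()].
#' @param sites character vector of sites (length = matrix positions).
#' @return Named numeric vector of predicted ddG (kJ/mol).
#' @export
additive_prediction <- function(em, sites) {
  stopifnot(inherits(em, "energy_matrix"))
  m <- split_sites(sites, em$alphabet)
  if (ncol(m) != length(em$positions))
    stop("site length does not match the energy matrix")
  idx <- matrix(match(m, em$alphabet), nrow = nrow(m))
  out <- vapply(seq_len(nrow(m)), function(i) {
    sum(em$ddg[cbind(seq_len(ncol(m)), idx[i, ])])
  }, numeric(1))
  names(out) <- sites
  out
}

#' Additivity diagnostics for measured binding energies
#'
#' Compares measured relative binding energies with the
#' independent-additive prediction from an energy matrix: per-site
#' residuals, plus (optionally) squared Pearson correlations between
#' groups of sites that share all but one position -- e.g. comparing
#' `"GCN"` with `"TAN"` asks whether the energy ranking over the varying
#' base N is preserved between the two dinucleotide contexts, the
#' signature of (non-)independence.
#'
#' @param em an [energy_matrix()].
#' @param ddg_measured named numeric vector of measured ddG over sites.
#' @param groupings optional list of length-2 character vectors of site
#'   patterns with `"N"` at the shared varying position(s), e.g.
#'   `list(c("GCN", "TAN"))`.
#' @return A list: `residuals` (data frame site/measured/predicted/
#'   residual), `group_r2` (data frame pattern_a/pattern_b/r2, or NULL).
#' @export
additivity_report <- function(em, ddg_measured, groupings = NULL) {
  pred <- additive_prediction(em, names(ddg_measured))
  res <- data.frame(site = names(ddg_measured),
                    measured = as.numeric(ddg_measured),
                    predicted = as.numeric(pred),
                    residual = as.numeric(ddg_measured - pred),
                    stringsAsFactors = FALSE)
  gr <- NULL
  if (!is.null(groupings)) {
    gr <- do.call(rbind, lapply(groupings, function(g) {
      if (length(g) != 2L) stop("each grouping must be a pair of patterns")
      va <- expand_pattern(g[1L], em$alphabet)
      vb <- expand_pattern(g[2L], em$alphabet)
      if (length(va) != length(vb))
        stop("group size mismatch: ", g[1L], " vs ", g[2L])
      miss <- setdiff(c(va, vb), names(ddg_measured))
      if (length(miss))
        stop("sites missing from ddg_measured: ",
             paste(miss, collapse = ", "))
      data.frame(pattern_a = g[1L], pattern_b = g[2L],
                 r2 = stats::cor(ddg_measured[va], ddg_measured[vb])^2,
                 stringsAsFactors = FALSE)
    }))
  }
  list(residuals = res, group_r2 = gr)
}

# Expand a pattern like "GCN" into its matching sites, ordered by the
# varying symbol(s) so matched groups align.
expand_pattern <- function(pattern, alphabet) {
  ch <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  opts <- lapply(ch, function(c) if (c == "N") alphabet else c)
  g <- expand.grid(rev(opts), stringsAsFactors = FALSE)
  sites <- apply(g[, rev(seq_along(opts)), drop = FALSE], 1L, paste0,
                 collapse = "")
  as.character(sites)
}

#' Fold difference in affinity between two sites
#'
#' @param bt a [binding_table()].
#' @param site_a,site_b sites present in the table.
#' @return `ka(site_a) / ka(site_b)`.
#' @export
fold_affinity <- function(bt, site_a, site_b) {
  stopifnot(inherits(bt, "binding_table"))
  for (s in c(site_a, site_b))
    if (!(s %in% bt$data$site)) stop("site '", s, "' not in binding table")
  bt$data$ka[bt$data$site == site_a] / bt$data$ka[bt$data$site == site_b]
}
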