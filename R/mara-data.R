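#' Published MarA helix-3 variant tables
#'
#' Two small reference tables for the *E. coli* MarA DNA-binding-domain
#' study the package was built around, shipped as plain TSV under
#' `inst/extdata`.
#'
#' `mara_variant_counts()` lists the functional helix-3 variants
#' (residues 42-45-46) recovered by survival selection against each of
#' three target binding sites, with colony counts at two tetracycline
#' concentrations, the number of codon sets observed, and flags for the
#' fittest variant per site and for the variants characterised further.
#' The counts are transcribed as published (including the GAC/RQR row,
#' whose printed total differs from its printed per-concentration
#' counts by one).
#'
#' `mara_specific_binding()` gives, per characterised variant, the
#' published non-specific binding energy dGns (kJ/mol), the information
#' content of the affinity-derived energy logo and of the in vivo
#' selection logo over the three core positions (bits), their ratio,
#' and whether the dGns estimate was considered reliable (the SAR
#' boundary fit was not).
#'
#' @return A data frame (see above).
#' @examples
#' head(mara_variant_counts())
#' mara_specific_binding()
#' @name mara_data
NULL

#' @rdname mara_data
#' @export
mara_variant_counts <- function() {
  read_tsv_checked(system.file("extdata", "mara_variant_counts.tsv",
                               package = "bindspec", mustWork = TRUE))
}

#' @rdname mara_data
#' @export
mara_specific_binding <- function() {
  read_tsv_checked(system.file("extdata", "mara_specific_binding.tsv",
                               package = "bindspec", mustWork = TRUE))
}
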