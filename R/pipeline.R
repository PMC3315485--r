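#' Full single-variant analysis of a binding table
#'
#' The per-variant backbone of the pipeline: relative binding energies,
#' the single-mutant energy matrix (anchored at the table's strongest
#' site), its Boltzmann-converted frequency matrix and information
#' content over the core positions, the Ri weight model, site scores
#' over the full library, and the specific/non-specific boundary fit.
#'
#' @param bt a [binding_table()].
#' @param positions integer labels for the site positions (default: the
#'   binding-site core frame `-(L-1)..0`).
#' @param threshold Ri partition threshold in bits.
#' @param method dGns derivation method, see [nonspecific_energy()].
#' @param pseudocount pseudocount for [ri_weights()] (default 0:
#'   energy-derived frequencies have no zeros).
#' @return A list of class `variant_analysis`: `variant_id`, `ddg`,
#'   `consensus`, `energy_matrix`, `frequencies`, `information`,
#'   `ri_model`, `ri`, `boundary`.
#' @export
analyze_binding <- function(bt, positions = NULL, threshold = 0,
                            method = "intersection", pseudocount = 0) {
  stopifnot(inherits(bt, "binding_table"))
  L <- nchar(bt$data$site[1L])
  if (is.null(positions)) positions <- seq(-(L - 1L), 0L)
  ddg <- relative_binding_energies(bt)
  consensus <- attr(ddg, "consensus")
  em <- energy_matrix_from_single_mutants(ddg, consensus,
                                          alphabet = bt$alphabet,
                                          positions = positions,
                                          temperature_K = bt$temperature_K)
  fm <- boltzmann_frequencies(em)
  ic <- information_content(fm, apply_correction = FALSE)
  rm <- ri_weights(fm, pseudocount = pseudocount,
                   apply_correction = FALSE)
  ri <- score_sites(rm, names(ddg))
  boundary <- specificity_boundary(ri, ddg, threshold = threshold,
                                   method = method)
  structure(list(variant_id = bt$variant_id, ddg = ddg,
                 consensus = consensus, energy_matrix = em,
                 frequencies = fm, information = ic, ri_model = rm,
                 ri = ri, boundary = boundary),
            class = "variant_analysis")
}

#' @export
print.variant_analysis <- function(x, ...) {
  cat(sprintf(paste0("Variant %s: consensus %s, Rseq = %.2f bits, ",
                     "dGns = %.2f kJ/mol (%s)%s\n"),
              x$variant_id, x$consensus, x$information$total,
              x$boundary$dg_ns, x$boundary$method,
              if (!x$boundary$reliable) " [unreliable]" else ""))
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects every input and convention switch for [run_pipeline()] into
#' one object that is echoed into the run manifest, so a run is fully
#' described by its config and seed.
#'
#' @param binding_tables named list of [binding_table()] objects, or a
#'   directory path for [read_binding_bundle()].
#' @param peak_tables optional named list of [chromatogram_table()]
#'   objects (per variant), or `NULL`.
#' @param reference_variant variant against which quadrant overlaps are
#'   computed (default: the variant with the lowest energy-logo
#'   information content, the most permissive binder).
#' @param core_from,core_to position range over which information
#'   contents and in vivo models are computed (default: the full core).
#' @param temperature_K measurement temperature for tables read from
#'   disk.
#' @param threshold,method,pseudocount,kld_pseudocount convention
#'   switches passed through to the stages.
#' @param out_dir optional output directory for TSV reports (created if
#'   needed); `NULL` = in-memory results only.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(binding_tables, peak_tables = NULL,
                            reference_variant = NULL,
                            core_from = NULL, core_to = NULL,
                            temperature_K = 295, threshold = 0,
                            method = "intersection", pseudocount = 0,
                            kld_pseudocount = 1e-6, out_dir = NULL,
                            seed = 1L) {
  if (is.character(binding_tables))
    binding_tables <- read_binding_bundle(binding_tables,
                                          temperature_K = temperature_K)
  structure(list(binding_tables = binding_tables,
                 peak_tables = peak_tables,
                 reference_variant = reference_variant,
                 core_from = core_from, core_to = core_to,
                 temperature_K = temperature_K, threshold = threshold,
                 method = method, pseudocount = pseudocount,
                 kld_pseudocount = kld_pseudocount, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full cross-variant analysis pipeline
#'
#' For every variant: energies, energy matrix, Boltzmann logo,
#' information content, Ri model and boundary fit ([analyze_binding()]).
#' Across variants: the pairwise KLD table of the energy-derived models
#' (plus in vivo chromatogram models when peak tables are supplied, and
#' the in-vitro-vs-in-vivo divergence per variant), quadrant overlap of
#' every variant against the reference, and a summary table mirroring
#' the headline per-variant statistics. Deterministic given the config.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result`: `variants` (list of
#'   [analyze_binding()] results), `summary` (data frame), `kld`
#'   (pairwise matrix), `kld_invivo_vs_mitomi` (named vector or NULL),
#'   `selection` (list of [selection_logo()] results or NULL),
#'   `overlaps` (list of [overlap_quadrants()] summaries), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  variants <- lapply(config$binding_tables, analyze_binding,
                     threshold = config$threshold, method = config$method,
                     pseudocount = config$pseudocount)
  core_ic <- function(fm) {
    information_content(fm, from = config$core_from, to = config$core_to,
                        apply_correction = FALSE)$total
  }
  fms <- lapply(variants, `[[`, "frequencies")
  selection <- invivo_fms <- kld_iv <- NULL
  if (!is.null(config$peak_tables)) {
    selection <- lapply(config$peak_tables, selection_logo,
                        from = config$core_from, to = config$core_to)
    invivo_fms <- lapply(selection, `[[`, "frequencies")
    shared <- intersect(names(fms), names(invivo_fms))
    kld_iv <- vapply(shared, function(v) {
      core <- if (!is.null(config$core_from))
        subset_positions(invivo_fms[[v]], config$core_from,
                         config$core_to)
      else invivo_fms[[v]]
      matrix_kld(fms[[v]], core,
                 pseudocount = config$kld_pseudocount)$value
    }, numeric(1))
  }
  kld <- pairwise_kld(fms, pseudocount = config$kld_pseudocount)
  ref <- config$reference_variant
  if (is.null(ref))
    ref <- names(variants)[which.min(vapply(fms, core_ic, numeric(1)))]
  if (!(ref %in% names(variants)))
    stop("reference variant '", ref, "' has no binding table")
  overlaps <- lapply(variants[setdiff(names(variants), ref)], function(v) {
    overlap_quadrants(variants[[ref]]$ri, v$ri,
                      threshold = config$threshold)
  })
  summary <- data.frame(
    variant = names(variants),
    consensus = vapply(variants, `[[`, character(1), "consensus"),
    dg_ns = vapply(variants, function(v) v$boundary$dg_ns, numeric(1)),
    rseq_energy = vapply(fms, core_ic, numeric(1)),
    rseq_invivo = if (is.null(invivo_fms)) NA_real_ else
      vapply(names(variants), function(v) {
        if (v %in% names(invivo_fms)) core_ic(invivo_fms[[v]])
        else NA_real_
      }, numeric(1)),
    reliable = vapply(variants, function(v) v$boundary$reliable,
                      logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  summary$rseq_over_dgns <- summary$rseq_invivo / summary$dg_ns
  manifest <- list(created = format(t0, usetz = TRUE),
                   elapsed_s = as.numeric(Sys.time() - t0, units = "secs"),
                   seed = config$seed,
                   reference_variant = ref,
                   conventions = config[c("threshold", "method",
                                          "pseudocount",
                                          "kld_pseudocount",
                                          "temperature_K")],
                   variants = names(variants))
  res <- structure(list(variants = variants, summary = summary,
                        kld = kld, kld_invivo_vs_mitomi = kld_iv,
                        selection = selection, overlaps = overlaps,
                        reference_variant = ref, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(res, config$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d variant(s), reference %s\n",
              length(x$variants), x$reference_variant))
  print(x$summary, digits = 3)
  invisible(x)
}

# Write per-variant and cross-variant TSV reports under out_dir.
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(variant = rownames(res$kld), res$kld,
                                check.names = FALSE),
                     file.path(out_dir, "kld_pairwise.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (v in names(res$variants)) {
    a <- res$variants[[v]]
    write_matrix_tsv(a$energy_matrix,
                     file.path(out_dir, paste0(v, "_energy.tsv")))
    write_matrix_tsv(a$frequencies,
                     file.path(out_dir, paste0(v, "_frequencies.tsv")))
    utils::write.table(boundary_report(a$boundary),
                       file.path(out_dir, paste0(v, "_boundary.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(c(sprintf("created\t%s", res$manifest$created),
               sprintf("seed\t%d", res$manifest$seed),
               sprintf("reference_variant\t%s",
                       res$manifest$reference_variant),
               sprintf("threshold\t%g", res$manifest$conventions$threshold),
               sprintf("method\t%s", res$manifest$conventions$method),
               sprintf("kld_pseudocount\t%g",
                       res$manifest$conventions$kld_pseudocount),
               sprintf("temperature_K\t%g",
                       res$manifest$conventions$temperature_K),
               sprintf("variants\t%s",
                       paste(res$manifest$variants, collapse = ","))),
             file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}
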