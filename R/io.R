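#' Read and write matrix, site, binding and peak tables
#'
#' All tabular interchange uses plain tab-separated text. Matrix files
#' have a header row naming the alphabet and a first column `pos` of
#' integer position labels. Binding tables have columns `site` and `ka`.
#' Peak tables have a `pos` column plus one column per base. Site lists
#' are either one sequence per line or FASTA (detected by a leading
#' `>`; FASTA parsing uses Biostrings when available).
#'
#' @param path file path.
#' @param x object to write.
#' @param n,temperature_K,variant_id,alphabet,fixed metadata not stored
#'   in the files themselves, supplied at read time.
#' @name bindspec_io
NULL

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname bindspec_io
#' @export
read_frequency_matrix <- function(path, n = NA) {
  d <- read_tsv_checked(path)
  if (names(d)[1L] != "pos") stop("first column must be 'pos': ", path)
  frequency_matrix(as.matrix(d[, -1L, drop = FALSE]),
                   alphabet = names(d)[-1L], positions = d$pos, n = n)
}

#' @rdname bindspec_io
#' @export
read_energy_matrix <- function(path, temperature_K = 295) {
  d <- read_tsv_checked(path)
  if (names(d)[1L] != "pos") stop("first column must be 'pos': ", path)
  energy_matrix(as.matrix(d[, -1L, drop = FALSE]),
                alphabet = names(d)[-1L], positions = d$pos,
                temperature_K = temperature_K)
}

#' @rdname bindspec_io
#' @export
write_matrix_tsv <- function(x, path) {
  vals <- if (inherits(x, "freq_matrix")) x$probs
          else if (inherits(x, "energy_matrix")) x$ddg
          else stop("x must be a freq_matrix or energy_matrix")
  d <- data.frame(pos = rownames(vals), vals, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname bindspec_io
#' @export
read_sites <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no sequences in ", path)
  if (startsWith(lines[1L], ">")) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTA site lists requires the Biostrings package")
    seqs <- Biostrings::readBStringSet(path)
    return(as.character(seqs))
  }
  toupper(trimws(lines))
}

#' @rdname bindspec_io
#' @export
write_sites <- function(x, path) {
  writeLines(x, path)
  invisible(path)
}

#' @rdname bindspec_io
#' @export
read_binding_table <- function(path, variant_id = NULL,
                               temperature_K = 295,
                               alphabet = dna_alphabet()) {
  d <- read_tsv_checked(path)
  if (!all(c("site", "ka") %in% names(d)))
    stop("binding table needs columns 'site' and 'ka': ", path)
  bad <- which(!is.finite(d$ka) | d$ka <= 0)
  if (length(bad))
    stop("invalid ka in ", basename(path), " at row(s) ",
         paste(bad, collapse = ", "), " (site ",
         paste(d$site[bad], collapse = ", "), ")")
  if (is.null(variant_id))
    variant_id <- sub("\\.[^.]*$", "", basename(path))
  bt <- binding_table(variant_id, d$site, d$ka,
                      temperature_K = temperature_K, alphabet = alphabet)
  if ("dg" %in% names(d)) {
    drift <- max(abs(d$dg - bt$data$dg))
    if (drift > 1e-6)
      warning(sprintf(paste0("dg column in %s drifts from -RT ln ka by up ",
                             "to %.3g kJ/mol; recomputed values are used"),
                      basename(path), drift))
  }
  bt
}

#' @rdname bindspec_io
#' @export
write_binding_table <- function(x, path) {
  stopifnot(inherits(x, "binding_table"))
  utils::write.table(x$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a directory of per-variant binding tables
#'
#' A plain-text mirror of a multi-sheet affinity workbook: one
#' `<variant>.tsv` per protein variant (columns `site`, `ka`, optional
#' `dg` cross-checked against `-RT ln ka` with a warning on drift).
#'
#' @param dir directory containing `*.tsv` binding tables.
#' @inheritParams bindspec_io
#' @return Named list of [binding_table()] objects.
#' @export
read_binding_bundle <- function(dir, temperature_K = 295,
                                alphabet = dna_alphabet()) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stop("no .tsv binding tables in ", dir)
  tabs <- lapply(files, read_binding_table,
                 temperature_K = temperature_K, alphabet = alphabet)
  stats::setNames(tabs, vapply(tabs, `[[`, character(1), "variant_id"))
}

#' @rdname bindspec_io
#' @export
read_peak_table <- function(path, fixed = NULL,
                            alphabet = dna_alphabet()) {
  d <- read_tsv_checked(path)
  if (names(d)[1L] != "pos") stop("first column must be 'pos': ", path)
  if (!all(alphabet %in% names(d)))
    stop("peak table must have one column per base: ", path)
  chromatogram_table(as.matrix(d[, alphabet, drop = FALSE]),
                     positions = d$pos, fixed = fixed,
                     alphabet = alphabet)
}

#' @rdname bindspec_io
#' @export
write_peak_table <- function(x, path) {
  stopifnot(inherits(x, "chromatogram_table"))
  d <- data.frame(pos = rownames(x$heights), x$heights,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
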