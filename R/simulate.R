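#' Ground-truth specification for synthetic binding data
#'
#' Bundles everything the generators need: an additive truth energy
#' matrix, the height of the non-specific binding floor above the
#' consensus (`dg_ns_true`; `Inf` disables the floor), the standard
#' deviation of multiplicative log-normal measurement noise on Ka,
#' optional pairwise coupling terms that deliberately violate
#' additivity, and the seed recorded into every derived output.
#'
#' Defaults emulate a moderately specific three-position binder of the
#' kind the analysis was designed for: mean single-mutant penalty
#' 2.5 kJ/mol, floor 4 kJ/mol above the consensus, 10% log-normal Ka
#' noise.
#'
#' @param truth_matrix an [energy_matrix()] (default: a seeded
#'   [random_energy_matrix()] over positions -2..0).
#' @param dg_ns_true non-specific floor in kJ/mol above the consensus
#'   (>= 0; `Inf` = no floor).
#' @param noise_sigma sdlog of multiplicative log-normal Ka noise (>= 0).
#' @param coupling optional data frame of pairwise energy terms with
#'   columns `pos_i`, `pos_j` (position labels), `base_i`, `base_j`,
#'   `energy` (kJ/mol added when both bases are present).
#' @param seed integer seed recorded and used by the generators.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(truth_matrix = NULL, dg_ns_true = 4,
                            noise_sigma = 0.1, coupling = NULL,
                            seed = 1L) {
  if (is.null(truth_matrix))
    truth_matrix <- random_energy_matrix(seed = seed)
  stopifnot(inherits(truth_matrix, "energy_matrix"),
            dg_ns_true >= 0, noise_sigma >= 0)
  if (!is.null(coupling)) {
    req <- c("pos_i", "pos_j", "base_i", "base_j", "energy")
    if (!all(req %in% names(coupling)))
      stop("coupling needs columns ", paste(req, collapse = ", "))
  }
  structure(list(truth_matrix = truth_matrix,
                 dg_ns_true = dg_ns_true,
                 noise_sigma = noise_sigma,
                 coupling = coupling,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("Synthetic truth: %d positions, floor %g kJ/mol, ",
                     "Ka noise sdlog %g, seed %d%s\n"),
              length(x$truth_matrix$positions), x$dg_ns_true,
              x$noise_sigma, x$seed,
              if (is.null(x$coupling)) "" else
                sprintf(", %d coupling term(s)", nrow(x$coupling))))
  invisible(x)
}

#' Random consensus-anchored energy matrix
#'
#' Draws non-consensus penalties from a Gamma distribution with the
#' given mean and standard deviation (`spread = 0` gives all penalties
#' equal to `mean_penalty`); the consensus base at each position is
#' chosen uniformly and anchored at 0. Deterministic per seed.
#'
#' @param n_positions number of positions (>= 1).
#' @param mean_penalty mean non-consensus penalty, kJ/mol.
#' @param spread s.d. of the penalty distribution, kJ/mol.
#' @param seed integer seed (`NULL` = use the current RNG stream).
#' @param alphabet symbol alphabet.
#' @param positions integer labels (default `-(n_positions-1)..0`, the
#'   binding-site core frame).
#' @param temperature_K temperature recorded on the matrix.
#' @return An [energy_matrix()].
#' @export
random_energy_matrix <- function(n_positions = 3, mean_penalty = 2.5,
                                 spread = 1.0, seed = NULL,
                                 alphabet = dna_alphabet(),
                                 positions = NULL, temperature_K = 295) {
  stopifnot(n_positions >= 1, mean_penalty > 0, spread >= 0)
  if (is.null(positions)) positions <- seq(-(n_positions - 1L), 0L)
  k <- length(alphabet)
  with_seed(seed, {
    mat <- matrix(0, n_positions, k)
    for (l in seq_len(n_positions)) {
      cons <- sample.int(k, 1L)
      pen <- if (spread == 0) rep(mean_penalty, k - 1L)
             else stats::rgamma(k - 1L,
                                shape = (mean_penalty / spread)^2,
                                rate = mean_penalty / spread^2)
      mat[l, -cons] <- pen
    }
    energy_matrix(mat, alphabet = alphabet, positions = positions,
                  temperature_K = temperature_K)
  })
}

#' True additive (+ coupling) site energies under a synthetic truth
#'
#' @param truth a [synthetic_truth()].
#' @return Named numeric vector of true ddG (kJ/mol) over the full site
#'   universe of the truth matrix.
#' @export
true_site_energies <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  em <- truth$truth_matrix
  sites <- enumerate_sites(em$alphabet, length(em$positions))
  ddg <- additive_prediction(em, sites)
  if (!is.null(truth$coupling)) {
    m <- split_sites(sites, em$alphabet)
    for (r in seq_len(nrow(truth$coupling))) {
      ci <- match(truth$coupling$pos_i[r], em$positions)
      cj <- match(truth$coupling$pos_j[r], em$positions)
      if (is.na(ci) || is.na(cj)) stop("coupling position not in matrix")
      hit <- m[, ci] == truth$coupling$base_i[r] &
        m[, cj] == truth$coupling$base_j[r]
      ddg[hit] <- ddg[hit] + truth$coupling$energy[r]
    }
  }
  ddg
}

#' Simulate affinity measurements over the full site library
#'
#' Generates one variant's association constants for every site of the
#' truth matrix's universe under a two-state model: the specific Ka
#' contribution `exp(-ddG_true/RT)` plus a shared non-specific floor
#' `exp(-dg_ns_true/RT)`, times multiplicative log-normal noise of sdlog
#' `noise_sigma`. With no noise and no floor, the single-mutant energy
#' matrix reconstructed from the output equals the truth exactly; with a
#' floor, measured energies of weak sites saturate near `dg_ns_true`
#' (within RT ln 2), which is precisely the plateau the boundary
#' regression is designed to find.
#'
#' @param truth a [synthetic_truth()].
#' @param variant_id label for the output table.
#' @param seed seed for the noise draw (default: the truth's seed).
#' @return A [binding_table()] over all sites.
#' @export
simulate_mitomi <- function(truth, variant_id = "SYN", seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  em <- truth$truth_matrix
  rt <- thermal_energy(em$temperature_K)
  ddg <- true_site_energies(truth)
  ka <- exp(-ddg / rt) +
    if (is.infinite(truth$dg_ns_true)) 0 else exp(-truth$dg_ns_true / rt)
  if (truth$noise_sigma > 0)
    ka <- with_seed(seed,
                    ka * stats::rlnorm(length(ka), 0, truth$noise_sigma))
  binding_table(variant_id, names(ddg), as.numeric(ka),
                temperature_K = em$temperature_K, alphabet = em$alphabet)
}

#' Simulate a binding-site selection and its pooled chromatogram
#'
#' Emulates a survival selection at a fixed stringency: sites whose true
#' energy penalty is at most `stringency_ddg` survive, and surviving
#' clones appear in the competed population in proportion to their
#' Boltzmann weight `exp(-ddG_true/RT)`. The pooled read's peak heights
#' are the population's per-position base frequencies times a scale
#' factor, optionally biased by the preceding base and perturbed by
#' truncated Gaussian noise. Unrandomised flanking positions are added
#' around the core: two fixed bases (T, G) immediately 5' of it and two
#' neutral (uniform) randomised positions 3' of it, giving the
#' seven-position frame of the selection construct.
#'
#' @param truth a [synthetic_truth()].
#' @param stringency_ddg survival threshold in kJ/mol (>= 0; `Inf` keeps
#'   every site).
#' @param library_size clones drawn (multinomially) for the returned
#'   population counts; the peak heights use the exact Boltzmann
#'   frequencies, not the sampled counts.
#' @param seed seed for the count draw and peak noise.
#' @param neighbor_bias optional k x k matrix of multiplicative bias
#'   factors indexed `[preceding base, base]`; heights are multiplied by
#'   `1 + neighbor_bias[prev, b]` where `prev` is the population-majority
#'   base at the preceding position. `NULL` = unbiased.
#' @param peak_noise s.d. of additive Gaussian peak noise as a fraction
#'   of `peak_scale`; negative heights are truncated to 0.
#' @param peak_scale full-column peak height in fluorescence units.
#' @return A list: `population` (data frame site/ddg_true/freq/count),
#'   `chromatogram` (a [chromatogram_table()]), `survivors`,
#'   `stringency_ddg`, `seed`.
#' @export
simulate_selection <- function(truth, stringency_ddg, library_size = 10000,
                               seed = truth$seed, neighbor_bias = NULL,
                               peak_noise = 0, peak_scale = 1000) {
  stopifnot(inherits(truth, "synthetic_truth"), stringency_ddg >= 0)
  em <- truth$truth_matrix
  rt <- thermal_energy(em$temperature_K)
  k <- length(em$alphabet)
  ddg <- true_site_energies(truth)
  surv <- names(ddg)[ddg <= stringency_ddg]
  if (length(surv) == 0L)
    stop("no site survives at stringency ", stringency_ddg,
         " kJ/mol; loosen the stringency (the weakest single mutant ",
         "costs ", signif(min(ddg[ddg > 0]), 3), " kJ/mol)")
  w <- exp(-ddg[surv] / rt)
  freq <- w / sum(w)
  core_pos <- em$positions
  fixed_pos <- min(core_pos) - c(2L, 1L)
  flank_pos <- max(core_pos) + c(1L, 2L)
  fixed <- stats::setNames(c("T", "G")[seq_along(fixed_pos)],
                           as.character(fixed_pos))
  positions <- c(fixed_pos, core_pos, flank_pos)
  heights <- matrix(0, length(positions), k,
                    dimnames = list(as.character(positions), em$alphabet))
  m <- split_sites(surv, em$alphabet)
  for (li in seq_along(core_pos)) {
    for (bi in seq_len(k)) {
      heights[as.character(core_pos[li]), bi] <-
        sum(freq[m[, li] == em$alphabet[bi]]) * peak_scale
    }
  }
  heights[as.character(flank_pos), ] <- peak_scale / k
  for (p in names(fixed)) heights[p, fixed[[p]]] <- peak_scale
  if (!is.null(neighbor_bias)) {
    for (pi in seq_along(positions)[-1L]) {
      prev <- em$alphabet[which.max(heights[pi - 1L, ])]
      heights[pi, ] <- heights[pi, ] *
        (1 + neighbor_bias[prev, em$alphabet])
    }
  }
  out <- with_seed(seed, {
    counts <- as.integer(stats::rmultinom(1L, library_size, freq))
    if (peak_noise > 0) {
      rand_rows <- !(as.character(positions) %in% names(fixed))
      noise <- matrix(stats::rnorm(sum(rand_rows) * k, 0,
                                   peak_noise * peak_scale),
                      ncol = k)
      heights[rand_rows, ] <- pmax(heights[rand_rows, ] + noise, 0)
    }
    list(counts = counts, heights = heights)
  })
  list(population = data.frame(site = surv,
                               ddg_true = as.numeric(ddg[surv]),
                               freq = as.numeric(freq),
                               count = out$counts,
                               stringsAsFactors = FALSE),
       chromatogram = chromatogram_table(out$heights, positions,
                                         fixed = fixed,
                                         alphabet = em$alphabet),
       survivors = surv,
       stringency_ddg = stringency_ddg,
       seed = seed)
}

#' Truth-recovery report for a synthetic pipeline run
#'
#' Compares pipeline estimates against the generating truth: cell-wise
#' energy-matrix error, non-specific floor error, and information
#' content error, each judged against a declared tolerance.
#'
#' @param truth a [synthetic_truth()].
#' @param estimates list with any of `energy_matrix` (an
#'   [energy_matrix()]), `dg_ns` (numeric), `info_bits` (numeric; compared
#'   with the information content of the Boltzmann-converted truth).
#' @param tolerances list of tolerances: `matrix` (max abs cell error,
#'   kJ/mol), `dg_ns` (kJ/mol; default RT ln 2, the two-state plateau
#'   discretisation allowance), `info` (bits).
#' @return Data frame (parameter, truth, estimate, error, tol, pass).
#' @export
recovery_report <- function(truth, estimates,
                            tolerances = list(matrix = 1e-6,
                                              dg_ns = NULL,
                                              info = 1e-6)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  em <- truth$truth_matrix
  rt <- thermal_energy(em$temperature_K)
  if (is.null(tolerances$dg_ns)) tolerances$dg_ns <- rt * log(2)
  rows <- list()
  if (!is.null(estimates$energy_matrix)) {
    est <- estimates$energy_matrix
    if (!identical(dim(est$ddg), dim(em$ddg)))
      stop("energy matrix shape mismatch")
    err <- max(abs(est$ddg - em$ddg))
    rows$matrix <- data.frame(parameter = "energy_matrix_max_abs",
                              truth = 0, estimate = err, error = err,
                              tol = tolerances$matrix,
                              pass = err <= tolerances$matrix)
  }
  if (!is.null(estimates$dg_ns)) {
    err <- abs(estimates$dg_ns - truth$dg_ns_true)
    rows$dg_ns <- data.frame(parameter = "dg_ns", truth = truth$dg_ns_true,
                             estimate = estimates$dg_ns, error = err,
                             tol = tolerances$dg_ns,
                             pass = err <= tolerances$dg_ns)
  }
  if (!is.null(estimates$info_bits)) {
    tr <- information_content(boltzmann_frequencies(em),
                              apply_correction = FALSE)$total
    err <- abs(estimates$info_bits - tr)
    rows$info <- data.frame(parameter = "info_bits", truth = tr,
                            estimate = estimates$info_bits, error = err,
                            tol = tolerances$info,
                            pass = err <= tolerances$info)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
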