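# Shared fixture builders: everything is generated in code at test time.

RT295 <- bindspec::thermal_energy(295)

# A random valid frequency matrix (rows sum to 1), seeded.
random_freq_matrix <- function(n_pos = 3, alphabet = dna_alphabet(),
                               seed = NULL, n = NA) {
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(stats::rgamma(n_pos * length(alphabet), shape = 1),
              nrow = n_pos)
  frequency_matrix(p / rowSums(p), alphabet = alphabet, n = n)
}

# Fully conserved frequency matrix for a given site.
conserved_freq_matrix <- function(site, alphabet = dna_alphabet(),
                                  n = NA) {
  frequency_matrix_from_sites(rep(site, 2), alphabet = alphabet,
                              pseudocount = 0)
}

# Deterministic little truth: fixed matrix, consensus GCA over -2..0.
toy_truth <- function(dg_ns_true = Inf, noise_sigma = 0, seed = 42,
                      coupling = NULL) {
  em <- energy_matrix(rbind(c(2.0, 3.5, 0.0, 1.2),
                            c(2.8, 0.0, 1.5, 3.0),
                            c(0.0, 2.2, 3.8, 1.0)),
                      positions = -2:0)
  synthetic_truth(truth_matrix = em, dg_ns_true = dg_ns_true,
                  noise_sigma = noise_sigma, coupling = coupling,
                  seed = seed)
}

expect_freqmat_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$probs, b$probs, tolerance = tol)
  expect_identical(a$positions, b$positions)
  expect_identical(a$alphabet, b$alphabet)
}
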