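test_that("generators are deterministic per seed", {
  em1 <- random_energy_matrix(seed = 5)
  em2 <- random_energy_matrix(seed = 5)
  expect_identical(em1, em2)
  expect_false(identical(em1, random_energy_matrix(seed = 6)))
  tr <- synthetic_truth(seed = 5)
  expect_identical(simulate_mitomi(tr)$data, simulate_mitomi(tr)$data)
  s1 <- simulate_selection(tr, 3, peak_noise = 0.02)
  s2 <- simulate_selection(tr, 3, peak_noise = 0.02)
  expect_identical(s1$chromatogram$heights, s2$chromatogram$heights)
  expect_identical(s1$population, s2$population)
})

test_that("penalty distribution has the requested shape", {
  em <- random_energy_matrix(n_positions = 2, spread = 0, seed = 1)
  pen <- em$ddg[em$ddg > 0]
  expect_equal(pen, rep(2.5, 6))
  big <- random_energy_matrix(n_positions = 4000, mean_penalty = 2.5,
                              spread = 1, seed = 2)
  draws <- big$ddg[big$ddg > 0]
  expect_equal(mean(draws), 2.5, tolerance = 0.05)
  expect_equal(stats::sd(draws), 1, tolerance = 0.05)
  # consensus anchored at 0 in every row
  expect_true(all(apply(big$ddg, 1, min) == 0))
})

test_that("two-state floor saturates weak sites near dg_ns_true", {
  tr <- toy_truth(dg_ns_true = 3, noise_sigma = 0)
  ddg_true <- true_site_energies(tr)
  meas <- relative_binding_energies(simulate_mitomi(tr))
  weak <- names(ddg_true)[ddg_true > 3 + 2 * RT295]
  expect_gt(length(weak), 5)
  expect_true(all(abs(meas[weak] - 3) < RT295 * log(2)))
  # strongest site is the consensus when noise-free
  expect_equal(attr(meas, "consensus"), "GCA")
})

test_that("coupling terms enter the simulated energies", {
  coup <- data.frame(pos_i = -1, pos_j = 0, base_i = "A", base_j = "T",
                     energy = 2)
  tr <- toy_truth(coupling = coup)
  ddg <- true_site_energies(tr)
  plain <- true_site_energies(toy_truth())
  hit <- grepl("^.AT$", names(ddg))
  expect_equal(unname(ddg[hit] - plain[hit]), rep(2, 4))
  expect_equal(ddg[!hit], plain[!hit])
})

test_that("selection stringency monotonically shapes the logo", {
  # tighter stringency never reduces information (averaged over seeds)
  strs <- c(1.5, 3, 6)
  info <- sapply(1:10, function(s) {
    tr <- synthetic_truth(seed = 200 + s, dg_ns_true = Inf)
    vapply(strs, function(st) {
      sel <- try(simulate_selection(tr, st), silent = TRUE)
      if (inherits(sel, "try-error")) return(NA_real_)
      selection_logo(sel$chromatogram,
                     from = min(tr$truth_matrix$positions),
                     to = 0)$information$total
    }, numeric(1))
  })
  avg <- rowMeans(info, na.rm = TRUE)
  expect_true(all(diff(avg) <= 1e-9))
})

test_that("an empty survivor set is a helpful error", {
  # a strong penalty on the consensus dinucleotide lifts every site
  # above a tight stringency
  coup <- data.frame(pos_i = -2, pos_j = -1, base_i = "G", base_j = "C",
                     energy = 5)
  tr <- toy_truth(coupling = coup)
  expect_gt(min(true_site_energies(tr)), 0.5)
  expect_error(simulate_selection(tr, 0.5), "loosen the stringency")
})

test_that("peak noise is truncated at zero and bias multiplies heights", {
  tr <- toy_truth()
  noisy <- simulate_selection(tr, Inf, peak_noise = 0.5, seed = 77)
  expect_true(all(noisy$chromatogram$heights >= 0))
  nb <- matrix(0, 4, 4, dimnames = list(dna_alphabet(), dna_alphabet()))
  nb["G", "A"] <- 0.5  # A peaks inflate after a majority-G position
  biased <- simulate_selection(tr, Inf, neighbor_bias = nb)
  clean <- simulate_selection(tr, Inf)
  # position -2 follows the fixed G at -3
  expect_equal(biased$chromatogram$heights["-2", "A"],
               clean$chromatogram$heights["-2", "A"] * 1.5)
  expect_equal(biased$chromatogram$heights["-2", "C"],
               clean$chromatogram$heights["-2", "C"])
})

test_that("recovery report scores estimates against the truth", {
  tr <- toy_truth(dg_ns_true = 4)
  perfect <- list(energy_matrix = tr$truth_matrix, dg_ns = 4,
                  info_bits = information_content(
                    boltzmann_frequencies(tr$truth_matrix),
                    apply_correction = FALSE)$total)
  rep <- recovery_report(tr, perfect)
  expect_true(all(rep$pass))
  expect_true(all(rep$error == 0))
  # a known offset shows up as exactly that bias
  shifted <- perfect
  shifted$dg_ns <- 4 + 0.75
  rep2 <- recovery_report(tr, shifted)
  expect_equal(rep2$error[rep2$parameter == "dg_ns"], 0.75)
  expect_true(rep2$pass[rep2$parameter == "dg_ns"])  # < RT ln2
  bad <- list(energy_matrix = energy_matrix(tr$truth_matrix$ddg[1:2, ]))
  expect_error(recovery_report(tr, bad), "shape")
})
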