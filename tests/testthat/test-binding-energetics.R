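test_that("free energy follows -RT ln Ka", {
  expect_equal(free_energy_from_association(1), 0)
  expect_equal(free_energy_from_association(1) -
                 free_energy_from_association(2),
               RT295 * log(2), tolerance = 1e-12)  # 1.700 kJ/mol
  expect_equal(free_energy_from_association(1) -
                 free_energy_from_association(1.6),
               1.153, tolerance = 1e-3)
  expect_error(free_energy_from_association(0), "> 0")
  expect_error(free_energy_from_association(-2), "> 0")
})

test_that("relative energies anchor the strongest site at zero", {
  bt <- binding_table("V", c("AA", "CC"), c(2, 1))
  ddg <- relative_binding_energies(bt)
  expect_equal(unname(ddg[c("AA", "CC")]), c(0, RT295 * log(2)),
               tolerance = 1e-12)
  expect_equal(attr(ddg, "consensus"), "AA")
  # single site
  one <- binding_table("V", "GCA", 5)
  expect_equal(as.numeric(relative_binding_energies(one)), 0)
  # tie broken lexicographically with a warning
  tie <- binding_table("V", c("CC", "AA"), c(3, 3))
  expect_warning(ddg <- relative_binding_energies(tie), "tie")
  expect_equal(attr(ddg, "consensus"), "AA")
})

test_that("ddG is invariant to globally rescaling Ka", {
  tr <- toy_truth()
  bt <- simulate_mitomi(tr)
  bt2 <- binding_table(bt$variant_id, bt$data$site, bt$data$ka * 137.5)
  expect_equal(relative_binding_energies(bt),
               relative_binding_energies(bt2), tolerance = 1e-9)
})

test_that("single-mutant energies are read off into the matrix", {
  ddg <- c(GC = 0, AC = 1, CC = 2, TC = 3, GA = 1, GG = 1, GT = 1)
  em <- energy_matrix_from_single_mutants(ddg, "GC")
  expect_equal(unname(em$ddg[1, ]), c(1, 2, 0, 3))  # A C G T
  expect_equal(unname(em$ddg[2, ]), c(1, 0, 1, 1))
  # missing mutant is named
  expect_error(energy_matrix_from_single_mutants(ddg[-2], "GC"), "AC")
  # a mutant tighter than the nominated consensus re-anchors with warning
  ddg2 <- ddg; ddg2[["AC"]] <- -0.5
  expect_warning(em2 <- energy_matrix_from_single_mutants(ddg2, "GC"),
                 "re-anchoring")
  expect_equal(unname(em2$ddg[1, ]), c(0, 2.5, 0.5, 3.5))
})

test_that("additive predictions sum matrix cells over all 64 sites", {
  tr <- toy_truth()
  em <- tr$truth_matrix
  sites <- enumerate_sites(em$alphabet, 3)
  pred <- additive_prediction(em, sites)
  manual <- vapply(sites, function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(vapply(1:3, function(l) em$ddg[l, match(ch[l], em$alphabet)],
               numeric(1)))
  }, numeric(1))
  expect_equal(pred, manual, tolerance = 1e-12)
  expect_equal(unname(pred["GCA"]), 0)  # consensus
  expect_equal(unname(pred["ACA"]), em$ddg[1, "A"])  # single mutant
})

test_that("additivity report flags exactly the coupled sites", {
  tr <- toy_truth()
  ddg <- true_site_energies(tr)
  rep0 <- additivity_report(tr$truth_matrix, ddg,
                            groupings = list(c("GCN", "ACN")))
  expect_true(all(abs(rep0$residuals$residual) < 1e-12))
  expect_equal(rep0$group_r2$r2, 1, tolerance = 1e-12)

  coup <- data.frame(pos_i = -2, pos_j = -1, base_i = "T", base_j = "A",
                     energy = 1.5)
  trc <- toy_truth(coupling = coup)
  ddgc <- true_site_energies(trc)
  repc <- additivity_report(tr$truth_matrix, ddgc)
  hit <- grepl("^TA", repc$residuals$site)
  expect_true(all(abs(repc$residuals$residual[hit] - 1.5) < 1e-12))
  expect_true(all(abs(repc$residuals$residual[!hit]) < 1e-12))
  # group sizes must match
  expect_error(additivity_report(tr$truth_matrix, ddg,
                                 groupings = list(c("GCN", "NNA"))),
               "mismatch")
})

test_that("fold affinity divides association constants", {
  bt <- binding_table("V", c("AA", "CC", "GG"), c(3, 1.5, 1.5))
  expect_equal(fold_affinity(bt, "AA", "CC"), 2)
  expect_equal(fold_affinity(bt, "CC", "CC"), 1)
  expect_error(fold_affinity(bt, "AA", "TT"), "not in binding table")
})

test_that("noise-free simulated measurements round-trip to the truth", {
  tr <- toy_truth(dg_ns_true = Inf, noise_sigma = 0)
  bt <- simulate_mitomi(tr)
  ddg <- relative_binding_energies(bt)
  expect_equal(attr(ddg, "consensus"), "GCA")
  em <- energy_matrix_from_single_mutants(ddg, "GCA", positions = -2:0)
  expect_equal(em$ddg, tr$truth_matrix$ddg, tolerance = 1e-9)
})
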