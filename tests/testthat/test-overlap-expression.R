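test_that("quadrants partition the universe and swap cleanly", {
  set.seed(21)
  ri_a <- stats::setNames(rnorm(64), enumerate_sites(dna_alphabet(), 3))
  ri_b <- 0.5 * ri_a + rnorm(64, 0, 0.3)
  q <- overlap_quadrants(ri_a, ri_b)
  expect_setequal(c(q$shared_specific, q$neither, q$only_a, q$only_b),
                  names(ri_a))
  expect_equal(length(q$shared_specific) + length(q$neither) +
                 length(q$only_a) + length(q$only_b), 64)
  # swapping the variants swaps the one-sided lists, preserves r2
  qs <- overlap_quadrants(ri_b, ri_a)
  expect_setequal(qs$only_a, q$only_b)
  expect_setequal(qs$only_b, q$only_a)
  expect_equal(qs$pearson_r2, q$pearson_r2, tolerance = 1e-12)
})

test_that("identical and opposed models give the extreme overlaps", {
  ri <- c(AA = 2, AC = 1, CA = -1, CC = -2)
  q <- overlap_quadrants(ri, ri)
  expect_setequal(q$shared_specific, c("AA", "AC"))
  expect_setequal(q$neither, c("CA", "CC"))
  expect_length(q$only_a, 0)
  expect_equal(q$pearson_r2, 1)
  q2 <- overlap_quadrants(ri, -ri)
  expect_length(q2$shared_specific, 0)
  expect_error(overlap_quadrants(ri, ri[-1]), "universes differ")
})

test_that("relative expression normalises to the reference pair", {
  rec <- data.frame(variant_id = c("WQR", "WQR", "RQR"),
                    site = c("GCA", "TCC", "GCA"),
                    tet_abundance = c(10, 5, 40),
                    mara_abundance = c(2, 2, 4))
  out <- relative_expression(rec, c("WQR", "GCA"))
  expect_equal(out$relative_expression, c(1, 0.5, 2))
  # invariant to rescaling all tet (or all mara) abundances
  rec2 <- rec; rec2$tet_abundance <- rec2$tet_abundance * 3
  expect_equal(relative_expression(rec2, c("WQR", "GCA"))$relative_expression,
               out$relative_expression)
  same <- rec; same$tet_abundance <- 8; same$mara_abundance <- 2
  expect_true(all(relative_expression(same,
                                      c("WQR", "GCA"))$relative_expression == 1))
  expect_error(relative_expression(rec, c("SAR", "GCA")),
               "exactly once")
  bad <- rec; bad$tet_abundance[1] <- 0
  expect_error(relative_expression(bad, c("WQR", "GCA")), "positive")
})

test_that("expression-affinity correlation matches a Pearson oracle", {
  set.seed(31)
  sites <- enumerate_sites(dna_alphabet(), 2)[1:10]
  ka <- stats::setNames(runif(10, 0.1, 1), sites)
  rec <- data.frame(variant_id = "V", site = sites,
                    tet_abundance = 5 * ka + abs(rnorm(10, 0, 0.1)),
                    mara_abundance = 1)
  rec <- relative_expression(rec, c("V", sites[1]))
  r2 <- expression_affinity_correlation(rec, ka)
  oracle <- stats::cor(ka, rec$relative_expression)^2
  expect_equal(r2, oracle, tolerance = 1e-10)
  # perfectly linear synthetic pairs
  lin <- data.frame(variant_id = "V", site = sites,
                    tet_abundance = 2 * ka, mara_abundance = 1)
  lin <- relative_expression(lin, c("V", sites[1]))
  expect_equal(expression_affinity_correlation(lin, ka), 1,
               tolerance = 1e-9)
  # constant expression: defined as 0 with a warning
  flat <- data.frame(variant_id = "V", site = sites,
                     tet_abundance = 3, mara_abundance = 1)
  flat <- relative_expression(flat, c("V", sites[1]))
  expect_warning(r0 <- expression_affinity_correlation(flat, ka),
                 "zero variance")
  expect_equal(r0, 0)
  expect_error(expression_affinity_correlation(lin, ka[1:2]),
               "at least 3")
  # subsetting restricts the points
  sub <- expression_affinity_correlation(rec, ka, subset = sites[1:5])
  expect_equal(sub, stats::cor(ka[1:5],
                               rec$relative_expression[1:5])^2,
               tolerance = 1e-10)
})
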