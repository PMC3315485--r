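test_that("per-position information matches hand values", {
  fm <- frequency_matrix(rbind(rep(0.25, 4),
                               c(0.5, 0.5, 0, 0),
                               c(1, 0, 0, 0)))
  ic <- information_content(fm, apply_correction = FALSE)
  expect_equal(unname(ic$per_position), c(0, 1, 2))
  expect_equal(ic$total, 3)
})

test_that("total information equals the sum of per-position values", {
  for (seed in 1:5) {
    fm <- random_freq_matrix(n_pos = 4, seed = seed)
    ic <- information_content(fm, apply_correction = FALSE)
    expect_equal(ic$total, sum(ic$per_position), tolerance = 1e-9)
    expect_true(all(ic$per_position >= -1e-12))  # uncorrected: >= 0
  }
})

test_that("position-range subsetting and errors behave", {
  fm <- frequency_matrix(matrix(0.25, 5, 4), positions = -2:2)
  ic <- information_content(fm, from = -2, to = 0)
  expect_length(ic$per_position, 3)
  expect_error(information_content(fm, from = 1, to = 0), "empty")
  expect_error(information_content(fm, from = 7, to = 9), "no positions")
  expect_error(information_content(fm, apply_correction = TRUE),
               "unknown")
})

test_that("small-sample correction: exact values at tiny n", {
  # one site: observed entropy is 0, so the bias is the full 2 bits
  expect_equal(small_sample_correction(1, 4)$e_bits, 2)
  # brute-force oracle at n = 4, k = 4: enumerate all 4^4 draws
  g <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  H <- apply(g, 1, function(s) {
    p <- tabulate(s, 4) / 4
    -sum(ifelse(p == 0, 0, p * log2(p)))
  })
  expect_equal(small_sample_correction(4, 4)$e_bits, 2 - mean(H),
               tolerance = 1e-12)
  # and the exact variance against the same enumeration
  expect_equal(small_sample_correction(4, 4)$sd_bits, sqrt(mean(H^2) - mean(H)^2),
               tolerance = 1e-12)
  expect_error(small_sample_correction(0), ">= 1")
})

test_that("correction vanishes for large n and works for proteins", {
  expect_lt(small_sample_correction(1e9, 4)$e_bits, 1e-8)
  expect_equal(small_sample_correction(1, 20)$e_bits, log2(20))
  # 20-letter alphabet at n = 5 stays finite and positive
  e20 <- small_sample_correction(5, 20)$e_bits
  expect_gt(e20, 0)
  expect_lt(e20, log2(20))
})

test_that("correction at n = 16 agrees with a Monte-Carlo oracle", {
  set.seed(101)
  x <- stats::rmultinom(200000, 16, rep(0.25, 4))
  p <- x / 16
  H <- -colSums(ifelse(x == 0, 0, p * log2(p)))
  expect_lt(abs(small_sample_correction(16, 4)$e_bits - mean(2 - H)),
            0.01)
  expect_lt(abs(small_sample_correction(16, 4)$sd_bits - stats::sd(H)),
            0.02)
})

test_that("corrected information can be negative and carries an sd", {
  fm <- frequency_matrix_from_sites(c("AC", "CA"), pseudocount = 0)
  ic <- information_content(fm, apply_correction = TRUE)
  expect_true(all(ic$per_position < 0))  # 1 bit observed - e(2) > 1 bit
  expect_gt(ic$sd_total, 0)
  expect_equal(ic$sd_total,
               sqrt(2) * small_sample_correction(2, 4)$sd_bits)
})

test_that("logo heights split each stack in proportion to frequency", {
  for (seed in 6:8) {
    fm <- random_freq_matrix(n_pos = 3, seed = seed)
    lt <- logo_table(fm, apply_correction = FALSE)
    ic <- information_content(fm, apply_correction = FALSE)
    sums <- tapply(lt$height, lt$position, sum)
    expect_equal(as.numeric(sums[as.character(fm$positions)]),
                 unname(ic$per_position), tolerance = 1e-9)
    expect_true(all(lt$height >= -1e-12))
  }
  # blanked positions are zeroed
  fm <- conserved_freq_matrix("GCA")
  lt <- logo_table(fm, apply_correction = FALSE, blank_positions = 2)
  expect_true(all(lt$height[lt$position == 2] == 0))
  expect_equal(sum(lt$height), 4)  # the two remaining conserved stacks
})
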