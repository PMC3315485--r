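test_that("OLS line matches hand values and a normal-equations oracle", {
  x <- c(0, 1, 2, 3)
  f <- fit_line(x, -x + 3)
  expect_equal(f$slope, -1, tolerance = 1e-12)
  expect_equal(f$intercept, 3, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  # two points always fit exactly
  expect_equal(fit_line(c(0, 2), c(5, 1))$r2, 1, tolerance = 1e-12)
  # random cloud vs closed-form normal equations
  set.seed(7)
  xr <- rnorm(40); yr <- 2 - 1.3 * xr + rnorm(40, 0, 0.4)
  f <- fit_line(xr, yr)
  slope <- sum((xr - mean(xr)) * (yr - mean(yr))) / sum((xr - mean(xr))^2)
  expect_equal(f$slope, slope, tolerance = 1e-10)
  expect_equal(f$intercept, mean(yr) - slope * mean(xr),
               tolerance = 1e-10)
  expect_equal(f$r2, stats::cor(xr, yr)^2, tolerance = 1e-10)
  expect_error(fit_line(rep(1, 5), rnorm(5)), "degenerate")
})

test_that("Ri partition is disjoint, exhaustive, ties to specific", {
  ri <- c(a = 1, b = 0.5, c = 0, d = -0.5)
  p <- partition_by_ri(ri)
  expect_setequal(c(p$specific, p$nonspecific), names(ri))
  expect_length(intersect(p$specific, p$nonspecific), 0)
  expect_true("c" %in% p$specific)           # tie at threshold
  expect_length(partition_by_ri(abs(ri))$nonspecific, 0)
  expect_equal(partition_by_ri(ri, threshold = max(ri))$specific, "a")
})

test_that("non-specific energy from two lines follows the algebra", {
  pos <- list(slope = -1, intercept = 4)
  neg <- list(slope = 0, intercept = 4)
  ns <- nonspecific_energy(pos, neg, "intersection")
  expect_equal(ns$dg_ns, 4)
  expect_equal(ns$ri_at_boundary, 0)
  expect_equal(nonspecific_energy(pos, neg, "ri0-intercept")$dg_ns, 4)
  # both horizontal at c: parallel, falls back to the Ri=0 intercept = c
  flat <- list(slope = 0, intercept = 2.5)
  expect_warning(ns2 <- nonspecific_energy(flat, flat, "intersection"),
                 "parallel")
  expect_equal(ns2$dg_ns, 2.5)
  expect_equal(ns2$method, "ri0-intercept")
  expect_error(nonspecific_energy(pos, NULL), "required")
})

test_that("boundary fit recovers a synthetic non-specific floor", {
  tr <- toy_truth(dg_ns_true = 4, noise_sigma = 0)
  a <- analyze_binding(simulate_mitomi(tr))
  expect_s3_class(a$boundary, "boundary_fit")
  # informative truth: specific branch slopes downward
  expect_lt(a$boundary$fit_pos$slope, 0)
  # dGns within the two-state plateau allowance of the truth
  expect_lt(abs(a$boundary$dg_ns - 4), RT295 * log(2))
  # invariant to a global Ka rescaling (i.e. a constant dG offset)
  bt <- simulate_mitomi(tr)
  bt2 <- binding_table(bt$variant_id, bt$data$site, bt$data$ka * 50)
  a2 <- analyze_binding(bt2)
  expect_equal(a2$boundary$dg_ns, a$boundary$dg_ns, tolerance = 1e-9)
})

test_that("boundary fit model methods are coherent", {
  tr <- toy_truth(dg_ns_true = 4, noise_sigma = 0.05, seed = 9)
  a <- analyze_binding(simulate_mitomi(tr))
  b <- a$boundary
  co <- coef(b)
  expect_named(co, c("dg_ns", "slope_specific", "intercept_specific",
                     "slope_nonspecific", "intercept_nonspecific"))
  # predict routes each Ri to its branch's line
  expect_equal(predict(b, 2),
               unname(co["intercept_specific"] + 2 * co["slope_specific"]))
  expect_equal(predict(b, -3),
               unname(co["intercept_nonspecific"] -
                        3 * co["slope_nonspecific"]))
  s <- summary(b)
  expect_equal(s$dg_ns, b$dg_ns)
  expect_equal(s$n_specific + s$n_nonspecific, 64)
  rep <- boundary_report(b)
  expect_equal(nrow(rep), 64)
  expect_true(!is.unsorted(rev(rep$ri)))
  expect_output(print(b), "dGns")
  # plot runs without error on a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(b))
})

test_that("floor recovery is unbiased across noisy replicates", {
  tr0 <- toy_truth(dg_ns_true = 4, noise_sigma = 0)
  ref <- analyze_binding(simulate_mitomi(tr0))$boundary$dg_ns
  est <- vapply(1:30, function(i) {
    tr <- toy_truth(dg_ns_true = 4, noise_sigma = 0.1, seed = 500 + i)
    analyze_binding(simulate_mitomi(tr))$boundary$dg_ns
  }, numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - ref), 2 * se + 0.1)
})
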