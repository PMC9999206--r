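test_that("Poisson pmf matches the direct series and normalizes", {
  for (lam in c(0.05, 0.5, 1, 2, 5)) {
    expect_equal(poisson_pmf(0:20, lam), pmf_oracle(0:20, lam),
                 tolerance = 1e-12)
    expect_lt(abs(sum(poisson_pmf(0:60, lam)) - 1), 1e-12)
  }
  expect_equal(poisson_pmf(1, 1), 0.3679, tolerance = 1e-4)
  expect_equal(poisson_pmf(0, 0), 1)
  expect_equal(poisson_pmf(2, 0.5), pmf_oracle(2, 0.5), tolerance = 1e-12)
  expect_error(poisson_pmf(-1, 1), "non-negative")
  expect_error(poisson_pmf(1, -0.1), ">= 0")
})

test_that("multi-cell probability is exact, monotone and matches bounds", {
  expect_equal(multi_cell_probability(1), 0.2642, tolerance = 5e-4)
  expect_equal(multi_cell_probability(0), 0)
  # oracle: 1 - e^-l (1 + l)
  expect_equal(multi_cell_probability(0.05), 1 - exp(-0.05) * 1.05,
               tolerance = 1e-12)
  expect_lt(multi_cell_probability(0.05), 0.005)
  expect_lt(multi_cell_probability(0.04), 0.002)
  lam <- seq(0.01, 4, by = 0.01)
  expect_true(all(diff(multi_cell_probability(lam)) > 0))
  expect_error(multi_cell_probability(-1))
})

test_that("theoretical purity is a pmf ratio, decreasing, limit 1", {
  expect_lt(theoretical_purity(1), 0.60)
  expect_equal(theoretical_purity(2),
               pmf_oracle(1, 2) / (1 - pmf_oracle(0, 2)), tolerance = 1e-12)
  expect_equal(theoretical_purity(1e-9), 1, tolerance = 1e-6)
  lam <- seq(0.001, 4, by = 0.001)
  expect_true(all(diff(theoretical_purity(lam)) < 0))
  expect_error(theoretical_purity(0))
})

test_that("single-cell probability peaks at lambda = 1", {
  lam <- seq(0.001, 4, by = 0.001)
  p <- single_cell_probability(lam)
  expect_equal(lam[which.max(p)], 1, tolerance = 2e-3)
})

test_that("suspension concentration maps to lambda by droplet volume", {
  expect_equal(lambda_from_suspension(0, 40), 0)
  # oracle: volume arithmetic in ml
  vol_ml <- (pi / 6) * (40e-4)^3
  expect_equal(lambda_from_suspension(1e7, 40), 1e7 * vol_ml,
               tolerance = 1e-12)
  expect_equal(lambda_from_suspension(1e7, 40), 0.335, tolerance = 0.01)
  expect_equal(lambda_from_suspension(1e7, 45.6), 0.5, tolerance = 0.01)
  expect_error(lambda_from_suspension(1e7, 0))
})

test_that("sorted throughput is capped rate times single-cell probability", {
  expect_lt(theoretical_sorted_throughput(0.05, 200), 10)
  expect_equal(theoretical_sorted_throughput(0.05, 200),
               200 * pmf_oracle(1, 0.05), tolerance = 1e-12)
  expect_equal(theoretical_sorted_throughput(0, 200), 0)
  expect_equal(theoretical_sorted_throughput(1, 200), 200 * exp(-1),
               tolerance = 1e-12)
})

test_that("presets expose the published loading calibrations", {
  expect_equal(encapsulation_presets("paper_low")$lam, 0.05)
  expect_equal(encapsulation_presets("paper_high")$lam, 0.5)
})

test_that("sampled streams have Poisson class fractions and valid structure", {
  p <- encapsulation_params(lam = 1)
  st <- sample_stream(p, 2e4, seed = 3)
  expect_true(all(diff(st$arrival_time_s) > 0))
  expect_true(all(lengths(st$cell_positions) == st$cell_count))
  expect_true(all(lengths(st$viable_flags) == st$cell_count))
  # goodness of fit against the analytic pmf
  k <- pmin(st$cell_count, 6)
  obs <- tabulate(k + 1, nbins = 7)
  pr <- c(poisson_pmf(0:5, 1), 1 - sum(poisson_pmf(0:5, 1)))
  gof <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.01)
  # law of large numbers on the single-cell fraction
  frac <- mean(st$cell_count == 1)
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 2e4)
  expect_lt(abs(frac - exp(-1)), 3 * se)
})

test_that("degenerate and regular streams behave as configured", {
  st0 <- sample_stream(encapsulation_params(lam = 0), 100, seed = 1)
  expect_true(all(st0$cell_count == 0))
  str <- sample_stream(encapsulation_params(lam = 0.5, arrival = "regular",
                                            generation_rate_hz = 100),
                       50, seed = 1)
  expect_equal(unique(round(diff(str$arrival_time_s), 12)), 0.01)
  # reproducible per seed, independent of caller RNG state
  a <- sample_stream(encapsulation_params(lam = 0.5), 100, seed = 9)
  runif(10)
  b <- sample_stream(encapsulation_params(lam = 0.5), 100, seed = 9)
  expect_identical(a, b)
})

test_that("streams round-trip through CSV exactly", {
  st <- quick_stream(50, lam = 1)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_stream(st, path)
  back <- read_stream(path)
  expect_equal(back$cell_count, st$cell_count)
  expect_equal(back$cell_positions, st$cell_positions, tolerance = 1e-15)
  expect_equal(back$viable_flags, st$viable_flags)
  expect_equal(back$arrival_time_s, st$arrival_time_s, tolerance = 1e-15)
})

test_that("permeabilized fraction marks cells non-viable", {
  p <- encapsulation_params(lam = 2, permeabilized_fraction = 1)
  st <- sample_stream(p, 200, seed = 5)
  flags <- unlist(st$viable_flags)
  expect_true(length(flags) > 0 && all(!flags))
})
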