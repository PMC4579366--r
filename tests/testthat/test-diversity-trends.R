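# Synthetic cohort series with a known constant per-year rate delta:
# F_t = 1 - (1 - delta)^(t - t0), so ln(1 - F_t) is exactly linear in t
# with slope ln(1 - delta).
geometric_series <- function(delta, years = 1980:2014, n_born = 100L) {
  s <- data.frame(year = years, n_born = n_born,
                  mean_F = 1 - (1 - delta)^(years - years[1]),
                  expected_F = NA_real_, expected_F_sd = NA_real_,
                  regime = "exhaustive", stringsAsFactors = FALSE)
  class(s) <- c("cohort_series", "data.frame")
  s
}

test_that("annual rate recovers the generating slope of ln(1 - F)", {
  s <- geometric_series(0.002)
  r <- annual_inbreeding_rate(s)
  expect_equal(r$slope_b, log(1 - 0.002), tolerance = 1e-9)
  expect_equal(r$dF_annual, -log(1 - 0.002), tolerance = 1e-9)
  # the exp transform returns delta itself
  r2 <- annual_inbreeding_rate(s, method = "exp")
  expect_equal(r2$dF_annual, 0.002, tolerance = 1e-12)

  # constant F: zero rate; declining F: negative rate is legitimate
  sc <- geometric_series(0)
  sc$mean_F <- 0.1
  expect_equal(annual_inbreeding_rate(sc)$dF_annual, 0, tolerance = 1e-12)
  sd <- geometric_series(0.002)
  sd$mean_F <- rev(sd$mean_F)
  expect_lt(annual_inbreeding_rate(sd)$dF_annual, 0)

  # guard rails
  expect_error(annual_inbreeding_rate(geometric_series(0.002, 1980:1981)),
               "at least 3 years")
  sb <- geometric_series(0.002)
  sb$mean_F[5] <- 1
  expect_error(annual_inbreeding_rate(sb), "degenerate")
  # years with no animals born are omitted, not treated as F = 0
  sz <- geometric_series(0.002)
  sz$n_born[10] <- 0L
  sz$mean_F[10] <- NA_real_
  expect_equal(annual_inbreeding_rate(sz)$n_years, 34L)
  expect_equal(annual_inbreeding_rate(sz)$slope_b, log(1 - 0.002),
               tolerance = 1e-9)
})

test_that("per-generation scaling and Ne inversion are exact", {
  expect_equal(delta_f_per_generation(0.0025, 4), 0.01)
  expect_equal(delta_f_per_generation(0, 7.3), 0)
  expect_equal(delta_f_per_generation(-0.001, 3.5), -0.0035)

  expect_equal(effective_population_size(0.01)$Ne, 50)
  expect_equal(effective_population_size(0.125)$Ne, 4)
  for (dF in c(1e-4, 0.004, 0.01, 0.037, 0.125, 0.5)) {
    ne <- effective_population_size(dF)
    expect_equal(2 * dF * ne$Ne, 1, tolerance = 4 * .Machine$double.eps)
  }
  expect_equal(effective_population_size(-0.003)$status,
               "undetermined_negative")
  expect_true(is.na(effective_population_size(-0.003)$Ne))
  expect_equal(effective_population_size(0)$status, "undetermined_zero")
})

test_that("sign coherence of annual and generational rates", {
  for (delta in c(0.004, -0.002)) {
    s <- geometric_series(abs(delta))
    if (delta < 0) s$mean_F <- rev(s$mean_F)
    tr <- trend_estimate(s, 3.8)
    expect_equal(sign(tr$dF_annual), sign(delta))
    expect_equal(sign(tr$dF_gen), sign(delta))
    expect_equal(sign(diff(range(s$mean_F)) *
                        (s$mean_F[35] - s$mean_F[1])), sign(delta))
  }
})

test_that("block statistics partition the window and flag inclusion", {
  blocks <- five_year_blocks()
  expect_equal(nrow(blocks), 7L)
  expect_equal(blocks$label[1], "1980-1984")
  expect_equal(blocks$label[7], "2010-2014")

  # stationary generating process: every block estimates the same rate
  sim <- simulate_pedigree(sim_config(1952:2014, 15, 30, 5,
                                      parental_ages = c(3, 4, 5), seed = 4))
  s <- cohort_series(sim$pedigree, c(1980, 2014), include_expected = FALSE)
  bs <- block_statistics(sim$pedigree, s, L = 4)
  expect_equal(nrow(bs$blocks), 7L)
  expect_true(bs$included)  # 150 registrations/year on average
  expect_true(all(is.finite(bs$blocks$dF_gen)))
  # block estimates scatter around the whole-period rate
  whole <- trend_estimate(s, 4)$dF_gen
  expect_true(all(abs(bs$blocks$dF_gen - whole) < 0.05))

  # sparse pedigree: undetermined blocks rather than errors
  p3 <- trio_pedigree()
  s3 <- cohort_series(p3, c(1980, 2014), include_expected = FALSE)
  bs3 <- block_statistics(p3, s3, L = 4)
  expect_true(all(bs3$blocks$status == "undetermined_insufficient_years"))
  expect_false(bs3$included)
})

test_that("block ANOVA behaves on constructed data", {
  set.seed(1)
  # identical block means, nonzero within-block spread: F small, p large
  bv <- data.frame(breed = rep(sprintf("B%02d", 1:20), times = 3),
                   block = rep(c("b1", "b2", "b3"), each = 20),
                   dF_gen = 0.01 + rnorm(60, 0, 0.002))
  r <- compare_blocks(bv)
  expect_gt(r$p_value, 0.05)

  # two blocks separated far beyond the within-block sd: p < 0.001
  bv2 <- data.frame(breed = rep(sprintf("B%02d", 1:20), times = 2),
                    block = rep(c("early", "late"), each = 20),
                    dF_gen = c(rnorm(20, 0.02, 0.001),
                               rnorm(20, -0.01, 0.001)))
  r2 <- compare_blocks(bv2)
  expect_lt(r2$p_value, 0.001)
  expect_gt(r2$F_statistic, 100)

  # degenerate: zero within-block variance
  bv3 <- data.frame(breed = rep(c("x", "y"), 2),
                    block = rep(c("b1", "b2"), each = 2),
                    dF_gen = rep(c(0.01, 0.02), each = 2))
  expect_error(compare_blocks(bv3), "degenerate")
  expect_error(compare_blocks(bv2[bv2$block == "early", ]), "2 blocks")
})
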