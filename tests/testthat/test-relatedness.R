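test_that("inbreeding matches the classical recursive values on textbook cases", {
  # unrelated parents
  expect_equal(unname(inbreeding_all(trio_pedigree())[["C"]]), 0)

  # half-sib mating: F = 1/8
  F <- inbreeding_all(half_sib_pedigree())
  expect_identical(unname(F[c("P1", "P2")]), c(0, 0))
  expect_equal(unname(F[["X"]]), 0.125)

  # full-sib mating: F = 1/4
  p <- pedigree(data.frame(
    id = c("S", "D", "B1", "B2", "X"), sire = c(NA, NA, "S", "S", "B1"),
    dam = c(NA, NA, "D", "D", "B2"), stringsAsFactors = FALSE))
  expect_equal(unname(inbreeding_all(p)[["X"]]), 0.25)

  # parent-offspring mating: F = 1/4
  p2 <- pedigree(data.frame(
    id = c("S", "D", "K", "X"), sire = c(NA, NA, "S", "S"),
    dam = c(NA, NA, "D", "K"), stringsAsFactors = FALSE))
  expect_equal(unname(inbreeding_all(p2)[["X"]]), 0.25)
})

test_that("kinship obeys the standard identities", {
  p <- half_sib_pedigree()
  expect_equal(kinship(p, "S", "S"), 0.5)         # non-inbred self-kinship
  expect_equal(kinship(p, "S", "P1"), 0.25)       # parent-offspring
  expect_equal(kinship(p, "P1", "P2"), 0.125)     # half sibs
  expect_equal(kinship(p, "P1", "P2"), kinship(p, "P2", "P1"))
  expect_equal(kinship(p, "S", "D1"), 0)          # unrelated founders
  expect_error(kinship(p, "S", "nosuch"), "unknown")
})

test_that("F equals parental kinship for every non-founder (identity)", {
  for (seed in 1:5) {
    p <- random_pedigree(80, seed)
    F <- inbreeding_all(p)
    r <- p$records
    both <- which(!is.na(r$sire) & !is.na(r$dam))
    pick <- both[seq_len(min(12, length(both)))]
    for (i in pick)
      expect_equal(unname(F[[r$id[i]]]), kinship(p, r$sire[i], r$dam[i]),
                   tolerance = 1e-12)
  }
})

test_that("tabular inbreeding equals the naive recursive oracle", {
  for (seed in 1:8) {
    p <- random_pedigree(120, seed)
    expect_equal(inbreeding_all(p), naive_inbreeding(p), tolerance = 1e-12)
  }
})

test_that("cohort series applies the size-dependent sampling regimes", {
  p <- constant_kinship_cohort(40)
  s <- cohort_series(p, c(2005, 2005), seed = 7)
  expect_equal(s$regime, "exhaustive")
  expect_equal(s$n_born, 40L)
  expect_equal(s$mean_F, 0)
  expect_equal(s$expected_F, 0.125)
  expect_true(is.na(s$expected_F_sd))

  # regime boundaries: 500 exhaustive, 501 single sample of 500
  p500 <- constant_kinship_cohort(500)
  s500 <- cohort_series(p500, c(2005, 2005), seed = 1)
  expect_equal(s500$regime, "exhaustive")
  p501 <- constant_kinship_cohort(501)
  s501 <- cohort_series(p501, c(2005, 2005), seed = 1)
  expect_equal(s501$regime, "single_sample_500")
  expect_equal(s501$expected_F, 0.125)

  # unrelated, non-inbred cohort: expected inbreeding exactly zero
  n <- 30
  pu <- pedigree(data.frame(id = sprintf("U%02d", 1:n), sire = NA, dam = NA,
                            birth_date = 2005, stringsAsFactors = FALSE))
  su <- cohort_series(pu, c(2005, 2005), seed = 3)
  expect_identical(su$expected_F, 0)
  expect_identical(su$mean_F, 0)

  # single animal: mean defined, expected undefined
  p1 <- pedigree(data.frame(id = "solo", sire = NA, dam = NA,
                            birth_date = 2005, stringsAsFactors = FALSE))
  s1 <- cohort_series(p1, c(2005, 2005))
  expect_equal(s1$n_born, 1L)
  expect_equal(s1$mean_F, 0)
  expect_true(is.na(s1$expected_F))
})

test_that("cohort sampling is reproducible and year-stable under one seed", {
  sim <- simulate_pedigree(sim_config(1995:2010, 15, 60, 10, seed = 11))
  s1 <- cohort_series(sim$pedigree, c(1998, 2008), seed = 5)
  s2 <- cohort_series(sim$pedigree, c(1998, 2008), seed = 5)
  expect_identical(s1, s2)
  # extending the range must not perturb other years' samples
  s3 <- cohort_series(sim$pedigree, c(1996, 2010), seed = 5)
  shared <- match(s1$year, s3$year)
  expect_equal(s3$expected_F[shared], s1$expected_F)
})

test_that("expected inbreeding is staggered forward by round(L)", {
  p <- constant_kinship_cohort(20, year = 1990)
  s <- cohort_series(p, c(1990, 1992), seed = 1)
  st <- stagger_expected(s, 4.0)
  expect_equal(attr(st, "stagger_offset"), 4)
  expect_equal(st$expected_F[st$year == 1994], 0.125)
  expect_true(is.na(st$expected_F[st$year == 1990]))
  expect_equal(st$mean_F[st$year == 1990], 0)        # observed untouched
  expect_true(all(st$beyond_window[st$year > 1992]))

  expect_equal(attr(stagger_expected(s, 3.88), "stagger_offset"), 4)
  expect_equal(attr(stagger_expected(s, 3.5), "stagger_offset"), 4)
  expect_warning(st0 <- stagger_expected(s, 0.4), "zero-year")
  expect_equal(attr(st0, "stagger_offset"), 0)
})

test_that("cohort series writer emits one row per year", {
  p <- constant_kinship_cohort(10, year = 2001)
  s <- cohort_series(p, c(2000, 2002), seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_cohort_series(s, f)
  got <- read.delim(f)
  expect_equal(nrow(got), 3L)
  expect_equal(got$year, 2000:2002)
  expect_equal(got$expected_F[2], 0.125)
})
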