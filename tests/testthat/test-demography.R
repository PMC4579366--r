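test_that("generation interval follows the breeding-progeny definition", {
  # chain of breeders: yearly means at 1984 and 1988 are both 4.0
  p <- pedigree(data.frame(
    id = c("A", "Am", "B", "Bm", "C", "Cm", "D"),
    sire = c(NA, NA, "A", NA, "B", NA, "C"),
    dam = c(NA, NA, "Am", NA, "Bm", NA, "Cm"),
    sex = c("male", "female", "male", "female", "male", "female", "male"),
    birth_date = c(1980, 1980, 1984, 1984, 1988, 1988, 1992),
    stringsAsFactors = FALSE))
  gi <- generation_interval(p, c(1980, 1992))
  by <- gi$by_year
  expect_equal(by$mean_age[by$year == 1984], 4)
  expect_equal(by$mean_age[by$year == 1988], 4)
  # 1992 animal never reproduces: no value for that year
  expect_true(is.na(by$mean_age[by$year == 1992]))
  expect_equal(gi$L, 4)

  # L is the unweighted mean of yearly means
  p2 <- pedigree(data.frame(
    id = c("S1", "D1", "K1", "S2", "D2", "K2", "E1", "E2"),
    sire = c(NA, NA, "S1", NA, NA, "S2", "K1", "K2"),
    dam = c(NA, NA, "D1", NA, NA, "D2", "D1", "D2"),
    sex = c("male", "female", "male", "male", "female", "male", "female",
            "female"),
    birth_date = c(2000, 2000, 2003, 1999, 1999, 2004, 2010, 2011),
    stringsAsFactors = FALSE))
  gi2 <- generation_interval(p2, c(2003, 2004))
  expect_equal(gi2$by_year$mean_age, c(3, 5))
  expect_equal(gi2$L, 4)

  expect_error(generation_interval(trio_pedigree(), c(2000, 2004)),
               "undeterminable")
})

test_that("generation interval is invariant to input row order", {
  set.seed(42)
  n <- 60
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sire <- dam <- rep(NA_character_, n)
  id <- sprintf("A%02d", seq_len(n))
  for (i in seq(2L, n)) {
    males <- which(sex[seq_len(i - 1L)] == "male")
    females <- which(sex[seq_len(i - 1L)] == "female")
    if (length(males)) sire[i] <- id[males[sample.int(length(males), 1L)]]
    if (length(females)) dam[i] <- id[females[sample.int(length(females), 1L)]]
  }
  df <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                   birth_date = 1980L + seq_len(n) %/% 4L,
                   stringsAsFactors = FALSE)
  perm <- sample(seq_len(n))
  g1 <- tryCatch(generation_interval(pedigree(df))$L,
                 error = function(e) NA)
  g2 <- tryCatch(generation_interval(pedigree(df[perm, ]))$L,
                 error = function(e) NA)
  expect_equal(g1, g2)
})

test_that("a simulator with fixed parental age recovers that age as L", {
  sim <- simulate_pedigree(sim_config(2000:2011, 8, 16, 4,
                                      parental_ages = 4, seed = 9))
  gi <- generation_interval(sim$pedigree, c(2000, 2011))
  expect_equal(gi$L, 4)
})

test_that("sire usage concentration matches hand-computed values", {
  # 4 sires with progeny counts 10, 5, 3, 2
  kids <- c(rep("S1", 10), rep("S2", 5), rep("S3", 3), rep("S4", 2))
  p <- pedigree(data.frame(
    id = sprintf("K%02d", seq_along(kids)), sire = kids, dam = NA,
    birth_date = 2005, stringsAsFactors = FALSE))
  u <- sire_usage(p, 2005, "sire")
  expect_equal(u$n_unique, 4)
  expect_equal(u$n_progeny, 20)
  expect_equal(u$max, 10)
  expect_equal(u$mean, 5)
  expect_equal(u$median, 4)
  expect_equal(u$mode, 2)          # all-distinct multimodal set: smallest
  expect_true(u$multimodal)
  expect_equal(u$sd, sqrt(38 / 3), tolerance = 1e-12)
  expect_equal(unname(u$pct_top[c("50", "25")]), c(75, 50))

  # single sire: all tiers 100, sd flagged zero
  p1 <- pedigree(data.frame(id = sprintf("K%d", 1:7), sire = "S",
                            dam = NA, birth_date = 2005,
                            stringsAsFactors = FALSE))
  u1 <- sire_usage(p1, 2005, "sire")
  expect_true(all(u1$pct_top == 100))
  expect_equal(u1$sd, 0)
  expect_true(u1$sd_single_parent)

  # uniform usage: top-50% of sires accounts for exactly 50%
  p2 <- pedigree(data.frame(id = sprintf("K%d", 1:8),
                            sire = sprintf("S%d", 1:8), dam = NA,
                            birth_date = 2005, stringsAsFactors = FALSE))
  u2 <- sire_usage(p2, 2005, "sire")
  expect_equal(unname(u2$pct_top[["50"]]), 50)
  expect_equal(u2$mode, 1)

  expect_error(sire_usage(p2, 1990, "sire"), "no registrations")
})

test_that("usage tier percentages are monotone and mean*count consistent", {
  for (seed in c(2, 5)) {
    sim <- simulate_pedigree(sim_config(2000:2008, 10, 30, 4,
                                        sire_skew = 0.5, seed = seed))
    for (yr in c(2003, 2006)) for (role in c("sire", "dam")) {
      u <- sire_usage(sim$pedigree, yr, role)
      pt <- u$pct_top
      expect_true(all(diff(pt[c("5", "10", "25", "50")]) >= 0))
      expect_true(all(pt >= 0 & pt <= 100))
      if (u$max > 1) expect_gte(pt[["50"]], 50)
      expect_equal(u$n_unique * u$mean, u$n_progeny)
    }
  }
})

test_that("registration trend is the OLS slope on yearly counts", {
  # exactly linear growth 100, 110, ...: slope 10, se 0
  rows <- do.call(rbind, lapply(0:4, function(k) data.frame(
    id = sprintf("Y%d_%03d", k, seq_len(100 + 10 * k)),
    sire = NA, dam = NA, birth_date = 2000 + k, stringsAsFactors = FALSE)))
  p <- pedigree(rows)
  tr <- suppressWarnings(registration_trend(p, c(2000, 2004)))
  expect_equal(tr$slope, 10, tolerance = 1e-9)
  expect_equal(tr$se, 0, tolerance = 1e-9)

  # constant counts: slope 0
  rows2 <- do.call(rbind, lapply(0:3, function(k) data.frame(
    id = sprintf("C%d_%02d", k, 1:20), sire = NA, dam = NA,
    birth_date = 2000 + k, stringsAsFactors = FALSE)))
  tr2 <- suppressWarnings(registration_trend(pedigree(rows2), c(2000, 2003)))
  expect_equal(tr2$slope, 0, tolerance = 1e-9)

  expect_error(registration_trend(pedigree(rows2), c(2000, 2001)),
               "at least 3 years")
})
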