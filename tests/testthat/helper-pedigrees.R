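# Pedigree fixtures built in code.

# The textbook popular-sire pedigree: one founder sire S over unrelated
# founder dams; mating two of the half-sib progeny gives X with F = 0.125.
half_sib_pedigree <- function(n_dams = 2) {
  dams <- sprintf("D%d", seq_len(n_dams))
  prog <- sprintf("P%d", seq_len(n_dams))
  pedigree(data.frame(
    id = c("S", dams, prog, "X"),
    sire = c(NA, rep(NA, n_dams), rep("S", n_dams), "P1"),
    dam = c(NA, rep(NA, n_dams), dams, "P2"),
    sex = c("male", rep("female", n_dams),
            rep(c("male", "female"), length.out = n_dams), "female"),
    birth_date = c(2000, rep(2000, n_dams), rep(2004, n_dams), 2008),
    stringsAsFactors = FALSE))
}

trio_pedigree <- function() {
  pedigree(data.frame(
    id = c("A", "B", "C"), sire = c(NA, NA, "A"), dam = c(NA, NA, "B"),
    sex = c("male", "female", "female"),
    birth_date = c("2000-03-15", "2000-06-01", "2004-05-20"),
    stringsAsFactors = FALSE))
}

# One founder sire over n unrelated founder dams, one offspring each, all
# offspring born the same year: every pair of cohort members are paternal
# half-sibs with kinship exactly 1/8.
constant_kinship_cohort <- function(n, year = 2005) {
  dams <- sprintf("D%04d", seq_len(n))
  off <- sprintf("O%04d", seq_len(n))
  pedigree(data.frame(
    id = c("S", dams, off),
    sire = c(NA, rep(NA, n), rep("S", n)),
    dam = c(NA, rep(NA, n), dams),
    sex = c("male", rep("female", n),
            rep(c("female", "male"), length.out = n)),
    birth_date = c(2000, rep(2000, n), rep(year, n)),
    stringsAsFactors = FALSE))
}

# Random acyclic pedigree with founders, one-parent records and inbreeding
# loops; parent rows always precede offspring rows.
random_pedigree <- function(n, seed, p_founder = 0.3) {
  set.seed(seed)
  id <- sprintf("A%04d", seq_len(n))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sire <- dam <- rep(NA_character_, n)
  for (i in seq(2L, n)) {
    if (runif(1) < p_founder) next
    males <- which(sex[seq_len(i - 1L)] == "male")
    females <- which(sex[seq_len(i - 1L)] == "female")
    if (length(males) && runif(1) < 0.95)
      sire[i] <- id[males[sample.int(length(males), 1L)]]
    if (length(females) && runif(1) < 0.95)
      dam[i] <- id[females[sample.int(length(females), 1L)]]
  }
  pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                      birth_date = 1980L + seq_len(n) %/% 5L,
                      stringsAsFactors = FALSE))
}

write_ped_file <- function(p, path = tempfile(fileext = ".tsv")) {
  write_pedigree(p, path)
  path
}
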