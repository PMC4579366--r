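#' @useDynLib pedtrends, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aov coef cor.test lm median rbinom rpois runif sd setNames
#' @importFrom utils read.table write.table packageVersion head
NULL

# Tokens read as a missing parent / unknown field in pedigree files.
MISSING_TOKENS <- c("", "0", "NA")

#' Construct a studbook pedigree
#'
#' Builds a validated `pedigree` object from a data frame with one row per
#' registered animal. Parents that are referenced but have no row of their
#' own are materialised as founder stubs (both parents unknown, birth date
#' unknown), so that every parent identifier resolves within the object.
#'
#' @param records data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex` (`"male"`, `"female"`, `"unknown"`), `birth_date` (ISO date or
#'   4-digit year) and `breed`. Empty strings, `"0"` and `"NA"` in the parent
#'   columns denote an unknown parent. Identifiers are compared by exact
#'   string match after whitespace trimming.
#' @return An object of class `pedigree`: a list with elements `records`
#'   (the normalised data frame, input order preserved, stubs appended),
#'   `resolution` (`"date"` if every known birth date carries day precision,
#'   else `"year"`), and cached integer parent indices and a topological
#'   order used by the algorithms.
#' @details A founder is an animal with *both* parents unknown. Animals with
#'   exactly one known parent are not founders; the unknown side simply
#'   contributes no co-ancestry. Duplicate identifiers, self-parentage and
#'   ancestry cycles are hard errors; softer inconsistencies (sex conflicts,
#'   chronology) are reported by [validate_pedigree()] instead.
#' @seealso [read_pedigree()], [validate_pedigree()], [topological_order()]
#' @examples
#' ped <- pedigree(data.frame(
#'   id = c("A", "B", "C"), sire = c(NA, NA, "A"), dam = c(NA, NA, "B"),
#'   sex = c("male", "female", "female"), birth_date = c(2000, 2000, 2004)))
#' ped
#' @export
pedigree <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(records)))
    stop("pedigree records need columns: ", paste(need, collapse = ", "))

  norm_id <- function(x) {
    x <- trimws(as.character(x))
    x[x %in% MISSING_TOKENS | is.na(x)] <- NA_character_
    x
  }
  id   <- trimws(as.character(records$id))
  sire <- norm_id(records$sire)
  dam  <- norm_id(records$dam)

  if (any(is.na(id) | id == ""))
    stop("empty animal identifier in row(s) ",
         paste(which(is.na(id) | id == ""), collapse = ", "))
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate animal identifier(s): ", paste(dup, collapse = ", "))
  }
  self <- which(!is.na(sire) & sire == id | !is.na(dam) & dam == id)
  if (length(self))
    stop("self-parentage for animal(s): ", paste(id[self], collapse = ", "))

  sex <- if ("sex" %in% names(records)) normalise_sex(records$sex)
         else rep("unknown", length(id))
  bd  <- parse_birth_dates(records)
  breed <- if ("breed" %in% names(records)) as.character(records$breed)
           else rep(NA_character_, length(id))
  breed[!is.na(breed) & (trimws(breed) == "" | breed == "NA")] <-
    NA_character_

  # founder stubs for referenced-but-unlisted parents
  refs <- setdiff(unique(c(sire, dam)), c(id, NA_character_))
  if (length(refs)) {
    used_as_sire <- refs %in% sire
    used_as_dam  <- refs %in% dam
    stub_sex <- ifelse(used_as_sire & used_as_dam, "unknown",
                ifelse(used_as_sire, "male", "female"))
    id    <- c(id, refs)
    sire  <- c(sire, rep(NA_character_, length(refs)))
    dam   <- c(dam, rep(NA_character_, length(refs)))
    sex   <- c(sex, stub_sex)
    bd$date <- c(bd$date, rep(as.Date(NA), length(refs)))
    bd$year <- c(bd$year, rep(NA_integer_, length(refs)))
    breed <- c(breed, rep(NA_character_, length(refs)))
  }

  rec <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                    birth_date = bd$date, birth_year = bd$year,
                    breed = breed, stringsAsFactors = FALSE)
  sire_idx <- match(sire, id); sire_idx[is.na(sire_idx)] <- 0L
  dam_idx  <- match(dam, id);  dam_idx[is.na(dam_idx)]  <- 0L

  p <- structure(list(records = rec, resolution = bd$resolution,
                      sire_idx = as.integer(sire_idx),
                      dam_idx = as.integer(dam_idx)),
                 class = "pedigree")
  p$topo <- topo_order_idx(p)  # errors on cycles
  p
}

normalise_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("m", "male", "1", "dog", "sire")]   <- "male"
  out[x %in% c("f", "female", "2", "bitch", "dam")] <- "female"
  out
}

# Accept ISO dates or bare 4-digit years; resolution drops to "year" if any
# known birth date lacks day precision.
parse_birth_dates <- function(records) {
  n <- nrow(records)
  if (!"birth_date" %in% names(records))
    return(list(date = rep(as.Date(NA), n), year = rep(NA_integer_, n),
                resolution = "year"))
  raw <- trimws(as.character(records$birth_date))
  raw[raw %in% MISSING_TOKENS | is.na(raw)] <- NA_character_
  date <- rep(as.Date(NA), n)
  year <- rep(NA_integer_, n)
  known <- !is.na(raw)
  is_year <- known & grepl("^\\d{4}$", raw)
  year[is_year] <- as.integer(raw[is_year])
  is_date <- known & !is_year
  if (any(is_date)) {
    d <- as.Date(raw[is_date], format = "%Y-%m-%d")
    bad <- which(is.na(d))
    if (length(bad))
      stop("unparseable birth date in row ", which(is_date)[bad[1]],
           ": '", raw[is_date][bad[1]], "' (expected YYYY-MM-DD or YYYY)")
    date[is_date] <- d
    year[is_date] <- as.integer(format(d, "%Y"))
  }
  resolution <- if (any(is_year) || !any(known)) "year" else "date"
  list(date = date, year = year, resolution = resolution)
}

# Topological order as integer indices: parents before offspring, ties broken
# by input row order (generation rank, then row). Level-wise assignment keeps
# it vectorised; depth is bounded by the number of generations.
topo_order_idx <- function(p) {
  n <- nrow(p$records)
  s <- p$sire_idx; d <- p$dam_idx
  gen <- rep(NA_integer_, n)
  remaining <- n
  level <- 0L
  while (remaining > 0L) {
    s_ok <- s == 0L | (!is.na(gen[pmax(s, 1L)]) & s != 0L)
    d_ok <- d == 0L | (!is.na(gen[pmax(d, 1L)]) & d != 0L)
    ready <- is.na(gen) & s_ok & d_ok
    if (!any(ready)) {
      cyc <- find_cycle(s, d, which(is.na(gen)))
      stop("pedigree contains an ancestry cycle: ",
           paste(p$records$id[cyc], collapse = " -> "))
    }
    gen[ready] <- level
    remaining <- remaining - sum(ready)
    level <- level + 1L
  }
  order(gen, seq_len(n))
}

find_cycle <- function(s, d, unresolved) {
  cur <- unresolved[1]
  seen <- integer(0)
  repeat {
    seen <- c(seen, cur)
    nxt <- if (s[cur] %in% unresolved) s[cur] else d[cur]
    if (nxt %in% seen)
      return(c(seen[which(seen == nxt)[1]:length(seen)], nxt))
    cur <- nxt
  }
}

#' Topological processing order of a pedigree
#'
#' Returns animal identifiers ordered so that every parent precedes all of
#' its offspring — the processing order required by the tabular inbreeding
#' algorithm. The order is deterministic: animals are ranked by generation
#' number (founders = 0) with ties broken by input row order, so a
#' founders-only pedigree is returned in input order.
#'
#' @param p a [pedigree] object.
#' @return Character vector of animal identifiers.
#' @export
topological_order <- function(p) {
  stopifnot(inherits(p, "pedigree"))
  p$records$id[p$topo]
}

#' Read a studbook pedigree file
#'
#' Reads a delimited text file with a header row and one row per animal
#' (columns `id`, `sire`, `dam`, optionally `sex`, `birth_date`, `breed`) and
#' returns a validated [pedigree]. Empty fields, `"0"` and `"NA"` in parent
#' columns denote an unknown parent; referenced-but-unlisted parents are
#' inserted as founder stubs.
#'
#' @param path path to the file.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A [pedigree]. Its `resolution` element is `"year"` when any birth
#'   date is known only to the year.
#' @export
read_pedigree <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                   colClasses = "character", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  names(df) <- tolower(trimws(names(df)))
  pedigree(df)
}

#' Write a pedigree file
#'
#' Writes the standard delimited pedigree format (header row; columns `id`,
#' `sire`, `dam`, `sex`, `birth_date`, `breed`), one row per animal in
#' topological order. Birth dates are written at the pedigree's resolution
#' (ISO date, or bare year when only the year is known).
#'
#' @param p a [pedigree].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(p, path, sep = "\t") {
  stopifnot(inherits(p, "pedigree"))
  r <- p$records[p$topo, , drop = FALSE]
  bd <- ifelse(!is.na(r$birth_date), format(r$birth_date, "%Y-%m-%d"),
               ifelse(!is.na(r$birth_year), as.character(r$birth_year), ""))
  out <- data.frame(id = r$id,
                    sire = ifelse(is.na(r$sire), "", r$sire),
                    dam = ifelse(is.na(r$dam), "", r$dam),
                    sex = r$sex, birth_date = bd,
                    breed = ifelse(is.na(r$breed), "", r$breed),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Structural lint of a pedigree
#'
#' Reports soft data-quality issues without modifying the pedigree. Hard
#' structural errors (duplicates, self-parentage, cycles) are raised at
#' construction time instead; the issues reported here occur in real registry
#' data and only exclude the affected records from age-based statistics,
#' never from relatedness computation.
#'
#' @param p a [pedigree].
#' @param max_parent_age maximum plausible parental age in years at the birth
#'   of an offspring (default 20); older parents are flagged.
#' @return Data frame with columns `code` (`"sex_conflict"`, `"chronology"`,
#'   `"parent_age"`), `animal_id` and `message`; zero rows when clean.
#' @export
validate_pedigree <- function(p, max_parent_age = 20) {
  stopifnot(inherits(p, "pedigree"))
  r <- p$records
  issues <- list()
  add <- function(code, aid, msg)
    issues[[length(issues) + 1L]] <<- data.frame(
      code = code, animal_id = aid, message = msg, stringsAsFactors = FALSE)

  # an identifier used both as a sire and as a dam, or against recorded sex
  as_sire <- unique(r$sire[!is.na(r$sire)])
  as_dam  <- unique(r$dam[!is.na(r$dam)])
  for (aid in intersect(as_sire, as_dam))
    add("sex_conflict", aid, "used both as sire and as dam")
  bad_sire <- intersect(as_sire, r$id[r$sex == "female"])
  for (aid in setdiff(bad_sire, intersect(as_sire, as_dam)))
    add("sex_conflict", aid, "recorded female but used as sire")
  bad_dam <- intersect(as_dam, r$id[r$sex == "male"])
  for (aid in setdiff(bad_dam, intersect(as_sire, as_dam)))
    add("sex_conflict", aid, "recorded male but used as dam")

  ages <- parent_ages(p)
  chron <- ages$offspring[!is.na(ages$age) & ages$age <= 0]
  for (aid in unique(chron))
    add("chronology", aid, "born on or before a parent's birth date")
  old <- ages$offspring[!is.na(ages$age) & ages$age > max_parent_age]
  for (aid in unique(old))
    add("parent_age", aid,
        sprintf("parent older than %g years at birth", max_parent_age))

  if (!length(issues))
    return(data.frame(code = character(), animal_id = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

# Long table of parental ages: one row per (offspring, parent role) with a
# known parent; age in years (date resolution: days / 365.25; year
# resolution: integer year difference). NA when either birth is unknown.
parent_ages <- function(p) {
  r <- p$records
  long <- rbind(
    data.frame(offspring = r$id, parent_idx = p$sire_idx, role = "sire",
               stringsAsFactors = FALSE),
    data.frame(offspring = r$id, parent_idx = p$dam_idx, role = "dam",
               stringsAsFactors = FALSE))
  long <- long[long$parent_idx > 0L, , drop = FALSE]
  off_idx <- match(long$offspring, r$id)
  if (p$resolution == "date") {
    a <- as.numeric(r$birth_date[off_idx] - r$birth_date[long$parent_idx]) /
      365.25
  } else {
    a <- as.numeric(r$birth_year[off_idx] - r$birth_year[long$parent_idx])
  }
  data.frame(offspring = long$offspring, parent = r$id[long$parent_idx],
             role = long$role, offspring_year = r$birth_year[off_idx],
             age = a, stringsAsFactors = FALSE)
}

#' @export
print.pedigree <- function(x, ...) {
  r <- x$records
  founders <- sum(is.na(r$sire) & is.na(r$dam))
  yrs <- range(r$birth_year, na.rm = TRUE)
  cat(sprintf("pedigree: %d animals (%d founders), resolution: %s\n",
              nrow(r), founders, x$resolution))
  if (all(is.finite(yrs)))
    cat(sprintf("  birth years %d-%d; sexes: %d male / %d female / %d unknown\n",
                yrs[1], yrs[2], sum(r$sex == "male"),
                sum(r$sex == "female"), sum(r$sex == "unknown")))
  invisible(x)
}

#' @export
as.data.frame.pedigree <- function(x, ...) x$records

#' Number of animals in a pedigree
#' @param p a [pedigree].
#' @return Integer count of records (including founder stubs).
#' @export
n_animals <- function(p) nrow(p$records)
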