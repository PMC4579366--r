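#' Generation interval
#'
#' The generation interval is the mean age of parents at the birth of
#' progeny which themselves go on to reproduce. For each year in
#' `year_range`, the sire and dam ages at birth are pooled over every animal
#' born that year that has at least one offspring anywhere in the pedigree
#' (the lookahead is not restricted to the analysis window); the yearly
#' value is the mean of that pool, and the overall interval L is the
#' unweighted mean of the yearly values over years where one is defined.
#'
#' Ages are computed in days and converted to years by division by 365.25
#' when full dates are available, or as integer year differences at year
#' resolution. Records with chronology problems (parent age non-positive or
#' implausibly large) are excluded from the pools.
#'
#' @param p a [pedigree].
#' @param year_range inclusive integer vector `c(first, last)`; defaults to
#'   all known birth years.
#' @param max_parent_age ages above this (years, default 20) are treated as
#'   chronology errors and excluded.
#' @return A list of class `generation_interval`: `by_year` (data frame with
#'   `year`, `mean_age`, `n_ages`) and `L` (overall mean, years).
#' @export
generation_interval <- function(p, year_range = NULL, max_parent_age = 20) {
  stopifnot(inherits(p, "pedigree"))
  r <- p$records
  if (is.null(year_range)) {
    if (all(is.na(r$birth_year))) stop("no birth years available")
    year_range <- range(r$birth_year, na.rm = TRUE)
  }
  breeds_on <- unique(c(r$sire, r$dam))        # ids with >= 1 offspring
  ages <- parent_ages(p)
  ages <- ages[ages$offspring %in% breeds_on &
               !is.na(ages$age) & ages$age > 0 & ages$age <= max_parent_age &
               !is.na(ages$offspring_year) &
               ages$offspring_year >= year_range[1] &
               ages$offspring_year <= year_range[2], , drop = FALSE]
  if (nrow(ages) == 0L)
    stop("generation interval undeterminable: no breeding progeny with ",
         "usable parental ages in range")
  years <- seq.int(year_range[1], year_range[2])
  by_year <- data.frame(year = years, mean_age = NA_real_, n_ages = 0L)
  agg <- tapply(ages$age, ages$offspring_year, mean)
  cnt <- tapply(ages$age, ages$offspring_year, length)
  i <- match(as.integer(names(agg)), years)
  by_year$mean_age[i] <- as.numeric(agg)
  by_year$n_ages[i] <- as.integer(cnt)
  structure(list(by_year = by_year,
                 L = mean(by_year$mean_age, na.rm = TRUE)),
            class = "generation_interval")
}

#' @export
print.generation_interval <- function(x, ...) {
  cat(sprintf("generation interval L = %.2f years (mean of %d yearly means)\n",
              x$L, sum(!is.na(x$by_year$mean_age))))
  invisible(x)
}

#' Sire (or dam) usage concentration for one birth-year cohort
#'
#' Tabulates progeny born in `year` per unique parent of the given role and
#' summarises the concentration of usage: the maximum, mean, median, mode
#' and standard deviation of progeny per parent, and the percentage of the
#' year's known-parent registrations born to the most prolific 50, 25, 10
#' and 5 percent of parents — the footprint of "popular sires".
#'
#' @param p a [pedigree].
#' @param year birth year of the progeny cohort.
#' @param role `"sire"` or `"dam"`.
#' @return A list of class `usage_stats`: `year`, `role`, `n_unique`
#'   (parents used), `n_progeny` (registrations with known parent of the
#'   role; animals with that parent unknown are excluded from the
#'   denominator), `max`, `mean`, `median`, `mode` (smallest modal value;
#'   `multimodal` flags ties), `sd` (sample standard deviation; 0 with
#'   `sd_single_parent = TRUE` when only one parent was used) and `pct_top`
#'   (named numeric for the 50/25/10/5 percent tiers).
#' @details The top-q% tier contains `ceiling(q/100 * n_unique)` parents —
#'   never empty — selected by descending progeny count with ties broken by
#'   ascending identifier, so results are deterministic.
#' @export
sire_usage <- function(p, year, role = c("sire", "dam")) {
  stopifnot(inherits(p, "pedigree"))
  role <- match.arg(role)
  r <- p$records
  parent <- if (role == "sire") r$sire else r$dam
  keep <- !is.na(r$birth_year) & r$birth_year == year & !is.na(parent)
  if (!any(keep))
    stop("no registrations with known ", role, " born in ", year)
  counts <- table(parent[keep])
  counts <- counts[order(-as.numeric(counts), names(counts))]
  cnt <- as.numeric(counts)
  n_unique <- length(cnt)
  n_progeny <- sum(cnt)

  tab <- table(cnt)
  modal <- as.numeric(names(tab)[tab == max(tab)])
  pct_top <- vapply(c(`50` = 50, `25` = 25, `10` = 10, `5` = 5), function(q) {
    top <- ceiling(q / 100 * n_unique)
    100 * sum(cnt[seq_len(top)]) / n_progeny
  }, numeric(1))

  structure(list(
    year = year, role = role, n_unique = n_unique, n_progeny = n_progeny,
    max = max(cnt), mean = mean(cnt), median = median(cnt),
    mode = min(modal), multimodal = length(modal) > 1L,
    sd = if (n_unique > 1L) sd(cnt) else 0,
    sd_single_parent = n_unique == 1L,
    pct_top = pct_top,
    counts = setNames(cnt, names(counts))), class = "usage_stats")
}

#' @export
print.usage_stats <- function(x, ...) {
  cat(sprintf("%s usage, %d: %d unique, %d progeny; max %g mean %.2f sd %.2f\n",
              x$role, x$year, x$n_unique, x$n_progeny, x$max, x$mean, x$sd))
  cat(sprintf("  %% born to top 50/25/10/5%%: %.1f / %.1f / %.1f / %.1f\n",
              x$pct_top[["50"]], x$pct_top[["25"]], x$pct_top[["10"]],
              x$pct_top[["5"]]))
  invisible(x)
}

#' Usage statistics over a span of years
#'
#' Convenience wrapper: [sire_usage()] for every year in range, long-format
#' output (one row per year per role), suitable for the usage-table writer.
#' Years with no known-parent registrations are skipped.
#'
#' @param p a [pedigree].
#' @param year_range inclusive integer vector `c(first, last)`.
#' @param roles roles to tabulate.
#' @return Data frame, one row per (year, role).
#' @export
usage_table <- function(p, year_range, roles = c("sire", "dam")) {
  rows <- list()
  for (role in roles) for (yr in seq.int(year_range[1], year_range[2])) {
    u <- tryCatch(sire_usage(p, yr, role), error = function(e) NULL)
    if (is.null(u)) next
    rows[[length(rows) + 1L]] <- data.frame(
      year = yr, role = role, n_unique = u$n_unique, n_progeny = u$n_progeny,
      max = u$max, mean = u$mean, median = u$median, mode = u$mode,
      sd = u$sd, pct_top50 = u$pct_top[["50"]], pct_top25 = u$pct_top[["25"]],
      pct_top10 = u$pct_top[["10"]], pct_top5 = u$pct_top[["5"]],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no usable years for usage statistics")
  do.call(rbind, rows)
}

#' Trend in annual registrations
#'
#' Ordinary least-squares regression of the number of registered animals
#' born per year on year of birth; the regression coefficient describes the
#' overall trend in breed registrations over the window. Years with zero
#' registrations inside the window count as data points.
#'
#' @param p a [pedigree].
#' @param year_range inclusive integer vector `c(first, last)` spanning at
#'   least 3 years.
#' @return List with `slope` (animals/year), `se` (its standard error),
#'   `n_years`, and `counts` (the per-year census used).
#' @export
registration_trend <- function(p, year_range = NULL) {
  stopifnot(inherits(p, "pedigree"))
  r <- p$records
  if (is.null(year_range)) {
    if (all(is.na(r$birth_year))) stop("no birth years available")
    year_range <- range(r$birth_year, na.rm = TRUE)
  }
  years <- seq.int(year_range[1], year_range[2])
  if (length(years) < 3L)
    stop("registration trend needs at least 3 years")
  n <- vapply(years, function(y)
    sum(!is.na(r$birth_year) & r$birth_year == y), integer(1))
  fit <- lm(n ~ years)
  sm <- summary(fit)$coefficients
  list(slope = unname(coef(fit)[2]), se = unname(sm["years", "Std. Error"]),
       n_years = length(years),
       counts = data.frame(year = years, n_born = n))
}
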