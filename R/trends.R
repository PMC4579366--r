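#' Annual rate of inbreeding from a cohort series
#'
#' The rate of inbreeding per annum is obtained from the regression
#' coefficient of ln(1 - F_t) on year of birth, where F_t is the mean
#' inbreeding coefficient of animals born in year t. The regression is
#' unweighted across years (set `weighted = TRUE` to weight by cohort
#' size); years with no animals born are omitted. The reported rate is the
#' negated slope, so rising inbreeding gives a positive rate; a negative
#' rate (declining mean F) is a legitimate result. The default follows the
#' literal rate-equals-regression-coefficient convention; `method = "exp"`
#' applies the transform 1 - exp(slope) that the log scale strictly
#' implies — the difference is negligible at observed scales.
#'
#' @param series a [cohort_series()] result (un-staggered).
#' @param window inclusive integer vector `c(first, last)`; default, the
#'   full series.
#' @param method `"linear"` (rate = -slope, default) or `"exp"`
#'   (rate = 1 - exp(slope)).
#' @param weighted weight years by cohort size (default `FALSE`).
#' @return List with `slope_b` (per year), `dF_annual`, `n_years`, `window`.
#' @export
annual_inbreeding_rate <- function(series, window = NULL,
                                   method = c("linear", "exp"),
                                   weighted = FALSE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(series), all(c("year", "n_born", "mean_F") %in%
                                       names(series)))
  if (is.null(window)) window <- range(series$year)
  s <- series[series$year >= window[1] & series$year <= window[2] &
              series$n_born >= 1L & !is.na(series$mean_F), , drop = FALSE]
  if (nrow(s) < 3L)
    stop("rate of inbreeding needs at least 3 years with animals born ",
         "(have ", nrow(s), ")")
  if (any(s$mean_F >= 1))
    stop("degenerate cohort mean inbreeding >= 1")
  y <- log(1 - s$mean_F)
  fit <- if (weighted) lm(y ~ s$year, weights = s$n_born) else lm(y ~ s$year)
  slope_b <- unname(coef(fit)[2])
  dF_annual <- if (method == "linear") -slope_b else 1 - exp(slope_b)
  list(slope_b = slope_b, dF_annual = dF_annual, n_years = nrow(s),
       window = c(min(s$year), max(s$year)), method = method)
}

#' Rate of inbreeding per generation
#'
#' Scales the annual rate by the breed mean generation interval L:
#' `dF_gen = dF_annual * L`. Negative values are allowed and indicate an
#' apparent gain of genetic diversity over the window.
#'
#' @param dF_annual annual rate of inbreeding (per year).
#' @param L generation interval in years (> 0).
#' @return The per-generation rate of inbreeding.
#' @export
delta_f_per_generation <- function(dF_annual, L) {
  stopifnot(L > 0)
  dF_annual * L
}

#' Effective population size
#'
#' The effective population size is the size of an idealised population
#' with the same per-generation increment in inbreeding as observed:
#' `Ne = 1 / (2 * dF_gen)`. A non-positive rate leaves Ne undetermined
#' (an apparent increase in diversity has no idealised-population size);
#' this is a first-class result value, never an error, so batch reports
#' over many breeds do not abort.
#'
#' @param dF_gen per-generation rate of inbreeding.
#' @return A list of class `ne_estimate`: `Ne` (numeric, `NA` when
#'   undetermined) and `status` (`"ok"`, `"undetermined_negative"` or
#'   `"undetermined_zero"`).
#' @examples
#' effective_population_size(0.01)$Ne  # 50, the sustainability threshold
#' @export
effective_population_size <- function(dF_gen) {
  stopifnot(is.numeric(dF_gen), length(dF_gen) == 1L)
  if (is.na(dF_gen))
    out <- list(Ne = NA_real_, status = "undetermined_missing")
  else if (dF_gen > 0)
    out <- list(Ne = 1 / (2 * dF_gen), status = "ok")
  else if (dF_gen == 0)
    out <- list(Ne = NA_real_, status = "undetermined_zero")
  else
    out <- list(Ne = NA_real_, status = "undetermined_negative")
  structure(out, class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  if (x$status == "ok") cat(sprintf("Ne = %.1f\n", x$Ne))
  else cat("Ne undetermined (", x$status, ")\n", sep = "")
  invisible(x)
}

#' Whole-window trend estimate
#'
#' Convenience composition of [annual_inbreeding_rate()],
#' [delta_f_per_generation()] and [effective_population_size()] into the
#' standard per-breed summary row.
#'
#' @param series a [cohort_series()].
#' @param L generation interval (years).
#' @param window inclusive year window.
#' @param ... passed to [annual_inbreeding_rate()].
#' @return List of class `trend_estimate`: `slope_b`, `dF_annual`, `L`,
#'   `dF_gen`, `Ne`, `ne_status`, `window`, `n_years`.
#' @export
trend_estimate <- function(series, L, window = NULL, ...) {
  rate <- annual_inbreeding_rate(series, window, ...)
  dF_gen <- delta_f_per_generation(rate$dF_annual, L)
  ne <- effective_population_size(dF_gen)
  structure(list(slope_b = rate$slope_b, dF_annual = rate$dF_annual,
                 L = L, dF_gen = dF_gen, Ne = ne$Ne, ne_status = ne$status,
                 window = rate$window, n_years = rate$n_years),
            class = "trend_estimate")
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf(
    "trend %d-%d: dF/yr = %.5f, L = %.2f, dF/gen = %.5f, Ne = %s\n",
    x$window[1], x$window[2], x$dF_annual, x$L, x$dF_gen,
    if (x$ne_status == "ok") sprintf("%.1f", x$Ne) else x$ne_status))
  invisible(x)
}

#' Default 5-year analysis blocks
#'
#' The seven fixed 5-year blocks 1980–1984 through 2010–2014 used for
#' within-window trend detail.
#'
#' @param window inclusive year window to partition (default 1980–2014).
#' @param width block width in years (default 5).
#' @return Data frame with `label`, `start`, `end`.
#' @export
five_year_blocks <- function(window = c(1980, 2014), width = 5) {
  starts <- seq.int(window[1], window[2], by = width)
  ends <- pmin(starts + width - 1, window[2])
  data.frame(label = sprintf("%d-%d", starts, ends),
             start = starts, end = ends, stringsAsFactors = FALSE)
}

#' Per-block trend and usage statistics
#'
#' Recomputes the trend machinery within each 5-year block to expose
#' changes hidden by the whole-window fit: mean registrations per year,
#' the within-block regression of ln(1 - F_t) on year, per-generation rate
#' and Ne, plus pooled progeny-per-parent usage summaries. The whole-period
#' generation interval is used inside block trends unless `L_per_block` is
#' set (per-block L is descriptive). A block with fewer than 3 usable years
#' yields an undetermined trend, not an error. The cross-breed inclusion
#' rule — mean registrations above 50 per year in every block — is
#' evaluated and returned as the `included` flag.
#'
#' @param p a [pedigree].
#' @param series a [cohort_series()] spanning the blocks.
#' @param L whole-period generation interval (years); computed from `p`
#'   when `NULL`.
#' @param blocks block table as from [five_year_blocks()].
#' @param L_per_block recompute L within each block (default `FALSE`).
#' @param min_mean_reg inclusion threshold on mean registrations per year
#'   in every block (default 50).
#' @return List of class `block_summary`: `blocks` (one row per block:
#'   label, years, mean registrations, slope, rates, Ne, status), `usage`
#'   (per block per role pooled progeny-per-parent stats), `L`, `included`.
#' @export
block_statistics <- function(p, series, L = NULL,
                             blocks = five_year_blocks(),
                             L_per_block = FALSE, min_mean_reg = 50) {
  stopifnot(inherits(p, "pedigree"))
  if (is.null(L)) L <- generation_interval(
    p, c(min(blocks$start), max(blocks$end)))$L
  rows <- list(); usage <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    in_b <- series$year >= b$start & series$year <= b$end
    mean_reg <- mean(series$n_born[in_b])
    Lb <- if (L_per_block)
      tryCatch(generation_interval(p, c(b$start, b$end))$L,
               error = function(e) L)
    else L
    tr <- tryCatch(trend_estimate(series, Lb, c(b$start, b$end)),
                   error = function(e) NULL)
    if (is.null(tr)) {
      rows[[i]] <- data.frame(
        label = b$label, start = b$start, end = b$end, mean_reg = mean_reg,
        slope_b = NA_real_, dF_annual = NA_real_, L = Lb, dF_gen = NA_real_,
        Ne = NA_real_, status = "undetermined_insufficient_years",
        stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        label = b$label, start = b$start, end = b$end, mean_reg = mean_reg,
        slope_b = tr$slope_b, dF_annual = tr$dF_annual, L = Lb,
        dF_gen = tr$dF_gen, Ne = tr$Ne, status = tr$ne_status,
        stringsAsFactors = FALSE)
    }
    for (role in c("sire", "dam")) {
      u <- tryCatch(block_usage(p, b$start, b$end, role),
                    error = function(e) NULL)
      if (!is.null(u)) usage[[length(usage) + 1L]] <- u
    }
  }
  structure(list(blocks = do.call(rbind, rows),
                 usage = if (length(usage)) do.call(rbind, usage) else NULL,
                 L = L,
                 included = all(vapply(rows, function(r)
                   !is.na(r$mean_reg) && r$mean_reg > min_mean_reg,
                   logical(1)))),
            class = "block_summary")
}

# Pooled progeny-per-parent statistics over a block of years.
block_usage <- function(p, start, end, role) {
  r <- p$records
  parent <- if (role == "sire") r$sire else r$dam
  keep <- !is.na(r$birth_year) & r$birth_year >= start &
    r$birth_year <= end & !is.na(parent)
  if (!any(keep)) stop("no known-", role, " registrations in block")
  cnt <- as.numeric(table(parent[keep]))
  data.frame(block = sprintf("%d-%d", start, end), role = role,
             n_unique = length(cnt), n_progeny = sum(cnt), max = max(cnt),
             mean = mean(cnt), median = median(cnt),
             sd = if (length(cnt) > 1) sd(cnt) else 0,
             stringsAsFactors = FALSE)
}

#' @export
print.block_summary <- function(x, ...) {
  cat("block summary (L =", round(x$L, 2), "years, included =",
      x$included, ")\n")
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA of per-generation rates across blocks
#'
#' Tests whether mean per-generation rates of inbreeding differ between
#' 5-year blocks, treating breeds as replicates within blocks.
#'
#' @param block_values data frame with columns `breed`, `block` and
#'   `dF_gen` (one row per breed per block).
#' @return List with `F_statistic`, `p_value`, `df` (numerator,
#'   denominator) and the fitted `aov` object.
#' @export
compare_blocks <- function(block_values) {
  stopifnot(is.data.frame(block_values),
            all(c("breed", "block", "dF_gen") %in% names(block_values)))
  bv <- block_values[!is.na(block_values$dF_gen), , drop = FALSE]
  if (length(unique(bv$block)) < 2L)
    stop("ANOVA needs at least 2 blocks")
  if (any(table(bv$block) < 2L))
    stop("ANOVA needs at least 2 breeds per block")
  fit <- aov(dF_gen ~ factor(block), data = bv)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  res_ss <- tab["Residuals", "Sum Sq"]
  if (res_ss <= 1e-10 * max(sum(tab[, "Sum Sq"]), .Machine$double.eps))
    stop("degenerate ANOVA: zero within-block variance everywhere")
  list(F_statistic = tab["factor(block)", "F value"],
       p_value = tab["factor(block)", "Pr(>F)"],
       df = c(tab["factor(block)", "Df"], tab["Residuals", "Df"]),
       fit = fit)
}
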