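# Closed enumeration of reason codes attached to UNDETERMINED report cells.
UNDETERMINED_REASONS <- c(
  "insufficient_years", "undetermined_negative", "undetermined_zero",
  "undetermined_missing", "insufficient_data", "no_known_parents",
  "no_breeding_progeny", "refused_insufficient_breeds")

undetermined <- function(reason) {
  reason <- match.arg(reason, UNDETERMINED_REASONS)
  list(status = "UNDETERMINED", reason = reason)
}

#' Per-breed population analysis report
#'
#' Runs the full pipeline on one pedigree and writes the standard report
#' tables: registrations per year with the census trend, per-year sire and
#' dam usage, the observed/expected inbreeding cohort series (raw and
#' staggered by the generation interval), the whole-window trend row
#' (annual and per-generation rate of inbreeding, generation interval,
#' effective population size), the seven 5-year block rows, and a
#' machine-readable JSON summary with provenance (input digest, seed,
#' package version). Components that cannot be computed from the data are
#' emitted as `UNDETERMINED` with a machine-readable reason code — a sparse
#' pedigree yields a partial report, never a failure.
#'
#' @param ped a [pedigree], or a path to a pedigree file.
#' @param out_dir output directory (created if needed).
#' @param window inclusive analysis window (default `c(1980, 2014)`).
#' @param seed run-level seed for the kinship sampling regimes.
#' @param breed breed label; defaults to the label on the records.
#' @param make_plots also write PNG figures (observed vs expected
#'   inbreeding; block rate bars; progeny-per-sire histograms). Tables are
#'   the canonical output; plots are optional artifacts.
#' @return Invisibly, a list of class `breed_report` with all computed
#'   components and the paths written.
#' @export
run_report <- function(ped, out_dir, window = c(1980, 2014), seed = 1L,
                       breed = NULL, make_plots = FALSE) {
  digest <- NA_character_
  if (is.character(ped)) {
    digest <- unname(tools::md5sum(ped))
    ped <- read_pedigree(ped)
  }
  stopifnot(inherits(ped, "pedigree"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  r <- ped$records
  if (is.null(breed)) {
    breed <- unique(r$breed[!is.na(r$breed)])
    breed <- if (length(breed) == 1L) breed else "UNKNOWN"
  }
  issues <- validate_pedigree(ped)

  reg <- tryCatch(registration_trend(ped, window),
                  error = function(e) undetermined("insufficient_years"))
  years <- seq.int(window[1], window[2])
  counts <- data.frame(year = years, n_born = vapply(years, function(y)
    sum(!is.na(r$birth_year) & r$birth_year == y), integer(1)))
  write.table(counts, file.path(out_dir, "registrations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  usage <- tryCatch(usage_table(ped, window),
                    error = function(e) undetermined("no_known_parents"))
  if (is.data.frame(usage)) {
    for (role in c("sire", "dam")) {
      u <- usage[usage$role == role, , drop = FALSE]
      if (nrow(u))
        write.table(u, file.path(out_dir, paste0(role, "_usage.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  series <- cohort_series(ped, window, seed = seed)
  gi <- tryCatch(generation_interval(ped, window),
                 error = function(e) undetermined("no_breeding_progeny"))
  L <- if (inherits(gi, "generation_interval")) gi$L else NA_real_

  write_cohort_series(series, file.path(out_dir, "cohort_series.tsv"))
  if (!is.na(L) && L > 0.5) {
    stag <- stagger_expected(series, L)
    write_cohort_series(stag, file.path(out_dir, "cohort_series_staggered.tsv"))
  } else stag <- NULL

  trend <- if (is.na(L)) undetermined("no_breeding_progeny") else
    tryCatch(trend_estimate(series, L, window),
             error = function(e) undetermined("insufficient_years"))
  blocks <- if (is.na(L)) undetermined("no_breeding_progeny") else
    tryCatch(block_statistics(ped, series, L = L,
                              blocks = five_year_blocks(window)),
             error = function(e) undetermined("insufficient_data"))
  write_trend_table(trend, blocks, file.path(out_dir, "trend.tsv"))

  summary <- list(
    breed = breed, window = window,
    n_animals = n_animals(ped), n_issues = nrow(issues),
    registration_trend = strip_fit(reg),
    generation_interval = if (is.na(L)) gi else list(L = L),
    trend = strip_fit(trend),
    blocks = if (inherits(blocks, "block_summary")) blocks$blocks else blocks,
    included = if (inherits(blocks, "block_summary")) blocks$included else NA,
    provenance = list(input_digest = digest, seed = seed,
                      package_version = as.character(packageVersion("pedtrends")),
                      generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)

  rep <- structure(list(breed = breed, window = window, counts = counts,
                        registration_trend = reg, usage = usage,
                        series = series, staggered = stag, L = L,
                        generation_interval = gi, trend = trend,
                        blocks = blocks, issues = issues, out_dir = out_dir),
                   class = "breed_report")
  if (make_plots) plot_breed_report(rep)
  invisible(rep)
}

strip_fit <- function(x) {
  if (is.list(x)) unclass(x)[setdiff(names(x), c("counts", "fit"))] else x
}

write_trend_table <- function(trend, blocks, path) {
  fmt <- function(x, digits = 6)
    ifelse(is.na(x), "UNDETERMINED", formatC(x, digits = digits, format = "g"))
  rows <- list()
  if (inherits(trend, "trend_estimate")) {
    rows[[1]] <- data.frame(
      scope = "whole_period",
      label = sprintf("%d-%d", trend$window[1], trend$window[2]),
      dF_annual = fmt(trend$dF_annual), L = fmt(trend$L),
      dF_gen = fmt(trend$dF_gen), Ne = fmt(trend$Ne),
      status = if (trend$ne_status == "ok") "ok" else trend$ne_status,
      stringsAsFactors = FALSE)
  } else {
    rows[[1]] <- data.frame(scope = "whole_period", label = "",
                            dF_annual = "UNDETERMINED", L = "UNDETERMINED",
                            dF_gen = "UNDETERMINED", Ne = "UNDETERMINED",
                            status = trend$reason, stringsAsFactors = FALSE)
  }
  if (inherits(blocks, "block_summary")) {
    b <- blocks$blocks
    for (i in seq_len(nrow(b)))
      rows[[length(rows) + 1L]] <- data.frame(
        scope = "block", label = b$label[i],
        dF_annual = fmt(b$dF_annual[i]), L = fmt(b$L[i]),
        dF_gen = fmt(b$dF_gen[i]), Ne = fmt(b$Ne[i]), status = b$status[i],
        stringsAsFactors = FALSE)
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Optional figures; tables remain the canonical output.
plot_breed_report <- function(rep) {
  out <- rep$out_dir
  if (!is.null(rep$staggered)) {
    grDevices::png(file.path(out, "observed_expected.png"), 800, 500)
    s <- rep$staggered
    plot(s$year, s$mean_F, type = "l", col = "blue", lwd = 2,
         xlab = "year of birth", ylab = "inbreeding coefficient",
         main = paste(rep$breed, "- observed and expected inbreeding"))
    graphics::lines(s$year, s$expected_F, col = "red", lwd = 2)
    if (any(!is.na(s$expected_F_sd))) {
      up <- s$expected_F + s$expected_F_sd
      lo <- s$expected_F - s$expected_F_sd
      graphics::lines(s$year, up, col = "red", lty = 3)
      graphics::lines(s$year, lo, col = "red", lty = 3)
    }
    graphics::legend("topleft", c("observed", "expected (staggered)"),
                     col = c("blue", "red"), lwd = 2, bty = "n")
    grDevices::dev.off()
  }
  if (inherits(rep$blocks, "block_summary")) {
    b <- rep$blocks$blocks
    grDevices::png(file.path(out, "block_dF.png"), 700, 450)
    graphics::barplot(b$dF_gen, names.arg = b$label, las = 2,
                      ylab = "rate of inbreeding per generation",
                      main = paste(rep$breed, "- block rates"))
    grDevices::dev.off()
  }
  invisible(NULL)
}

#' @export
print.breed_report <- function(x, ...) {
  cat("breed report:", x$breed, sprintf("(%d-%d)\n", x$window[1],
                                        x$window[2]))
  if (inherits(x$trend, "trend_estimate")) print(x$trend)
  else cat("trend UNDETERMINED (", x$trend$reason, ")\n", sep = "")
  cat("tables in:", x$out_dir, "\n")
  invisible(x)
}

#' Cross-breed summary tables
#'
#' Combines per-breed reports into the across-breed outputs: the table of
#' whole-period effective population size against mean annual registrations
#' (with a log-log correlation test of the independence of Ne from census
#' size), the per-block mean per-generation rate of inbreeding with its
#' standard error across breeds, and a one-way ANOVA of block differences.
#' Only breeds passing the inclusion rule — mean registrations above
#' `min_mean_reg` per year in every block — enter the block statistics.
#'
#' @param reports list of `breed_report` objects from [run_report()].
#' @param out_dir optional directory for the delimited-text tables.
#' @param min_mean_reg inclusion threshold (default 50).
#' @return List of class `cross_breed`: `ne_census` (per breed), `block_dF`
#'   (per block mean, sd, se, n), `anova` (F and p, or an UNDETERMINED
#'   marker when fewer than 2 breeds are included), `cor_ne_census`
#'   (log-log correlation test, or `NULL` with fewer than 3 determinable
#'   Ne values), `included` breed labels.
#' @export
run_cross_breed <- function(reports, out_dir = NULL, min_mean_reg = 50) {
  stopifnot(length(reports) >= 2L)
  ne_rows <- list(); block_rows <- list(); included <- character(0)
  for (rep in reports) {
    stopifnot(inherits(rep, "breed_report"))
    mean_reg <- mean(rep$counts$n_born)
    tr <- rep$trend
    ne_rows[[length(ne_rows) + 1L]] <- data.frame(
      breed = rep$breed, mean_registrations = mean_reg,
      Ne = if (inherits(tr, "trend_estimate")) tr$Ne else NA_real_,
      status = if (inherits(tr, "trend_estimate")) tr$ne_status
               else tr$reason,
      stringsAsFactors = FALSE)
    if (inherits(rep$blocks, "block_summary") && rep$blocks$included &&
        all(rep$blocks$blocks$mean_reg > min_mean_reg)) {
      included <- c(included, rep$breed)
      b <- rep$blocks$blocks
      block_rows[[length(block_rows) + 1L]] <- data.frame(
        breed = rep$breed, block = b$label, dF_gen = b$dF_gen,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(included))
    stop("no breed passes the inclusion rule (mean registrations > ",
         min_mean_reg, " in every block)")
  ne_census <- do.call(rbind, ne_rows)
  bv <- do.call(rbind, block_rows)
  agg <- do.call(rbind, lapply(split(bv, bv$block), function(d) data.frame(
    block = d$block[1], n_breeds = sum(!is.na(d$dF_gen)),
    mean_dF_gen = mean(d$dF_gen, na.rm = TRUE),
    sd_dF_gen = sd(d$dF_gen, na.rm = TRUE),
    se_dF_gen = sd(d$dF_gen, na.rm = TRUE) /
      sqrt(max(sum(!is.na(d$dF_gen)), 1)),
    stringsAsFactors = FALSE)))
  agg <- agg[order(agg$block), , drop = FALSE]

  anova_res <- if (length(included) < 2L)
    undetermined("refused_insufficient_breeds")
  else tryCatch(compare_blocks(bv),
                error = function(e) list(status = "UNDETERMINED",
                                         reason = conditionMessage(e)))

  det <- ne_census[!is.na(ne_census$Ne) & ne_census$Ne > 0 &
                   ne_census$mean_registrations > 0, , drop = FALSE]
  cor_res <- if (nrow(det) >= 3L)
    cor.test(log(det$Ne), log(det$mean_registrations)) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(ne_census, file.path(out_dir, "ne_census.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(agg, file.path(out_dir, "block_dF.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  structure(list(ne_census = ne_census, block_dF = agg, anova = anova_res,
                 cor_ne_census = cor_res, included = included,
                 block_values = bv),
            class = "cross_breed")
}

#' @export
print.cross_breed <- function(x, ...) {
  cat("cross-breed summary:", nrow(x$ne_census), "breeds,",
      length(x$included), "included\n")
  print(x$block_dF, row.names = FALSE)
  if (!is.null(x$anova$F_statistic))
    cat(sprintf("block ANOVA: F = %.2f, p = %.3g\n", x$anova$F_statistic,
                x$anova$p_value))
  if (!is.null(x$cor_ne_census))
    cat(sprintf("cor(log Ne, log registrations) = %.3f, p = %.3g\n",
                x$cor_ne_census$estimate, x$cor_ne_census$p.value))
  invisible(x)
}
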