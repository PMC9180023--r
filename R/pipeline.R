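# Orchestration: growth rates, the full index/trend analysis over a
# panel, and the CSV + manifest report bundle.

#' Growth rates of an annual series
#'
#' `total_growth()` is the overall relative change `(v_T - v_0) / v_0`.
#' `average_growth()` is the per-year rate; by default the geometric
#' (compound annual) rate `(v_T / v_0)^(1/(T - t0)) - 1`, with
#' `method = "arithmetic"` giving the arithmetic mean of the yearly
#' relative changes as an alternative reading.
#'
#' @param x Numeric series in time order (annual steps), length >= 2.
#' @param method `"geometric"` (compound) or `"arithmetic"`.
#' @return A fraction (0.05 = 5% growth).
#' @examples
#' total_growth(c(100, 120, 133.1))    # 0.331
#' average_growth(c(100, 110, 121, 133.1))  # 0.10
#' @export
total_growth <- function(x) {
  if (length(x) < 2) stop_equipanel("series", "need at least 2 values")
  if (x[1] == 0) stop_equipanel("growth", "undefined growth: first value is 0")
  (x[length(x)] - x[1]) / x[1]
}

#' @rdname total_growth
#' @export
average_growth <- function(x, method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  if (length(x) < 2) stop_equipanel("series", "need at least 2 values")
  if (any(x <= 0)) {
    stop_equipanel("domain", "average growth needs strictly positive values")
  }
  if (method == "geometric") {
    (x[length(x)] / x[1])^(1 / (length(x) - 1)) - 1
  } else {
    mean(diff(x) / x[-length(x)])
  }
}

#' National resource totals and growth per tier-kind
#'
#' The status-quo summary: for each valid (tier, kind), the national total
#' in the first and last panel year, the overall growth and the average
#' (compound) yearly growth rate, both as fractions.
#'
#' @param panel A `resource_panel`.
#' @param growth_mean Passed to [average_growth()].
#' @return A tibble: `tier`, `kind`, `first_year`, `last_year`,
#'   `first_total`, `last_total`, `total_growth`, `average_growth`.
#' @export
status_quo_table <- function(panel, growth_mean = "geometric") {
  panel <- as_resource_panel(panel)
  combos <- tier_kind_combos()
  years <- sort(unique(panel$year))
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    col <- paste(combos$tier[i], combos$kind[i], sep = "_")
    totals <- vapply(years, function(y) sum(panel[[col]][panel$year == y]), 0)
    tibble::tibble(
      tier = combos$tier[i], kind = combos$kind[i],
      first_year = years[1], last_year = years[length(years)],
      first_total = totals[1], last_total = totals[length(totals)],
      total_growth = total_growth(totals),
      average_growth = average_growth(totals, growth_mean))
  })
}

#' Run the full equity analysis over a panel
#'
#' For every valid (tier, kind): Gini series under the requested
#' calibre(s), HRDI series at zone and national level, a Theil
#' decomposition series, the within-zone contribution table, a
#' province-level HRDI cross-section at `cross_section_year`, the
#' status-quo growth table, and Mann-Kendall trend tables over every
#' emitted index series. Theil reporting defaults to the population
#' calibre, whose trend the dispersion indices track most directly; set
#' `theil_calibre = "geography"` for the area-weighted decomposition.
#' Deterministic: a pure function of its inputs.
#'
#' @param panel A `resource_panel`.
#' @param calibre `"both"` (default), `"population"` or `"geography"` --
#'   the calibres for the Gini series.
#' @param theil_calibre Calibre for the Theil decomposition series and
#'   contribution table.
#' @param cross_section_year Year of the province-level HRDI table;
#'   default the panel's last year.
#' @param growth_mean `"geometric"` or `"arithmetic"`, see
#'   [average_growth()].
#' @param pop_unit,area_unit HRDI display units, see [hrdi()].
#' @return A list of class `report_bundle` with elements `status_quo`,
#'   `gini_series`, `hrdi_series`, `hrdi_cross_section`, `theil_series`,
#'   `contribution`, `trend_gini`, `trend_theil`, `trend_hrdi`,
#'   `metadata`.
#' @export
run_analysis <- function(panel, calibre = c("both", "population", "geography"),
                         theil_calibre = c("population", "geography"),
                         cross_section_year = NULL,
                         growth_mean = "geometric",
                         pop_unit = 1000, area_unit = 1) {
  panel <- as_resource_panel(panel)
  calibre <- match.arg(calibre)
  theil_calibre <- match.arg(theil_calibre)
  calibres <- if (calibre == "both") calibre_levels() else calibre
  combos <- tier_kind_combos()
  yr <- attr(panel, "year_range")
  if (is.null(cross_section_year)) cross_section_year <- yr[2]

  gini_all <- purrr::map_dfr(calibres, function(cal) {
    purrr::map_dfr(seq_len(nrow(combos)), function(i) {
      gini_series(panel, combos$tier[i], combos$kind[i], cal)
    })
  })
  theil_all <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    theil_series(panel, combos$tier[i], combos$kind[i], theil_calibre)
  })
  hrdi_all <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    hrdi_series(panel, combos$tier[i], combos$kind[i], pop_unit, area_unit)
  })

  sid <- function(...) paste(..., sep = ".")
  gini_bundle <- split(gini_all$gini,
                       sid(gini_all$calibre, gini_all$tier, gini_all$kind))
  theil_long <- tidyr::pivot_longer(
    theil_all[c("year", "tier", "kind", "T_total", "T_inter", "T_intra")],
    dplyr::all_of(c("T_total", "T_inter", "T_intra")),
    names_to = "component", values_to = "value")
  theil_bundle <- split(theil_long$value,
                        sid(theil_long$component, theil_long$tier, theil_long$kind))
  hrdi_bundle <- split(hrdi_all$hrdi,
                       sid(hrdi_all$scope, hrdi_all$tier, hrdi_all$kind))
  # splits keep year order within series because inputs are year-ordered
  structure(list(
    status_quo = status_quo_table(panel, growth_mean),
    gini_series = gini_all,
    hrdi_series = hrdi_all,
    hrdi_cross_section = hrdi_table(panel, cross_section_year, "province",
                                    pop_unit, area_unit),
    theil_series = theil_all,
    contribution = contribution_table(panel, theil_calibre),
    trend_gini = trend_table(gini_bundle),
    trend_theil = trend_table(theil_bundle),
    trend_hrdi = trend_table(hrdi_bundle),
    metadata = list(
      n_regions = length(unique(panel$region_id)),
      year_range = yr, calibres = calibres, theil_calibre = theil_calibre,
      cross_section_year = cross_section_year, growth_mean = growth_mean,
      pop_unit = pop_unit, area_unit = area_unit,
      generator = attr(panel, "generator"),
      version = as.character(utils::packageVersion("equipanel")))),
    class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<report_bundle> %d regions, %d-%d\n", md$n_regions,
              md$year_range[1], md$year_range[2]))
  cat(sprintf("  gini: %d series | theil: %d series | hrdi: %d series\n",
              nrow(x$trend_gini), nrow(x$trend_theil), nrow(x$trend_hrdi)))
  invisible(x)
}

#' Write a report bundle to CSV files plus a JSON manifest
#'
#' One CSV per table/series plus `manifest.json` (file list with md5
#' hashes, and the run metadata). Writing is byte-stable: re-running on
#' the same panel and configuration reproduces identical files.
#'
#' @param bundle A `report_bundle` from [run_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop_equipanel("io", paste0("cannot create output directory: ", out_dir))
  }
  tables <- c("status_quo", "gini_series", "hrdi_series",
              "hrdi_cross_section", "theil_series", "contribution",
              "trend_gini", "trend_theil", "trend_hrdi")
  files <- character(0)
  for (tb in tables) {
    path <- file.path(out_dir, paste0(tb, ".csv"))
    readr::write_csv(bundle[[tb]], path, progress = FALSE)
    files <- c(files, path)
  }
  manifest <- list(
    files = lapply(files, function(f) list(
      name = basename(f), md5 = unname(tools::md5sum(f)),
      rows = nrow(readr::read_csv(f, show_col_types = FALSE, progress = FALSE)))),
    metadata = bundle$metadata)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
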