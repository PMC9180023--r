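# Health resource density index: resources per geometric mean of
# population and area.

#' Health resource density index
#'
#' `HRDI = HR / sqrt((A / area_unit) * (P / pop_unit))`: the resource
#' quantity divided by the geometric mean of area and population, which
#' balances per-capita against per-area density and avoids the bias of
#' judging regions on either base alone. The index is homogeneous of
#' degree -1 in the joint scale of (A, P): scaling both by `c` divides
#' HRDI by `c`.
#'
#' Default display units are thousands of persons (`pop_unit = 1000`) and
#' square kilometres (`area_unit = 1`), i.e. resources per
#' sqrt(km^2 x 10^3 persons). The indices elsewhere in the package are
#' share-based and unit-free; units matter only here.
#'
#' @param resource Non-negative resource quantity (count).
#' @param area Positive land area (km^2).
#' @param population Positive population (persons).
#' @param pop_unit,area_unit Positive unit divisors applied before the
#'   geometric mean.
#' @return The density index (non-negative; 0 iff `resource` is 0).
#' @examples
#' hrdi(100, area = 25, population = 4, pop_unit = 1, area_unit = 1)  # 10
#' @export
hrdi <- function(resource, area, population, pop_unit = 1000, area_unit = 1) {
  if (any(resource < 0)) {
    stop_equipanel("domain", "resource quantity must be non-negative")
  }
  if (any(area <= 0) || any(population <= 0) || pop_unit <= 0 || area_unit <= 0) {
    stop_equipanel("domain", "area, population and units must be positive")
  }
  resource / sqrt((area / area_unit) * (population / pop_unit))
}

#' HRDI table for one year at province, zone or national level
#'
#' At zone and national level, resources, areas and populations are first
#' summed over members and the index is then applied to the sums. Note the
#' aggregate is *not* the mean of member indices.
#'
#' @param panel A `resource_panel`.
#' @param year Year within the panel's range.
#' @param level `"province"`, `"zone"` or `"national"`.
#' @param pop_unit,area_unit Display units, as in [hrdi()].
#' @return A tibble with `scope` (region id, zone, or `"national"`),
#'   `level`, `tier`, `kind`, `year`, `hrdi` -- one row per scope per valid
#'   tier-kind combination.
#' @export
hrdi_table <- function(panel, year, level = c("province", "zone", "national"),
                       pop_unit = 1000, area_unit = 1) {
  panel <- as_resource_panel(panel)
  level <- match.arg(level)
  yr <- attr(panel, "year_range")
  if (year < yr[1] || year > yr[2]) {
    stop_equipanel("range", sprintf(
      "year %s outside panel range [%d, %d]", year, yr[1], yr[2]))
  }
  rows <- panel[panel$year == year, ]
  groups <- switch(level,
    province = split(rows, rows$region_id),
    zone = split(rows, factor(rows$zone, intersect(zone_levels(),
                                                   unique(rows$zone)))),
    national = list(national = rows))
  combos <- tier_kind_combos()
  purrr::map_dfr(names(groups), function(g) {
    sub <- groups[[g]]
    tibble::tibble(
      scope = g, level = level,
      tier = combos$tier, kind = combos$kind, year = as.integer(year),
      hrdi = vapply(seq_len(nrow(combos)), function(i) {
        hrdi(sum(sub[[paste(combos$tier[i], combos$kind[i], sep = "_")]]),
             sum(sub$area_km2), sum(sub$population),
             pop_unit = pop_unit, area_unit = area_unit)
      }, 0))
  })
}

#' HRDI time series at zone and national level
#'
#' The data behind a zones-versus-national density plot: for each year,
#' the zone-level and national HRDI for one (tier, kind).
#'
#' @inheritParams hrdi_table
#' @param tier,kind Facility tier and resource kind.
#' @return A tibble: `scope`, `tier`, `kind`, `year`, `hrdi`, ascending in
#'   year within scope.
#' @export
hrdi_series <- function(panel, tier, kind, pop_unit = 1000, area_unit = 1) {
  panel <- as_resource_panel(panel)
  tk <- check_tier_kind(tier, kind)
  years <- sort(unique(panel$year))
  out <- purrr::map_dfr(years, function(y) {
    dplyr::bind_rows(
      hrdi_table(panel, y, "zone", pop_unit, area_unit),
      hrdi_table(panel, y, "national", pop_unit, area_unit))
  })
  out <- out[out$tier == tk$tier & out$kind == tk$kind, ]
  out <- out[order(match(out$scope, c(zone_levels(), "national")), out$year), ]
  out[, c("scope", "tier", "kind", "year", "hrdi")]
}
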