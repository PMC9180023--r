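# Region-year resource panels: data model, validation, I/O, slicing.

#' Facility tiers, resource kinds, calibres and zones
#'
#' The tiered system distinguishes county-level medical and health
#' institutions (`"cmhi"`), township hospitals (`"th"`) and village clinics
#' (`"vc"`). Resources come in three kinds: `"institution"` and `"bed"`
#' (capital) and `"personnel"` (labour). Village clinics carry no beds, so
#' there are eight valid tier-kind combinations. A calibre is the weighting
#' base an allocation is judged against: `"population"` or `"geography"`
#' (land area). Zones are the economic macro-regions grouping provinces;
#' the default scheme has `"eastern"`, `"central"` and `"western"`.
#'
#' @return Character vectors of the valid level names; `resource_columns()`
#'   returns the eight `tier_kind` column names of the panel CSV dialect.
#' @examples
#' tier_levels()
#' resource_columns()
#' @export
tier_levels <- function() c("cmhi", "th", "vc")

#' @rdname tier_levels
#' @export
kind_levels <- function() c("institution", "bed", "personnel")

#' @rdname tier_levels
#' @export
calibre_levels <- function() c("population", "geography")

#' @rdname tier_levels
#' @export
zone_levels <- function() c("eastern", "central", "western")

#' @rdname tier_levels
#' @export
resource_columns <- function() {
  combos <- tier_kind_combos()
  paste(combos$tier, combos$kind, sep = "_")
}

#' @rdname tier_levels
#' @export
tier_kind_combos <- function() {
  grid <- expand.grid(kind = kind_levels(), tier = tier_levels(),
                      stringsAsFactors = FALSE)[, c("tier", "kind")]
  grid <- grid[!(grid$tier == "vc" & grid$kind == "bed"), ]
  tibble::as_tibble(grid)
}

panel_columns <- function() {
  c("region_id", "zone", "year", "population", "area_km2", resource_columns())
}

#' Assemble and validate a resource panel
#'
#' A `resource_panel` is a tibble with one row per (region, year) and the
#' columns of the panel CSV dialect (see [resource_columns()]). Validation
#' enforces the contracts every downstream index relies on: positive
#' population and area, non-negative resource counts, unique (region, year)
#' pairs, and a balanced panel (every region observed in every year of the
#' range) -- regions appearing or disappearing mid-series are rejected
#' rather than silently imputed, because imputation would change every
#' index. Rows are stored in canonical order (year, then region id in C
#' locale), so file row order never affects results.
#'
#' @param x A data frame with the panel columns.
#' @return A validated `resource_panel` tibble, canonically ordered.
#' @examples
#' pan <- generate_panel(generator_config(n_provinces_per_zone =
#'   c(eastern = 2, central = 2, western = 2), years = 2003:2005), seed = 1)
#' as_resource_panel(pan)
#' @export
as_resource_panel <- function(x) {
  if (inherits(x, "resource_panel")) return(x)  # already validated
  x <- tibble::as_tibble(x)
  missing <- setdiff(panel_columns(), names(x))
  if (length(missing) > 0) {
    stop_equipanel("schema", paste0(
      "panel is missing column(s): ", paste(missing, collapse = ", ")))
  }
  x <- x[panel_columns()]
  x$region_id <- as.character(x$region_id)
  x$zone <- as.character(x$zone)
  x$year <- as.integer(x$year)

  bad_zone <- setdiff(unique(x$zone), zone_levels())
  if (length(bad_zone) > 0) {
    stop_equipanel("validation", paste0(
      "unknown zone label(s): ", paste(bad_zone, collapse = ", ")))
  }
  bad <- which(!is.finite(x$population) | x$population <= 0 |
                 !is.finite(x$area_km2) | x$area_km2 <= 0)
  if (length(bad) > 0) {
    stop_equipanel("validation", paste0(
      "population and area must be positive; offending (region, year): ",
      paste(sprintf("(%s, %d)", x$region_id[bad], x$year[bad]), collapse = ", ")))
  }
  for (col in resource_columns()) {
    v <- x[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      stop_equipanel("validation", paste0(
        "resource column ", col, " must be non-negative and complete"))
    }
  }
  key <- paste(x$region_id, x$year)
  if (anyDuplicated(key)) {
    stop_equipanel("validation", paste0(
      "duplicate (region, year) pair(s): ",
      paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  # balanced panel: every region in every year of the range
  years <- sort(unique(x$year))
  regions <- sort(unique(x$region_id), method = "radix")
  tab <- table(factor(x$region_id, regions), factor(x$year, years))
  if (any(tab != 1L)) {
    holes <- which(tab == 0L, arr.ind = TRUE)
    stop_equipanel("validation", paste0(
      "unbalanced panel; missing (region, year): ",
      paste(sprintf("(%s, %s)", regions[holes[, 1]], years[holes[, 2]]),
            collapse = ", ")))
  }
  # each zone label must be constant per region
  zmap <- unique(x[, c("region_id", "zone")])
  if (anyDuplicated(zmap$region_id)) {
    stop_equipanel("validation", "a region is assigned to more than one zone")
  }
  x <- x[order(x$year, x$region_id, method = "radix"), ]
  class(x) <- c("resource_panel", class(tibble::tibble()))
  attr(x, "year_range") <- range(years)
  x
}

#' Read / write a resource panel as CSV
#'
#' The dialect is UTF-8 CSV with a header row and columns `region_id, zone,
#' year, population, area_km2` plus the eight resource columns of
#' [resource_columns()]. A `vc_bed` column may be present only if entirely
#' empty (village clinics carry no beds). Row order in the file is
#' irrelevant: the panel is canonicalised on read, so
#' `write_panel(read_panel(f))` reproduces the record set exactly.
#'
#' @param path Path to a CSV file.
#' @param panel A `resource_panel`.
#' @return `read_panel()` a validated `resource_panel`; `write_panel()` the
#'   path, invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    stop_equipanel("schema", paste0("file not found: ", path))
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("vc_bed" %in% names(x)) {
    if (any(!is.na(x$vc_bed) & x$vc_bed != 0)) {
      stop_equipanel("validation",
        "vc_bed column present and non-empty: village clinics carry no beds")
    }
    x$vc_bed <- NULL
  }
  as_resource_panel(x)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  panel <- as_resource_panel(panel)
  readr::write_csv(panel, path, progress = FALSE)
  invisible(path)
}

#' @export
print.resource_panel <- function(x, ...) {
  yr <- attr(x, "year_range")
  cat(sprintf("<resource_panel> %d regions x %d years (%d-%d)\n",
              length(unique(x$region_id)), length(unique(x$year)),
              yr[1], yr[2]))
  NextMethod()
}

check_tier_kind <- function(tier, kind) {
  tier <- match.arg(tier, tier_levels())
  kind <- match.arg(kind, kind_levels())
  if (tier == "vc" && kind == "bed") {
    stop_equipanel("combination",
      "village clinics carry no beds: (vc, bed) is not a valid combination")
  }
  list(tier = tier, kind = kind)
}

#' Slice a panel into a single-year allocation vector
#'
#' An allocation vector is the cross-section every index consumes: one
#' entry per region with a measure `m` (population or area, by calibre) and
#' a resource quantity `e` for one (tier, kind) in one year. Entries are in
#' canonical region order so floating-point sums are reproducible.
#'
#' @param panel A `resource_panel`.
#' @param year Calendar year within the panel's range.
#' @param tier,kind Facility tier and resource kind (not `("vc", "bed")`).
#' @param calibre `"population"` or `"geography"`.
#' @return A tibble of class `hre_allocation` with columns `region_id`,
#'   `zone`, `m`, `e` and attributes `calibre`, `tier`, `kind`, `year`.
#' @examples
#' pan <- generate_panel(generator_config(), seed = 1)
#' slice_allocation(pan, 2003, "cmhi", "bed", "population")
#' @export
slice_allocation <- function(panel, year, tier, kind,
                             calibre = c("population", "geography")) {
  panel <- as_resource_panel(panel)
  tk <- check_tier_kind(tier, kind)
  calibre <- match.arg(calibre)
  yr <- attr(panel, "year_range")
  if (year < yr[1] || year > yr[2] || !(year %in% panel$year)) {
    stop_equipanel("range", sprintf(
      "year %s outside panel range [%d, %d]", year, yr[1], yr[2]))
  }
  rows <- panel[panel$year == year, ]
  out <- tibble::tibble(
    region_id = rows$region_id,
    zone = rows$zone,
    m = if (calibre == "population") rows$population else rows$area_km2,
    e = rows[[paste(tk$tier, tk$kind, sep = "_")]]
  )
  new_allocation(out, calibre = calibre, tier = tk$tier, kind = tk$kind,
                 year = as.integer(year))
}

new_allocation <- function(entries, calibre, tier, kind, year = NA_integer_) {
  entries <- tibble::as_tibble(entries)
  if (any(entries$m <= 0) || !all(is.finite(entries$m))) {
    stop_equipanel("validation", "allocation measures must all be positive")
  }
  if (any(entries$e < 0)) {
    stop_equipanel("validation", "allocation resources must be non-negative")
  }
  entries <- entries[order(entries$region_id, method = "radix"), ]
  structure(entries,
            class = c("hre_allocation", class(tibble::tibble())),
            calibre = calibre, tier = tier, kind = kind, year = year)
}

#' Construct an allocation vector directly
#'
#' Mostly useful for worked examples and tests; analysis code normally goes
#' through [slice_allocation()].
#'
#' @param m Positive measure per region (population or area).
#' @param e Non-negative resource quantity per region.
#' @param zone Zone label per region (recycled if length 1).
#' @param region_id Region identifiers; defaults to `r01, r02, ...`.
#' @param calibre,tier,kind,year Metadata carried along to results.
#' @return An `hre_allocation` tibble.
#' @export
allocation <- function(m, e, zone = "eastern", region_id = NULL,
                       calibre = "population", tier = "cmhi",
                       kind = "institution", year = NA_integer_) {
  n <- length(m)
  stopifnot(length(e) == n)
  if (is.null(region_id)) region_id <- sprintf("r%02d", seq_len(n))
  new_allocation(
    tibble::tibble(region_id = region_id, zone = rep_len(zone, n), m = m, e = e),
    calibre = calibre, tier = tier, kind = kind, year = year)
}

#' Aggregate an allocation to zone totals
#'
#' Sums the measure and resource columns over zone members (in canonical
#' region order, so totals are reproducible). Feeds the between-zone term
#' of the Theil decomposition and zone-level HRDI.
#'
#' @param alloc An `hre_allocation`.
#' @return A tibble with one row per zone: `zone`, `M_g`, `E_g`, ordered by
#'   the canonical zone levels then alphabetically for any other labels.
#' @export
aggregate_zones <- function(alloc) {
  zones <- unique(alloc$zone)
  known <- intersect(zone_levels(), zones)
  zones <- c(known, sort(setdiff(zones, known), method = "radix"))
  tibble::tibble(
    zone = zones,
    M_g = vapply(zones, function(z) sum(alloc$m[alloc$zone == z]), 0,
                 USE.NAMES = FALSE),
    E_g = vapply(zones, function(z) sum(alloc$e[alloc$zone == z]), 0,
                 USE.NAMES = FALSE)
  )
}
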