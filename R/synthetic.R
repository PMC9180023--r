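# Synthetic province-panel generator: lognormal populations/areas with
# zone-level structure, lognormal resource densities with persistent
# province effects, iid year noise, and optional drifts.

#' Generator configuration for synthetic resource panels
#'
#' The generator emulates a provincial yearbook panel: ~31 provinces in
#' three economic zones observed over 18 years. Populations and areas are
#' lognormal with zone-specific location shifts (the eastern zone dense
#' and small, the western sparse and large); resource densities (counts
#' per person) are lognormal around a per-tier-kind base with a zone
#' offset, a persistent province effect of scale `within_sigma`, iid
#' year-level noise of scale `year_sigma`, and optional per-year drifts.
#' Counts are rounded to integers with a floor of 1 wherever the base
#' density is positive (yearbook semantics); `continuous = TRUE` disables
#' rounding for exactness tests.
#'
#' Resource count for province i, year t:
#' `round(density_base * exp(zone_offset + eta_i(t) + eps_it + trend * (t - t0)) * P_i)`
#' where `eta_i(t) = z_i * (within_sigma + inequality_drift * (t - t0))`
#' with `z_i ~ N(0, 1)` fixed per province (so series are smooth and a
#' positive `inequality_drift` widens the cross-section over time), and
#' `eps_it ~ N(0, year_sigma^2)` iid (so index series fluctuate
#' exchangeably under the null).
#'
#' @param n_provinces_per_zone Named integer vector, provinces per zone.
#' @param years Integer vector of calendar years (consecutive).
#' @param pop_lognormal,area_lognormal `c(meanlog, sdlog)` for province
#'   population (persons) and area (km^2).
#' @param pop_zone_shift,area_zone_shift Named per-zone shifts added to the
#'   respective `meanlog`.
#' @param density_base Named per-tier-kind base densities (counts per
#'   person), names as [resource_columns()].
#' @param zone_offsets Named per-zone log-density shifts.
#' @param within_sigma Province-level log-density dispersion (>= 0).
#' @param year_sigma Year-level iid log-density noise (>= 0).
#' @param trend Per-tier-kind log-density drift per year (named, recycled).
#' @param inequality_drift Per-year growth of the province-effect scale.
#' @param continuous If `TRUE`, keep fractional counts (no rounding/floor).
#' @param seed Default RNG seed used by [generate_panel()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    n_provinces_per_zone = c(eastern = 11, central = 8, western = 12),
    years = 2003:2020,
    pop_lognormal = c(meanlog = log(4e7), sdlog = 0.8),
    area_lognormal = c(meanlog = log(2e5), sdlog = 1.0),
    pop_zone_shift = c(eastern = 0.3, central = 0, western = -0.3),
    area_zone_shift = c(eastern = -0.6, central = 0, western = 0.8),
    density_base = c(cmhi_institution = 1e-5, cmhi_bed = 2e-3,
                     cmhi_personnel = 3e-3, th_institution = 3e-5,
                     th_bed = 1e-3, th_personnel = 1.2e-3,
                     vc_institution = 5e-4, vc_personnel = 1e-3),
    zone_offsets = c(eastern = 0.3, central = 0, western = -0.3),
    within_sigma = 0.3,
    year_sigma = 0.05,
    trend = 0,
    inequality_drift = 0,
    continuous = FALSE,
    seed = 20030101) {
  zones <- names(n_provinces_per_zone)
  if (is.null(zones) || any(n_provinces_per_zone < 1)) {
    stop_equipanel("config", "n_provinces_per_zone must be a named vector of positive counts")
  }
  cols <- resource_columns()
  if (!all(cols %in% names(density_base)) || any(density_base < 0)) {
    stop_equipanel("config", "density_base must name every tier-kind combination, non-negative")
  }
  if (length(trend) == 1 && is.null(names(trend))) {
    trend <- setNames(rep(trend, length(cols)), cols)
  }
  if (!all(cols %in% names(trend))) {
    stop_equipanel("config", "trend must be a scalar or name every tier-kind combination")
  }
  if (within_sigma < 0 || year_sigma < 0) {
    stop_equipanel("config", "noise scales must be non-negative")
  }
  if (!all(zones %in% names(zone_offsets)) ||
      !all(zones %in% names(pop_zone_shift)) ||
      !all(zones %in% names(area_zone_shift))) {
    stop_equipanel("config", "zone_offsets and zone shifts must cover every zone")
  }
  structure(list(
    n_provinces_per_zone = n_provinces_per_zone, years = as.integer(years),
    pop_lognormal = pop_lognormal, area_lognormal = area_lognormal,
    pop_zone_shift = pop_zone_shift, area_zone_shift = area_zone_shift,
    density_base = density_base[cols], zone_offsets = zone_offsets,
    within_sigma = within_sigma, year_sigma = year_sigma,
    trend = trend[cols], inequality_drift = inequality_drift,
    continuous = continuous, seed = seed), class = "generator_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Generate a synthetic resource panel
#'
#' Deterministic given `seed`: the same (config, seed) pair always yields a
#' bit-identical panel. The config's md5 hash is recorded in the panel's
#' `generator` attribute.
#'
#' @param config A [generator_config()].
#' @param seed RNG seed; defaults to the config's.
#' @return A validated `resource_panel`.
#' @examples
#' pan <- generate_panel(generator_config(), seed = 1)
#' dim(pan)  # 31 provinces x 18 years
#' @export
generate_panel <- function(config = generator_config(), seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  zones <- names(config$n_provinces_per_zone)
  zone_of <- rep(zones, config$n_provinces_per_zone)
  n <- length(zone_of)
  yrs <- config$years
  t0 <- min(yrs)
  cols <- resource_columns()

  panel <- withr::with_seed(seed, {
    region_id <- sprintf("p%02d", seq_len(n))
    pop <- rlnorm(n, config$pop_lognormal[["meanlog"]] +
                    config$pop_zone_shift[zone_of],
                  config$pop_lognormal[["sdlog"]])
    area <- rlnorm(n, config$area_lognormal[["meanlog"]] +
                     config$area_zone_shift[zone_of],
                   config$area_lognormal[["sdlog"]])
    grid <- tidyr::expand_grid(year = yrs,
                               idx = seq_len(n))
    out <- tibble::tibble(
      region_id = region_id[grid$idx], zone = zone_of[grid$idx],
      year = grid$year, population = pop[grid$idx],
      area_km2 = area[grid$idx])
    dt <- out$year - t0
    for (col in cols) {
      z <- rnorm(n)                       # persistent province effect
      eps <- rnorm(nrow(out), 0, config$year_sigma)
      sigma_t <- config$within_sigma + config$inequality_drift * dt
      logdev <- config$zone_offsets[out$zone] + z[grid$idx] * sigma_t +
        eps + config$trend[[col]] * dt
      cnt <- config$density_base[[col]] * exp(logdev) * out$population
      if (!config$continuous && config$density_base[[col]] > 0) {
        cnt <- pmax(round(cnt), 1)
      }
      out[[col]] <- unname(cnt)
    }
    out
  })
  panel <- as_resource_panel(panel)
  attr(panel, "generator") <- list(seed = seed, config_md5 = config_hash(config))
  panel
}

#' Two-region allocation with closed-form Gini and Theil
#'
#' A minimal oracle instance: two regions holding measure shares
#' `(p, 1 - p)` and resource shares `(s, 1 - s)`. Closed forms:
#' `G = |s - p|` and, for `0 < s < 1`,
#' `T = p log(p/s) + (1 - p) log((1 - p)/(1 - s))`.
#'
#' @param p Measure share of the first region, in (0, 1).
#' @param s Resource share of the first region, in `[0, 1]`.
#' @return An `hre_allocation` with two entries in different zones.
#' @examples
#' gini(generate_two_block(0.5, 0.25))  # G = 0.25
#' @export
generate_two_block <- function(p, s) {
  if (!is.finite(p) || p <= 0 || p >= 1 || !is.finite(s) || s < 0 || s > 1) {
    stop_equipanel("domain", "need 0 < p < 1 and 0 <= s <= 1")
  }
  allocation(m = c(p, 1 - p), e = c(s, 1 - s),
             zone = c("eastern", "western"))
}

#' Inject a monotone trend into a panel's index series
#'
#' Deterministically reshapes a panel so that a named index rises or falls
#' over the years. For `"gini"` and `"theil"` the log-density deviations
#' of each year's cross-section are widened (or narrowed) by a factor
#' growing linearly in time, which makes the dispersion indices
#' stochastically monotone; for `"hrdi"` all counts are drifted by
#' `exp(direction * strength * (t - t0))`. `direction = 0` returns the
#' panel unchanged.
#'
#' @param panel A `resource_panel`.
#' @param target `"gini"`, `"theil"` or `"hrdi"`.
#' @param direction Sign of the requested trend: `+1`, `-1` or `0`.
#' @param strength Per-year relative change of the dispersion factor
#'   (gini/theil) or of the resource level (hrdi).
#' @return A `resource_panel` with the same regions, years and
#'   population/area columns.
#' @export
inject_trend <- function(panel, target = c("gini", "theil", "hrdi"),
                         direction, strength = 0.05) {
  panel <- as_resource_panel(panel)
  target <- match.arg(target)
  direction <- sign(direction)
  if (direction == 0) return(panel)
  t0 <- min(panel$year)
  dt <- panel$year - t0
  for (col in resource_columns()) {
    e <- panel[[col]]
    if (target == "hrdi") {
      newe <- e * exp(direction * strength * dt)
    } else {
      if (any(e <= 0)) {
        stop_equipanel("domain",
          "dispersion injection needs strictly positive counts")
      }
      d <- log(e / panel$population)
      # widen/narrow each year's cross-section about its mean log-density
      newd <- d
      for (y in unique(panel$year)) {
        sel <- panel$year == y
        f <- max(1 + direction * strength * (y - t0), 0.05)
        newd[sel] <- mean(d[sel]) + f * (d[sel] - mean(d[sel]))
      }
      newe <- exp(newd) * panel$population
    }
    panel[[col]] <- pmax(round(newe), 1)
  }
  as_resource_panel(panel)
}
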