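# Theil index and its between-zone / within-zone decomposition.

#' Theil index of an allocation
#'
#' The measure-weighted mean log deviation
#' `T = sum_i (m_i/M) * log((m_i/M) / (e_i/E))` (natural log). `T = 0` iff
#' resource shares are proportional to measure shares; larger values mean
#' less equitable allocation. Regions with zero resources make the index
#' diverge, so they raise an error naming the offending regions rather
#' than being silently dropped or patched with an epsilon (exclusion
#' changes every share; see [drop_zero_resources()] for an explicit
#' filter).
#'
#' @param alloc An `hre_allocation`.
#' @return `theil_total()`: the index (non-negative scalar).
#'   `theil_index()`: the same from bare measure/resource vectors.
#' @examples
#' theil_index(c(1, 1), c(1, 3))  # 0.5*log(2) + 0.5*log(2/3)
#' @export
theil_total <- function(alloc) theil_index(alloc$m, alloc$e, alloc$region_id)

#' @rdname theil_total
#' @param m Positive measures per region.
#' @param e Resource quantities per region; all must be positive.
#' @param region_id Optional labels used in the zero-resource error.
#' @export
theil_index <- function(m, e, region_id = NULL) {
  if (any(m <= 0)) stop_equipanel("validation", "measures must be positive")
  zero <- which(e <= 0)
  if (length(zero) > 0) {
    who <- if (is.null(region_id)) paste0("#", zero) else region_id[zero]
    stop_equipanel("zero_resource", paste0(
      "Theil index diverges for zero-resource region(s): ",
      paste(who, collapse = ", ")))
  }
  w <- m / sum(m)
  s <- e / sum(e)
  sum(w * log(w / s))
}

#' Decompose the Theil index into between-zone and within-zone parts
#'
#' `T_inter` is the Theil index of the zone totals; `T_intra` is the
#' measure-weighted sum of the within-zone Theil indices, computed with
#' zone-internal shares. The decomposition is exact:
#' `T_total = T_inter + T_intra`. Contribution rates are the shares
#' `T_intra / T_total` and `T_inter / T_total`; for a perfectly
#' proportional allocation (`T_total = 0`) there is no inequity to
#' apportion and the within-zone contribution is reported as 1 by
#' convention.
#'
#' @param alloc An `hre_allocation`.
#' @return A list of class `theil_decomposition`: `T_total`, `T_inter`,
#'   `T_intra`, `per_zone` (tibble: `zone`, `weight` = M_g/M, `T_g`),
#'   `contrib_intra`, `contrib_inter`, plus the allocation metadata.
#' @examples
#' al <- allocation(m = c(1, 1, 2), e = c(0.5, 1.5, 2),
#'                  zone = c("eastern", "eastern", "western"))
#' theil_decompose(al)
#' @export
theil_decompose <- function(alloc) {
  T_total <- theil_total(alloc)
  groups <- aggregate_zones(alloc)
  M <- sum(alloc$m)
  T_inter <- theil_index(groups$M_g, groups$E_g, groups$zone)
  per_zone <- tibble::tibble(
    zone = groups$zone,
    weight = groups$M_g / M,
    T_g = vapply(groups$zone, function(z) {
      sel <- alloc$zone == z
      theil_index(alloc$m[sel], alloc$e[sel], alloc$region_id[sel])
    }, 0, USE.NAMES = FALSE))
  T_intra <- sum(per_zone$weight * per_zone$T_g)
  if (T_total > .theil_zero_tol) {
    ci <- T_intra / T_total
  } else {
    ci <- 1
  }
  structure(list(
    T_total = T_total, T_inter = T_inter, T_intra = T_intra,
    per_zone = per_zone, contrib_intra = ci, contrib_inter = 1 - ci,
    year = attr(alloc, "year"), tier = attr(alloc, "tier"),
    kind = attr(alloc, "kind"), calibre = attr(alloc, "calibre")),
    class = "theil_decomposition")
}

# below this, an allocation is treated as exactly proportional
.theil_zero_tol <- 1e-12

#' @export
print.theil_decomposition <- function(x, ...) {
  cat(sprintf("<theil_decomposition> T_total = %.6f (inter %.6f + intra %.6f)\n",
              x$T_total, x$T_inter, x$T_intra))
  cat(sprintf("  within-zone contribution: %.2f%%\n", 100 * x$contrib_intra))
  invisible(x)
}

#' Drop zero-resource regions from an allocation, with a message
#'
#' An explicit preprocessing filter for users who want the Theil index on
#' the supported sub-panel. Exclusion changes all shares, so it is never
#' done implicitly.
#'
#' @param alloc An `hre_allocation`.
#' @return The filtered allocation; messages the dropped region ids.
#' @export
drop_zero_resources <- function(alloc) {
  drop <- alloc$e <= 0
  if (any(drop)) {
    message("dropping zero-resource region(s): ",
            paste(alloc$region_id[drop], collapse = ", "))
    kept <- alloc[!drop, ]
    alloc <- new_allocation(kept, calibre = attr(alloc, "calibre"),
                            tier = attr(alloc, "tier"),
                            kind = attr(alloc, "kind"),
                            year = attr(alloc, "year"))
  }
  alloc
}

#' Theil decomposition series over a panel
#'
#' @inheritParams slice_allocation
#' @return A tibble with one row per year: `year`, `tier`, `kind`,
#'   `calibre`, `T_total`, `T_inter`, `T_intra`, `contrib_intra`,
#'   `contrib_inter`, and one `T_<zone>` column per zone.
#' @export
theil_series <- function(panel, tier, kind, calibre = c("population", "geography")) {
  panel <- as_resource_panel(panel)
  calibre <- match.arg(calibre)
  years <- sort(unique(panel$year))
  dplyr::bind_rows(lapply(years, function(y) {
    d <- theil_decompose(slice_allocation(panel, y, tier, kind, calibre))
    row <- tibble::tibble(
      year = y, tier = d$tier, kind = d$kind, calibre = d$calibre,
      T_total = d$T_total, T_inter = d$T_inter, T_intra = d$T_intra,
      contrib_intra = d$contrib_intra, contrib_inter = d$contrib_inter)
    for (i in seq_len(nrow(d$per_zone))) {
      row[[paste0("T_", d$per_zone$zone[i])]] <- d$per_zone$T_g[i]
    }
    row
  }))
}

#' Within-zone contribution table
#'
#' `contribution_table()` computes, for every year and every valid
#' (tier, kind) combination, the within-zone share of total inequity
#' `100 * T_intra / T_total`, then appends the column means.
#' `format_contribution_table()` is the formatting half: it takes an
#' already-computed year-by-combination percentage table, appends the mean
#' row, and rounds everything to two decimals.
#'
#' @param panel A `resource_panel`.
#' @param calibre Weighting base; within-zone/between-zone reporting
#'   defaults to the population calibre.
#' @return A tibble with a `year` column (character; last row `"mean"`) and
#'   one 2-decimal percentage column per tier-kind combination.
#' @export
contribution_table <- function(panel, calibre = c("population", "geography")) {
  panel <- as_resource_panel(panel)
  calibre <- match.arg(calibre)
  combos <- tier_kind_combos()
  years <- sort(unique(panel$year))
  cols <- lapply(seq_len(nrow(combos)), function(i) {
    vapply(years, function(y) {
      d <- theil_decompose(slice_allocation(panel, y, combos$tier[i],
                                            combos$kind[i], calibre))
      100 * d$contrib_intra
    }, 0)
  })
  tbl <- tibble::as_tibble(setNames(cols, paste(combos$tier, combos$kind, sep = "_")))
  tbl <- dplyr::bind_cols(tibble::tibble(year = years), tbl)
  format_contribution_table(tbl)
}

#' @rdname contribution_table
#' @param yearly A tibble with a `year` column and numeric percentage
#'   columns, one row per year.
#' @export
format_contribution_table <- function(yearly) {
  yearly <- tibble::as_tibble(yearly)
  stopifnot("year" %in% names(yearly))
  vals <- yearly[setdiff(names(yearly), "year")]
  mean_row <- dplyr::summarise(vals, dplyr::across(dplyr::everything(),
                                                   ~ mean(.x)))
  out <- dplyr::bind_rows(vals, mean_row)
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), ~ round(.x, 2)))
  dplyr::bind_cols(
    tibble::tibble(year = c(as.character(yearly$year), "mean")), out)
}
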