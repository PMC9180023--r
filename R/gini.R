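# Lorenz curves and the trapezoid Gini coefficient on grouped data.

#' Lorenz curve of an allocation
#'
#' Regions are sorted ascending by resource density `e/m` (ties broken by
#' region id), then cumulative measure shares X and cumulative resource
#' shares Y are formed and prefixed with the origin (0, 0). With this
#' ordering the curve is convex and lies on or below the diagonal; a
#' proportional allocation lies exactly on it.
#'
#' @param alloc An `hre_allocation` (see [slice_allocation()], [allocation()]).
#' @return A tibble with columns `x`, `y`; first row (0, 0), last (1, 1).
#' @examples
#' lorenz_curve(allocation(m = c(1, 1), e = c(0, 1)))
#' @export
lorenz_curve <- function(alloc) {
  if (sum(alloc$e) <= 0) {
    stop_equipanel("degenerate",
      "all resource quantities are zero: Lorenz curve undefined")
  }
  ord <- order(alloc$e / alloc$m, alloc$region_id, method = "radix")
  m <- alloc$m[ord]
  e <- alloc$e[ord]
  tibble::tibble(x = c(0, cumsum(m) / sum(m)),
                 y = c(0, cumsum(e) / sum(e)))
}

#' Trapezoid Gini coefficient with fairness banding
#'
#' Computes `G = 1 - sum_i (X_i - X_{i-1}) (Y_i + Y_{i-1})` on the sorted
#' Lorenz curve -- the grouped-data trapezoid rule, equal to the
#' measure-weighted relative mean absolute difference of regional
#' densities. `G = 0` is perfect equity; `classify_gini()` maps G onto the
#' conventional fairness bands: below 0.3 optimal, 0.3-0.4 normal, 0.4-0.5
#' gap, 0.5-0.6 alert, 0.6 and above danger (intervals closed on the left
#' so every G maps to exactly one band).
#'
#' @param alloc An `hre_allocation`.
#' @return `gini()`: a one-row tibble with `gini`, `band` and the
#'   allocation's `calibre`, `tier`, `kind`, `year`. `gini_index()`: the
#'   bare coefficient from measure/resource vectors. `classify_gini()`: a
#'   character band label (vectorised).
#' @examples
#' gini(allocation(m = c(1, 1), e = c(0, 1)))           # G = 0.5
#' gini_index(c(0.25, 0.25, 0.5), c(0.1, 0.2, 0.7))     # 0.225
#' classify_gini(c(0.169, 0.55))
#' @export
gini <- function(alloc) {
  g <- gini_index(alloc$m, alloc$e)
  tibble::tibble(
    year = attr(alloc, "year"), tier = attr(alloc, "tier"),
    kind = attr(alloc, "kind"), calibre = attr(alloc, "calibre"),
    gini = g, band = classify_gini(g))
}

#' @rdname gini
#' @param m Positive measures (population or area) per region.
#' @param e Non-negative resource quantities per region.
#' @export
gini_index <- function(m, e) {
  if (any(m <= 0)) stop_equipanel("validation", "measures must be positive")
  if (any(e < 0)) stop_equipanel("validation", "resources must be non-negative")
  if (sum(e) <= 0) {
    stop_equipanel("degenerate",
      "all resource quantities are zero: Gini undefined")
  }
  ord <- order(e / m, method = "radix")
  x <- cumsum(m[ord]) / sum(m)
  y <- cumsum(e[ord]) / sum(e)
  1 - sum(diff(c(0, x)) * (y + c(0, y[-length(y)])))
}

#' @rdname gini
#' @param G Gini coefficient(s) in `[0, 1)`.
#' @export
classify_gini <- function(G) {
  if (any(!is.finite(G) | G < 0 | G >= 1)) {
    stop_equipanel("domain", "Gini coefficient must lie in [0, 1)")
  }
  bands <- c("optimal", "normal", "gap", "alert", "danger")
  bands[findInterval(G, c(0, 0.3, 0.4, 0.5, 0.6))]
}

#' Gini coefficient series over a panel
#'
#' One Gini per year for a fixed (tier, kind, calibre), in ascending year
#' order -- the data behind a time-series fairness plot.
#'
#' @inheritParams slice_allocation
#' @return A tibble with one row per year: `year`, `tier`, `kind`,
#'   `calibre`, `gini`, `band`.
#' @export
gini_series <- function(panel, tier, kind, calibre = c("population", "geography")) {
  panel <- as_resource_panel(panel)
  calibre <- match.arg(calibre)
  years <- sort(unique(panel$year))
  dplyr::bind_rows(lapply(years, function(y) {
    gini(slice_allocation(panel, y, tier, kind, calibre))
  }))
}
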