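# Independent oracles and fixture builders, deliberately written as naive
# brute force so they share no code path with the implementation.

# Gini as the measure-weighted relative mean absolute difference of
# densities: sum_ij w_i w_j |d_i - d_j| / (2 dbar).
gini_mean_difference <- function(m, e) {
  w <- m / sum(m)
  d <- e / m
  dbar <- sum(w * d)
  sum(outer(w, w) * abs(outer(d, d, "-"))) / (2 * dbar)
}

# Theil decomposition by direct per-group evaluation of the defining sums.
theil_brute <- function(m, e, zone) {
  M <- sum(m); E <- sum(e)
  total <- sum((m / M) * log((m / M) / (e / E)))
  inter <- 0; intra <- 0
  for (z in unique(zone)) {
    sel <- zone == z
    Mg <- sum(m[sel]); Eg <- sum(e[sel])
    inter <- inter + (Mg / M) * log((Mg / M) / (Eg / E))
    intra <- intra + sum((m[sel] / M) * log((m[sel] / Mg) / (e[sel] / Eg)))
  }
  list(total = total, inter = inter, intra = intra)
}

# Mann-Kendall S by explicit pair enumeration.
mk_s_brute <- function(x) {
  s <- 0L
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  }
  as.integer(s)
}

# All permutations of 1..n (recursive; only used at tiny n).
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

random_allocation <- function(n = 31, zones = c("eastern", "central", "western"),
                              zero_ok = FALSE) {
  m <- exp(rnorm(n, 0, 1))
  e <- exp(rnorm(n, 0, 1))
  if (zero_ok && n > 2) e[sample(n, 1)] <- 0
  allocation(m = m, e = e, zone = sample(rep_len(zones, n)))
}

# a tiny well-formed panel data frame (2 zones, balanced)
small_panel_df <- function(years = 2003:2004) {
  grid <- expand.grid(region_id = c("ra", "rb", "rc"), year = years,
                      stringsAsFactors = FALSE)
  df <- data.frame(
    region_id = grid$region_id,
    zone = c(ra = "eastern", rb = "eastern", rc = "western")[grid$region_id],
    year = grid$year,
    population = c(ra = 1e6, rb = 2e6, rc = 3e6)[grid$region_id],
    area_km2 = c(ra = 5e4, rb = 4e4, rc = 9e4)[grid$region_id])
  for (col in resource_columns()) {
    df[[col]] <- seq_len(nrow(df)) * 10 + nchar(col)
  }
  df
}
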