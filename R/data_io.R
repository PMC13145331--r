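#' Fill missing counts by linear interpolation
#'
#' Interior gaps in each site's annual count series are filled by linear
#' interpolation between the nearest observed years and rounded to the nearest
#' integer (half-up); leading and trailing gaps are filled with the nearest
#' observed value, so no extrapolation beyond the observed range is attempted.
#'
#' @param counts Numeric matrix, sites in rows and years in columns; `NA`
#'   marks a missing count. A vector is treated as a single site.
#' @return Matrix (or vector) of the same shape with no missing cells.
#' @export
interpolate_counts <- function(counts) {
  vec <- is.null(dim(counts))
  m <- if (vec) matrix(counts, nrow = 1) else as.matrix(counts)
  if (ncol(m) < 1L) stop("count series needs at least one year")
  site_names <- rownames(m)
  if (is.null(site_names)) site_names <- as.character(seq_len(nrow(m)))
  yrs <- seq_len(ncol(m))
  for (s in seq_len(nrow(m))) {
    obs <- which(!is.na(m[s, ]))
    if (length(obs) == 0L) {
      stop("site '", site_names[s], "' has no observed counts")
    }
    if (any(m[s, obs] < 0)) {
      stop("site '", site_names[s], "' has negative counts")
    }
    if (length(obs) == 1L) {
      m[s, ] <- round_half_up(m[s, obs])
    } else if (length(obs) < ncol(m)) {
      filled <- stats::approx(x = obs, y = m[s, obs], xout = yrs,
                              method = "linear", rule = 2)$y
      m[s, ] <- round_half_up(filled)
    }
  }
  if (vec) drop(m) else m
}

#' Convert total counts to female counts
#'
#' The modelled population is female-only; assuming an even sex ratio, total
#' counts are halved and rounded half-up.
#'
#' @param count Non-negative numeric vector of total counts.
#' @return Integer-valued vector of female counts.
#' @export
female_counts <- function(count) {
  if (any(is.na(count)) || any(count < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  round_half_up(count / 2)
}

#' Pooled age ratio for a set of sites
#'
#' Combines site-level juvenile:adult age ratios into a single ratio for a
#' pooled group, weighting each site by its total count.
#'
#' @param ratios Non-negative numeric vector of site age ratios.
#' @param weights Non-negative numeric vector of site counts (weights).
#' @return Weighted mean ratio.
#' @export
elsewhere_age_ratio <- function(ratios, weights) {
  if (length(ratios) != length(weights)) stop("ratios and weights differ in length")
  if (any(is.na(ratios)) || any(is.na(weights))) stop("missing values not allowed")
  if (any(ratios < 0) || any(weights < 0)) stop("ratios and weights must be non-negative")
  if (sum(weights) <= 0) stop("weights are all zero")
  sum(weights * ratios) / sum(weights)
}

#' Juvenile count implied by an age ratio
#'
#' Splits a total female count into juveniles using the juvenile:adult ratio
#' r, i.e. juveniles = total * r / (1 + r), rounded half-up, so that the
#' implied juvenile:adult ratio of the split equals r.
#'
#' @param ratio Non-negative juvenile:adult ratio.
#' @param total_females Non-negative total female count.
#' @return Integer juvenile count.
#' @export
juveniles_from_ratio <- function(ratio, total_females) {
  if (any(ratio < 0) || any(total_females < 0)) stop("inputs must be non-negative")
  round_half_up(total_females * ratio / (1 + ratio))
}

#' Cumulative growing degree days
#'
#' Sum of daily mean temperature excess above a base temperature, a standard
#' proxy for vegetation phenology.
#'
#' @param temps Daily mean temperatures (degrees C).
#' @param base Base temperature (degrees C), default 0.
#' @param window Optional integer index vector selecting days.
#' @return Cumulative GDD (degree-days).
#' @export
growing_degree_days <- function(temps, base = 0, window = NULL) {
  if (!is.null(window)) temps <- temps[window]
  if (length(temps) == 0L) stop("empty window")
  sum(pmax(temps - base, 0))
}

#' Cumulative snowfall
#'
#' Total precipitation on days whose mean temperature is below a snow
#' threshold; used as the cumulative-snow covariate on breeding areas.
#'
#' @param precip Daily precipitation (mm).
#' @param temps Daily mean temperatures (degrees C), aligned with `precip`.
#' @param snow_temp Temperature threshold below which precipitation is
#'   counted as snow (degrees C), default 0.
#' @param window Optional integer index vector selecting days.
#' @return Cumulative snowfall (mm).
#' @export
cumulative_snow <- function(precip, temps, snow_temp = 0, window = NULL) {
  if (length(precip) != length(temps)) stop("precipitation and temperature series are misaligned")
  if (!is.null(window)) {
    precip <- precip[window]
    temps <- temps[window]
  }
  if (length(precip) == 0L) stop("empty window")
  sum(precip[temps < snow_temp])
}

#' Count severe storm days
#'
#' Number of days whose minimum barometric pressure falls below a severe-storm
#' threshold during a migration window.
#'
#' @param pressure Daily minimum pressure (hPa).
#' @param threshold Pressure threshold (hPa), default 980.
#' @param window Optional integer index vector selecting days.
#' @return Integer count of storm days.
#' @export
storm_days <- function(pressure, threshold = 980, window = NULL) {
  if (!is.null(window)) pressure <- pressure[window]
  if (length(pressure) == 0L) stop("empty window")
  sum(pressure < threshold)
}

#' Hunting-protection period index
#'
#' Maps a calendar year to the hunting-protection regime in force:
#' 0 for 1983-2005 (protection on the wintering range only), 1 for 2006-2008
#' (additional protection on staging areas) and 2 for 2009-2022 (additional
#' protection on staging and breeding areas).
#'
#' @param winter_year Integer calendar year(s), 1983-2022.
#' @return Integer vector of period indices in `{0, 1, 2}`.
#' @export
hunting_period <- function(winter_year) {
  if (any(winter_year < 1983 | winter_year > 2022)) {
    stop("year outside the 1983-2022 study span")
  }
  ifelse(winter_year >= 2009, 2L, ifelse(winter_year >= 2006, 1L, 0L))
}

#' Standardize a covariate series
#'
#' Centers and scales to unit standard deviation; a constant series maps to
#' all zeros so that degenerate covariates drop out of linear predictors.
#'
#' @param series Numeric vector, length at least 2.
#' @return Standardized vector (mean 0, sd 1 unless constant).
#' @export
standardize <- function(series) {
  if (length(series) < 2L) stop("need at least two values to standardize")
  # population (n-denominator) standard deviation
  s <- sqrt(mean((series - mean(series))^2))
  if (!is.finite(s) || s == 0) return(rep(0, length(series)))
  (series - mean(series)) / s
}

# ---- CSV readers (External Interfaces) --------------------------------------

#' Read a site table
#'
#' `sites.csv` must have columns `site`, `group` (one of [imm_groups()]) and
#' optionally region identifiers for weather series.
#' @param path CSV path.
#' @return data.frame of sites.
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "group")
  if (!all(need %in% names(df))) stop("sites.csv needs columns: site, group")
  if (!all(df$group %in% imm_groups())) stop("unknown group code in sites.csv")
  if (anyDuplicated(df$site)) stop("each site must map to exactly one group")
  df
}

#' Read a long-format count table into a site-by-year matrix
#' @param path CSV path with columns `site`, `year`, `count` (NA allowed).
#' @return Numeric matrix, sites x years (all years spanned, sorted).
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "year", "count")
  if (!all(need %in% names(df))) stop("counts.csv needs columns: site, year, count")
  long_to_matrix(df, "count")
}

#' Read a long-format age-ratio table
#' @param path CSV path with columns `site`, `year`, `ratio`, `weight`.
#' @return List of two matrices `ratio` and `weight` (sites x years).
#' @export
read_age_ratios <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "year", "ratio", "weight")
  if (!all(need %in% names(df))) stop("age_ratios.csv needs columns: site, year, ratio, weight")
  list(ratio = long_to_matrix(df, "ratio"), weight = long_to_matrix(df, "weight"))
}

#' Read a daily weather series
#' @param path CSV path with columns `date`, `tmean_c`, `precip_mm`, `pmin_hpa`.
#' @return data.frame with `date` parsed as `Date`, strictly increasing.
#' @export
read_weather <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmean_c", "precip_mm", "pmin_hpa")
  if (!all(need %in% names(df))) {
    stop("weather csv needs columns: date, tmean_c, precip_mm, pmin_hpa")
  }
  df$date <- as.Date(df$date)
  if (any(diff(as.numeric(df$date)) <= 0)) stop("weather dates must be strictly increasing")
  df
}

long_to_matrix <- function(df, value) {
  sites <- sort(unique(df$site))
  years <- seq(min(df$year), max(df$year))
  m <- matrix(NA_real_, nrow = length(sites), ncol = length(years),
              dimnames = list(sites, as.character(years)))
  m[cbind(match(df$site, sites), match(df$year, years))] <- df[[value]]
  m
}

#' Aggregate site counts into group-level female counts
#'
#' Interpolates missing site counts, sums sites within each subpopulation
#' group and halves the totals to females.
#'
#' @param counts Site-by-year count matrix (rownames are site ids).
#' @param sites Site table from [read_sites()].
#' @return Group-by-year matrix of female counts (rows ordered as
#'   [imm_groups()]).
#' @export
prepare_counts <- function(counts, sites) {
  if (!all(rownames(counts) %in% sites$site)) stop("count sites missing from site table")
  filled <- interpolate_counts(counts)
  grp <- sites$group[match(rownames(counts), sites$site)]
  out <- matrix(0, nrow = length(imm_groups()), ncol = ncol(counts),
                dimnames = list(imm_groups(), colnames(counts)))
  for (g in imm_groups()) {
    rows <- which(grp == g)
    if (length(rows)) out[g, ] <- colSums(filled[rows, , drop = FALSE])
  }
  matrix(female_counts(out), nrow = nrow(out), dimnames = dimnames(out))
}

#' Derive group-level juvenile counts from age ratios
#'
#' Focal groups use their own (single-site) ratio; the pooled Elsewhere group
#' uses a count-weighted average of its member sites' ratios. The group ratio
#' is then applied to the group female count. Years with no sampled ratio for
#' a group are returned as `NA` (the model treats them as latent).
#'
#' @param ratios List from [read_age_ratios()].
#' @param female Group-by-year female counts from [prepare_counts()].
#' @param sites Site table.
#' @return Group-by-year matrix of juvenile female counts, `NA` where no
#'   ratio was sampled.
#' @export
prepare_jobs <- function(ratios, female, sites) {
  grp <- sites$group[match(rownames(ratios$ratio), sites$site)]
  out <- matrix(NA_real_, nrow = length(imm_groups()), ncol = ncol(female),
                dimnames = dimnames(female))
  for (gi in seq_along(imm_groups())) {
    g <- imm_groups()[gi]
    rows <- which(grp == g)
    if (!length(rows)) next
    for (t in seq_len(ncol(female))) {
      r <- ratios$ratio[rows, t]
      w <- ratios$weight[rows, t]
      ok <- !is.na(r) & !is.na(w)
      if (!any(ok) || sum(w[ok]) <= 0) next
      pooled <- elsewhere_age_ratio(r[ok], w[ok])
      out[gi, t] <- juveniles_from_ratio(pooled, female[gi, t])
    }
  }
  out
}

#' Compute standardized group-year environmental covariates
#'
#' From per-region daily weather series, computes cumulative growing degree
#' days on wintering, staging and breeding areas, cumulative snow on breeding
#' areas and severe-storm days during migration, for each group and year, then
#' standardizes each series within group across years. Window boundaries are
#' month-day strings; a window whose start month is later in the calendar than
#' its end month wraps across the year boundary (ending in `year`).
#'
#' @param weather Named list of weather data.frames (from [read_weather()]),
#'   one per region id.
#' @param regions Named list mapping each group code to a list with elements
#'   `winter`, `stage`, `breed` giving the region id of each seasonal range.
#' @param years Integer vector of calendar year labels (autumn year of each
#'   winter).
#' @param windows List of window specs, each `c(start, end)` in `"mm-dd"`
#'   form, with elements `gdd_winter`, `gdd_stage`, `gdd_breed`, `snow`,
#'   `storms_spring`, `storms_autumn`. Defaults span early spring (winter
#'   range), spring staging, early summer (breeding), winter-spring snow and
#'   the two migration periods.
#' @param gdd_base GDD base temperature (degrees C), default 0.
#' @param snow_temp Snow temperature threshold (degrees C), default 0.
#' @param storm_threshold Storm pressure threshold (hPa), default 980.
#' @return An `imm_covs` object: list with array `x` (group x year x 4
#'   fecundity covariates), matrix `storms` (group x interval) and integer
#'   vector `h` of hunting-period indices per interval.
#' @export
compute_covariates <- function(weather, regions, years,
                               windows = default_windows(),
                               gdd_base = 0, snow_temp = 0,
                               storm_threshold = 980) {
  G <- length(imm_groups())
  T_ <- length(years)
  covn <- c("gdd_winter", "gdd_stage", "gdd_breed", "snow_breed")
  raw <- array(NA_real_, dim = c(G, T_, 4),
               dimnames = list(imm_groups(), years, covn))
  # storm covariate is per survival interval t -> t+1; the migrations of that
  # interval happen in the calendar year of winter t+1
  storms_raw <- matrix(NA_real_, G, T_ - 1L,
                       dimnames = list(imm_groups(), years[-1]))
  for (gi in seq_len(G)) {
    g <- imm_groups()[gi]
    reg <- regions[[g]]
    ww <- weather[[reg$winter]]
    ws <- weather[[reg$stage]]
    wb <- weather[[reg$breed]]
    for (ti in seq_len(T_)) {
      # fecundity covariates for winter t reflect the spring/summer of the
      # calendar year the winter is labelled by (juveniles hatch that summer)
      yr <- years[ti]
      raw[gi, ti, 1] <- growing_degree_days(ww$tmean_c, gdd_base,
                                            window_idx(ww$date, windows$gdd_winter, yr))
      raw[gi, ti, 2] <- growing_degree_days(ws$tmean_c, gdd_base,
                                            window_idx(ws$date, windows$gdd_stage, yr))
      raw[gi, ti, 3] <- growing_degree_days(wb$tmean_c, gdd_base,
                                            window_idx(wb$date, windows$gdd_breed, yr))
      raw[gi, ti, 4] <- cumulative_snow(wb$precip_mm, wb$tmean_c, snow_temp,
                                        window_idx(wb$date, windows$snow, yr))
    }
    for (ti in seq_len(T_ - 1L)) {
      yr <- years[ti + 1L]
      storms_raw[gi, ti] <-
        storm_days(ws$pmin_hpa, storm_threshold,
                   window_idx(ws$date, windows$storms_spring, yr)) +
        storm_days(ws$pmin_hpa, storm_threshold,
                   window_idx(ws$date, windows$storms_autumn, yr))
    }
  }
  x <- raw
  for (gi in seq_len(G)) for (k in 1:4) x[gi, , k] <- standardize(raw[gi, , k])
  storms <- storms_raw
  for (gi in seq_len(G)) storms[gi, ] <- standardize(storms_raw[gi, ])
  new_covs(x = x,
           storms = storms,
           h = hunting_period(years[-1]),
           raw = list(x = raw, storms = storms_raw))
}

#' Default seasonal windows for covariate computation
#' @return Named list of `c(start, end)` month-day windows.
#' @export
default_windows <- function() {
  list(gdd_winter = c("02-01", "03-31"),
       gdd_stage = c("04-15", "05-15"),
       gdd_breed = c("05-20", "06-30"),
       snow = c("11-01", "05-31"),
       storms_spring = c("04-01", "05-20"),
       storms_autumn = c("09-15", "10-31"))
}

window_idx <- function(dates, win, year) {
  start_md <- win[1]; end_md <- win[2]
  wraps <- start_md > end_md
  start <- as.Date(paste0(if (wraps) year - 1L else year, "-", start_md))
  end <- as.Date(paste0(year, "-", end_md))
  idx <- which(dates >= start & dates <= end)
  if (!length(idx)) stop("window ", start, "..", end, " not covered by weather series")
  idx
}

new_covs <- function(x, storms, h, raw = NULL) {
  structure(list(x = x, storms = storms, h = as.integer(h), raw = raw),
            class = "imm_covs")
}
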