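#' ISO-8601 week and week-based year of a date
#'
#' @param dates Date vector.
#' @return Integer vector of ISO week numbers (1-53) / week-based years.
#' @export
iso_week <- function(dates) as.integer(format(as.Date(dates), "%V"))

#' @rdname iso_week
#' @export
iso_year <- function(dates) as.integer(format(as.Date(dates), "%G"))

#' The winter/summer season definition
#'
#' Winter runs from ISO week 40 through week 20 of the following year
#' (the weeks when respiratory-infection surveillance is active in England);
#' summer is weeks 21-39. The two partition every ISO week of any year,
#' including week 53 when present (week 53 is winter).
#'
#' @return List with integer vectors `summer_weeks` and `winter_weeks`.
#' @export
season_definition <- function() {
  list(summer_weeks = 21:39, winter_weeks = c(40:53, 1:20))
}

#' Season of a calendar date
#'
#' @param dates Date vector.
#' @return Character vector, `"winter"` or `"summer"`, by ISO week number:
#'   weeks 21-39 are summer, all other weeks (40-52/53 and 1-20) winter.
#' @examples
#' season_of(as.Date(c("2005-06-20", "2005-01-03", "2009-12-31")))
#' @export
season_of <- function(dates) {
  w <- iso_week(dates)
  ifelse(w >= 21L & w <= 39L, "summer", "winter")
}

# Accrue person-time from annual band-level denominators by calendar day.
# Each day contributes population(band, year(day)) / 365.25 person-years to
# the chosen stratum of that day. Returns band x stratum person-years.
accrue_persontime <- function(population, study_start, study_end,
                              by = c("season", "week", "month")) {
  by <- match.arg(by)
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  stopifnot(study_end >= study_start)
  days <- seq(study_start, study_end, by = "day")
  yr <- as.integer(format(days, "%Y"))
  stratum <- switch(by,
    season = season_of(days),
    week   = iso_week(days),
    month  = as.integer(format(days, "%m"))
  )
  need <- unique(yr)
  pop_years <- sort(unique(population$year))
  missing_years <- setdiff(need, pop_years)
  if (length(missing_years) > 0L) {
    stop("population table lacks year(s): ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  day_tbl <- tibble::tibble(year = yr, stratum = stratum) |>
    dplyr::count(.data$year, .data$stratum, name = "n_days")
  out <- dplyr::inner_join(population, day_tbl, by = "year",
                           relationship = "many-to-many") |>
    dplyr::group_by(.data$age_band, .data$stratum) |>
    dplyr::summarise(
      person_years = sum(.data$population * .data$n_days) / 365.25,
      .groups = "drop"
    )
  names(out)[names(out) == "stratum"] <- by
  out
}

#' Person-years at risk per season
#'
#' Adjusts the population denominator for the differing person-time at risk
#' in winter versus summer: every calendar day in the study window accrues
#' that day's band population divided by 365.25 to the day's season.
#'
#' @param population Tibble with columns `age_band`, `year`, `population`.
#' @param study_start,study_end Dates bounding the study window (inclusive).
#' @return Tibble with columns `age_band`, `season`, `person_years`,
#'   including an `"all"` band row aggregated over bands.
#' @export
season_persontime <- function(population, study_start, study_end) {
  pt <- accrue_persontime(population, study_start, study_end, by = "season")
  all_band <- pt |>
    dplyr::group_by(.data$season) |>
    dplyr::summarise(person_years = sum(.data$person_years), .groups = "drop") |>
    dplyr::mutate(age_band = "all", .before = 1L)
  dplyr::bind_rows(pt, all_band)
}

# Poisson rate CI per 100,000 person-years. Default: normal approximation on
# the log rate; "exact" uses the chi-square inversion of the Poisson count.
# Zero counts always get an exact one-sided interval (lower bound 0).
rate_ci <- function(deaths, person_years, conf = 0.95,
                    method = c("wald", "exact")) {
  method <- match.arg(method)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rate <- deaths / person_years * 1e5
  if (method == "wald") {
    lo <- ifelse(deaths > 0, rate * exp(-z / sqrt(deaths)), 0)
    hi <- ifelse(deaths > 0, rate * exp(z / sqrt(deaths)),
                 stats::qchisq(conf, 2) / 2 / person_years * 1e5)
  } else {
    lo <- ifelse(deaths > 0,
                 stats::qchisq((1 - conf) / 2, 2 * deaths) / 2 /
                   person_years * 1e5, 0)
    hi <- stats::qchisq(1 - (1 - conf) / 2, 2 * (deaths + 1)) / 2 /
      person_years * 1e5
  }
  tibble::tibble(rate = rate, lo = lo, hi = hi)
}

#' Winter and summer mortality rates
#'
#' Counts flagged deaths per band and season, divides by season person-time,
#' and attaches 95% confidence intervals on each rate.
#'
#' @param cases Phenotyped cohort (see [phenotype_cases()]); needs `dod`,
#'   `age_band` and the flag column.
#' @param persontime Output of [season_persontime()].
#' @param flag Name of a logical column selecting the indicator deaths
#'   (e.g. `"rti_related"`), or `NULL` for all deaths.
#' @param ci_method `"wald"` (normal approximation on the log rate, default)
#'   or `"exact"` (chi-square inversion of the Poisson count).
#' @return Tibble, one row per band (plus `"all"`): `deaths_winter`,
#'   `deaths_summer`, `persontime_winter`, `persontime_summer`,
#'   `rate_winter`/`rate_summer` per 100,000 person-years with `*_lo`/`*_hi`
#'   bounds.
#' @export
season_rates <- function(cases, persontime, flag = "rti_related",
                         ci_method = c("wald", "exact")) {
  ci_method <- match.arg(ci_method)
  sel <- if (is.null(flag)) rep(TRUE, nrow(cases)) else cases[[flag]]
  dd <- cases[sel, , drop = FALSE]
  dd$season <- season_of(dd$dod)
  counts <- dd |>
    dplyr::count(.data$age_band, .data$season, name = "deaths")
  counts <- dplyr::bind_rows(
    counts,
    counts |>
      dplyr::group_by(.data$season) |>
      dplyr::summarise(deaths = sum(.data$deaths), .groups = "drop") |>
      dplyr::mutate(age_band = "all", .before = 1L)
  )
  grid <- tidyr::expand_grid(
    age_band = unique(persontime$age_band),
    season = c("winter", "summer")
  )
  out <- grid |>
    dplyr::left_join(counts, by = c("age_band", "season")) |>
    dplyr::mutate(deaths = dplyr::coalesce(.data$deaths, 0L)) |>
    dplyr::inner_join(persontime, by = c("age_band", "season"))
  if (any(out$person_years <= 0)) {
    stop("zero or negative person-time in a band x season cell", call. = FALSE)
  }
  ci <- rate_ci(out$deaths, out$person_years, method = ci_method)
  out$rate <- ci$rate
  out$rate_lo <- ci$lo
  out$rate_hi <- ci$hi
  out |>
    tidyr::pivot_wider(
      names_from = "season",
      values_from = c("deaths", "person_years", "rate", "rate_lo", "rate_hi"),
      names_glue = "{.value}_{season}"
    ) |>
    dplyr::rename(
      persontime_winter = "person_years_winter",
      persontime_summer = "person_years_summer",
      rate_winter_lo = "rate_lo_winter", rate_winter_hi = "rate_hi_winter",
      rate_summer_lo = "rate_lo_summer", rate_summer_hi = "rate_hi_summer"
    )
}

#' Excess winter deaths by rate differencing
#'
#' Estimates the winter excess as the winter-minus-summer rate difference
#' applied to winter person-time: `excess = (rate_w - rate_s) *
#' persontime_winter / 1e5`, identically the number of winter deaths beyond
#' those expected at summer rates. Rate-ratio CI is computed on the log
#' scale; rate-difference CI is Wald with `var = d_w/PT_w^2 + d_s/PT_s^2`
#' (independent Poisson counts). The excess range propagates the
#' rate-difference CI endpoints through the same person-time multiplication.
#'
#' @param srates One or more rows of [season_rates()] output.
#' @param n_years Number of calendar study years (the annual average divides
#'   by this).
#' @param winter_noninjury_deaths Total non-injury deaths occurring in winter,
#'   per row of `srates` (denominator for one percentage).
#' @param total_indicator_deaths Total indicator deaths over the study period,
#'   per row of `srates` (denominator for the other percentage).
#' @param conf Confidence level (default 0.95).
#' @return Tibble, one row per input row: `rate_ratio` (`_lo`, `_hi`),
#'   `rate_difference` (`_lo`, `_hi`), `excess_total` (`_lo`, `_hi`),
#'   `excess_annual` (`_lo`, `_hi`), `pct_of_winter_noninjury`,
#'   `pct_of_all_indicator_deaths`. A zero summer rate yields `NA` ratio
#'   columns; the difference is still returned.
#' @export
excess_estimate <- function(srates, n_years,
                            winter_noninjury_deaths = NA_real_,
                            total_indicator_deaths = NA_real_,
                            conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  dw <- srates$deaths_winter
  ds <- srates$deaths_summer
  ptw <- srates$persontime_winter
  pts <- srates$persontime_summer
  rw <- srates$rate_winter
  rs <- srates$rate_summer

  rr <- ifelse(ds > 0, rw / rs, NA_real_)
  se_lrr <- ifelse(dw > 0 & ds > 0, sqrt(1 / dw + 1 / ds), NA_real_)
  rr_lo <- rr * exp(-z * se_lrr)
  rr_hi <- rr * exp(z * se_lrr)

  rd <- rw - rs
  se_rd <- sqrt(dw / ptw^2 + ds / pts^2) * 1e5
  rd_lo <- rd - z * se_rd
  rd_hi <- rd + z * se_rd

  ex <- rd * ptw / 1e5
  ex_lo <- rd_lo * ptw / 1e5
  ex_hi <- rd_hi * ptw / 1e5

  tibble::tibble(
    age_band = srates$age_band,
    rate_ratio = rr, rate_ratio_lo = rr_lo, rate_ratio_hi = rr_hi,
    rate_difference = rd, rate_difference_lo = rd_lo,
    rate_difference_hi = rd_hi,
    excess_total = ex, excess_total_lo = ex_lo, excess_total_hi = ex_hi,
    excess_annual = ex / n_years,
    excess_annual_lo = ex_lo / n_years, excess_annual_hi = ex_hi / n_years,
    pct_of_winter_noninjury = ex / winter_noninjury_deaths * 100,
    pct_of_all_indicator_deaths = ex / total_indicator_deaths * 100
  )
}

#' Pooled weekly mortality rates
#'
#' Deaths pooled over study years by ISO week-of-year, divided by the pooled
#' week-level person-time, per 100,000 person-years.
#'
#' @inheritParams season_rates
#' @param population Tibble with columns `age_band`, `year`, `population`.
#' @param study_start,study_end Study window (inclusive).
#' @return Tibble of (`age_band`, `week`, `deaths`, `person_years`, `rate`),
#'   including an `"all"` band.
#' @export
weekly_rates <- function(cases, population, study_start, study_end,
                         flag = "rti_related") {
  pt <- accrue_persontime(population, study_start, study_end, by = "week")
  pooled_rates(cases, pt, flag, unit = "week",
               unit_of = function(d) iso_week(d))
}

#' Pooled monthly rates with circular-plot coordinates
#'
#' Month-of-year pooled rates plus plot-ready polar coordinates:
#' `angle = 2 * pi * (month - 1) / 12` and `radius = rate`, so that the
#' distance from the centre is proportional to the mortality rate.
#'
#' @inheritParams weekly_rates
#' @return Tibble of (`age_band`, `month`, `deaths`, `person_years`, `rate`,
#'   `angle`, `radius`), including an `"all"` band.
#' @export
monthly_circular <- function(cases, population, study_start, study_end,
                             flag = "rti_related") {
  pt <- accrue_persontime(population, study_start, study_end, by = "month")
  out <- pooled_rates(cases, pt, flag, unit = "month",
                      unit_of = function(d) as.integer(format(d, "%m")))
  out$angle <- 2 * pi * (out$month - 1L) / 12
  out$radius <- out$rate
  out
}

pooled_rates <- function(cases, pt, flag, unit, unit_of) {
  sel <- if (is.null(flag)) rep(TRUE, nrow(cases)) else cases[[flag]]
  dd <- cases[sel, , drop = FALSE]
  dd$.unit <- unit_of(dd$dod)
  counts <- dd |>
    dplyr::count(.data$age_band, .data$.unit, name = "deaths")
  counts <- dplyr::bind_rows(
    counts,
    counts |>
      dplyr::group_by(.data$.unit) |>
      dplyr::summarise(deaths = sum(.data$deaths), .groups = "drop") |>
      dplyr::mutate(age_band = "all", .before = 1L)
  )
  pt_all <- dplyr::bind_rows(
    pt,
    pt |>
      dplyr::group_by(.data[[unit]]) |>
      dplyr::summarise(person_years = sum(.data$person_years),
                       .groups = "drop") |>
      dplyr::mutate(age_band = "all", .before = 1L)
  )
  names(counts)[names(counts) == ".unit"] <- unit
  out <- pt_all |>
    dplyr::left_join(counts, by = c("age_band", unit)) |>
    dplyr::mutate(
      deaths = dplyr::coalesce(.data$deaths, 0L),
      rate = .data$deaths / .data$person_years * 1e5
    ) |>
    dplyr::arrange(.data$age_band, .data[[unit]])
  out
}

#' Assemble the winter-excess summary table
#'
#' One row per age band (plus all ages) and indicator: season rates with CIs,
#' rate ratio, rate difference, total and annual excess with ranges, and the
#' excess as a percentage of winter non-injury deaths and of all indicator
#' deaths.
#'
#' @param cases Phenotyped cohort.
#' @param population Population denominators (`age_band`, `year`,
#'   `population`).
#' @param study_start,study_end Study window (inclusive).
#' @param flags Named character vector of indicator flag columns; names label
#'   the `indicator` column of the output.
#' @param ci_method Passed to [season_rates()].
#' @return Tibble with one row per indicator x band.
#' @export
excess_table <- function(cases, population, study_start, study_end,
                         flags = c(rti = "rti_related",
                                   respiratory = "any_respiratory_related"),
                         ci_method = "wald") {
  pt <- season_persontime(population, study_start, study_end)
  n_years <- length(unique(population$year))
  season <- season_of(cases$dod)
  winter_noninj <- cases |>
    dplyr::mutate(season = season) |>
    dplyr::filter(.data$season == "winter") |>
    dplyr::count(.data$age_band, name = "winter_noninjury")
  winter_noninj <- dplyr::bind_rows(
    winter_noninj,
    tibble::tibble(age_band = "all",
                   winter_noninjury = sum(winter_noninj$winter_noninjury))
  )
  out <- lapply(names(flags), function(ind) {
    fl <- flags[[ind]]
    sr <- season_rates(cases, pt, flag = fl, ci_method = ci_method)
    totals <- cases |>
      dplyr::filter(.data[[fl]]) |>
      dplyr::count(.data$age_band, name = "total_indicator")
    totals <- dplyr::bind_rows(
      totals,
      tibble::tibble(age_band = "all",
                     total_indicator = sum(totals$total_indicator))
    )
    sr <- sr |>
      dplyr::left_join(winter_noninj, by = "age_band") |>
      dplyr::left_join(totals, by = "age_band") |>
      dplyr::mutate(
        winter_noninjury = dplyr::coalesce(.data$winter_noninjury, 0L),
        total_indicator = dplyr::coalesce(.data$total_indicator, 0L)
      )
    ex <- excess_estimate(sr, n_years,
                          winter_noninjury_deaths = sr$winter_noninjury,
                          total_indicator_deaths = sr$total_indicator)
    dplyr::bind_cols(
      tibble::tibble(indicator = ind),
      dplyr::left_join(sr, ex, by = "age_band")
    )
  })
  dplyr::bind_rows(out)
}
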