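#' Annual mortality rate series
#'
#' Counts flagged deaths per age band and calendar year and attaches rates
#' per 100,000 population. Every band x year cell of the denominator table
#' is retained (zero-death cells included); a death in a band x year with no
#' denominator is an error naming the cell.
#'
#' @param cases Phenotyped cohort.
#' @param population Denominator tibble (`age_band`, `year`, `population`).
#' @param flag Logical indicator column name, or `NULL` for all deaths.
#' @return Tibble (`age_band`, `year`, `deaths`, `population`, `rate`),
#'   including `"all"` band rows.
#' @export
annual_series <- function(cases, population, flag = "rti_related") {
  sel <- if (is.null(flag)) rep(TRUE, nrow(cases)) else cases[[flag]]
  dd <- cases[sel, , drop = FALSE]
  dd$year <- as.integer(format(dd$dod, "%Y"))
  have <- paste(population$age_band, population$year)
  need <- unique(paste(dd$age_band, dd$year))
  miss <- setdiff(need, have)
  if (length(miss) > 0L) {
    stop("no population denominator for cell(s): ",
         paste(miss, collapse = "; "), call. = FALSE)
  }
  counts <- dd |> dplyr::count(.data$age_band, .data$year, name = "deaths")
  out <- population |>
    dplyr::left_join(counts, by = c("age_band", "year")) |>
    dplyr::mutate(deaths = dplyr::coalesce(.data$deaths, 0L))
  all_band <- out |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(deaths = sum(.data$deaths),
                     population = sum(.data$population), .groups = "drop") |>
    dplyr::mutate(age_band = "all", .before = 1L)
  dplyr::bind_rows(out, all_band) |>
    dplyr::mutate(rate = .data$deaths / .data$population * 1e5) |>
    dplyr::arrange(.data$age_band, .data$year)
}

check_one_band <- function(series) {
  if (length(unique(series$age_band)) != 1L) {
    stop("series must cover a single age band; filter first", call. = FALSE)
  }
}

#' Poisson log-linear trend fit
#'
#' Fits deaths ~ year with a log-population offset (Poisson family), year
#' centred for numerical stability. The trend is tested against the
#' intercept-only model by a likelihood-ratio test; significance is defined
#' as `lr_p < 0.05`.
#'
#' @param series One band of [annual_series()] output (at least 3 years).
#' @param conf Confidence level (default 0.95).
#' @return Object of class `trend_fit`: `slope` (log-rate change per year)
#'   with `slope_se` and CI, `annual_pct_change` (`(exp(slope)-1)*100`) with
#'   CI, `annual_pct_decline` (its negative), `lr_p`, `aic`, `n_years`.
#' @export
fit_trend <- function(series, conf = 0.95) {
  check_one_band(series)
  if (nrow(series) < 3L) stop("need at least 3 years of data", call. = FALSE)
  if (all(series$deaths == 0)) stop("all counts are zero", call. = FALSE)
  yc <- series$year - mean(series$year)
  off <- log(series$population)
  fit1 <- stats::glm(series$deaths ~ yc + offset(off), family = stats::poisson())
  fit0 <- stats::glm(series$deaths ~ 1 + offset(off), family = stats::poisson())
  z <- stats::qnorm(1 - (1 - conf) / 2)
  slope <- unname(stats::coef(fit1)["yc"])
  se <- sqrt(diag(stats::vcov(fit1)))[["yc"]]
  ci <- slope + c(-1, 1) * z * se
  lr <- fit0$deviance - fit1$deviance
  structure(list(
    slope = slope,
    slope_se = se,
    slope_lo = ci[1], slope_hi = ci[2],
    annual_pct_change = (exp(slope) - 1) * 100,
    annual_pct_change_lo = (exp(ci[1]) - 1) * 100,
    annual_pct_change_hi = (exp(ci[2]) - 1) * 100,
    annual_pct_decline = (1 - exp(slope)) * 100,
    lr_stat = lr,
    lr_p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
    aic = stats::AIC(fit1),
    aic_intercept = stats::AIC(fit0),
    n_years = nrow(series),
    changepoint_year = NULL,
    segment_slopes = NULL
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> annual %% change %.2f (%.2f, %.2f), LR p = %.3g, AIC %.1f\n",
    x$annual_pct_change, x$annual_pct_change_lo, x$annual_pct_change_hi,
    x$lr_p, x$aic))
  if (!is.null(x$changepoint_year)) {
    cat(sprintf("  change point %d: %% change %.2f before, %.2f after\n",
                x$changepoint_year, x$segment_slopes[1], x$segment_slopes[2]))
  }
  invisible(x)
}

#' Piecewise Poisson trend with AIC change-point selection
#'
#' For every interior candidate year (at least 2 years on each side), fits a
#' piecewise-linear (in year, on the log-rate scale) Poisson model with a
#' slope change at the candidate — continuous at the change point by default
#' (hinge term), or with an additional level shift when
#' `continuous = FALSE`. The minimum-AIC candidate is selected, and a change
#' point is reported only when its AIC beats the single-slope model's.
#'
#' @param series One band of [annual_series()] output (at least 5 years).
#' @param continuous Keep the fitted curve continuous at the change point?
#' @param conf Confidence level for the linear-fit summaries.
#' @return A `trend_fit` (see [fit_trend()]) with `changepoint_year` (`NULL`
#'   when no candidate improves on the straight line), `segment_slopes`
#'   (annual % change before/after), `aic` of the selected model,
#'   `aic_linear`, and a `candidates` tibble (`year`, `aic`, `converged`).
#' @export
fit_changepoint <- function(series, continuous = TRUE, conf = 0.95) {
  check_one_band(series)
  if (nrow(series) < 5L) stop("need at least 5 years of data", call. = FALSE)
  series <- dplyr::arrange(series, .data$year)
  base <- fit_trend(series, conf = conf)
  yrs <- series$year
  cand_years <- yrs[3:(length(yrs) - 2L)]
  yc <- yrs - mean(yrs)
  off <- log(series$population)
  rows <- lapply(cand_years, function(cp) {
    cpc <- cp - mean(yrs)
    hinge <- pmax(yc - cpc, 0)
    form <- if (continuous) {
      series$deaths ~ yc + hinge + offset(off)
    } else {
      series$deaths ~ yc + hinge + I(yc > cpc) + offset(off)
    }
    fit <- tryCatch(
      suppressWarnings(stats::glm(form, family = stats::poisson())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      return(tibble::tibble(year = cp, aic = NA_real_, converged = FALSE,
                            b1 = NA_real_, b2 = NA_real_))
    }
    co <- stats::coef(fit)
    tibble::tibble(year = cp, aic = stats::AIC(fit), converged = TRUE,
                   b1 = unname(co["yc"]), b2 = unname(co["hinge"]))
  })
  cand <- dplyr::bind_rows(rows)
  ok <- which(cand$converged)
  out <- base
  out$aic_linear <- base$aic
  out$candidates <- cand[, c("year", "aic", "converged")]
  if (length(ok) > 0L) {
    best <- ok[which.min(cand$aic[ok])]
    if (cand$aic[best] < base$aic) {
      out$changepoint_year <- cand$year[best]
      out$segment_slopes <- c(
        before = (exp(cand$b1[best]) - 1) * 100,
        after = (exp(cand$b1[best] + cand$b2[best]) - 1) * 100
      )
      out$aic <- cand$aic[best]
    }
  }
  out
}

#' Per-band trend summary table
#'
#' Runs [fit_trend()] on every band of an annual series and, where the
#' linear trend is significant at the given level and the series is long
#' enough, [fit_changepoint()].
#'
#' @param series Full [annual_series()] output.
#' @param alpha Significance level gating the change-point search.
#' @param continuous Passed to [fit_changepoint()].
#' @return Tibble with one row per band: slope, annual % change with CI,
#'   `lr_p`, `aic`, `changepoint_year` and segment % changes (`NA` when no
#'   change point is reported).
#' @export
trend_table <- function(series, alpha = 0.05, continuous = TRUE) {
  bands <- unique(series$age_band)
  rows <- lapply(bands, function(b) {
    s <- series[series$age_band == b, , drop = FALSE]
    ft <- fit_trend(s)
    cp <- NA_integer_
    seg <- c(NA_real_, NA_real_)
    if (ft$lr_p < alpha && nrow(s) >= 5L) {
      fc <- fit_changepoint(s, continuous = continuous)
      if (!is.null(fc$changepoint_year)) {
        cp <- fc$changepoint_year
        seg <- unname(fc$segment_slopes)
      }
    }
    tibble::tibble(
      age_band = b, slope = ft$slope,
      annual_pct_change = ft$annual_pct_change,
      annual_pct_change_lo = ft$annual_pct_change_lo,
      annual_pct_change_hi = ft$annual_pct_change_hi,
      lr_p = ft$lr_p, aic = ft$aic,
      changepoint_year = cp,
      pct_change_before = seg[1], pct_change_after = seg[2]
    )
  })
  dplyr::bind_rows(rows)
}
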