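#' Age-band labels used throughout the package
#' @return Character vector: 28-364 days, 1-4 years, 5-18 years.
#' @export
age_band_levels <- function() c("28-364d", "1-4y", "5-18y")

# day-count ranges sampled per band; band-2/3 boundaries keep a safety margin
# from the birthday-based band edges so the generator's band always agrees
# with the band re-derived from dates downstream
.band_age_ranges <- list(
  "28-364d" = c(28L, 364L),
  "1-4y"    = c(365L, 1820L),
  "5-18y"   = c(1832L, 6900L)
)

# planted ICD-10 codes: RTI cluster hits, one exemplar pool per chronic
# group (inside that group's default cluster, outside the RTI cluster),
# acute codes outside every shipped cluster, and non-specific underlying
# causes outside every shipped cluster
.rti_code_pool <- c("J189", "J219", "J123", "J069", "J180", "A370", "J210",
                    "J111")
.chronic_code_pools <- list(
  mental_behavioural = c("F729", "F799"),
  cancer_blood       = c("C911", "D619", "C719"),
  chronic_infection  = c("B200", "B909"),
  respiratory        = c("J459", "E840", "J448"),
  endocrine_metabolic_renal_digestive_genitourinary =
    c("E109", "N189", "K738", "Q613"),
  musculoskeletal_skin = c("M419", "L930", "Q780"),
  neurological_sensory = c("G809", "G409", "Q059"),
  cardiac              = c("Q212", "I429", "Q249")
)
.generic_acute_pool <- c("A099", "R509", "R112", "A080")
.base_cause_pool <- c("R99", "R568", "A419", "R570", "A408")

#' Simulation parameters for the synthetic linked cohort
#'
#' Defaults emulate the headline structure of national linked
#' death-registration and hospital-episode data for English children,
#' 2001-2010: roughly 22% of non-injury child deaths RTI-related (15%
#' detectable from the certificate alone), 63% of deaths linked to a hospital
#' episode within 30 days, a winter:summer RTI death-hazard ratio of 1.74, a
#' 2.3%/year decline in infant RTI deaths, and chronic-condition prevalence
#' of 89% among RTI deaths versus 80% among other deaths. These defaults are
#' an illustrative fixture, not ground truth about any real dataset.
#'
#' @param study_years Inclusive calendar-year range.
#' @param age_band_populations Named numeric vector (one per age band):
#'   persons per band, constant across years.
#' @param annual_noninjury_deaths Expected non-injury deaths per band per
#'   year (before any trend).
#' @param rti_fraction Probability a death is truly RTI-related.
#' @param winter_multiplier Ratio of the weekly RTI death hazard in winter
#'   weeks to summer weeks (>= 1). Non-RTI deaths are uniform over the year.
#' @param annual_trend Multiplicative year-on-year change in the infant
#'   truly-RTI death rate (0.977 = 2.3%/year decline). Other bands and
#'   non-RTI deaths have no trend.
#' @param changepoint_year Optional year at which the trend switches to
#'   `trend_after`.
#' @param trend_after Year-on-year multiplier after `changepoint_year`.
#' @param chronic_prev_rti,chronic_prev_nonrti Probability of at least one
#'   chronic condition given a truly-RTI / non-RTI death.
#' @param chronic_group_weights Length-8 vector of relative group
#'   probabilities (order of [chronic_group_names()]).
#' @param multimorbidity_p Per-trial probability in the 1 + Binomial(4, p)
#'   draw of the number of chronic groups per chronic child.
#' @param cert_sensitivity Probability a truly-RTI death carries an
#'   RTI-cluster code among its certificate mentions.
#' @param hosp_sensitivity Probability a linked truly-RTI death carries an
#'   RTI-cluster code on a pre-death episode.
#' @param p_linked Probability a death has at least one hospital episode
#'   starting within 30 days before death.
#' @param chronic_episode_p Probability a linked chronic death also has a
#'   lookback episode (31-365 days pre-death) carrying its chronic codes.
#' @param linkage_corruption_rate Probability an episode's child key is
#'   perturbed to an unused key (see [corrupt_keys()]).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Validated parameter list of class `sim_params`.
#' @export
sim_params <- function(study_years = 2001:2010,
                       age_band_populations = c("28-364d" = 600000,
                                                "1-4y" = 2400000,
                                                "5-18y" = 8500000),
                       annual_noninjury_deaths = c("28-364d" = 920,
                                                   "1-4y" = 430,
                                                   "5-18y" = 900),
                       rti_fraction = 0.28,
                       winter_multiplier = 1.74,
                       annual_trend = 0.977,
                       changepoint_year = NULL,
                       trend_after = NULL,
                       chronic_prev_rti = 0.89,
                       chronic_prev_nonrti = 0.80,
                       chronic_group_weights = c(15.7, 18.1, 2.8, 41.0, 39.7,
                                                 20.0, 64.6, 23.8),
                       multimorbidity_p = 0.294,
                       cert_sensitivity = 0.53,
                       hosp_sensitivity = 0.91,
                       p_linked = 0.63,
                       chronic_episode_p = 0.8,
                       linkage_corruption_rate = 0,
                       seed = 1L) {
  p <- list(study_years = as.integer(study_years),
            age_band_populations = age_band_populations,
            annual_noninjury_deaths = annual_noninjury_deaths,
            rti_fraction = rti_fraction,
            winter_multiplier = winter_multiplier,
            annual_trend = annual_trend,
            changepoint_year = changepoint_year,
            trend_after = trend_after,
            chronic_prev_rti = chronic_prev_rti,
            chronic_prev_nonrti = chronic_prev_nonrti,
            chronic_group_weights = chronic_group_weights,
            multimorbidity_p = multimorbidity_p,
            cert_sensitivity = cert_sensitivity,
            hosp_sensitivity = hosp_sensitivity,
            p_linked = p_linked,
            chronic_episode_p = chronic_episode_p,
            linkage_corruption_rate = linkage_corruption_rate,
            seed = as.integer(seed))
  probs <- c(rti_fraction, chronic_prev_rti, chronic_prev_nonrti,
             multimorbidity_p, cert_sensitivity, hosp_sensitivity, p_linked,
             chronic_episode_p, linkage_corruption_rate)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop("all probability parameters must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(winter_multiplier) || winter_multiplier < 1) {
    stop("winter_multiplier must be >= 1", call. = FALSE)
  }
  if (length(age_band_populations) != 3L ||
      is.null(names(age_band_populations)) ||
      !setequal(names(age_band_populations), age_band_levels())) {
    stop("age_band_populations must be named after age_band_levels()",
         call. = FALSE)
  }
  if (any(age_band_populations <= 0)) {
    stop("populations must be positive", call. = FALSE)
  }
  if (is.null(names(annual_noninjury_deaths))) {
    names(annual_noninjury_deaths) <- names(age_band_populations)
    p$annual_noninjury_deaths <- annual_noninjury_deaths
  }
  if (any(annual_noninjury_deaths <= 0)) {
    stop("annual_noninjury_deaths must be positive", call. = FALSE)
  }
  if (length(chronic_group_weights) != 8L || any(chronic_group_weights < 0)) {
    stop("chronic_group_weights must be 8 non-negative values", call. = FALSE)
  }
  if (!is.null(changepoint_year)) {
    if (is.null(trend_after)) {
      stop("trend_after must be given with changepoint_year", call. = FALSE)
    }
    if (!(changepoint_year %in% study_years)) {
      stop("changepoint_year must lie within study_years", call. = FALSE)
    }
  }
  if (abs(p$seed) > 2^31 - 1e5) stop("seed too large", call. = FALSE)
  structure(p, class = c("sim_params", "list"))
}

# cumulative infant-RTI trend factor for each year
trend_factor <- function(params, years) {
  y0 <- min(params$study_years)
  if (is.null(params$changepoint_year)) {
    params$annual_trend^(years - y0)
  } else {
    cp <- params$changepoint_year
    params$annual_trend^(pmin(years, cp) - y0) *
      params$trend_after^pmax(years - cp, 0)
  }
}

#' Population denominator table
#'
#' @param params A [sim_params()] object.
#' @return Tibble with one row per age band x study year and the configured
#'   (constant) population counts.
#' @export
generate_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  tidyr::expand_grid(age_band = names(params$age_band_populations),
                     year = params$study_years) |>
    dplyr::mutate(
      population = unname(params$age_band_populations[.data$age_band])
    )
}

# death dates for one calendar year: winter days weighted w, summer days 1
sample_days <- function(year, n, winter_weight) {
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  if (n == 0L) return(days[0])
  w <- ifelse(season_of(days) == "winter", winter_weight, 1)
  days[sample.int(length(days), n, replace = TRUE, prob = w)]
}

#' Simulate death-certificate records
#'
#' Death counts per band x year are Poisson draws around the configured
#' expectations (infant truly-RTI deaths additionally scaled by the annual
#' trend); truly-RTI deaths get death dates with winter weeks upweighted by
#' `winter_multiplier`, other deaths uniform dates; certificate mentions
#' carry an RTI-cluster code with probability `cert_sensitivity` for
#' truly-RTI deaths; chronic-condition codes are planted per the chronic
#' prevalence and group-weight parameters. The underlying cause is drawn
#' from the mentions and is never an injury/external code.
#'
#' @param params A [sim_params()] object.
#' @return Tibble of death records: `child_key`, `dob`, `dod`, `sex`,
#'   `underlying_cause`, `mention_codes` (list column), `died_in_hospital`,
#'   `resident`, plus simulation ground-truth columns `true_rti`,
#'   `true_chronic` and `chronic_codes` (list column; consumed by
#'   [simulate_episodes()]).
#' @export
simulate_deaths <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  bands <- names(params$age_band_populations)
  grid <- tidyr::expand_grid(age_band = bands, year = params$study_years)
  e_total <- unname(params$annual_noninjury_deaths[grid$age_band])
  mu_rti <- e_total * params$rti_fraction *
    ifelse(grid$age_band == "28-364d", trend_factor(params, grid$year), 1)
  mu_non <- e_total * (1 - params$rti_fraction)
  n_rti <- stats::rpois(nrow(grid), mu_rti)
  n_non <- stats::rpois(nrow(grid), mu_non)

  band <- c(rep(grid$age_band, n_rti), rep(grid$age_band, n_non))
  year <- c(rep(grid$year, n_rti), rep(grid$year, n_non))
  true_rti <- c(rep(TRUE, sum(n_rti)), rep(FALSE, sum(n_non)))
  n <- length(band)
  if (n == 0L) stop("no deaths simulated; increase expected counts",
                    call. = FALSE)

  dod <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  for (y in params$study_years) {
    iw <- which(year == y & true_rti)
    if (length(iw)) dod[iw] <- sample_days(y, length(iw),
                                           params$winter_multiplier)
    iu <- which(year == y & !true_rti)
    if (length(iu)) dod[iu] <- sample_days(y, length(iu), 1)
  }

  age_days <- integer(n)
  for (b in bands) {
    i <- which(band == b)
    rng <- .band_age_ranges[[b]]
    age_days[i] <- sample(rng[1]:rng[2], length(i), replace = TRUE)
  }
  dob <- dod - age_days

  # certificate coding
  rti_coded <- true_rti & stats::runif(n) < params$cert_sensitivity
  rti_code <- ifelse(rti_coded,
                     sample(.rti_code_pool, n, replace = TRUE), NA_character_)
  chronic <- stats::runif(n) < ifelse(true_rti, params$chronic_prev_rti,
                                      params$chronic_prev_nonrti)
  k_groups <- integer(n)
  k_groups[chronic] <- 1L + stats::rbinom(sum(chronic), 4L,
                                          params$multimorbidity_p)
  w <- params$chronic_group_weights
  chronic_codes <- vector("list", n)
  chronic_codes[] <- list(character())
  pools <- .chronic_code_pools
  for (i in which(chronic)) {
    gs <- sample.int(8L, k_groups[i], prob = w)
    chronic_codes[[i]] <- vapply(gs, function(g) {
      pool <- pools[[g]]
      pool[sample.int(length(pool), 1L)]
    }, "")
  }
  base_code <- sample(.base_cause_pool, n, replace = TRUE)
  mention_codes <- vector("list", n)
  underlying <- character(n)
  for (i in seq_len(n)) {
    m <- unique(c(chronic_codes[[i]],
                  if (!is.na(rti_code[i])) rti_code[i], base_code[i]))
    mention_codes[[i]] <- m
    underlying[i] <- m[sample.int(length(m), 1L)]
  }

  tibble::tibble(
    child_key = sprintf("C%06d", seq_len(n)),
    dob = dob,
    dod = dod,
    sex = sample(c("M", "F"), n, replace = TRUE),
    underlying_cause = underlying,
    mention_codes = mention_codes,
    died_in_hospital = stats::runif(n) < 0.75,
    resident = TRUE,
    true_rti = true_rti,
    true_chronic = chronic,
    chronic_codes = chronic_codes
  )
}

#' Simulate hospital-episode records for simulated deaths
#'
#' Each death gains at least one episode starting within the 30 days before
#' death with probability `p_linked`; linked truly-RTI deaths carry an
#' RTI-cluster code on one in-window episode with probability
#' `hosp_sensitivity` (independently of certificate coding, so both
#' sensitivities below 1 yield cross-source discordance). Linked chronic
#' deaths additionally receive a lookback episode (31-365 days pre-death)
#' carrying their chronic codes with probability `chronic_episode_p`.
#'
#' @param params A [sim_params()] object.
#' @param deaths Output of [simulate_deaths()].
#' @return Tibble of episode records: `child_key`, `start_date`, `end_date`,
#'   `diagnosis_codes` (list column).
#' @export
simulate_episodes <- function(params, deaths) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 1000L)
  n <- nrow(deaths)
  empty <- tibble::tibble(child_key = character(),
                          start_date = as.Date(character()),
                          end_date = as.Date(character()),
                          diagnosis_codes = list())
  if (n == 0L || params$p_linked == 0) return(empty)
  linked <- stats::runif(n) < params$p_linked
  idx <- which(linked)
  if (length(idx) == 0L) return(empty)

  age_days <- as.integer(deaths$dod - deaths$dob)
  n_ep <- 1L + stats::rpois(length(idx), 0.4)
  case <- rep(idx, n_ep)
  max_off <- pmin(30L, age_days[case])
  offset <- floor(stats::runif(length(case)) * (max_off + 1L))
  start <- deaths$dod[case] - offset
  los <- stats::rpois(length(case), 4)
  codes <- lapply(sample(.generic_acute_pool, length(case), replace = TRUE),
                  identity)

  # plant an RTI code on the first in-window episode of hospital-coded deaths
  hosp_coded <- deaths$true_rti[idx] &
    stats::runif(length(idx)) < params$hosp_sensitivity
  first_ep <- match(idx[hosp_coded], case)
  if (length(first_ep)) {
    planted <- sample(.rti_code_pool, length(first_ep), replace = TRUE)
    for (j in seq_along(first_ep)) {
      codes[[first_ep[j]]] <- unique(c(planted[j], codes[[first_ep[j]]]))
    }
  }

  ep <- tibble::tibble(
    child_key = deaths$child_key[case],
    start_date = start,
    end_date = start + los,
    diagnosis_codes = codes
  )

  # chronic lookback episodes for linked chronic deaths old enough to have one
  ch_idx <- idx[deaths$true_chronic[idx] & age_days[idx] > 31L &
                  stats::runif(length(idx)) < params$chronic_episode_p]
  if (length(ch_idx)) {
    lb_max <- pmin(365L, age_days[ch_idx])
    lb_off <- 31L + floor(stats::runif(length(ch_idx)) * (lb_max - 30L))
    lb_start <- deaths$dod[ch_idx] - lb_off
    lb_codes <- lapply(seq_along(ch_idx), function(j) {
      unique(c(deaths$chronic_codes[[ch_idx[j]]],
               sample(.generic_acute_pool, 1L)))
    })
    ep <- dplyr::bind_rows(ep, tibble::tibble(
      child_key = deaths$child_key[ch_idx],
      start_date = lb_start,
      end_date = lb_start + stats::rpois(length(ch_idx), 6),
      diagnosis_codes = lb_codes
    ))
  }
  dplyr::arrange(ep, .data$child_key, .data$start_date)
}

#' Perturb a fraction of episode child keys
#'
#' Emulates imperfect deterministic linkage: each episode's child key is
#' independently replaced by an unused key with the given probability, so
#' the corrupted episodes match no death downstream.
#'
#' @param records Episode tibble with a `child_key` column.
#' @param rate Corruption probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return `records` with the perturbed keys; otherwise unchanged.
#' @export
corrupt_keys <- function(records, rate, seed = 1L) {
  stopifnot(is.numeric(rate), rate >= 0, rate <= 1)
  if (rate == 0 || nrow(records) == 0L) return(records)
  set.seed(as.integer(seed))
  hit <- stats::runif(nrow(records)) < rate
  records$child_key[hit] <- sprintf("GHOST%06d", seq_len(sum(hit)))
  records
}

#' Simulate a full linked cohort
#'
#' Convenience wrapper: population, deaths, episodes (with key corruption if
#' configured), all from the single seed in `params`.
#'
#' @param params A [sim_params()] object.
#' @return List with elements `deaths`, `episodes`, `population`.
#' @export
simulate_cohort <- function(params) {
  deaths <- simulate_deaths(params)
  episodes <- simulate_episodes(params, deaths)
  if (params$linkage_corruption_rate > 0) {
    episodes <- corrupt_keys(episodes, params$linkage_corruption_rate,
                             seed = params$seed + 2000L)
  }
  list(deaths = deaths, episodes = episodes,
       population = generate_population(params))
}
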