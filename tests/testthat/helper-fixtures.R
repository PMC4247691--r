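# shared fixtures and independent oracles, all built in code

empty_episodes <- function() {
  tibble::tibble(child_key = character(),
                 start_date = as.Date(character()),
                 end_date = as.Date(character()),
                 diagnosis_codes = list())
}

make_death <- function(child_key = "C1",
                       dob = as.Date("2003-05-10"),
                       dod = as.Date("2005-02-01"),
                       sex = "F",
                       underlying_cause = "R99",
                       mention_codes = list(c("R99")),
                       died_in_hospital = TRUE,
                       resident = TRUE) {
  tibble::tibble(child_key = child_key, dob = dob, dod = dod, sex = sex,
                 underlying_cause = underlying_cause,
                 mention_codes = mention_codes,
                 died_in_hospital = died_in_hospital, resident = resident)
}

make_episode <- function(child_key = "C1",
                         start_date = as.Date("2005-01-20"),
                         end_date = start_date + 3,
                         diagnosis_codes = list(c("J189"))) {
  tibble::tibble(child_key = child_key, start_date = as.Date(start_date),
                 end_date = as.Date(end_date),
                 diagnosis_codes = diagnosis_codes)
}

# one-tenth-scale simulation parameters used by the stochastic suites
small_params <- function(...) {
  sim_params(annual_noninjury_deaths = c("28-364d" = 92, "1-4y" = 43,
                                         "5-18y" = 90), ...)
}

# full default simulation, phenotyped, cached per test run
default_cohort <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$cohort)) {
      sim <- simulate_cohort(sim_params(seed = 99L))
      cases <- link_records(sim$deaths, sim$episodes, quiet = TRUE)
      cohort <- filter_eligible(cases, "2001-01-01", "2010-12-31",
                                quiet = TRUE)
      cache$cohort <- phenotype_cases(cohort)
      cache$population <- sim$population
    }
    list(cohort = cache$cohort, population = cache$population)
  }
})

# --- independent oracles -------------------------------------------------

# expand a cluster's member spec into the explicit set of 3- and 4-character
# codes it covers (set-lookup semantics, independent of the interval matcher)
all_stems <- function() {
  as.vector(outer(LETTERS, sprintf("%02d", 0:99), paste0))
}

expand_cluster_codes <- function(members) {
  out <- character()
  stems <- all_stems()
  for (m in members) {
    m <- toupper(gsub(".", "", trimws(m), fixed = TRUE))
    if (grepl("-", m, fixed = TRUE)) {
      ends <- strsplit(m, "-", fixed = TRUE)[[1]]
      covered <- stems[stems >= ends[1] & stems <= ends[2]]
      out <- c(out, covered, as.vector(outer(covered, 0:9, paste0)))
    } else if (nchar(m) == 3L) {
      out <- c(out, m, paste0(m, 0:9))
    } else {
      out <- c(out, m)
    }
  }
  unique(out)
}

# Poisson hinge-model AIC by direct likelihood maximisation (no glm)
cp_aic_oracle <- function(series, cp) {
  yc <- series$year - mean(series$year)
  cpc <- cp - mean(series$year)
  hinge <- pmax(yc - cpc, 0)
  off <- log(series$population)
  nll <- function(b) {
    mu <- exp(b[1] + b[2] * yc + b[3] * hinge + off)
    -sum(stats::dpois(series$deaths, mu, log = TRUE))
  }
  start <- c(log(sum(series$deaths) / sum(series$population)), 0, 0)
  fit <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  2 * fit$value + 2 * 3
}

# straight-line Poisson AIC by direct likelihood maximisation
line_aic_oracle <- function(series) {
  yc <- series$year - mean(series$year)
  off <- log(series$population)
  nll <- function(b) {
    mu <- exp(b[1] + b[2] * yc + off)
    -sum(stats::dpois(series$deaths, mu, log = TRUE))
  }
  start <- c(log(sum(series$deaths) / sum(series$population)), 0)
  fit <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  2 * fit$value + 2 * 2
}

# Cochran-Armitage chi-square statistic, closed form
ca_statistic <- function(x, n, s = seq_along(x)) {
  N <- sum(n)
  p <- sum(x) / N
  num <- (sum(s * x) - p * sum(s * n))^2
  den <- p * (1 - p) * (sum(s^2 * n) - sum(s * n)^2 / N)
  num / den
}

toy_series <- function(deaths, years = 2001:(2000 + length(deaths)),
                       population = 1e6, band = "x") {
  tibble::tibble(age_band = band, year = years, deaths = deaths,
                 population = population,
                 rate = deaths / population * 1e5)
}
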