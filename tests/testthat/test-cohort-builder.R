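test_that("linkage keeps matching episodes and drops the rest", {
  deaths <- make_death(child_key = "A")
  eps <- dplyr::bind_rows(
    make_episode(child_key = "A", start_date = as.Date("2005-01-25")),
    make_episode(child_key = "A", start_date = as.Date("2004-11-01")),
    make_episode(child_key = "B")
  )
  cases <- link_records(deaths, eps, quiet = TRUE)
  expect_equal(nrow(cases), 1L)
  expect_equal(cases$n_episodes, 2L)
  expect_equal(attr(cases, "dropped_episodes"), 1L)
})

test_that("an empty episode table yields episode-free cases", {
  cases <- link_records(make_death(child_key = c("A", "B"),
                                   mention_codes = list("R99", "R99")),
                        empty_episodes(), quiet = TRUE)
  expect_equal(cases$n_episodes, c(0L, 0L))
})

test_that("duplicate death keys abort with the offending key", {
  deaths <- make_death(child_key = c("DUP1", "DUP1"),
                       mention_codes = list("R99", "R99"))
  expect_error(link_records(deaths, empty_episodes(), quiet = TRUE), "DUP1")
})

test_that("exact duplicate episode rows are deduplicated with a count", {
  ep <- make_episode(child_key = "A")
  cases <- link_records(make_death(child_key = "A"),
                        dplyr::bind_rows(ep, ep), quiet = TRUE)
  expect_equal(cases$n_episodes, 1L)
  expect_equal(attr(cases, "deduplicated_episodes"), 1L)
})

test_that("re-linking linked output changes nothing", {
  sim <- simulate_cohort(small_params(seed = 21L))
  once <- link_records(sim$deaths, sim$episodes, quiet = TRUE)
  again <- link_records(once[, names(sim$deaths)],
                        dplyr::bind_rows(once$episodes), quiet = TRUE)
  expect_identical(once$episodes, again$episodes)
  expect_identical(once$age_band, again$age_band)
})

test_that("age bands follow the stated boundary definitions", {
  expect_equal(assign_age_band(as.Date("2004-01-01"), as.Date("2004-12-30")),
               "28-364d")   # 364 days
  expect_equal(assign_age_band(as.Date("2004-01-01"), as.Date("2004-12-31")),
               "1-4y")      # 365 days
  expect_equal(assign_age_band(as.Date("2000-06-01"), as.Date("2005-05-31")),
               "1-4y")      # day before 5th birthday
  expect_equal(assign_age_band(as.Date("2000-06-01"), as.Date("2005-06-01")),
               "5-18y")     # 5th birthday
  expect_equal(assign_age_band(as.Date("1992-01-01"), as.Date("2010-12-31")),
               "5-18y")     # aged 18, before 19th birthday
  expect_error(assign_age_band(as.Date("2004-01-01"), as.Date("2004-01-28")),
               "outside")   # 27 days
  expect_error(assign_age_band(as.Date("1991-12-31"), as.Date("2010-12-31")),
               "outside")   # 19th birthday reached
  # Feb 29 birthday resolves to Mar 1 in non-leap years
  expect_equal(assign_age_band(as.Date("2004-02-29"), as.Date("2009-02-28")),
               "1-4y")
  expect_equal(assign_age_band(as.Date("2004-02-29"), as.Date("2009-03-01")),
               "5-18y")
})

test_that("eligibility filter applies every criterion and logs counts", {
  deaths <- dplyr::bind_rows(
    make_death("ok", dob = as.Date("2004-01-01"), dod = as.Date("2004-01-29"),
               underlying_cause = "J189", mention_codes = list("J189")),
    make_death("young", dob = as.Date("2004-01-01"),
               dod = as.Date("2004-01-28")),
    make_death("injury", underlying_cause = "V011",
               mention_codes = list("V011")),
    make_death("nonres", resident = FALSE),
    make_death("late", dod = as.Date("2011-06-01"),
               dob = as.Date("2008-01-01"))
  )
  cases <- link_records(deaths, empty_episodes(), quiet = TRUE)
  kept <- filter_eligible(cases, "2001-01-01", "2010-12-31", quiet = TRUE)
  expect_equal(kept$child_key, "ok")
  excl <- attr(kept, "exclusions")
  expect_equal(excl$n_excluded[excl$criterion == "age_under_28_days"], 1L)
  expect_equal(excl$n_excluded[excl$criterion == "injury_underlying_cause"],
               1L)
  expect_equal(excl$n_excluded[excl$criterion == "non_resident"], 1L)
  expect_equal(excl$n_excluded[excl$criterion == "outside_window"], 1L)
})

test_that("filtering is idempotent and band counts partition the cohort", {
  sim <- simulate_cohort(small_params(seed = 22L))
  cases <- link_records(sim$deaths, sim$episodes, quiet = TRUE)
  once <- filter_eligible(cases, "2001-01-01", "2010-12-31", quiet = TRUE)
  twice <- filter_eligible(once, "2001-01-01", "2010-12-31", quiet = TRUE)
  expect_equal(nrow(once), nrow(twice))
  expect_equal(sum(table(once$age_band)), nrow(once))
  expect_setequal(unique(once$age_band), age_band_levels())
})

test_that("30-day linkage fraction matches the configured probability", {
  sim <- simulate_cohort(sim_params(seed = 23L))   # ~22,500 deaths
  cases <- link_records(sim$deaths, sim$episodes, quiet = TRUE)
  frac <- mean(linked_within_window(cases, 30))
  n <- nrow(cases)
  expect_lt(abs(frac - 0.63), 3 * sqrt(0.63 * 0.37 / n))
})
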