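test_that("season assignment follows the ISO-week rule", {
  expect_equal(season_of(as.Date("2005-06-22")), "summer")  # week 25
  expect_equal(season_of(as.Date("2005-01-04")), "winter")  # week 1
  expect_equal(season_of(as.Date("2005-05-22")), "winter")  # Sunday, week 20
  expect_equal(season_of(as.Date("2005-05-23")), "summer")  # Monday, week 21
  # 2009-12-31 falls in ISO week 53 of 2009 -> winter by the 40-to-20 rule
  expect_equal(iso_week(as.Date("2009-12-31")), 53L)
  expect_equal(season_of(as.Date("2009-12-31")), "winter")
  sd <- season_definition()
  expect_setequal(c(sd$summer_weeks, sd$winter_weeks), 1:53)
  expect_length(intersect(sd$summer_weeks, sd$winter_weeks), 0)
})

test_that("person-time accrual conserves the year and handles zero", {
  pop <- tibble::tibble(age_band = "1-4y", year = 2001, population = 1000)
  pt <- season_persontime(pop, "2001-01-01", "2001-12-31")
  band <- pt[pt$age_band == "1-4y", ]
  expect_equal(sum(band$person_years), 1000 * 365 / 365.25)
  zero <- season_persontime(
    tibble::tibble(age_band = "1-4y", year = 2001, population = 0),
    "2001-01-01", "2001-12-31")
  expect_equal(sum(zero$person_years[zero$age_band == "1-4y"]), 0)
  expect_error(season_persontime(pop, "2000-06-01", "2001-06-01"), "2000")
})

test_that("winter share of a 52-week ISO year is exactly 33/52", {
  # 2001-01-01 is the Monday of 2001-W01; 2001-12-30 the Sunday of W52
  pop <- tibble::tibble(age_band = "1-4y", year = 2001, population = 52000)
  pt <- season_persontime(pop, "2001-01-01", "2001-12-30")
  band <- pt[pt$age_band == "1-4y", ]
  share <- band$person_years[band$season == "winter"] / sum(band$person_years)
  expect_equal(share, 33 / 52)
})

test_that("weekly rates conserve deaths and reflect the winter forcing", {
  sim <- default_cohort()
  wk <- weekly_rates(sim$cohort, sim$population, "2001-01-01", "2010-12-31")
  all_rows <- wk[wk$age_band == "all", ]
  expect_equal(sum(all_rows$rate * all_rows$person_years) / 1e5,
               sum(sim$cohort$rti_related))
  winter_weeks <- setdiff(1:52, 21:39)
  m_hat <- mean(all_rows$rate[all_rows$week %in% winter_weeks]) /
    mean(all_rows$rate[all_rows$week %in% 21:39])
  expect_lt(abs(m_hat - 1.74), 0.25)
})

test_that("monthly circular coordinates are polar and recountable", {
  sim <- default_cohort()
  mo <- monthly_circular(sim$cohort, sim$population,
                         "2001-01-01", "2010-12-31")
  expect_equal(sort(unique(mo$angle)), 2 * pi * (0:11) / 12)
  expect_equal(mo$radius, mo$rate)
  # recount oracle for one band x month
  sub <- sim$cohort[sim$cohort$rti_related, ]
  dec_deaths <- sum(format(sub$dod, "%m") == "12" & sub$age_band == "1-4y")
  row <- mo[mo$age_band == "1-4y" & mo$month == 12L, ]
  expect_equal(row$deaths, dec_deaths)
  expect_equal(row$rate, dec_deaths / row$person_years * 1e5)
})

test_that("December-only deaths put all monthly mass at December", {
  cases <- tibble::tibble(
    age_band = "1-4y",
    dod = as.Date(c("2001-12-05", "2001-12-20")),
    rti_related = TRUE)
  pop <- tibble::tibble(age_band = "1-4y", year = 2001, population = 1e5)
  mo <- monthly_circular(cases, pop, "2001-01-01", "2001-12-31")
  band <- mo[mo$age_band == "1-4y", ]
  expect_true(all(band$rate[band$month != 12] == 0))
  expect_gt(band$rate[band$month == 12], 0)
})

test_that("season rates do the division and handle zero counts", {
  cases <- tibble::tibble(
    age_band = rep("1-4y", 100),
    dod = as.Date("2005-01-10"),     # winter
    rti_related = TRUE)
  pt <- tibble::tibble(age_band = c("1-4y", "1-4y"),
                       season = c("winter", "summer"),
                       person_years = c(2e6, 2e6))
  sr <- season_rates(cases, pt, "rti_related")
  expect_equal(sr$rate_winter, 5.0)
  expect_equal(sr$deaths_summer, 0L)
  expect_equal(sr$rate_summer, 0)
  expect_equal(sr$rate_summer_lo, 0)
  expect_gt(sr$rate_summer_hi, 0)   # one-sided interval
  bad_pt <- pt
  bad_pt$person_years[1] <- 0
  expect_error(season_rates(cases, bad_pt, "rti_related"), "person-time")
})

test_that("winter/summer partition conserves deaths and person-time", {
  sim <- default_cohort()
  pt <- season_persontime(sim$population, "2001-01-01", "2010-12-31")
  sr <- season_rates(sim$cohort, pt, "rti_related")
  all_row <- sr[sr$age_band == "all", ]
  expect_equal(all_row$deaths_winter + all_row$deaths_summer,
               sum(sim$cohort$rti_related))
  # constant annual populations: total PT = yearly population x days/365.25
  n_days <- as.numeric(as.Date("2010-12-31") - as.Date("2001-01-01")) + 1
  expect_equal(all_row$persontime_winter + all_row$persontime_summer,
               sum(sim$population$population) / 10 * n_days / 365.25,
               tolerance = 1e-6)
  band_rows <- sr[sr$age_band != "all", ]
  expect_equal(sum(band_rows$deaths_winter), all_row$deaths_winter)
  expect_equal(sum(band_rows$persontime_winter), all_row$persontime_winter)
})

test_that("excess estimation reproduces hand arithmetic and identities", {
  sr <- tibble::tibble(
    age_band = "all",
    deaths_winter = 3840L, deaths_summer = 1225L,
    persontime_winter = 3840 / 5.0 * 1e5,
    persontime_summer = 1225 / 2.9 * 1e5,
    rate_winter = 5.0, rate_summer = 2.9)
  ex <- excess_estimate(sr, n_years = 10, total_indicator_deaths = 5065)
  expect_equal(ex$rate_difference, 2.1)
  expect_equal(ex$rate_ratio, 5.0 / 2.9)
  # algebraic identity: RD route equals count-minus-expected route
  expect_equal(ex$excess_total,
               sr$deaths_winter -
                 sr$persontime_winter * sr$rate_summer / 1e5)
  expect_equal(ex$excess_annual * 10, ex$excess_total)
  # degenerate inputs
  eq <- sr
  eq$deaths_summer <- eq$deaths_winter
  eq$persontime_summer <- eq$persontime_winter
  eq$rate_summer <- eq$rate_winter
  exq <- excess_estimate(eq, 10)
  expect_equal(exq$rate_difference, 0)
  expect_equal(exq$excess_total, 0)
  expect_equal(exq$rate_ratio, 1)
  zs <- sr
  zs$deaths_summer <- 0L
  zs$rate_summer <- 0
  exz <- excess_estimate(zs, 10)
  expect_true(is.na(exz$rate_ratio))
  expect_equal(exz$rate_difference, 5.0)
})

test_that("with no winter forcing the rate-difference CI covers zero", {
  set.seed(61)
  cover <- replicate(200, {
    ptw <- 33 / 52 * 1e6
    pts <- 19 / 52 * 1e6
    dw <- rpois(1, 5e-5 * ptw)
    ds <- rpois(1, 5e-5 * pts)
    sr <- tibble::tibble(age_band = "x", deaths_winter = dw,
                         deaths_summer = ds,
                         persontime_winter = ptw, persontime_summer = pts,
                         rate_winter = dw / ptw * 1e5,
                         rate_summer = ds / pts * 1e5)
    ex <- excess_estimate(sr, 1)
    ex$rate_difference_lo <= 0 && 0 <= ex$rate_difference_hi
  })
  expect_gt(mean(cover), 0.95 - 3 * sqrt(0.95 * 0.05 / 200))
})
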