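test_that("episode window is closed at both ends and excludes post-death", {
  dod <- as.Date("2005-02-01")
  expect_true(episode_in_window(dod - 30, dod))
  expect_false(episode_in_window(dod - 31, dod))
  expect_true(episode_in_window(dod, dod))
  expect_false(episode_in_window(dod + 1, dod))
  expect_true(episode_in_window(dod - 40, dod, window_days = 60))
})

phenotyped_fixture <- function(deaths, episodes = empty_episodes(), ...) {
  phenotype_cases(link_records(deaths, episodes, quiet = TRUE), ...)
}

test_that("certificate and episode routes both flag RTI correctly", {
  dod <- as.Date("2005-02-01")
  # certificate route, no episodes
  c1 <- phenotyped_fixture(
    make_death("A", dod = dod, mention_codes = list(c("Q909", "J180")),
               underlying_cause = "Q909"))
  expect_true(c1$rti_related)
  expect_true(c1$cert_rti)
  expect_false(c1$hosp_rti)
  # episode route: certificate silent, in-window episode coded
  c2 <- phenotyped_fixture(
    make_death("A", dod = dod, mention_codes = list("G809"),
               underlying_cause = "G809"),
    make_episode("A", start_date = dod - 10))
  expect_true(c2$rti_related)
  expect_false(c2$cert_rti)
  expect_true(c2$hosp_rti)
  # out-of-window episode never flags RTI
  c3 <- phenotyped_fixture(
    make_death("A", dod = dod, mention_codes = list("G809"),
               underlying_cause = "G809"),
    make_episode("A", start_date = dod - 40))
  expect_false(c3$rti_related)
  expect_true(c3$chronic_neurological_sensory)  # G80.9 on the certificate
})

test_that("chronic lookback accepts episodes up to one year before death", {
  dod <- as.Date("2005-02-01")
  cc <- phenotyped_fixture(
    make_death("A", dod = dod, dob = as.Date("2001-01-01"),
               mention_codes = list("R99")),
    make_episode("A", start_date = dod - 200,
                 diagnosis_codes = list("Q212")))
  expect_true(cc$chronic_cardiac)
  far <- phenotyped_fixture(
    make_death("A", dod = dod, dob = as.Date("2001-01-01"),
               mention_codes = list("R99")),
    make_episode("A", start_date = dod - 400,
                 diagnosis_codes = list("Q212")))
  expect_false(far$chronic_cardiac)
})

test_that("single-case phenotyping carries evidence for every true flag", {
  dod <- as.Date("2005-02-01")
  cases <- link_records(
    make_death("A", dod = dod, mention_codes = list(c("G809", "J180")),
               underlying_cause = "G809"),
    make_episode("A", start_date = dod - 5,
                 diagnosis_codes = list(c("J219", "Q212"))),
    quiet = TRUE)
  res <- phenotype_case(cases[1, ])
  expect_true(res$rti_related)
  expect_true(res$any_respiratory_related)
  expect_setequal(res$chronic_groups_present,
                  c("neurological_sensory", "cardiac"))
  expect_true(all(c("rti_related", "neurological_sensory", "cardiac") %in%
                    names(res$evidence)))
  ev <- res$evidence$rti_related
  expect_true(length(ev$certificate) > 0 || nrow(ev$episodes) > 0)
  expect_equal(res$evidence$cardiac$episodes$start_date, dod - 5)
})

test_that("phenotyping is invariant to episode and code order", {
  dod <- as.Date("2005-02-01")
  d <- make_death("A", dod = dod, mention_codes = list(c("G809", "J180")),
                  underlying_cause = "G809")
  eps <- dplyr::bind_rows(
    make_episode("A", start_date = dod - 5,
                 diagnosis_codes = list(c("A099", "J219"))),
    make_episode("A", start_date = dod - 200,
                 diagnosis_codes = list("Q212")))
  base <- phenotyped_fixture(d, eps)
  d2 <- d
  d2$mention_codes <- list(rev(d$mention_codes[[1]]))
  eps2 <- eps[2:1, ]
  eps2$diagnosis_codes <- lapply(eps2$diagnosis_codes, rev)
  perm <- phenotyped_fixture(d2, eps2)
  cols <- c("rti_related", "any_respiratory_related",
            paste0("chronic_", chronic_group_names()))
  expect_identical(base[cols], perm[cols])
})

test_that("cluster and window monotonicity hold on a simulated cohort", {
  sim <- simulate_cohort(small_params(seed = 31L))
  cases <- link_records(sim$deaths, sim$episodes, quiet = TRUE)
  ph30 <- phenotype_cases(cases, window_days = 30)
  ph60 <- phenotype_cases(cases, window_days = 60)
  expect_true(all(ph30$any_respiratory_related[ph30$rti_related]))
  expect_true(all(ph60$rti_related[ph30$rti_related]))
  expect_true(all(ph60$any_respiratory_related[ph30$any_respiratory_related]))
})

test_that("agreement is plain 2x2 concordance arithmetic", {
  dod <- as.Date("2005-02-01")
  deaths <- dplyr::bind_rows(
    make_death("A", dod = dod, mention_codes = list("J180"),
               underlying_cause = "J180"),     # cert only
    make_death("B", dod = dod, mention_codes = list("R99")),  # hosp only
    make_death("C", dod = dod, mention_codes = list("J180"),
               underlying_cause = "J180"),     # both
    make_death("D", dod = dod, mention_codes = list("R99"))   # neither
  )
  eps <- dplyr::bind_rows(
    make_episode("B", start_date = dod - 3),
    make_episode("C", start_date = dod - 3))
  ph <- phenotyped_fixture(deaths, eps)
  agr <- agreement_table(ph, "rti", restrict_to_hospital_deaths = FALSE)
  expect_equal(agr$percent_agreement, 50)
  expect_equal(agr$both, 1L)
  expect_equal(agr$neither, 1L)
  expect_error(agreement_table(ph[0, ], "rti"), "no cases")
})

test_that("agreement on synthetic data matches the 2x2 expectation", {
  f <- 0.28
  p <- small_params(cert_sensitivity = 0.8, hosp_sensitivity = 0.8,
                    p_linked = 1, rti_fraction = f, seed = 32L)
  sim <- simulate_cohort(p)
  ph <- phenotype_cases(link_records(sim$deaths, sim$episodes, quiet = TRUE))
  agr <- agreement_table(ph, "rti", restrict_to_hospital_deaths = FALSE)
  expected <- (1 - f) + f * (0.8 * 0.8 + 0.2 * 0.2)
  se <- sqrt(expected * (1 - expected) / agr$n)
  expect_lt(abs(agr$percent_agreement / 100 - expected), 3 * se)
})

test_that("mention-vs-underlying ratio reduces to a count ratio", {
  dod <- as.Date("2005-02-01")
  pop <- tibble::tibble(age_band = "1-4y", year = 2005, population = 1e5)
  all_under <- phenotyped_fixture(
    make_death(c("A", "B"), dod = dod,
               mention_codes = list("J180", "J219"),
               underlying_cause = c("J180", "J219")))
  r1 <- mention_vs_underlying_ratio(all_under, cluster_rti(), pop)
  expect_equal(r1$ratio[r1$age_band == "all"], 1.0)
  # 4 any-mention, 1 underlying -> ratio 4
  deaths <- make_death(c("A", "B", "C", "D"), dod = dod,
                       mention_codes = list(c("J180"), c("R99", "J180"),
                                            c("R99", "J180"), c("R99", "J180")),
                       underlying_cause = c("J180", "R99", "R99", "R99"))
  r2 <- mention_vs_underlying_ratio(phenotyped_fixture(deaths),
                                    cluster_rti(), pop)
  expect_equal(r2$ratio[r2$age_band == "all"], 4.0)
  # zero underlying count flagged, not an exception
  none <- make_death("A", dod = dod, mention_codes = list(c("R99", "J180")),
                     underlying_cause = "R99")
  r3 <- mention_vs_underlying_ratio(phenotyped_fixture(none),
                                    cluster_rti(), pop)
  expect_true(r3$undefined[r3$age_band == "all"])
  expect_true(is.na(r3$ratio[r3$age_band == "all"]))
})

test_that("mention-vs-underlying matches a direct recount on synthetic data", {
  sim <- simulate_cohort(small_params(seed = 33L))
  cases <- link_records(sim$deaths, sim$episodes, quiet = TRUE)
  res <- mention_vs_underlying_ratio(cases, cluster_rti(), sim$population)
  # independent rowwise recount
  n_any <- sum(vapply(seq_len(nrow(cases)), function(i) {
    cert <- any(code_in_cluster(cases$mention_codes[[i]], cluster_rti()))
    ep <- cases$episodes[[i]]
    hosp <- FALSE
    if (nrow(ep) > 0) {
      for (j in seq_len(nrow(ep))) {
        if (ep$start_date[j] >= cases$dod[i] - 30 &&
            ep$start_date[j] <= cases$dod[i] &&
            any(code_in_cluster(ep$diagnosis_codes[[j]], cluster_rti()))) {
          hosp <- TRUE
        }
      }
    }
    cert || hosp
  }, TRUE))
  n_under <- sum(code_in_cluster(cases$underlying_cause, cluster_rti()))
  row_all <- res[res$age_band == "all", ]
  expect_equal(row_all$n_any, n_any)
  expect_equal(row_all$n_underlying, n_under)
  expect_equal(row_all$ratio, n_any / n_under)
})
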