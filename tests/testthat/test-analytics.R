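test_that("standard-IVS eligibility screen: age >= 12 and ASA I-II", {
  expect_true(ivs_eligible(12, 2))    # boundary of the criterion
  expect_false(ivs_eligible(11, 1))
  expect_false(ivs_eligible(30, 3))
  expect_equal(ivs_eligible(c(12, 11, 30, 80), c(2, 1, 3, 2)),
               c(TRUE, FALSE, FALSE, TRUE))
  expect_error(ivs_eligible(10, 7), "asa_grade")
  expect_error(ivs_eligible(-1, 1), "age_years")
})

test_that("service summary aggregates footprints and rates", {
  ep <- make_episodes_with_co2e(c(10, 20))
  s <- summarise_service(ep)
  expect_equal(s$n_episodes, 2L)
  expect_equal(s$total_co2e_kg, 30)
  expect_equal(s$mean_co2e_kg_per_episode, 15)
  # single worked-example episode: mean = total ~ 15.77
  one <- make_episodes(n = 1L)
  s1 <- summarise_service(one)
  expect_lt(abs(s1$total_co2e_kg - 15.77), 0.01)
  expect_equal(s1$mean_co2e_kg_per_episode, s1$total_co2e_kg)
  expect_error(summarise_service(ep[0, ]), "empty")
  multi <- rbind(ep, make_episodes_with_co2e(5, service_id = "svcB"))
  expect_error(summarise_service(multi), "exactly one")
})

test_that("no hidden cross-service state in multi-service summaries", {
  cohort <- generate_cohort(generator_params(n_episodes = 300L, seed = 9))
  ep <- cohort$episodes
  all_s <- summarise_services(ep)
  drop_id <- all_s$service_id[1]
  reduced <- summarise_services(ep[ep$service_id != drop_id, ])
  kept <- all_s[all_s$service_id != drop_id, ]
  rownames(kept) <- NULL
  expect_equal(reduced, kept)
})

test_that("eligibility rate ignores ordering and footprint constants", {
  cohort <- generate_cohort(generator_params(n_episodes = 200L, seed = 3))
  ep <- cohort$episodes[cohort$episodes$service_id ==
                          cohort$episodes$service_id[1], ]
  a <- summarise_service(ep)$eligibility_rate
  b <- summarise_service(ep[rev(seq_len(nrow(ep))), ])$eligibility_rate
  c2 <- summarise_service(ep, gas_constants(gwp = 273))$eligibility_rate
  expect_identical(a, b)
  expect_identical(a, c2)
})

test_that("acclimatisation comparison pools per-service rates unweighted", {
  # services with exact success rates 0.90, 0.92 (offering) and 0.94 (not)
  mk <- function(id, n, n_ok, offers) {
    ep <- make_episodes(n = n, service_id = id,
                        procedure = if (offers) "acclimatisation" else "extraction")
    ep$success <- seq_len(n) <= n_ok
    ep
  }
  ep <- rbind(mk("s1", 10L, 9L, TRUE), mk("s2", 25L, 23L, TRUE),
              mk("s3", 50L, 47L, FALSE))
  pol <- data.frame(service_id = c("s1", "s2", "s3"),
                    offers_acclimatisation = c(TRUE, TRUE, FALSE))
  got <- success_by_acclimatisation_policy(ep, pol)
  expect_equal(got$offering, mean(c(0.90, 0.92)))
  expect_equal(got$non_offering, 0.94)
  # episode weighting is the n-weighted alternative
  w <- success_by_acclimatisation_policy(ep, pol, weighting = "episode")
  expect_equal(w$offering, (9 + 23) / 35)
  # degenerate: everyone succeeds
  ep$success <- TRUE
  all_ok <- success_by_acclimatisation_policy(ep, pol)
  expect_equal(c(all_ok$offering, all_ok$non_offering), c(1, 1))
  # an empty group is NA, never zero
  pol$offers_acclimatisation <- TRUE
  na_grp <- success_by_acclimatisation_policy(ep, pol)
  expect_true(is.na(na_grp$non_offering))
})

test_that("acclimatisation success probabilities are recovered from simulation", {
  p <- generator_params(n_episodes = 8000L, seed = 17)
  cohort <- generate_cohort(p)
  got <- success_by_acclimatisation_policy(cohort$episodes, cohort$services,
                                           weighting = "episode")
  # binomial error at group sizes of thousands is well under 2 points
  expect_lt(abs(got$offering - p$success_rate_acclim), 0.02)
  expect_lt(abs(got$non_offering - p$success_rate_no_acclim), 0.02)
})

test_that("national rollup pools exactly and anonymises stably", {
  s1 <- summarise_service(make_episodes_with_co2e(c(40, 60), "alpha"))
  s2 <- summarise_service(make_episodes_with_co2e(c(100, 150, 50), "beta"))
  both <- rbind(s1, s2)
  roll <- national_rollup(both, anonymise = FALSE)
  # identity on a single service
  solo <- national_rollup(s1, anonymise = FALSE)
  expect_equal(solo$pooled$mean_co2e_kg_per_episode,
               s1$mean_co2e_kg_per_episode)
  # per-service mean of period totals: (100 + 300) / 2
  expect_equal(roll$pooled$mean_service_total_co2e_kg, 200)
  # episode-weighted pooled mean is total / total episodes, exactly
  expect_equal(roll$pooled$mean_co2e_kg_per_episode,
               sum(both$total_co2e_kg) / sum(both$n_episodes))
  expect_equal(roll$pooled$mean_co2e_kg_per_episode, 400 / 5)
  anon <- national_rollup(both, anonymise = TRUE)
  expect_equal(anon$services$service_id, c("service_01", "service_02"))
  expect_error(national_rollup(both[0, ]), "no service summaries")
})

test_that("pseudonyms are stable under reordering", {
  ids <- c("zeta", "alpha", "mid", "alpha")
  expect_equal(service_pseudonyms(ids),
               c("service_03", "service_01", "service_02", "service_01"))
  expect_equal(service_pseudonyms(rev(ids)), rev(service_pseudonyms(ids)))
})

test_that("flow-by-age export carries a rank-correlation diagnostic", {
  ep <- make_episodes(n = 6L, flow = c(4, 5, 6, 5, 7, 4),
                      age = c(5L, 9L, 12L, 30L, 7L, 15L))
  out <- flow_by_age(ep)
  expect_named(out, c("age_years", "flow_lpm"))
  expect_equal(attr(out, "spearman_rho"),
               cor(ep$age_years, ep$flow_lpm, method = "spearman"))
})
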