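test_that("annual procurement reproduces the printed weekly volumes", {
  reg <- cylinder_registry()
  e10 <- data.frame(site_id = "A", cylinder_size = "E", quantity = 10L,
                    period_days = 365L)
  g6 <- data.frame(site_id = "B", cylinder_size = "G", quantity = 6L,
                   period_days = 365L)
  expect_equal(round(weekly_procured_volume(e10, reg)), 346)
  expect_equal(round(weekly_procured_volume(g6, reg)), 1038)
  # unit period: one E cylinder over exactly 7 days
  e1 <- data.frame(site_id = "A", cylinder_size = "E", quantity = 1L,
                   period_days = 7L)
  expect_equal(weekly_procured_volume(e1, reg), 1800)
  # mixed records sum
  both <- rbind(e10, transform(g6, site_id = "A"))
  expect_equal(weekly_procured_volume(both, reg),
               weekly_procured_volume(e10, reg) + weekly_procured_volume(g6, reg))
  expect_error(weekly_procured_volume(transform(e10, cylinder_size = "Q"), reg),
               "unknown cylinder size code")
})

test_that("wastage worked examples: 13% and 50% as printed", {
  reg <- cylinder_registry()
  p_e <- weekly_procured_volume(
    data.frame(site_id = "A", cylinder_size = "E", quantity = 10L,
               period_days = 365L), reg)
  p_g <- weekly_procured_volume(
    data.frame(site_id = "B", cylinder_size = "G", quantity = 6L,
               period_days = 365L), reg)
  expect_equal(estimate_wastage(p_e, 300)$wastage_pct, 13)
  expect_equal(estimate_wastage(p_g, 519)$wastage_pct, 50)
})

test_that("wastage flags: ok / investigate / negative_anomaly", {
  expect_equal(estimate_wastage(100, 100)$flag, "ok")
  expect_equal(estimate_wastage(100, 100)$wastage_fraction, 0)
  neg <- estimate_wastage(100, 150)
  expect_equal(neg$wastage_fraction, -0.5)
  expect_equal(neg$flag, "negative_anomaly")
  expect_equal(estimate_wastage(100, 75, threshold = 0.20)$flag, "investigate")
  expect_equal(estimate_wastage(100, 75, threshold = 0.25)$flag, "ok")
  expect_error(estimate_wastage(0, 10), "procured")
  expect_error(estimate_wastage(100, -1), "administered")
})

test_that("recovery: estimate_wastage(p, p(1-w)) returns w", {
  for (p in c(50, 346.153846153846, 1038.46, 5000)) {
    for (w in c(-0.5, 0, 0.13, 0.5, 0.9)) {
      expect_equal(estimate_wastage(p, p * (1 - w))$wastage_fraction, w,
                   tolerance = 1e-12)
    }
  }
})

test_that("wastage fraction is monotone in administered volume and threshold-free", {
  admin <- seq(0, 200, by = 10)
  w <- vapply(admin, function(a) estimate_wastage(120, a)$wastage_fraction,
              numeric(1))
  expect_true(all(diff(w) < 0))
  # flag depends on threshold, the fraction never does
  for (th in c(0, 0.1, 0.25, 1)) {
    expect_equal(estimate_wastage(120, 80, threshold = th)$wastage_fraction,
                 1 - 80 / 120)
  }
})

test_that("wastage eligibility: only shared manifolds are excluded", {
  sites <- data.frame(
    supply_type = c("cylinder", "manifold", "manifold"),
    shared_supply = c(FALSE, TRUE, FALSE)
  )
  expect_equal(eligible_for_wastage(sites), c(TRUE, FALSE, TRUE))
})

test_that("episodes per cylinder from the national mean footprint", {
  k <- gas_constants()
  mean_vol <- 28.62 / (k$gwp * k$density_kg_per_l)  # back-derived, ~54.42 L
  expect_equal(mean_vol, 54.42, tolerance = 0.01 / 54.42)
  n <- episodes_per_cylinder(mean_vol)
  expect_equal(n, 1800 / mean_vol)
  expect_equal(round(n), 33)
  # inverse proportionality and the unit case
  expect_equal(episodes_per_cylinder(1800), 1)
  expect_equal(episodes_per_cylinder(mean_vol / 2), 2 * n)
  expect_error(episodes_per_cylinder(0), "mean_episode_volume_l")
})

test_that("period conversion follows the 52-week-year convention", {
  expect_equal(period_weeks(365), 52)
  expect_equal(period_weeks(7), 1)
  expect_equal(period_weeks(14), 2)
  expect_equal(period_weeks(30), 30 / 7)
  expect_error(period_weeks(0), "period_days")
})

test_that("registry is user-extensible and rejects duplicates", {
  reg <- cylinder_registry(E = 1800, G = 9000, J = 18000)
  expect_equal(cylinder_volume(reg, c("J", "E")), c(18000, 1800))
  expect_error(cylinder_registry(E = 1800, E = 2000), "unique")
  expect_error(cylinder_registry(E = -5), "positive")
})
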