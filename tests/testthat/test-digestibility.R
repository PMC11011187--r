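test_that("nutrient intake follows the daily mass balance", {
  # 7 days x (offered 100, refused 0), diet DM 90%, CP 12% on a DM basis:
  # CP intake = 7 x 100 x 0.9 x 0.12 = 75.6 g
  diet <- diet_spec("D", data.frame(ingredient_id = "RD", fraction = 1),
                    role = "reference")
  prof <- proximate_profile("RD", 90, 12, 4, 6, 75, 3,
                            basis = "dry_matter")
  fec <- proximate_profile("fec", 100, 20, 5, 15, 50, 10,
                           basis = "dry_matter")
  recs <- data.frame(animal_id = "a1", day = 1:7, offered_g = 100,
                     refused_g = 0, feces_fresh_g = 10,
                     feces_dm_fraction = 0.3)
  ds <- trial_dataset(diet, prof, list(a1 = fec), recs,
                      data.frame(animal_id = "a1", initial_g = 800,
                                 final_g = 830))
  fx <- nutrient_flux(ds, "a1")
  expect_equal(fx$intake_g[["cp"]], 75.6)
  expect_equal(fx$intake_g[["dm"]], 7 * 100 * 0.9)

  # a day with offered == refused contributes nothing
  recs2 <- rbind(recs, data.frame(animal_id = "a1", day = 8,
                                  offered_g = 50, refused_g = 50,
                                  feces_fresh_g = 0,
                                  feces_dm_fraction = 0.3))
  ds2 <- trial_dataset(diet, prof, list(a1 = fec), recs2, ds$weights)
  expect_equal(nutrient_flux(ds2, "a1")$intake_g, fx$intake_g)

  expect_error(nutrient_flux(ds, "nope"), "unknown animal")
})

test_that("fluxes match a naive day-by-day summation on simulated data", {
  sim <- simulate_trial(trial_sim_config(seed = 301))
  for (a in animal_ids(sim$dataset)) {
    fx <- nutrient_flux(sim$dataset, a)
    or <- oracle_flux(sim$dataset, a)
    expect_equal(fx$intake_g, or$intake_g, tolerance = 1e-12)
    expect_equal(fx$fecal_g, or$fecal_g, tolerance = 1e-12)
  }
})

test_that("apparent digestibility is (I - F)/I x 100, never clamped", {
  fx <- list(intake_g = c(cp = 75.6), fecal_g = c(cp = 0))
  expect_equal(as.numeric(apparent_digestibility(fx)), 100)
  fx2 <- list(intake_g = c(cp = 100), fecal_g = c(cp = 25))
  expect_equal(as.numeric(apparent_digestibility(fx2)), 75)
  fx3 <- list(intake_g = c(cp = 80), fecal_g = c(cp = 88))
  d <- apparent_digestibility(fx3)
  expect_equal(as.numeric(d), -10)
  expect_true(attr(d, "out_of_range")[["cp"]])
  fx4 <- list(intake_g = c(cp = 0), fecal_g = c(cp = 0))
  expect_error(apparent_digestibility(fx4), "zero intake.*cp")
})

test_that("digested mass balances: I - F equals D x I / 100", {
  sim <- simulate_trial(trial_sim_config(seed = 302))
  for (a in animal_ids(sim$dataset)[1:3]) {
    fx <- nutrient_flux(sim$dataset, a)
    d <- apparent_digestibility(fx)
    expect_equal(fx$intake_g[names(d)] - fx$fecal_g[names(d)],
                 d * fx$intake_g[names(d)] / 100, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("treatment aggregation gives mean and n-1 sd across animals", {
  # per-animal values {70, 75, 80} -> mean 75, sd 5
  co <- digestibility_coefficients(
    mean_pct = c(cp = mean(c(70, 75, 80))),
    sd_pct = c(cp = sd(c(70, 75, 80))), n_animals = 3L)
  expect_equal(unname(co$mean_pct), 75)
  expect_equal(unname(co$sd_pct), 5)

  # identical animals -> sd exactly 0
  sim <- simulate_trial(noise_free(trial_sim_config(seed = 303)))
  co2 <- diet_digestibility(sim$dataset)
  expect_equal(unname(co2$sd_pct), rep(0, length(co2$sd_pct)),
               tolerance = 1e-10)
  expect_identical(co2$n_animals, 9L)

  pooled <- diet_digestibility(sim$dataset, method = "pooled")
  expect_equal(pooled$mean_pct, co2$mean_pct, tolerance = 1e-10)
})

test_that("nutrient shares weight by nutrient intake, not DM proportion", {
  ref <- proximate_profile("RD", 91, 12, 4, 5.8, 75.5, 2.7)
  rcm <- proximate_profile("RCM", 85, 15, 5.5, 38, 30.5, 11)
  s <- nutrient_share(ref, rcm, 0.8)
  expect_equal(s[["cp"]], 9.6 / 12.6, tolerance = 1e-12)

  # equal concentrations collapse to the as-fed fraction
  same <- nutrient_share(ref, ref, 0.8)
  expect_equal(as.numeric(same), rep(0.8, 5), tolerance = 1e-12)

  # an ingredient without CF leaves the reference supplying all of it
  bm <- suppressWarnings(proximate_profile("BM", 92, 72.4, 0.5, NA, NA, 4))
  s2 <- nutrient_share(ref, bm, 0.8)
  expect_identical(s2[["cf"]], 1)

  expect_error(nutrient_share(ref, rcm, 1), "strictly between")
})

test_that("difference method inverts the blend identity", {
  nuts <- c(cp = 70)
  expect_equal(difference_method(nuts, c(cp = 70), c(cp = 0.5))[["cp"]], 70)
  expect_equal(difference_method(c(cp = 80), c(cp = 70), c(cp = 0))[["cp"]],
               80)
  expect_warning(
    out <- difference_method(c(cf = 60), c(cf = 60), c(cf = 1)),
    "unidentifiable")
  expect_true(is.na(out[["cf"]]))

  # strictly increasing in the mixed-diet digestibility
  dd <- seq(50, 90, by = 5)
  rec <- vapply(dd, function(x) {
    difference_method(c(cp = x), c(cp = 70), c(cp = 0.6))[["cp"]]
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("noise-free trials invert exactly through the full chain", {
  set.seed(99)
  for (i in 1:10) {
    cfg <- noise_free(random_truth_config(seed = 1000 + i))
    sim <- simulate_trial(cfg)
    rec <- recover_ingredient_digestibility(
      sim$dataset, cfg$ref_digestibility, cfg$ref_profile, cfg$ing_profile)
    truth <- cfg$ing_digestibility[names(rec$mean_pct)]
    expect_equal(rec$mean_pct, truth, tolerance = 1e-11)
  }
})
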