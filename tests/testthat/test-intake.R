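test_that("metabolic weight is (kg)^0.75 and strictly monotone", {
  expect_equal(metabolic_weight(1000), 1)
  expect_equal(metabolic_weight(822), 0.8633, tolerance = 5e-5)
  w <- seq(200, 2000, by = 50)
  expect_true(all(diff(metabolic_weight(w)) > 0))
  expect_error(metabolic_weight(0), "> 0")
})

test_that("attributed intake scales with inclusion and body size", {
  diet <- diet_spec("D", data.frame(ingredient_id = c("RD", "X"),
                                    fraction = c(0.8, 0.2)),
                    role = "test", test_ingredient_id = "X")
  prof <- proximate_profile("mix", 100, 12, 4, 6, 75, 3, closure_tol = Inf)
  fec <- proximate_profile("fec", 100, 20, 5, 15, 50, 10,
                           basis = "dry_matter")
  recs <- data.frame(animal_id = "a1", day = 1:7, offered_g = 50,
                     refused_g = 0, feces_fresh_g = 10,
                     feces_dm_fraction = 0.3)
  wts <- data.frame(animal_id = "a1", initial_g = 1000, final_g = 1000)
  ds <- trial_dataset(diet, prof, list(a1 = fec), recs, wts)

  # 50 g DM/day at 20% inclusion -> 10 g/day attributed
  s <- intake_summary(ds, 0.2)
  expect_equal(s$per_animal$daily_dm_g, 50)
  expect_equal(s$per_animal$attributed_dm_g, 10)
  expect_equal(s$per_animal$pct_live_weight, 1)  # 10 g at 1000 g
  expect_equal(s$per_animal$g_per_kg_metabolic, 10)

  # 6.5 g/day attributed at 1000 g -> 0.65 % of live weight
  s2 <- intake_summary(ds, 0.13)
  expect_equal(s2$per_animal$pct_live_weight, 0.65)

  expect_error(intake_summary(ds, 1.2), "inclusion_fraction")
  ds$weights <- wts[0, ]
  expect_error(intake_summary(ds, 0.2), "a1")
})

test_that("reference and test attributed intakes sum to the total exactly", {
  sim <- simulate_trial(trial_sim_config(seed = 401))
  cfg <- trial_sim_config(seed = 401)
  incl <- cfg$inclusion_fraction
  s_test <- intake_summary(sim$dataset, incl,
                           ingredient_dm_pct = cfg$ing_profile$dm_pct)
  s_ref <- intake_summary(sim$dataset, 1 - incl,
                          ingredient_dm_pct = cfg$ref_profile$dm_pct)
  expect_equal(s_test$per_animal$attributed_dm_g +
                 s_ref$per_animal$attributed_dm_g,
               s_test$per_animal$daily_dm_g, tolerance = 1e-12)
})

test_that("treatment intake means match a per-animal recomputation", {
  sim <- simulate_trial(trial_sim_config(seed = 402))
  s <- intake_summary(sim$dataset, 0.2)
  # brute force over animals
  vals <- vapply(animal_ids(sim$dataset), function(a) {
    r <- sim$dataset$records[sim$dataset$records$animal_id == a, ]
    mean(r$offered_g - r$refused_g) * sim$dataset$diet_profile$dm_pct / 100
  }, numeric(1))
  expect_equal(s$treatment$mean[s$treatment$metric == "daily_dm_g"],
               mean(vals), tolerance = 1e-12)
  expect_equal(s$treatment$sd[s$treatment$metric == "daily_dm_g"],
               sd(vals), tolerance = 1e-12)
})

test_that("doubling masses and weights rescales metabolic intake by 2^0.25", {
  sim <- simulate_trial(trial_sim_config(seed = 403))
  ds2 <- sim$dataset
  for (col in c("offered_g", "refused_g", "feces_fresh_g")) {
    ds2$records[[col]] <- 2 * ds2$records[[col]]
  }
  ds2$weights$initial_g <- 2 * ds2$weights$initial_g
  ds2$weights$final_g <- 2 * ds2$weights$final_g
  s1 <- intake_summary(sim$dataset, 0.2)
  s2 <- intake_summary(ds2, 0.2)
  expect_equal(s2$per_animal$g_per_kg_metabolic,
               s1$per_animal$g_per_kg_metabolic * 2 / 2^0.75,
               tolerance = 1e-12)
  expect_equal(s2$per_animal$pct_live_weight, s1$per_animal$pct_live_weight,
               tolerance = 1e-12)
})

test_that("gain summaries divide total gain over the experimental days", {
  diet <- diet_spec("D", data.frame(ingredient_id = "RD", fraction = 1),
                    role = "reference")
  prof <- proximate_profile("RD", 91, 12, 4, 5.8, 75.5, 2.7)
  fec <- proximate_profile("fec", 100, 20, 5, 15, 50, 10,
                           basis = "dry_matter")
  recs <- data.frame(animal_id = "a1", day = 1, offered_g = 50,
                     refused_g = 0, feces_fresh_g = 10,
                     feces_dm_fraction = 0.3)
  wts <- data.frame(animal_id = "a1", initial_g = 807.78, final_g = 836.33)
  ds <- trial_dataset(diet, prof, list(a1 = fec), recs, wts)
  g <- gain_summary(ds, n_days = 7)
  expect_equal(g$per_animal$total_gain_g, 28.55)
  expect_equal(g$per_animal$daily_gain_g, 4.08, tolerance = 0.01 / 4.08)

  wts0 <- data.frame(animal_id = "a1", initial_g = 800, final_g = 800)
  ds0 <- trial_dataset(ds$diet, prof, ds$fecal_profiles, recs, wts0)
  expect_equal(gain_summary(ds0)$per_animal$total_gain_g, 0)
  expect_error(gain_summary(ds, n_days = 0), "n_days")
})

test_that("gain aggregates match independent recomputation", {
  sim <- simulate_trial(trial_sim_config(seed = 404))
  g <- gain_summary(sim$dataset, n_days = 7)
  w <- sim$dataset$weights
  expect_equal(g$per_animal$daily_gain_g, (w$final_g - w$initial_g) / 7,
               tolerance = 1e-12)
  expect_equal(g$treatment$mean[g$treatment$metric == "daily_gain_g"],
               mean((w$final_g - w$initial_g) / 7), tolerance = 1e-12)
})
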