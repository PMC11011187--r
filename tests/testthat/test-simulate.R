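test_that("simulation is deterministic under a fixed seed", {
  cfg <- trial_sim_config(seed = 123)
  s1 <- simulate_trial(cfg)
  s2 <- simulate_trial(cfg)
  expect_identical(s1$dataset$records, s2$dataset$records)
  expect_identical(s1$dataset$weights, s2$dataset$weights)
  expect_identical(s1$truth$per_animal_diet, s2$truth$per_animal_diet)

  s3 <- simulate_trial(trial_sim_config(seed = 124))
  expect_false(identical(s1$dataset$records, s3$dataset$records))

  # the caller's RNG stream is untouched
  set.seed(55)
  before <- rnorm(3)
  set.seed(55)
  invisible(simulate_trial(cfg))
  expect_identical(rnorm(3), before)
})

test_that("analyze(simulate(truth, noise = 0)) returns truth", {
  set.seed(500)
  for (i in 1:8) {
    cfg <- noise_free(random_truth_config(seed = 2000 + i))
    sim <- simulate_trial(cfg)
    # mixed-diet digestibility recovers the configured blend truth
    co <- diet_digestibility(sim$dataset)
    expect_equal(co$mean_pct, sim$truth$diet_digestibility[names(co$mean_pct)],
                 tolerance = 1e-11)
    # and the difference method returns the ingredient truth
    rec <- recover_ingredient_digestibility(
      sim$dataset, cfg$ref_digestibility, cfg$ref_profile, cfg$ing_profile)
    expect_equal(rec$mean_pct,
                 cfg$ing_digestibility[names(rec$mean_pct)],
                 tolerance = 1e-11)
  }
})

test_that("a pure reference configuration is fed alone and fully direct", {
  cfg <- noise_free(trial_sim_config(seed = 9, inclusion_fraction = 0))
  sim <- simulate_trial(cfg)
  expect_identical(sim$dataset$diet$role, "reference")
  expect_equal(sum(sim$dataset$diet$components$fraction), 1)
  co <- diet_digestibility(sim$dataset)
  expect_equal(co$mean_pct, cfg$ref_digestibility[names(co$mean_pct)],
               tolerance = 1e-11)
})

test_that("infeasible truth configurations are rejected with a diagnostic", {
  expect_error(trial_sim_config(seed = 1, inclusion_fraction = 1.2),
               "inclusion_fraction")
  cfg <- trial_sim_config(seed = 1)
  cfg$ing_digestibility[["cp"]] <- 130
  expect_error(simulate_trial(cfg), "outside \\[0, 100\\]")

  # jointly inconsistent truths: fecal CF would exceed fecal DM
  bad <- trial_sim_config(
    seed = 2,
    ref_profile = proximate_profile("R", 90, 10, 4, 40, 40, 6),
    ref_digestibility = c(dm = 99, cp = 99, ee = 99, cf = 5, nfe = 99),
    ing_profile = proximate_profile("I", 90, 60, 10, NA, NA, 30),
    ing_digestibility = c(dm = 99, cp = 99, ee = 99, cf = NA, nfe = NA))
  expect_error(simulate_trial(noise_free(bad)), "fecal")
})

test_that("distinct seeds give uncorrelated recovered estimates", {
  ests <- vapply(1:12, function(s) {
    sim <- simulate_trial(trial_sim_config(seed = 6000 + s))
    diet_digestibility(sim$dataset)$mean_pct[["cp"]]
  }, numeric(1))
  expect_gt(sd(ests), 0)
  expect_gt(length(unique(ests)), 10L)
})

test_that("study scenario configs reproduce the published formulation", {
  scen <- biowaste_scenarios(seed = 14)
  expect_named(scen, c("T0", "T1", "T2", "T3", "T4"))
  expect_identical(scen$T0$inclusion_fraction, 0)

  # T1 blend CP must equal the published ration value, 12.60%
  sim <- simulate_trial(noise_free(scen$T1))
  expect_equal(sim$dataset$diet_profile$cp_pct, 12.60, tolerance = 1e-12)

  # published ration table reproduced for every diet (DM, CP, EE, CF)
  tab <- biowaste_diet_table()
  profs <- biowaste_meal_profiles()
  ref <- reference_diet_profile()
  for (i in 2:5) {
    b <- blend_diet_profile(list(ref, profs[[tab$test_ingredient[i]]]),
                            c(0.8, 0.2))
    expect_lt(abs(b$dm_pct - tab$dm_pct[i]), 0.005)
    expect_lt(abs(b$cp_pct - tab$cp_pct[i]), 0.005)
    expect_lt(abs(b$ee_pct - tab$ee_pct[i]), 0.005)
    expect_lt(abs(b$cf_pct - tab$cf_pct[i]), 0.005)
  }
})

test_that("full pipeline on noise-free scenarios returns published means", {
  scen <- biowaste_scenarios(seed = 15)
  t0 <- simulate_trial(noise_free(scen$T0))
  d_ref <- diet_digestibility(t0$dataset)$mean_pct
  digs <- biowaste_meal_digestibility()
  profs <- biowaste_meal_profiles()
  ref <- reference_diet_profile()
  for (i in 1:4) {
    m <- names(profs)[i]
    sim <- simulate_trial(noise_free(scen[[paste0("T", i)]]))
    rec <- recover_ingredient_digestibility(sim$dataset, d_ref, ref,
                                            profs[[m]])
    truth <- digs[[m]]$mean_pct[names(rec$mean_pct)]
    # >= 6 significant digits
    expect_lt(max(abs(rec$mean_pct - truth) / truth), 1e-7)
  }
})

test_that("recovered between-animal spread tracks the configured deviations", {
  # deviations set to the published between-animal sds; the recovered sds
  # (deviation + measurement noise, share-amplified) must stay within a
  # factor of 2 of the inputs
  scen <- biowaste_scenarios(seed = 21)
  dev_in <- biowaste_meal_digestibility()$RCM$sd_pct
  ref <- reference_diet_profile()
  rcm <- biowaste_meal_profiles()$RCM
  n_rep <- 80
  sds <- matrix(NA_real_, n_rep, 5,
                dimnames = list(NULL, c("dm", "cp", "ee", "cf", "nfe")))
  for (r in seq_len(n_rep)) {
    cfg <- scen$T1
    cfg$seed <- 40000 + r
    sim <- simulate_trial(cfg)
    rec <- recover_ingredient_digestibility(
      sim$dataset, cfg$ref_digestibility, ref, rcm)
    sds[r, names(rec$sd_pct)] <- rec$sd_pct
  }
  ratio <- colMeans(sds) / dev_in[colnames(sds)]
  expect_true(all(ratio > 0.5 & ratio < 2),
              label = sprintf("sd ratios %s",
                              paste(round(ratio, 2), collapse = ", ")))
})
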