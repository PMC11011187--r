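test_that("digestible fractions are composition x digestibility", {
  expect_equal(digestible_fraction(15.00, 67.65), 10.1475,
               tolerance = 0.005 / 10)
  expect_equal(digestible_fraction(62.64, 71.10), 44.54, tolerance = 0.005)
  expect_equal(digestible_fraction(c(12, 40), 100), c(12, 40))
  expect_error(digestible_fraction(-1, 50), ">= 0")
})

test_that("TDN weights digestible EE by 2.25 and zeroes absent terms", {
  expect_equal(tdn(10.1475, 4.5518, 34.7776, 23.76255), 78.9292,
               tolerance = 2e-5)
  expect_equal(tdn(44.53704, 21.08064, NA, NA), 91.96848,
               tolerance = 1e-10)
  expect_identical(tdn(0, 0, 0, 0), 0)
})

test_that("energy chain applies DE = TDN x 44.09 and ME = DE x 0.82", {
  en <- energy_from_tdn(78.93)
  expect_equal(en[["de_kcal_kg"]], 3480, tolerance = 2 / 3480)
  expect_equal(en[["me_kcal_kg"]], 2853, tolerance = 2 / 2853)
  en2 <- energy_from_tdn(93.65)
  expect_equal(en2[["de_kcal_kg"]], 4129, tolerance = 2 / 4129)
  expect_equal(en2[["me_kcal_kg"]], 3386, tolerance = 2 / 3386)
  expect_equal(unname(energy_from_tdn(0)), c(0, 0))
  expect_error(energy_constants(me_factor = 0), "positive")
})

test_that("published energy rows reproduce where the inputs are consistent", {
  profs <- biowaste_meal_profiles()
  digs <- biowaste_meal_digestibility()
  expected <- list(  # published: dCP, TDN, DE, ME
    RCM = c(10.15, 78.93, 3480, 2853),
    EaM = c(44.54, 91.97, 4055, 3325),
    CM  = c(80.84, 93.65, 4129, 3386))
  for (m in names(expected)) {
    ep <- ingredient_energy_profile(profs[[m]], digs[[m]])
    got <- c(ep$mean[["dcp"]], ep$mean[["tdn_pct"]],
             ep$mean[["de_kcal_kg"]], ep$mean[["me_kcal_kg"]])
    expect_lt(abs(got[1] - expected[[m]][1]), 0.02)
    expect_lt(abs(got[2] - expected[[m]][2]), 0.02)
    expect_lt(abs(got[3] - expected[[m]][3]), 2)
    expect_lt(abs(got[4] - expected[[m]][4]), 2)
  }
  # blood meal: the chain's own arithmetic, frozen independently
  # (dCP = 72.40 x 0.9763; dEE = 0.50 x 0.6525; TDN = dCP + 2.25 dEE)
  bm <- ingredient_energy_profile(profs$BM, digs$BM)
  expect_equal(bm$mean[["dcp"]], 70.68412, tolerance = 1e-7)
  expect_equal(bm$mean[["dee"]], 0.32625, tolerance = 1e-7)
  expect_equal(bm$mean[["tdn_pct"]], 71.4181825, tolerance = 1e-7)
  expect_true(is.na(bm$mean[["dcf"]]))
})

test_that("the energy chain matches term-by-term recomputation", {
  set.seed(42)
  for (i in 1:20) {
    with_fiber <- i %% 2 == 0
    comp <- c(dm = runif(1, 80, 95), cp = runif(1, 10, 80),
              ee = runif(1, 1, 20),
              cf = if (with_fiber) runif(1, 2, 40) else NA,
              nfe = if (with_fiber) runif(1, 5, 40) else NA)
    dig <- c(dm = runif(1, 50, 95), cp = runif(1, 50, 99),
             ee = runif(1, 50, 99), cf = runif(1, 30, 95),
             nfe = runif(1, 50, 95))
    prof <- proximate_profile("X", comp[["dm"]], comp[["cp"]],
                              comp[["ee"]], comp[["cf"]], comp[["nfe"]],
                              5, closure_tol = Inf)
    co <- digestibility_coefficients(dig, n_animals = 9L)
    ep <- ingredient_energy_profile(prof, co)
    or <- oracle_energy_row(comp, dig)
    expect_equal(ep$mean[["tdn_pct"]], or[["tdn"]], tolerance = 1e-12)
    expect_equal(ep$mean[["de_kcal_kg"]], or[["de"]], tolerance = 1e-12)
    expect_equal(ep$mean[["me_kcal_kg"]], or[["me"]], tolerance = 1e-12)
  }
})

test_that("per-animal energy aggregation reports the empirical sd", {
  sim <- simulate_trial(trial_sim_config(seed = 77))
  co <- diet_digestibility(sim$dataset)
  prof <- sim$dataset$diet_profile
  ep <- ingredient_energy_profile(prof, co)
  # sd of the per-animal TDN values, recomputed directly
  per_tdn <- apply(co$per_animal, 1, function(d) {
    oracle_energy_row(nutrient_pcts(prof), d)[["tdn"]]
  })
  expect_equal(ep$sd[["tdn_pct"]], sd(per_tdn), tolerance = 1e-10)
  expect_equal(ep$mean[["tdn_pct"]],
               oracle_energy_row(nutrient_pcts(prof),
                                 co$mean_pct)[["tdn"]],
               tolerance = 1e-10)
})

test_that("diet blending is the fraction-weighted mean of components", {
  ref <- reference_diet_profile()
  profs <- biowaste_meal_profiles()
  b <- blend_diet_profile(list(ref, profs$RCM), c(0.8, 0.2),
                          me_kcal_kg = c(2884, 2853))
  expect_equal(b$cp_pct, 12.60, tolerance = 1e-12)
  expect_equal(attr(b, "me_kcal_kg"), 2877.80, tolerance = 1e-12)

  # degenerate blend returns the reference unchanged
  b0 <- blend_diet_profile(list(ref, profs$RCM), c(1, 0))
  expect_equal(nutrient_pcts(b0), nutrient_pcts(ref))

  # blending identical profiles is the identity
  bb <- blend_diet_profile(list(profs$RCM, profs$RCM), c(0.3, 0.7))
  expect_equal(nutrient_pcts(bb), nutrient_pcts(profs$RCM))

  expect_error(blend_diet_profile(list(ref, profs$RCM), c(0.8, 0.1)),
               "sum to 1")
})

test_that("blending commutes with digestible_fraction at shared coefficients", {
  ref <- reference_diet_profile()
  rcm <- biowaste_meal_profiles()$RCM
  d_cp <- 72
  lhs <- digestible_fraction(
    blend_diet_profile(list(ref, rcm), c(0.8, 0.2))$cp_pct, d_cp)
  rhs <- 0.8 * digestible_fraction(ref$cp_pct, d_cp) +
    0.2 * digestible_fraction(rcm$cp_pct, d_cp)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})
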