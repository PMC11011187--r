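# Bundled summary data from a published guinea-pig feeding trial that
# evaluated four bovine slaughterhouse by-product meals (rumen-content,
# ear, blood and cheek meal) against a barley-meal reference diet in a
# 9-animal, 7-day metabolic-cage design. Only treatment-level summaries
# were published; per-animal records were not, which is why the package
# pairs these tables with a simulator rather than raw data.

#' Proximate composition of the four bovine by-product meals
#'
#' Published treatment means (analysed-fraction basis, percent): rumen
#' content meal (RCM), ear meal (EaM), blood meal (BM) and cheek meal (CM).
#' EaM, BM and CM contain no crude fiber or nitrogen-free extract. The BM
#' row does not close to 100 (its components sum to 76.9); it is loaded
#' with the package's standard closure warning, which `suppress_closure`
#' (default `TRUE`) silences for convenience.
#'
#' @param suppress_closure silence the closure warning for the BM row.
#' @return Named list of four [proximate_profile()]s.
#' @export
biowaste_meal_profiles <- function(suppress_closure = TRUE) {
  tol <- if (suppress_closure) Inf else 2
  list(
    RCM = proximate_profile("RCM", 85.00, 15.00, 5.50, 38.00, 30.50, 11.00),
    EaM = proximate_profile("EaM", 88.91, 62.64, 22.40, NA, NA, 14.86),
    BM  = proximate_profile("BM", 92.00, 72.40, 0.50, NA, NA, 4.00,
                            closure_tol = tol),
    CM  = proximate_profile("CM", 91.76, 84.19, 6.91, NA, NA, 8.90)
  )
}

#' Apparent digestibility coefficients of the by-product meals
#'
#' Published treatment means ± between-animal sd (n = 9 per treatment),
#' percent, recovered in the original trial by the difference method from
#' 80/20 reference/test diets.
#'
#' @return Named list of four [digestibility_coefficients()].
#' @export
biowaste_meal_digestibility <- function() {
  mk <- function(m, s) {
    digestibility_coefficients(mean_pct = m, sd_pct = s, n_animals = 9L)
  }
  list(
    RCM = mk(c(dm = 83.05, cp = 67.65, ee = 82.76, cf = 91.52, nfe = 77.91),
             c(dm = 5.51, cp = 4.69, ee = 11.35, cf = 4.73, nfe = 9.21)),
    EaM = mk(c(dm = 88.28, cp = 71.10, ee = 94.11),
             c(dm = 2.38, cp = 7.95, ee = 3.02)),
    BM  = mk(c(dm = 88.53, cp = 97.63, ee = 65.25),
             c(dm = 3.20, cp = 0.74, ee = 20.77)),
    CM  = mk(c(dm = 76.34, cp = 96.03, ee = 82.37),
             c(dm = 1.53, cp = 0.39, ee = 1.28))
  )
}

#' Published metabolizable energy of the by-product meals
#'
#' Treatment-mean ME (kcal/kg) as published, used as blending inputs when
#' reproducing the formulated rations' energy cells.
#'
#' @return Named numeric vector (kcal/kg).
#' @export
biowaste_meal_me <- function() {
  c(RCM = 2853, EaM = 3325, BM = 2583, CM = 3386)
}

#' Barley-meal reference diet
#'
#' The reference diet of the bundled study: barley meal fed alone. Published
#' values are DM 91, CP 12, EE 4, CF 5.8 (percent, analysed basis) and
#' ME 2884 kcal/kg (attached as attribute `"me_kcal_kg"`). Ash (2.7) and NFE
#' (75.5, by difference) were not published and are assumed here; none of
#' the reproduced formulation cells depend on them.
#'
#' @return A [proximate_profile()] with attribute `"me_kcal_kg"`.
#' @export
reference_diet_profile <- function() {
  p <- proximate_profile("RD", dm_pct = 91, cp_pct = 12, ee_pct = 4,
                         cf_pct = 5.8, nfe_pct = 75.5, ash_pct = 2.7)
  attr(p, "me_kcal_kg") <- 2884
  p
}

#' Stand-in digestibility truths for the barley reference diet
#'
#' The original trial never published the reference diet's own digestibility
#' coefficients, so simulations that need them use these plausible
#' barley-meal values: DM 83, CP 75, EE 80, CF 40, NFE 85 (percent). They
#' are synthetic stand-ins, not measurements; every recovery claim made on
#' simulated data is conditional on them.
#'
#' @return Named numeric vector over `dm, cp, ee, cf, nfe`.
#' @export
barley_reference_digestibility <- function() {
  c(dm = 83, cp = 75, ee = 80, cf = 40, nfe = 85)
}

#' Formulated rations of the bundled study
#'
#' The five evaluated rations: T0, the barley reference diet alone, and
#' T1–T4, 80/20 as-fed blends of the reference with each by-product meal.
#'
#' @return Named list of five [diet_spec()]s.
#' @export
biowaste_diet_specs <- function() {
  out <- list(T0 = diet_spec(
    "T0", data.frame(ingredient_id = "RD", fraction = 1),
    role = "reference"))
  meals <- c("RCM", "EaM", "BM", "CM")
  for (i in seq_along(meals)) {
    out[[paste0("T", i)]] <- diet_spec(
      paste0("T", i),
      data.frame(ingredient_id = c("RD", meals[i]),
                 fraction = c(0.8, 0.2)),
      role = "test", reference_diet_id = "T0",
      test_ingredient_id = meals[i])
  }
  out
}

#' Published summary of the formulated rations
#'
#' The published chemical composition of the five rations (percent as-fed;
#' ME kcal/kg), for cross-checking blend arithmetic.
#'
#' @return data.frame with one row per ration.
#' @export
biowaste_diet_table <- function() {
  data.frame(
    diet_id = c("T0", "T1", "T2", "T3", "T4"),
    test_ingredient = c(NA, "RCM", "EaM", "BM", "CM"),
    dm_pct = c(91, 89.80, 90.58, 91.20, 91.15),
    cp_pct = c(12, 12.60, 22.13, 24.08, 26.44),
    ee_pct = c(4, 4.30, 7.68, 3.30, 4.58),
    cf_pct = c(5.8, 12.24, 4.64, 4.64, 4.64),
    me_kcal_kg = c(2884, 2877.80, 2972.20, 2823.80, 2984.40))
}
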