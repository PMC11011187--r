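#' Energy-estimation constants
#'
#' The conventional constants of the TDN energy system: digestible energy is
#' `DE (kcal/kg) = TDN% × de_factor`, metabolizable energy is
#' `ME = DE × me_factor`, and the ether-extract term of TDN carries weight
#' `ee_weight` to reflect fat's higher energy density. The crude-protein
#' nitrogen factor is carried for provenance only (6.25 conventional; 5.7
#' appears in parts of the literature) — the package never converts N to CP.
#'
#' @param de_factor kcal/kg per TDN percentage point (default 44.09).
#' @param me_factor ME/DE ratio (default 0.82).
#' @param ee_weight TDN weight of digestible ether extract (default 2.25).
#' @param cp_nitrogen_factor informational N-to-CP factor (default 6.25).
#' @return An object of class `energy_constants`.
#' @export
energy_constants <- function(de_factor = 44.09, me_factor = 0.82,
                             ee_weight = 2.25, cp_nitrogen_factor = 6.25) {
  vals <- c(de_factor = de_factor, me_factor = me_factor,
            ee_weight = ee_weight, cp_nitrogen_factor = cp_nitrogen_factor)
  if (any(!vapply(vals, is_number, logical(1))) || any(vals <= 0)) {
    stop("all energy constants must be strictly positive numbers",
         call. = FALSE)
  }
  structure(as.list(vals), class = "energy_constants")
}

#' Digestible fraction of a proximate component
#'
#' Each digestible component is simply composition × digestibility:
#' `component_pct × digestibility_pct / 100`. Vectorised over both
#' arguments.
#'
#' @param component_pct component content, percent.
#' @param digestibility_pct apparent digestibility, percent.
#' @return Digestible content, percent (same basis as `component_pct`).
#' @examples
#' digestible_fraction(15, 67.65)  # 10.15
#' @export
digestible_fraction <- function(component_pct, digestibility_pct) {
  if (any(component_pct < 0, na.rm = TRUE)) {
    stop("component_pct must be >= 0", call. = FALSE)
  }
  component_pct * digestibility_pct / 100
}

#' Total digestible nutrients
#'
#' `TDN% = dCP + ee_weight · dEE + dCF + dNFE`, the classical weighted sum
#' of digestible components. Components flagged absent (passed as `NA`)
#' contribute zero, matching how fiber-free animal meals are tabulated.
#'
#' @param dcp,dee,dcf,dnfe digestible component percentages (`NA` = absent).
#' @param constants an [energy_constants()].
#' @return TDN, percent.
#' @examples
#' tdn(10.15, 4.55, 34.78, 23.76)  # about 78.93
#' @export
tdn <- function(dcp, dee, dcf = NA, dnfe = NA,
                constants = energy_constants()) {
  z <- function(x) ifelse(is.na(x), 0, x)
  if (any(c(z(dcp), z(dee), z(dcf), z(dnfe)) < 0)) {
    stop("digestible components must be >= 0 or NA (absent)", call. = FALSE)
  }
  z(dcp) + constants$ee_weight * z(dee) + z(dcf) + z(dnfe)
}

#' Digestible and metabolizable energy from TDN
#'
#' `DE = TDN% × de_factor` kcal/kg and `ME = DE × me_factor`.
#'
#' @param tdn_pct TDN, percent (>= 0).
#' @param constants an [energy_constants()].
#' @return Named numeric vector `c(de_kcal_kg, me_kcal_kg)`.
#' @examples
#' energy_from_tdn(78.93)  # DE about 3480, ME about 2853
#' @export
energy_from_tdn <- function(tdn_pct, constants = energy_constants()) {
  if (any(tdn_pct < 0)) stop("tdn_pct must be >= 0", call. = FALSE)
  de <- tdn_pct * constants$de_factor
  c(de_kcal_kg = de, me_kcal_kg = de * constants$me_factor)
}

#' Full digestible-nutrient and energy profile of an ingredient
#'
#' Chains composition × digestibility through TDN to DE and ME, producing
#' the standard feed-table row: digestible DM, CP, EE, CF, NFE (percent),
#' TDN (percent), DE and ME (kcal/kg). Components absent from the
#' ingredient are carried as `NA` and contribute zero to TDN.
#'
#' Standard deviations: the per-component sds are the same linear map of the
#' coefficient sds (`component × sd/100`). For TDN/DE/ME, if per-animal
#' coefficients are available (the default path out of
#' [diet_digestibility()] or [recover_ingredient_digestibility()]) the chain
#' is evaluated per animal and the empirical sd reported — between-animal
#' correlation of the component digestibilities is then handled exactly.
#' Without per-animal values the sds are combined in quadrature, which
#' assumes independent coefficients.
#'
#' @param profile [proximate_profile()] of the ingredient (analysed basis).
#' @param coeffs [digestibility_coefficients()] for the ingredient.
#' @param constants an [energy_constants()].
#' @return An object of class `energy_profile`: list with named vectors
#'   `mean` and `sd` over
#'   `ddm, dcp, dee, dcf, dnfe, tdn_pct, de_kcal_kg, me_kcal_kg`.
#' @export
ingredient_energy_profile <- function(profile, coeffs,
                                      constants = energy_constants()) {
  stopifnot(inherits(profile, "proximate_profile"),
            inherits(coeffs, "digestibility_coefficients"))
  comp <- nutrient_pcts(profile)
  absent <- nutrient_absent(profile)

  one_row <- function(d) {
    # d: named digestibility vector (subset of NUTRIENTS)
    dig <- vapply(NUTRIENTS, function(k) {
      if (absent[[k]] || !k %in% names(d)) NA_real_
      else digestible_fraction(comp[[k]], d[[k]])
    }, numeric(1))
    t <- tdn(dig[["cp"]], dig[["ee"]], dig[["cf"]], dig[["nfe"]], constants)
    en <- energy_from_tdn(t, constants)
    c(ddm = dig[["dm"]], dcp = dig[["cp"]], dee = dig[["ee"]],
      dcf = dig[["cf"]], dnfe = dig[["nfe"]], tdn_pct = t, en)
  }

  mean_row <- one_row(coeffs$mean_pct)
  sd_comp <- vapply(NUTRIENTS, function(k) {
    if (absent[[k]] || !k %in% names(coeffs$sd_pct)) NA_real_
    else comp[[k]] * coeffs$sd_pct[[k]] / 100
  }, numeric(1))

  per_rows <- NULL
  if (!is.null(coeffs$per_animal) && nrow(coeffs$per_animal) >= 2L) {
    per_rows <- t(apply(coeffs$per_animal, 1, one_row))
    sd_chain <- apply(per_rows[, c("tdn_pct", "de_kcal_kg", "me_kcal_kg"),
                               drop = FALSE], 2, stats::sd)
  } else {
    z <- function(x) ifelse(is.na(x), 0, x)
    sd_tdn <- sqrt(z(sd_comp[["cp"]])^2 +
                   (constants$ee_weight * z(sd_comp[["ee"]]))^2 +
                   z(sd_comp[["cf"]])^2 + z(sd_comp[["nfe"]])^2)
    sd_chain <- c(tdn_pct = sd_tdn,
                  de_kcal_kg = sd_tdn * constants$de_factor,
                  me_kcal_kg = sd_tdn * constants$de_factor * constants$me_factor)
  }
  sd_row <- c(ddm = sd_comp[["dm"]], dcp = sd_comp[["cp"]],
              dee = sd_comp[["ee"]], dcf = sd_comp[["cf"]],
              dnfe = sd_comp[["nfe"]], sd_chain)

  structure(list(ingredient_id = profile$ingredient_id,
                 mean = mean_row, sd = sd_row, per_animal = per_rows,
                 n_animals = coeffs$n_animals, constants = constants),
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("<energy_profile> %s (n = %s)\n", x$ingredient_id,
              x$n_animals))
  for (nm in names(x$mean)) {
    if (is.na(x$mean[[nm]])) {
      cat(sprintf("  %-10s    -\n", nm))
    } else {
      cat(sprintf("  %-10s %9.2f ± %s\n", nm, x$mean[[nm]],
                  ifelse(is.na(x$sd[[nm]]), "NA",
                         sprintf("%.2f", x$sd[[nm]]))))
    }
  }
  invisible(x)
}

#' Blend ingredient profiles into a diet profile
#'
#' Every proximate component (and, when supplied, metabolizable energy) of a
#' mixed ration is the inclusion-weighted mean of its ingredients' values on
#' the as-fed basis. A component is absent from the blend only if absent
#' from every ingredient; ingredients lacking it simply contribute zero
#' (e.g. the crude fiber of a barley/animal-meal mix comes entirely from the
#' barley).
#'
#' @param profiles list of [proximate_profile()]s (analysed/as-fed basis).
#' @param fractions as-fed inclusion fractions, summing to 1 within 1e-9.
#' @param me_kcal_kg optional per-ingredient ME values to blend alongside.
#' @param diet_id label for the blended profile.
#' @return A [proximate_profile()] for the blend; if `me_kcal_kg` is given,
#'   the blended ME is attached as attribute `"me_kcal_kg"`.
#' @examples
#' ref <- proximate_profile("RD", 91, 12, 4, 5.8, 75.5, 2.7)
#' rcm <- proximate_profile("RCM", 85, 15, 5.5, 38, 30.5, 11)
#' blend_diet_profile(list(ref, rcm), c(0.8, 0.2))  # CP 12.60, DM 89.80
#' @export
blend_diet_profile <- function(profiles, fractions, me_kcal_kg = NULL,
                               diet_id = "blend") {
  stopifnot(is.list(profiles), length(profiles) == length(fractions))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("inclusion fractions must sum to 1", call. = FALSE)
  }
  profiles <- lapply(profiles, as_analyzed)
  wmean <- function(get) sum(fractions * vapply(profiles, get, numeric(1)))
  all_absent <- function(flag) {
    all(vapply(profiles, function(p) isTRUE(p[[flag]]), logical(1)))
  }
  cf_abs <- all_absent("cf_absent")
  nfe_abs <- all_absent("nfe_absent")
  out <- proximate_profile(
    ingredient_id = diet_id,
    dm_pct = wmean(function(p) p$dm_pct),
    cp_pct = wmean(function(p) p$cp_pct),
    ee_pct = wmean(function(p) p$ee_pct),
    cf_pct = if (cf_abs) NA else wmean(function(p) p$cf_pct),
    nfe_pct = if (nfe_abs) NA else wmean(function(p) p$nfe_pct),
    ash_pct = wmean(function(p) p$ash_pct),
    closure_tol = Inf)
  if (!is.null(me_kcal_kg)) {
    stopifnot(length(me_kcal_kg) == length(fractions))
    attr(out, "me_kcal_kg") <- sum(fractions * me_kcal_kg)
  }
  out
}
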