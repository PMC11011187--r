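#' Per-animal nutrient intake and fecal output over the collection period
#'
#' Sums, over every recorded day, the as-fed net consumption
#' (offered − refused) and fecal output of one animal, and converts both to
#' nutrient masses: intake `I` from the diet profile and fecal loss `F` from
#' the animal's pooled fecal composition. DM flux uses the DM masses
#' themselves; organic nutrients use the profile percentages on whichever
#' basis the profile declares (`as_analyzed`: percent of as-fed mass;
#' `dry_matter`: percent of DM, multiplied through the DM fraction). Fecal
#' profiles are on a dry-matter basis, so `F = Σ feces_fresh ×
#' feces_dm_fraction × pct/100`.
#'
#' @param dataset a [trial_dataset()].
#' @param animal_id one animal present in the dataset.
#' @return An object of class `nutrient_flux`: list with named vectors
#'   `intake_g` and `fecal_g` over `dm, cp, ee, cf, nfe`, the absence flags
#'   of the diet, and `animal_id`.
#' @export
nutrient_flux <- function(dataset, animal_id) {
  stopifnot(inherits(dataset, "trial_dataset"))
  animal_id <- as.character(animal_id)
  r <- dataset$records[as.character(dataset$records$animal_id) == animal_id, ,
                       drop = FALSE]
  if (nrow(r) == 0L) {
    stop(sprintf("unknown animal '%s' in diet %s", animal_id,
                 dataset$diet$diet_id), call. = FALSE)
  }
  fec_prof <- dataset$fecal_profiles[[animal_id]]
  if (is.null(fec_prof)) {
    stop(sprintf("animal '%s' has no fecal composition profile", animal_id),
         call. = FALSE)
  }

  net_g <- sum(r$offered_g - r$refused_g)
  dm_intake <- net_g * dataset$diet_profile$dm_pct / 100
  if (dm_intake <= 0) {
    stop(sprintf("animal '%s' has zero total intake; digestibility undefined",
                 animal_id), call. = FALSE)
  }
  diet_p <- nutrient_pcts(dataset$diet_profile)
  intake <- if (dataset$diet_profile$basis == "as_analyzed") {
    net_g * diet_p / 100
  } else {
    dm_intake * diet_p / 100
  }
  intake[["dm"]] <- dm_intake

  feces_dm <- sum(r$feces_fresh_g * r$feces_dm_fraction)
  fec_p <- nutrient_pcts(as_dry_matter(fec_prof))
  fecal <- feces_dm * fec_p / 100
  fecal[["dm"]] <- feces_dm

  structure(list(animal_id = animal_id, intake_g = intake, fecal_g = fecal,
                 absent = nutrient_absent(dataset$diet_profile)),
            class = "nutrient_flux")
}

#' Apparent digestibility from a nutrient mass balance
#'
#' Applies the classical apparent-digestibility equation
#' `D = (I − F) / I × 100` per nutrient, where `I` is the mass ingested and
#' `F` the mass recovered in feces over the collection period. Values are
#' never clamped: apparent digestibility can fall outside \[0, 100\] under
#' measurement noise (or genuinely, through endogenous fecal losses), and
#' clamping would bias every downstream energy estimate. Out-of-range values
#' are flagged instead.
#'
#' @param flux a [nutrient_flux()], or a list with named numeric vectors
#'   `intake_g` and `fecal_g`.
#' @param nutrients which nutrients to compute (default: all with recorded
#'   intake).
#' @return Named numeric vector of digestibility percentages with attribute
#'   `"out_of_range"` (logical vector).
#' @export
apparent_digestibility <- function(flux, nutrients = NULL) {
  I <- flux$intake_g
  F_ <- flux$fecal_g
  nutrients <- nutrients %||% names(I)
  bad <- nutrients[I[nutrients] <= 0]
  if (length(bad)) {
    stop("digestibility undefined (zero intake) for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- (I[nutrients] - F_[nutrients]) / I[nutrients] * 100
  attr(d, "out_of_range") <- d < 0 | d > 100
  d
}

#' Treatment-level apparent digestibility coefficients
#'
#' Computes apparent digestibility per animal, then aggregates across the
#' animals of one treatment. The default (`method = "per_animal"`) averages
#' the per-animal coefficients — the mean-of-ratios convention that matches
#' reporting a between-animal standard deviation. `method = "pooled"`
#' instead forms one ratio from the treatment's summed intake and fecal
#' masses (no sd).
#'
#' Nutrients flagged absent from the diet are dropped: their intake is zero
#' and their digestibility undefined.
#'
#' @param dataset a [trial_dataset()].
#' @param method `"per_animal"` (default) or `"pooled"`.
#' @return An object of class `digestibility_coefficients`: list with
#'   `mean_pct`, `sd_pct`, `n_animals`, `flag` (any per-animal value outside
#'   \[0, 100\]) and the per-animal matrix as `per_animal`.
#' @export
diet_digestibility <- function(dataset, method = c("per_animal", "pooled")) {
  method <- match.arg(method)
  ids <- animal_ids(dataset)
  fluxes <- lapply(ids, function(a) nutrient_flux(dataset, a))
  present <- NUTRIENTS[!nutrient_absent(dataset$diet_profile)]
  per <- t(vapply(fluxes, function(fx) {
    as.numeric(apparent_digestibility(fx, present))
  }, numeric(length(present))))
  colnames(per) <- present
  rownames(per) <- ids

  if (method == "per_animal") {
    mean_pct <- colMeans(per)
    sd_pct <- apply(per, 2, stats::sd)
  } else {
    I_tot <- Reduce(`+`, lapply(fluxes, function(fx) fx$intake_g[present]))
    F_tot <- Reduce(`+`, lapply(fluxes, function(fx) fx$fecal_g[present]))
    mean_pct <- (I_tot - F_tot) / I_tot * 100
    sd_pct <- rep(NA_real_, length(present))
    names(sd_pct) <- present
  }
  digestibility_coefficients(mean_pct, sd_pct, n_animals = length(ids),
                             per_animal = per, method = method)
}

#' Construct a digestibility-coefficient summary
#'
#' @param mean_pct named numeric vector of mean digestibility percentages.
#' @param sd_pct matching standard deviations (NA when unavailable).
#' @param n_animals number of animals the summary is based on.
#' @param per_animal optional matrix of per-animal values (animals × nutrients).
#' @param method aggregation method label.
#' @return An object of class `digestibility_coefficients`.
#' @export
digestibility_coefficients <- function(mean_pct, sd_pct = NULL,
                                       n_animals = NA_integer_,
                                       per_animal = NULL,
                                       method = "per_animal") {
  if (is.null(sd_pct)) {
    sd_pct <- rep(NA_real_, length(mean_pct))
    names(sd_pct) <- names(mean_pct)
  }
  stopifnot(!is.null(names(mean_pct)))
  if (any(sd_pct < 0, na.rm = TRUE)) stop("sd_pct must be >= 0", call. = FALSE)
  structure(list(
    mean_pct = mean_pct, sd_pct = sd_pct,
    n_animals = as.integer(n_animals),
    flag = mean_pct < 0 | mean_pct > 100,
    per_animal = per_animal, method = method
  ), class = "digestibility_coefficients")
}

#' @export
print.digestibility_coefficients <- function(x, ...) {
  cat(sprintf("<digestibility_coefficients> n = %d (%s)\n", x$n_animals,
              x$method))
  for (nm in names(x$mean_pct)) {
    cat(sprintf("  %-4s %7.2f ± %s %s\n", nm, x$mean_pct[[nm]],
                ifelse(is.na(x$sd_pct[[nm]]), "  NA",
                       sprintf("%5.2f", x$sd_pct[[nm]])),
                if (isTRUE(x$flag[[nm]])) "[out of range]" else ""))
  }
  invisible(x)
}

#' Reference-diet share of a mixed diet's nutrient intake
#'
#' For the difference method, the reference diet's indigestibility must be
#' subtracted in proportion to how much of each *nutrient's* intake the
#' reference supplies — not the raw as-fed inclusion fractions, which are
#' dimensionally wrong whenever the two feeds differ in nutrient
#' concentration. The share of nutrient k is
#' `s_k = f · ref_k / (f · ref_k + (1 − f) · ing_k)`
#' with `f` the reference's as-fed fraction and `ref_k`, `ing_k` the as-fed
#' nutrient concentrations. For DM the share uses `dm_pct`, so it coincides
#' with DM-proportion weighting.
#'
#' A nutrient the ingredient lacks entirely has `s = 1` (the reference
#' supplies all of it); the ingredient's digestibility for it is
#' unidentifiable and flagged.
#'
#' @param ref_profile,ing_profile [proximate_profile()]s on the analysed
#'   (as-fed) basis.
#' @param ref_fraction as-fed inclusion fraction of the reference diet,
#'   in (0, 1).
#' @return Named numeric vector of shares over `dm, cp, ee, cf, nfe`, with
#'   attribute `"absent"` marking nutrients absent from the whole blend.
#' @examples
#' ref <- proximate_profile("RD", 91, 12, 4, 5.8, 75.5, 2.7)
#' rcm <- proximate_profile("RCM", 85, 15, 5.5, 38, 30.5, 11)
#' nutrient_share(ref, rcm, 0.8)[["cp"]]  # 9.6 / 12.6
#' @export
nutrient_share <- function(ref_profile, ing_profile, ref_fraction) {
  stopifnot(inherits(ref_profile, "proximate_profile"),
            inherits(ing_profile, "proximate_profile"))
  if (!is_number(ref_fraction) || ref_fraction <= 0 || ref_fraction >= 1) {
    stop("ref_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  ref_p <- nutrient_pcts(as_analyzed(ref_profile))
  ing_p <- nutrient_pcts(as_analyzed(ing_profile))
  num <- ref_fraction * ref_p
  den <- num + (1 - ref_fraction) * ing_p
  s <- ifelse(den > 0, num / den, NA_real_)
  names(s) <- NUTRIENTS
  attr(s, "absent") <- den <= 0
  s
}

#' Ingredient digestibility by the difference (indirect) method
#'
#' Recovers a test ingredient's digestibility from a mixed-diet trial under
#' the standard assumption that the reference diet's indigestibility is
#' unchanged by mixing: with `s` the reference's share of the nutrient's
#' intake ([nutrient_share()]),
#' `D_ing = (D_diet − s · D_ref) / (1 − s)`.
#'
#' Nutrients with `s = 1` (ingredient supplies none of the nutrient) are
#' unidentifiable and returned as `NA` with a warning; `s = 0` returns
#' `D_diet` unchanged (the ingredient is the whole supply).
#'
#' @param d_test_diet named per-nutrient digestibility of the mixed diet, %.
#' @param d_ref matching digestibility of the reference diet fed alone, %.
#' @param ref_share matching reference intake shares in \[0, 1\].
#' @return Named numeric vector of ingredient digestibility percentages,
#'   `NA` where unidentifiable (attribute `"absent"`).
#' @export
difference_method <- function(d_test_diet, d_ref, ref_share) {
  nms <- names(d_test_diet)
  if (is.null(nms)) stop("d_test_diet must be named", call. = FALSE)
  d_ref <- d_ref[nms]
  s <- ref_share[nms]
  if (any(is.na(s) | s < 0 | s > 1)) {
    stop("ref_share must lie in [0, 1] for every nutrient of d_test_diet",
         call. = FALSE)
  }
  out <- rep(NA_real_, length(nms))
  names(out) <- nms
  ident <- s < 1
  out[ident] <- (d_test_diet[ident] - s[ident] * d_ref[ident]) / (1 - s[ident])
  if (any(!ident)) {
    warn_fe("ingredient supplies none of: ",
            paste(nms[!ident], collapse = ", "),
            "; digestibility unidentifiable, reported absent")
  }
  attr(out, "absent") <- !ident
  out
}

#' Recover a test ingredient's digestibility coefficients from a trial
#'
#' End-to-end difference method for one test-diet [trial_dataset()]:
#' computes the mixed diet's apparent digestibility, derives the reference
#' intake shares from the two composition profiles, and inverts the blend.
#' With `per_animal = TRUE` (default) the inversion is applied to each
#' animal's diet digestibility — the treatment mean and between-animal sd
#' then refer to the ingredient itself, matching how trial tables report
#' coefficients. Otherwise only the treatment means are inverted.
#'
#' @param dataset test-diet [trial_dataset()].
#' @param d_ref named per-nutrient mean digestibility of the reference diet
#'   fed alone (treatment means of the reference trial), or a
#'   `digestibility_coefficients` object.
#' @param ref_profile,ing_profile as-fed [proximate_profile()]s of reference
#'   diet and test ingredient.
#' @param ref_fraction as-fed reference inclusion (default from the diet
#'   spec, else 0.8).
#' @param per_animal invert per animal (default) or on treatment means only.
#' @return A [digestibility_coefficients()] for the test ingredient;
#'   unidentifiable nutrients are dropped (with a warning).
#' @export
recover_ingredient_digestibility <- function(dataset, d_ref, ref_profile,
                                             ing_profile,
                                             ref_fraction = NULL,
                                             per_animal = TRUE) {
  if (inherits(d_ref, "digestibility_coefficients")) d_ref <- d_ref$mean_pct
  if (is.null(ref_fraction)) {
    comp <- dataset$diet$components
    ing_row <- comp$ingredient_id == ing_profile$ingredient_id
    ref_fraction <- if (any(ing_row)) 1 - sum(comp$fraction[ing_row]) else 0.8
  }
  s <- nutrient_share(ref_profile, ing_profile, ref_fraction)
  diet_d <- diet_digestibility(dataset)
  present <- names(diet_d$mean_pct)
  present <- present[!nutrient_absent(ing_profile)[present]]
  s_use <- s[present]

  if (per_animal && !is.null(diet_d$per_animal)) {
    per <- diet_d$per_animal[, present, drop = FALSE]
    inv <- t(apply(per, 1, function(row) {
      suppressWarnings(difference_method(row, d_ref[present], s_use))
    }))
    colnames(inv) <- present
    keep <- present[s_use < 1]
    inv <- inv[, keep, drop = FALSE]
    digestibility_coefficients(colMeans(inv), apply(inv, 2, stats::sd),
                               n_animals = diet_d$n_animals,
                               per_animal = inv, method = "per_animal")
  } else {
    est <- difference_method(diet_d$mean_pct[present], d_ref[present], s_use)
    keep <- !attr(est, "absent")
    digestibility_coefficients(est[keep], n_animals = diet_d$n_animals,
                               method = "means")
  }
}
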