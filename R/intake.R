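#' Metabolic body weight
#'
#' The conventional interspecies scaling of intake and metabolic rate:
#' body weight in kilograms raised to the 0.75 power.
#'
#' @param weight_g body weight in grams (> 0).
#' @return Metabolic size, kg^0.75. Vectorised.
#' @examples
#' metabolic_weight(1000)  # 1
#' metabolic_weight(822)   # 0.8633
#' @export
metabolic_weight <- function(weight_g) {
  if (any(weight_g <= 0)) stop("weight_g must be > 0", call. = FALSE)
  (weight_g / 1000)^0.75
}

#' Voluntary-intake summary scaled to live and metabolic weight
#'
#' Computes each animal's mean daily DM intake and the share attributable to
#' the test ingredient, then scales the attributed intake to body size as a
#' percentage of live weight and as g per kg metabolic weight (W^0.75).
#'
#' Attribution assumes non-selective refusal (a ground mash cannot be
#' sorted): the test ingredient's as-fed share of what was eaten equals its
#' inclusion fraction, and its DM is converted with the ingredient's own DM
#' content. With `ingredient_dm_pct = NULL` the diet's DM is used, making
#' attributed DM exactly `inclusion_fraction ×` total DM intake.
#'
#' The body weight used for scaling is, by default, the mean of initial and
#' final weight; `weight_basis` makes the choice explicit.
#'
#' @param dataset a [trial_dataset()].
#' @param inclusion_fraction as-fed inclusion of the test ingredient in
#'   \[0, 1\].
#' @param ingredient_dm_pct DM content of the test ingredient, percent;
#'   `NULL` (default) uses the diet's DM.
#' @param weight_basis `"mean"` (default), `"initial"` or `"final"`.
#' @return An object of class `intake_summary`: list with `per_animal`
#'   data.frame (`animal_id`, `daily_dm_g`, `attributed_dm_g`,
#'   `pct_live_weight`, `g_per_kg_metabolic`) and `treatment` data.frame of
#'   means ± sd.
#' @export
intake_summary <- function(dataset, inclusion_fraction,
                           ingredient_dm_pct = NULL,
                           weight_basis = c("mean", "initial", "final")) {
  stopifnot(inherits(dataset, "trial_dataset"))
  weight_basis <- match.arg(weight_basis)
  if (!is_number(inclusion_fraction) || inclusion_fraction < 0 ||
      inclusion_fraction > 1) {
    stop("inclusion_fraction must lie in [0, 1]", call. = FALSE)
  }
  diet_dm <- dataset$diet_profile$dm_pct
  ing_dm <- ingredient_dm_pct %||% diet_dm
  ids <- animal_ids(dataset)
  wts <- dataset$weights

  rows <- lapply(ids, function(a) {
    r <- dataset$records[as.character(dataset$records$animal_id) == a, ,
                         drop = FALSE]
    w <- wts[as.character(wts$animal_id) == a, , drop = FALSE]
    if (nrow(w) == 0L) {
      stop(sprintf("no weights recorded for animal '%s'", a), call. = FALSE)
    }
    bw <- switch(weight_basis,
                 mean = (w$initial_g[1] + w$final_g[1]) / 2,
                 initial = w$initial_g[1], final = w$final_g[1])
    net_asfed <- mean(r$offered_g - r$refused_g)
    daily_dm <- net_asfed * diet_dm / 100
    attributed <- inclusion_fraction * net_asfed * ing_dm / 100
    data.frame(
      animal_id = a,
      daily_dm_g = daily_dm,
      attributed_dm_g = attributed,
      pct_live_weight = attributed / bw * 100,
      g_per_kg_metabolic = attributed / metabolic_weight(bw))
  })
  per <- do.call(rbind, rows)
  num <- per[, -1, drop = FALSE]
  treatment <- data.frame(metric = names(num),
                          mean = vapply(num, mean, numeric(1)),
                          sd = vapply(num, stats::sd, numeric(1)),
                          n = nrow(per), row.names = NULL)
  structure(list(per_animal = per, treatment = treatment,
                 inclusion_fraction = inclusion_fraction,
                 weight_basis = weight_basis),
            class = "intake_summary")
}

#' Weight-gain summary over the experimental phase
#'
#' Per-animal initial and final weights, total gain and daily gain
#' (total / `n_days`), with treatment-level means ± sd.
#'
#' @param dataset a [trial_dataset()].
#' @param n_days length of the experimental phase in days (default 7).
#' @return An object of class `gain_summary`: list with `per_animal` and
#'   `treatment` data.frames.
#' @export
gain_summary <- function(dataset, n_days = 7) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!is_number(n_days) || n_days <= 0) {
    stop("n_days must be > 0", call. = FALSE)
  }
  w <- dataset$weights
  per <- data.frame(
    animal_id = as.character(w$animal_id),
    initial_g = w$initial_g,
    final_g = w$final_g,
    total_gain_g = w$final_g - w$initial_g,
    daily_gain_g = (w$final_g - w$initial_g) / n_days)
  num <- per[, -1, drop = FALSE]
  treatment <- data.frame(metric = names(num),
                          mean = vapply(num, mean, numeric(1)),
                          sd = vapply(num, stats::sd, numeric(1)),
                          n = nrow(per), row.names = NULL)
  structure(list(per_animal = per, treatment = treatment, n_days = n_days),
            class = "gain_summary")
}
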