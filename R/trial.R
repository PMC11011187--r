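#' Diet formulation specification
#'
#' A `diet_spec` names the as-fed inclusion fractions of the ingredients
#' making up one ration. A `reference` diet is a feed that can be offered
#' alone (here barley meal); a `test` diet mixes one test ingredient into the
#' reference diet so that the ingredient's digestibility can be recovered by
#' the difference method.
#'
#' Formal well-formedness (fractions in (0, 1], summing to 1 within 1e-9;
#' a test diet naming exactly one test ingredient) is reported by
#' [validate_trial()] rather than enforced at construction, so malformed
#' input files can be loaded, diagnosed and reported in one pass.
#'
#' @param diet_id character label.
#' @param components data.frame with columns `ingredient_id`, `fraction`
#'   (as-fed inclusion fractions).
#' @param role `"reference"` or `"test"`.
#' @param reference_diet_id for test diets, the id of their reference diet.
#' @param test_ingredient_id for test diets, the id of the single test
#'   ingredient.
#' @return An object of class `diet_spec`.
#' @export
diet_spec <- function(diet_id, components, role = c("reference", "test"),
                      reference_diet_id = NULL, test_ingredient_id = NULL) {
  role <- match.arg(role)
  stopifnot(is.character(diet_id), length(diet_id) == 1L)
  if (!is.data.frame(components) ||
      !all(c("ingredient_id", "fraction") %in% names(components))) {
    stop("components must be a data.frame with ingredient_id and fraction",
         call. = FALSE)
  }
  components$fraction <- as.numeric(components$fraction)
  structure(list(
    diet_id = diet_id,
    components = components[, c("ingredient_id", "fraction")],
    role = role,
    reference_diet_id = reference_diet_id,
    test_ingredient_id = test_ingredient_id
  ), class = "diet_spec")
}

#' @export
print.diet_spec <- function(x, ...) {
  cat(sprintf("<diet_spec> %s (%s)\n", x$diet_id, x$role))
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  %-12s %.3f\n", x$components$ingredient_id[i],
                x$components$fraction[i]))
  }
  invisible(x)
}

#' Metabolic-cage trial dataset for one dietary treatment
#'
#' Bundles everything one digestibility trial produces: the diet
#' specification, the proximate profile of the mixed feed as offered, each
#' animal's pooled fecal composition over the collection period, the daily
#' offered/refused/feces records, and initial/final body weights. The
#' canonical design is 9 animals observed over a 7-day collection period.
#'
#' @param diet a [diet_spec()].
#' @param diet_profile [proximate_profile()] of the feed as offered
#'   (components on the analysed/as-fed basis).
#' @param fecal_profiles named list of [proximate_profile()], one per animal,
#'   components on a dry-matter basis (feces are analysed after drying).
#' @param records data.frame with columns `animal_id`, `day`, `offered_g`,
#'   `refused_g`, `feces_fresh_g`, `feces_dm_fraction`.
#' @param weights data.frame with columns `animal_id`, `initial_g`,
#'   `final_g`.
#' @return An object of class `trial_dataset`.
#' @seealso [validate_trial()] for the full invariant report.
#' @export
trial_dataset <- function(diet, diet_profile, fecal_profiles, records, weights) {
  stopifnot(inherits(diet, "diet_spec"),
            inherits(diet_profile, "proximate_profile"),
            is.list(fecal_profiles), is.data.frame(records),
            is.data.frame(weights))
  need_rec <- c("animal_id", "day", "offered_g", "refused_g",
                "feces_fresh_g", "feces_dm_fraction")
  miss <- setdiff(need_rec, names(records))
  if (length(miss)) {
    stop("records is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(c("animal_id", "initial_g", "final_g"), names(weights))
  if (length(miss)) {
    stop("weights is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    diet = diet, diet_profile = diet_profile,
    fecal_profiles = fecal_profiles,
    records = records, weights = weights
  ), class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> diet %s (%s): %d animals, %d day-records\n",
              x$diet$diet_id, x$diet$role,
              length(animal_ids(x)), nrow(x$records)))
  invisible(x)
}

#' Animal identifiers present in a trial dataset
#' @param dataset a [trial_dataset()].
#' @return Character vector of animal ids, in first-appearance order.
#' @export
animal_ids <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  as.character(unique(dataset$records$animal_id))
}

#' Validate a trial dataset against its design invariants
#'
#' Pure reporting: never errors. Checks the diet (fractions in (0, 1] summing
#' to 1; test diets name one test ingredient), the records (refusals not
#' exceeding offers, non-negative masses, fecal DM fractions in \[0, 1\]),
#' and completeness (every animal has day records, a weight pair, and a
#' fecal composition profile). An empty report means the dataset is ready
#' for analysis.
#'
#' @param dataset a [trial_dataset()].
#' @return data.frame with columns `scope` (diet/record/animal), `id`
#'   (offending animal/day or diet id) and `message`; zero rows when valid.
#' @export
validate_trial <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  v <- list()
  add <- function(scope, id, message) {
    v[[length(v) + 1L]] <<- data.frame(scope = scope, id = id,
                                       message = message)
  }

  comp <- dataset$diet$components
  if (any(comp$fraction <= 0 | comp$fraction > 1)) {
    add("diet", dataset$diet$diet_id, "inclusion fractions outside (0, 1]")
  }
  if (abs(sum(comp$fraction) - 1) > 1e-9) {
    add("diet", dataset$diet$diet_id, "inclusion fractions do not sum to 1")
  }
  if (dataset$diet$role == "test" && is.null(dataset$diet$test_ingredient_id)) {
    add("diet", dataset$diet$diet_id, "test diet names no test ingredient")
  }

  r <- dataset$records
  ids <- animal_ids(dataset)
  if (length(ids) < 1L) add("animal", "-", "dataset has no animals")
  for (i in seq_len(nrow(r))) {
    tag <- sprintf("%s/day %s", r$animal_id[i], r$day[i])
    if (r$refused_g[i] > r$offered_g[i]) {
      add("record", tag, "refused_g exceeds offered_g")
    }
    for (col in c("offered_g", "refused_g", "feces_fresh_g")) {
      if (is.na(r[[col]][i]) || r[[col]][i] < 0) {
        add("record", tag, sprintf("%s is negative or missing", col))
      }
    }
    if (is.na(r$feces_dm_fraction[i]) || r$feces_dm_fraction[i] < 0 ||
        r$feces_dm_fraction[i] > 1) {
      add("record", tag, "feces_dm_fraction outside [0, 1]")
    }
  }
  for (id in ids) {
    if (!id %in% as.character(dataset$weights$animal_id)) {
      add("animal", id, "no initial/final weight pair")
    }
    if (!id %in% names(dataset$fecal_profiles)) {
      add("animal", id, "no fecal composition profile")
    }
  }

  if (length(v) == 0L) {
    return(data.frame(scope = character(), id = character(),
                      message = character()))
  }
  do.call(rbind, v)
}
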