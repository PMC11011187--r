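#' Configuration for a full feed-evaluation pipeline run
#'
#' Collects everything [run_pipeline()] needs: the trial datasets (a
#' reference trial plus test trials), the ingredient composition profiles,
#' the energy constants, the comparison settings, and an optional output
#' directory for the CSV/markdown report bundle.
#'
#' @param datasets named list of [trial_dataset()] containing exactly one
#'   dataset whose diet role is `"reference"`; alternatively `NULL` with
#'   `input_dir` pointing at a CSV bundle for [read_trial_bundle()].
#' @param compositions named list of [proximate_profile()] for every
#'   ingredient referenced by the diets (defaults to the bundle's
#'   compositions when `input_dir` is used).
#' @param input_dir directory with the five-CSV trial bundle.
#' @param constants an [energy_constants()].
#' @param alpha significance level for treatment comparisons.
#' @param aggregation `"per_animal"` (default) or `"pooled"` digestibility
#'   aggregation.
#' @param protected gate Duncan letters on a significant ANOVA F?
#' @param out_dir directory for the report bundle (`NULL`: no files).
#' @param seed optional integer recorded with the run (the analysis itself
#'   is deterministic).
#' @return An object of class `run_config`.
#' @export
run_config <- function(datasets = NULL, compositions = NULL,
                       input_dir = NULL, constants = energy_constants(),
                       alpha = 0.05,
                       aggregation = c("per_animal", "pooled"),
                       protected = FALSE, out_dir = NULL, seed = NULL) {
  aggregation <- match.arg(aggregation)
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(datasets)) {
    if (is.null(input_dir)) {
      stop("provide datasets or input_dir", call. = FALSE)
    }
    if (!dir.exists(input_dir)) {
      stop("input_dir does not exist: ", input_dir, call. = FALSE)
    }
    datasets <- read_trial_bundle(input_dir)
    compositions <- compositions %||% attr(datasets, "compositions")
  }
  roles <- vapply(datasets, function(d) d$diet$role, character(1))
  if (sum(roles == "reference") != 1L) {
    stop("datasets must contain exactly one reference trial", call. = FALSE)
  }
  structure(list(datasets = datasets, compositions = compositions,
                 constants = constants, alpha = alpha,
                 aggregation = aggregation, protected = protected,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run the full feed-evaluation pipeline
#'
#' Orchestrates the analysis chain over one reference trial and any number
#' of test trials: (1) validation of every dataset; (2) reference-diet
#' digestibility measured directly, then each test ingredient's
#' digestibility by the difference method; (3) digestible nutrients, TDN,
#' DE and ME per ingredient; (4) intake and weight-gain summaries; (5)
#' treatment comparisons (one-way ANOVA + Duncan letters) for every
#' digestibility component, ME, daily gain and scaled intake. Any stage
#' failure aborts with the stage name in the error. When the configuration
#' names an output directory, tidy CSVs and markdown tables are written
#' there.
#'
#' @param config a [run_config()].
#' @return An object of class `feedeval_run`: list with `reference_coeffs`,
#'   `ingredient_coeffs`, `energy_profiles`, `intake`, `gains`,
#'   `comparisons`, `constants`, `validation`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ds <- config$datasets
  roles <- vapply(ds, function(d) d$diet$role, character(1))
  ref_ds <- ds[[which(roles == "reference")]]
  test_ds <- ds[roles == "test"]

  # -- validate ---------------------------------------------------------
  validation <- lapply(ds, validate_trial)
  n_bad <- sum(vapply(validation, nrow, integer(1)))
  if (n_bad > 0L) {
    bad <- do.call(rbind, validation)
    stop_fe("validate", sprintf(
      "%d invariant violation(s); first: %s (%s)", n_bad,
      bad$message[1], bad$id[1]))
  }

  # -- digestibility ----------------------------------------------------
  ref_coeffs <- tryCatch(
    diet_digestibility(ref_ds, method = config$aggregation),
    error = function(e) stop_fe("digestibility", conditionMessage(e)))
  ref_prof <- ref_ds$diet_profile
  ing_coeffs <- list()
  for (nm in names(test_ds)) {
    d <- test_ds[[nm]]
    ing_id <- d$diet$test_ingredient_id
    ing_prof <- config$compositions[[ing_id]]
    if (is.null(ing_prof)) {
      stop_fe("digestibility",
              sprintf("no composition profile for test ingredient '%s'",
                      ing_id))
    }
    ing_coeffs[[ing_id]] <- tryCatch(
      recover_ingredient_digestibility(
        d, ref_coeffs, ref_prof, ing_prof,
        per_animal = config$aggregation == "per_animal"),
      error = function(e) stop_fe("digestibility", conditionMessage(e)))
  }

  # -- energy -----------------------------------------------------------
  energy <- lapply(names(ing_coeffs), function(ing_id) {
    tryCatch(
      ingredient_energy_profile(config$compositions[[ing_id]],
                                ing_coeffs[[ing_id]], config$constants),
      error = function(e) stop_fe("energy", conditionMessage(e)))
  })
  names(energy) <- names(ing_coeffs)

  # -- intake & gains ---------------------------------------------------
  intake <- list()
  gains <- list()
  for (nm in names(test_ds)) {
    d <- test_ds[[nm]]
    ing_id <- d$diet$test_ingredient_id
    comp <- d$diet$components
    incl <- sum(comp$fraction[comp$ingredient_id == ing_id])
    ing_dm <- config$compositions[[ing_id]]$dm_pct
    intake[[ing_id]] <- tryCatch(
      intake_summary(d, incl, ingredient_dm_pct = ing_dm),
      error = function(e) stop_fe("intake", conditionMessage(e)))
    n_days <- max(d$records$day)
    gains[[ing_id]] <- tryCatch(
      gain_summary(d, n_days = n_days),
      error = function(e) stop_fe("intake", conditionMessage(e)))
  }

  # -- comparisons ------------------------------------------------------
  comparisons <- list()
  if (length(ing_coeffs) >= 2L) {
    cmp <- function(extract, label) {
      vals <- lapply(ing_coeffs, extract)
      keep <- !vapply(vals, is.null, logical(1))
      if (sum(keep) < 2L) return(NULL)
      tryCatch(
        compare_treatments(vals[keep], labels = names(vals)[keep],
                           alpha = config$alpha,
                           protected = config$protected),
        error = function(e) stop_fe("compare", conditionMessage(e)))
    }
    for (k in NUTRIENTS) {
      comparisons[[paste0("digestibility_", k)]] <- cmp(function(co) {
        if (!is.null(co$per_animal) && k %in% colnames(co$per_animal)) {
          co$per_animal[, k]
        } else {
          NULL
        }
      }, k)
    }
    comparisons$me_kcal_kg <- local({
      vals <- lapply(energy, function(ep) {
        if (is.null(ep$per_animal)) NULL else ep$per_animal[, "me_kcal_kg"]
      })
      keep <- !vapply(vals, is.null, logical(1))
      if (sum(keep) < 2L) NULL else {
        compare_treatments(vals[keep], labels = names(vals)[keep],
                           alpha = config$alpha,
                           protected = config$protected)
      }
    })
    comparisons$daily_gain <- local({
      vals <- lapply(gains, function(g) g$per_animal$daily_gain_g)
      compare_treatments(vals, labels = names(gains),
                         alpha = config$alpha, protected = config$protected)
    })
    comparisons$intake_pct_lw <- local({
      vals <- lapply(intake, function(s) s$per_animal$pct_live_weight)
      compare_treatments(vals, labels = names(intake),
                         alpha = config$alpha, protected = config$protected)
    })
    comparisons$intake_g_kg_mw <- local({
      vals <- lapply(intake, function(s) s$per_animal$g_per_kg_metabolic)
      compare_treatments(vals, labels = names(intake),
                         alpha = config$alpha, protected = config$protected)
    })
    comparisons <- Filter(Negate(is.null), comparisons)
  }

  run <- structure(list(
    reference_coeffs = ref_coeffs, ingredient_coeffs = ing_coeffs,
    energy_profiles = energy, intake = intake, gains = gains,
    comparisons = comparisons, constants = config$constants,
    validation = validation, alpha = config$alpha,
    aggregation = config$aggregation, seed = config$seed
  ), class = "feedeval_run")

  if (!is.null(config$out_dir)) write_run_bundle(run, config$out_dir)
  run
}

#' @export
print.feedeval_run <- function(x, ...) {
  cat(sprintf(
    "<feedeval_run> %d test ingredient(s), alpha = %g, aggregation = %s\n",
    length(x$ingredient_coeffs), x$alpha, x$aggregation))
  cat("  ingredients:", paste(names(x$ingredient_coeffs), collapse = ", "),
      "\n")
  invisible(x)
}

# Tidy CSV + markdown report bundle.
write_run_bundle <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dig <- do.call(rbind, lapply(names(run$ingredient_coeffs), function(id) {
    co <- run$ingredient_coeffs[[id]]
    data.frame(diet_id = id, nutrient = names(co$mean_pct),
               mean_pct = unname(co$mean_pct), sd_pct = unname(co$sd_pct),
               n = co$n_animals, flag = unname(co$flag))
  }))
  utils::write.csv(dig, file.path(out_dir, "digestibility.csv"),
                   row.names = FALSE)
  en <- do.call(rbind, lapply(names(run$energy_profiles), function(id) {
    ep <- run$energy_profiles[[id]]
    data.frame(ingredient_id = id, quantity = names(ep$mean),
               mean = unname(ep$mean), sd = unname(ep$sd))
  }))
  utils::write.csv(en, file.path(out_dir, "energy_profiles.csv"),
                   row.names = FALSE)
  ink <- do.call(rbind, lapply(names(run$intake), function(id) {
    cbind(ingredient_id = id, run$intake[[id]]$per_animal)
  }))
  utils::write.csv(ink, file.path(out_dir, "intake.csv"), row.names = FALSE)
  gn <- do.call(rbind, lapply(names(run$gains), function(id) {
    cbind(ingredient_id = id, run$gains[[id]]$per_animal)
  }))
  utils::write.csv(gn, file.path(out_dir, "gains.csv"), row.names = FALSE)
  if (length(run$comparisons)) {
    cl <- do.call(rbind, lapply(names(run$comparisons), function(v) {
      g <- run$comparisons[[v]]$groups
      data.frame(variable = v, treatment = g$label, n = g$n, mean = g$mean,
                 sd = g$sd, letters = g$letters)
    }))
    utils::write.csv(cl, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  writeLines(render_table(run$energy_profiles,
                          comparisons = run$comparisons),
             file.path(out_dir, "energy_table.md"))
  writeLines(render_digestibility_table(run$ingredient_coeffs,
                                        run$comparisons),
             file.path(out_dir, "digestibility_table.md"))
  log <- c(
    sprintf("aggregation: %s; alpha: %g; protected: n/a", run$aggregation,
            run$alpha),
    sprintf("energy constants: de_factor=%g me_factor=%g ee_weight=%g",
            run$constants$de_factor, run$constants$me_factor,
            run$constants$ee_weight),
    sprintf("seed: %s", run$seed %||% "none"))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

fmt_cell <- function(mean, sd, letter = NULL, digits = 2, absent = FALSE) {
  if (absent || is.na(mean)) return("-")
  cell <- sprintf(paste0("%.", digits, "f"), mean)
  if (!is.na(sd)) cell <- paste0(cell, " ± ",
                                 sprintf(paste0("%.", digits, "f"), sd))
  if (!is.null(letter) && !is.na(letter) && nzchar(letter)) {
    cell <- paste0(cell, " ^", letter, "^")
  }
  cell
}

letter_for <- function(comparisons, variable, treatment) {
  cm <- comparisons[[variable]]
  if (is.null(cm)) return(NA_character_)
  g <- cm$groups
  hit <- g$letters[g$label == treatment]
  if (length(hit)) hit[1] else NA_character_
}

#' Render results as markdown tables
#'
#' Formats a named list of [ingredient_energy_profile()] results (or, via
#' `render_digestibility_table()`, of digestibility coefficients) as a
#' markdown table in the conventional feed-table layout: one row per
#' ingredient, "mean ± sd ^letters^" cells, and "-" for absent components.
#'
#' @param x named list of `energy_profile` objects.
#' @param comparisons optional comparison list (from a [run_pipeline()]
#'   result) supplying superscript letters.
#' @param digits decimal places for percent columns.
#' @return Character vector of markdown lines.
#' @export
render_table <- function(x, comparisons = NULL, digits = 2) {
  header <- c("| Ingredient | dDM (%) | dCP (%) | dEE (%) | dCF (%) | dNFE (%) | TDN (%) | DE (kcal/kg) | ME (kcal/kg) |",
              "|---|---|---|---|---|---|---|---|---|")
  if (length(x) == 0L) return(header)
  rows <- vapply(names(x), function(id) {
    ep <- x[[id]]
    cells <- c(
      fmt_cell(ep$mean[["ddm"]], ep$sd[["ddm"]], digits = digits),
      fmt_cell(ep$mean[["dcp"]], ep$sd[["dcp"]], digits = digits),
      fmt_cell(ep$mean[["dee"]], ep$sd[["dee"]], digits = digits),
      fmt_cell(ep$mean[["dcf"]], ep$sd[["dcf"]], digits = digits),
      fmt_cell(ep$mean[["dnfe"]], ep$sd[["dnfe"]], digits = digits),
      fmt_cell(ep$mean[["tdn_pct"]], ep$sd[["tdn_pct"]], digits = digits),
      fmt_cell(ep$mean[["de_kcal_kg"]], ep$sd[["de_kcal_kg"]], digits = 0),
      fmt_cell(ep$mean[["me_kcal_kg"]], ep$sd[["me_kcal_kg"]],
               letter = letter_for(comparisons, "me_kcal_kg", id),
               digits = 0))
    paste0("| ", id, " | ", paste(cells, collapse = " | "), " |")
  }, character(1))
  c(header, rows)
}

#' @rdname render_table
#' @param coeffs named list of [digestibility_coefficients()].
#' @export
render_digestibility_table <- function(coeffs, comparisons = NULL,
                                       digits = 2) {
  header <- c("| Ingredient | DM (%) | CP (%) | EE (%) | CF (%) | NFE (%) |",
              "|---|---|---|---|---|---|")
  if (length(coeffs) == 0L) return(header)
  rows <- vapply(names(coeffs), function(id) {
    co <- coeffs[[id]]
    cells <- vapply(NUTRIENTS, function(k) {
      if (!k %in% names(co$mean_pct)) return("-")
      fmt_cell(co$mean_pct[[k]], co$sd_pct[[k]],
               letter = letter_for(comparisons,
                                   paste0("digestibility_", k), id),
               digits = digits)
    }, character(1))
    paste0("| ", id, " | ", paste(cells, collapse = " | "), " |")
  }, character(1))
  c(header, rows)
}
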