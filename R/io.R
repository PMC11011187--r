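# Tabular readers and writers for the trial CSV schemas.
#
# Dialect: comma-separated, UTF-8, "." decimal. In the CF and NFE columns
# only, a dagger ("†"), "NA" or an empty cell marks an absent component;
# everywhere else every cell must parse as a number. Readers are total over
# their inputs: malformed cells yield located diagnostics, never crashes.

ABSENT_MARKERS <- c("†", "NA", "")

parse_cell <- function(x, row, col, allow_absent = FALSE) {
  x <- trimws(x)
  if (allow_absent && x %in% ABSENT_MARKERS) return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) {
    stop(sprintf("cannot parse '%s' as a number (row %d, column %s)",
                 x, row, col), call. = FALSE)
  }
  v
}

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  if (file.size(path) == 0L) {
    warn_fe(sprintf("%s file is empty: %s", what, path))
    return(NULL)
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE, fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s file %s is missing required column(s): %s",
                 what, path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read and write ingredient composition tables
#'
#' `read_composition_table()` loads a CSV with columns
#' `ingredient_id, dm_pct, cp_pct, ee_pct, cf_pct, nfe_pct, ash_pct` into a
#' list of [proximate_profile()]s, preserving row order. Absent CF/NFE
#' (marked "†", "NA" or an empty cell) map to zero with the absence flag
#' set. `write_composition_table()` is the inverse, writing "†" back for
#' absent components so a read/write cycle preserves the table.
#'
#' @param path CSV file path.
#' @param basis basis of the component columns, passed to
#'   [proximate_profile()].
#' @param closure_tol closure-warning tolerance, percentage points.
#' @return `read_composition_table()`: a (possibly empty) list of
#'   `proximate_profile`; `write_composition_table()`: `path`, invisibly.
#' @export
read_composition_table <- function(path, basis = "as_analyzed",
                                   closure_tol = 2) {
  req <- c("ingredient_id", "dm_pct", "cp_pct", "ee_pct", "cf_pct",
           "nfe_pct", "ash_pct")
  df <- read_csv_checked(path, req, "composition")
  if (is.null(df) || nrow(df) == 0L) return(list())
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    cf <- parse_cell(df$cf_pct[i], i, "cf_pct", allow_absent = TRUE)
    nfe <- parse_cell(df$nfe_pct[i], i, "nfe_pct", allow_absent = TRUE)
    out[[i]] <- proximate_profile(
      ingredient_id = df$ingredient_id[i],
      dm_pct = parse_cell(df$dm_pct[i], i, "dm_pct"),
      cp_pct = parse_cell(df$cp_pct[i], i, "cp_pct"),
      ee_pct = parse_cell(df$ee_pct[i], i, "ee_pct"),
      cf_pct = cf, nfe_pct = nfe,
      ash_pct = parse_cell(df$ash_pct[i], i, "ash_pct"),
      basis = basis, closure_tol = closure_tol)
  }
  names(out) <- vapply(out, function(p) p$ingredient_id, character(1))
  out
}

#' @rdname read_composition_table
#' @param profiles list of [proximate_profile()] to write.
#' @export
write_composition_table <- function(profiles, path) {
  fmt <- function(v) formatC(v, format = "fg", digits = 15)
  rows <- lapply(profiles, function(p) {
    data.frame(
      ingredient_id = p$ingredient_id,
      dm_pct = fmt(p$dm_pct), cp_pct = fmt(p$cp_pct), ee_pct = fmt(p$ee_pct),
      cf_pct = if (p$cf_absent) "†" else fmt(p$cf_pct),
      nfe_pct = if (p$nfe_absent) "†" else fmt(p$nfe_pct),
      ash_pct = fmt(p$ash_pct))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read diet formulation tables
#'
#' Loads `diets.csv` (`diet_id, ingredient_id, fraction, role`) into a named
#' list of [diet_spec()]s. `role` applies per diet (`reference` or `test`);
#' for a test diet the single non-reference component is taken as the test
#' ingredient.
#'
#' @param path CSV file path.
#' @param reference_ids ingredient ids to treat as reference-diet components
#'   when identifying the test ingredient; defaults to the components of the
#'   reference diet(s) in the same file.
#' @return Named list of `diet_spec`.
#' @export
read_diet_table <- function(path, reference_ids = NULL) {
  df <- read_csv_checked(path, c("diet_id", "ingredient_id", "fraction",
                                 "role"), "diet")
  if (is.null(df) || nrow(df) == 0L) return(list())
  df$fraction <- vapply(seq_len(nrow(df)),
                        function(i) parse_cell(df$fraction[i], i, "fraction"),
                        numeric(1))
  if (is.null(reference_ids)) {
    reference_ids <- unique(df$ingredient_id[df$role == "reference"])
  }
  out <- list()
  for (id in unique(df$diet_id)) {
    sub <- df[df$diet_id == id, , drop = FALSE]
    role <- unique(sub$role)
    if (length(role) != 1L) {
      stop(sprintf("diet %s has inconsistent roles", id), call. = FALSE)
    }
    test_ing <- NULL
    if (role == "test") {
      cand <- setdiff(sub$ingredient_id, reference_ids)
      if (length(cand) == 1L) test_ing <- cand
    }
    out[[id]] <- diet_spec(id, sub[, c("ingredient_id", "fraction")],
                           role = role, test_ingredient_id = test_ing)
  }
  out
}

#' Read per-animal trial record tables
#'
#' `read_trial_records()` loads `records.csv`
#' (`diet_id, animal_id, day, offered_g, refused_g, feces_fresh_g,
#' feces_dm_fraction`); `read_weight_table()` loads `weights.csv`
#' (`diet_id, animal_id, initial_g, final_g`); `read_fecal_composition()`
#' loads `fecal_composition.csv`
#' (`diet_id, animal_id, cp_pct, ee_pct, cf_pct, nfe_pct, ash_pct`, dry-matter
#' basis) into a nested list of [proximate_profile()] keyed by diet then
#' animal.
#'
#' @param path CSV file path.
#' @return A data.frame (records, weights) or nested list (fecal profiles).
#' @export
read_trial_records <- function(path) {
  req <- c("diet_id", "animal_id", "day", "offered_g", "refused_g",
           "feces_fresh_g", "feces_dm_fraction")
  df <- read_csv_checked(path, req, "records")
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(diet_id = character(), animal_id = character(),
                      day = integer(), offered_g = numeric(),
                      refused_g = numeric(), feces_fresh_g = numeric(),
                      feces_dm_fraction = numeric()))
  }
  for (col in c("day", "offered_g", "refused_g", "feces_fresh_g",
                "feces_dm_fraction")) {
    df[[col]] <- vapply(seq_len(nrow(df)),
                        function(i) parse_cell(df[[col]][i], i, col),
                        numeric(1))
  }
  df$day <- as.integer(df$day)
  df
}

#' @rdname read_trial_records
#' @export
read_weight_table <- function(path) {
  df <- read_csv_checked(path, c("diet_id", "animal_id", "initial_g",
                                 "final_g"), "weights")
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(diet_id = character(), animal_id = character(),
                      initial_g = numeric(), final_g = numeric()))
  }
  for (col in c("initial_g", "final_g")) {
    df[[col]] <- vapply(seq_len(nrow(df)),
                        function(i) parse_cell(df[[col]][i], i, col),
                        numeric(1))
  }
  df
}

#' @rdname read_trial_records
#' @export
read_fecal_composition <- function(path) {
  req <- c("diet_id", "animal_id", "cp_pct", "ee_pct", "cf_pct", "nfe_pct",
           "ash_pct")
  df <- read_csv_checked(path, req, "fecal composition")
  out <- list()
  if (is.null(df)) return(out)
  for (i in seq_len(nrow(df))) {
    cf <- parse_cell(df$cf_pct[i], i, "cf_pct", allow_absent = TRUE)
    nfe <- parse_cell(df$nfe_pct[i], i, "nfe_pct", allow_absent = TRUE)
    prof <- proximate_profile(
      ingredient_id = sprintf("feces:%s:%s", df$diet_id[i], df$animal_id[i]),
      dm_pct = 100,
      cp_pct = parse_cell(df$cp_pct[i], i, "cp_pct"),
      ee_pct = parse_cell(df$ee_pct[i], i, "ee_pct"),
      cf_pct = cf, nfe_pct = nfe,
      ash_pct = parse_cell(df$ash_pct[i], i, "ash_pct"),
      basis = "dry_matter")
    out[[df$diet_id[i]]][[df$animal_id[i]]] <- prof
  }
  out
}

#' Assemble trial datasets from the standard CSV bundle
#'
#' Reads the five CSV schemas from `dir` (`compositions.csv`, `diets.csv`,
#' `records.csv`, `fecal_composition.csv`, `weights.csv`) and assembles one
#' [trial_dataset()] per diet. Each diet's offered-feed profile is the
#' inclusion-weighted blend of its ingredient compositions.
#'
#' @param dir directory containing the CSV bundle.
#' @return Named list of `trial_dataset`, plus the ingredient profiles as
#'   attribute `"compositions"`.
#' @export
read_trial_bundle <- function(dir) {
  comps <- read_composition_table(file.path(dir, "compositions.csv"))
  diets <- read_diet_table(file.path(dir, "diets.csv"))
  recs <- read_trial_records(file.path(dir, "records.csv"))
  fec <- read_fecal_composition(file.path(dir, "fecal_composition.csv"))
  wts <- read_weight_table(file.path(dir, "weights.csv"))
  out <- list()
  for (id in names(diets)) {
    d <- diets[[id]]
    parts <- comps[d$components$ingredient_id]
    if (any(vapply(parts, is.null, logical(1)))) {
      stop(sprintf("diet %s references ingredients missing from compositions.csv", id),
           call. = FALSE)
    }
    prof <- blend_diet_profile(parts, d$components$fraction, diet_id = id)
    out[[id]] <- trial_dataset(
      diet = d, diet_profile = prof,
      fecal_profiles = fec[[id]] %||% list(),
      records = recs[recs$diet_id == id, , drop = FALSE],
      weights = wts[wts$diet_id == id, , drop = FALSE])
  }
  attr(out, "compositions") <- comps
  out
}
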