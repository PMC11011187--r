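#' Proximate (Weende) composition of a feedstuff or diet
#'
#' A `proximate_profile` holds the Weende partition of one ingredient, diet or
#' fecal sample: dry matter (DM) plus crude protein (CP), ether extract (EE),
#' crude fiber (CF), nitrogen-free extract (NFE) and ash. Component
#' percentages refer either to the analysed (air-dry) fraction
#' (`basis = "as_analyzed"`) or to dry matter (`basis = "dry_matter"`);
#' `dm_pct` is always percent of as-fed mass. Animal by-product meals often
#' genuinely lack CF and NFE; those components are flagged absent and carried
#' as exact zeros rather than missing values so that downstream mass-balance
#' arithmetic stays total.
#'
#' The organic components plus ash are expected to close to 100 on the
#' analysed-fraction basis. Closure failures beyond `closure_tol` percentage
#' points raise a warning (never an error): published composition tables do
#' not always close, and the analysis must be able to proceed on them.
#'
#' @param ingredient_id character label.
#' @param dm_pct dry matter, percent of as-fed mass (> 0).
#' @param cp_pct,ee_pct,cf_pct,nfe_pct,ash_pct component percentages on
#'   `basis`; `cf_pct`/`nfe_pct` may be `NA` to mark the component absent.
#' @param cf_absent,nfe_absent logical absence flags; defaulted from `NA`
#'   values of the corresponding percentage.
#' @param basis `"as_analyzed"` (default) or `"dry_matter"`.
#' @param closure_tol tolerance, percentage points, for the closure check
#'   (default 2).
#' @return An object of class `proximate_profile`.
#' @examples
#' rcm <- proximate_profile("RCM", 85, 15, 5.5, 38, 30.5, 11)
#' bm  <- suppressWarnings(proximate_profile("BM", 92, 72.4, 0.5, NA, NA, 4))
#' nutrient_pcts(bm)[["cf"]]  # absent -> exact 0
#' @export
proximate_profile <- function(ingredient_id, dm_pct, cp_pct, ee_pct,
                              cf_pct = NA, nfe_pct = NA, ash_pct,
                              cf_absent = is.na(cf_pct),
                              nfe_absent = is.na(nfe_pct),
                              basis = c("as_analyzed", "dry_matter"),
                              closure_tol = 2) {
  basis <- match.arg(basis)
  if (!is.character(ingredient_id) || length(ingredient_id) != 1L) {
    stop("ingredient_id must be a single character label", call. = FALSE)
  }
  if (cf_absent) cf_pct <- 0
  if (nfe_absent) nfe_pct <- 0
  vals <- c(dm = dm_pct, cp = cp_pct, ee = ee_pct, cf = cf_pct,
            nfe = nfe_pct, ash = ash_pct)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is_number(v)) stop(sprintf("%s_pct must be a single finite number", nm), call. = FALSE)
    if (v < 0 || v > 100) stop(sprintf("%s_pct = %g outside [0, 100]", nm, v), call. = FALSE)
  }
  if (dm_pct <= 0) stop("dm_pct must be > 0", call. = FALSE)
  if (cf_absent && cf_pct != 0) stop("cf flagged absent but cf_pct != 0", call. = FALSE)
  if (nfe_absent && nfe_pct != 0) stop("nfe flagged absent but nfe_pct != 0", call. = FALSE)

  p <- structure(list(
    ingredient_id = ingredient_id,
    dm_pct = dm_pct, cp_pct = cp_pct, ee_pct = ee_pct,
    cf_pct = cf_pct, nfe_pct = nfe_pct, ash_pct = ash_pct,
    cf_absent = isTRUE(cf_absent), nfe_absent = isTRUE(nfe_absent),
    basis = basis
  ), class = "proximate_profile")

  closure <- cp_pct + ee_pct + cf_pct + nfe_pct + ash_pct
  if (basis == "as_analyzed" && abs(closure - 100) > closure_tol) {
    warn_fe(sprintf(
      "proximate components of '%s' sum to %.2f, outside 100 ± %g; proceeding",
      ingredient_id, closure, closure_tol))
  }
  p
}

#' @export
print.proximate_profile <- function(x, ...) {
  fmt <- function(v, absent) if (absent) "†" else sprintf("%.2f", v)
  cat(sprintf("<proximate_profile> %s (basis: %s)\n", x$ingredient_id, x$basis))
  cat(sprintf("  DM %.2f | CP %s EE %s CF %s NFE %s ash %s\n",
              x$dm_pct, fmt(x$cp_pct, FALSE), fmt(x$ee_pct, FALSE),
              fmt(x$cf_pct, x$cf_absent), fmt(x$nfe_pct, x$nfe_absent),
              fmt(x$ash_pct, FALSE)))
  invisible(x)
}

#' Nutrient percentages of a profile as a named vector
#'
#' Returns `c(dm, cp, ee, cf, nfe)` with absent components as exact zeros.
#' The companion `nutrient_absent()` returns the absence flags (DM is never
#' absent).
#'
#' @param profile a [proximate_profile()].
#' @return Named numeric (or logical) vector over `dm, cp, ee, cf, nfe`.
#' @export
nutrient_pcts <- function(profile) {
  stopifnot(inherits(profile, "proximate_profile"))
  c(dm = profile$dm_pct, cp = profile$cp_pct, ee = profile$ee_pct,
    cf = profile$cf_pct, nfe = profile$nfe_pct)
}

#' @rdname nutrient_pcts
#' @export
nutrient_absent <- function(profile) {
  stopifnot(inherits(profile, "proximate_profile"))
  c(dm = FALSE, cp = FALSE, ee = FALSE,
    cf = profile$cf_absent, nfe = profile$nfe_absent)
}

#' Convert a proximate profile between bases
#'
#' `as_dry_matter()` rescales organic components and ash from the analysed
#' fraction to a dry-matter basis (divides by `dm_pct/100`); `as_analyzed()`
#' is the inverse. `dm_pct` itself (percent of as-fed mass) is unchanged.
#' Conversion is always explicit: no function in the package silently guesses
#' the basis of its input.
#'
#' @param profile a [proximate_profile()].
#' @return The converted `proximate_profile`.
#' @export
as_dry_matter <- function(profile) {
  stopifnot(inherits(profile, "proximate_profile"))
  if (profile$basis == "dry_matter") return(profile)
  f <- 100 / profile$dm_pct
  convert_basis(profile, f, "dry_matter")
}

#' @rdname as_dry_matter
#' @export
as_analyzed <- function(profile) {
  stopifnot(inherits(profile, "proximate_profile"))
  if (profile$basis == "as_analyzed") return(profile)
  f <- profile$dm_pct / 100
  convert_basis(profile, f, "as_analyzed")
}

convert_basis <- function(profile, f, basis) {
  p <- profile
  for (nm in c("cp_pct", "ee_pct", "cf_pct", "nfe_pct", "ash_pct")) {
    p[[nm]] <- p[[nm]] * f
  }
  p$basis <- basis
  p
}
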