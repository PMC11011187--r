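#' One-way analysis of variance
#'
#' Classical fixed-effects one-way decomposition over a list of group
#' samples, reporting the F statistic, its p-value, degrees of freedom and
#' the within-group mean square (MSE) that range tests need. Fitted through
#' [stats::lm()].
#'
#' Degenerate inputs are reported, not errored: if every observation is
#' identical (no between- or within-group variation) the F ratio is
#' undefined and the result carries `f = NA`, `p_value = 1` (no evidence of
#' difference). Zero within-group variance with distinct means yields
#' `f = Inf`, `p_value = 0`.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups,
#'   each of length >= 2).
#' @param labels optional group labels (default: list names or G1, G2, ...).
#' @return An object of class `anova_oneway`: list with `f`, `p_value`,
#'   `df_between`, `df_within`, `mse`, and a `groups` data.frame
#'   (`label`, `n`, `mean`, `sd`).
#' @export
anova_oneway <- function(groups, labels = NULL) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  labels <- labels %||% names(groups) %||%
    paste0("G", seq_along(groups))
  if (length(labels) != length(groups)) {
    stop("labels length does not match number of groups", call. = FALSE)
  }
  n_i <- lengths(groups)
  if (any(n_i < 2L)) stop("every group needs n >= 2", call. = FALSE)

  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n_i))
  df_b <- length(groups) - 1L
  df_w <- length(y) - length(groups)

  fit <- stats::lm(y ~ g)
  # zero-residual fits warn inside anova.lm; the degenerate cases are
  # handled explicitly below
  an <- suppressWarnings(stats::anova(fit))
  ms_between <- an$`Mean Sq`[1]
  mse <- an$`Mean Sq`[2]

  # guard against floating-point residue in exactly degenerate data
  eps <- 1e-12 * (1 + mean(y)^2)
  if (mse <= eps && ms_between <= eps) {
    f <- NA_real_; p <- 1; mse <- 0       # no variation at all
  } else if (mse <= eps) {
    f <- Inf; p <- 0; mse <- 0            # separated, zero within-variance
  } else {
    f <- ms_between / mse
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  gstats <- data.frame(label = labels, n = as.integer(n_i),
                       mean = vapply(groups, mean, numeric(1)),
                       sd = vapply(groups, stats::sd, numeric(1)))
  structure(list(f = f, p_value = p, df_between = df_b, df_within = df_w,
                 mse = mse, groups = gstats),
            class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("<anova_oneway> F(%d, %d) = %s, p = %s, MSE = %.4g\n",
              x$df_between, x$df_within,
              format(x$f, digits = 4), format(x$p_value, digits = 4),
              x$mse))
  invisible(x)
}

# Duncan's span-dependent critical range: the studentized-range quantile at
# protection level 1 - (1 - alpha)^(p - 1), scaled by sqrt(MSE / n_h).
duncan_lsr <- function(p, alpha, df_within, mse, n_harmonic) {
  alpha_p <- 1 - (1 - alpha)^(p - 1)
  stats::qtukey(1 - alpha_p, nmeans = p, df = df_within) *
    sqrt(mse / n_harmonic)
}

#' Duncan's multiple range test with compact letter display
#'
#' Stepwise multiple comparison of group means. Means are ranked in
#' descending order (ties broken by input order) and every span of p
#' consecutive ranked means is compared against its least significant range
#' `LSR_p = q(p, df; alpha_p) × sqrt(MSE / n_h)`, where `q` is the
#' studentized-range quantile at Duncan's protection level
#' `alpha_p = 1 − (1 − alpha)^(p−1)` and `n_h` the harmonic mean group size
#' (unequal group sizes are accommodated this way and noted). Testing runs
#' from the widest span inward and a span nested inside a non-significant
#' span is never declared significant (the standard shielding rule).
#'
#' Maximal non-significant spans become letter groups: lowercase letters,
#' contiguous from "a", with the largest mean carrying "a". Groups sharing
#' any letter do not differ at level `alpha`.
#'
#' By default the test is unprotected (no prior ANOVA-F gate), as is common
#' in animal-science software; `protected = TRUE` assigns a single shared
#' letter whenever the ANOVA p-value is >= `alpha`.
#'
#' @param groups list of numeric group samples (a single group is allowed
#'   and yields letter "a").
#' @param alpha nominal comparisonwise significance level (default 0.05).
#' @param labels optional group labels.
#' @param protected gate the letter display on ANOVA p < alpha?
#' @return An object of class `duncan_mrt`: list with a `groups` data.frame
#'   (`label`, `n`, `mean`, `sd`, `letters`, input order), the underlying
#'   `anova_oneway`, `alpha`, and the LSR table.
#' @export
duncan_mrt <- function(groups, alpha = 0.05, labels = NULL,
                       protected = FALSE) {
  if (!is.list(groups)) stop("groups must be a list", call. = FALSE)
  labels <- labels %||% names(groups) %||% paste0("G", seq_along(groups))
  if (length(labels) != length(groups)) {
    stop("labels length does not match number of groups", call. = FALSE)
  }
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  k <- length(groups)
  if (k == 1L) {
    gstats <- data.frame(label = labels, n = lengths(groups),
                         mean = vapply(groups, mean, numeric(1)),
                         sd = vapply(groups, stats::sd, numeric(1)),
                         letters = "a")
    return(structure(list(groups = gstats, anova = NULL, alpha = alpha,
                          lsr = NULL, protected = protected),
                     class = "duncan_mrt"))
  }

  an <- anova_oneway(groups, labels)
  means <- an$groups$mean
  n_i <- an$groups$n
  if (any(n_i != n_i[1])) {
    warn_fe("unequal group sizes; Duncan ranges use the harmonic mean n")
  }
  n_h <- k / sum(1 / n_i)

  # order: descending mean, ties by input order
  ord <- order(-means, seq_len(k))
  m_sorted <- means[ord]

  lsr <- vapply(2:k, function(p) {
    if (an$mse <= 0) 0 else duncan_lsr(p, alpha, an$df_within, an$mse, n_h)
  }, numeric(1))
  names(lsr) <- paste0("p", 2:k)

  if (protected && !is.na(an$p_value) && an$p_value >= alpha) {
    letters_sorted <- rep("a", k)
  } else {
    nonsig <- nonsig_spans(m_sorted, lsr, mse_zero = an$mse <= 0)
    letters_sorted <- letters_from_spans(nonsig, k)
  }
  gstats <- an$groups
  gstats$letters <- NA_character_
  gstats$letters[ord] <- letters_sorted
  structure(list(groups = gstats, anova = an, alpha = alpha, lsr = lsr,
                 protected = protected),
            class = "duncan_mrt")
}

# Top-down range-testing over sorted (descending) means. Returns the list of
# retained maximal non-significant spans as (start, end) index pairs.
nonsig_spans <- function(m_sorted, lsr, mse_zero = FALSE) {
  k <- length(m_sorted)
  spans <- list()
  covered <- function(i, j) {
    any(vapply(spans, function(s) s[1] <= i && j <= s[2], logical(1)))
  }
  for (p in k:2) {
    for (i in seq_len(k - p + 1L)) {
      j <- i + p - 1L
      if (covered(i, j)) next  # shielded by a wider non-significant span
      range_ij <- m_sorted[i] - m_sorted[j]
      ns <- if (mse_zero) range_ij <= 0 else range_ij <= lsr[[p - 1L]]
      if (ns) spans[[length(spans) + 1L]] <- c(i, j)
    }
  }
  spans
}

# Compact letter display from maximal non-significant spans over ranks
# 1..k (sorted by descending mean): each span gets a letter in order of its
# start; uncovered singletons get their own letter.
letters_from_spans <- function(spans, k) {
  in_span <- rep(FALSE, k)
  for (s in spans) in_span[s[1]:s[2]] <- TRUE
  for (i in which(!in_span)) spans[[length(spans) + 1L]] <- c(i, i)
  starts <- vapply(spans, `[`, numeric(1), 1)
  ends <- vapply(spans, `[`, numeric(1), 2)
  o <- order(starts, ends)
  spans <- spans[o]
  out <- character(k)
  for (si in seq_along(spans)) {
    s <- spans[[si]]
    idx <- s[1]:s[2]
    out[idx] <- paste0(out[idx], letters[si])
  }
  out
}

#' @export
print.duncan_mrt <- function(x, ...) {
  cat(sprintf("<duncan_mrt> alpha = %g%s\n", x$alpha,
              if (x$protected) " (protected)" else ""))
  g <- x$groups
  for (i in order(-g$mean)) {
    cat(sprintf("  %-12s %8.3f ± %-8.3f %s\n", g$label[i], g$mean[i],
                g$sd[i], g$letters[i]))
  }
  invisible(x)
}

#' Compare treatments on one measured variable
#'
#' Wraps [anova_oneway()] and [duncan_mrt()] into the standard trial-table
#' summary: per-treatment n, mean, sd and Duncan letter, plus the ANOVA
#' statistics, with a `format()` method producing "mean ± sd ^letters^"
#' cells.
#'
#' @param values list of numeric vectors (one per treatment), or a
#'   data.frame with columns `treatment` and `value`.
#' @param labels treatment labels (required when `values` is an unnamed
#'   list; length must match).
#' @param alpha significance level for the letter display.
#' @param protected gate letters on a significant ANOVA F?
#' @return An object of class `group_comparison`: list with `groups`
#'   data.frame (`label`, `n`, `mean`, `sd`, `letters`), `anova`, `alpha`.
#' @export
compare_treatments <- function(values, labels = NULL, alpha = 0.05,
                               protected = FALSE) {
  if (is.data.frame(values)) {
    stopifnot(all(c("treatment", "value") %in% names(values)))
    split_v <- split(values$value, factor(values$treatment,
                                          levels = unique(values$treatment)))
    labels <- labels %||% names(split_v)
    values <- split_v
  }
  labels <- labels %||% names(values)
  if (is.null(labels) || length(labels) != length(values)) {
    stop("labels must be provided and match the number of treatments",
         call. = FALSE)
  }
  d <- duncan_mrt(values, alpha = alpha, labels = labels,
                  protected = protected)
  structure(list(groups = d$groups, anova = d$anova, alpha = alpha,
                 duncan = d), class = "group_comparison")
}

#' @export
format.group_comparison <- function(x, digits = 2, ...) {
  g <- x$groups
  cells <- sprintf(paste0("%.", digits, "f ± %.", digits, "f ^%s^"),
                   g$mean, g$sd, g$letters)
  names(cells) <- g$label
  cells
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  cells <- format(x)
  for (nm in names(cells)) cat(sprintf("  %-12s %s\n", nm, cells[[nm]]))
  if (!is.null(x$anova)) {
    cat(sprintf("  ANOVA: F(%d, %d) = %s, p = %s\n",
                x$anova$df_between, x$anova$df_within,
                format(x$anova$f, digits = 4),
                format(x$anova$p_value, digits = 4)))
  }
  invisible(x)
}
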