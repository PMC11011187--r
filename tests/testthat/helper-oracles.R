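# Independent brute-force oracles. Deliberately naive: plain loops straight
# from the defining formulas, sharing no code with the implementation paths
# they check.

# Day-by-day nutrient flux for one animal.
oracle_flux <- function(dataset, animal_id) {
  r <- dataset$records[dataset$records$animal_id == animal_id, ]
  diet <- dataset$diet_profile
  fec <- dataset$fecal_profiles[[animal_id]]
  I <- c(dm = 0, cp = 0, ee = 0, cf = 0, nfe = 0)
  F_ <- I
  for (i in seq_len(nrow(r))) {
    net <- r$offered_g[i] - r$refused_g[i]
    I[["dm"]] <- I[["dm"]] + net * diet$dm_pct / 100
    for (k in c("cp", "ee", "cf", "nfe")) {
      I[[k]] <- I[[k]] + net * diet[[paste0(k, "_pct")]] / 100
    }
    fdm <- r$feces_fresh_g[i] * r$feces_dm_fraction[i]
    F_[["dm"]] <- F_[["dm"]] + fdm
    for (k in c("cp", "ee", "cf", "nfe")) {
      F_[[k]] <- F_[[k]] + fdm * fec[[paste0(k, "_pct")]] / 100
    }
  }
  list(intake_g = I, fecal_g = F_)
}

# One-way ANOVA F from the definitional sums of squares.
oracle_anova_f <- function(groups) {
  all_y <- unlist(groups)
  grand <- mean(all_y)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                     numeric(1)))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- length(groups) - 1
  df_w <- length(all_y) - length(groups)
  (ss_b / df_b) / (ss_w / df_w)
}

# Exhaustive-span Duncan letter display. A pair of ranked means is "not
# separated" iff SOME span covering both has observed range <= its least
# significant range (the shielding rule, stated existentially). Letters are
# the maximal non-separated intervals.
oracle_duncan_letters <- function(groups, alpha = 0.05) {
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  n_i <- lengths(groups)
  all_y <- unlist(groups)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_w <- length(all_y) - k
  mse <- ss_w / df_w
  n_h <- k / sum(1 / n_i)

  ord <- order(-means, seq_len(k))
  m <- means[ord]
  lsr_p <- vapply(2:k, function(p) {
    a_p <- 1 - (1 - alpha)^(p - 1)
    qtukey(1 - a_p, nmeans = p, df = df_w) * sqrt(mse / n_h)
  }, numeric(1))
  nonsep <- matrix(FALSE, k, k)
  for (i in 1:k) nonsep[i, i] <- TRUE
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      found <- FALSE
      for (a in 1:i) {
        for (b in j:k) {
          rng <- m[a] - m[b]
          ok <- if (mse <= 0) rng <= 0 else rng <= lsr_p[b - a]
          if (ok) found <- TRUE
        }
      }
      nonsep[i, j] <- nonsep[j, i] <- found
    }
  }
  # maximal intervals of pairwise non-separation
  intervals <- list()
  for (i in 1:k) {
    for (j in i:k) {
      if (nonsep[i, j]) {
        wider <- (i > 1 && nonsep[i - 1, j]) || (j < k && nonsep[i, j + 1])
        if (!wider) intervals[[length(intervals) + 1L]] <- c(i, j)
      }
    }
  }
  starts <- vapply(intervals, `[`, numeric(1), 1)
  intervals <- intervals[order(starts)]
  lets <- character(k)
  for (s in seq_along(intervals)) {
    idx <- intervals[[s]][1]:intervals[[s]][2]
    lets[idx] <- paste0(lets[idx], letters[s])
  }
  out <- character(k)
  out[ord] <- lets
  out
}

# Term-by-term recomputation of the digestible-nutrient/energy chain.
oracle_energy_row <- function(comp, dig, ee_weight = 2.25,
                              de_factor = 44.09, me_factor = 0.82) {
  d <- function(k) comp[[k]] * dig[[k]] / 100
  terms <- c(cp = d("cp"), ee = d("ee"),
             cf = if (is.na(comp[["cf"]])) 0 else d("cf"),
             nfe = if (is.na(comp[["nfe"]])) 0 else d("nfe"))
  tdn <- terms[["cp"]] + ee_weight * terms[["ee"]] + terms[["cf"]] +
    terms[["nfe"]]
  de <- tdn * de_factor
  c(tdn = tdn, de = de, me = de * me_factor)
}
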