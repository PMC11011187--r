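# Fixture builders used across the suite. Everything is generated in code;
# no data files.

# A tiny hand-held dataset: 2 animals x 3 days on a reference-style diet.
tiny_dataset <- function(dm = 90, cp = 12, ee = 4, cf = 6, nfe = 75,
                         ash = 3) {
  diet <- diet_spec("D1", data.frame(ingredient_id = "RD", fraction = 1),
                    role = "reference")
  prof <- proximate_profile("RD", dm, cp, ee, cf, nfe, ash,
                            closure_tol = Inf)
  fec <- function(id) {
    proximate_profile(paste0("fec", id), 100, 20, 5, 15, 50, 10,
                      basis = "dry_matter")
  }
  records <- rbind(
    data.frame(animal_id = "a1", day = 1:3, offered_g = c(50, 52, 48),
               refused_g = c(5, 6, 4), feces_fresh_g = c(20, 22, 18),
               feces_dm_fraction = c(0.3, 0.32, 0.28)),
    data.frame(animal_id = "a2", day = 1:3, offered_g = c(55, 50, 53),
               refused_g = c(8, 2, 6), feces_fresh_g = c(25, 19, 21),
               feces_dm_fraction = c(0.31, 0.29, 0.33)))
  weights <- data.frame(animal_id = c("a1", "a2"),
                        initial_g = c(800, 850), final_g = c(830, 890))
  trial_dataset(diet, prof, list(a1 = fec(1), a2 = fec(2)), records,
                weights)
}

# Random but physically consistent truth configuration for inversion
# sweeps: component digestibilities are drawn freely and the DM
# digestibility of each feed derived from its own mass balance (ash taken
# indigestible), so fecal components can never exceed fecal DM.
random_truth_config <- function(seed, with_fiber = runif(1) < 0.5) {
  mk <- function(id, cp, ee, cf, nfe, ash, dm) {
    proximate_profile(id, dm, cp, ee, cf, nfe, ash, closure_tol = Inf)
  }
  derive_dm_dig <- function(prof, dig) {
    p <- nutrient_pcts(prof)
    f <- prof$ash_pct / 100
    for (k in c("cp", "ee", "cf", "nfe")) {
      f <- f + p[[k]] / 100 * (1 - dig[[k]] / 100)
    }
    100 * (1 - f / (prof$dm_pct / 100))
  }
  ref_dm <- runif(1, 86, 94)
  ref_ash <- runif(1, 2, 6)
  ref_cp <- runif(1, 8, 16)
  ref_ee <- runif(1, 2, 6)
  ref_cf <- runif(1, 4, 10)
  ref_nfe <- 100 - ref_cp - ref_ee - ref_cf - ref_ash
  ref <- mk("REF", ref_cp, ref_ee, ref_cf, ref_nfe, ref_ash, ref_dm)
  ref_dig <- c(dm = NA, cp = runif(1, 60, 95), ee = runif(1, 60, 95),
               cf = runif(1, 40, 90), nfe = runif(1, 60, 95))
  ref_dig[["dm"]] <- derive_dm_dig(ref, ref_dig)

  ing_dm <- runif(1, 86, 94)
  ing_ash <- runif(1, 2, 8)
  ing_cp <- runif(1, 40, 70)
  ing_ee <- runif(1, 2, 12)
  if (with_fiber) {
    ing_cf <- runif(1, 2, 8)
    ing_nfe <- 100 - ing_cp - ing_ee - ing_cf - ing_ash
  } else {
    ing_cf <- NA
    ing_nfe <- NA
  }
  ing <- mk("ING", ing_cp, ing_ee, ing_cf, ing_nfe, ing_ash, ing_dm)
  ing_dig <- c(dm = NA, cp = runif(1, 60, 98), ee = runif(1, 60, 95),
               cf = if (with_fiber) runif(1, 40, 90) else NA,
               nfe = if (with_fiber) runif(1, 60, 95) else NA)
  dig_for_dm <- ing_dig
  dig_for_dm[is.na(dig_for_dm)] <- 0
  ing_dig[["dm"]] <- derive_dm_dig(ing, dig_for_dm)

  trial_sim_config(
    seed = seed,
    inclusion_fraction = runif(1, 0.1, 0.4),
    ref_profile = ref, ref_digestibility = ref_dig,
    ing_profile = ing, ing_digestibility = ing_dig)
}

# Random group samples for range-test sweeps.
random_groups <- function(k = sample(2:6, 1), n_range = c(3L, 9L),
                          equal_n = runif(1) < 0.5) {
  n_vals <- n_range[1]:n_range[2]
  n_i <- if (equal_n) {
    rep(n_vals[sample.int(length(n_vals), 1)], k)
  } else {
    n_vals[sample.int(length(n_vals), k, replace = TRUE)]
  }
  means <- runif(k, 0, 12)
  sds <- runif(k, 0.5, 3)
  lapply(seq_len(k), function(i) rnorm(n_i[i], means[i], sds[i]))
}
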