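# Water-fractionation arithmetic, the statistical gate, and the
# branch-removal contrasts.

test_that("relative water content follows (wet - dry) / dry x 100", {
  expect_equal(relative_water_content(0.5, 0.5), 0)
  expect_equal(relative_water_content(2.1, 0.1), 2000)  # >= 20x biomass in water
  expect_equal(relative_water_content(0.28, 0.20), 40, tolerance = 1e-12)
  expect_equal(relative_water_content(c(1, 2), 0.5), c(100, 300))
  expect_error(relative_water_content(1, 0), "dry")
  expect_error(relative_water_content(-0.1, 0.2), "wet")
  expect_warning(v <- relative_water_content(0.1, 0.2), "physically suspect")
  expect_equal(v, -50)
})

test_that("per-force losses use the initial weight and add to the cumulative", {
  rec <- centrifuge_record("p1", "S. testii", "intact",
                           saturated_weight = 2.0,
                           forces = c(17, 66, 149, 266),
                           released = c(0.1, 0.2, 0, 0.3), dry_weight = 0.2)
  s <- percent_weight_loss(rec)
  expect_equal(unname(s$percent_loss_per_force), c(5, 10, 0, 15))
  expect_equal(unname(s$cumulative_percent_loss), c(5, 15, 15, 30))
  expect_equal(sum(s$percent_loss_per_force),
               s$cumulative_percent_loss[[length(s$cumulative_percent_loss)]])
  expect_equal(s$exchangeable_fraction, 0.6 / 1.8)

  # all-zero release
  rec0 <- centrifuge_record("p2", "S. testii", "intact", 2.0,
                            c(17, 66), c(0, 0), dry_weight = 0.2)
  s0 <- percent_weight_loss(rec0)
  expect_true(all(s0$percent_loss_per_force == 0))
  expect_equal(s0$rwc_before, s0$rwc_after)
})

test_that("cumulative loss is non-decreasing for random valid ledgers", {
  set.seed(7)
  for (i in 1:20) {
    rel <- runif(4, 0, 0.2)
    rec <- centrifuge_record("p", "s", "intact", saturated_weight = 2,
                             forces = c(17, 66, 149, 266), released = rel,
                             dry_weight = 0.3)
    s <- percent_weight_loss(rec)
    expect_true(all(diff(s$cumulative_percent_loss) >= -1e-12))
    expect_lte(s$rwc_after, s$rwc_before)
  }
})

test_that("RWC before/after match hand arithmetic and both ledger paths agree", {
  rec <- centrifuge_record("p1", "s", "intact", saturated_weight = 2.0,
                           forces = c(17, 66), released = c(0.3, 0.3),
                           dry_weight = 0.2)
  expect_equal(rwc_before_after(rec),
               c(rwc_before = 900, rwc_after = 600))
  # measured post-spin weight consistent with the ledger: same answer
  rec2 <- centrifuge_record("p1", "s", "intact", 2.0, c(17, 66), c(0.3, 0.3),
                            dry_weight = 0.2, post_spin_weight = 1.4)
  expect_equal(rwc_before_after(rec2), rwc_before_after(rec))
  # alternative normalisation relative to the initial weight
  alt <- rwc_before_after(rec, normalise = "initial_weight")
  expect_equal(unname(alt), c(90, 60))
})

test_that("inconsistent ledgers fail loudly", {
  rec <- centrifuge_record("p1", "s", "intact", saturated_weight = 1.0,
                           forces = c(17, 66), released = c(0.5, 0.45),
                           dry_weight = 0.2)
  expect_error(rwc_before_after(rec), "inconsistent ledger")
  rec2 <- centrifuge_record("p1", "s", "intact", 2.0, 17, 0.3,
                            dry_weight = 0.2, post_spin_weight = 1.0)
  expect_error(rwc_before_after(rec2), "disagrees")
})

test_that("constructor rejects malformed records", {
  expect_error(centrifuge_record("p", "s", "intact", 1, c(17, 17), c(0, 0), 0.1),
               "strictly increasing")
  expect_error(centrifuge_record("p", "s", "intact", 1, 17, -0.1, 0.1), ">= 0")
  expect_error(centrifuge_record("p", "s", "intact", 0.05, 17, 0, 0.1),
               "saturated_weight")
  expect_error(centrifuge_record("p", "s", "bad_treatment", 1, 17, 0, 0.1))
})

## -------------------------------------------------------- statistical gate

test_that("exact rank-sum p matches full enumeration and base-R oracle", {
  # hand case: all 20 assignments, the observed split is one extreme
  cg <- compare_groups(c(1, 2, 3), c(4, 5, 6), method = "wilcoxon",
                       remove_outliers = FALSE)
  expect_equal(cg$p_value, 0.1)
  expect_true(cg$exact)
  # elementwise-identical samples: p = 1 under exact rank-sum
  cg1 <- compare_groups(c(1, 2, 3), c(1, 2, 3), method = "wilcoxon",
                        remove_outliers = FALSE)
  expect_equal(cg1$p_value, 1)
  # tie-free random samples up to n = 8 per group: match wilcox.test exact
  set.seed(31)
  for (i in 1:40) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    a <- round(rnorm(na), 6); b <- round(rnorm(nb, 0.5), 6)
    ours <- compare_groups(a, b, method = "wilcoxon", remove_outliers = FALSE)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("the gate picks Welch t for normal data and rank-sum otherwise", {
  set.seed(5)
  a <- rnorm(12); b <- rnorm(12)
  cg <- compare_groups(a, b)
  expect_identical(cg$statistic_name, "t")
  expect_equal(cg$p_value, t.test(a, b)$p.value)
  # grossly skewed data fails Shapiro-Wilk and falls through to rank-sum
  x <- exp(rnorm(15, sd = 2)); y <- exp(rnorm(15, sd = 2)) * 3
  cg2 <- compare_groups(x, y)
  expect_identical(cg2$statistic_name, "wilcoxon_rank_sum")
})

test_that("outlier screening logs removed ids and small groups error", {
  a <- c(1.1, 0.9, 1.0, 1.05, 0.95, 50)   # one gross outlier
  b <- c(1.2, 1.1, 1.15, 1.25, 1.18)
  cg <- compare_groups(a, b, ids_a = paste0("plant", 1:6))
  expect_identical(cg$outliers_removed, "plant6")
  expect_equal(unname(cg$n["a"]), 5L)
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("dry weight and saturated RWC decouple in simulation", {
  # perfectly linear pairs -> r = 1; reversed -> r = -1
  mk_rec <- function(id, dry, rwc) {
    centrifuge_record(id, "s", "intact",
                      saturated_weight = dry * (1 + rwc / 100),
                      forces = 17, released = 0, dry_weight = dry)
  }
  recs <- Map(mk_rec, paste0("p", 1:3), c(0.1, 0.2, 0.3), c(100, 200, 300))
  r <- dryweight_rwc_correlation(recs)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$r_squared, 1)
  recs_rev <- Map(mk_rec, paste0("p", 1:3), c(1, 2, 3), c(300, 200, 100))
  expect_equal(dryweight_rwc_correlation(recs_rev)$pearson_r, -1)
  # zero variance errors
  recs_const <- Map(mk_rec, paste0("p", 1:3), c(0.2, 0.2, 0.2), c(100, 200, 300))
  expect_error(dryweight_rwc_correlation(recs_const), "zero variance")

  # rwc independent of dry weight: p > 0.05 in >= 90% of seeded replicates
  set.seed(1234)
  nonsig <- mean(replicate(300, {
    recs <- Map(mk_rec, paste0("p", 1:10), runif(10, 0.05, 0.4),
                rnorm(10, 1500, 200))
    dryweight_rwc_correlation(recs)$p_value > 0.05
  }))
  expect_gte(nonsig, 0.90)
})

test_that("equal per-gram water pools give equal RWC whatever the dry weight", {
  # water scaled to biomass: storage per unit biomass is unaffected
  per_gram <- c(branch_capillary = 9, interstem = 5, hyaline = 3.5,
                intracellular = 1.5)  # g water per g biomass
  rwcs <- sapply(c(0.05, 0.1, 0.2, 0.4), function(dw) {
    pools <- water_pools(per_gram[1] * dw, per_gram[2] * dw,
                         per_gram[3] * dw, per_gram[4] * dw)
    rec <- simulate_centrifuge_run(pools, dry_weight = dw)
    rwc_before_after(rec)[["rwc_before"]]
  })
  expect_true(all(abs(rwcs - rwcs[1]) < 1e-9))
})

## ----------------------------------------------------- branch contribution

test_that("zeroing a branch pool produces a positive recovered-water effect", {
  mk_group <- function(zero_pools = character(0), treatment, n = 8, seed0 = 0) {
    lapply(seq_len(n), function(i) {
      masses <- c(branch_capillary = 0.9, interstem = 0.5,
                  hyaline = 0.35, intracellular = 0.15)
      masses[zero_pools] <- 0
      pools <- water_pools(masses[1], masses[2], masses[3], masses[4],
                           noise_sd = 0.01)
      simulate_centrifuge_run(pools, dry_weight = 0.1,
                              plant_id = paste0(treatment, i),
                              treatment = treatment, seed = seed0 + i)
    })
  }
  intact <- mk_group(treatment = "intact", seed0 = 100)
  no_spreading <- mk_group("branch_capillary", "no_spreading", seed0 = 200)
  bc <- branch_contribution(intact, no_spreading, n_boot = 2000, seed = 1)
  expect_gt(bc$effect_g, 0)
  expect_gt(bc$effect_ci_g[1], 0)  # interval excludes zero at this effect size

  # removing every branch structure leaves only noise to recover
  no_branches <- mk_group(c("branch_capillary", "interstem"), "no_branches",
                          seed0 = 300)
  recovered <- vapply(no_branches, function(r) sum(r$released), numeric(1))
  expect_lt(max(recovered), 0.1)  # noise only, against 1.4 g when intact

  # identical groups: effect ~ 0, p ~ 1
  same <- branch_contribution(intact, intact, n_boot = 500, seed = 2)
  expect_equal(same$effect_g, 0)
  expect_gt(same$comparison$p_value, 0.9)
})

test_that("mixed-species contrasts are refused", {
  a <- simulate_centrifuge_run(water_pools(), dry_weight = 0.1, species = "A")
  b <- simulate_centrifuge_run(water_pools(), dry_weight = 0.1, species = "B")
  expect_error(branch_contribution(list(a), list(b)), "mixed species")
})
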