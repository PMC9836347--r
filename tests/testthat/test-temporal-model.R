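test_that("EM-REML agrees with the balanced ANOVA estimator to 1e-6 relative", {
  for (seed in c(11, 12, 13, 14, 15)) {
    sh <- list(flight = 0.55, rep_in_flight = 0.1,
               genotype_in_flight = 0.15, residual = 0.2)
    b <- balanced_table(sh, f = 4, g = 12, r = 2, seed = seed)
    fa <- fit_nested_model(b$table, "NGRDI", nested_model_spec(estimation = "anova_mom"))
    fe <- fit_nested_model(b$table, "NGRDI", nested_model_spec(estimation = "em_reml"))
    expect_lt(max(abs(fe$components - fa$components_raw) /
                    pmax(fa$components_raw, 1e-12)), 1e-6)
    # BLUPs from the two paths coincide too
    expect_equal(fe$blups, fa$blups, tolerance = 1e-6)
  }
})

test_that("the EM restricted likelihood never decreases across iterations", {
  b <- balanced_table(shares_default, f = 5, g = 15, r = 2, seed = 3)
  fe <- fit_nested_model(b$table, "NGRDI", nested_model_spec(estimation = "em_reml"))
  expect_true(fe$converged)
  expect_true(all(diff(fe$loglik) >= -1e-8 * abs(fe$loglik[-1])))
})

test_that("EM-REML matches lme4 on a balanced fixture", {
  b <- balanced_table(list(flight = 0.6, rep_in_flight = 0.08,
                           genotype_in_flight = 0.12, residual = 0.2),
                      f = 5, g = 15, r = 2, seed = 8)
  fe <- fit_nested_model(b$table, "NGRDI", nested_model_spec(estimation = "em_reml"))
  df <- b$table
  df$fl <- factor(df$flight_day)
  df$fr <- interaction(df$fl, df$rep)
  df$fg <- interaction(df$fl, df$genotype)
  lm4 <- lme4::lmer(value ~ 1 + (1 | fl) + (1 | fr) + (1 | fg), data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lm4))
  ours <- fe$components
  expect_equal(ours[["flight"]], vc$vcov[vc$grp == "fl"], tolerance = 1e-3)
  expect_equal(ours[["rep_in_flight"]], vc$vcov[vc$grp == "fr"], tolerance = 1e-3)
  expect_equal(ours[["genotype_in_flight"]], vc$vcov[vc$grp == "fg"], tolerance = 1e-3)
  expect_equal(ours[["residual"]], vc$vcov[vc$grp == "Residual"], tolerance = 1e-3)
})

test_that("unbalanced tables are handled by EM-REML and refused by ANOVA", {
  b <- balanced_table(shares_default, f = 4, g = 14, r = 2, seed = 5)
  tab <- b$table
  drop_geno <- unique(tab$genotype)[1:3]
  tab <- tab[!(tab$genotype %in% drop_geno & tab$flight_day == tab$flight_day[1]), ]
  expect_error(fit_nested_model(tab, "NGRDI", nested_model_spec(estimation = "anova_mom")),
               "balanced")
  fe <- fit_nested_model(tab, "NGRDI", nested_model_spec(estimation = "em_reml"))
  expect_true(all(fe$components >= 0))
  expect_equal(sum(fe$percentages), 100, tolerance = 1e-6)
  # genotypes unobserved at a flight give NA genotypic values there
  expect_true(all(is.na(fe$blups[drop_geno, 1])))
  expect_true(all(!is.na(fe$blups[drop_geno, -1])))
})

test_that("noiseless replicates give zero residual and unshrunken cell means", {
  sh <- list(flight = 0.9, rep_in_flight = 0, genotype_in_flight = 0.1, residual = 0)
  b <- balanced_table(sh, f = 4, g = 12, r = 2, seed = 6)
  f <- fit_nested_model(b$table, "NGRDI")
  expect_lt(f$components[["residual"]], 1e-10)
  cell <- tapply(b$table$value, list(b$table$genotype, b$table$flight_day), mean)
  expect_equal(f$blups[rownames(cell), colnames(cell)], cell, tolerance = 1e-6)
})

test_that("a null genotype component stays near zero downstream", {
  hits <- 0L
  for (seed in 1:10) {
    cfg <- small_config(
      n_hybrids = 150, n_hybrids_sm = 150, n_parents = 22,
      n_flights_rgb = 10,
      flight_days = as.integer(round(seq(27, 144, length.out = 10))),
      temporal_traits = list(NGRDI = list(mean = 0.3, sd = 0.15)),
      variance_shares = list(flight = 0.9, rep_in_flight = 0.02,
                             genotype_in_flight = 0, residual = 0.08),
      seed = seed)
    tr <- simulate_trial(cfg)
    f <- fit_nested_model(tr$phenomic, "NGRDI", trial = "OM")
    ok_comp <- f$components[["genotype_in_flight"]] <= 0.05 * sum(f$components)
    ok_tr <- temporal_repeatability(f)$tr <= 0.05
    if (ok_comp && ok_tr) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("temporal repeatability follows the entry-mean formula and its bounds", {
  fake <- function(sg, se, n_rep) structure(
    list(components = c(flight = 1, rep_in_flight = 0.1,
                        genotype_in_flight = sg, residual = se),
         n_rep = n_rep), class = "nested_fit")
  expect_equal(temporal_repeatability(fake(0, 2, 2))$tr, 0)
  expect_equal(temporal_repeatability(fake(3, 0, 2))$tr, 1)
  expect_equal(temporal_repeatability(fake(1, 2, 2))$tr, 0.5)
  expect_error(temporal_repeatability(fake(1, 2, 0)), "n_rep")
  for (seed in 1:5) {
    b <- balanced_table(shares_default, f = 3, g = 10, r = 2, seed = seed)
    f <- fit_nested_model(b$table, "NGRDI")
    tr <- temporal_repeatability(f)$tr
    expect_gte(tr, 0); expect_lte(tr, 1)
  }
})

test_that("genotypic values are shrunken toward the flight mean", {
  b <- balanced_table(shares_default, f = 4, g = 15, r = 2, seed = 9)
  f <- fit_nested_model(b$table, "NGRDI")
  gv <- genotypic_values(f)
  cell <- tapply(b$table$value, list(b$table$genotype, b$table$flight_day), mean)
  cell <- cell[rownames(gv), colnames(gv)]
  for (fl in colnames(gv)) {
    raw_dev <- cell[, fl] - mean(cell[, fl])
    blup_dev <- gv[, fl] - mean(gv[, fl])
    expect_true(all(abs(blup_dev) <= abs(raw_dev) + 1e-10))
    expect_true(all(sign(blup_dev) == sign(raw_dev) | raw_dev == 0))
  }
})

test_that("noiseless genotypic values rank exactly like the simulated truth", {
  cfg <- small_config(
    variance_shares = list(flight = 0.9, rep_in_flight = 0.02,
                           genotype_in_flight = 0.08, residual = 0),
    temporal_traits = list(NGRDI = list(mean = 0.3, sd = 0.15)), seed = 10)
  tr <- simulate_trial(cfg)
  f <- fit_nested_model(tr$phenomic, "NGRDI", trial = "OM")
  gv <- genotypic_values(f)
  truth <- tr$truth$temporal_genetic_values[["NGRDI"]]
  for (fl in colnames(gv)) {
    rho <- stats::cor(gv[, fl], truth[rownames(gv), fl], method = "spearman")
    expect_equal(rho, 1)
  }
})

test_that("zero genotype variance collapses genotypic values to the flight mean", {
  cfg <- small_config(
    variance_shares = list(flight = 0.9, rep_in_flight = 0.02,
                           genotype_in_flight = 0, residual = 0.08),
    temporal_traits = list(NGRDI = list(mean = 0.3, sd = 0.15)), seed = 11)
  tr <- simulate_trial(cfg)
  f <- fit_nested_model(tr$phenomic, "NGRDI", trial = "OM",
                        spec = nested_model_spec(estimation = "em_reml"))
  # the genotype component is estimated at (near) zero, so rows coincide
  if (f$components[["genotype_in_flight"]] == 0) {
    expect_equal(f$blups[1, ], f$blups[2, ])
  } else {
    expect_lt(stats::sd(f$blups[, 1]), 0.02 * stats::sd(tr$phenomic$value))
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  b <- balanced_table(shares_default, f = 3, g = 8, r = 2, seed = 12)
  expect_error(fit_nested_model(b$table, "NOPE"), "absent")
  one_flight <- b$table[b$table$flight_day == b$table$flight_day[1], ]
  expect_error(fit_nested_model(one_flight, "NGRDI"), "[Ss]ingle flight")
  both <- b$trial$phenomic
  expect_error(fit_nested_model(both, "NGRDI"), "trial")
  expect_error(variance_percentages(c(flight = 0, residual = 0)), "zero")
  expect_equal(unname(variance_percentages(c(a = 4, b = 3, c = 2, d = 1))),
               c(40, 30, 20, 10))
})
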