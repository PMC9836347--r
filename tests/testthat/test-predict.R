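genos <- function(n) sprintf("H%03d", seq_len(n))

test_that("split plans partition the genotype set with the floor rule", {
  p <- make_split_plan(genos(10), 0.7, n_iter = 20, seed = 2)
  for (it in p$iterations) {
    expect_length(it$train, 7)
    expect_length(it$test, 3)
    expect_length(intersect(it$train, it$test), 0)
    expect_setequal(c(it$train, it$test), genos(10))
  }
  # identical inputs -> identical plans (and fingerprints)
  p2 <- make_split_plan(genos(10), 0.7, n_iter = 20, seed = 2)
  expect_identical(p$iterations, p2$iterations)
  expect_identical(p$fingerprint, p2$fingerprint)
  p3 <- make_split_plan(genos(10), 0.7, n_iter = 20, seed = 3)
  expect_false(identical(p$fingerprint, p3$fingerprint))
  # floor(0.7 * 118) = 82
  p118 <- make_split_plan(genos(118), 0.7, n_iter = 3, seed = 1)
  expect_length(p118$iterations[[1]]$train, 82)
  expect_length(p118$iterations[[1]]$test, 36)
  expect_error(make_split_plan(genos(3), 0.05, 5, 1), "degenerate")
})

test_that("ridge at the penalty limits reduces to OLS and the training mean", {
  set.seed(8)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- X %*% c(1, -2, 0.5, 0, 3) + rnorm(40, 0, 0.2)
  f0 <- fit_phenomic_model(model_spec("ridge", lambda = 0), X, y)
  ols <- stats::lm.fit(cbind(1, scale(X)), y)$coefficients
  expect_equal(unname(f0$fit$beta), unname(ols[-1]), tolerance = 1e-8)
  finf <- fit_phenomic_model(model_spec("ridge", lambda = 1e12), X, y)
  expect_equal(unname(stats::predict(finf, X)), rep(mean(y), 40), tolerance = 1e-6)
})

test_that("ridge with a fixed penalty matches the normal-equations solution", {
  set.seed(9)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- as.numeric(X %*% rnorm(5) + rnorm(40))
  lam <- 3.7
  f <- fit_phenomic_model(model_spec("ridge", lambda = lam), X, y)
  Xs <- scale(X)
  beta_ne <- solve(crossprod(Xs) + diag(lam, 5), crossprod(Xs, y - mean(y)))
  expect_equal(unname(f$fit$beta), unname(beta_ne[, 1]), tolerance = 1e-8)
})

test_that("penalized and forest families fit, tune and stay deterministic", {
  set.seed(10)
  X <- matrix(rnorm(60 * 12), 60, 12)
  y <- as.numeric(X[, 1] - 2 * X[, 2] + rnorm(60, 0, 0.5))
  for (fam in c("ridge", "lasso", "elasticnet", "randomforest")) {
    f1 <- fit_phenomic_model(model_spec(fam), X, y)
    f2 <- fit_phenomic_model(model_spec(fam), X, y)
    expect_equal(stats::predict(f1, X[1:5, ]), stats::predict(f2, X[1:5, ]),
                 label = fam)
  }
  # standardization uses training statistics only
  f <- fit_phenomic_model(model_spec("ridge"), X[1:40, ], y[1:40])
  expect_equal(unname(f$std$center), unname(colMeans(X[1:40, ])))
  expect_equal(unname(f$std$scale), unname(apply(X[1:40, ], 2, sd)))
  expect_error(fit_phenomic_model(model_spec("lasso"), X, rep(1, 60)), "constant")
})

test_that("the VanRaden kernel matches hand computation and Gram properties", {
  # two genotypes, one marker, dosages 0 and 2, p = 0.5
  M <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "m1"))
  k <- grm_vanraden(M, maf_filter = 0)
  expect_equal(unname(k$grm), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  # duplicated genotypes give identical rows; off-diagonal equals diagonal
  set.seed(11)
  M2 <- matrix(rbinom(20 * 30, 2, 0.4), 20, 30,
               dimnames = list(genos(20), paste0("m", 1:30)))
  M2[2, ] <- M2[1, ]
  k2 <- grm_vanraden(M2, maf_filter = 0)
  expect_equal(k2$grm[1, ], k2$grm[2, ])
  expect_equal(k2$grm[1, 2], k2$grm[1, 1])
  expect_equal(k2$grm, t(k2$grm))
  expect_gte(min(eigen(k2$grm, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_error(grm_vanraden(matrix(2, 4, 3)), "monomorphic")
  # MAF filter excludes with a message
  M3 <- M2; M3[, 1] <- 0; M3[1, 1] <- 1
  expect_message(k3 <- grm_vanraden(M3, maf_filter = 0.05), "excluding 1")
  expect_equal(k3$n_markers, 29)
})

test_that("GBLUP equals the RR-BLUP marker-effect formulation", {
  cfg <- small_config(seed = 12)
  mk <- simulate_marker_panel(cfg)
  k <- grm_vanraden(mk, maf_filter = 0)
  ids <- rownames(mk$dosages)
  set.seed(12)
  y <- stats::setNames(rnorm(length(ids)), ids)
  trn <- ids[1:16]; tst <- ids[17:24]
  lam <- 0.8
  p_g <- gblup_predict(k, y[trn], trn, tst, lambda = lam)
  # independent marker-space route
  p_freq <- colMeans(mk$dosages) / 2
  Z <- sweep(mk$dosages, 2, 2 * p_freq)
  keep <- p_freq > 0 & p_freq < 1
  Z <- Z[, keep]
  m <- solve(crossprod(Z[trn, ]) + diag(lam * k$denom, ncol(Z)),
             crossprod(Z[trn, ], y[trn] - mean(y[trn])))
  p_m <- as.numeric(Z[tst, ] %*% m) + mean(y[trn])
  expect_equal(unname(p_g), p_m, tolerance = 1e-8)
})

test_that("GBLUP limits: infinite shrinkage and perfect-information duplicates", {
  # enough parents that the training kernel block is full rank (hybrid rows
  # span at most n_parents - 1 dimensions)
  cfg <- small_config(n_parents = 30, seed = 13)
  mk <- simulate_marker_panel(cfg)
  k <- grm_vanraden(mk, maf_filter = 0)
  ids <- rownames(mk$dosages)
  set.seed(13)
  y <- stats::setNames(rnorm(length(ids)), ids)
  trn <- ids[1:16]; tst <- ids[17:24]
  p_inf <- gblup_predict(k, y[trn], trn, tst, lambda = 1e12)
  expect_equal(unname(p_inf), rep(mean(y[trn]), 8), tolerance = 1e-6)
  # heritability-1 trait, test genotype duplicated inside the training set
  dup <- mk$dosages
  dup <- rbind(dup, COPY = dup["H001", ])
  kd <- grm_vanraden(dup, maf_filter = 0)
  beta <- rnorm(ncol(dup))
  g <- as.numeric(scale(dup, scale = FALSE) %*% beta)
  names(g) <- rownames(dup)
  trn2 <- c(ids[2:20], "COPY")
  p <- gblup_predict(kd, g[trn2], trn2, "H001", lambda = 1e-8)
  expect_equal(unname(p), unname(g["COPY"]), tolerance = 1e-6)
})

test_that("prediction metrics match their definitions", {
  m <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m), c(accuracy = 1, rmse = 0, mae = 0, r2 = 1))
  expect_equal(evaluate_predictions(c(1, 2, 3), c(-1, -2, -3))$accuracy, -1)
  m2 <- evaluate_predictions(c(1, 2, 3), c(2, 2, 5))
  expect_equal(m2$accuracy, 0.866, tolerance = 1e-3)
  expect_equal(m2$rmse, sqrt(5 / 3))
  expect_equal(m2$mae, 1)
  expect_error(evaluate_predictions(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(evaluate_predictions(1:2, 1:2), "3 pairs")
  expect_error(evaluate_predictions(1:4, 1:3), "length")
})

test_that("CV1 with an unpenalized interpolating model is a perfect overfit", {
  set.seed(14)
  n <- 20
  ids <- genos(n)
  X <- matrix(rnorm(n * 30), n, 30, dimnames = list(ids, NULL))
  class(X) <- c("feature_matrix", "matrix", "array")
  y <- stats::setNames(rnorm(n), ids)
  plan <- make_split_plan(ids, 0.7, n_iter = 10, seed = 4)
  res <- run_cv_scheme("CV1", model_spec("linear"), X, y, plan = plan, trait = "GY")
  expect_equal(res$records$accuracy, rep(1, 10), tolerance = 1e-6)
})

test_that("held-out schemes never leak test genotypes into training", {
  set.seed(15)
  n <- 24; ids <- genos(n)
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(ids, NULL))
  class(X) <- c("feature_matrix", "matrix", "array")
  y_om <- stats::setNames(rnorm(n), ids)
  y_sm <- stats::setNames(rnorm(n), ids)
  plan <- make_split_plan(ids, 0.7, n_iter = 25, seed = 5)
  for (it in plan$iterations)
    expect_length(intersect(it$train, it$test), 0)
  # CV2 and CV4 observed values come from held-out genotypes only; poisoning
  # the training trait values of the test set must not move the fit
  res <- run_cv_scheme("CV4", model_spec("ridge", lambda = 1),
                       X, y_om, y_sm, plan, trait = "GY")
  expect_equal(nrow(res$records), 25)
  expect_true(all(abs(res$records$accuracy) <= 1))
})

test_that("schemes needing the stressed trial fail without it", {
  n <- 12; ids <- genos(n)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(ids, NULL))
  class(X) <- c("feature_matrix", "matrix", "array")
  y <- stats::setNames(rnorm(n), ids)
  plan <- make_split_plan(ids, 0.7, n_iter = 2, seed = 6)
  expect_error(run_cv_scheme("CV3", model_spec("ridge", lambda = 1), X, y,
                             plan = plan), "traits_sm")
})

test_that("ridge CV2 matches an independently coded end-to-end reimplementation", {
  set.seed(16)
  n <- 40; p <- 20; ids <- genos(n)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(ids, NULL))
  y <- stats::setNames(as.numeric(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.7)), ids)
  Xf <- X; class(Xf) <- c("feature_matrix", "matrix", "array")
  lam <- 5
  plan <- make_split_plan(ids, 0.7, n_iter = 100, seed = 7)
  res <- run_cv_scheme("CV2", model_spec("ridge", lambda = lam), Xf, y,
                       plan = plan, trait = "GY")
  # independent loop: standardize on train, solve normal equations, correlate
  acc <- vapply(plan$iterations, function(it) {
    Xtr <- X[it$train, ]; ctr <- colMeans(Xtr); scl <- apply(Xtr, 2, sd)
    Xs <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")
    b <- solve(crossprod(Xs) + diag(lam, p), crossprod(Xs, y[it$train] - mean(y[it$train])))
    Xte <- sweep(sweep(X[it$test, ], 2, ctr), 2, scl, "/")
    pred <- as.numeric(Xte %*% b) + mean(y[it$train])
    cor(pred, y[it$test])
  }, numeric(1))
  expect_lt(abs(mean(acc) - res$summary$mean_accuracy), 0.02)
})

test_that("method comparison enforces the shared-plan contract", {
  set.seed(17)
  n <- 20; ids <- genos(n)
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(ids, NULL))
  class(X) <- c("feature_matrix", "matrix", "array")
  y <- stats::setNames(as.numeric(X[, 1] + rnorm(n, 0, 0.5)), ids)
  plan <- make_split_plan(ids, 0.7, n_iter = 15, seed = 8)
  r1 <- run_cv_scheme("CV2", model_spec("ridge", lambda = 2), X, y, plan = plan)
  cmp <- compare_methods(list(r1, r1))
  expect_equal(cmp$pairs$mean_diff, 0)
  expect_equal(cmp$pairs$lower, 0)
  expect_equal(cmp$pairs$upper, 0)
  plan_b <- make_split_plan(ids, 0.7, n_iter = 15, seed = 9)
  r2 <- run_cv_scheme("CV2", model_spec("ridge", lambda = 2), X, y, plan = plan_b)
  expect_error(compare_methods(list(r1, r2)), "different split plans")
})

test_that("per-timepoint genomic prediction profiles flights by genetic content", {
  cfg <- small_config(
    n_hybrids = 80, n_hybrids_sm = 60, n_parents = 16, n_markers = 150,
    n_flights_rgb = 3, flight_days = c(50L, 85L, 120L),
    temporal_traits = list(NGRDI = list(mean = 0.3, sd = 0.15)),
    variance_shares = list(flight = 0.88, rep_in_flight = 0.02,
                           genotype_in_flight = 0.04, residual = 0.06),
    flight_genetic_weights = c(0.25, 1, 2),  # shares 0.01, 0.04, 0.08
    seed = 18)
  deltas <- replicate(10, {
    cfg$seed <- cfg$seed + 1
    tr <- simulate_trial(cfg)
    fit <- fit_nested_model(tr$phenomic, "NGRDI", trial = "OM")
    k <- grm_vanraden(tr$markers, maf_filter = 0)
    plan <- make_split_plan(rownames(k$grm), 0.7, n_iter = 15, seed = cfg$seed)
    pt <- per_timepoint_gp(k, list(NGRDI = fit$blups), plan)
    pt$mean_accuracy
  })
  expect_equal(dim(deltas), c(3, 10))
  avg <- rowMeans(deltas)
  expect_true(all(diff(avg) > 0))
})

test_that("a zero-genetic flight predicts inside the permutation null band", {
  cfg <- small_config(
    n_hybrids = 60, n_hybrids_sm = 50, n_parents = 14, n_markers = 120,
    n_flights_rgb = 2, flight_days = c(60L, 100L),
    temporal_traits = list(NGRDI = list(mean = 0.3, sd = 0.15)),
    variance_shares = list(flight = 0.9, rep_in_flight = 0.02,
                           genotype_in_flight = 0, residual = 0.08),
    seed = 19)
  tr <- simulate_trial(cfg)
  fit <- fit_nested_model(tr$phenomic, "NGRDI", trial = "OM")
  k <- grm_vanraden(tr$markers, maf_filter = 0)
  plan <- make_split_plan(rownames(k$grm), 0.7, n_iter = 20, seed = 3)
  pt <- per_timepoint_gp(k, list(NGRDI = fit$blups), plan, lambda = 1)
  # permutation null for the mean accuracy at the first flight
  y <- fit$blups[plan$genotypes, 1]
  set.seed(20)
  null_means <- replicate(99, {
    yp <- stats::setNames(sample(y), names(y))
    mean(vapply(plan$iterations[1:10], function(it) {
      stats::cor(gblup_predict(k, yp[it$train], it$train, it$test, lambda = 1),
                 yp[it$test])
    }, numeric(1)))
  })
  band <- stats::quantile(null_means, c(0.025, 0.975))
  expect_gte(pt$mean_accuracy[1], band[1])
  expect_lte(pt$mean_accuracy[1], band[2])
})

test_that("genomic CV2 accuracy respects the heritability ceiling", {
  accs <- vapply(1:5, function(s) {
    cfg <- small_config(
      n_hybrids = 100, n_hybrids_sm = 80, n_parents = 18, n_markers = 200,
      n_flights_rgb = 2, flight_days = c(60L, 100L),
      temporal_traits = list(NGRDI = list(mean = 0.3, sd = 0.15)),
      trait_h2 = c(GY = 0.5, DTA = 0.8, DTS = 0.8, PHT = 0.7), seed = 100 + s)
    tr <- simulate_trial(cfg)
    k <- grm_vanraden(tr$markers, maf_filter = 0)
    y <- stats::setNames(tr$traits$OM$GY, tr$traits$OM$genotype)
    plan <- make_split_plan(names(y), 0.7, n_iter = 30, seed = s)
    run_cv_scheme("CV2", model_spec("gblup"), k, y, plan = plan)$summary$mean_accuracy
  }, numeric(1))
  expect_lte(mean(accs), sqrt(0.5) + 0.05)
})
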