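#' Make a shared cross-validation split plan
#'
#' Draws \code{n_iter} independent 70/30-style partitions of the genotype
#' set (train size \code{floor(train_frac * n)}). The same plan object must
#' be consumed by every method that is to be compared — per-iteration
#' accuracies are then directly comparable — and [compare_methods()] enforces
#' this through a fingerprint of the full plan.
#'
#' @param genotypes character vector of genotype ids (n >= 3).
#' @param train_frac fraction trained on, in (0, 1); default 0.7.
#' @param n_iter number of partitions; default 500.
#' @param seed RNG seed; identical inputs give identical plans.
#' @return class \code{"split_plan"}: \code{iterations} (list of
#'   \code{train}/\code{test} id sets), \code{fingerprint}.
#' @export
make_split_plan <- function(genotypes, train_frac = 0.7, n_iter = 500, seed = 1) {
  genotypes <- as.character(genotypes)
  n <- length(genotypes)
  if (n < 3) stop_("need at least 3 genotypes")
  if (anyDuplicated(genotypes)) stop_("genotype ids must be unique")
  if (train_frac <= 0 || train_frac >= 1) stop_("train_frac must be in (0, 1)")
  n_train <- floor(train_frac * n)
  if (n_train < 1 || n_train >= n)
    stop_("train/test split degenerate: %d train of %d after flooring", n_train, n)
  iterations <- with_seed(seed, {
    lapply(seq_len(n_iter), function(i) {
      tr <- sort(sample.int(n, n_train))
      list(train = genotypes[tr], test = genotypes[-tr])
    })
  })
  plan <- list(genotypes = genotypes, train_frac = train_frac,
               n_iter = as.integer(n_iter), seed = seed,
               iterations = iterations)
  plan$fingerprint <- plan_fingerprint(plan)
  structure(plan, class = "split_plan")
}

# canonicalized so that a JSON round-trip hashes identically
plan_fingerprint <- function(plan) {
  object_fingerprint(list(genotypes = as.character(plan$genotypes),
                          train_frac = as.numeric(plan$train_frac),
                          n_iter = as.integer(plan$n_iter),
                          seed = as.numeric(plan$seed),
                          iterations = plan$iterations))
}

#' @exportS3Method base::print
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d genotypes, %d iterations, train_frac %.2f, seed %s, fingerprint %s\n",
              length(x$genotypes), x$n_iter, x$train_frac, format(x$seed), x$fingerprint))
  invisible(x)
}

#' Cross-validation scheme descriptor
#'
#' The four schemes cross tested/untested genotypes with tested/untested
#' environments. Training always happens on the training genotypes in the
#' optimal-management (OM) trial; prediction targets are CV1 = training
#' genotypes in OM (resubstitution, the overfitting control), CV2 = held-out
#' genotypes in OM, CV3 = training genotypes in the stressed (SM) trial,
#' CV4 = held-out genotypes in SM.
#'
#' @param id one of "CV1", "CV2", "CV3", "CV4".
#' @export
cv_scheme <- function(id = c("CV1", "CV2", "CV3", "CV4")) {
  id <- match.arg(id)
  def <- list(CV1 = list(test_env = "OM", test_genotypes = "trained"),
              CV2 = list(test_env = "OM", test_genotypes = "held_out"),
              CV3 = list(test_env = "SM", test_genotypes = "trained"),
              CV4 = list(test_env = "SM", test_genotypes = "held_out"))[[id]]
  structure(c(list(id = id), def, train_env = "OM"), class = "cv_scheme")
}

#' Model specification for phenomic/genomic prediction
#'
#' @param family one of \code{"linear"}, \code{"ridge"}, \code{"lasso"},
#'   \code{"elasticnet"}, \code{"randomforest"}, \code{"gblup"}.
#' @param penalty_grid penalties tuned over by inner CV (penalized
#'   families); default 25 log-spaced values over 1e-4..1e4.
#' @param l1_ratio_grid elastic-net mixing grid.
#' @param num_trees,mtry,min_node random-forest hyperparameters (defaults
#'   500 trees, p/3 features per split, leaf size 5).
#' @param inner_folds inner CV folds used for penalty tuning on the training
#'   rows only.
#' @param tune_seed seed for inner-fold assignment and the forest.
#' @param lambda fixed variance ratio for gblup (NULL = REML per fit) or a
#'   fixed penalty for ridge (NULL = tune).
#' @export
model_spec <- function(family = c("linear", "ridge", "lasso", "elasticnet",
                                  "randomforest", "gblup"),
                       penalty_grid = 10^seq(-4, 4, length.out = 25),
                       l1_ratio_grid = seq(0.1, 0.9, by = 0.1),
                       num_trees = 500, mtry = NULL, min_node = 5,
                       inner_folds = 5, tune_seed = 11, lambda = NULL) {
  family <- match.arg(family)
  if (family %in% c("ridge", "lasso", "elasticnet") && length(penalty_grid) == 0)
    stop_("penalty_grid must be non-empty for %s", family)
  if (family == "elasticnet" && length(l1_ratio_grid) == 0)
    stop_("l1_ratio_grid must be non-empty for elasticnet")
  structure(list(family = family, penalty_grid = sort(penalty_grid),
                 l1_ratio_grid = l1_ratio_grid, num_trees = num_trees,
                 mtry = mtry, min_node = min_node, inner_folds = inner_folds,
                 tune_seed = tune_seed, lambda = lambda),
            class = "model_spec")
}

# ---- standardization (training statistics only) -----------------------------

.std_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < .Machine$double.eps] <- 1
  list(center = ctr, scale = scl)
}
.std_apply <- function(X, st) sweep(sweep(X, 2, st$center), 2, st$scale, "/")

# exact ridge solution by SVD of the standardized design (centered response):
# beta = V diag(d / (d^2 + lambda)) U' yc
.ridge_solve <- function(Xs, yc, lambda) {
  sv <- svd(Xs)
  keep <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[keep]
  shrink <- d / (d^2 + lambda)
  as.numeric(sv$v[, keep, drop = FALSE] %*% (shrink * crossprod(sv$u[, keep, drop = FALSE], yc)))
}

.make_folds <- function(n, k, seed) {
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

.tune_ridge <- function(Xs, yc, grid, k, seed) {
  folds <- .make_folds(nrow(Xs), k, seed)
  mse <- numeric(length(grid))
  for (fold in seq_len(k)) {
    tr <- folds != fold
    sv <- svd(Xs[tr, , drop = FALSE])
    keep <- sv$d > max(sv$d) * 1e-12
    d <- sv$d[keep]
    uty <- crossprod(sv$u[, keep, drop = FALSE], yc[tr])
    V <- sv$v[, keep, drop = FALSE]
    Xte <- Xs[!tr, , drop = FALSE]
    yte <- yc[!tr]
    for (j in seq_along(grid)) {
      b <- V %*% ((d / (d^2 + grid[j])) * uty)
      mse[j] <- mse[j] + sum((yte - Xte %*% b)^2)
    }
  }
  grid[which.min(mse)]
}

#' Fit a phenomic prediction model
#'
#' Standardizes features with training means/SDs (stored for transforming
#' test rows), tunes penalized families by inner k-fold CV on the training
#' rows only, and returns a predictor that is a pure function of new feature
#' rows. Ridge is solved exactly by SVD; lasso and elastic net use
#' coordinate descent (glmnet) over the penalty grid; the unpenalized linear
#' family uses the minimum-norm least-squares solution (so it interpolates
#' when p >= n); random forests use 500 seeded trees by default.
#'
#' @param spec a [model_spec()] (any family except gblup).
#' @param X training feature rows (matrix, no missing values).
#' @param y training trait values.
#' @return class \code{"phenomic_model"} with a [predict()] method.
#' @export
fit_phenomic_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family == "gblup")
    stop_("gblup is fitted by gblup_predict()/run_cv_scheme(), not here")
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop_("missing values not allowed")
  if (nrow(X) < 2) stop_("need at least 2 training rows")
  if (length(y) != nrow(X)) stop_("y length must match rows of X")
  if (spec$family %in% c("ridge", "lasso", "elasticnet") && stats::sd(y) == 0)
    stop_("constant response: penalty tuning undefined for %s", spec$family)
  st <- .std_fit(X)
  Xs <- .std_apply(X, st)
  b0 <- mean(y)
  yc <- y - b0
  fitobj <- switch(spec$family,
    linear = {
      # minimum-norm OLS via pseudoinverse of [1 | Xs]
      A <- cbind(1, Xs)
      sv <- svd(A)
      keep <- sv$d > max(sv$d) * 1e-10
      coefs <- sv$v[, keep, drop = FALSE] %*%
        ((1 / sv$d[keep]) * crossprod(sv$u[, keep, drop = FALSE], y))
      list(intercept = coefs[1], beta = coefs[-1])
    },
    ridge = {
      lam <- spec$lambda %||%
        .tune_ridge(Xs, yc, spec$penalty_grid, min(spec$inner_folds, nrow(Xs)), spec$tune_seed)
      list(intercept = b0, beta = .ridge_solve(Xs, yc, lam), lambda = lam)
    },
    lasso = ,
    elasticnet = {
      alphas <- if (spec$family == "lasso") 1 else spec$l1_ratio_grid
      folds <- .make_folds(nrow(Xs), min(spec$inner_folds, nrow(Xs)), spec$tune_seed)
      # glmnet's lambda is on the 1/(2n) loss scale; tune on the given grid
      grid <- sort(spec$penalty_grid / nrow(Xs), decreasing = TRUE)
      best <- NULL; best_mse <- Inf
      for (a in alphas) {
        cv <- glmnet::cv.glmnet(Xs, yc, alpha = a, lambda = grid,
                                foldid = folds, standardize = FALSE,
                                intercept = FALSE)
        m <- min(cv$cvm)
        if (m < best_mse) { best_mse <- m; best <- list(alpha = a, cv = cv) }
      }
      beta <- as.numeric(stats::coef(best$cv, s = "lambda.min"))[-1]
      list(intercept = b0, beta = beta, lambda = best$cv$lambda.min * nrow(Xs),
           alpha = best$alpha)
    },
    randomforest = {
      p <- ncol(Xs)
      df <- as.data.frame(Xs)
      names(df) <- paste0("f", seq_len(p))
      rf <- ranger::ranger(
        y = y, x = df, num.trees = spec$num_trees,
        mtry = spec$mtry %||% max(1L, floor(p / 3)),
        min.node.size = spec$min_node, seed = spec$tune_seed,
        num.threads = 1)
      list(rf = rf)
    })
  structure(list(spec = spec, std = st, fit = fitobj, family = spec$family),
            class = "phenomic_model")
}

#' @rdname fit_phenomic_model
#' @param object fitted model.
#' @param newdata feature rows to predict.
#' @param ... unused.
#' @export
predict.phenomic_model <- function(object, newdata, ...) {
  Xs <- .std_apply(as.matrix(newdata), object$std)
  f <- object$fit
  if (object$family == "randomforest") {
    df <- as.data.frame(Xs)
    names(df) <- paste0("f", seq_len(ncol(Xs)))
    return(stats::predict(f$rf, data = df, num.threads = 1)$predictions)
  }
  as.numeric(f$intercept + Xs %*% f$beta)
}

# ---- genomic kernel and GBLUP -----------------------------------------------

#' VanRaden genomic relationship matrix
#'
#' Method-1 GRM: dosages centered by twice the observed allele frequency,
#' \eqn{G = ZZ' / (2\sum_m p_m(1-p_m))}. Monomorphic markers and markers
#' below the MAF filter are excluded with a message.
#'
#' @param markers a \code{marker_set} or genotype x marker dosage matrix
#'   (0/1/2).
#' @param maf_filter minimum minor-allele frequency retained.
#' @return class \code{"genomic_kernel"}: \code{grm}, \code{allele_freqs},
#'   \code{n_markers}, \code{denom}.
#' @export
grm_vanraden <- function(markers, maf_filter = 0.025) {
  X <- if (inherits(markers, "marker_set")) markers$dosages else as.matrix(markers)
  p <- colMeans(X) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf > 0 & maf >= maf_filter
  if (!any(keep)) stop_("all markers monomorphic or below the MAF filter")
  if (any(!keep))
    message(sprintf("excluding %d monomorphic/low-MAF markers", sum(!keep)))
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  Z <- sweep(X, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  structure(list(grm = G, allele_freqs = p, n_markers = ncol(X), denom = denom),
            class = "genomic_kernel")
}

#' @exportS3Method base::print
print.genomic_kernel <- function(x, ...) {
  cat(sprintf("<genomic_kernel> %d genotypes, %d markers\n", nrow(x$grm), x$n_markers))
  invisible(x)
}

# profiled REML for y = 1*mu + g + e with g ~ N(0, sg2 * G); returns
# lambda = se2/sg2, maximized over log-lambda in the eigenspace of G_tt
.reml_lambda <- function(G_tt, y) {
  eg <- eigen(G_tt, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  z <- crossprod(eg$vectors, y)[, 1]
  x1 <- crossprod(eg$vectors, rep(1, length(y)))[, 1]
  n <- length(y)
  neg2ll <- function(loglam) {
    w <- d + exp(loglam)
    sxx <- sum(x1^2 / w)
    mu <- sum(x1 * z / w) / sxx
    rss <- sum((z - x1 * mu)^2 / w)
    sg2 <- rss / (n - 1)
    (n - 1) * log(sg2) + sum(log(w)) + log(sxx)
  }
  opt <- stats::optimize(neg2ll, interval = c(-12, 12))
  exp(opt$minimum)
}

#' GBLUP prediction
#'
#' \deqn{\hat u_{test} = G_{test,train} (G_{train,train} + \lambda I)^{-1}
#'   (y_{train} - \bar y) + \bar y,}
#' with the variance ratio \eqn{\lambda = \sigma^2_e/\sigma^2_g} estimated by
#' restricted maximum likelihood on the training data (profiled over the
#' eigenspace of the training kernel) unless fixed. Equivalent to RR-BLUP
#' marker-effect ridge with penalty \eqn{\lambda} times the VanRaden
#' denominator.
#'
#' @param kernel a [grm_vanraden()] result.
#' @param y_train named trait values for \code{train_ids} (or unnamed,
#'   positionally matched).
#' @param train_ids,test_ids genotype ids within the kernel; overlap is
#'   allowed (resubstitution schemes).
#' @param lambda fixed ratio; NULL estimates it by REML.
#' @param jitter ridge added to a numerically singular training block before
#'   failing.
#' @return named predictions for \code{test_ids}.
#' @export
gblup_predict <- function(kernel, y_train, train_ids, test_ids, lambda = NULL,
                          jitter = 1e-8) {
  stopifnot(inherits(kernel, "genomic_kernel"))
  ids <- rownames(kernel$grm)
  missing_ids <- setdiff(c(train_ids, test_ids), ids)
  if (length(missing_ids))
    stop_("ids absent from kernel: %s", paste(utils::head(missing_ids, 5), collapse = ", "))
  G_tt <- kernel$grm[train_ids, train_ids]
  G_st <- kernel$grm[test_ids, train_ids, drop = FALSE]
  y <- as.numeric(y_train)
  if (length(y) != length(train_ids)) stop_("y_train must match train_ids")
  lam <- lambda %||% .reml_lambda(G_tt, y)
  ybar <- mean(y)
  A <- G_tt + diag(lam, nrow(G_tt))
  sol <- tryCatch(solve(A, y - ybar), error = function(e) NULL)
  if (is.null(sol)) {
    A <- A + diag(jitter * mean(diag(G_tt)), nrow(G_tt))
    sol <- tryCatch(solve(A, y - ybar), error = function(e)
      stop_("training kernel singular beyond jitter tolerance"))
  }
  stats::setNames(as.numeric(G_st %*% sol) + ybar, test_ids)
}

#' Prediction metrics
#'
#' Accuracy is the Pearson correlation between predicted and observed;
#' RMSE, MAE and R2 use their standard definitions (R2 = 1 - SS_res/SS_tot).
#' Zero variance in either vector makes accuracy undefined and is an
#' explicit error, never a silent zero.
#'
#' @param predicted,observed numeric vectors of equal length >= 3.
#' @return list with \code{accuracy}, \code{rmse}, \code{mae}, \code{r2}.
#' @export
evaluate_predictions <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop_("length mismatch")
  if (length(predicted) < 3) stop_("need at least 3 pairs")
  if (anyNA(predicted) || anyNA(observed)) stop_("missing values not allowed")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    stop_("zero variance in predicted or observed values: accuracy undefined")
  err <- predicted - observed
  list(accuracy = stats::cor(predicted, observed),
       rmse = sqrt(mean(err^2)),
       mae = mean(abs(err)),
       r2 = 1 - sum(err^2) / sum((observed - mean(observed))^2))
}

#' Run one cross-validation scheme for one model and trait
#'
#' Per iteration of the shared plan: fit on the training genotypes' OM data,
#' then predict the scheme's target set — CV1: the training genotypes in OM
#' (resubstitution, the overfitting control); CV2: held-out genotypes in OM;
#' CV3: training genotypes in SM; CV4: held-out genotypes in SM. Phenomic
#' families always use OM-measured features (an untested environment
#' contributes no data at prediction time); observed values come from the
#' target environment's trait table.
#'
#' @param scheme a [cv_scheme()] or scheme id string.
#' @param model a [model_spec()].
#' @param data [assemble_feature_matrix()] result (phenomic families) or
#'   [grm_vanraden()] kernel (gblup).
#' @param traits_om named genotype-level trait values in OM.
#' @param traits_sm same for SM; required by CV3/CV4.
#' @param plan a [make_split_plan()] over genotypes covered by \code{data}
#'   and the trait vectors.
#' @param trait label stored on the result.
#' @return class \code{"prediction_result"}: per-iteration records and the
#'   mean-accuracy summary.
#' @export
run_cv_scheme <- function(scheme, model, data, traits_om, traits_sm = NULL,
                          plan, trait = "trait") {
  if (is.character(scheme)) scheme <- cv_scheme(scheme)
  stopifnot(inherits(scheme, "cv_scheme"), inherits(model, "model_spec"),
            inherits(plan, "split_plan"))
  is_gblup <- model$family == "gblup"
  data_ids <- if (is_gblup) rownames(data$grm) else rownames(data)
  missing_ids <- setdiff(plan$genotypes, data_ids)
  if (length(missing_ids))
    stop_("plan genotypes missing from data: %s",
          paste(utils::head(missing_ids, 5), collapse = ", "))
  if (!all(plan$genotypes %in% names(traits_om)))
    stop_("plan genotypes missing from traits_om")
  if (scheme$test_env == "SM") {
    if (is.null(traits_sm)) stop_("scheme %s tests SM but traits_sm is absent", scheme$id)
    if (!all(plan$genotypes %in% names(traits_sm)))
      stop_("plan genotypes missing from traits_sm")
  }
  recs <- vector("list", plan$n_iter)
  for (i in seq_len(plan$n_iter)) {
    it <- plan$iterations[[i]]
    target <- if (scheme$test_genotypes == "trained") it$train else it$test
    y_obs <- if (scheme$test_env == "OM") traits_om[target] else traits_sm[target]
    if (is_gblup) {
      pred <- gblup_predict(data, traits_om[it$train], it$train, target,
                            lambda = model$lambda)
    } else {
      fit <- fit_phenomic_model(model, data[it$train, , drop = FALSE],
                                traits_om[it$train])
      pred <- stats::predict(fit, data[target, , drop = FALSE])
    }
    m <- evaluate_predictions(as.numeric(pred), as.numeric(y_obs))
    recs[[i]] <- data.frame(iteration = i, scheme = scheme$id,
                            model = model$family, trait = trait,
                            accuracy = m$accuracy, rmse = m$rmse,
                            mae = m$mae, r2 = m$r2)
  }
  records <- do.call(rbind, recs)
  structure(list(records = records,
                 summary = data.frame(scheme = scheme$id, model = model$family,
                                      trait = trait,
                                      mean_accuracy = mean(records$accuracy),
                                      sd_accuracy = stats::sd(records$accuracy),
                                      mean_rmse = mean(records$rmse),
                                      mean_mae = mean(records$mae),
                                      mean_r2 = mean(records$r2)),
                 plan_fingerprint = plan$fingerprint, n_iter = plan$n_iter),
            class = "prediction_result")
}

#' @exportS3Method base::print
print.prediction_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<prediction_result> %s %s %s: mean r = %.3f (sd %.3f, %d iter)\n",
              s$scheme, s$model, s$trait, s$mean_accuracy, s$sd_accuracy, x$n_iter))
  invisible(x)
}

#' Per-timepoint genomic prediction of temporal traits
#'
#' Applies GBLUP to every (trait, flight) column of the genotypic-value
#' matrices under held-out-genotype splits, yielding the trait x flight
#' profile of genomic predictability. Columns with (near) zero variance are
#' recorded missing.
#'
#' @param kernel a [grm_vanraden()] covering the plan genotypes.
#' @param blups named list (by trait) of genotype x flight matrices.
#' @param plan a [make_split_plan()].
#' @param lambda fixed variance ratio, NULL for per-iteration REML.
#' @return data.frame (trait_id, flight_day, mean_accuracy, sd_accuracy,
#'   n_iter).
#' @export
per_timepoint_gp <- function(kernel, blups, plan, lambda = NULL) {
  stopifnot(inherits(kernel, "genomic_kernel"), inherits(plan, "split_plan"))
  out <- list()
  for (tid in names(blups)) {
    m <- blups[[tid]]
    if (!all(plan$genotypes %in% rownames(m)))
      stop_("blup matrix for %s does not cover the plan genotypes", tid)
    for (fl in colnames(m)) {
      y <- m[plan$genotypes, fl]
      if (anyNA(y) || stats::sd(y) < 1e-12) {
        out[[length(out) + 1L]] <- data.frame(
          trait_id = tid, flight_day = as.integer(fl),
          mean_accuracy = NA_real_, sd_accuracy = NA_real_, n_iter = plan$n_iter)
        next
      }
      names(y) <- plan$genotypes
      acc <- vapply(plan$iterations, function(it) {
        pred <- gblup_predict(kernel, y[it$train], it$train, it$test, lambda = lambda)
        stats::cor(pred, y[it$test])
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        trait_id = tid, flight_day = as.integer(fl),
        mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
        n_iter = plan$n_iter)
    }
  }
  do.call(rbind, out)
}

#' Compare prediction methods sharing one split plan
#'
#' Refuses results from different plans (the comparability contract). For
#' each (scheme, trait) group it reports per-model mean accuracy and, for
#' every model pair, the mean paired per-iteration difference with a paired
#' bootstrap percentile interval.
#'
#' @param results list of [run_cv_scheme()] results.
#' @param n_boot bootstrap resamples for the paired interval.
#' @param conf interval coverage.
#' @param seed bootstrap seed.
#' @return class \code{"method_comparison"}: \code{means}, \code{pairs}.
#' @export
compare_methods <- function(results, n_boot = 2000, conf = 0.95, seed = 1) {
  stopifnot(length(results) >= 1)
  fps <- vapply(results, function(r) r$plan_fingerprint, character(1))
  if (length(unique(fps)) != 1)
    stop_("results come from different split plans (fingerprints %s); refusing to compare",
          paste(unique(fps), collapse = " vs "))
  recs <- do.call(rbind, lapply(results, `[[`, "records"))
  means <- stats::aggregate(accuracy ~ scheme + trait + model, recs, mean)
  names(means)[names(means) == "accuracy"] <- "mean_accuracy"
  pairs <- list()
  alpha <- (1 - conf) / 2
  for (grp in split(seq_along(results),
                    vapply(results, function(r)
                      paste(r$summary$scheme, r$summary$trait), character(1)))) {
    if (length(grp) < 1) next
    for (a in seq_along(grp)) for (b in seq_along(grp)) {
      if (b < a || (length(grp) > 1 && a == b)) next
      ra <- results[[grp[a]]]; rb <- results[[grp[b]]]
      da <- ra$records$accuracy; db <- rb$records$accuracy
      diffs <- da - db
      boots <- with_seed(seed, {
        vapply(seq_len(n_boot), function(i)
          mean(diffs[sample.int(length(diffs), replace = TRUE)]), numeric(1))
      })
      pairs[[length(pairs) + 1L]] <- data.frame(
        scheme = ra$summary$scheme, trait = ra$summary$trait,
        model_a = ra$summary$model, model_b = rb$summary$model,
        mean_diff = mean(diffs),
        lower = unname(stats::quantile(boots, alpha)),
        upper = unname(stats::quantile(boots, 1 - alpha)),
        frac_positive = mean(diffs > 0))
    }
  }
  structure(list(means = means,
                 pairs = if (length(pairs)) do.call(rbind, pairs) else NULL),
            class = "method_comparison")
}

#' @exportS3Method base::print
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\nMean accuracy by model:\n")
  print(x$means, row.names = FALSE)
  if (!is.null(x$pairs)) {
    cat("Paired differences (bootstrap interval):\n")
    print(x$pairs, row.names = FALSE)
  }
  invisible(x)
}
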