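#' Area under a temporal curve (trapezoidal rule)
#'
#' Cumulative area under a trait's temporal curve across flights, integrated
#' over the observed span only (no extrapolation toward planting or harvest).
#' Units are value x days.
#'
#' @param times days after planting, strictly increasing, length >= 2.
#' @param values measurements at \code{times}; no missing values.
#' @return scalar integral.
#' @examples
#' auc_trapezoid(c(0, 10, 20), c(1, 1, 1))  # 20
#' @export
auc_trapezoid <- function(times, values) {
  if (length(times) != length(values)) stop_("times and values differ in length")
  if (length(times) < 2) stop_("need at least 2 time points")
  if (anyNA(times) || anyNA(values)) stop_("missing values not allowed")
  if (is.unsorted(times, strictly = TRUE))
    stop_("times must be strictly increasing (no duplicates)")
  pracma::trapz(times, values)
}

#' Evaluate the asymptotic Weibull growth curve
#'
#' \eqn{H(t) = A (1 - \exp(-(t/B)^C))}: height rises sigmoidally from 0 and
#' approaches the asymptote A; B is the characteristic time (days) at which
#' 63.2% of A is reached and C controls steepness. Monotone non-decreasing in
#' t for A, B, C > 0.
#'
#' @param t days after planting.
#' @param A,B,C curve parameters, all > 0.
#' @export
weibull_growth <- function(t, A, B, C) A * (1 - exp(-(t / B)^C))

#' Fit a Weibull growth curve to temporal canopy heights
#'
#' Least-squares fit of \eqn{H(t) = A(1-\exp(-(t/B)^C))} by
#' Levenberg-Marquardt with positivity bounds and a self-starting
#' initialization (A0 = 1.05 x max height, B0 = time at half maximum by
#' linear interpolation, C0 = 2). Jittered restarts are attempted on
#' failure; non-convergence after restarts errors with the best attempt's
#' diagnostics.
#'
#' @param times days after planting, >= 4 points.
#' @param heights canopy heights >= 0.
#' @param n_restarts extra jittered starts tried after a failure.
#' @return class \code{"growth_fit"}: \code{A}, \code{B}, \code{C},
#'   \code{rmse}, \code{n_points}, \code{fitted}.
#' @export
fit_weibull <- function(times, heights, n_restarts = 5) {
  if (length(times) != length(heights)) stop_("times and heights differ in length")
  if (length(times) < 4) stop_("need at least 4 points to fit 3 parameters")
  if (anyNA(times) || anyNA(heights)) stop_("missing values not allowed")
  if (any(heights < 0)) stop_("heights must be non-negative")
  if (max(heights) <= 0)
    stop_("all heights are zero: asymptote A > 0 is infeasible")
  hmax <- max(heights)
  # time at half-max via linear interpolation of the first crossing
  above <- which(heights >= hmax / 2)
  i <- above[1]
  b0 <- if (i == 1) times[1] else {
    t0 <- times[i - 1]; t1 <- times[i]
    h0 <- heights[i - 1]; h1 <- heights[i]
    t0 + (hmax / 2 - h0) / (h1 - h0) * (t1 - t0)
  }
  b0 <- max(b0, min(times[times > 0], 1))
  starts <- list(c(A = 1.05 * hmax, B = b0, C = 2))
  with_seed(derive_seed(1L, "weibull-jitter"), {
    for (j in seq_len(n_restarts))
      starts[[j + 1]] <- c(A = 1.05 * hmax * stats::runif(1, 0.8, 1.3),
                           B = b0 * stats::runif(1, 0.6, 1.6),
                           C = stats::runif(1, 0.8, 5))
  })
  best <- NULL; best_rss <- Inf; errors <- character(0)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(h ~ A * (1 - exp(-(t / B)^C)),
                        data = data.frame(t = times, h = heights),
                        start = as.list(st),
                        lower = c(A = 1e-8, B = 1e-8, C = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) { errors <- c(errors, conditionMessage(fit)); next }
    rss <- sum(stats::resid(fit)^2)
    if (rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best))
    stop_("Weibull fit failed after %d starts; last errors: %s",
          length(starts), paste(utils::tail(unique(errors), 2), collapse = " | "))
  cf <- stats::coef(best)
  structure(list(A = unname(cf["A"]), B = unname(cf["B"]), C = unname(cf["C"]),
                 rmse = sqrt(best_rss / length(times)),
                 n_points = length(times),
                 fitted = as.numeric(stats::fitted(best))),
            class = "growth_fit")
}

#' @exportS3Method base::print
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> A = %.3f, B = %.3f d, C = %.3f (rmse %.4g, n = %d)\n",
              x$A, x$B, x$C, x$rmse, x$n_points))
  invisible(x)
}

#' Assemble a temporal phenomic feature matrix
#'
#' Builds the genotype x feature predictor table: one temporal column per
#' (trait, flight) pair — the convention behind 35 traits x 15 flights = 525
#' features for an RGB platform and 89 x 12 = 1,068 for a multispectral one
#' — plus optional derived columns (per-trait AUC, Weibull A/B/C from canopy
#' heights). Temporal columns are ordered by (trait_id, flight_day); derived
#' columns are appended. Genotypes with any missing cell are dropped with a
#' message, or fail the assembly under \code{strict = TRUE}.
#'
#' @param blup_matrices named list (by trait_id) of genotype x flight
#'   matrices with flight-day column names, e.g. from [genotypic_values()].
#' @param flight_days flights to include; default the columns of the first
#'   matrix. Every trait must cover all of them.
#' @param growth_fits optional named list (by genotype) of [fit_weibull()]
#'   results; adds Weibull_A/B/C columns.
#' @param add_auc append one AUC column per trait (trapezoid over
#'   flight_days).
#' @param platform label stored on the result (\code{"TPP_RGB"} or
#'   \code{"TPP_Multi"}).
#' @param strict fail instead of dropping genotypes with missing cells.
#' @return class \code{"feature_matrix"}: numeric matrix with genotype
#'   rownames and \code{trait@day} column names; attributes \code{platform},
#'   \code{n_temporal}.
#' @export
assemble_feature_matrix <- function(blup_matrices, flight_days = NULL,
                                    growth_fits = NULL, add_auc = FALSE,
                                    platform = "TPP_RGB", strict = FALSE) {
  stopifnot(is.list(blup_matrices), length(blup_matrices) >= 1)
  trait_ids <- sort(names(blup_matrices))
  flight_days <- flight_days %||% as.integer(colnames(blup_matrices[[1]]))
  flight_days <- sort(as.integer(flight_days))
  genos <- rownames(blup_matrices[[1]])
  for (tid in trait_ids) {
    m <- blup_matrices[[tid]]
    missing_fl <- setdiff(as.character(flight_days), colnames(m))
    if (length(missing_fl))
      stop_("trait %s lacks flights: %s", tid, paste(missing_fl, collapse = ", "))
    if (!setequal(rownames(m), genos))
      stop_("trait %s covers a different genotype set", tid)
  }
  cols <- list()
  for (tid in trait_ids) {
    m <- blup_matrices[[tid]][genos, as.character(flight_days), drop = FALSE]
    colnames(m) <- paste0(tid, "@", flight_days)
    cols[[tid]] <- m
  }
  X <- do.call(cbind, cols)
  n_temporal <- ncol(X)
  if (add_auc) {
    for (tid in trait_ids) {
      m <- blup_matrices[[tid]][genos, as.character(flight_days), drop = FALSE]
      ok <- !apply(m, 1, anyNA)
      auc <- rep(NA_real_, length(genos))
      auc[ok] <- apply(m[ok, , drop = FALSE], 1, function(v)
        auc_trapezoid(flight_days, v))
      X <- cbind(X, stats::setNames(data.frame(auc), paste0("AUC_", tid))[[1]])
      colnames(X)[ncol(X)] <- paste0("AUC_", tid)
    }
  }
  if (!is.null(growth_fits)) {
    wb <- t(vapply(genos, function(g) {
      f <- growth_fits[[g]]
      if (is.null(f)) c(NA_real_, NA_real_, NA_real_) else c(f$A, f$B, f$C)
    }, numeric(3)))
    colnames(wb) <- c("Weibull_A", "Weibull_B", "Weibull_C")
    X <- cbind(X, wb)
  }
  rownames(X) <- genos
  bad <- apply(X, 1, anyNA)
  if (any(bad)) {
    if (strict)
      stop_("%d genotypes have missing feature cells (strict mode)", sum(bad))
    message(sprintf("dropping %d genotypes with missing feature cells", sum(bad)))
    X <- X[!bad, , drop = FALSE]
  }
  structure(X, platform = platform, n_temporal = n_temporal,
            class = c("feature_matrix", "matrix", "array"))
}

#' Temporal correlation profile of features against a trait
#'
#' Pearson correlation of every temporal feature column with a genotype-level
#' trait vector, plus each trait's maximum absolute correlation over flights.
#' Zero-variance columns are recorded as missing, not errors.
#'
#' @param features a [assemble_feature_matrix()] result (temporal columns are
#'   recognized by their \code{trait@day} names).
#' @param trait named numeric vector (genotype-level trait values).
#' @return data.frame (trait_id, flight_day, r) with attribute
#'   \code{per_trait_max}.
#' @export
temporal_correlation_profile <- function(features, trait) {
  genos <- intersect(rownames(features), names(trait))
  if (length(genos) < 3) stop_("need >= 3 shared genotypes")
  temporal <- grep("@", colnames(features), value = TRUE)
  X <- features[genos, temporal, drop = FALSE]
  y <- trait[genos]
  r <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  }, numeric(1))
  parts <- strsplit(temporal, "@", fixed = TRUE)
  out <- data.frame(trait_id = vapply(parts, `[`, "", 1),
                    flight_day = as.integer(vapply(parts, `[`, "", 2)),
                    r = r, stringsAsFactors = FALSE)
  mx <- tapply(abs(out$r), out$trait_id, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  attr(out, "per_trait_max") <- mx
  out
}

#' Per-genotype Weibull fits of canopy height trajectories
#'
#' Convenience wrapper fitting [fit_weibull()] to every row of a genotype x
#' flight canopy-height matrix.
#'
#' @param chm_blups genotype x flight matrix (flight-day column names).
#' @return named list of \code{growth_fit} objects (NULL where fitting
#'   failed, with a message).
#' @export
fit_weibull_per_genotype <- function(chm_blups) {
  days <- as.integer(colnames(chm_blups))
  out <- list()
  n_fail <- 0L
  for (g in rownames(chm_blups)) {
    h <- chm_blups[g, ]
    f <- tryCatch(fit_weibull(days, pmax(h, 0)), error = function(e) NULL)
    if (is.null(f)) n_fail <- n_fail + 1L
    out[[g]] <- f
  }
  if (n_fail > 0) message(sprintf("Weibull fit failed for %d genotypes", n_fail))
  out
}
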