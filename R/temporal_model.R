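#' Specification of the flight-nested variance model
#'
#' The model for every temporal trait is
#' \deqn{y = \mu + \beta_i + R_{j(i)} + \Omega_{k(i)} + \varepsilon,}
#' where \eqn{\beta_i} is the drone-flight effect, \eqn{R_{j(i)}} the
#' replicate nested within flight, \eqn{\Omega_{k(i)}} the genotype nested
#' within flight, and all terms are random with the intercept fixed — the
#' decomposition that yields the flight share, the genotype-within-flight
#' share and temporal repeatability.
#'
#' @param terms random terms to fit; \code{flight} and
#'   \code{genotype_in_flight} are required, \code{rep_in_flight} may be
#'   dropped for unreplicated designs.
#' @param estimation \code{"auto"} (balanced ANOVA if the design is balanced,
#'   EM-REML otherwise), \code{"em_reml"}, or \code{"anova_mom"} (refuses
#'   unbalanced input).
#' @param tol EM convergence tolerance: relative change of every variance
#'   component below \code{tol} stops iteration.
#' @param max_iter EM iteration cap.
#' @return class \code{"nested_model_spec"}.
#' @export
nested_model_spec <- function(terms = c("flight", "rep_in_flight", "genotype_in_flight"),
                              estimation = c("auto", "em_reml", "anova_mom"),
                              tol = 1e-8, max_iter = 10000L) {
  estimation <- match.arg(estimation)
  terms <- match.arg(terms, c("flight", "rep_in_flight", "genotype_in_flight"),
                     several.ok = TRUE)
  if (!"genotype_in_flight" %in% terms)
    stop_("genotype_in_flight is required (temporal repeatability needs it)")
  if (!"flight" %in% terms) stop_("flight term is required")
  structure(list(terms = terms, estimation = estimation, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "nested_model_spec")
}

# ---- internal: design bookkeeping -------------------------------------------

.nested_design <- function(df, terms) {
  fl <- factor(df$flight_day)
  design <- list(
    y = df$value,
    flight = fl,
    rep_in_flight = factor(paste(df$flight_day, df$rep, sep = ":")),
    genotype_in_flight = factor(paste(df$flight_day, df$genotype, sep = ":")),
    genotype = factor(df$genotype), terms = terms)
  tab <- table(df$flight_day, df$rep, df$genotype)
  design$balanced <- length(unique(as.vector(tab))) == 1L && all(tab >= 1)
  design$k <- if (design$balanced) as.vector(tab)[1] else NA_integer_
  design$f <- nlevels(fl)
  design$r <- length(unique(df$rep))
  design$g <- nlevels(design$genotype)
  design
}

# balanced ANOVA method-of-moments estimates from expected mean squares
.anova_mom <- function(d) {
  y <- d$y; n <- length(y)
  k <- d$k; f <- d$f; r <- d$r; g <- d$g
  ybar <- mean(y)
  m_f  <- tapply(y, d$flight, mean)
  m_fr <- tapply(y, d$rep_in_flight, mean)
  m_fg <- tapply(y, d$genotype_in_flight, mean)
  fl_of_fr <- sub(":.*", "", names(m_fr))
  fl_of_fg <- sub(":.*", "", names(m_fg))
  ss_f <- k * r * g * sum((m_f - ybar)^2)
  ss_r <- k * g * sum((m_fr - m_f[fl_of_fr])^2)
  ss_g <- k * r * sum((m_fg - m_f[fl_of_fg])^2)
  ss_t <- sum((y - ybar)^2)
  ss_e <- ss_t - ss_f - ss_r - ss_g
  df_f <- f - 1
  df_r <- f * (r - 1)
  df_g <- f * (g - 1)
  df_e <- n - 1 - df_f - df_r - df_g
  ms <- c(flight = ss_f / df_f,
          rep_in_flight = if (df_r > 0) ss_r / df_r else 0,
          genotype_in_flight = ss_g / df_g,
          residual = if (df_e > 0) ss_e / df_e else 0)
  raw <- c(
    flight = (ms["flight"] - ms["rep_in_flight"] - ms["genotype_in_flight"] + ms["residual"]) / (k * r * g),
    rep_in_flight = (ms["rep_in_flight"] - ms["residual"]) / (k * g),
    genotype_in_flight = (ms["genotype_in_flight"] - ms["residual"]) / (k * r),
    residual = ms["residual"])
  names(raw) <- c("flight", "rep_in_flight", "genotype_in_flight", "residual")
  raw
}

# sparse design matrix [X | Z_flight | Z_rep | Z_geno]
.nested_mme_parts <- function(d, terms) {
  n <- length(d$y)
  blocks <- list(Matrix::sparseMatrix(i = seq_len(n), j = rep(1L, n), x = 1,
                                      dims = c(n, 1)))
  sizes <- c(fixed = 1L)
  for (tm in terms) {
    fct <- d[[tm]]
    blocks[[length(blocks) + 1L]] <- Matrix::sparseMatrix(
      i = seq_len(n), j = as.integer(fct), x = 1,
      dims = c(n, nlevels(fct)))
    sizes[tm] <- nlevels(fct)
  }
  W <- do.call(cbind, blocks)
  list(W = W, sizes = sizes)
}

# solve the mixed-model equations for given component values; zero components
# are treated as dropped (their effects are exactly zero), a zero residual is
# floored for the solve only (the BLUP limit).
.solve_mme <- function(d, comps) {
  active <- names(comps)[comps > 0 & names(comps) != "residual"]
  active <- intersect(d$terms, active)
  mp <- .nested_mme_parts(d, active)
  sig_e <- max(comps["residual"], 1e-12 * max(stats::var(d$y), 1e-300))
  lambda <- numeric(0)
  for (tm in active) lambda <- c(lambda, rep(sig_e / comps[tm], mp$sizes[tm]))
  C <- Matrix::crossprod(mp$W) + Matrix::Diagonal(x = c(0, lambda))
  rhs <- Matrix::crossprod(mp$W, d$y)
  sol <- as.numeric(Matrix::solve(C, rhs))
  # unpack
  out <- list(mu = sol[1])
  off <- 1L
  for (tm in active) {
    idx <- off + seq_len(mp$sizes[tm])
    out[[tm]] <- stats::setNames(sol[idx], levels(d[[tm]]))
    off <- off + mp$sizes[tm]
  }
  for (tm in setdiff(d$terms, active))
    out[[tm]] <- stats::setNames(rep(0, nlevels(d[[tm]])), levels(d[[tm]]))
  out
}

# EM-REML via Henderson's mixed-model equations (dense inverse for the
# per-block traces; intended for MME dimensions up to a few thousand).
.em_reml <- function(d, terms, tol, max_iter) {
  y <- d$y; n <- length(y)
  vy <- stats::var(y)
  mp <- .nested_mme_parts(d, terms)
  W <- as.matrix(mp$W)
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  yty <- sum(y^2)
  nterm <- length(terms)
  idx <- vector("list", nterm); names(idx) <- terms
  off <- 1L
  for (tm in terms) { idx[[tm]] <- off + seq_len(mp$sizes[tm]); off <- off + mp$sizes[tm] }
  comps <- stats::setNames(rep(vy / (nterm + 1), nterm + 1), c(terms, "residual"))
  dropped <- stats::setNames(rep(FALSE, nterm), terms)
  zero_tol <- 1e-10 * vy
  loglik <- numeric(0)
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    lam <- rep(0, ncol(W))
    for (tm in terms[!dropped]) lam[idx[[tm]]] <- comps["residual"] / comps[tm]
    for (tm in terms[dropped]) lam[idx[[tm]]] <- Inf
    act_cols <- c(1L, unlist(idx[terms[!dropped]], use.names = FALSE))
    C <- WtW[act_cols, act_cols, drop = FALSE] + diag(lam[act_cols], length(act_cols))
    ch <- chol(C)
    Cinv <- chol2inv(ch)
    sol <- Cinv %*% Wty[act_cols, , drop = FALSE]
    ypy_num <- yty - sum(sol * Wty[act_cols])
    new <- comps
    for (tm in terms[!dropped]) {
      loc <- match(idx[[tm]], act_cols)
      u <- sol[loc]
      tr <- sum(diag(Cinv)[loc])
      new[tm] <- (sum(u^2) + comps["residual"] * tr) / mp$sizes[tm]
    }
    new["residual"] <- ypy_num / (n - 1)
    # restricted log-likelihood (-2 logL_R) at the current (pre-update) comps
    q_act <- sum(mp$sizes[terms[!dropped]])
    logdetC <- 2 * sum(log(diag(ch)))
    m2ll <- (n - 1 - q_act) * log(comps["residual"]) +
      sum(vapply(terms[!dropped], function(tm) mp$sizes[tm] * log(comps[tm]), numeric(1))) +
      logdetC + ypy_num / comps["residual"] + (n - 1) * log(2 * pi)
    loglik <- c(loglik, -0.5 * m2ll)
    rel <- abs(new - comps) / pmax(comps, 1e-300)
    comps <- new
    # pin vanishing components at zero and drop their term
    for (tm in terms[!dropped]) if (comps[tm] < zero_tol) {
      comps[tm] <- 0; dropped[tm] <- TRUE
    }
    if (all(rel[c(terms[!dropped], "residual")] < tol)) { converged <- TRUE; break }
  }
  comps[comps < 0] <- 0
  list(components = comps, converged = converged, n_iter = iter, loglik = loglik)
}

#' Fit the flight-nested variance decomposition to a phenomic table
#'
#' Estimates the variance components of the flight-nested model for one
#' temporal trait in one trial, by EM-REML (Henderson mixed-model equations,
#' all terms random, intercept fixed; monotone in the restricted likelihood)
#' or, for balanced designs, by closed-form ANOVA method of moments with
#' negative estimates truncated to zero. Genotype-within-flight BLUPs are
#' obtained from a single sparse mixed-model-equation solve at the estimated
#' components.
#'
#' @param table long phenomic table (columns trial, flight_day, rep, plot,
#'   genotype, trait_id, value).
#' @param trait_id trait to fit.
#' @param spec a [nested_model_spec()].
#' @param trial which trial to fit when the table holds several.
#' @return class \code{"nested_fit"}: \code{components} (named variances),
#'   \code{percentages}, \code{blups} (genotype x flight matrix of genotypic
#'   values \eqn{\hat\mu + \hat\beta_i + \hat\Omega_{k(i)}}), \code{n_rep},
#'   \code{converged}, \code{n_iter}, \code{method}, \code{loglik}
#'   (per-iteration restricted log-likelihood, EM path), and
#'   \code{components_raw} (ANOVA estimates before truncation).
#' @export
fit_nested_model <- function(table, trait_id, spec = nested_model_spec(),
                             trial = NULL) {
  stopifnot(is.data.frame(table))
  if (!trait_id %in% table$trait_id)
    stop_("trait '%s' absent from table (has: %s)", trait_id,
          paste(unique(table$trait_id), collapse = ", "))
  df <- table[table$trait_id == trait_id, ]
  trials <- unique(df$trial)
  if (is.null(trial)) {
    if (length(trials) > 1)
      stop_("table holds trials %s; pass trial=", paste(trials, collapse = ", "))
  } else {
    if (!trial %in% trials) stop_("trial '%s' not present", trial)
    df <- df[df$trial == trial, ]
  }
  if (length(unique(df$flight_day)) < 2)
    stop_("single flight: the flight variance component is unidentifiable")
  if (length(unique(df$genotype)) < 2) stop_("need at least 2 genotypes")
  d <- .nested_design(df, spec$terms)
  estimation <- spec$estimation
  if (estimation == "auto") estimation <- if (d$balanced) "anova_mom" else "em_reml"
  if (estimation == "anova_mom" && !d$balanced)
    stop_("anova_mom requires a balanced design; use em_reml")
  if (estimation == "anova_mom") {
    raw <- .anova_mom(d)
    comps <- pmax(raw, 0)
    comps <- comps[c(spec$terms, "residual")]
    raw <- raw[c(spec$terms, "residual")]
    converged <- TRUE; n_iter <- 0L; loglik <- numeric(0)
  } else {
    em <- .em_reml(d, spec$terms, spec$tol, spec$max_iter)
    comps <- em$components
    raw <- comps
    converged <- em$converged; n_iter <- em$n_iter; loglik <- em$loglik
  }
  sol <- .solve_mme(d, comps)
  # genotypic values: mu + flight + genotype-in-flight
  flights <- levels(d$flight)
  genos <- levels(d$genotype)
  blups <- matrix(NA_real_, length(genos), length(flights),
                  dimnames = list(genos, flights))
  gf_levels <- levels(d$genotype_in_flight)
  gf_fl <- sub(":.*", "", gf_levels)
  gf_ge <- sub("^[^:]*:", "", gf_levels)
  observed <- unique(paste(as.character(d$flight), as.character(d$genotype), sep = ":"))
  for (l in seq_along(gf_levels)) {
    if (!gf_levels[l] %in% observed) next
    blups[gf_ge[l], gf_fl[l]] <- sol$mu + sol$flight[gf_fl[l]] +
      sol$genotype_in_flight[gf_levels[l]]
  }
  n_rep <- if (d$balanced) d$r * d$k else
    stats::median(table(paste(df$flight_day, df$genotype)))
  total <- sum(comps)
  pct <- if (total > 0) 100 * comps / total else comps * NA
  structure(list(components = comps, components_raw = raw, percentages = pct,
                 blups = blups, n_rep = n_rep, converged = converged,
                 n_iter = n_iter, method = estimation, loglik = loglik,
                 trait_id = trait_id, effects = sol),
            class = "nested_fit")
}

#' @exportS3Method base::print
print.nested_fit <- function(x, ...) {
  cat(sprintf("<nested_fit> %s (%s%s)\n", x$trait_id, x$method,
              if (x$method == "em_reml") sprintf(", %d iter, converged=%s",
                                                 x$n_iter, x$converged) else ""))
  print(round(rbind(variance = x$components, percent = x$percentages), 4))
  invisible(x)
}

#' Variance-component percentages
#'
#' Each component divided by the total of all components, times 100 — the
#' flight / replicate / genotype / residual shares of phenotypic variance.
#'
#' @param fit a [fit_nested_model()] result (or a bare named vector of
#'   non-negative components).
#' @return named numeric vector summing to 100.
#' @export
variance_percentages <- function(fit) {
  comps <- if (inherits(fit, "nested_fit")) fit$components else fit
  total <- sum(comps)
  if (total <= 0) stop_("all variance components are zero; percentages undefined")
  100 * comps / total
}

#' Temporal repeatability
#'
#' Entry-mean repeatability of the genotype-within-flight signal:
#' \deqn{TR = \sigma^2_\Omega / (\sigma^2_\Omega + \sigma^2_\varepsilon / n_{rep}),}
#' clamped to \[0, 1\]. With zero genotype variance TR is 0 regardless of the
#' residual.
#'
#' @param fit a [fit_nested_model()] result.
#' @param n_rep replicates per genotype-flight cell; defaults to the fit's.
#' @return class \code{"repeatability_report"}: \code{tr} plus the component
#'   values used.
#' @export
temporal_repeatability <- function(fit, n_rep = NULL) {
  stopifnot(inherits(fit, "nested_fit"))
  n_rep <- n_rep %||% fit$n_rep
  if (is.na(n_rep) || n_rep < 1) stop_("n_rep must be >= 1")
  s_g <- fit$components[["genotype_in_flight"]]
  s_e <- fit$components[["residual"]]
  tr <- if (s_g <= 0) 0 else s_g / (s_g + s_e / n_rep)
  tr <- min(max(tr, 0), 1)
  structure(list(tr = tr,
                 per_component_inputs = c(genotype_in_flight = s_g,
                                          residual = s_e, n_rep = n_rep)),
            class = "repeatability_report")
}

#' @exportS3Method base::print
print.repeatability_report <- function(x, ...) {
  cat(sprintf("TR = %.4f (sigma2_G = %.4g, sigma2_e = %.4g, n_rep = %g)\n",
              x$tr, x$per_component_inputs[1], x$per_component_inputs[2],
              x$per_component_inputs[3]))
  invisible(x)
}

#' Flight-wise genotypic values (BLUPs)
#'
#' The genotype x flight matrix of shrunken genotypic values
#' \eqn{\hat\mu + \hat\beta_i + \hat\Omega_{k(i)}}; cells unobserved at a
#' flight are \code{NA}.
#'
#' @param fit a converged [fit_nested_model()] result.
#' @export
genotypic_values <- function(fit) {
  stopifnot(inherits(fit, "nested_fit"))
  if (!fit$converged) stop_("fit did not converge; genotypic values unreliable")
  fit$blups
}

#' Fit the nested model for several traits at once
#'
#' @param table phenomic table.
#' @param trait_ids traits to fit; default all present.
#' @param spec,trial passed to [fit_nested_model()].
#' @return named list of \code{nested_fit} objects.
#' @export
decompose_traits <- function(table, trait_ids = NULL, spec = nested_model_spec(),
                             trial = NULL) {
  trait_ids <- trait_ids %||% unique(table$trait_id)
  fits <- lapply(trait_ids, function(tid) fit_nested_model(table, tid, spec, trial))
  stats::setNames(fits, trait_ids)
}
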