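#' Configuration for the synthetic-trial generator
#'
#' Defines the study conditions the generator emulates: ~280 maize hybrids
#' from inbred crosses, grown in a randomized complete block design with two
#' replications under two managements (optimal \code{OM} and stressed
#' \code{SM}, the stressed trial a subset of 230 hybrids), surveyed by 12--16
#' drone flights between 27 and 144 days after planting. Temporal plot
#' phenotypes follow a flight-nested decomposition with a dominant flight
#' component (default share 0.90, inside the reported 31--96% range), a small
#' replicate-within-flight share (0.02), a genotype-within-flight share of
#' 0.04 (inside the reported 1.5--5.2%) and residual 0.04. Marker effects on
#' temporal traits vary across flights with a configurable correlation, and
#' end-of-season traits (GY, DTA, DTS, PHT) are heritable marker-linear
#' traits.
#'
#' @param n_parents number of inbred parents crossed to form hybrids.
#' @param n_hybrids number of hybrids in the optimal-management trial.
#' @param n_hybrids_sm hybrids in the stressed trial (subset of OM).
#' @param n_markers biallelic markers simulated before MAF filtering.
#' @param maf_range allele-frequency window (0, 0.5] enforced on realized
#'   hybrid minor-allele frequencies.
#' @param n_flights_rgb,n_flights_multi flight counts for the two platforms.
#' @param flight_days integer days after planting; default evenly spaced
#'   27--144 over \code{n_flights_rgb} flights.
#' @param n_rep replications per trial (RCBD).
#' @param temporal_traits named list: trait_id -> list(mean, sd) on the
#'   trait's own scale (VIs unitless, CHM in cm).
#' @param variance_shares either one named list
#'   \code{(flight, rep_in_flight, genotype_in_flight, residual)} summing to
#'   1 (applied to every temporal trait) or a per-trait map of such lists.
#' @param flight_genetic_weights optional per-flight multipliers on the
#'   genotype-within-flight variance (default all 1), letting the genetic
#'   share change over growth stages.
#' @param flight_effect_corr across-flight correlation of marker effects on
#'   temporal traits.
#' @param trait_h2 named narrow-sense heritabilities for GY, DTA, DTS, PHT.
#' @param trait_means,trait_sds trait scales (GY t/ha at 15.5% moisture,
#'   DTA/DTS days, PHT cm).
#' @param trait_cor genetic correlation matrix among the four traits (must be
#'   positive semidefinite).
#' @param env_shift named OM-to-SM mean offsets per terminal trait.
#' @param env_shift_temporal SM offset for temporal traits, in within-trait
#'   SD units.
#' @param gxe_corr genetic correlation of genotype effects between OM and SM.
#' @param vi_trait_env_link fraction (0-1) of each temporal trait's
#'   genotype-within-flight variance carried by a trial-specific, non-marker
#'   genotype factor (permanent micro-environment / GxE response). The
#'   mixture is variance-preserving, so the configured variance shares are
#'   unaffected; 0 (default) makes the genotype signal purely marker-driven.
#' @param gy_env_link weight (in GY standard deviations) with which the same
#'   non-marker factor enters grain yield. Together with
#'   \code{vi_trait_env_link} this creates signal that phenomic features can
#'   exploit but genome-wide markers cannot.
#' @param vi_gy_genetic_corr correlation between the shared component of
#'   each temporal trait's marker effects and the grain-yield marker
#'   effects, making vegetation indices genetically informative about yield
#'   (the premise of phenomic prediction). Default 0.4.
#' @param effect_dist distribution of flight/replicate/residual draws:
#'   \code{"gaussian"} (default) or \code{"t5"} (scaled Student t, 5 df).
#' @param raster rendering options: \code{plot_px} (c(w, h) pixels),
#'   \code{gap_px}, \code{n_genotypes} rendered, \code{ncol_plots},
#'   \code{noise_sd} (pixel noise on the index scale), \code{vi} (index to
#'   render, NGRDI or NDVI).
#' @param seed root seed; named substreams (markers/effects/trial/raster) are
#'   derived from it so stages can be re-run independently.
#' @return validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_parents = 40, n_hybrids = 280, n_hybrids_sm = 230,
                       n_markers = 500, maf_range = c(0.05, 0.5),
                       n_flights_rgb = 15, n_flights_multi = 12,
                       flight_days = NULL, n_rep = 2,
                       temporal_traits = list(
                         NGRDI = list(mean = 0.30, sd = 0.15),
                         RCC   = list(mean = 0.35, sd = 0.08),
                         GLI   = list(mean = 0.20, sd = 0.10),
                         ExG   = list(mean = 0.25, sd = 0.12),
                         CHM   = list(mean = 150,  sd = 45)),
                       variance_shares = list(flight = 0.90, rep_in_flight = 0.02,
                                              genotype_in_flight = 0.04, residual = 0.04),
                       flight_genetic_weights = NULL,
                       flight_effect_corr = 0.9,
                       trait_h2 = c(GY = 0.6, DTA = 0.8, DTS = 0.8, PHT = 0.7),
                       trait_means = c(GY = 9.5, DTA = 70, DTS = 72, PHT = 220),
                       trait_sds = c(GY = 1.4, DTA = 3.5, DTS = 3.5, PHT = 12),
                       trait_cor = NULL,
                       env_shift = c(GY = -2.5, DTA = 2, DTS = 3, PHT = -25),
                       env_shift_temporal = -0.3,
                       gxe_corr = 0.7, vi_trait_env_link = 0,
                       gy_env_link = 0, vi_gy_genetic_corr = 0.4,
                       effect_dist = c("gaussian", "t5"),
                       raster = list(), seed = 1) {
  effect_dist <- match.arg(effect_dist)
  for (v in list(n_parents, n_hybrids, n_hybrids_sm, n_markers, n_flights_rgb,
                 n_flights_multi, n_rep))
    if (!is_count(v)) stop_("all counts must be positive integers")
  if (n_parents < 2) stop_("need at least 2 parents")
  if (n_hybrids_sm > n_hybrids) stop_("SM genotypes must be a subset of OM genotypes")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_("maf_range must lie within (0, 0.5]")
  if (is.null(flight_days))
    flight_days <- round(seq(27, 144, length.out = n_flights_rgb))
  flight_days <- as.integer(flight_days)
  if (is.unsorted(flight_days, strictly = TRUE)) stop_("flight_days must be strictly increasing")
  # variance shares: recycle a single share list over all temporal traits
  comp_names <- c("flight", "rep_in_flight", "genotype_in_flight", "residual")
  if (all(comp_names %in% names(variance_shares)))
    variance_shares <- stats::setNames(
      rep(list(variance_shares), length(temporal_traits)), names(temporal_traits))
  for (tid in names(variance_shares)) {
    sh <- variance_shares[[tid]]
    if (!setequal(names(sh), comp_names))
      stop_("variance_shares for %s must name %s", tid, paste(comp_names, collapse = ", "))
    tot <- sum(unlist(sh))
    if (abs(tot - 1) > 1e-12)
      stop_("variance_shares for %s sum to %.15f, not 1", tid, tot)
    if (any(unlist(sh) < 0)) stop_("variance shares must be non-negative")
  }
  if (!all(names(temporal_traits) %in% names(variance_shares)))
    stop_("variance_shares missing for: %s",
          paste(setdiff(names(temporal_traits), names(variance_shares)), collapse = ", "))
  if (any(trait_h2 < 0 | trait_h2 > 1)) stop_("trait_h2 must lie in [0, 1]")
  if (abs(gxe_corr) > 1) stop_("gxe_corr must lie in [-1, 1]")
  if (flight_effect_corr < 0 || flight_effect_corr > 1)
    stop_("flight_effect_corr must lie in [0, 1]")
  if (vi_gy_genetic_corr < 0 || vi_gy_genetic_corr > 1)
    stop_("vi_gy_genetic_corr must lie in [0, 1]")
  if (vi_trait_env_link < 0 || vi_trait_env_link > 1)
    stop_("vi_trait_env_link is a variance fraction in [0, 1]")
  if (is.null(flight_genetic_weights))
    flight_genetic_weights <- rep(1, length(flight_days))
  if (length(flight_genetic_weights) != length(flight_days))
    stop_("flight_genetic_weights must have one entry per flight")
  if (is.null(trait_cor)) {
    trait_cor <- diag(4)
    dimnames(trait_cor) <- list(names(trait_h2), names(trait_h2))
    trait_cor["DTA", "DTS"] <- trait_cor["DTS", "DTA"] <- 0.9
    trait_cor["DTA", "PHT"] <- trait_cor["PHT", "DTA"] <- 0.3
    trait_cor["DTS", "PHT"] <- trait_cor["PHT", "DTS"] <- 0.3
    trait_cor["GY", "PHT"]  <- trait_cor["PHT", "GY"]  <- 0.3
  }
  raster_def <- list(plot_px = c(12L, 8L), gap_px = 2L, n_genotypes = 10L,
                     ncol_plots = 5L, noise_sd = 0, vi = "NGRDI")
  raster <- utils::modifyList(raster_def, raster)
  structure(list(
    n_parents = n_parents, n_hybrids = n_hybrids, n_hybrids_sm = n_hybrids_sm,
    n_markers = n_markers, maf_range = maf_range,
    n_flights_rgb = n_flights_rgb, n_flights_multi = n_flights_multi,
    flight_days = flight_days, n_rep = n_rep,
    temporal_traits = temporal_traits, variance_shares = variance_shares,
    flight_genetic_weights = flight_genetic_weights,
    flight_effect_corr = flight_effect_corr,
    trait_h2 = trait_h2, trait_means = trait_means, trait_sds = trait_sds,
    trait_cor = trait_cor, env_shift = env_shift,
    env_shift_temporal = env_shift_temporal, gxe_corr = gxe_corr,
    vi_trait_env_link = vi_trait_env_link, gy_env_link = gy_env_link,
    vi_gy_genetic_corr = vi_gy_genetic_corr, effect_dist = effect_dist,
    raster = raster, seed = seed), class = "sim_config")
}

.rdraw <- function(n, dist) {
  if (dist == "t5") stats::rt(n, df = 5) / sqrt(5 / 3) else stats::rnorm(n)
}

#' Simulate a biallelic marker panel for an inbred-cross hybrid population
#'
#' Inbred parents are homozygous at every marker (dosage 0 or 2); each hybrid
#' is an F1 of two distinct parents, so its dosage is the parental mean and
#' is heterozygous exactly where the parents differ. Markers whose realized
#' hybrid minor-allele frequency falls outside \code{maf_range} are removed.
#'
#' @param config a [sim_config()].
#' @return class \code{"marker_set"}: \code{dosages} (hybrids x markers),
#'   \code{parent_dosages}, \code{pedigree}, \code{map} (marker, chrom, pos),
#'   \code{maf} (realized hybrid MAF).
#' @export
simulate_marker_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "markers"), {
    M <- config$n_markers
    p <- stats::runif(M, config$maf_range[1], config$maf_range[2])
    parents <- matrix(2L * stats::rbinom(config$n_parents * M, 1, rep(p, each = config$n_parents)),
                      nrow = config$n_parents, ncol = M)
    rownames(parents) <- sprintf("P%03d", seq_len(config$n_parents))
    n_pairs <- choose(config$n_parents, 2)
    if (config$n_hybrids > n_pairs)
      stop_("cannot form %d distinct hybrids from %d parents (%d pairs)",
            config$n_hybrids, config$n_parents, n_pairs)
    pairs <- utils::combn(config$n_parents, 2)
    sel <- pairs[, sample.int(n_pairs, config$n_hybrids), drop = FALSE]
    dos <- (parents[sel[1, ], , drop = FALSE] + parents[sel[2, ], , drop = FALSE]) / 2
    rownames(dos) <- sprintf("H%03d", seq_len(config$n_hybrids))
    colnames(dos) <- colnames(parents) <- sprintf("M%05d", seq_len(M))
    freq <- colMeans(dos) / 2
    maf <- pmin(freq, 1 - freq)
    keep <- maf >= config$maf_range[1] & maf <= config$maf_range[2] & maf > 0
    if (!any(keep))
      stop_("MAF filter (window [%.3f, %.3f] on realized hybrid frequencies) removed all markers",
            config$maf_range[1], config$maf_range[2])
    dos <- dos[, keep, drop = FALSE]
    map <- data.frame(marker = colnames(dos),
                      chrom = rep_len(1:10, ncol(dos)),
                      pos = seq_len(ncol(dos)) * 1e5,
                      stringsAsFactors = FALSE)
    structure(list(
      dosages = dos,
      parent_dosages = parents[, keep, drop = FALSE],
      pedigree = data.frame(hybrid = rownames(dos),
                            parent1 = rownames(parents)[sel[1, ]],
                            parent2 = rownames(parents)[sel[2, ]],
                            stringsAsFactors = FALSE),
      map = map, maf = maf[keep]), class = "marker_set")
  })
}

#' @exportS3Method base::print
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d genotypes x %d markers (MAF %.3f-%.3f)\n",
              nrow(x$dosages), ncol(x$dosages), min(x$maf), max(x$maf)))
  invisible(x)
}

#' Simulate the genetic architecture of temporal and terminal traits
#'
#' Marker effects on each temporal trait are drawn per flight with a
#' configured across-flight correlation, then each flight's genotype effects
#' are rescaled so that their sample variance equals exactly the configured
#' genotype-within-flight variance for that flight (share x trait variance x
#' flight weight). Terminal traits are marker-linear with genetic variance
#' h2 x trait variance and a configured genetic correlation structure.
#' Stressed-trial genotype effects mix the optimal-trial effects with an
#' independent marker-based draw at weights \code{(gxe_corr,
#' sqrt(1 - gxe_corr^2))}.
#'
#' @param markers a [simulate_marker_panel()] result.
#' @param config a [sim_config()].
#' @return class \code{"truth_record"} with per-trait marker-effect matrices,
#'   genotype x flight temporal genetic values (OM and SM), terminal genetic
#'   values and the realized variance components.
#' @export
simulate_genetic_architecture <- function(markers, config) {
  stopifnot(inherits(markers, "marker_set"), inherits(config, "sim_config"))
  if (ncol(markers$dosages) < 1) stop_("marker set is empty")
  missing_shares <- setdiff(names(config$temporal_traits), names(config$variance_shares))
  if (length(missing_shares))
    stop_("variance_shares undefined for: %s", paste(missing_shares, collapse = ", "))
  ev <- eigen(config$trait_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_("trait correlation matrix is not positive semidefinite (min eigenvalue %.3g)", min(ev))
  with_seed(derive_seed(config$seed, "effects"), {
    Z <- scale(markers$dosages, center = TRUE, scale = FALSE)
    M <- ncol(Z); G <- nrow(Z)
    Ff <- length(config$flight_days)
    rho <- config$flight_effect_corr
    scale_cols <- function(vals, effs, targets) {
      # rescale genotype-effect columns to exact sample variance targets,
      # carrying the same factor into the marker effects
      for (f in seq_along(targets)) {
        tv <- targets[f]
        if (tv <= 0) { vals[, f] <- 0; effs[, f] <- 0; next }
        s <- stats::sd(vals[, f])
        if (s < .Machine$double.eps) stop_("degenerate genotype effects at flight %d", f)
        fac <- sqrt(tv) / s
        vals[, f] <- (vals[, f] - mean(vals[, f])) * fac
        effs[, f] <- effs[, f] * fac
      }
      list(vals = vals, effs = effs)
    }
    # terminal traits first: correlated marker effects, exact-variance
    # calibration; the raw GY effect vector seeds the genetic VI-yield link
    tr_names <- names(config$trait_h2)
    L <- chol(config$trait_cor + diag(1e-10, length(tr_names)))
    beta_raw <- matrix(stats::rnorm(M * length(tr_names)), M) %*% L
    colnames(beta_raw) <- tr_names
    beta <- beta_raw
    gv_om <- Z %*% beta
    beta_ind <- matrix(stats::rnorm(M * length(tr_names)), M) %*% L
    gv_ind <- Z %*% beta_ind
    for (tr in tr_names) {
      tv <- config$trait_h2[tr] * config$trait_sds[tr]^2
      gv_om[, tr] <- scale_to_var(gv_om[, tr], tv)
      gv_ind[, tr] <- scale_to_var(gv_ind[, tr], tv)
      if (tv > 0) beta[, tr] <- beta[, tr] * sqrt(tv) / stats::sd((Z %*% beta[, tr, drop = FALSE])[, 1])
    }
    gv_sm <- config$gxe_corr * gv_om + sqrt(1 - config$gxe_corr^2) * gv_ind

    temporal_om <- temporal_sm <- marker_effects <- list()
    realized <- list()
    rho_gy <- config$vi_gy_genetic_corr
    for (tid in names(config$temporal_traits)) {
      sh <- config$variance_shares[[tid]]
      sd_t <- config$temporal_traits[[tid]]$sd
      targets <- sh$genotype_in_flight * sd_t^2 * config$flight_genetic_weights
      draw_effects <- function() {
        # shared component partially aligned with the GY marker effects, so
        # vegetation indices are genetically informative about yield
        shared <- rho_gy * beta_raw[, "GY"] +
          sqrt(1 - rho_gy^2) * stats::rnorm(M)
        sapply(seq_len(Ff), function(f)
          sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(M))
      }
      eff_om <- draw_effects()
      som <- scale_cols(Z %*% eff_om, eff_om, targets)
      eff_ind <- draw_effects()
      sind <- scale_cols(Z %*% eff_ind, eff_ind, targets)
      w1 <- config$gxe_corr; w2 <- sqrt(1 - w1^2)
      vals_sm <- w1 * som$vals + w2 * sind$vals
      temporal_om[[tid]] <- som$vals
      temporal_sm[[tid]] <- vals_sm
      marker_effects[[tid]] <- som$effs
      realized[[tid]] <- list(genotype_in_flight = apply(som$vals, 2, stats::var))
      dimnames(temporal_om[[tid]]) <- list(rownames(Z), config$flight_days)
      dimnames(temporal_sm[[tid]]) <- list(rownames(Z), config$flight_days)
    }
    structure(list(
      marker_effects = marker_effects, terminal_effects = beta,
      genetic_values = gv_om, genetic_values_sm = gv_sm,
      temporal_genetic_values = temporal_om,
      temporal_genetic_values_sm = temporal_sm,
      realized_components = realized,
      flight_days = config$flight_days,
      genotypes = rownames(Z)), class = "truth_record")
  })
}

#' Simulate a replicated two-management temporal trial
#'
#' Every plot observation is grand mean + flight effect + replicate-within-
#' flight effect + genotype-within-flight effect + residual. Flight and
#' replicate effects are drawn once per level and rescaled to their exact
#' target sample variance (they have few levels, so unscaled draws would make
#' the realized shares drift far from the configured ones); residuals are
#' left unscaled. Flight effects follow a growth trajectory (asymptotic
#' Weibull-shaped for CHM, a mid-season bump for VIs) plus jitter, preserving
#' the configured flight variance share while giving temporal curves a
#' realistic shape. The stressed trial adds \code{env_shift} and uses
#' genotype effects correlated \code{gxe_corr} with the optimal trial.
#'
#' @param truth a [simulate_genetic_architecture()] result.
#' @param config a [sim_config()].
#' @param markers optional [simulate_marker_panel()] result stored alongside.
#' @return class \code{"synthetic_trial"}: \code{phenomic} (long plot table),
#'   \code{traits} (genotype-level tables per trial), \code{markers},
#'   \code{truth}, \code{layout}, \code{env_effects}.
#' @export
simulate_temporal_trial <- function(truth, config, markers = NULL) {
  stopifnot(inherits(truth, "truth_record"), inherits(config, "sim_config"))
  missing_shares <- setdiff(names(config$temporal_traits), names(config$variance_shares))
  if (length(missing_shares))
    stop_("variance_shares undefined for: %s", paste(missing_shares, collapse = ", "))
  with_seed(derive_seed(config$seed, "trial"), {
    days <- config$flight_days
    Ff <- length(days); R <- config$n_rep
    genos_om <- truth$genotypes
    genos_sm <- genos_om[seq_len(config$n_hybrids_sm)]
    dist <- config$effect_dist
    env_eff <- list(OM = stats::setNames(stats::rnorm(length(genos_om)), genos_om),
                    SM = stats::setNames(stats::rnorm(length(genos_om)), genos_om))
    w_link <- config$vi_trait_env_link
    trait_rows <- list()
    pheno <- list()
    for (trial in c("OM", "SM")) {
      genos <- if (trial == "OM") genos_om else genos_sm
      Gn <- length(genos)
      plot_id <- matrix(sprintf("%s_P%04d", trial, seq_len(Gn * R)), nrow = Gn)
      for (tid in names(config$temporal_traits)) {
        sh <- config$variance_shares[[tid]]
        mu <- config$temporal_traits[[tid]]$mean
        sd_t <- config$temporal_traits[[tid]]$sd
        if (trial == "SM") mu <- mu + config$env_shift_temporal * sd_t
        # flight effects: trajectory + jitter, exact variance
        traj <- if (tid == "CHM") {
          1 - exp(-(days / (0.55 * max(days)))^3)
        } else {
          exp(-0.5 * ((days - stats::quantile(days, 0.45)) / (0.3 * diff(range(days))))^2)
        }
        fl <- traj + 0.2 * stats::sd(traj) * .rdraw(Ff, dist)
        fl <- scale_to_var(fl, sh$flight * sd_t^2)
        # replicate effects: centered within flight and calibrated so the
        # pooled within-flight sample variance is exact (the quantity the
        # nested decomposition estimates)
        rp <- matrix(.rdraw(Ff * R, dist), nrow = Ff, ncol = R)
        rp <- rp - rowMeans(rp)
        tv_rep <- sh$rep_in_flight * sd_t^2
        if (R > 1 && tv_rep > 0) {
          rp <- rp * sqrt(tv_rep * Ff * (R - 1) / sum(rp^2))
        } else rp[] <- 0
        gmat <- if (trial == "OM") truth$temporal_genetic_values[[tid]]
                else truth$temporal_genetic_values_sm[[tid]]
        gmat <- gmat[genos, , drop = FALSE]
        if (w_link > 0) {
          # variance-preserving mixture: a fraction w_link of the
          # genotype-within-flight variance is the non-marker trial factor
          E <- scale_to_var(env_eff[[trial]][genos], 1)
          col_sd <- apply(gmat, 2, stats::sd)
          gmat <- sqrt(1 - w_link) * gmat +
            sqrt(w_link) * outer(E, col_sd)
        }
        res_sd <- sqrt(sh$residual) * sd_t
        for (f in seq_len(Ff)) for (r in seq_len(R)) {
          val <- mu + fl[f] + rp[f, r] + gmat[, f] +
            res_sd * .rdraw(Gn, dist)
          pheno[[length(pheno) + 1L]] <- data.frame(
            trial = trial, flight_day = days[f], rep = r,
            plot = plot_id[, r], genotype = genos, trait_id = tid,
            value = as.numeric(val), stringsAsFactors = FALSE)
        }
      }
      # terminal traits, genotype level
      gv <- if (trial == "OM") truth$genetic_values else truth$genetic_values_sm
      gv <- gv[genos, , drop = FALSE]
      tt <- data.frame(trial = trial, genotype = genos, stringsAsFactors = FALSE)
      for (tr in names(config$trait_h2)) {
        mu <- config$trait_means[tr] + if (trial == "SM") config$env_shift[tr] else 0
        noise <- sqrt(1 - config$trait_h2[tr]) * config$trait_sds[tr] * .rdraw(Gn, dist)
        link <- if (tr == "GY" && config$gy_env_link > 0)
          config$gy_env_link * config$trait_sds[tr] *
            scale_to_var(env_eff[[trial]][genos], 1) else 0
        tt[[tr]] <- as.numeric(mu + gv[, tr] + link + noise)
      }
      trait_rows[[trial]] <- tt
    }
    phenomic <- do.call(rbind, pheno)
    layout <- .make_layout(genos_om, config)
    structure(list(phenomic = phenomic, traits = trait_rows, markers = markers,
                   truth = truth, layout = layout, env_effects = env_eff,
                   flight_days = days, n_rep = R, config = config),
              class = "synthetic_trial")
  })
}

#' @exportS3Method base::print
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial> %d OM / %d SM genotypes, %d flights, %d reps, traits: %s\n",
              length(unique(x$phenomic$genotype[x$phenomic$trial == "OM"])),
              length(unique(x$phenomic$genotype[x$phenomic$trial == "SM"])),
              length(x$flight_days), x$n_rep,
              paste(unique(x$phenomic$trait_id), collapse = ", ")))
  invisible(x)
}

# rectangular-grid layout for the rendered subset of OM plots
.make_layout <- function(genotypes, config) {
  rs <- config$raster
  ng <- min(rs$n_genotypes, length(genotypes))
  genos <- genotypes[seq_len(ng)]
  R <- config$n_rep
  w <- rs$plot_px[1]; h <- rs$plot_px[2]; gap <- rs$gap_px
  plots <- expand.grid(genotype = genos, rep = seq_len(R),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # plot ids must match the simulated OM plot ids (genotype index x rep)
  gi <- match(plots$genotype, genotypes)
  plots$plot <- sprintf("OM_P%04d", gi + (plots$rep - 1L) * length(genotypes))
  plots$trial <- "OM"
  polys <- list()
  nc <- rs$ncol_plots
  for (k in seq_len(nrow(plots))) {
    rowk <- (k - 1L) %/% nc
    colk <- (k - 1L) %% nc
    x0 <- colk * (w + gap) + gap
    y0 <- rowk * (h + gap) + gap
    polys[[plots$plot[k]]] <- cbind(x = c(x0, x0 + w, x0 + w, x0),
                                    y = c(y0, y0, y0 + h, y0 + h))
  }
  field_layout(plots[, c("plot", "genotype", "trial", "rep")], polys)
}

#' Render synthetic band stacks and height grids for a simulated trial
#'
#' For each flight, draws per-pixel index targets around the simulated plot
#' value (plus optional pixel noise) and inverts the index formula per pixel,
#' so that extracting the plot mean of the recomputed index recovers the
#' simulated plot value (exactly when \code{noise_sd = 0}). A height grid is
#' rendered analogously from the CHM trait. Raster dimensions equal the
#' layout bounding box at the configured resolution; the background carries
#' soil-like reflectance.
#'
#' @param trial a [simulate_temporal_trial()] result.
#' @param config the same [sim_config()].
#' @return list with \code{stacks} (per-flight [band_stack()]),
#'   \code{height_grids} (per-flight matrices, NULL if no CHM trait) and
#'   \code{layout}.
#' @export
render_band_stacks <- function(trial, config) {
  stopifnot(inherits(trial, "synthetic_trial"), inherits(config, "sim_config"))
  rs <- config$raster
  vi <- rs$vi
  if (!vi %in% c("NGRDI", "NDVI"))
    stop_("renderable indices are NGRDI and NDVI, got %s", vi)
  if (!vi %in% names(config$temporal_traits))
    stop_("config simulates no '%s' trait to render", vi)
  layout <- trial$layout
  xs <- unlist(lapply(layout$polygons, function(p) p[, 1]))
  ys <- unlist(lapply(layout$polygons, function(p) p[, 2]))
  nc <- ceiling(max(xs)); nr <- ceiling(max(ys))
  if (any(xs < 0) || any(ys < 0)) stop_("layout polygons fall outside the raster extent")
  # rasterize plots, detecting overlap
  owner <- matrix(NA_character_, nr, nc)
  pix <- list()
  for (id in layout$plots$plot) {
    ij <- pixels_in_polygon(c(nr, nc), layout$polygons[[id]])
    clash <- !is.na(owner[ij])
    if (any(clash))
      stop_("overlapping plot polygons: %s and %s", id,
            paste(unique(owner[ij][clash]), collapse = ", "))
    owner[ij] <- id
    pix[[id]] <- ij
  }
  has_chm <- "CHM" %in% names(config$temporal_traits)
  ph <- trial$phenomic
  ph <- ph[ph$trial == "OM" & ph$plot %in% layout$plots$plot, ]
  with_seed(derive_seed(config$seed, "raster"), {
    stacks <- list(); hgrids <- if (has_chm) list() else NULL
    for (f in seq_along(trial$flight_days)) {
      day <- trial$flight_days[f]
      soil <- list(R = 0.30, G = 0.26, B = 0.22, RE = 0.30, NIR = 0.32)
      bands <- lapply(soil, function(v) matrix(v, nr, nc))
      hg <- matrix(0, nr, nc)
      sub <- ph[ph$flight_day == day, ]
      for (id in layout$plots$plot) {
        ij <- pix[[id]]
        v0 <- sub$value[sub$plot == id & sub$trait_id == vi]
        tgt <- v0 + if (rs$noise_sd > 0) stats::rnorm(nrow(ij), 0, rs$noise_sd) else 0
        tgt <- pmin(pmax(tgt, -0.9), 0.9)
        if (vi == "NGRDI") {
          s <- 0.5
          bands$G[ij] <- s * (1 + tgt) / 2
          bands$R[ij] <- s * (1 - tgt) / 2
          bands$B[ij] <- 0.12
        } else {
          r0 <- 0.05
          bands$R[ij] <- r0
          bands$NIR[ij] <- r0 * (1 + tgt) / (1 - tgt)
          bands$G[ij] <- 0.2; bands$B[ij] <- 0.12; bands$RE[ij] <- 0.25
        }
        if (has_chm) {
          h0 <- sub$value[sub$plot == id & sub$trait_id == "CHM"]
          hij <- h0 + if (rs$noise_sd > 0) stats::rnorm(nrow(ij), 0, rs$noise_sd) else 0
          hg[ij] <- pmax(hij, 0)
        }
      }
      keep <- if (vi == "NGRDI") c("R", "G", "B") else c("R", "G", "B", "RE", "NIR")
      stacks[[f]] <- band_stack(bands[keep], flight_day = day)
      if (has_chm) hgrids[[f]] <- hg
    }
    list(stacks = stacks, height_grids = hgrids, layout = layout)
  })
}

#' One-call simulation of markers, architecture and trial
#'
#' @param config a [sim_config()].
#' @return a [simulate_temporal_trial()] result with markers attached.
#' @export
simulate_trial <- function(config = sim_config()) {
  mk <- simulate_marker_panel(config)
  tr <- simulate_genetic_architecture(mk, config)
  simulate_temporal_trial(tr, config, markers = mk)
}
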