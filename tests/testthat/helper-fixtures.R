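# Shared fixtures: small study designs generated in code.

small_config <- function(..., seed = 101) {
  defaults <- list(
    n_parents = 10, n_hybrids = 24, n_hybrids_sm = 18, n_markers = 120,
    n_flights_rgb = 5, flight_days = c(30L, 55L, 80L, 105L, 130L),
    temporal_traits = list(NGRDI = list(mean = 0.3, sd = 0.15),
                           CHM = list(mean = 150, sd = 45)),
    raster = list(n_genotypes = 6, noise_sd = 0),
    seed = seed)
  dots <- list(...)
  args <- defaults
  for (k in names(dots)) args[[k]] <- dots[[k]]  # full replace, no list merge
  do.call(sim_config, args)
}

# independently coded linear-interpolation quantile (type-7 convention):
# h = 1 + p (n - 1); interpolate between the flanking order statistics
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- 1 + p * (n - 1)
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# balanced single-trait table straight from the generator
balanced_table <- function(shares, f = 4, g = 15, r = 2, sd = 0.15, seed = 7) {
  cfg <- small_config(
    n_hybrids = g, n_hybrids_sm = g, n_parents = max(6, ceiling(sqrt(2 * g)) + 2),
    n_flights_rgb = f, flight_days = as.integer(round(seq(30, 130, length.out = f))),
    temporal_traits = list(NGRDI = list(mean = 0.3, sd = sd)),
    variance_shares = shares, n_rep = r, seed = seed)
  tr <- simulate_trial(cfg)
  list(table = tr$phenomic[tr$phenomic$trial == "OM", ], trial = tr, config = cfg)
}

shares_default <- list(flight = 0.90, rep_in_flight = 0.02,
                       genotype_in_flight = 0.04, residual = 0.04)
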