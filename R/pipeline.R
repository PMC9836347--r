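#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Stages:
#' \code{simulate} (synthetic trial), \code{extract} (render band stacks for
#' the layout subset and re-extract the phenomic values through the
#' polygons), \code{decompose} (flight-nested variance model per trait),
#' \code{features} (BLUP matrices, AUC, Weibull fits, feature matrix),
#' \code{predict} (CV schemes x models), \code{compare}. Every enabled
#' stage's inputs must be produced by an earlier enabled stage or supplied
#' as paths.
#'
#' @param out_dir output directory.
#' @param stages named logical list enabling stages.
#' @param sim a [sim_config()] or a list of its arguments.
#' @param models model families to run in the predict stage.
#' @param schemes CV scheme ids.
#' @param traits terminal traits to predict.
#' @param n_iter split-plan iterations.
#' @param train_frac split-plan training fraction.
#' @param add_auc,fit_weibull_chm feature-stage toggles.
#' @param paths named list of input paths (phenomic, markers, traits_om,
#'   traits_sm) used when the producing stage is disabled.
#' @param seed global seed.
#' @param strict fail feature assembly on any missing cell.
#' @export
pipeline_config <- function(out_dir = tempfile("tppr_run_"),
                            stages = list(),
                            sim = list(), models = c("ridge", "gblup"),
                            schemes = c("CV1", "CV2", "CV4"),
                            traits = "GY", n_iter = 50, train_frac = 0.7,
                            add_auc = TRUE, fit_weibull_chm = TRUE,
                            paths = list(), seed = 1, strict = FALSE) {
  stage_def <- list(simulate = TRUE, extract = FALSE, decompose = TRUE,
                    features = TRUE, predict = TRUE, compare = TRUE)
  stages <- utils::modifyList(stage_def, stages)
  if (!inherits(sim, "sim_config")) {
    sim$seed <- sim$seed %||% seed
    sim <- do.call(sim_config, sim)
  }
  cfg <- structure(list(out_dir = out_dir, stages = stages, sim = sim,
                        models = models, schemes = schemes, traits = traits,
                        n_iter = n_iter, train_frac = train_frac,
                        add_auc = add_auc, fit_weibull_chm = fit_weibull_chm,
                        paths = paths, seed = seed, strict = strict),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  st <- cfg$stages
  need <- function(input, producer, path_key) {
    if (!isTRUE(st[[producer]]) && is.null(cfg$paths[[path_key]]))
      stop_("stage dependency unsatisfied: %s needs %s from stage '%s' or paths$%s",
            input$stage, input$what, producer, path_key)
  }
  if (isTRUE(st$decompose))
    need(list(stage = "decompose", what = "a phenomic table"), "simulate", "phenomic")
  if (isTRUE(st$extract) && !isTRUE(st$simulate))
    stop_("stage dependency unsatisfied: extract needs the simulate stage (rendered rasters)")
  if (isTRUE(st$features) && !isTRUE(st$decompose))
    stop_("stage dependency unsatisfied: features needs the decompose stage")
  if (isTRUE(st$predict)) {
    if (!isTRUE(st$features))
      stop_("stage dependency unsatisfied: predict needs the features stage")
    if (!isTRUE(st$simulate) &&
        (is.null(cfg$paths$traits_om) ||
         (any(cfg$schemes %in% c("CV3", "CV4")) && is.null(cfg$paths$traits_sm))))
      stop_("stage dependency unsatisfied: predict needs trait tables (simulate stage or paths)")
    if ("gblup" %in% cfg$models && !isTRUE(st$simulate) && is.null(cfg$paths$markers))
      stop_("stage dependency unsatisfied: gblup needs markers (simulate stage or paths$markers)")
  }
  if (isTRUE(st$compare) && !isTRUE(st$predict))
    stop_("stage dependency unsatisfied: compare needs the predict stage")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]'s arguments (nested \code{sim} block
#' for the simulator).
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order (simulate, extract, decompose,
#' features, predict, compare), writing every product as delimited text /
#' JSON under \code{out_dir} together with a machine-readable manifest
#' (package version, seeds, input hashes, output hashes). Reruns with the
#' same configuration produce byte-identical outputs. Any stage failure
#' aborts with the stage name and cause.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  outputs <- character(0)
  st <- config$stages
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  trial <- NULL; phenomic <- NULL; traits_om <- NULL; traits_sm <- NULL
  markers <- NULL
  if (isTRUE(st$simulate)) run_stage("simulate", {
    trial <- simulate_trial(config$sim)
    phenomic <- trial$phenomic
    write_phenomic_table(phenomic, out("phenomic.tsv"))
    write_marker_table(trial$markers, out("markers.tsv"))
    write_trait_table(trial$traits$OM, out("traits_OM.tsv"))
    write_trait_table(trial$traits$SM, out("traits_SM.tsv"))
    write_layout_geojson(trial$layout, out("layout.geojson"))
    outputs <- c(outputs, out(c("phenomic.tsv", "markers.tsv", "traits_OM.tsv",
                                "traits_SM.tsv", "layout.geojson")))
    traits_om <- trial$traits$OM
    traits_sm <- trial$traits$SM
    markers <- trial$markers
  })
  if (is.null(phenomic) && !is.null(config$paths$phenomic))
    phenomic <- read_phenomic_table(config$paths$phenomic)
  if (is.null(traits_om) && !is.null(config$paths$traits_om))
    traits_om <- read_trait_table(config$paths$traits_om)
  if (is.null(traits_sm) && !is.null(config$paths$traits_sm))
    traits_sm <- read_trait_table(config$paths$traits_sm)
  if (is.null(markers) && !is.null(config$paths$markers))
    markers <- read_marker_table(config$paths$markers)

  if (isTRUE(st$extract)) run_stage("extract", {
    rend <- render_band_stacks(trial, config$sim)
    vi <- config$sim$raster$vi
    extracted <- build_phenomic_table(
      rend$stacks, rend$height_grids, rend$layout, panel = vi)
    write_phenomic_table(extracted, out("phenomic_extracted.tsv"))
    outputs <- c(outputs, out("phenomic_extracted.tsv"))
  })

  fits_om <- NULL
  if (isTRUE(st$decompose)) run_stage("decompose", {
    spec <- nested_model_spec()
    comp_rows <- list()
    fits_om <- decompose_traits(phenomic, spec = spec, trial = "OM")
    for (tid in names(fits_om)) {
      f <- fits_om[[tid]]
      tr <- temporal_repeatability(f)
      comp_rows[[tid]] <- data.frame(
        trial = "OM", trait_id = tid, t(f$components), t(f$percentages),
        tr = tr$tr, check.names = FALSE)
      write_blup_matrix(f$blups, out(sprintf("blups_%s.tsv", tid)))
      outputs <- c(outputs, out(sprintf("blups_%s.tsv", tid)))
    }
    comp <- do.call(rbind, comp_rows)
    names(comp)[3:6] <- paste0("var_", names(comp)[3:6])
    names(comp)[7:10] <- paste0("pct_", sub("\\.1$", "", names(comp)[7:10]))
    write_tsv_(comp, out("variance_components_OM.tsv"))
    outputs <- c(outputs, out("variance_components_OM.tsv"))
  })

  features <- NULL
  if (isTRUE(st$features)) run_stage("features", {
    blups <- lapply(fits_om, genotypic_values)
    growth <- NULL
    # a 3-parameter growth curve needs at least 4 flights
    if (isTRUE(config$fit_weibull_chm) && "CHM" %in% names(blups) &&
        ncol(blups[["CHM"]]) >= 4)
      growth <- fit_weibull_per_genotype(blups[["CHM"]])
    features <- assemble_feature_matrix(
      blups, growth_fits = growth, add_auc = config$add_auc,
      platform = "TPP_RGB", strict = config$strict)
    write_feature_matrix(features, out("features.tsv"))
    outputs <- c(outputs, out("features.tsv"))
  })

  results <- list()
  if (isTRUE(st$predict)) run_stage("predict", {
    common <- rownames(features)
    common <- intersect(common, traits_om$genotype)
    if (!is.null(traits_sm) && any(config$schemes %in% c("CV3", "CV4")))
      common <- intersect(common, traits_sm$genotype)
    plan <- make_split_plan(common, config$train_frac, config$n_iter,
                            seed = derive_seed(config$seed, "split-plan"))
    write_split_plan(plan, out("plan.json"))
    outputs <- c(outputs, out("plan.json"))
    kernel <- if ("gblup" %in% config$models)
      grm_vanraden(markers$dosages[common, , drop = FALSE]) else NULL
    for (trt in config$traits) {
      y_om <- stats::setNames(traits_om[[trt]], traits_om$genotype)[common]
      y_sm <- if (!is.null(traits_sm))
        stats::setNames(traits_sm[[trt]], traits_sm$genotype)[common] else NULL
      for (mod in config$models) for (sch in config$schemes) {
        spec <- model_spec(mod)
        dat <- if (mod == "gblup") kernel else features
        res <- run_cv_scheme(sch, spec, dat, y_om, y_sm, plan, trait = trt)
        key <- sprintf("%s_%s_%s", trt, mod, sch)
        results[[key]] <- res
        write_tsv_(res$records, out(sprintf("result_%s.tsv", key)))
        outputs <- c(outputs, out(sprintf("result_%s.tsv", key)))
      }
    }
  })

  if (isTRUE(st$compare)) run_stage("compare", {
    cmp_rows <- list()
    for (trt in config$traits) for (sch in config$schemes) {
      grp <- results[grepl(sprintf("^%s_.*_%s$", trt, sch), names(results))]
      if (length(grp) < 1) next
      cmp <- compare_methods(unname(grp), seed = derive_seed(config$seed, "boot"))
      cmp_rows[[length(cmp_rows) + 1L]] <- cmp$means
    }
    if (length(cmp_rows)) {
      write_tsv_(do.call(rbind, cmp_rows), out("comparison.tsv"))
      outputs <- c(outputs, out("comparison.tsv"))
    }
  })

  manifest <- list(
    package = "tppr",
    version = as.character(utils::packageVersion("tppr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_fingerprint = object_fingerprint(
      config[setdiff(names(config), "out_dir")]),
    inputs = lapply(config$paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
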