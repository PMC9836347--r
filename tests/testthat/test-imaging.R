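uniform_stack <- function(vals, n = 4) {
  band_stack(lapply(vals, function(v) matrix(v, n, n)), flight_day = 60)
}

test_that("the registry ships the named RGB and RE/NIR index panels", {
  rgb <- vi_registry("rgb")
  multi <- vi_registry("multi")
  expect_gte(length(rgb), 20)
  expect_gte(length(multi), 20)
  expect_true(all(c("RCC", "NGRDI", "MGRVI", "VARI", "ExG", "ExR", "ExGR",
                    "GLI", "GCC", "BCC", "RGBVI", "CIVE") %in% names(rgb)))
  expect_true(all(c("NDVI", "GNDVI", "NDRE", "SAVI", "OSAVI", "NLI", "MNLI",
                    "EVI2", "MSAVI", "RDVI", "SR") %in% names(multi)))
  # every entry's formula touches only its declared bands
  for (id in names(vi_registry())) {
    e <- vi_registry()[[id]]
    bands <- stats::setNames(lapply(c("R", "G", "B", "RE", "NIR"),
                                    function(b) matrix(0.4, 2, 2)),
                             c("R", "G", "B", "RE", "NIR"))
    out <- e$fn(bands[e$bands])
    expect_true(is.matrix(out), label = id)
  }
})

test_that("compute_vi evaluates formulas and masks undefined pixels", {
  st <- uniform_stack(list(R = 0.3, G = 0.3, B = 0.1))
  expect_true(all(compute_vi(st, "NGRDI") == 0))
  st2 <- uniform_stack(list(R = 0.2, G = 0.2, B = 0.2))
  expect_equal(compute_vi(st2, "RCC"), matrix(1 / 3, 4, 4))
  st3 <- uniform_stack(list(R = 0.1, NIR = 0.5))
  expect_equal(compute_vi(st3, "NDVI")[1, 1], 0.666667, tolerance = 1e-6)
  # division by zero is missing, not infinite
  st0 <- uniform_stack(list(R = 0, G = 0, B = 0))
  expect_true(all(is.na(compute_vi(st0, "NGRDI"))))
  expect_error(compute_vi(st, "NOPE"), "unknown index")
  expect_error(compute_vi(st, "NDVI"), "missing band.*NIR")
})

test_that("registered indices respect their registered output ranges", {
  reg <- vi_registry()
  set.seed(42)
  n <- 100  # 10^4 random pixels
  bands <- stats::setNames(lapply(1:5, function(i) matrix(runif(n * n), n, n)),
                           c("R", "G", "B", "RE", "NIR"))
  st <- band_stack(bands, flight_day = 60)
  for (id in names(reg)) {
    v <- compute_vi(st, id, reg)
    v <- v[!is.na(v)]
    rng <- reg[[id]]$range
    expect_true(all(v >= rng[1] - 1e-12 & v <= rng[2] + 1e-12), label = id)
  }
})

test_that("plot extraction aggregates pixel centers inside the polygon", {
  arr <- matrix(0.7, 10, 10)
  poly <- cbind(c(2, 8, 8, 2), c(2, 2, 6, 6))
  expect_equal(extract_plot_value(arr, poly), 0.7)
  expect_equal(extract_plot_value(arr, poly, "median"), 0.7)
  # 2x2 checkerboard fully covered -> mean 0.5, enumerated directly
  chk <- matrix(c(0, 1, 1, 0), 2, 2)
  full <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  expect_equal(extract_plot_value(chk, full), 0.5)
  expect_error(extract_plot_value(arr, poly + 100, plot_id = "p9"),
               "p9.*geometric miss")
  arr_na <- arr; arr_na[] <- NA
  expect_error(extract_plot_value(arr_na, poly, plot_id = "p9"),
               "all pixels.*missing")
  # missing pixels are excluded, not propagated
  arr2 <- arr; arr2[3, 3] <- NA
  expect_equal(extract_plot_value(arr2, poly), 0.7)
})

test_that("extraction is invariant to translating raster origin and polygons together", {
  set.seed(1)
  arr <- matrix(runif(400), 20, 20)
  poly <- cbind(c(3, 11, 11, 3), c(4, 4, 9, 9))
  v0 <- extract_plot_value(arr, poly)
  off <- c(17.5, -4.25)
  v1 <- extract_plot_value(arr, sweep(poly, 2, -off), origin = off)
  expect_identical(v0, v1)
})

test_that("the half-open pixel rule partitions adjacent plots", {
  arr <- matrix(seq_len(36) / 36, 6, 6)
  left <- cbind(c(0, 3, 3, 0), c(0, 0, 6, 6))
  right <- cbind(c(3, 6, 6, 3), c(0, 0, 6, 6))
  il <- tppr:::pixels_in_polygon(dim(arr), left)
  ir <- tppr:::pixels_in_polygon(dim(arr), right)
  key <- function(m) paste(m[, 1], m[, 2])
  expect_length(intersect(key(il), key(ir)), 0)
  expect_equal(nrow(il) + nrow(ir), 36)
})

test_that("percentile canopy heights follow the linear-interpolation convention", {
  grid <- matrix(2, 8, 8)
  poly <- cbind(c(1, 7, 7, 1), c(1, 1, 7, 7))
  expect_equal(extract_canopy_height(grid, poly), 2)
  g2 <- matrix(seq_len(100), 10, 10)
  full <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_equal(extract_canopy_height(g2, full, percentile = 100), 100)
  expect_equal(extract_canopy_height(g2, full, percentile = 99),
               quantile_oracle(seq_len(100), 0.99))
  set.seed(2)
  g3 <- matrix(rnorm(100), 10, 10)
  expect_equal(extract_canopy_height(g3, full, percentile = 37.5),
               quantile_oracle(as.numeric(g3), 0.375))
})

test_that("build_phenomic_table counts rows and matches per-plot recomputation", {
  set.seed(3)
  mk_stack <- function(day) band_stack(
    list(R = matrix(runif(144, 0.1, 0.4), 12, 12),
         G = matrix(runif(144, 0.2, 0.6), 12, 12),
         B = matrix(runif(144, 0.05, 0.2), 12, 12)), flight_day = day)
  stacks <- lapply(c(40L, 70L, 100L), mk_stack)
  grids <- lapply(1:3, function(i) matrix(runif(144, 0, 2), 12, 12))
  plots <- data.frame(plot = paste0("p", 1:4), genotype = paste0("g", 1:4),
                      trial = "OM", rep = 1, stringsAsFactors = FALSE)
  polys <- list(p1 = cbind(c(0, 5, 5, 0), c(0, 0, 5, 5)),
                p2 = cbind(c(6, 11, 11, 6), c(0, 0, 5, 5)),
                p3 = cbind(c(0, 5, 5, 0), c(6, 6, 11, 11)),
                p4 = cbind(c(6, 11, 11, 6), c(6, 6, 11, 11)))
  layout <- field_layout(plots, polys)
  tab <- build_phenomic_table(stacks, grids, layout, panel = c("NGRDI", "GLI"))
  expect_equal(nrow(tab), 4 * 3 * 3)
  # compositional oracle: recompute one cell by hand
  vi <- compute_vi(stacks[[2]], "GLI")
  expect_equal(tab$value[tab$plot == "p3" & tab$flight_day == 70 &
                           tab$trait_id == "GLI"],
               extract_plot_value(vi, polys$p3))
  expect_equal(tab$value[tab$plot == "p2" & tab$flight_day == 100 &
                           tab$trait_id == "CHM"],
               extract_canopy_height(grids[[3]], polys$p2, 99))
  # empty panel: CHM-only table
  chm_only <- build_phenomic_table(stacks, grids, layout, panel = character(0))
  expect_equal(nrow(chm_only), 4 * 3)
  expect_true(all(chm_only$trait_id == "CHM"))
  # duplicated flights rejected
  expect_error(build_phenomic_table(stacks[c(1, 1)], grids[c(1, 1)], layout,
                                    panel = "NGRDI"), "flight_day")
})

test_that("rendered band stacks round-trip the simulated plot values", {
  cfg <- small_config(raster = list(n_genotypes = 6, noise_sd = 0), seed = 19)
  tr <- simulate_trial(cfg)
  rend <- render_band_stacks(tr, cfg)
  lay <- rend$layout
  # raster dimensions equal the layout bounding box
  xs <- unlist(lapply(lay$polygons, function(p) p[, 1]))
  ys <- unlist(lapply(lay$polygons, function(p) p[, 2]))
  expect_equal(dim(rend$stacks[[1]]$bands$R), c(ceiling(max(ys)), ceiling(max(xs))))
  for (f in c(1, 3)) {
    vi <- compute_vi(rend$stacks[[f]], "NGRDI")
    sub <- tr$phenomic[tr$phenomic$trial == "OM" &
                         tr$phenomic$flight_day == tr$flight_days[f], ]
    for (id in lay$plots$plot) {
      got <- extract_plot_value(vi, lay$polygons[[id]], plot_id = id)
      want <- sub$value[sub$plot == id & sub$trait_id == "NGRDI"]
      expect_equal(got, want, tolerance = 1e-12)
      goth <- extract_canopy_height(rend$height_grids[[f]], lay$polygons[[id]],
                                    plot_id = id)
      wanth <- sub$value[sub$plot == id & sub$trait_id == "CHM"]
      expect_equal(goth, max(wanth, 0), tolerance = 1e-12)
    }
  }
})

test_that("pixel noise averages out over a plot at the Monte-Carlo rate", {
  cfg <- small_config(
    raster = list(n_genotypes = 10, plot_px = c(20L, 20L), noise_sd = 0.01),
    seed = 23)
  tr <- simulate_trial(cfg)
  rend <- render_band_stacks(tr, cfg)
  lay <- rend$layout
  errs <- c()
  for (f in seq_along(rend$stacks)) {
    vi <- compute_vi(rend$stacks[[f]], "NGRDI")
    sub <- tr$phenomic[tr$phenomic$trial == "OM" &
                         tr$phenomic$flight_day == tr$flight_days[f] &
                         tr$phenomic$trait_id == "NGRDI", ]
    for (id in lay$plots$plot) {
      got <- extract_plot_value(vi, lay$polygons[[id]], plot_id = id)
      errs <- c(errs, abs(got - sub$value[sub$plot == id]))
    }
  }
  # 400 px/plot, sigma = 0.01: plot-mean error ~ N(0, 5e-4)
  expect_gte(mean(errs < 0.005), 0.99)
})

test_that("overlapping plot polygons are rejected with the offending ids", {
  cfg <- small_config(raster = list(n_genotypes = 4), seed = 29)
  tr <- simulate_trial(cfg)
  p1 <- tr$layout$plots$plot[1]
  p2 <- tr$layout$plots$plot[2]
  tr$layout$polygons[[p2]] <- tr$layout$polygons[[p1]] + 1
  expect_error(render_band_stacks(tr, cfg), "overlapping")
})
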