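#' Construct a band stack
#'
#' A band stack is one flight's co-registered reflectance rasters. Bands are
#' numeric matrices in row-major image orientation (row = y, column = x); the
#' pixel in row i, column j has its center at x = j - 0.5, y = i - 0.5 in
#' raster pixel coordinates (plus \code{origin}). Reflectance is stored as
#' floating point on the 0--1 scale; integer-valued 8-bit input (values > 1)
#' is rescaled by 1/255.
#'
#' @param bands named list of numeric matrices; names from
#'   \code{c("R","G","B","RE","NIR")}.
#' @param flight_day integer days after planting.
#' @param resolution ground distance per pixel (arbitrary units).
#' @param origin numeric length-2, spatial anchor of pixel (0, 0).
#' @return an object of class \code{"band_stack"}.
#' @export
band_stack <- function(bands, flight_day, resolution = 1, origin = c(0, 0)) {
  stopifnot(is.list(bands), length(bands) >= 1)
  known <- c("R", "G", "B", "RE", "NIR")
  if (is.null(names(bands)) || !all(names(bands) %in% known))
    stop_("band names must be among %s", paste(known, collapse = ", "))
  dims <- lapply(bands, dim)
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1))))
    stop_("all band arrays must share identical shape")
  scale8 <- FALSE
  bands <- lapply(bands, function(m) {
    if (!all(is.finite(m))) stop_("reflectance values must be finite")
    if (max(m) > 1) { scale8 <<- TRUE; m / 255 } else m
  })
  structure(list(bands = bands, flight_day = as.integer(flight_day),
                 resolution = resolution, origin = origin,
                 rescaled_8bit = scale8),
            class = "band_stack")
}

#' @exportS3Method base::print
print.band_stack <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<band_stack> day %d, %dx%d px, bands: %s\n",
              x$flight_day, d[1], d[2], paste(names(x$bands), collapse = ",")))
  invisible(x)
}

#' Construct a field layout
#'
#' @param plots data.frame with columns \code{plot}, \code{genotype},
#'   \code{trial}, \code{rep}; one row per plot.
#' @param polygons named list (by plot id) of two-column matrices of polygon
#'   vertices (x, y) in raster pixel coordinates; polygons must be simple.
#' @return class \code{"field_layout"}.
#' @export
field_layout <- function(plots, polygons) {
  req <- c("plot", "genotype", "trial", "rep")
  miss <- setdiff(req, names(plots))
  if (length(miss)) stop_("layout plots missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(plots$plot)) stop_("plot ids must be unique")
  if (!all(plots$plot %in% names(polygons)))
    stop_("every plot needs a polygon; missing: %s",
          paste(setdiff(plots$plot, names(polygons)), collapse = ", "))
  for (id in plots$plot) {
    p <- polygons[[id]]
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3)
      stop_("polygon for plot %s must be a >=3-vertex two-column matrix", id)
  }
  structure(list(plots = plots, polygons = polygons), class = "field_layout")
}

# PNPOLY even-odd crossing test, vectorized over points. Half-open edge
# handling: a point on the shared edge of two adjacent polygons is claimed by
# exactly one of them (partition-safe), and the rule is deterministic.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# indices (row, col) of pixels whose centers fall inside the polygon
pixels_in_polygon <- function(dims, poly, origin = c(0, 0)) {
  nr <- dims[1]; nc <- dims[2]
  # restrict to the polygon's bounding box for speed
  xr <- range(poly[, 1]) - origin[1]
  yr <- range(poly[, 2]) - origin[2]
  cols <- seq(max(1L, floor(xr[1] + 0.5)), min(nc, ceiling(xr[2] + 0.5)))
  rows <- seq(max(1L, floor(yr[1] + 0.5)), min(nr, ceiling(yr[2] + 0.5)))
  if (!length(cols) || !length(rows) || xr[2] < 0 || yr[2] < 0 || xr[1] > nc || yr[1] > nr)
    return(cbind(row = integer(0), col = integer(0)))
  grid <- expand.grid(row = rows, col = cols)
  cx <- grid$col - 0.5 + origin[1]
  cy <- grid$row - 0.5 + origin[2]
  keep <- points_in_polygon(cx, cy, poly)
  cbind(row = grid$row[keep], col = grid$col[keep])
}

#' Compute a vegetation index over a band stack
#'
#' Evaluates the registered formula element-wise. Pixels where the formula is
#' undefined (division by zero, 0/0) are flagged missing (\code{NA}), never
#' infinite.
#'
#' @param stack a [band_stack()].
#' @param index_id registry identifier, e.g. \code{"NGRDI"}.
#' @param registry a [vi_registry()]; defaults to the full registry.
#' @return numeric matrix, same shape as the bands.
#' @examples
#' st <- band_stack(list(R = matrix(0.2, 2, 2), G = matrix(0.2, 2, 2),
#'                       B = matrix(0.2, 2, 2)), flight_day = 50)
#' compute_vi(st, "RCC")  # 1/3 everywhere
#' @export
compute_vi <- function(stack, index_id, registry = vi_registry()) {
  stopifnot(inherits(stack, "band_stack"))
  entry <- registry[[index_id]]
  if (is.null(entry))
    stop_("unknown index '%s'; available: %s", index_id,
          paste(names(registry), collapse = ", "))
  missing_bands <- setdiff(entry$bands, names(stack$bands))
  if (length(missing_bands))
    stop_("index %s requires missing band(s): %s", index_id,
          paste(missing_bands, collapse = ", "))
  out <- entry$fn(stack$bands)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Extract a plot-level value from a raster through a polygon
#'
#' Aggregates the pixels whose centers fall inside the polygon; missing pixels
#' are excluded. Errors distinguish a geometric miss (no pixel centers inside)
#' from an all-missing plot.
#'
#' @param array numeric matrix (e.g. a computed VI).
#' @param polygon two-column vertex matrix in raster pixel coordinates.
#' @param aggregator \code{"mean"} or \code{"median"}.
#' @param plot_id optional id used in error messages.
#' @param origin raster origin (anchor of pixel (0,0)).
#' @return scalar aggregate.
#' @export
extract_plot_value <- function(array, polygon, aggregator = c("mean", "median"),
                               plot_id = "<unnamed>", origin = c(0, 0)) {
  aggregator <- match.arg(aggregator)
  idx <- pixels_in_polygon(dim(array), polygon, origin)
  if (nrow(idx) == 0)
    stop_("plot %s: polygon contains no pixel centers (geometric miss)", plot_id)
  vals <- array[idx]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop_("plot %s: all pixels inside the polygon are missing", plot_id)
  if (aggregator == "mean") mean(vals) else stats::median(vals)
}

#' Extract percentile canopy height for a plot
#'
#' The stated percentile of in-plot heights, with the linear-interpolation
#' quantile convention (R quantile type 7). Default is the 99th percentile,
#' the usual canopy height measurement (CHM) definition for photogrammetric
#' height grids.
#'
#' @param height_grid numeric matrix of heights.
#' @param polygon,plot_id,origin as in [extract_plot_value()].
#' @param percentile percentile in \[0, 100\]; 100 gives the in-plot maximum.
#' @return scalar height.
#' @export
extract_canopy_height <- function(height_grid, polygon, percentile = 99,
                                  plot_id = "<unnamed>", origin = c(0, 0)) {
  stopifnot(percentile >= 0, percentile <= 100)
  idx <- pixels_in_polygon(dim(height_grid), polygon, origin)
  if (nrow(idx) == 0)
    stop_("plot %s: polygon contains no pixel centers (geometric miss)", plot_id)
  vals <- height_grid[idx]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop_("plot %s: all pixels inside the polygon are missing", plot_id)
  unname(stats::quantile(vals, probs = percentile / 100, type = 7))
}

#' Build a phenomic table from imagery
#'
#' Computes every panel index per flight, extracts plot values through the
#' layout polygons, and extracts percentile canopy heights from the height
#' grids, producing the long-format phenomic table consumed by the
#' flight-nested variance model.
#'
#' @param stacks list of [band_stack()], one per flight, strictly increasing
#'   \code{flight_day}.
#' @param height_grids optional list of height matrices parallel to
#'   \code{stacks} (named or positional); \code{NULL} drops CHM rows.
#' @param layout a [field_layout()].
#' @param panel character vector of registry index ids (may be empty for a
#'   CHM-only table).
#' @param registry a [vi_registry()].
#' @param aggregator plot aggregator for VI extraction.
#' @param chm_percentile percentile for canopy height.
#' @return data.frame with columns trial, flight_day, rep, plot, genotype,
#'   trait_id, value.
#' @export
build_phenomic_table <- function(stacks, height_grids = NULL, layout, panel,
                                 registry = vi_registry(),
                                 aggregator = "mean", chm_percentile = 99) {
  stopifnot(inherits(layout, "field_layout"))
  days <- vapply(stacks, function(s) s$flight_day, integer(1))
  if (anyDuplicated(days)) stop_("duplicated flight_day: %s",
                                 paste(days[duplicated(days)], collapse = ", "))
  if (is.unsorted(days, strictly = TRUE)) stop_("flight_days must be strictly increasing")
  if (!is.null(height_grids) && length(height_grids) != length(stacks))
    stop_("height_grids must parallel stacks (one per flight)")
  rows <- list()
  for (f in seq_along(stacks)) {
    st <- stacks[[f]]
    vi_arrays <- lapply(panel, function(id) compute_vi(st, id, registry))
    names(vi_arrays) <- panel
    for (k in seq_len(nrow(layout$plots))) {
      pl <- layout$plots[k, ]
      poly <- layout$polygons[[pl$plot]]
      for (id in panel) {
        val <- extract_plot_value(vi_arrays[[id]], poly, aggregator,
                                  plot_id = pl$plot, origin = st$origin)
        rows[[length(rows) + 1L]] <- data.frame(
          trial = pl$trial, flight_day = days[f], rep = pl$rep, plot = pl$plot,
          genotype = pl$genotype, trait_id = id, value = val,
          stringsAsFactors = FALSE)
      }
      if (!is.null(height_grids)) {
        val <- extract_canopy_height(height_grids[[f]], poly, chm_percentile,
                                     plot_id = pl$plot, origin = st$origin)
        rows[[length(rows) + 1L]] <- data.frame(
          trial = pl$trial, flight_day = days[f], rep = pl$rep, plot = pl$plot,
          genotype = pl$genotype, trait_id = "CHM", value = val,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Optional ExG soil mask
#'
#' Returns a logical matrix marking vegetation pixels (ExG above threshold).
#' No mask is applied by default anywhere in the pipeline; this helper exists
#' for users who want one.
#'
#' @param stack a [band_stack()] with R, G, B.
#' @param threshold ExG threshold; pixels at or below it are soil.
#' @export
exg_soil_mask <- function(stack, threshold = 0.05) {
  compute_vi(stack, "ExG") > threshold
}
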