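# Readers/writers for the on-disk formats. One pinned dialect everywhere:
# tab-separated, UTF-8, '.' decimal, explicit "NA" for missing.

write_tsv_ <- function(df, path, rownames_col = NULL) {
  if (!is.null(rownames_col)) {
    df <- cbind(stats::setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                                rownames_col),
                as.data.frame(df, check.names = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_ <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  utils::read.delim(path, sep = "\t", na.strings = "NA", check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write / read a phenomic table
#'
#' Long format, columns \code{trial, flight_day, rep, plot, genotype,
#' trait_id, value}. The reader also accepts wide input (one column per
#' flight, integer-like column names) and melts it, accepts a column-name
#' mapping for foreign dialects, normalizes calendar-date flight identifiers
#' to integer days after planting when \code{planting_date} is given, and
#' rejects duplicated (trial, plot, flight_day, trait_id) keys.
#'
#' @param table phenomic data.frame.
#' @param path file path.
#' @export
write_phenomic_table <- function(table, path) {
  req <- c("trial", "flight_day", "rep", "plot", "genotype", "trait_id", "value")
  miss <- setdiff(req, names(table))
  if (length(miss)) stop_("phenomic table missing columns: %s", paste(miss, collapse = ", "))
  write_tsv_(table[, req], path)
}

#' @rdname write_phenomic_table
#' @param col_map optional named character vector mapping the standard
#'   column names to the file's column names, e.g.
#'   \code{c(genotype = "Hybrid")}.
#' @param planting_date optional \code{Date} (or string) used to convert
#'   calendar-date flight identifiers to days after planting.
#' @export
read_phenomic_table <- function(path, col_map = NULL, planting_date = NULL) {
  df <- read_tsv_(path)
  if (!is.null(col_map))
    for (std in names(col_map))
      names(df)[names(df) == col_map[[std]]] <- std
  req <- c("trial", "flight_day", "rep", "plot", "genotype", "trait_id", "value")
  if (!all(req %in% names(df))) {
    # wide candidate: one column per flight
    base <- c("trial", "rep", "plot", "genotype", "trait_id")
    flight_cols <- setdiff(names(df), base)
    parsed <- suppressWarnings(as.integer(gsub("[^0-9]", "", flight_cols)))
    if (all(base %in% names(df)) && length(flight_cols) >= 2 && !anyNA(parsed)) {
      long <- do.call(rbind, lapply(seq_along(flight_cols), function(j) {
        out <- df[, base]
        out$flight_day <- parsed[j]
        out$value <- df[[flight_cols[j]]]
        out
      }))
      df <- long[, req]
    } else {
      stop_("missing required columns; expected %s (long) or %s plus one column per flight (wide)",
            paste(req, collapse = ", "), paste(base, collapse = ", "))
    }
  }
  # normalize flight identifiers to integer days after planting
  fd <- df$flight_day
  if (!is.numeric(fd)) {
    as_date <- suppressWarnings(as.Date(as.character(fd)))
    if (!anyNA(as_date)) {
      if (is.null(planting_date))
        stop_("flight_day holds calendar dates; pass planting_date to convert")
      fd <- as.integer(as_date - as.Date(planting_date))
    } else {
      fd <- suppressWarnings(as.integer(gsub("[^0-9-]", "", as.character(fd))))
      if (anyNA(fd)) stop_("cannot parse flight_day identifiers")
    }
  }
  df$flight_day <- as.integer(fd)
  key <- paste(df$trial, df$plot, df$flight_day, df$trait_id)
  if (anyDuplicated(key))
    stop_("duplicated (trial, plot, flight, trait) rows, first: %s",
          key[duplicated(key)][1])
  df$value <- as.numeric(df$value)
  df[, req]
}

#' Write / read a marker dosage table
#'
#' Plain-matrix dialect: genotypes x markers, first column \code{genotype},
#' header row of marker ids. The reader also accepts a HapMap-style layout
#' (marker-major rows with \code{marker/alleles/chrom/pos} metadata columns
#' followed by one column per genotype) and transposes it. Dosages must be
#' in \{0, 1, 2\} or missing; missing cells are imputed to the per-marker
#' mean dosage with a message; non-numeric or non-biallelic codes fail with
#' the offending cell's coordinates.
#'
#' @param markers \code{marker_set} or dosage matrix.
#' @param path file path.
#' @export
write_marker_table <- function(markers, path) {
  X <- if (inherits(markers, "marker_set")) markers$dosages else as.matrix(markers)
  write_tsv_(X, path, rownames_col = "genotype")
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  df <- read_tsv_(path)
  meta_names <- c("marker", "rs", "rs#", "alleles", "chrom", "pos", "strand")
  is_hapmap <- tolower(names(df)[1]) %in% c("marker", "rs", "rs#") &&
    any(tolower(names(df)) %in% c("chrom", "pos"))
  map <- NULL
  if (is_hapmap) {
    meta <- names(df)[tolower(names(df)) %in% meta_names]
    genos <- setdiff(names(df), meta)
    markers_id <- as.character(df[[1]])
    X <- t(as.matrix(df[, genos, drop = FALSE]))
    colnames(X) <- markers_id
    rownames(X) <- genos
    if (all(c("chrom", "pos") %in% tolower(names(df)))) {
      cn <- names(df)[match(c("chrom", "pos"), tolower(names(df)))]
      map <- data.frame(marker = markers_id, chrom = df[[cn[1]]],
                        pos = df[[cn[2]]], stringsAsFactors = FALSE)
    }
  } else {
    if (tolower(names(df)[1]) != "genotype")
      stop_("expected first column 'genotype' (plain matrix) or 'marker' (HapMap-style)")
    X <- as.matrix(df[, -1, drop = FALSE])
    rownames(X) <- as.character(df[[1]])
  }
  na_before <- is.na(X)
  suppressWarnings(storage.mode(X) <- "numeric")
  # cells that became NA in coercion were non-numeric codes, not missing
  bad <- which((is.na(X) & !na_before) | (!is.na(X) & !(X %in% c(0, 1, 2))),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_("non-biallelic or non-numeric dosage at genotype '%s', marker '%s'",
          rownames(X)[bad[1, 1]], colnames(X)[bad[1, 2]])
  n_missing <- sum(is.na(X))
  if (n_missing > 0) {
    message(sprintf("imputing %d missing dosages to per-marker means", n_missing))
    for (j in which(colSums(is.na(X)) > 0)) {
      mu <- mean(X[, j], na.rm = TRUE)
      X[is.na(X[, j]), j] <- mu
    }
  }
  p <- colMeans(X) / 2
  structure(list(dosages = X, parent_dosages = NULL, pedigree = NULL,
                 map = map, maf = pmin(p, 1 - p)),
            class = "marker_set")
}

#' Write / read a genotype-level trait table
#' @param traits data.frame with columns trial, genotype and one column per
#'   trait.
#' @param path file path.
#' @export
write_trait_table <- function(traits, path) write_tsv_(traits, path)

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) read_tsv_(path)

#' Write / read a feature matrix
#' @param features [assemble_feature_matrix()] result.
#' @param path file path.
#' @export
write_feature_matrix <- function(features, path) {
  write_tsv_(unclass(features), path, rownames_col = "genotype")
}

#' @rdname write_feature_matrix
#' @param platform platform label restored on read.
#' @export
read_feature_matrix <- function(path, platform = "TPP_RGB") {
  df <- read_tsv_(path)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- as.character(df[[1]])
  structure(X, platform = platform,
            n_temporal = sum(grepl("@", colnames(X))),
            class = c("feature_matrix", "matrix", "array"))
}

#' Write / read a genotype x flight matrix (BLUPs, heights)
#' @param mat matrix with genotype rownames and flight-day column names.
#' @param path file path.
#' @export
write_blup_matrix <- function(mat, path) write_tsv_(mat, path, rownames_col = "genotype")

#' @rdname write_blup_matrix
#' @export
read_blup_matrix <- function(path) {
  df <- read_tsv_(path)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- as.character(df[[1]])
  X
}

#' Write / read a split plan as JSON (seed plus explicit id lists)
#' @param plan a [make_split_plan()] result.
#' @param path file path.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  jsonlite::write_json(
    list(genotypes = plan$genotypes, train_frac = plan$train_frac,
         n_iter = plan$n_iter, seed = plan$seed,
         iterations = lapply(plan$iterations, function(it)
           list(train = it$train, test = it$test))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  iterations <- lapply(seq_len(j$n_iter), function(i)
    list(train = as.character(j$iterations$train[[i]]),
         test = as.character(j$iterations$test[[i]])))
  plan <- list(genotypes = as.character(j$genotypes), train_frac = j$train_frac,
               n_iter = as.integer(j$n_iter), seed = j$seed,
               iterations = iterations)
  plan$fingerprint <- plan_fingerprint(plan)
  structure(plan, class = "split_plan")
}

#' Write / read a field layout as GeoJSON
#'
#' Polygon coordinates are raster pixel coordinates unless a CRS is declared
#' in the file; plot, genotype, trial and rep ride along as feature
#' properties.
#'
#' @param layout a [field_layout()].
#' @param path file path.
#' @export
write_layout_geojson <- function(layout, path) {
  stopifnot(inherits(layout, "field_layout"))
  features <- lapply(seq_len(nrow(layout$plots)), function(k) {
    pl <- layout$plots[k, ]
    poly <- layout$polygons[[pl$plot]]
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(plot = pl$plot, genotype = pl$genotype,
                           trial = pl$trial, rep = pl$rep),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)), function(i)
                           c(ring[i, 1], ring[i, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_geojson
#' @export
read_layout_geojson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(j$type, "FeatureCollection")) stop_("not a GeoJSON FeatureCollection")
  plots <- list(); polys <- list()
  for (ft in j$features) {
    pr <- ft$properties
    ring <- ft$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    plots[[length(plots) + 1L]] <- data.frame(
      plot = pr$plot, genotype = pr$genotype, trial = pr$trial, rep = pr$rep,
      stringsAsFactors = FALSE)
    polys[[pr$plot]] <- m
  }
  field_layout(do.call(rbind, plots), polys)
}

#' Write / read a band stack as multi-page TIFF plus JSON sidecar
#'
#' One 32-bit float page per band; the sidecar (same path with
#' \code{.json} appended) records band order, flight day, resolution and
#' origin.
#'
#' @param stack a [band_stack()].
#' @param path file path (.tif).
#' @export
write_band_stack <- function(stack, path) {
  stopifnot(inherits(stack, "band_stack"))
  tiff::writeTIFF(unname(stack$bands), path, bits.per.sample = 32)
  jsonlite::write_json(list(bands = names(stack$bands),
                            flight_day = stack$flight_day,
                            resolution = stack$resolution,
                            origin = stack$origin,
                            scale = "reflectance_0_1"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_band_stack
#' @param band_order band names overriding the sidecar (for foreign files).
#' @export
read_band_stack <- function(path, band_order = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(bands = band_order, flight_day = NA_integer_,
                    resolution = 1, origin = c(0, 0))
  bands <- band_order %||% meta$bands
  if (is.null(bands) || length(bands) != length(pages))
    stop_("band order unknown; pass band_order (file has %d pages)", length(pages))
  band_stack(stats::setNames(pages, bands),
             flight_day = meta$flight_day %||% NA_integer_,
             resolution = meta$resolution %||% 1,
             origin = unlist(meta$origin) %||% c(0, 0))
}

#' Write / read a single-band height grid as TIFF
#' @param grid numeric matrix of heights.
#' @param path file path (.tif).
#' @param scale heights are stored divided by \code{scale} to fit TIFF's
#'   0-1 float convention; recorded in the sidecar.
#' @export
write_height_grid <- function(grid, path, scale = max(grid, 1)) {
  tiff::writeTIFF(grid / scale, path, bits.per.sample = 32)
  jsonlite::write_json(list(scale = scale), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_height_grid
#' @export
read_height_grid <- function(path) {
  g <- tiff::readTIFF(path)
  side <- paste0(path, ".json")
  scale <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE)$scale else 1
  g * scale
}
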