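#' @include AllClasses.R AllGenerics.R raster.R sampling.R accuracy.R
NULL

#' Write / read a raster as an Esri ASCII grid
#'
#' Plain-text georeferenced raster format: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed
#' by rows of values, top row first. Values are written in full precision;
#' integer-valued rasters round-trip exactly.
#'
#' @param x A [ClassRaster-class] (or subclass).
#' @param path Output path (conventionally `.asc`).
#' @param nodata Nodata code to write for `NA` (default 255 suits byte-coded
#'   class maps; it must not collide with a real value).
#' @return `writeAsciiGrid` returns `path` invisibly; `readAsciiGrid`
#'   returns a [ClassRaster-class].
#' @export
writeAsciiGrid <- function(x, path, nodata = 255) {
  stopifnot(is(x, "ClassRaster"))
  g <- x@grid
  v <- x@values
  if (any(!is.na(v) & v == nodata)) {
    stop("nodata code collides with a raster value")
  }
  v[is.na(v)] <- nodata
  ext <- gridExtent(g)
  hdr <- c(sprintf("ncols %d", g@ncol),
           sprintf("nrows %d", g@nrow),
           sprintf("xllcorner %.10g", ext["xmin"]),
           sprintf("yllcorner %.10g", ext["ymin"]),
           sprintf("cellsize %.10g", g@pixel),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1L, function(row)
    paste(formatC(row, format = "g", digits = 15), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @param crs CRS label to attach on read.
#' @export
readAsciiGrid <- function(path, crs = "local") {
  lines <- readLines(path)
  if (length(lines) < 7L) stop(sprintf("'%s': not an ASCII grid", path))
  hdr <- lines[1:6]
  keys <- tolower(vapply(strsplit(hdr, "\\s+"), `[`, character(1), 1L))
  vals <- suppressWarnings(
    as.numeric(vapply(strsplit(hdr, "[ \t]+"), `[`, character(1), 2L)))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys) || any(is.na(vals))) {
    stop(sprintf("'%s': malformed ASCII grid header (line: %s)", path,
                 hdr[which(is.na(vals) | !(keys %in% need))[1L]]))
  }
  nr <- as.integer(vals["nrows"])
  nc <- as.integer(vals["ncols"])
  body <- lines[-(1:6)]
  if (length(body) != nr) {
    stop(sprintf("'%s': expected %d data rows, found %d", path, nr,
                 length(body)))
  }
  v <- t(vapply(strsplit(trimws(body), "\\s+"),
                function(z) as.numeric(z), numeric(nc)))
  v <- matrix(v, nrow = nr, ncol = nc)
  v[v == vals["nodata_value"]] <- NA
  g <- gridSpecNew(vals["xllcorner"],
                   vals["yllcorner"] + nr * vals["cellsize"],
                   vals["cellsize"], nr, nc, crs)
  classRaster(g, v)
}

#' Write / read a BinaryCropMap (ASCII grid + JSON metadata sidecar)
#'
#' The raster goes to `path` as an Esri ASCII grid; product metadata (name,
#' native resolution, nominal year, CRS) goes to `paste0(path, ".json")`.
#'
#' @param x A [BinaryCropMap-class].
#' @param path Raster path.
#' @return `writeCropMap` returns `path` invisibly; `readCropMap` a
#'   [BinaryCropMap-class].
#' @export
writeCropMap <- function(x, path) {
  stopifnot(is(x, "BinaryCropMap"))
  writeAsciiGrid(x, path)
  meta <- list(name = x@metadata@name,
               native_resolution = x@metadata@nativeResolution,
               nominal_year = x@metadata@nominalYear,
               crs = x@grid@crs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeCropMap
#' @export
readCropMap <- function(path) {
  metaPath <- paste0(path, ".json")
  meta <- if (file.exists(metaPath)) {
    jsonlite::read_json(metaPath)
  } else {
    list(name = basename(path), native_resolution = NA, nominal_year = 0,
         crs = "local")
  }
  r <- readAsciiGrid(path, crs = meta$crs %||% "local")
  res <- meta$native_resolution
  if (is.null(res) || is.na(res)) res <- r@grid@pixel
  binaryCropMap(r@grid, r@values,
                mapMetadata(meta$name, res, meta$nominal_year))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an NDVI cube (one ASCII grid per band + JSON index)
#'
#' @param x An [NDVICube-class].
#' @param prefix Path prefix; bands become `<prefix>_b01.asc` etc. and the
#'   band index `<prefix>.json`.
#' @export
writeNdviCube <- function(x, prefix) {
  stopifnot(is(x, "NDVICube"))
  nT <- dim(x@values)[3L]
  paths <- sprintf("%s_b%02d.asc", prefix, seq_len(nT))
  for (k in seq_len(nT)) {
    writeAsciiGrid(classRaster(x@grid, x@values[, , k]), paths[k],
                   nodata = -9999)
  }
  jsonlite::write_json(list(dates = x@dates, bands = basename(paths),
                            crs = x@grid@crs),
                       paste0(prefix, ".json"), digits = NA)
  invisible(prefix)
}

#' @rdname writeNdviCube
#' @export
readNdviCube <- function(prefix) {
  idx <- jsonlite::read_json(paste0(prefix, ".json"),
                             simplifyVector = TRUE)
  bands <- file.path(dirname(prefix), idx$bands)
  first <- readAsciiGrid(bands[1L], crs = idx$crs %||% "local")
  g <- first@grid
  arr <- array(NA_real_, dim = c(g@nrow, g@ncol, length(bands)))
  arr[, , 1L] <- first@values
  for (k in seq_along(bands)[-1L]) {
    arr[, , k] <- readAsciiGrid(bands[k])@values
  }
  new("NDVICube", grid = g, values = arr, dates = as.integer(idx$dates))
}

#' Write / read reference points as GeoJSON
#'
#' Points become a GeoJSON FeatureCollection (one Point feature per row;
#' labels, truth and final label as properties; region/year/design as
#' top-level foreign members).
#'
#' @param x A [ReferenceDataset-class].
#' @param path Output path.
#' @export
writeReferenceGeoJSON <- function(x, path) {
  stopifnot(is(x, "ReferenceDataset"))
  p <- x@points
  propCols <- setdiff(names(p), c("x", "y"))
  features <- lapply(seq_len(nrow(p)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(p$x[i], p$y[i])),
         properties = as.list(p[i, propCols, drop = FALSE]))
  })
  obj <- list(type = "FeatureCollection", region = x@region,
              year = x@year, design = x@design, features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeReferenceGeoJSON
#' @export
readReferenceGeoJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$type) || obj$type != "FeatureCollection") {
    stop(sprintf("'%s': not a GeoJSON FeatureCollection", path))
  }
  rows <- lapply(obj$features, function(f) {
    if (is.null(f$geometry) || f$geometry$type != "Point") {
      stop(sprintf("'%s': feature without Point geometry (id: %s)", path,
                   f$properties$id %||% "?"))
    }
    cbind(data.frame(x = f$geometry$coordinates[[1L]],
                     y = f$geometry$coordinates[[2L]]),
          as.data.frame(f$properties))
  })
  p <- do.call(rbind, rows)
  p <- p[c("id", "x", "y", setdiff(names(p), c("id", "x", "y")))]
  new("ReferenceDataset", region = obj$region %||% "region",
      year = as.integer(obj$year %||% 0L), points = p,
      design = obj$design %||% "uniform")
}

#' Write / read reference points as flat CSV
#'
#' Columns: `region`, `year`, `design`, then the point table.
#'
#' @param x A [ReferenceDataset-class].
#' @param path Output path.
#' @export
writeReferenceCsv <- function(x, path) {
  stopifnot(is(x, "ReferenceDataset"))
  df <- cbind(data.frame(region = x@region, year = x@year,
                         design = x@design), x@points)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReferenceCsv
#' @export
readReferenceCsv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("region", "year", "design", "id", "x", "y", "final_label")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("'%s': missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  }
  new("ReferenceDataset", region = df$region[1L],
      year = as.integer(df$year[1L]),
      points = df[setdiff(names(df), c("region", "year", "design"))],
      design = df$design[1L])
}

#' Write / read a boundary polygon as GeoJSON
#'
#' @param rings Two-column matrix or list of ring matrices.
#' @param path Output path.
#' @export
writeBoundaryGeoJSON <- function(rings, path) {
  rl <- if (is.list(rings)) rings else list(rings)
  closed <- lapply(rl, function(r) {
    r <- as.matrix(r)
    if (!all(r[1L, ] == r[nrow(r), ])) r <- rbind(r, r[1L, ])
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1L], r[i, 2L]))
  })
  obj <- list(type = "Feature",
              geometry = list(type = "Polygon", coordinates = closed),
              properties = list())
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBoundaryGeoJSON
#' @export
readBoundaryGeoJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = TRUE)
  geom <- if (!is.null(obj$geometry)) obj$geometry else obj
  if (is.null(geom$type) || !geom$type %in% c("Polygon", "MultiPolygon")) {
    stop(sprintf("'%s': not a (Multi)Polygon GeoJSON", path))
  }
  coords <- geom$coordinates
  if (geom$type == "Polygon") {
    lapply(seq_len(dim(coords)[1L] %||% length(coords)), function(i) {
      if (is.array(coords)) coords[i, , ] else as.matrix(coords[[i]])
    })
  } else {
    unlist(lapply(coords, function(poly) {
      lapply(poly, as.matrix)
    }), recursive = FALSE)
  }
}

#' Write / read a long-format metric table as CSV
#' @param x Data frame from [evaluationTable()].
#' @param path Output path.
#' @export
writeMetricTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMetricTable
#' @export
readMetricTable <- function(path) {
  df <- utils::read.csv(path)
  need <- c("map", "region", "metric", "value", "se")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("'%s': missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  }
  df
}

#' Write a named square matrix (agreement / rank) as CSV with headers
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @export
writeMatrixCsv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeMatrixCsv
#' @export
readMatrixCsv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' Serialize / parse a scenario as a flat key=value config
#'
#' Products are encoded one per line as
#' `product_<k> = name,resolution,year,omission,commission`. The same text
#' is echoed verbatim into the run manifest.
#'
#' @param scenario A [SyntheticScenario-class].
#' @return Character vector of `key = value` lines.
#' @export
scenarioConfigLines <- function(scenario) {
  s <- scenario
  g <- s@grid
  np <- s@ndviParams
  lines <- c(
    sprintf("seed = %d", s@seed),
    sprintf("region_name = %s", s@regionName),
    sprintf("reference_year = %d", s@referenceYear),
    sprintf("grid_xmin = %.10g", g@xmin),
    sprintf("grid_ymax = %.10g", g@ymax),
    sprintf("grid_pixel = %.10g", g@pixel),
    sprintf("grid_nrow = %d", g@nrow),
    sprintf("grid_ncol = %d", g@ncol),
    sprintf("grid_crs = %s", g@crs),
    sprintf("crop_fraction = %.10g", s@cropFraction),
    sprintf("smooth_scale = %.10g", s@smoothScale),
    sprintf("n_reference_points = %d", s@nReferencePoints),
    sprintf("interpreters_per_point = %d", s@interpretersPerPoint),
    sprintf("label_noise_rate = %.10g", s@labelNoiseRate),
    sprintf("ndvi_crop_baseline = %.10g", np$cropBaseline),
    sprintf("ndvi_crop_amplitude = %.10g", np$cropAmplitude),
    sprintf("ndvi_noncrop_baseline = %.10g", np$noncropBaseline),
    sprintf("ndvi_noncrop_amplitude = %.10g", np$noncropAmplitude),
    sprintf("ndvi_noise_sd = %.10g", np$noiseSd),
    sprintf("ndvi_n_timesteps = %d", np$nTimesteps))
  for (k in seq_along(s@products)) {
    p <- s@products[[k]]
    lines <- c(lines, sprintf("product_%d = %s,%.10g,%d,%.10g,%.10g", k,
                              p@name, p@nativeResolution, p@nominalYear,
                              p@omissionRate, p@commissionRate))
  }
  lines
}

#' @rdname scenarioConfigLines
#' @param path File of `key = value` lines.
#' @export
writeScenarioConfig <- function(scenario, path) {
  writeLines(scenarioConfigLines(scenario), path)
  invisible(path)
}

#' @rdname scenarioConfigLines
#' @export
readScenarioConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines,
                   regexec("^[ \t]*([A-Za-z0-9_.]+)[ \t]*=[ \t]*(.*)$",
                           lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) {
    stop(sprintf("'%s': malformed config line: %s", path,
                 lines[which(bad)[1L]]))
  }
  vals <- vapply(kv, `[`, character(1), 3L)
  names(vals) <- vapply(kv, `[`, character(1), 2L)
  num <- function(k) as.numeric(vals[[k]])
  products <- lapply(grep("^product_", names(vals), value = TRUE),
                     function(k) {
    f <- strsplit(vals[[k]], ",")[[1L]]
    if (length(f) != 5L) {
      stop(sprintf("'%s': malformed product record: %s", path, vals[[k]]))
    }
    productSpec(f[1L], as.numeric(f[2L]), as.integer(f[3L]),
                as.numeric(f[4L]), as.numeric(f[5L]))
  })
  syntheticScenario(
    seed = num("seed"),
    grid = gridSpecNew(num("grid_xmin"), num("grid_ymax"),
                       num("grid_pixel"), num("grid_nrow"),
                       num("grid_ncol"), vals[["grid_crs"]]),
    cropFraction = num("crop_fraction"),
    products = products,
    nReferencePoints = num("n_reference_points"),
    interpretersPerPoint = num("interpreters_per_point"),
    labelNoiseRate = num("label_noise_rate"),
    smoothScale = num("smooth_scale"),
    ndviParams = list(cropBaseline = num("ndvi_crop_baseline"),
                      cropAmplitude = num("ndvi_crop_amplitude"),
                      noncropBaseline = num("ndvi_noncrop_baseline"),
                      noncropAmplitude = num("ndvi_noncrop_amplitude"),
                      noiseSd = num("ndvi_noise_sd"),
                      nTimesteps = as.integer(num("ndvi_n_timesteps"))),
    regionName = vals[["region_name"]],
    referenceYear = num("reference_year"))
}
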