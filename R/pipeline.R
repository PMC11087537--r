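#' @include AllClasses.R AllGenerics.R io.R synthetic.R agreement.R correlates.R
NULL

#' Construct a RunConfig
#'
#' @param scenario A [SyntheticScenario-class], or `NULL` when running on
#'   files.
#' @param inputs Named list of paths (`maps` = character vector of crop-map
#'   rasters, `boundary` = GeoJSON polygon, `points` = reference CSV), or
#'   empty when `scenario` is given.
#' @param commonResolution Common analysis resolution (map units/pixel);
#'   defaults to the scenario grid's pixel size.
#' @param majorityThreshold Minimum crop votes for the ensemble (`NA` =
#'   strict majority).
#' @param varianceMode `"printed"` or `"standard"`.
#' @param outputDir Where [runPipeline()] writes its artifact bundle.
#' @param seed Run seed.
#' @return A [RunConfig-class].
#' @export
runConfig <- function(scenario = NULL, inputs = list(),
                      commonResolution = NULL, majorityThreshold = NA,
                      varianceMode = "printed", outputDir = tempfile("run"),
                      seed = 1L) {
  if (is.null(commonResolution)) {
    if (is.null(scenario)) stop("commonResolution is required with file inputs")
    commonResolution <- scenario@grid@pixel
  }
  new("RunConfig", scenario = scenario, inputs = inputs,
      commonResolution = as.numeric(commonResolution),
      majorityThreshold = as.numeric(majorityThreshold),
      varianceMode = varianceMode, outputDir = outputDir,
      seed = as.integer(seed))
}

# rectangle ring covering a grid's extent
extentPolygon <- function(grid) {
  e <- gridExtent(grid)
  rbind(c(e["xmin"], e["ymin"]), c(e["xmax"], e["ymin"]),
        c(e["xmax"], e["ymax"]), c(e["xmin"], e["ymax"]),
        c(e["xmin"], e["ymin"]))
}

#' Run the full intercomparison pipeline
#'
#' For a synthetic scenario: simulates the truth landscape and degraded
#' product maps, harmonizes them to the common grid, draws and labels a
#' reference sample, applies the unanimity filter, evaluates every map (and
#' the majority-vote ensemble) with design-based standard errors, computes
#' the consensus raster and its summary, pairwise agreement and rank
#' matrices, metric/covariate correlations, and masked NDVI series — and
#' writes the whole bundle (CSV tables, ASCII-grid rasters, GeoJSON points
#' and a manifest echoing the configuration) to `outputDir`. Running the
#' same config twice yields byte-identical outputs. For file inputs, reads
#' maps, boundary and points and runs the same evaluation/consensus stages.
#'
#' @param config A [RunConfig-class].
#' @return Invisibly, a list with the in-memory results (`evaluations`,
#'   `table`, `consensus`, `consensusSummary`, `agreement`, `rank`,
#'   `majority`, `correlations`, `ndviSeries`, `dataset`).
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  result <- tryCatch({
    if (!is.null(config@scenario)) {
      runSyntheticPipeline(config)
    } else {
      runFilePipeline(config)
    }
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s",
                 attr(e, "stage") %||% stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(result)
}

stageStop <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    attr(e, "stage") <- stage
    stop(e)
  })
}

runSyntheticPipeline <- function(config) {
  s <- config@scenario
  out <- config@outputDir

  truth <- stageStop("simulate", generateTrueLandscape(s))
  boundary <- extentPolygon(truth@grid)

  # common analysis grid over the same extent
  e <- gridExtent(truth@grid)
  res <- config@commonResolution
  common <- gridSpecNew(e["xmin"], e["ymax"], res,
                        round((e["ymax"] - e["ymin"]) / res),
                        round((e["xmax"] - e["xmin"]) / res),
                        truth@grid@crs)

  native <- stageStop("simulate", lapply(seq_along(s@products), function(k) {
    degradeMap(truth, s@products[[k]], s@seed + 1000L + k)
  }))
  maps <- stageStop("harmonize", lapply(native, function(m) {
    clipToBoundary(resampleToGrid(m, common), boundary)
  }))
  maps <- orderMapsByResolution(maps)

  # reference sample, labels, unanimity filter
  dataset <- stageStop("sample", {
    loc <- sampleUniform(boundary, s@nReferencePoints, s@seed + 1L)
    truthLab <- extractAt(truth, loc$x, loc$y)
    labs <- generateInterpreterLabels(truthLab, s@interpretersPerPoint,
                                      s@labelNoiseRate, s@seed + 2L)
    ds <- consensusFilter(referencePoints(loc, labs, truth = truthLab),
                          region = s@regionName, year = s@referenceYear)
    message(sprintf("unanimity filter: retained %d of %d points",
                    nrow(refPoints(ds)), s@nReferencePoints))
    ds
  })

  evals <- stageStop("evaluate", lapply(maps, function(m)
    evaluateMap(m, dataset, varianceMode = config@varianceMode)))

  cr <- stageStop("agree", consensusRaster(maps))
  thr <- if (is.na(config@majorityThreshold)) NULL else
    config@majorityThreshold
  mv <- majorityVote(cr, thr)
  evals <- c(evals, list(
    evaluateMap(mv, dataset, varianceMode = config@varianceMode)))
  crSummary <- consensusSummary(cr)
  agree <- pairwiseAgreement(maps)
  mr <- meanAndRankMatrices(list(agree))

  correlations <- stageStop("correlate", {
    perMap <- vapply(evals[seq_along(maps)],
                     function(e) metricValue(e), numeric(4))
    meta <- lapply(maps, mapMeta)
    if (length(maps) >= 3L) {
      do.call(rbind, lapply(seq_len(4L), function(r) {
        metricName <- c("overall_accuracy", "users_accuracy",
                        "producers_accuracy", "f1")[r]
        vals <- perMap[r, ]
        names(vals) <- vapply(maps, mapName, character(1))
        rbind(
          corRow(metricName, vals, meta, "resolution", s@referenceYear),
          corRow(metricName, vals, meta, "temporal_mismatch",
                 s@referenceYear))
      }))
    } else {
      NULL
    }
  })

  ndvi <- stageStop("ndvi", generateNdviCube(s, truth))
  ndviSeries <- stageStop("ndvi", {
    do.call(rbind, lapply(c(list(truth), maps), function(m) {
      mres <- resampleToGrid(m, ndvi@grid)
      ser <- maskedNdviSeries(ndvi, mres, boundary)
      ser$mask <- mapName(m)
      ser$region <- s@regionName
      ser
    }))
  })

  tab <- evaluationTable(evals)
  stageStop("report", {
    writeMetricTable(tab, file.path(out, "evaluations.csv"))
    utils::write.csv(cbind(region = s@regionName, crSummary),
                     file.path(out, "consensus_summary.csv"),
                     row.names = FALSE)
    writeMatrixCsv(mr$mean, file.path(out, "agreement_mean.csv"))
    writeMatrixCsv(mr$rank, file.path(out, "agreement_rank.csv"))
    writeAsciiGrid(cr, file.path(out, "consensus.asc"))
    writeCropMap(mv, file.path(out, "majority_vote.asc"))
    writeCropMap(truth, file.path(out, "truth.asc"))
    if (!is.null(correlations)) {
      utils::write.csv(correlations, file.path(out, "correlations.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(ndviSeries, file.path(out, "ndvi_series.csv"),
                     row.names = FALSE)
    writeReferenceCsv(dataset, file.path(out, "reference_points.csv"))
    writeReferenceGeoJSON(dataset,
                          file.path(out, "reference_points.geojson"))
    writeManifest(config, file.path(out, "manifest.txt"))
  })

  list(evaluations = evals, table = tab, consensus = cr,
       consensusSummary = crSummary, agreement = agree, rank = mr$rank,
       majority = mv, correlations = correlations,
       ndviSeries = ndviSeries, dataset = dataset)
}

corRow <- function(metricName, vals, meta, covariate, referenceYear) {
  res <- metricCovariateCorrelation(vals, meta, covariate,
                                    referenceYear = referenceYear)
  data.frame(metric = metricName, covariate = covariate,
             r = res$r, n = res$n,
             excluded = paste(res$excluded, collapse = ";"))
}

runFilePipeline <- function(config) {
  inp <- config@inputs
  out <- config@outputDir
  maps <- stageStop("read", lapply(inp$maps, readCropMap))
  boundary <- stageStop("read", readBoundaryGeoJSON(inp$boundary))
  dataset <- stageStop("read", readReferenceCsv(inp$points))

  bb <- polygonBBox(boundary)
  res <- config@commonResolution
  common <- gridSpecNew(bb["xmin"], bb["ymax"], res,
                        ceiling((bb["ymax"] - bb["ymin"]) / res),
                        ceiling((bb["xmax"] - bb["xmin"]) / res),
                        maps[[1L]]@grid@crs)
  maps <- stageStop("harmonize", lapply(maps, function(m) {
    clipToBoundary(resampleToGrid(m, common), boundary)
  }))
  maps <- orderMapsByResolution(maps)

  evals <- stageStop("evaluate", lapply(maps, function(m)
    evaluateMap(m, dataset, varianceMode = config@varianceMode)))
  cr <- stageStop("agree", consensusRaster(maps))
  thr <- if (is.na(config@majorityThreshold)) NULL else
    config@majorityThreshold
  mv <- majorityVote(cr, thr)
  evals <- c(evals, list(
    evaluateMap(mv, dataset, varianceMode = config@varianceMode)))
  crSummary <- consensusSummary(cr)
  agree <- pairwiseAgreement(maps)
  mr <- meanAndRankMatrices(list(agree))
  tab <- evaluationTable(evals)

  stageStop("report", {
    writeMetricTable(tab, file.path(out, "evaluations.csv"))
    utils::write.csv(cbind(region = dataset@region, crSummary),
                     file.path(out, "consensus_summary.csv"),
                     row.names = FALSE)
    writeMatrixCsv(mr$mean, file.path(out, "agreement_mean.csv"))
    writeMatrixCsv(mr$rank, file.path(out, "agreement_rank.csv"))
    writeAsciiGrid(cr, file.path(out, "consensus.asc"))
    writeCropMap(mv, file.path(out, "majority_vote.asc"))
    writeManifest(config, file.path(out, "manifest.txt"))
  })

  list(evaluations = evals, table = tab, consensus = cr,
       consensusSummary = crSummary, agreement = agree, rank = mr$rank,
       majority = mv, correlations = NULL, ndviSeries = NULL,
       dataset = dataset)
}

writeManifest <- function(config, path) {
  lines <- c(
    sprintf("package_version = %s",
            as.character(utils::packageVersion("cropconsensus"))),
    sprintf("seed = %d", config@seed),
    sprintf("common_resolution = %.10g", config@commonResolution),
    sprintf("majority_threshold = %s",
            if (is.na(config@majorityThreshold)) "strict-majority"
            else sprintf("%g", config@majorityThreshold)),
    sprintf("variance_mode = %s", config@varianceMode))
  if (!is.null(config@scenario)) {
    lines <- c(lines, "", "# scenario", scenarioConfigLines(config@scenario))
  } else {
    lines <- c(lines, "", "# inputs",
               vapply(names(config@inputs), function(k)
                 sprintf("%s = %s", k,
                         paste(config@inputs[[k]], collapse = ";")),
                 character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}
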