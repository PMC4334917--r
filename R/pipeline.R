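#' Assemble a pipeline run configuration
#'
#' Every option has a recorded default; the full configuration is written
#' into the run's provenance record (as a YAML block that round-trips
#' byte-identically) so results are reproducible from the provenance
#' alone.
#'
#' @param seed integer RNG seed for the run.
#' @param outdir output directory for the result bundle.
#' @param simulate generate a study-like synthetic dataset (default) or
#'   read the four input files below.
#' @param peaksPath,metaPath,isPath,mapPath input files when
#'   \code{simulate = FALSE} (see \code{\link{readPeakTable}},
#'   \code{\link{readPathwayMap}}).
#' @param contrast length-2 character: control group then treatment group
#'   for the discrimination and the z-score effect metric.
#' @param components PLS-DA components (default 3).
#' @param vipThreshold,vipInclusive VIP significance cutoff (default 1.5,
#'   boundary inclusive).
#' @param normalizationReference \code{"grand_median"} or \code{"unity"}.
#' @param imputeRule \code{"half_min"} or \code{"none"}.
#' @param transformBase log base (10, 2 or \code{exp(1)}).
#' @param unitVariance autoscale to unit variance (default TRUE).
#' @param zScale z-score scale, \code{"concentration"} or \code{"log"}.
#' @param fourClassScores also fit the all-group model and write its
#'   3-D score projection (default TRUE).
#' @param replayVip optional path to a fixed VIP table (columns
#'   metabolite, vip, direction) injected in place of the PLS-DA fit
#'   ("replay" mode, for arithmetic verification of the impact table).
#' @param overlapSets optional named character vector of pathway-list
#'   files; \code{NULL} uses the packaged Fragile X / MIA / human-ASD
#'   sets.
#' @return a named list of class \code{"RunConfig"}.
#' @export
runConfig <- function(seed = 1L, outdir = tempfile("metaboimpact_run_"),
                      simulate = TRUE, peaksPath = NULL, metaPath = NULL,
                      isPath = NULL, mapPath = NULL,
                      contrast = c("KO-Sal", "KO-Sur"), components = 3L,
                      vipThreshold = 1.5, vipInclusive = TRUE,
                      normalizationReference = "grand_median",
                      imputeRule = "half_min", transformBase = 10,
                      unitVariance = TRUE, zScale = "concentration",
                      fourClassScores = TRUE, replayVip = NULL,
                      overlapSets = NULL) {
  cfg <- list(seed = as.integer(seed), outdir = outdir, simulate = simulate,
              peaksPath = peaksPath, metaPath = metaPath, isPath = isPath,
              mapPath = mapPath, contrast = as.character(contrast),
              components = as.integer(components),
              vipThreshold = vipThreshold, vipInclusive = vipInclusive,
              normalizationReference = normalizationReference,
              imputeRule = imputeRule, transformBase = transformBase,
              unitVariance = unitVariance, zScale = zScale,
              fourClassScores = fourClassScores, replayVip = replayVip,
              overlapSets = overlapSets)
  if (length(cfg$contrast) != 2) .stopf("contrast must name two groups")
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a fixed VIP table for replay mode
#'
#' @param path delimited file with columns \code{metabolite}, \code{vip},
#'   \code{direction} (pathway assignment comes from the run's map).
#' @return data.frame.
#' @export
readVipTable <- function(path) {
  tab <- .readDelim(path)
  if (!all(c("metabolite", "vip") %in% names(tab)))
    .stopf("'%s' needs columns metabolite and vip", path)
  tab
}

#' Run the full discrimination pipeline
#'
#' Orchestrates the stages: (optionally) simulate a study-like dataset,
#' normalize by internal standards, impute, log-transform, autoscale,
#' fit the two-class PLS-DA on the configured contrast (or inject a fixed
#' VIP table in replay mode), call significance at the VIP threshold,
#' build the pathway impact table, compute z-score effects and the
#' pathway-grouped network, intersect the cross-model pathway sets, and
#' write every artifact plus a provenance record into \code{cfg$outdir}:
#' \code{vip_table.tsv}, \code{impact_table.tsv}, \code{scores.tsv},
#' \code{network.sif} / \code{network_nodes.tsv} / \code{network.graphml},
#' \code{overlap.json} (+ \code{overlap_membership.tsv}), and
#' \code{provenance.json}.  Runs are fully deterministic under a fixed
#' configuration and seed.
#'
#' @param cfg a \code{\link{runConfig}} list.
#' @return invisibly, a result bundle: the intermediate objects plus
#'   \code{paths} of the written artifacts.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  if (cfg$simulate) {
    spec <- studyLikeSpec(seed = cfg$seed)
    ds <- stage("simulate", generateDataset(spec))
    peaks <- ds$peaks
    map <- pathwayMapFromSpec(spec)
  } else {
    peaks <- stage("read", readPeakTable(cfg$peaksPath, cfg$metaPath,
                                         cfg$isPath))
    map <- stage("read", readPathwayMap(cfg$mapPath))
  }
  norm <- stage("preprocess",
                normalizeByInternalStandards(peaks,
                                             cfg$normalizationReference))
  norm <- stage("preprocess", imputeMissing(norm, cfg$imputeRule))
  logt <- stage("preprocess", logTransform(norm, cfg$transformBase))
  sc <- stage("preprocess", autoscale(logt, cfg$unitVariance))

  zsc <- stage("network",
               computeZScores(logt, treatGroup = cfg$contrast[2],
                              ctrlGroup = cfg$contrast[1],
                              scale = cfg$zScale))
  zdir <- stats::setNames(zsc$z, zsc$metabolite)

  grp <- sampleGroups(peaks)
  model <- model4 <- NULL
  if (is.null(cfg$replayVip)) {
    in2 <- grp %in% cfg$contrast
    # centre/scale within the contrast samples, not over all four groups
    sc2 <- stage("preprocess", autoscale(logt[, in2], cfg$unitVariance))
    model <- stage("plsda",
                   fitPlsda(sc2$X, grp[in2], ncomp = cfg$components))
    vip <- vipScores(model)
    if (cfg$fourClassScores && length(unique(grp)) > 2)
      model4 <- stage("plsda", fitPlsda(sc$X, grp, ncomp = cfg$components))
  } else {
    tab <- stage("plsda", readVipTable(cfg$replayVip))
    vip <- stats::setNames(rep(0, map@totalMeasured),
                           names(map@assignment))
    vip[tab$metabolite] <- tab$vip
    if ("direction" %in% names(tab)) {
      d <- stats::setNames(rep(NA_character_, length(vip)), names(vip))
      d[tab$metabolite] <- tab$direction
      zdir <- d
    }
  }
  ranking <- stage("plsda",
                   selectSignificant(vip, map, directions = zdir,
                                     threshold = cfg$vipThreshold,
                                     inclusive = cfg$vipInclusive))
  impact <- stage("impact", buildImpactTable(ranking, map))
  net <- stage("network", buildNetwork(zsc, impact, map, ranking))

  setsv <- if (is.null(cfg$overlapSets))
    list(fragileXPathwaySet(), miaPathwaySet(), humanAsdPathwaySet())
  else lapply(names(cfg$overlapSets), function(m)
    readPathwaySet(cfg$overlapSets[[m]], model = m))
  overlap <- stage("overlap", intersectPathwaySets(setsv))

  paths <- c(vip = file.path(cfg$outdir, "vip_table.tsv"),
             impact = file.path(cfg$outdir, "impact_table.tsv"),
             scores = file.path(cfg$outdir, "scores.tsv"),
             overlap = file.path(cfg$outdir, "overlap.json"),
             membership = file.path(cfg$outdir, "overlap_membership.tsv"),
             provenance = file.path(cfg$outdir, "provenance.json"))
  utils::write.table(rankingTable(ranking), paths[["vip"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  writeImpactTable(impact, paths[["impact"]])
  scores_fit <- if (!is.null(model4)) model4 else model
  if (!is.null(scores_fit))
    utils::write.table(
      projectScores(scores_fit, min(3, scores_fit@ncomp)),
      paths[["scores"]], sep = "\t", quote = FALSE, row.names = FALSE)
  else
    utils::write.table(data.frame(sample_id = character(),
                                  group = character()),
                       paths[["scores"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  netPaths <- exportNetwork(net, cfg$outdir, "network", "sif")
  gml <- exportNetwork(net, cfg$outdir, "network", "graphml")
  writeOverlapReport(overlap, paths[["overlap"]], paths[["membership"]])
  jsonlite::write_json(
    list(package = "MetaboImpact",
         version = as.character(utils::packageVersion("MetaboImpact")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = cfg$seed,
         config_yaml = yaml::as.yaml(unclass(cfg))),
    paths[["provenance"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(list(peaks = peaks, map = map, normalized = logt,
                 analysis = sc, model = model, model4 = model4,
                 ranking = ranking, impact = impact, zscores = zsc,
                 network = net, overlap = overlap,
                 paths = c(paths, network = netPaths[1],
                           network_nodes = netPaths[2], graphml = gml)))
}
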