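#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors metadata DataFrame
NULL

.GENOTYPES  <- c("WT", "KO")
.TREATMENTS <- c("Sal", "Sur")
.GROUPS     <- c("WT-Sal", "WT-Sur", "KO-Sal", "KO-Sur")

#' Container for a raw targeted-metabolomics peak-area table
#'
#' A \linkS4class{SummarizedExperiment} with one assay, \code{"areas"},
#' holding integrated peak areas (arbitrary detector units) with metabolites
#' as rows and samples as columns.  Missing (undetected) cells are \code{NA};
#' zero is a legal measured value, distinct from missing.  \code{rowData}
#' carries the logical column \code{is_internal_standard} flagging
#' stable-isotope internal standards; \code{colData} carries \code{genotype}
#' (WT/KO), \code{treatment} (Sal/Sur), the derived \code{group} label
#' (genotype-treatment) and an optional \code{batch}.
#'
#' On disk the corresponding delimited format has samples as rows and
#' metabolites as columns (see \code{\link{readPeakTable}}); the container
#' follows the Bioconductor features-by-samples convention.
#'
#' @seealso \code{\link{readPeakTable}}, \code{\link{PeakTable}},
#'   \code{\link{normalizeByInternalStandards}}
#' @export
setClass("PeakTable", contains = "SummarizedExperiment")

setValidity("PeakTable", function(object) {
  msg <- character()
  if (!"areas" %in% assayNames(object))
    msg <- c(msg, "assay 'areas' is required")
  rn <- rownames(object); cn <- colnames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "metabolite ids must be present and unique")
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "sample ids must be present and unique")
  if (!"is_internal_standard" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'is_internal_standard' is required")
  else {
    isis <- rowData(object)$is_internal_standard
    if (!is.logical(isis) || anyNA(isis))
      msg <- c(msg, "'is_internal_standard' must be logical without NA")
    else if (!any(isis))
      msg <- c(msg, "at least one internal-standard row is required")
  }
  cd <- colData(object)
  for (f in c("genotype", "treatment", "group"))
    if (!f %in% colnames(cd)) msg <- c(msg, sprintf("colData column '%s' is required", f))
  if (all(c("genotype", "treatment", "group") %in% colnames(cd))) {
    if (!all(cd$genotype %in% .GENOTYPES))
      msg <- c(msg, "genotype must be one of WT, KO")
    if (!all(cd$treatment %in% .TREATMENTS))
      msg <- c(msg, "treatment must be one of Sal, Sur")
    if (!all(cd$group == paste(cd$genotype, cd$treatment, sep = "-")))
      msg <- c(msg, "group must equal genotype-treatment")
  }
  if ("areas" %in% assayNames(object)) {
    a <- assay(object, "areas")
    if (!is.numeric(a))
      msg <- c(msg, "areas must be numeric")
    else {
      if (any(a < 0, na.rm = TRUE)) msg <- c(msg, "peak areas must be non-negative")
      if (any(is.infinite(a))) msg <- c(msg, "peak areas must be finite or NA")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Container for a normalized, optionally imputed / log-transformed table
#'
#' A \linkS4class{SummarizedExperiment} with assay \code{"normalized"}
#' (metabolites x samples, internal-standard rows removed).  The provenance
#' record in \code{metadata(x)$provenance} stores the per-sample
#' internal-standard scale factors, the normalization reference, the number
#' of imputed cells, metabolites flagged for high missingness, and the
#' transform applied (\code{"none"}, \code{"log10"}, \code{"log2"} or
#' \code{"ln"}).
#'
#' @seealso \code{\link{normalizeByInternalStandards}},
#'   \code{\link{imputeMissing}}, \code{\link{logTransform}},
#'   \code{\link{autoscale}}
#' @export
setClass("NormalizedTable", contains = "SummarizedExperiment")

setValidity("NormalizedTable", function(object) {
  msg <- character()
  if (!"normalized" %in% assayNames(object))
    msg <- c(msg, "assay 'normalized' is required")
  prov <- metadata(object)$provenance
  if (is.null(prov)) {
    msg <- c(msg, "metadata 'provenance' is required")
  } else {
    s <- prov$scale_factors
    if (is.null(s) || !is.numeric(s) || any(!is.finite(s)) || any(s <= 0))
      msg <- c(msg, "provenance scale_factors must be strictly positive")
    if (is.null(prov$transform) ||
        !prov$transform %in% c("none", "log10", "log2", "ln"))
      msg <- c(msg, "provenance transform must be one of none, log10, log2, ln")
  }
  if (length(msg)) msg else TRUE
})

#' Metabolite-to-pathway assignment map
#'
#' Assigns every measured metabolite to exactly one biochemical pathway and
#' records pathway sizes (the N column of the pathway impact table), the
#' total number of measured metabolites and the number of pathways in the
#' universe.  Pathway names are canonicalized through a synonym table at
#' construction.
#'
#' @slot assignment named character; \code{assignment[metabolite]} is the
#'   canonical pathway name.
#' @slot pathwaySizes named integer; metabolites measured per pathway.
#' @slot totalMeasured integer(1); size of the measured universe.
#' @slot nPathways integer(1); number of pathways in the universe.
#' @seealso \code{\link{readPathwayMap}}, \code{\link{PathwayMap}}
#' @export
setClass("PathwayMap",
  slots = c(assignment = "character", pathwaySizes = "integer",
            totalMeasured = "integer", nPathways = "integer"))

setValidity("PathwayMap", function(object) {
  msg <- character()
  a <- object@assignment
  if (is.null(names(a)) || anyDuplicated(names(a)))
    msg <- c(msg, "assignment must be named by unique metabolite ids")
  if (any(!nzchar(a)) || anyNA(a))
    msg <- c(msg, "pathway names must be non-empty")
  sz <- table(a)
  ps <- object@pathwaySizes
  if (!setequal(names(sz), names(ps)) ||
      !all(ps[names(sz)] == as.integer(sz)))
    msg <- c(msg, "pathwaySizes must equal recounts of the assignment")
  if (sum(ps) != object@totalMeasured)
    msg <- c(msg, "pathway sizes must sum to totalMeasured")
  if (length(ps) != object@nPathways)
    msg <- c(msg, "nPathways must equal the number of distinct pathways")
  if (length(msg)) msg else TRUE
})

#' Fitted PLS-DA model (NIPALS PLS2)
#'
#' Holds the weights, scores, loadings, per-component explained class
#' sum-of-squares and VIP scores of a partial least squares discriminant
#' analysis fit.  Weight columns have unit Euclidean norm and a fixed sign
#' convention (largest-magnitude entry positive); score columns are mutually
#' orthogonal; the mean squared VIP over metabolites equals one.
#'
#' @slot ncomp integer(1); number of components A.
#' @slot weights p x A weight matrix W.
#' @slot scores n x A score matrix T.
#' @slot xLoadings p x A X-loading matrix.
#' @slot yLoadings g x A class-indicator loading matrix Q.
#' @slot ssy numeric(A); explained Y sum-of-squares per component.
#' @slot vip numeric(p); VIP score per metabolite.
#' @slot metabolites character(p); column ids of the analysis matrix.
#' @slot groups factor(n); group label per sample.
#' @slot groupLevels character(g); order of indicator columns.
#' @seealso \code{\link{fitPlsda}}, \code{\link{computeVip}},
#'   \code{\link{projectScores}}
#' @export
setClass("PlsdaModel",
  slots = c(ncomp = "integer", weights = "matrix", scores = "matrix",
            xLoadings = "matrix", yLoadings = "matrix", ssy = "numeric",
            vip = "numeric", metabolites = "character", groups = "factor",
            groupLevels = "character"))

setValidity("PlsdaModel", function(object) {
  msg <- character()
  W <- object@weights; Tm <- object@scores
  if (ncol(W) != object@ncomp || ncol(Tm) != object@ncomp)
    msg <- c(msg, "weights and scores must have ncomp columns")
  wn <- sqrt(colSums(W^2))
  if (any(abs(wn - 1) > 1e-8))
    msg <- c(msg, "weight columns must have unit norm")
  if (object@ncomp > 1) {
    G <- crossprod(Tm)
    nrm <- sqrt(diag(G))
    off <- abs(G) - 1e-8 * outer(nrm, nrm)
    diag(off) <- 0
    if (any(off > 0)) msg <- c(msg, "score columns must be mutually orthogonal")
  }
  v <- object@vip
  if (length(v)) {
    if (any(v < 0)) msg <- c(msg, "vip must be non-negative")
    if (abs(mean(v^2) - 1) > 1e-9)
      msg <- c(msg, "mean squared VIP must equal 1")
  }
  if (length(object@metabolites) != nrow(W))
    msg <- c(msg, "metabolites must label the weight rows")
  if (length(msg)) msg else TRUE
})

#' VIP ranking with threshold significance calls
#'
#' Metabolites sorted by decreasing VIP score with their pathway, treatment
#' direction and a significance flag at the configured VIP threshold
#' (default 1.5, boundary inclusive).
#'
#' @slot table data.frame with columns \code{metabolite}, \code{pathway},
#'   \code{vip}, \code{direction} ("increased"/"decreased"),
#'   \code{significant}.
#' @slot threshold numeric(1); VIP significance cutoff.
#' @slot inclusive logical(1); whether vip == threshold is significant.
#' @seealso \code{\link{selectSignificant}}
#' @export
setClass("VipRanking",
  slots = c(table = "data.frame", threshold = "numeric",
            inclusive = "logical"))

setValidity("VipRanking", function(object) {
  msg <- character()
  tb <- object@table
  need <- c("metabolite", "pathway", "vip", "direction", "significant")
  if (!all(need %in% names(tb)))
    msg <- c(msg, paste("table needs columns", paste(need, collapse = ", ")))
  else {
    if (is.unsorted(rev(tb$vip))) msg <- c(msg, "table must be sorted by vip descending")
    sig <- if (object@inclusive) tb$vip >= object@threshold else tb$vip > object@threshold
    if (!identical(as.logical(tb$significant), sig))
      msg <- c(msg, "significant flag must match the threshold rule")
    bad <- tb$significant & (is.na(tb$direction) |
      !tb$direction %in% c("increased", "decreased"))
    if (any(bad))
      msg <- c(msg, "significant metabolites must carry a direction")
  }
  if (length(msg)) msg else TRUE
})

#' Pathway impact table (summed-VIP enrichment statistic)
#'
#' One row per pathway with at least one significant metabolite: pathway
#' size N, expected proportion P = N / total measured, expected hits
#' P x n_sig, observed hits, fold enrichment, impact (summed VIP over the
#' pathway's significant metabolites), fraction of total impact, and
#' direction counts.  Rows are sorted by impact descending (ties by pathway
#' name); display-rounded and unrounded shadow columns are both kept.  The
#' totals slot summarises pathways hit, combined N, combined expected hits,
#' significant metabolites, total impact and metabolites increased.
#'
#' @slot rows data.frame of per-pathway statistics.
#' @slot totals named list of table-wide totals.
#' @seealso \code{\link{buildImpactTable}}, \code{\link{writeImpactTable}}
#' @export
setClass("ImpactTable", slots = c(rows = "data.frame", totals = "list"))

setValidity("ImpactTable", function(object) {
  msg <- character()
  r <- object@rows; tot <- object@totals
  if (nrow(r)) {
    if (any(r$observed_hits < 1)) msg <- c(msg, "rows are restricted to pathways with observed hits >= 1")
    if (any(r$observed_hits > r$n_measured)) msg <- c(msg, "observed hits cannot exceed pathway size")
    if (!all(r$n_increased + r$n_decreased == r$observed_hits))
      msg <- c(msg, "direction counts must sum to observed hits")
    if (any(r$fold_enrichment_raw < 0)) msg <- c(msg, "fold enrichment must be non-negative")
    if (any(r$fraction_raw < 0 | r$fraction_raw > 1))
      msg <- c(msg, "fraction of impact must lie in [0, 1]")
    if (abs(sum(r$fraction_raw) - 1) > 1e-9)
      msg <- c(msg, "fractions must sum to 1")
    if (sum(r$observed_hits) != tot$n_significant)
      msg <- c(msg, "observed hits must sum to the significant count")
    if (abs(sum(r$impact_raw) - tot$total_impact) > 1e-9)
      msg <- c(msg, "impacts must sum to the total impact")
  }
  if (length(msg)) msg else TRUE
})

#' Pathway-grouped metabolite effect network
#'
#' A bipartite star graph: one hub node per pathway (annotated with impact
#' and fraction of impact) and one leaf node per metabolite (annotated with
#' z-score, clipped z, hex color, VIP and significance), joined by
#' membership edges.
#'
#' @slot graph an \pkg{igraph} graph.
#' @seealso \code{\link{buildNetwork}}, \code{\link{exportNetwork}}
#' @export
setClass("EffectNetwork", slots = c(graph = "ANY"))

setValidity("EffectNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::vcount(g) == 0) return(TRUE)
  type <- igraph::V(g)$type
  if (is.null(type) || !all(type %in% c("pathway", "metabolite")))
    return("every node needs type 'pathway' or 'metabolite'")
  met <- which(type == "metabolite")
  if (length(met) && any(igraph::degree(g, met) != 1))
    return("every metabolite node must link to exactly one pathway")
  TRUE
})

#' Named set of canonical pathway names for one disease model
#'
#' @slot model character(1); model label (e.g. "FragileX", "MIA",
#'   "HumanASD").
#' @slot pathways character; canonical pathway names (post synonym
#'   resolution), non-empty.
#' @seealso \code{\link{intersectPathwaySets}}, \code{\link{readPathwaySet}}
#' @export
setClass("PathwaySet", slots = c(model = "character", pathways = "character"))

setValidity("PathwaySet", function(object) {
  msg <- character()
  if (length(object@model) != 1 || !nzchar(object@model))
    msg <- c(msg, "model must be a single non-empty label")
  if (!length(object@pathways)) msg <- c(msg, "pathway set must be non-empty")
  if (anyDuplicated(object@pathways)) msg <- c(msg, "pathway names must be unique")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic study-like peak-area dataset
#'
#' Defines the design emulated by \code{\link{generateDataset}}: per-group
#' animal counts, pathway sizes, planted treatment effects in within-group
#' SD units, lognormal baseline abundances, internal-standard scale-factor
#' dispersion, missingness and the RNG seed.
#'
#' @slot nPerGroup named integer; animals per group.
#' @slot pathwaySizes named integer; metabolites per pathway.
#' @slot plantedEffects data.frame(metabolite, group, delta); effect of
#'   membership in \code{group} on \code{metabolite}, expressed in
#'   within-group SD units on the log10 scale.
#' @slot mu0,tau numeric(1); mean and SD of the log10 baseline abundances.
#' @slot sigmaRange numeric(2); uniform range of within-group log10 SDs.
#' @slot nInternalStandards integer(1); number of spiked internal standards.
#' @slot sigmaScale numeric(1); sdlog of the per-sample lognormal scale
#'   factors.
#' @slot missingRate numeric(1); probability a non-IS cell is masked.
#' @slot seed integer(1); RNG seed, mandatory.
#' @seealso \code{\link{simSpec}}, \code{\link{studyLikeSpec}}
#' @export
setClass("SimSpec",
  slots = c(nPerGroup = "integer", pathwaySizes = "integer",
            plantedEffects = "data.frame", mu0 = "numeric", tau = "numeric",
            sigmaRange = "numeric", nInternalStandards = "integer",
            sigmaScale = "numeric", missingRate = "numeric",
            seed = "integer"))

setValidity("SimSpec", function(object) {
  msg <- character()
  if (any(object@nPerGroup < 2)) msg <- c(msg, "at least 2 samples per group")
  if (!all(names(object@nPerGroup) %in% .GROUPS))
    msg <- c(msg, "group names must be genotype-treatment labels")
  pe <- object@plantedEffects
  if (nrow(pe)) {
    if (!all(c("metabolite", "group", "delta") %in% names(pe)))
      msg <- c(msg, "plantedEffects needs metabolite, group, delta")
    else {
      if (any(!is.finite(pe$delta))) msg <- c(msg, "delta must be finite")
      if (!all(pe$metabolite %in% .metaboliteIds(object@pathwaySizes)))
        msg <- c(msg, "planted metabolites must exist in the pathway layout")
      if (!all(pe$group %in% names(object@nPerGroup)))
        msg <- c(msg, "planted groups must be in the design")
    }
  }
  if (length(object@sigmaRange) != 2 || any(object@sigmaRange <= 0) ||
      diff(object@sigmaRange) < 0)
    msg <- c(msg, "sigmaRange must be an increasing positive pair")
  if (object@nInternalStandards < 1) msg <- c(msg, "need at least one internal standard")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (is.na(object@seed)) msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})
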