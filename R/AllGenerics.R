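#' @include AllClasses.R
NULL

#' Peak-area matrix accessor
#'
#' Returns the assay matrix (metabolites x samples) of a
#' \linkS4class{PeakTable}.
#' @param x a \linkS4class{PeakTable}.
#' @return numeric matrix, metabolites as rows, \code{NA} marking missing
#'   cells.
#' @export
setGeneric("peakAreas", function(x) standardGeneric("peakAreas"))

#' @rdname peakAreas
#' @export
setMethod("peakAreas", "PeakTable", function(x) assay(x, "areas"))

#' Internal-standard flags accessor
#' @param x a \linkS4class{PeakTable}.
#' @return named logical vector over metabolites.
#' @export
setGeneric("isInternalStandard", function(x) standardGeneric("isInternalStandard"))

#' @rdname isInternalStandard
#' @export
setMethod("isInternalStandard", "PeakTable", function(x)
  stats::setNames(rowData(x)$is_internal_standard, rownames(x)))

#' Sample group labels accessor
#' @param x a \linkS4class{PeakTable} or \linkS4class{NormalizedTable}.
#' @return named character vector, \code{"genotype-treatment"} per sample.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "SummarizedExperiment", function(x)
  stats::setNames(as.character(colData(x)$group), colnames(x)))

#' Normalized value matrix accessor
#' @param x a \linkS4class{NormalizedTable}.
#' @return numeric matrix (metabolites x samples).
#' @export
setGeneric("normValues", function(x) standardGeneric("normValues"))

#' @rdname normValues
#' @export
setMethod("normValues", "NormalizedTable", function(x) assay(x, "normalized"))

#' Preprocessing provenance accessor
#' @param x a \linkS4class{NormalizedTable}.
#' @return list with elements \code{scale_factors}, \code{reference},
#'   \code{n_imputed}, \code{high_missing}, \code{transform},
#'   \code{transform_base}.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname provenance
#' @export
setMethod("provenance", "NormalizedTable", function(x) metadata(x)$provenance)

#' Per-sample internal-standard scale factors accessor
#' @param x a \linkS4class{NormalizedTable}.
#' @return named numeric vector of the s_i factors divided out per sample.
#' @export
setGeneric("scaleFactors", function(x) standardGeneric("scaleFactors"))

#' @rdname scaleFactors
#' @export
setMethod("scaleFactors", "NormalizedTable", function(x)
  metadata(x)$provenance$scale_factors)

#' VIP scores accessor
#' @param x a \linkS4class{PlsdaModel} or \linkS4class{VipRanking}.
#' @return named numeric vector (model) or the ranking data.frame column.
#' @export
setGeneric("vipScores", function(x) standardGeneric("vipScores"))

#' @rdname vipScores
#' @export
setMethod("vipScores", "PlsdaModel", function(x)
  stats::setNames(x@vip, x@metabolites))

#' @rdname vipScores
#' @export
setMethod("vipScores", "VipRanking", function(x)
  stats::setNames(x@table$vip, x@table$metabolite))

#' Ranking table accessor
#' @param x a \linkS4class{VipRanking}.
#' @return data.frame sorted by decreasing VIP.
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @rdname rankingTable
#' @export
setMethod("rankingTable", "VipRanking", function(x) x@table)

#' Significant metabolite ids accessor
#' @param x a \linkS4class{VipRanking}.
#' @return character vector of metabolites at or above the VIP threshold.
#' @export
setGeneric("significantMetabolites",
           function(x) standardGeneric("significantMetabolites"))

#' @rdname significantMetabolites
#' @export
setMethod("significantMetabolites", "VipRanking", function(x)
  x@table$metabolite[x@table$significant])

#' Impact-table rows accessor
#' @param x an \linkS4class{ImpactTable}.
#' @return data.frame of per-pathway statistics.
#' @export
setGeneric("impactRows", function(x) standardGeneric("impactRows"))

#' @rdname impactRows
#' @export
setMethod("impactRows", "ImpactTable", function(x) x@rows)

#' Impact-table totals accessor
#' @param x an \linkS4class{ImpactTable}.
#' @return named list of table-wide totals.
#' @export
setGeneric("impactTotals", function(x) standardGeneric("impactTotals"))

#' @rdname impactTotals
#' @export
setMethod("impactTotals", "ImpactTable", function(x) x@totals)

#' Pathway assignment accessor
#' @param x a \linkS4class{PathwayMap}.
#' @return named character; canonical pathway per metabolite.
#' @export
setGeneric("pathwayAssignment", function(x) standardGeneric("pathwayAssignment"))

#' @rdname pathwayAssignment
#' @export
setMethod("pathwayAssignment", "PathwayMap", function(x) x@assignment)

#' Pathway sizes accessor
#' @param x a \linkS4class{PathwayMap}.
#' @return named integer; metabolites measured per pathway (N).
#' @export
setGeneric("pathwaySizes", function(x) standardGeneric("pathwaySizes"))

#' @rdname pathwaySizes
#' @export
setMethod("pathwaySizes", "PathwayMap", function(x) x@pathwaySizes)

#' Network graph accessor
#' @param x an \linkS4class{EffectNetwork}.
#' @return the underlying \pkg{igraph} graph.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname networkGraph
#' @export
setMethod("networkGraph", "EffectNetwork", function(x) x@graph)

setMethod("show", "PeakTable", function(object) {
  isn <- sum(rowData(object)$is_internal_standard)
  cat(sprintf(
    "PeakTable: %d metabolites (%d internal standards) x %d samples\n",
    nrow(object), isn, ncol(object)))
  grp <- table(colData(object)$group)
  cat("groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  cat(sprintf("missing cells: %d\n", sum(is.na(assay(object, "areas")))))
})

setMethod("show", "NormalizedTable", function(object) {
  prov <- metadata(object)$provenance
  cat(sprintf("NormalizedTable: %d metabolites x %d samples (transform: %s)\n",
              nrow(object), ncol(object), prov$transform))
  cat(sprintf("imputed cells: %d; scale factor range: [%.3f, %.3f]\n",
              prov$n_imputed, min(prov$scale_factors), max(prov$scale_factors)))
})

setMethod("show", "PathwayMap", function(object) {
  cat(sprintf("PathwayMap: %d metabolites across %d pathways\n",
              object@totalMeasured, object@nPathways))
})

setMethod("show", "PlsdaModel", function(object) {
  cat(sprintf("PlsdaModel: %d components, %d metabolites, %d samples, groups: %s\n",
              object@ncomp, length(object@metabolites), nrow(object@scores),
              paste(object@groupLevels, collapse = " vs ")))
  cat("explained Y SS per component:",
      paste(signif(object@ssy, 4), collapse = ", "), "\n")
})

setMethod("show", "VipRanking", function(object) {
  op <- if (object@inclusive) ">=" else ">"
  cat(sprintf("VipRanking: %d metabolites, %d significant at VIP %s %.2f\n",
              nrow(object@table), sum(object@table$significant), op,
              object@threshold))
})

setMethod("show", "ImpactTable", function(object) {
  t <- object@totals
  cat(sprintf(
    "ImpactTable: %d of %d pathways hit; %d significant metabolites; total impact %.1f\n",
    t$n_pathways_hit, t$n_pathways_total, t$n_significant, t$total_impact))
})

setMethod("show", "EffectNetwork", function(object) {
  g <- object@graph
  np <- sum(igraph::V(g)$type == "pathway")
  cat(sprintf("EffectNetwork: %d pathway hubs, %d metabolites, %d edges\n",
              np, igraph::vcount(g) - np, igraph::ecount(g)))
})

setMethod("show", "PathwaySet", function(object) {
  cat(sprintf("PathwaySet '%s': %d pathways\n", object@model,
              length(object@pathways)))
})

setMethod("show", "SimSpec", function(object) {
  cat(sprintf(
    "SimSpec: %d metabolites / %d pathways; groups %s; %d planted effects; seed %d\n",
    sum(object@pathwaySizes), length(object@pathwaySizes),
    paste(sprintf("%s=%d", names(object@nPerGroup), object@nPerGroup),
          collapse = ", "),
    nrow(object@plantedEffects), object@seed))
})
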