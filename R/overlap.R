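#' Construct a PathwaySet of canonical pathway names
#'
#' Names are resolved through the synonym table with set-valued expansion
#' (a combined name like "sphingolipids/gangliosides" contributes both
#' pathways); unresolvable names are an error listing them.
#'
#' @param model model label (e.g. \code{"FragileX"}).
#' @param pathways character vector of pathway names.
#' @param synonyms synonym table, or \code{NULL} to take names as already
#'   canonical.
#' @return a \linkS4class{PathwaySet}.
#' @export
PathwaySet <- function(model, pathways,
                       synonyms = defaultPathwaySynonyms()) {
  pw <- if (is.null(synonyms)) unique(pathways)
        else expandPathwayNames(pathways, synonyms)
  new("PathwaySet", model = model, pathways = pw)
}

#' Read a one-pathway-per-line set file
#'
#' Lines starting with \code{#} and blank lines are ignored.
#'
#' @param path path to the list file.
#' @param model model label; defaults to the file stem.
#' @inheritParams PathwaySet
#' @return a \linkS4class{PathwaySet}.
#' @export
readPathwaySet <- function(path, model = NULL,
                           synonyms = defaultPathwaySynonyms()) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (is.null(model))
    model <- sub("\\.[^.]*$", "", basename(path))
  PathwaySet(model, lines, synonyms = synonyms)
}

.packagedSet <- function(file, model) {
  readPathwaySet(system.file("extdata", file, package = "MetaboImpact",
                             mustWork = TRUE), model = model)
}

#' Packaged cross-model pathway sets
#'
#' Pathway lists transcribed from the published cross-model comparison:
#' \code{fragileXPathwaySet()} is the 20 pathways affected by suramin in
#' the Fragile X knockout model; \code{humanAsdPathwaySet()} the 17 of
#' those pathways reported in human ASD (bile acids, cardiolipin and the
#' pentose phosphate pathway are absent — bile acids have not been studied
#' in human autism); \code{miaPathwaySet()} the 11 pathways the maternal
#' immune activation (MIA) model shares with the Fragile X model (the MIA
#' model's full 18-pathway list is not enumerated in the source, so this
#' set is the published shared subset).
#'
#' @return a \linkS4class{PathwaySet}.
#' @export
fragileXPathwaySet <- function()
  .packagedSet("pathway_set_fragilex.txt", "FragileX")

#' @rdname fragileXPathwaySet
#' @export
humanAsdPathwaySet <- function()
  .packagedSet("pathway_set_human_asd.txt", "HumanASD")

#' @rdname fragileXPathwaySet
#' @export
miaPathwaySet <- function() .packagedSet("pathway_set_mia.txt", "MIA")

#' Intersect pathway sets across disease models
#'
#' Computes all pairwise and higher-order intersections of two or more
#' canonicalized pathway sets, plus the exclusive Venn-region counts
#' (which sum to the union size) and a membership matrix.
#'
#' @param sets list of \linkS4class{PathwaySet} objects (>= 2, distinct
#'   model labels).
#' @return list with elements \code{models}, \code{union} (all pathways),
#'   \code{membership} (logical pathway x model matrix),
#'   \code{intersections} (named list over every combination of >= 2
#'   models: \code{size} and \code{members}), and \code{regions} (named
#'   integer vector of exclusive Venn regions, keys like
#'   \code{"FragileX&HumanASD"}).
#' @examples
#' a <- PathwaySet("A", c("purines", "glycolysis"))
#' b <- PathwaySet("B", c("purines", "Krebs cycle"))
#' intersectPathwaySets(list(a, b))$intersections[["A&B"]]$size
#' @export
intersectPathwaySets <- function(sets) {
  if (length(sets) < 2) .stopf("need at least 2 pathway sets")
  if (!all(vapply(sets, is, logical(1), "PathwaySet")))
    .stopf("all elements must be PathwaySet objects")
  models <- vapply(sets, function(s) s@model, character(1))
  if (anyDuplicated(models)) .stopf("model labels must be distinct")
  univ <- sort(unique(unlist(lapply(sets, function(s) s@pathways))))
  mem <- vapply(sets, function(s) univ %in% s@pathways,
                logical(length(univ)))
  dimnames(mem) <- list(univ, models)
  k <- length(sets)
  inter <- list()
  for (m in 2:k) {
    for (cmb in utils::combn(k, m, simplify = FALSE)) {
      members <- univ[rowSums(mem[, cmb, drop = FALSE]) == m]
      inter[[paste(models[cmb], collapse = "&")]] <-
        list(size = length(members), members = members)
    }
  }
  pattern <- apply(mem, 1, function(row)
    paste(models[row], collapse = "&"))
  regions <- table(pattern)
  list(models = models, union = univ, membership = mem,
       intersections = inter,
       regions = stats::setNames(as.integer(regions), names(regions)))
}

#' Write an overlap report to JSON and a membership matrix to TSV
#'
#' @param report result of \code{\link{intersectPathwaySets}}.
#' @param jsonPath,tsvPath output paths (either may be \code{NULL} to
#'   skip).
#' @return invisibly, the written paths.
#' @export
writeOverlapReport <- function(report, jsonPath = NULL, tsvPath = NULL) {
  if (!is.null(jsonPath)) {
    out <- list(models = report$models, union_size = length(report$union),
                intersections = lapply(report$intersections, function(x)
                  list(size = x$size, members = x$members)),
                regions = as.list(report$regions))
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(tsvPath)) {
    m <- data.frame(pathway = rownames(report$membership),
                    report$membership * 1L, check.names = FALSE)
    utils::write.table(m, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(jsonPath, tsvPath))
}
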