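#' Packaged pathway-name synonym table
#'
#' The controlled vocabulary of the 20 named biochemical pathways (purines,
#' fatty acid oxidation, eicosanoids, ...) appears under variant spellings
#' in different reports ("NAD+ metabolism" vs "Vitamin B3 (Niacin, NAD+)
#' metabolism"; "bile acids" vs "Bile salt metabolism").  This table maps
#' variants to canonical names, case-insensitively.  A variant listed twice
#' expands to several canonical names (e.g. "sphingolipids/gangliosides"
#' covers both the sphingolipid and the ganglioside pathway).
#'
#' @return data.frame with columns \code{variant}, \code{canonical}.
#' @seealso \code{\link{canonicalizePathways}}
#' @export
defaultPathwaySynonyms <- function() {
  .readDelim(system.file("extdata", "pathway_synonyms.tsv",
                         package = "MetaboImpact", mustWork = TRUE))
}

.normName <- function(x) tolower(trimws(x))

#' Canonicalize pathway names through the synonym table
#'
#' Single-target resolution: each input name maps to exactly one canonical
#' name.  Names not in the table pass through unchanged unless
#' \code{strict = TRUE}; a name whose variant expands to several canonical
#' pathways is an error here (use \code{\link{expandPathwayNames}} for
#' set-valued resolution).
#'
#' @param x character vector of pathway names.
#' @param synonyms synonym table (\code{\link{defaultPathwaySynonyms}}).
#' @param strict error on names absent from the table instead of passing
#'   them through.
#' @return character vector, same length as \code{x}.
#' @export
canonicalizePathways <- function(x, synonyms = defaultPathwaySynonyms(),
                                 strict = FALSE) {
  key <- .normName(x)
  out <- as.character(x)
  for (i in seq_along(x)) {
    hit <- synonyms$canonical[.normName(synonyms$variant) == key[i]]
    if (length(hit) > 1)
      .stopf("pathway name '%s' expands to %d canonical pathways; use expandPathwayNames()",
             x[i], length(hit))
    if (length(hit) == 1) out[i] <- hit
    else if (strict)
      .stopf("uncanonicalizable pathway name: '%s'", x[i])
  }
  out
}

#' Expand pathway names to sets of canonical names
#'
#' Set-valued resolution for pathway lists: variants mapping to several
#' canonical pathways contribute all of them; unknown names raise an error
#' listing them.
#'
#' @inheritParams canonicalizePathways
#' @return character vector of unique canonical names.
#' @export
expandPathwayNames <- function(x, synonyms = defaultPathwaySynonyms()) {
  key <- .normName(x)
  skey <- .normName(synonyms$variant)
  canon <- .normName(unique(synonyms$canonical))
  unknown <- x[!(key %in% skey | key %in% canon)]
  if (length(unknown))
    .stopf("uncanonicalizable pathway name(s): %s",
           paste(unique(unknown), collapse = "; "))
  out <- unlist(lapply(seq_along(x), function(i) {
    hit <- synonyms$canonical[skey == key[i]]
    if (length(hit)) hit else
      unique(synonyms$canonical)[canon == key[i]]
  }))
  unique(out)
}

#' Construct a PathwayMap from a metabolite-to-pathway assignment
#'
#' @param assignment named character; \code{assignment[metabolite]} is the
#'   pathway name (exactly one pathway per metabolite).  Names are
#'   canonicalized through the synonym table.
#' @param synonyms synonym table, or \code{NULL} to skip canonicalization.
#' @return a validated \linkS4class{PathwayMap}.
#' @examples
#' PathwayMap(c(hypoxanthine = "purines", uridine = "pyrimidines"))
#' @export
PathwayMap <- function(assignment, synonyms = defaultPathwaySynonyms()) {
  if (is.null(names(assignment)))
    .stopf("assignment must be named by metabolite ids")
  dup <- unique(names(assignment)[duplicated(names(assignment))])
  if (length(dup))
    .stopf("metabolite(s) assigned twice: %s", paste(dup, collapse = ", "))
  if (any(is.na(assignment) | !nzchar(assignment)))
    .stopf("empty pathway name for metabolite(s): %s",
           paste(names(assignment)[is.na(assignment) | !nzchar(assignment)],
                 collapse = ", "))
  if (!is.null(synonyms))
    assignment <- stats::setNames(canonicalizePathways(assignment, synonyms),
                                  names(assignment))
  sizes <- table(assignment)
  new("PathwayMap",
      assignment = assignment,
      pathwaySizes = stats::setNames(as.integer(sizes), names(sizes)),
      totalMeasured = length(assignment),
      nPathways = length(sizes))
}

#' Read a metabolite-to-pathway map from a two-column delimited file
#'
#' Expects columns \code{metabolite_id} and \code{pathway_name} (tab
#' default, comma accepted).  Pathway sizes are computed by counting;
#' names are canonicalized through the synonym table.
#'
#' @param path path to the map file.
#' @inheritParams PathwayMap
#' @return a validated \linkS4class{PathwayMap}.
#' @seealso \code{\link{writePathwayMap}}
#' @export
readPathwayMap <- function(path, synonyms = defaultPathwaySynonyms()) {
  tab <- .readDelim(path)
  if (!all(c("metabolite_id", "pathway_name") %in% names(tab)))
    .stopf("'%s' needs columns metabolite_id and pathway_name", path)
  PathwayMap(stats::setNames(as.character(tab$pathway_name),
                             as.character(tab$metabolite_id)),
             synonyms = synonyms)
}

#' Write a PathwayMap to a two-column delimited file
#' @param x a \linkS4class{PathwayMap}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePathwayMap <- function(x, path) {
  utils::write.table(
    data.frame(metabolite_id = names(x@assignment),
               pathway_name = unname(x@assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
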