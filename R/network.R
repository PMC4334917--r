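#' Per-metabolite z-score effect metric between two groups
#'
#' For each metabolite the z-score is the arithmetic difference between
#' its mean normalized concentration in the treatment group and the
#' control group, divided by the standard deviation (n - 1 denominator)
#' in the controls.  The sign gives the treatment direction consumed by
#' \code{\link{selectSignificant}}.  By default the metric is computed on
#' the normalized concentration scale; \code{scale = "log"} computes it on
#' log-transformed values (where a planted effect of d control-SDs has
#' expectation d).  Metabolites with zero control SD are excluded and
#' reported in the \code{"excluded"} attribute.
#'
#' @param t a \linkS4class{NormalizedTable}.
#' @param treatGroup,ctrlGroup group labels with at least 2 samples each.
#' @param scale \code{"concentration"} (default) or \code{"log"}.  When
#'   the table is log-transformed, \code{"concentration"} back-transforms
#'   first; when it is not, \code{"log"} takes log10 (the z-score on the
#'   log scale is invariant to the log base).
#' @return data.frame with columns \code{metabolite}, \code{mean_treat},
#'   \code{mean_ctrl}, \code{sd_ctrl}, \code{z}, \code{z_clipped} (clamped
#'   to [-2, 2]) and \code{color} (hex, red-white-green), one row per
#'   retained metabolite.
#' @export
computeZScores <- function(t, treatGroup, ctrlGroup,
                           scale = c("concentration", "log")) {
  scale <- match.arg(scale)
  stopifnot(is(t, "NormalizedTable"))
  grp <- sampleGroups(t)
  for (g in c(treatGroup, ctrlGroup))
    if (!g %in% grp) .stopf("unknown group label: '%s'", g)
  if (sum(grp == treatGroup) < 2 || sum(grp == ctrlGroup) < 2)
    .stopf("both groups need at least 2 samples")
  v <- normValues(t)
  prov <- metadata(t)$provenance
  logged <- prov$transform != "none"
  if (scale == "concentration" && logged)
    v <- prov$transform_base^v
  if (scale == "log" && !logged) {
    if (any(v <= 0, na.rm = TRUE))
      .stopf("non-positive values; cannot compute log-scale z-scores")
    v <- log10(v)
  }
  tr <- v[, grp == treatGroup, drop = FALSE]
  ct <- v[, grp == ctrlGroup, drop = FALSE]
  mt <- rowMeans(tr, na.rm = TRUE)
  mc <- rowMeans(ct, na.rm = TRUE)
  sdc <- apply(ct, 1, stats::sd, na.rm = TRUE)
  keep <- is.finite(sdc) & sdc > 0
  z <- (mt[keep] - mc[keep]) / sdc[keep]
  out <- data.frame(metabolite = rownames(v)[keep],
                    mean_treat = unname(mt[keep]),
                    mean_ctrl = unname(mc[keep]),
                    sd_ctrl = unname(sdc[keep]),
                    z = unname(z),
                    z_clipped = pmin(pmax(unname(z), -2), 2),
                    color = zToColor(unname(z)),
                    row.names = NULL)
  attr(out, "excluded") <- rownames(v)[!keep]
  out
}

#' Map z-scores to the red-white-green color scale
#'
#' Linear interpolation from white at z = 0 to red at z = +2 and green at
#' z = -2, clamped beyond: z >= +2 is pure red \code{#FF0000}, z <= -2
#' pure green \code{#00FF00}, z = +1 the midpoint \code{#FF8080}.
#'
#' @param z numeric vector of finite z-scores.
#' @return character vector of hex colors.
#' @export
zToColor <- function(z) {
  if (any(!is.finite(z))) .stopf("z must be finite")
  t <- pmin(pmax(z, -2), 2) / 2
  lo <- as.integer(round(255 * (1 - abs(t))))
  hex <- sprintf("#%02X%02X%02X",
                 ifelse(t >= 0, 255L, lo),
                 ifelse(t >= 0, lo, 255L),
                 lo)
  hex
}

#' Build the pathway-grouped effect network
#'
#' Star topology: one hub node per pathway, annotated with its impact and
#' fraction of impact, and one leaf node per metabolite, annotated with
#' z-score, clipped z, color, VIP and significance, joined by membership
#' edges.  By default only significant metabolites are included
#' (\code{significantOnly = FALSE} renders every scored metabolite, with
#' hubs for their pathways even when unaffected).
#'
#' @param scores z-score table from \code{\link{computeZScores}}.
#' @param impact an \linkS4class{ImpactTable}.
#' @param map a \linkS4class{PathwayMap}; must agree with \code{impact}
#'   on pathway sizes.
#' @param ranking optional \linkS4class{VipRanking} supplying VIP scores
#'   and significance flags (required when \code{significantOnly}).
#' @param significantOnly restrict to significant metabolites (default
#'   \code{TRUE}).
#' @return an \linkS4class{EffectNetwork}.
#' @export
buildNetwork <- function(scores, impact, map, ranking = NULL,
                         significantOnly = TRUE) {
  stopifnot(is(impact, "ImpactTable"), is(map, "PathwayMap"))
  r <- impact@rows
  bad <- r$pathway[!(r$pathway %in% names(map@pathwaySizes)) |
                   r$n_measured != map@pathwaySizes[r$pathway]]
  if (length(bad))
    .stopf("impact table and pathway map disagree on: %s",
           paste(bad, collapse = ", "))
  if (significantOnly) {
    if (is.null(ranking))
      .stopf("a VipRanking is required when significantOnly = TRUE")
    keep <- significantMetabolites(ranking)
  } else keep <- scores$metabolite
  sc <- scores[scores$metabolite %in% keep, , drop = FALSE]
  missing <- setdiff(keep, scores$metabolite)
  if (length(missing))
    .stopf("z-scores missing for metabolite(s): %s",
           paste(utils::head(missing, 5), collapse = ", "))
  if (!nrow(sc)) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(new("EffectNetwork", graph = g))
  }
  pw <- unname(map@assignment[sc$metabolite])
  if (anyNA(pw))
    .stopf("metabolite(s) absent from the pathway map: %s",
           paste(sc$metabolite[is.na(pw)], collapse = ", "))
  vip <- sig <- NULL
  if (!is.null(ranking)) {
    tb <- ranking@table
    vip <- stats::setNames(tb$vip, tb$metabolite)[sc$metabolite]
    sig <- stats::setNames(tb$significant, tb$metabolite)[sc$metabolite]
  }
  hubs <- unique(pw)
  hub_impact <- stats::setNames(rep(0, length(hubs)), hubs)
  hub_frac <- hub_impact
  hit <- intersect(hubs, r$pathway)
  hub_impact[hit] <- r$impact_raw[match(hit, r$pathway)]
  hub_frac[hit] <- r$fraction_raw[match(hit, r$pathway)]
  nodes <- rbind(
    data.frame(name = hubs, type = "pathway", pathway = hubs,
               z = NA_real_, z_clipped = NA_real_, color = NA_character_,
               vip = NA_real_, significant = NA,
               impact = unname(hub_impact), fraction = unname(hub_frac)),
    data.frame(name = sc$metabolite, type = "metabolite", pathway = pw,
               z = sc$z, z_clipped = sc$z_clipped, color = sc$color,
               vip = if (is.null(vip)) NA_real_ else unname(vip),
               significant = if (is.null(sig)) NA else unname(sig),
               impact = NA_real_, fraction = NA_real_))
  edges <- data.frame(from = pw, to = sc$metabolite)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  new("EffectNetwork", graph = g)
}

#' Export an effect network for Cytoscape and graph tools
#'
#' \code{format = "sif"} writes a SIF edge file
#' (\code{pathway<TAB>contains<TAB>metabolite}) plus a node-attribute TSV
#' (\code{<name>_nodes.tsv}: node_id, type, pathway, z, color_hex, vip,
#' significant, impact, fraction); \code{format = "graphml"} writes a
#' single GraphML document with the same attributes, re-parseable to an
#' isomorphic graph.
#'
#' @param net an \linkS4class{EffectNetwork}.
#' @param dir output directory (created if needed).
#' @param name file stem (default \code{"network"}).
#' @param format \code{"sif"} or \code{"graphml"}.
#' @return invisibly, character vector of the written paths.
#' @export
exportNetwork <- function(net, dir, name = "network",
                          format = c("sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(is(net, "EffectNetwork"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- net@graph
  if (format == "graphml") {
    path <- file.path(dir, paste0(name, ".graphml"))
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  sif <- file.path(dir, paste0(name, ".sif"))
  attr_path <- file.path(dir, paste0(name, "_nodes.tsv"))
  if (igraph::ecount(g)) {
    el <- igraph::as_edgelist(g)
    # orient pathway -> metabolite
    ptype <- stats::setNames(igraph::V(g)$type, igraph::V(g)$name)
    flip <- ptype[el[, 1]] == "metabolite"
    el[flip, ] <- el[flip, 2:1]
    writeLines(paste(el[, 1], "contains", el[, 2], sep = "\t"), sif)
  } else writeLines(character(), sif)
  v <- igraph::V(g)
  nodes <- if (igraph::vcount(g))
    data.frame(node_id = v$name, type = v$type, pathway = v$pathway,
               z = v$z, z_clipped = v$z_clipped, color_hex = v$color,
               vip = v$vip, significant = v$significant,
               impact = v$impact, fraction = v$fraction)
  else
    data.frame(node_id = character(), type = character(),
               pathway = character(), z = numeric(), z_clipped = numeric(),
               color_hex = character(), vip = numeric(),
               significant = logical(), impact = numeric(),
               fraction = numeric())
  utils::write.table(nodes, attr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(sif, attr_path))
}
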