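#' Construct a synthetic-dataset specification
#'
#' Defines a four-group (genotype x treatment) targeted-metabolomics
#' design with lognormal baseline abundances, per-sample internal-standard
#' scale factors and planted treatment effects expressed in within-group
#' SD units on the log10 scale (so the expected log-scale z-score of a
#' planted effect equals its delta).
#'
#' @param nPerGroup named integer vector of animals per group (defaults:
#'   WT-Sal 11, WT-Sur 10, KO-Sal 11, KO-Sur 9).
#' @param pathwaySizes named integer vector of metabolites per pathway.
#' @param plantedEffects data.frame(metabolite, group, delta): metabolite
#'   means in \code{group} are shifted by \code{delta} within-group SDs.
#' @param mu0,tau mean and SD of the log10 baseline abundances (defaults
#'   5 and 1: peak areas centred around 1e5 detector units).
#' @param sigmaRange range of within-group log10 SDs, drawn uniformly
#'   (default 0.05-0.3, typical analytical + biological spread for
#'   targeted plasma assays).
#' @param nInternalStandards number of spiked internal standards (default
#'   35, a commercial stable-isotope cocktail).
#' @param sigmaScale sdlog of the per-sample lognormal scale factors s_i
#'   (default 0.2).
#' @param missingRate probability that a non-internal-standard cell is
#'   masked missing (default 0.02).
#' @param seed RNG seed; mandatory.
#' @return a validated \linkS4class{SimSpec}.
#' @seealso \code{\link{studyLikeSpec}}, \code{\link{generateDataset}}
#' @export
simSpec <- function(nPerGroup = c("WT-Sal" = 11L, "WT-Sur" = 10L,
                                  "KO-Sal" = 11L, "KO-Sur" = 9L),
                    pathwaySizes = stats::setNames(
                      rep(10L, 5), sprintf("Pathway_%02d", 1:5)),
                    plantedEffects = data.frame(metabolite = character(),
                                                group = character(),
                                                delta = numeric()),
                    mu0 = 5, tau = 1, sigmaRange = c(0.05, 0.3),
                    nInternalStandards = 35L, sigmaScale = 0.2,
                    missingRate = 0.02, seed) {
  if (missing(seed)) .stopf("seed is mandatory")
  new("SimSpec",
      nPerGroup = stats::setNames(as.integer(nPerGroup), names(nPerGroup)),
      pathwaySizes = stats::setNames(as.integer(pathwaySizes),
                                     names(pathwaySizes)),
      plantedEffects = plantedEffects, mu0 = mu0, tau = tau,
      sigmaRange = sigmaRange,
      nInternalStandards = as.integer(nInternalStandards),
      sigmaScale = sigmaScale, missingRate = missingRate,
      seed = as.integer(seed))
}

#' Study-like specification: 673 metabolites, 60 pathways, 58 planted hits
#'
#' Reproduces the reported design: the 20 affected pathways at their
#' published sizes (purines 41, fatty acid oxidation 39, eicosanoids 36,
#' ..., summing to 532) plus 141 metabolites spread over 40 unnamed filler
#' pathways (21 of size 4, 19 of size 3), for 673 metabolites across 60
#' pathways; 58 planted treatment effects on the KO-Sur group distributed
#' per the published observed-hits column with signs per its direction
#' counts (33 increased, 25 decreased) at magnitude \code{|delta|}
#' within-group SDs; group sizes within the reported 9-11 animals per
#' group.
#'
#' @param seed RNG seed.
#' @param delta planted effect magnitude in control-SD units (default 2).
#' @param nPerGroup named group sizes (see \code{\link{simSpec}}).
#' @param ... further arguments passed to \code{\link{simSpec}}.
#' @return a \linkS4class{SimSpec}.
#' @export
studyLikeSpec <- function(seed, delta = 2,
                          nPerGroup = c("WT-Sal" = 11L, "WT-Sur" = 10L,
                                        "KO-Sal" = 11L, "KO-Sur" = 9L),
                          ...) {
  st <- fragileXPathwayStats()
  filler <- stats::setNames(rep(c(4L, 3L), c(21, 19)),
                            sprintf("Unnamed pathway %02d", 1:40))
  sizes <- c(stats::setNames(as.integer(st$n_measured), st$pathway), filler)
  ids <- .metaboliteIds(sizes)
  assign <- .assignmentFromSizes(sizes)
  eff <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
    hits <- names(assign)[assign == st$pathway[i]][seq_len(st$observed_hits[i])]
    data.frame(metabolite = hits, group = "KO-Sur",
               delta = rep(c(delta, -delta),
                           c(st$n_increased[i], st$n_decreased[i])))
  }))
  rownames(eff) <- NULL
  simSpec(nPerGroup = nPerGroup, pathwaySizes = sizes,
          plantedEffects = eff, seed = seed, ...)
}

#' Pathway map implied by a simulation specification
#'
#' @param spec a \linkS4class{SimSpec}.
#' @return the \linkS4class{PathwayMap} assigning each simulated
#'   metabolite to its pathway.
#' @export
pathwayMapFromSpec <- function(spec) {
  stopifnot(is(spec, "SimSpec"))
  PathwayMap(.assignmentFromSizes(spec@pathwaySizes), synonyms = NULL)
}

#' Generate a synthetic peak-area dataset with ground truth
#'
#' Draws, deterministically under the spec's seed: per-metabolite log10
#' baseline means mu_m ~ Normal(mu0, tau) and within-group SDs
#' sigma_m ~ Uniform(sigmaRange); per-sample scale factors
#' s_i ~ LogNormal(0, sigmaScale); log10 concentrations
#' Normal(mu_m + delta * sigma_m, sigma_m^2) for samples in a planted
#' effect's group (Normal(mu_m, sigma_m^2) otherwise); peak areas
#' 10^conc x s_i; internal-standard areas base_k x s_i (a fixed base per
#' standard, so dividing any emitted area by the true s_i recovers the
#' pre-scaling value exactly); non-IS cells masked missing uniformly at
#' the configured rate.
#'
#' @param spec a \linkS4class{SimSpec}.
#' @return list with \code{peaks} (a \linkS4class{PeakTable}) and
#'   \code{truth}: per-sample \code{scale_factors}, per-metabolite
#'   \code{mu} and \code{sigma}, the planted \code{effects} table and the
#'   \code{planted_significant} id set.
#' @export
generateDataset <- function(spec) {
  stopifnot(is(spec, "SimSpec"))
  validObject(spec)
  set.seed(spec@seed)
  sizes <- spec@pathwaySizes
  mets <- .metaboliteIds(sizes)
  p <- length(mets)
  groups <- rep(names(spec@nPerGroup), spec@nPerGroup)
  n <- length(groups)
  smp <- unlist(lapply(names(spec@nPerGroup), function(g)
    sprintf("%s_%02d", g, seq_len(spec@nPerGroup[[g]]))))
  mu <- stats::rnorm(p, spec@mu0, spec@tau)
  sigma <- stats::runif(p, spec@sigmaRange[1], spec@sigmaRange[2])
  names(mu) <- names(sigma) <- mets
  shift <- matrix(0, p, n, dimnames = list(mets, smp))
  pe <- spec@plantedEffects
  for (i in seq_len(nrow(pe))) {
    j <- match(pe$metabolite[i], mets)
    shift[j, groups == pe$group[i]] <- pe$delta[i] * sigma[j]
  }
  logconc <- mu + shift + sigma * matrix(stats::rnorm(p * n), p, n)
  s <- stats::rlnorm(n, 0, spec@sigmaScale)
  names(s) <- smp
  areas <- sweep(10^logconc, 2, s, "*")
  nIS <- spec@nInternalStandards
  isBase <- 10^stats::rnorm(nIS, 6, 0.2)
  isAreas <- outer(isBase, s)
  rownames(isAreas) <- sprintf("IS%02d", seq_len(nIS))
  colnames(isAreas) <- smp
  if (spec@missingRate > 0) {
    mask <- matrix(stats::runif(p * n) < spec@missingRate, p, n)
    areas[mask] <- NA_real_
  }
  full <- t(rbind(areas, isAreas))  # samples as rows for the constructor
  gt <- do.call(rbind, strsplit(groups, "-"))
  meta <- data.frame(sample_id = smp, genotype = gt[, 1],
                     treatment = gt[, 2], batch = "batch1")
  peaks <- PeakTable(full, meta, internalStandards = rownames(isAreas))
  truth <- list(scale_factors = s, mu = mu, sigma = sigma,
                is_base = stats::setNames(isBase, rownames(isAreas)),
                effects = pe,
                planted_significant = unique(pe$metabolite))
  list(peaks = peaks, truth = truth)
}

#' Write a generated dataset to its on-disk form
#'
#' Emits the peak table, sample metadata, internal-standard list, pathway
#' map and a ground-truth JSON ledger into \code{dir}.
#'
#' @param ds result of \code{\link{generateDataset}}.
#' @param spec the \linkS4class{SimSpec} that produced it.
#' @param dir output directory (created if needed).
#' @return invisibly, named character vector of the written paths.
#' @export
writeDataset <- function(ds, spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(peaks = file.path(dir, "peak_table.tsv"),
             meta = file.path(dir, "sample_metadata.tsv"),
             is = file.path(dir, "internal_standards.txt"),
             map = file.path(dir, "pathway_map.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  writePeakTable(ds$peaks, paths[["peaks"]], paths[["meta"]], paths[["is"]])
  writePathwayMap(pathwayMapFromSpec(spec), paths[["map"]])
  tr <- ds$truth
  jsonlite::write_json(
    list(seed = spec@seed,
         scale_factors = as.list(tr$scale_factors),
         mu = as.list(tr$mu), sigma = as.list(tr$sigma),
         effects = tr$effects,
         planted_significant = tr$planted_significant),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
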