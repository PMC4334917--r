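# in-code fixtures and independent oracles shared across test files

# 4-sample, 3-metabolite + 1-IS toy table; areas chosen so hand arithmetic
# is easy
makeToyPeakTable <- function(areas = NULL) {
  if (is.null(areas))
    areas <- matrix(c(10, 20, 40, 1e5,
                      12, 18, 44, 1e5,
                      30, 60, 80, 1e5,
                      28, 66, 76, 1e5), nrow = 4, byrow = TRUE)
  dimnames(areas) <- list(sprintf("s%d", 1:4), c("m1", "m2", "m3", "IS1"))
  meta <- data.frame(sample_id = sprintf("s%d", 1:4),
                     genotype = "KO",
                     treatment = c("Sal", "Sal", "Sur", "Sur"),
                     batch = "b1")
  PeakTable(areas, meta, internalStandards = "IS1")
}

toyMap <- function() {
  PathwayMap(c(m1 = "Purine metabolism", m2 = "Purine metabolism",
               m3 = "Glycolysis and gluconeogenesis"))
}

# small normalized table straight from values (bypasses normalization)
makeNormalizedTable <- function(values, groups,
                                transform = "none", base = NA_real_) {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%d", 1:n)
  if (is.null(rownames(values))) rownames(values) <- sprintf("m%d", seq_len(nrow(values)))
  gt <- do.call(rbind, strsplit(groups, "-"))
  cd <- S4Vectors::DataFrame(sample_id = colnames(values),
                             genotype = gt[, 1], treatment = gt[, 2],
                             group = groups, row.names = colnames(values))
  prov <- list(scale_factors = stats::setNames(rep(1, n), colnames(values)),
               reference = 1, reference_rule = "unity", n_imputed = 0L,
               high_missing = character(), transform = transform,
               transform_base = base, scaled = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(normalized = values), colData = cd,
    metadata = list(provenance = prov))
  new("NormalizedTable", se)
}

# independent brute-force evaluation of the VIP formula from a fitted
# model's stored weights and ssy (scalar loops, no linear algebra)
bruteVip <- function(m) {
  W <- m@weights; ssy <- m@ssy; p <- nrow(W)
  v <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_len(ncol(W))) acc <- acc + ssy[a] * W[j, a]^2
    v[j] <- sqrt(p * acc / sum(ssy))
  }
  v
}

# first-principles recomputation of every derived impact-table column
bruteImpactRow <- function(sigTable, pathway, assignment, total) {
  hits <- sigTable[assignment[sigTable$metabolite] == pathway, , drop = FALSE]
  N <- sum(assignment == pathway)
  n_sig <- nrow(sigTable)
  p_raw <- N / total
  p_disp <- round(p_raw, if (p_raw >= 0.1) 2 else 3)
  e_disp <- round(p_disp * n_sig, 2)
  imp <- sum(hits$vip)
  list(n_measured = N, prop_expected = p_disp, expected_hits = e_disp,
       observed_hits = nrow(hits),
       fold_enrichment = round(nrow(hits) / e_disp, 2),
       prop_raw = p_raw, expected_raw = p_raw * n_sig,
       fold_enrichment_raw = nrow(hits) / (p_raw * n_sig),
       impact_raw = imp,
       fraction_raw = imp / sum(sigTable$vip),
       n_increased = sum(hits$direction == "increased"),
       n_decreased = sum(hits$direction == "decreased"))
}

# random small VipRanking + map for oracle comparisons
randomRankingAndMap <- function(nPathways = sample(2:10, 1),
                                nMet = sample(5:30, 1)) {
  pws <- sprintf("PW%02d", seq_len(nPathways))
  assign <- stats::setNames(sample(pws, nMet, replace = TRUE),
                            sprintf("X%03d", seq_len(nMet)))
  map <- PathwayMap(assign, synonyms = NULL)
  vip <- stats::setNames(round(stats::runif(nMet, 0, 3), 3), names(assign))
  dirs <- stats::setNames(sample(c("increased", "decreased"), nMet, TRUE),
                          names(assign))
  ranking <- selectSignificant(vip, map, directions = dirs, threshold = 1.5)
  list(ranking = ranking, map = map)
}

contrastFit <- function(ds, ncomp = 3,
                        contrast = c("KO-Sal", "KO-Sur")) {
  nt <- imputeMissing(normalizeByInternalStandards(ds$peaks))
  lt <- logTransform(nt)
  grp <- sampleGroups(ds$peaks)
  in2 <- grp %in% contrast
  sc <- autoscale(lt[, in2])
  list(model = fitPlsda(sc$X, grp[in2], ncomp = ncomp), logt = lt)
}
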