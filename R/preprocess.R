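#' Normalize peak areas by the median internal-standard signal
#'
#' For each sample i the scale factor is
#' \deqn{s_i = \mathrm{median}(\mathrm{IS\ areas\ in\ sample\ } i) / r,}
#' where the reference r is the grand median over samples of the per-sample
#' IS medians (default), so normalized values keep the original magnitude
#' scale; with \code{reference = "unity"} r = 1.  Every non-IS area is
#' divided by s_i and the internal-standard rows are dropped from the
#' output.  This removes any per-sample or per-batch multiplicative factor
#' that applies to all peaks including the internal standards.
#'
#' @param raw a \linkS4class{PeakTable}.
#' @param reference \code{"grand_median"} or \code{"unity"}.
#' @return a \linkS4class{NormalizedTable} with assay \code{"normalized"}
#'   and the scale factors recorded in \code{provenance(x)}.
#' @export
normalizeByInternalStandards <- function(raw,
    reference = c("grand_median", "unity")) {
  reference <- match.arg(reference)
  stopifnot(is(raw, "PeakTable"))
  a <- peakAreas(raw)
  isis <- isInternalStandard(raw)
  ismat <- a[isis, , drop = FALSE]
  med <- apply(ismat, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else stats::median(v)
  })
  bad <- names(med)[is.na(med) | med <= 0]
  if (length(bad))
    .stopf("sample(s) with all-missing or non-positive internal-standard areas: %s",
           paste(bad, collapse = ", "))
  ref <- if (reference == "grand_median") stats::median(med) else 1
  s <- med / ref
  vals <- sweep(a[!isis, , drop = FALSE], 2, s, "/")
  prov <- list(scale_factors = s, reference = ref,
               reference_rule = reference, n_imputed = 0L,
               high_missing = character(), transform = "none",
               transform_base = NA_real_, scaled = FALSE)
  se <- SummarizedExperiment(
    assays = list(normalized = vals),
    colData = colData(raw),
    metadata = list(provenance = prov))
  new("NormalizedTable", se)
}

#' Impute missing values by the half-minimum rule
#'
#' Each missing cell is replaced by half the minimum observed positive
#' value of that metabolite (the small-value replacement conventional for
#' targeted metabolomics).  Metabolites missing in more than 50% of
#' samples are flagged in the provenance record; a metabolite missing in
#' all samples (or with no positive observation to anchor the replacement)
#' is an error.
#'
#' @param t a \linkS4class{NormalizedTable}.
#' @param rule \code{"half_min"} or \code{"none"} (leave missing cells).
#' @return a \linkS4class{NormalizedTable} without missing entries (for
#'   \code{rule = "half_min"}).
#' @export
imputeMissing <- function(t, rule = c("half_min", "none")) {
  rule <- match.arg(rule)
  stopifnot(is(t, "NormalizedTable"))
  if (rule == "none") return(t)
  v <- normValues(t)
  nmiss <- rowSums(is.na(v))
  if (!any(nmiss > 0)) return(t)
  high <- rownames(v)[nmiss / ncol(v) > 0.5]
  for (j in which(nmiss > 0)) {
    obs <- v[j, !is.na(v[j, ])]
    pos <- obs[obs > 0]
    if (!length(obs))
      .stopf("metabolite '%s' is missing in all samples; cannot impute",
             rownames(v)[j])
    if (!length(pos))
      .stopf("metabolite '%s' has no positive observed value to anchor imputation",
             rownames(v)[j])
    v[j, is.na(v[j, ])] <- min(pos) / 2
  }
  prov <- metadata(t)$provenance
  prov$n_imputed <- prov$n_imputed + as.integer(sum(nmiss))
  prov$high_missing <- union(prov$high_missing, high)
  .withValues(t, v, prov)
}

#' Log-transform normalized values
#'
#' Elementwise logarithm prior to multivariate analysis.  All values must
#' be strictly positive (impute first); the transform and base are recorded
#' in the provenance.
#'
#' @param t a \linkS4class{NormalizedTable} without missing values.
#' @param base 10 (default), 2, or \code{exp(1)}.
#' @return the transformed \linkS4class{NormalizedTable}.
#' @export
logTransform <- function(t, base = 10) {
  stopifnot(is(t, "NormalizedTable"))
  v <- normValues(t)
  if (anyNA(v)) .stopf("missing values present; impute before log-transform")
  if (any(v <= 0)) {
    bad <- which(v <= 0, arr.ind = TRUE)[1, ]
    .stopf("non-positive value for metabolite '%s' in sample '%s'",
           rownames(v)[bad[1]], colnames(v)[bad[2]])
  }
  label <- if (base == 10) "log10" else if (base == 2) "log2"
           else if (isTRUE(all.equal(base, exp(1)))) "ln"
           else .stopf("base must be 10, 2 or exp(1)")
  prov <- metadata(t)$provenance
  if (prov$transform != "none") .stopf("table is already log-transformed")
  prov$transform <- label
  prov$transform_base <- base
  .withValues(t, log(v, base = base), prov)
}

.withValues <- function(t, v, prov) {
  se <- SummarizedExperiment(assays = list(normalized = v),
                             colData = colData(t),
                             metadata = list(provenance = prov))
  new("NormalizedTable", se)
}

#' Mean-center and (optionally) unit-variance scale the analysis matrix
#'
#' Produces the samples-by-metabolites matrix consumed by
#' \code{\link{fitPlsda}}: columns are mean-centered and, by default,
#' divided by their sample standard deviation (autoscaling).  Zero-variance
#' columns are centered only and flagged, not dropped.
#'
#' @param t a \linkS4class{NormalizedTable} (log-transformed).
#' @param unitVariance divide by column SD (default \code{TRUE}).
#' @return list with \code{X} (n x p analysis matrix), \code{center},
#'   \code{scale} (1 for flagged columns), and \code{constant} (ids of
#'   zero-variance metabolites).
#' @export
autoscale <- function(t, unitVariance = TRUE) {
  stopifnot(is(t, "NormalizedTable"))
  v <- normValues(t)
  if (anyNA(v)) .stopf("missing values present; impute before scaling")
  X <- t(v)  # samples as rows for the model fit
  ctr <- colMeans(X)
  X <- sweep(X, 2, ctr, "-")
  sds <- apply(X, 2, stats::sd)
  constant <- colnames(X)[sds == 0]
  scl <- rep(1, ncol(X))
  if (unitVariance) {
    scl <- ifelse(sds == 0, 1, sds)
    X <- sweep(X, 2, scl, "/")
  }
  list(X = X, center = ctr, scale = stats::setNames(scl, colnames(X)),
       constant = constant)
}
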