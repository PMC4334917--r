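test_that("generation is deterministic under the spec seed", {
  s1 <- generateDataset(simSpec(seed = 42))
  s2 <- generateDataset(simSpec(seed = 42))
  expect_identical(peakAreas(s1$peaks), peakAreas(s2$peaks))
  expect_identical(s1$truth, s2$truth)
  s3 <- generateDataset(simSpec(seed = 43))
  expect_false(identical(peakAreas(s1$peaks), peakAreas(s3$peaks)))
})

test_that("the study-like spec reproduces the published design", {
  spec <- studyLikeSpec(seed = 1)
  expect_identical(sum(spec@pathwaySizes), 673L)
  expect_identical(length(spec@pathwaySizes), 60L)
  named <- spec@pathwaySizes[fragileXPathwayStats()$pathway]
  expect_identical(sum(named), 532L)
  expect_identical(nrow(spec@plantedEffects), 58L)
  expect_identical(sum(spec@plantedEffects$delta > 0), 33L)
  expect_identical(unname(spec@nPerGroup),
                   c(11L, 10L, 11L, 9L))  # within the 9-11 per group design
  expect_true(all(spec@plantedEffects$group == "KO-Sur"))
})

test_that("spec invariants are enforced", {
  expect_error(simSpec(seed = 1, missingRate = 1), "missingRate")
  expect_error(simSpec(seed = 1, nPerGroup = c("KO-Sal" = 1L,
                                               "KO-Sur" = 9L)),
               "at least 2")
  expect_error(simSpec(), "seed")
  expect_error(simSpec(seed = 1, plantedEffects = data.frame(
    metabolite = "nope", group = "KO-Sur", delta = 2)), "planted")
})

test_that("null data are calibrated: no planted effects means near-null z-scores", {
  fr <- mz <- numeric(5)
  for (i in 1:5) {
    ds <- generateDataset(simSpec(
      seed = 300 + i, missingRate = 0,
      pathwaySizes = stats::setNames(rep(25L, 8), sprintf("P%d", 1:8))))
    lt <- logTransform(normalizeByInternalStandards(ds$peaks))
    z <- computeZScores(lt, "KO-Sur", "KO-Sal", scale = "log")
    mz[i] <- mean(z$z)
    fr[i] <- mean(abs(z$z) > 2)
  }
  # sd(zhat) ~ sqrt(1/9 + 1/11) ~ 0.45 under the null; |z| > 2 is ~4.4 sigma
  expect_lt(abs(mean(mz)), 0.1)
  expect_lt(mean(fr), 0.02)
})

test_that("a planted two-SD effect is recovered by the z-score within its sampling envelope", {
  meds <- numeric(5)
  for (i in 1:5) {
    spec <- studyLikeSpec(seed = 400 + i, missingRate = 0,
                          nPerGroup = c("WT-Sal" = 10L, "WT-Sur" = 10L,
                                        "KO-Sal" = 10L, "KO-Sur" = 10L))
    ds <- generateDataset(spec)
    lt <- logTransform(normalizeByInternalStandards(ds$peaks))
    z <- computeZScores(lt, "KO-Sur", "KO-Sal", scale = "log")
    zs <- stats::setNames(z$z, z$metabolite)
    eff <- ds$truth$effects
    meds[i] <- stats::median(sign(eff$delta) * zs[eff$metabolite])
  }
  expect_gte(stats::median(meds), 1)
  expect_lte(stats::median(meds), 3)
})

test_that("dividing emitted areas by the true scale factors removes them exactly", {
  ds <- generateDataset(simSpec(seed = 9, missingRate = 0))
  s <- ds$truth$scale_factors
  a <- peakAreas(ds$peaks)
  unscaled <- sweep(a, 2, s, "/")
  # internal standards collapse to their fixed base values
  isr <- unscaled[isInternalStandard(ds$peaks), ]
  expect_equal(apply(isr, 1, function(r) max(abs(r / r[1] - 1))),
               stats::setNames(rep(0, nrow(isr)), rownames(isr)),
               tolerance = 1e-12)
  expect_equal(isr[, 1], ds$truth$is_base, tolerance = 1e-12)
})

test_that("the full pipeline ranks planted metabolites above the null and finds the top pathway", {
  spec <- studyLikeSpec(seed = 77)
  ds <- generateDataset(spec)
  fit <- contrastFit(ds)
  v <- vipScores(fit$model)
  planted <- names(v) %in% ds$truth$planted_significant
  expect_gt(median(v[planted]), median(v[!planted]))
  # impact ranking: the top pathway is among the three with most planted hits
  z <- computeZScores(fit$logt, "KO-Sur", "KO-Sal")
  map <- pathwayMapFromSpec(spec)
  rk <- selectSignificant(v, map,
                          directions = stats::setNames(z$z, z$metabolite))
  it <- buildImpactTable(rk, map)
  # pathways carrying at least as many planted hits as the third-largest
  # count (tie-inclusive: several pathways tie at 6 hits)
  hits <- table(pathwayAssignment(map)[ds$truth$planted_significant])
  cutoff <- sort(as.integer(hits), decreasing = TRUE)[3]
  expect_true(impactRows(it)$pathway[1] %in% names(hits)[hits >= cutoff])
})

test_that("the rank-sum AUROC identity agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  score <- c(rnorm(30, 1), rnorm(70))
  positive <- rep(c(TRUE, FALSE), c(30, 70))
  ref <- as.numeric(pROC::auc(pROC::roc(response = positive,
                                        predictor = score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(MetaboImpact:::.rankAuroc(score, positive), ref,
               tolerance = 1e-12)
})
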