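test_that("the replayed study fixture reproduces the published purine row and totals", {
  map <- pathwayMapFromSpec(studyLikeSpec(seed = 1))
  rk <- replayVipTable(map)
  expect_identical(length(significantMetabolites(rk)), 58L)
  it <- buildImpactTable(rk, map)
  r <- impactRows(it)
  pur <- r[r$pathway == "Purine metabolism", ]
  expect_identical(pur$n_measured, 41L)
  expect_identical(pur$prop_expected, 0.061)
  expect_identical(pur$expected_hits, 3.54)
  expect_identical(pur$observed_hits, 5L)
  expect_identical(pur$fold_enrichment, 1.41)
  expect_identical(pur$impact, 27.2)
  expect_identical(pur$fraction_pct, 20.0)
  expect_identical(directionCounts(rk, "Purine metabolism"),
                   c(n_increased = 1L, n_decreased = 4L))
  expect_identical(MetaboImpact:::.renderDirection(1, 4), "4/5 Decreased")
  tot <- impactTotals(it)
  expect_identical(tot$n_pathways_hit, 20L)
  expect_identical(tot$n_pathways_total, 60L)
  expect_identical(tot$n_measured_hit, 532L)
  expect_identical(tot$n_significant, 58L)
  expect_identical(tot$n_increased, 33L)
  expect_identical(tot$combined_expected, 46L)
  expect_equal(tot$total_impact, 136.0, tolerance = 1e-9)
  # the fatty-acid row carries 12.4% of the total impact
  fat <- r[r$pathway == "Fatty acid oxidation and synthesis", ]
  expect_identical(fat$fraction_pct, 12.4)
  # every printed impact and fraction is reproduced by the reconstruction
  st <- fragileXPathwayStats()
  expect_identical(r$impact, st$impact[match(r$pathway, st$pathway)])
})

test_that("degenerate impact configurations behave as specified", {
  map <- PathwayMap(c(a = "p1", b = "p1", c = "p2", d = "p2"),
                    synonyms = NULL)
  # all significant metabolites in one pathway -> 100% of impact
  rk <- selectSignificant(c(a = 2, b = 1.8, c = 0.2, d = 0.1), map,
                          directions = c(a = 1, b = 1, c = 1, d = -1))
  it <- buildImpactTable(rk, map)
  expect_identical(nrow(impactRows(it)), 1L)
  expect_identical(impactRows(it)$fraction_pct, 100)
  expect_equal(impactRows(it)$fraction_raw, 1)
  # observed equal to expected gives fold enrichment exactly 1
  map2 <- PathwayMap(stats::setNames(rep(c("p1", "p2"), each = 10),
                                     sprintf("x%02d", 1:20)),
                     synonyms = NULL)
  vip <- stats::setNames(c(rep(2, 2), rep(0.1, 8), rep(2, 2), rep(0.1, 8)),
                         sprintf("x%02d", 1:20))
  rk2 <- selectSignificant(vip, map2,
                           directions = stats::setNames(rep(1, 20),
                                                        names(vip)))
  it2 <- buildImpactTable(rk2, map2)
  expect_equal(it2@rows$fold_enrichment, c(1, 1))
  # empty significant set -> empty table with zero totals
  none <- selectSignificant(stats::setNames(rep(0.1, 20), names(vip)),
                            map2, directions = NULL)
  it0 <- buildImpactTable(none, map2)
  expect_identical(nrow(impactRows(it0)), 0L)
  expect_identical(impactTotals(it0)$total_impact, 0)
})

test_that("every derived column equals first-principles recomputation on random instances", {
  set.seed(10)
  for (i in 1:40) {
    rm <- randomRankingAndMap()
    it <- buildImpactTable(rm$ranking, rm$map)
    r <- impactRows(it)
    sig <- rankingTable(rm$ranking)
    sig <- sig[sig$significant, ]
    if (!nrow(sig)) {
      expect_identical(nrow(r), 0L)
      next
    }
    assign <- pathwayAssignment(rm$map)
    for (k in seq_len(nrow(r))) {
      o <- bruteImpactRow(sig, r$pathway[k], assign, rm$map@totalMeasured)
      for (col in names(o))
        expect_equal(r[[col]][k], o[[col]], tolerance = 1e-12,
                     label = sprintf("%s[%s]", col, r$pathway[k]))
    }
    # conservation across the table
    expect_identical(sum(r$observed_hits), nrow(sig))
    expect_equal(sum(r$impact_raw), sum(sig$vip), tolerance = 1e-9)
    expect_equal(sum(r$fraction_raw), 1, tolerance = 1e-9)
    # sorted by impact descending, ties by name
    expect_identical(order(-r$impact_raw, r$pathway), seq_len(nrow(r)))
  }
})

test_that("adding a significant metabolite never decreases a pathway's impact or hits", {
  set.seed(11)
  map <- PathwayMap(stats::setNames(rep(c("p1", "p2", "p3"), each = 5),
                                    sprintf("m%02d", 1:15)), synonyms = NULL)
  vip <- stats::setNames(runif(15, 0, 3), sprintf("m%02d", 1:15))
  dirs <- stats::setNames(rep(1, 15), names(vip))
  base <- buildImpactTable(selectSignificant(vip, map, directions = dirs),
                           map)
  # promote one previously non-significant metabolite
  low <- names(vip)[vip < 1.5][1]
  vip2 <- vip; vip2[low] <- 1.7
  more <- buildImpactTable(selectSignificant(vip2, map, directions = dirs),
                           map)
  pw <- pathwayAssignment(map)[[low]]
  get <- function(it, col) {
    r <- impactRows(it); x <- r[[col]][r$pathway == pw]
    if (length(x)) x else 0
  }
  expect_gte(get(more, "observed_hits"), get(base, "observed_hits") + 1L)
  expect_gt(get(more, "impact_raw"), get(base, "impact_raw"))
})
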