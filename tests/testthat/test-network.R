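test_that("z-scores follow the treated-minus-control over control-SD definition", {
  # both groups share the spread (sd 2), so the swap negates z exactly
  v <- matrix(c(10, 12, 14, 10, 12, 14,   # treat = ctrl -> z = 0
                10, 12, 14, 14, 16, 18),  # treat mean = ctrl + 2 sd -> z = 2
              nrow = 2, byrow = TRUE,
              dimnames = list(c("m1", "m2"), sprintf("s%d", 1:6)))
  grp <- rep(c("KO-Sal", "KO-Sur"), each = 3)
  nt <- makeNormalizedTable(v, grp)
  z <- computeZScores(nt, "KO-Sur", "KO-Sal")
  expect_equal(z$z[z$metabolite == "m1"], 0)
  expect_equal(z$z[z$metabolite == "m2"], 2)
  expect_equal(z$sd_ctrl, c(2, 2))
  # the swap negates z exactly here (equal group SDs); in general the
  # control-SD denominator changes, but the sign always flips
  zr <- computeZScores(nt, "KO-Sal", "KO-Sur")
  expect_equal(zr$z, -z$z)
  set.seed(41)
  vr <- matrix(10 + rnorm(40), 4, 10,
               dimnames = list(sprintf("m%d", 1:4), sprintf("s%d", 1:10)))
  ntr <- makeNormalizedTable(vr, rep(c("KO-Sal", "KO-Sur"), each = 5))
  za <- computeZScores(ntr, "KO-Sur", "KO-Sal")
  zb <- computeZScores(ntr, "KO-Sal", "KO-Sur")
  expect_equal(sign(zb$z), -sign(za$z))
  expect_equal(zb$z * zb$sd_ctrl, -(za$z * za$sd_ctrl))
  expect_error(computeZScores(nt, "KO-Sur", "nope"), "unknown group")
})

test_that("zero-SD metabolites are excluded and reported", {
  v <- matrix(c(5, 5, 5, 6, 7, 8,
                1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE,
              dimnames = list(c("flat", "ok"), sprintf("s%d", 1:6)))
  nt <- makeNormalizedTable(v, rep(c("KO-Sal", "KO-Sur"), each = 3))
  z <- computeZScores(nt, "KO-Sur", "KO-Sal")
  expect_identical(z$metabolite, "ok")
  expect_identical(attr(z, "excluded"), "flat")
})

test_that("the color scale is white at zero, clamped at two, monotone in between", {
  expect_identical(zToColor(0), "#FFFFFF")
  expect_identical(zToColor(3), "#FF0000")
  expect_identical(zToColor(2), "#FF0000")
  expect_identical(zToColor(1), "#FF8080")
  expect_identical(zToColor(-2), "#00FF00")
  expect_identical(zToColor(-5), "#00FF00")
  expect_error(zToColor(NaN), "finite")
  # monotone: green/blue channels fall as z rises on [0, 2]
  zz <- seq(0, 2, by = 0.05)
  gb <- strtoi(substr(zToColor(zz), 4, 5), 16L)
  expect_true(all(diff(gb) <= 0))
  rch <- strtoi(substr(zToColor(seq(-2, 0, 0.05)), 2, 3), 16L)
  expect_true(all(diff(rch) >= 0))
})

test_that("a toy network has one hub per pathway and one edge per metabolite", {
  map <- PathwayMap(stats::setNames(rep(c("p1", "p2"), each = 3),
                                    sprintf("m%d", 1:6)), synonyms = NULL)
  v <- matrix(rep(c(1, 2, 3, 4, 5, 6), each = 6), nrow = 6, byrow = TRUE,
              dimnames = list(sprintf("m%d", 1:6), sprintf("s%d", 1:6)))
  v <- v + matrix(seq(0.1, 3.6, by = 0.1), 6, 6)
  nt <- makeNormalizedTable(v, rep(c("KO-Sal", "KO-Sur"), each = 3))
  z <- computeZScores(nt, "KO-Sur", "KO-Sal")
  vip <- stats::setNames(rep(2, 6), sprintf("m%d", 1:6))
  rk <- selectSignificant(vip, map,
                          directions = stats::setNames(z$z, z$metabolite))
  it <- buildImpactTable(rk, map)
  net <- buildNetwork(z, it, map, rk)
  g <- networkGraph(net)
  expect_identical(sum(igraph::V(g)$type == "pathway"), 2L)
  expect_identical(sum(igraph::V(g)$type == "metabolite"), 6L)
  expect_equal(igraph::ecount(g), 6)
  expect_true(validObject(net))

  d <- withr::local_tempdir()
  paths <- exportNetwork(net, d, "toy", "sif")
  expect_length(readLines(paths[1]), 6L)
  attrs <- read.delim(paths[2])
  expect_identical(nrow(attrs), 8L)
  expect_true(all(grepl("^p", attrs$node_id[attrs$type == "pathway"])))
  # disagreement between impact table and map is rejected
  map2 <- PathwayMap(stats::setNames(rep(c("p1", "p2"), c(2, 4)),
                                     sprintf("m%d", 1:6)), synonyms = NULL)
  expect_error(buildNetwork(z, it, map2, rk), "disagree")
})

test_that("the study replay network carries 20 pathway hubs with impact annotations", {
  spec <- studyLikeSpec(seed = 3, missingRate = 0)
  map <- pathwayMapFromSpec(spec)
  rk <- replayVipTable(map)
  it <- buildImpactTable(rk, map)
  ds <- generateDataset(spec)
  lt <- logTransform(normalizeByInternalStandards(ds$peaks))
  z <- computeZScores(lt, "KO-Sur", "KO-Sal")
  net <- buildNetwork(z, it, map, rk)
  g <- networkGraph(net)
  expect_identical(sum(igraph::V(g)$type == "pathway"), 20L)
  expect_identical(sum(igraph::V(g)$type == "metabolite"), 58L)
  hub <- which(igraph::V(g)$name == "Purine metabolism")
  expect_equal(igraph::V(g)$impact[hub], 27.2, tolerance = 1e-9)
  expect_equal(igraph::V(g)$fraction[hub], 0.2, tolerance = 1e-9)
})

test_that("an empty significant set yields an empty graph", {
  map <- toyMap()
  v <- matrix(1:12 + 0.5, 3, 4,
              dimnames = list(c("m1", "m2", "m3"), sprintf("s%d", 1:4)))
  nt <- makeNormalizedTable(v, rep(c("KO-Sal", "KO-Sur"), each = 2))
  z <- computeZScores(nt, "KO-Sur", "KO-Sal")
  rk <- selectSignificant(c(m1 = 0.1, m2 = 0.2, m3 = 0.3), map,
                          directions = stats::setNames(z$z, z$metabolite))
  net <- buildNetwork(z, buildImpactTable(rk, map), map, rk)
  expect_equal(igraph::vcount(networkGraph(net)), 0)
  d <- withr::local_tempdir()
  paths <- exportNetwork(net, d, "empty", "sif")
  expect_length(readLines(paths[1]), 0L)
})

test_that("GraphML export re-parses to an isomorphic graph with identical attributes", {
  map <- PathwayMap(stats::setNames(rep(c("p1", "p2"), each = 3),
                                    sprintf("m%d", 1:6)), synonyms = NULL)
  set.seed(12)
  v <- matrix(10 + rnorm(36), 6, 6,
              dimnames = list(sprintf("m%d", 1:6), sprintf("s%d", 1:6)))
  nt <- makeNormalizedTable(v, rep(c("KO-Sal", "KO-Sur"), each = 3))
  z <- computeZScores(nt, "KO-Sur", "KO-Sal")
  vip <- stats::setNames(seq(1.5, 2.5, length.out = 6), sprintf("m%d", 1:6))
  rk <- selectSignificant(vip, map,
                          directions = stats::setNames(z$z, z$metabolite))
  net <- buildNetwork(z, buildImpactTable(rk, map), map, rk)
  d <- withr::local_tempdir()
  path <- exportNetwork(net, d, "net", "graphml")
  back <- igraph::read_graph(path, format = "graphml")
  g <- networkGraph(net)
  expect_true(igraph::isomorphic(g, back))
  # attribute fidelity on the metabolite leaves (hubs carry NA placeholders)
  ord <- match(igraph::V(g)$name, igraph::V(back)$name)
  met <- which(igraph::V(g)$type == "metabolite")
  expect_identical(igraph::V(back)$color[ord][met],
                   igraph::V(g)$color[met])
  expect_equal(igraph::V(back)$z[ord][met], igraph::V(g)$z[met])
  expect_equal(igraph::V(back)$vip[ord][met], igraph::V(g)$vip[met])
  # the zero-effect node renders white in the attribute export
  z0 <- z; z0$z[1] <- 0; z0$z_clipped[1] <- 0; z0$color[1] <- zToColor(0)
  net0 <- buildNetwork(z0, buildImpactTable(rk, map), map, rk)
  sifp <- exportNetwork(net0, d, "net0", "sif")
  attrs <- read.delim(sifp[2])
  expect_identical(attrs$color_hex[attrs$node_id == "m1"], "#FFFFFF")
})
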