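test_that("group separation along one metabolite dominates the first weight vector", {
  set.seed(2)
  n <- 20; p <- 8
  X <- matrix(rnorm(n * p, sd = 0.3), n, p,
              dimnames = list(NULL, paste0("m", 1:p)))
  grp <- rep(c("KO-Sal", "KO-Sur"), each = 10)
  X[grp == "KO-Sur", 1] <- X[grp == "KO-Sur", 1] + 3
  X <- scale(X, scale = FALSE)
  m <- fitPlsda(X, grp, ncomp = 2)
  expect_identical(unname(which.max(abs(m@weights[, 1]))), 1L)
  expect_gt(abs(m@weights[1, 1]), 0.9)
})

test_that("the one-component weight equals the dominant left singular vector of X'Y", {
  set.seed(3)
  for (i in 1:100) {
    X <- matrix(rnorm(60), 10, 6)
    X <- scale(X, scale = FALSE)
    grp <- sample(rep(c("A", "B"), each = 5))
    m <- fitPlsda(X, grp, ncomp = 1)
    Y <- groupEncoding(grp)$Y
    u1 <- svd(crossprod(X, Y))$u[, 1]
    expect_equal(abs(as.vector(m@weights[, 1])), abs(u1), tolerance = 1e-8)
  }
})

test_that("fitted scores are mutually orthogonal and weights unit-norm on random inputs", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(8:16, 1); p <- sample(4:12, 1)
    X <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
    grp <- sample(rep(c("A", "B"), length.out = n))
    if (min(table(grp)) < 2) next
    A <- min(3, n - 1, p)
    m <- suppressWarnings(fitPlsda(X, grp, ncomp = A))
    G <- crossprod(m@scores)
    off <- abs(G - diag(diag(G), nrow = nrow(G)))
    expect_lt(max(off), 1e-8 * max(diag(G)))
    expect_equal(unname(sqrt(colSums(m@weights^2))), rep(1, m@ncomp),
                 tolerance = 1e-10)
  }
})

test_that("VIP obeys its closed forms and matches a brute-force re-evaluation", {
  # p = 2, one component, equal weights -> both VIPs are 1
  base <- fitPlsda(
    scale(matrix(c(1, -1, 2, -2, 1.1, -0.9, 2.2, -1.6), 4, 2), scale = FALSE),
    c("A", "B", "A", "B"), ncomp = 1)
  w <- matrix(c(1, 1) / sqrt(2), 2, 1)
  m1 <- base; m1@weights <- w; m1@ssy <- 2; m1@metabolites <- c("a", "b")
  expect_equal(unname(computeVip(m1)), c(1, 1))
  # p = 2, w = (1, 0) -> VIP = (sqrt(2), 0)
  m2 <- m1; m2@weights <- matrix(c(1, 0), 2, 1)
  expect_equal(unname(computeVip(m2)), c(sqrt(2), 0))
  # random two-component fits: independent scalar-loop evaluation agrees
  set.seed(5)
  for (i in 1:10) {
    X <- scale(matrix(rnorm(12 * 8), 12, 8), scale = FALSE)
    grp <- rep(c("A", "B"), each = 6)
    m <- fitPlsda(X, grp, ncomp = 2)
    expect_equal(unname(vipScores(m)), bruteVip(m), tolerance = 1e-12)
    expect_equal(sum(vipScores(m)^2), 8, tolerance = 1e-9)
  }
})

test_that("VIP is equivariant under column permutation", {
  set.seed(6)
  X <- scale(matrix(rnorm(14 * 10), 14, 10,
                    dimnames = list(NULL, paste0("m", 1:10))), scale = FALSE)
  grp <- rep(c("A", "B"), each = 7)
  v <- vipScores(fitPlsda(X, grp, ncomp = 3))
  perm <- sample(10)
  vp <- vipScores(fitPlsda(X[, perm], grp, ncomp = 3))
  expect_equal(unname(vp), unname(v[perm]), tolerance = 1e-9)
})

test_that("an independent PLS-DA implementation reproduces scores and VIP", {
  skip_if_not_installed("mixOmics")
  set.seed(7)
  X <- matrix(rnorm(20 * 15), 20, 15,
              dimnames = list(paste0("s", 1:20), paste0("m", 1:15)))
  grp <- rep(c("A", "B"), each = 10)
  X[grp == "B", 1:3] <- X[grp == "B", 1:3] + 1.5
  Xs <- scale(X)
  mine <- fitPlsda(Xs, grp, ncomp = 2)
  ref <- mixOmics::plsda(X, factor(grp), ncomp = 2, scale = TRUE)
  refVip <- mixOmics::vip(ref)
  expect_equal(unname(vipScores(mine)), unname(refVip[, 2]),
               tolerance = 1e-8)
  expect_equal(abs(unname(mine@scores)),
               abs(unname(ref$variates$X)), tolerance = 1e-6)
})

test_that("rank-deficient requests truncate with a warning and degenerate fits error", {
  X <- scale(matrix(rnorm(12), 6, 2), scale = FALSE)
  grp <- rep(c("A", "B"), each = 3)
  expect_error(fitPlsda(X, grp, ncomp = 3), "ncomp")
  # rank 1 matrix: second component cannot be extracted
  X1 <- outer(c(rep(-1, 3), rep(1, 3)), c(1, 2))
  X1 <- scale(X1 + 0, scale = FALSE)
  expect_warning(m <- fitPlsda(X1, grp, ncomp = 2), "rank")
  expect_identical(m@ncomp, 1L)
  expect_error(fitPlsda(X, c("A", "A", "A", "A", "A", "B")), "2 samples")
  expect_error(groupEncoding(rep("A", 4)), "2 groups")
})

test_that("score projections carry groups and refuse k beyond the fit", {
  set.seed(8)
  ds <- generateDataset(studyLikeSpec(seed = 21, missingRate = 0))
  nt <- logTransform(normalizeByInternalStandards(ds$peaks))
  sc <- autoscale(nt)
  grp <- sampleGroups(ds$peaks)
  m4 <- fitPlsda(sc$X, grp, ncomp = 3)
  pr <- projectScores(m4, 3)
  expect_named(pr, c("sample_id", "group", "t1", "t2", "t3"))
  expect_identical(nrow(pr), 41L)
  expect_error(projectScores(m4, 4), "exceeds")
  # planted KO-Sur shift separates the treated centroid from control
  cen <- vapply(split(pr$t1, pr$group), mean, 1)
  wsd <- vapply(split(pr$t1, pr$group), sd, 1)
  expect_gt(abs(cen[["KO-Sur"]] - cen[["KO-Sal"]]),
            max(wsd[c("KO-Sal", "KO-Sur")]))
  # k = A returns the full score matrix
  expect_equal(as.matrix(pr[, 3:5]), unname(m4@scores), ignore_attr = TRUE)
})

test_that("significance thresholding is inclusive at the boundary and validated", {
  map <- PathwayMap(c(a = "p1", b = "p1", c = "p2"), synonyms = NULL)
  vip <- c(a = 1.6, b = 1.5, c = 1.49)
  dirs <- c(a = 1, b = -2, c = 0.5)
  rk <- selectSignificant(vip, map, directions = dirs)
  expect_identical(significantMetabolites(rk), c("a", "b"))
  expect_identical(rankingTable(rk)$direction[1:2],
                   c("increased", "decreased"))
  strict <- selectSignificant(vip, map, directions = dirs, inclusive = FALSE)
  expect_identical(significantMetabolites(strict), "a")
  # all below threshold: nothing significant
  none <- selectSignificant(c(a = 0.2, b = 0.1, c = 0), map,
                            directions = dirs)
  expect_length(significantMetabolites(none), 0)
  # unmapped metabolite and missing direction are errors
  expect_error(selectSignificant(c(zz = 2), map, directions = c(zz = 1)),
               "pathway")
  expect_error(selectSignificant(vip, map), "direction")
})
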