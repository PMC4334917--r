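#' Indicator (dummy) encoding of sample group labels
#'
#' @param groups factor or character vector of group labels, one per
#'   sample.
#' @param levels optional explicit level order for the indicator columns.
#' @return list with \code{groups} (factor) and \code{Y}, the n x g
#'   indicator matrix (each row sums to 1; g >= 2).
#' @export
groupEncoding <- function(groups, levels = NULL) {
  f <- if (is.null(levels)) factor(groups) else factor(groups, levels = levels)
  if (anyNA(f)) .stopf("unknown group label(s)")
  g <- nlevels(f)
  if (g < 2) .stopf("need at least 2 groups, got %d", g)
  Y <- matrix(0, length(f), g, dimnames = list(names(groups), levels(f)))
  Y[cbind(seq_along(f), as.integer(f))] <- 1
  list(groups = f, Y = Y)
}

#' Fit partial least squares discriminant analysis by NIPALS
#'
#' PLS2 regression of the group indicator matrix on the (centered, usually
#' autoscaled) metabolite matrix, one component at a time.  Per component:
#' iterate \eqn{w = X^T u / \|X^T u\|}, \eqn{t = Xw},
#' \eqn{q = Y^T t / t^T t}, \eqn{u = Yq} until the score change drops
#' below 1e-10 (up to \code{maxit} iterations; non-convergence is an error
#' naming the component), then deflate X by \eqn{t p^T} with
#' \eqn{p = X^T t / t^T t} and Y by \eqn{t q^T}.  The explained class
#' sum-of-squares per component is \eqn{ssy_a = (q_a^T q_a)(t_a^T t_a)}.
#' Sign indeterminacy is resolved by making each weight column's
#' largest-magnitude entry positive; the latent vector u is initialized
#' from the Y column with the largest variance, so fits are deterministic.
#' Components beyond the rank of X are dropped with a warning.
#'
#' @param X numeric n x p analysis matrix (samples x metabolites), columns
#'   centered — see \code{\link{autoscale}}.
#' @param groups group label per sample (length n, >= 2 levels, >= 2
#'   samples per group).
#' @param ncomp number of components A (default 3; must satisfy
#'   A <= min(n - 1, p)).
#' @param maxit iteration cap per component (default 5000; nearly
#'   degenerate class directions, e.g. two unaffected groups in a
#'   four-class fit, converge slowly).
#' @return a \linkS4class{PlsdaModel} with VIP scores computed.
#' @seealso \code{\link{computeVip}}, \code{\link{projectScores}}
#' @export
fitPlsda <- function(X, groups, ncomp = 3, maxit = 5000L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  enc <- groupEncoding(groups)
  n <- nrow(X); p <- ncol(X); g <- ncol(enc$Y)
  if (length(enc$groups) != n) .stopf("groups must have one label per row of X")
  if (any(table(enc$groups) < 2)) .stopf("need at least 2 samples per group")
  if (n < g) .stopf("need at least as many samples as groups")
  if (ncomp > min(n - 1, p))
    .stopf("ncomp must be <= min(n - 1, p) = %d", min(n - 1, p))
  if (max(abs(colMeans(X))) > 1e-6)
    warning("X columns do not appear to be mean-centered")

  W <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, n, ncomp, dimnames = list(rownames(X), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  Q <- matrix(0, g, ncomp, dimnames = list(colnames(enc$Y), NULL))
  ssy <- numeric(ncomp)
  Xd <- X; Yd <- enc$Y
  A <- 0L
  for (a in seq_len(ncomp)) {
    if (sum(Xd^2) < 1e-12 * max(1, sum(X^2))) break  # rank exhausted
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    t_old <- rep(0, n)
    converged <- FALSE
    for (it in seq_len(maxit)) {
      w <- crossprod(Xd, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break
      w <- w / nw
      tt <- Xd %*% w
      q <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% q
      if (sqrt(sum((tt - t_old)^2)) < 1e-10) { converged <- TRUE; break }
      t_old <- tt
    }
    if (!converged) {
      if (exists("nw") && nw < 1e-12) break  # no structure left
      .stopf("NIPALS did not converge for component %d", a)
    }
    s <- sign(w[which.max(abs(w))]); if (s == 0) s <- 1
    w <- w * s; tt <- tt * s; q <- q * s
    pl <- crossprod(Xd, tt) / sum(tt^2)
    Xd <- Xd - tt %*% t(pl)
    Yd <- Yd - tt %*% t(q)
    A <- a
    W[, a] <- w; Tm[, a] <- tt; P[, a] <- pl; Q[, a] <- q
    ssy[a] <- sum(q^2) * sum(tt^2)
  }
  if (A == 0L) .stopf("no PLS component could be extracted")
  if (A < ncomp)
    warning(sprintf("rank limited the fit to %d of %d components", A, ncomp))
  idx <- seq_len(A)
  m <- new("PlsdaModel", ncomp = A,
           weights = W[, idx, drop = FALSE], scores = Tm[, idx, drop = FALSE],
           xLoadings = P[, idx, drop = FALSE],
           yLoadings = Q[, idx, drop = FALSE],
           ssy = ssy[idx], vip = numeric(0), metabolites = colnames(X),
           groups = enc$groups, groupLevels = colnames(enc$Y))
  m@vip <- unname(computeVip(m))
  validObject(m)
  m
}

#' Variable importance in projection (VIP) scores
#'
#' The weight-based VIP aggregated over all fitted components, weighted by
#' the explained class sum-of-squares:
#' \deqn{VIP_j = \sqrt{p \sum_a ssy_a w_{ja}^2 / \sum_a ssy_a},}
#' with unit-norm weight columns, so the mean squared VIP over the p
#' metabolites equals 1.
#'
#' @param m a fitted \linkS4class{PlsdaModel}.
#' @return named numeric vector of VIP scores (length p).
#' @export
computeVip <- function(m) {
  stopifnot(is(m, "PlsdaModel"))
  if (all(m@ssy == 0)) .stopf("no explained class variance; cannot compute VIP")
  p <- nrow(m@weights)
  v <- sqrt(p * as.vector(m@weights^2 %*% m@ssy) / sum(m@ssy))
  stats::setNames(v, m@metabolites)
}

#' Score projections for plotting
#'
#' First k score columns with sample and group labels, for the
#' three-dimensional class-separation projection.
#'
#' @param m a fitted \linkS4class{PlsdaModel}.
#' @param k number of components to return (default 3, must be <= A).
#' @return data.frame with columns \code{sample_id}, \code{group},
#'   \code{t1}..\code{tk}.
#' @export
projectScores <- function(m, k = 3) {
  stopifnot(is(m, "PlsdaModel"))
  if (k > m@ncomp) .stopf("k = %d exceeds the %d fitted components", k, m@ncomp)
  sc <- m@scores[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("t", seq_len(k))
  data.frame(sample_id = if (is.null(rownames(sc)))
               sprintf("sample%02d", seq_len(nrow(sc))) else rownames(sc),
             group = as.character(m@groups), sc, row.names = NULL)
}

#' Threshold VIP scores into a significance ranking
#'
#' Builds the ranked metabolite table behind the pathway impact statistic:
#' metabolites sorted by decreasing VIP, joined with their pathway and the
#' treatment direction (sign of the z-score effect metric), and flagged
#' significant at the VIP threshold (default 1.5; the boundary is counted
#' as significant unless \code{inclusive = FALSE}).
#'
#' @param vip a fitted \linkS4class{PlsdaModel} or a named numeric vector
#'   of VIP scores.
#' @param map a \linkS4class{PathwayMap} covering every scored metabolite.
#' @param directions named vector giving the treatment direction per
#'   metabolite: numeric (sign used; from \code{\link{computeZScores}}) or
#'   character \code{"increased"}/\code{"decreased"}.  Directions may be
#'   omitted (NA) for non-significant metabolites only.
#' @param threshold VIP significance cutoff (default 1.5).
#' @param inclusive treat vip == threshold as significant (default TRUE).
#' @return a \linkS4class{VipRanking}.
#' @export
selectSignificant <- function(vip, map, directions, threshold = 1.5,
                              inclusive = TRUE) {
  v <- if (is(vip, "PlsdaModel")) vipScores(vip) else vip
  if (is.null(names(v))) .stopf("vip vector must be named by metabolite ids")
  stopifnot(is(map, "PathwayMap"))
  unmapped <- setdiff(names(v), names(map@assignment))
  if (length(unmapped))
    .stopf("metabolite(s) lacking a pathway assignment: %s",
           paste(utils::head(unmapped, 5), collapse = ", "))
  dir <- rep(NA_character_, length(v))
  names(dir) <- names(v)
  if (!missing(directions) && length(directions)) {
    d <- directions[names(v)]
    dir <- if (is.numeric(directions))
      ifelse(is.na(d), NA_character_,
             ifelse(d > 0, "increased", "decreased"))
    else as.character(d)
  }
  ord <- order(-v, names(v))
  sig <- if (inclusive) v >= threshold else v > threshold
  tb <- data.frame(metabolite = names(v)[ord],
                   pathway = unname(map@assignment[names(v)[ord]]),
                   vip = unname(v[ord]),
                   direction = unname(dir[ord]),
                   significant = unname(sig[ord]),
                   row.names = NULL)
  miss <- tb$significant & is.na(tb$direction)
  if (any(miss))
    .stopf("missing direction for significant metabolite(s): %s",
           paste(utils::head(tb$metabolite[miss], 5), collapse = ", "))
  new("VipRanking", table = tb, threshold = threshold, inclusive = inclusive)
}
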