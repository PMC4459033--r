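#' Pointwise t-test map across participants
#'
#' Compares two stacks of phase-alignment maps (participants x freqs x times)
#' with a two-sided t-test at every time-frequency point. The default is a
#' paired test across participants (the same people contribute both
#' conditions); \code{paired = FALSE} gives a Welch two-sample test.
#' Points with zero variance of the paired differences get t = 0 and p = 1
#' (with a warning) rather than an error.
#'
#' @param paiSE,paiUE numeric arrays, participants x freqs x times, matching
#'   shapes, >= 3 participants.
#' @param paired logical; default TRUE.
#' @return list with matrices \code{tMap} and \code{pMap} (freqs x times) and
#'   \code{df}.
#' @export
pointwiseTMap <- function(paiSE, paiUE, paired = TRUE) {
  if (!identical(dim(paiSE), dim(paiUE)))
    stop("the two condition arrays must have matching shapes", call. = FALSE)
  d <- dim(paiSE)
  if (length(d) != 3L || d[1L] < 3L)
    stop("need participants x freqs x times arrays with >= 3 participants",
         call. = FALSE)
  nP <- d[1L]; M <- d[2L] * d[3L]
  if (paired) {
    D  <- matrix(paiSE - paiUE, nP, M)
    mu <- colMeans(D)
    v  <- (colSums(D^2) - nP * mu^2) / (nP - 1)
    df <- nP - 1
    tt <- ifelse(v > 0, mu / sqrt(v / nP), 0)
    if (any(v <= 0))
      warning(sum(v <= 0), " point(s) had zero variance of paired ",
              "differences; their p was set to 1")
    pp <- ifelse(v > 0, 2 * stats::pt(-abs(tt), df), 1)
  } else {
    A <- matrix(paiSE, nP, M); B <- matrix(paiUE, nP, M)
    va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
    se2 <- va / nP + vb / nP
    tt <- ifelse(se2 > 0, (colMeans(A) - colMeans(B)) / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / ((va / nP)^2 / (nP - 1) + (vb / nP)^2 / (nP - 1)),
                 nP - 1)
    if (any(se2 <= 0))
      warning(sum(se2 <= 0), " point(s) had zero variance; p set to 1")
    pp <- ifelse(se2 > 0, 2 * stats::pt(-abs(tt), df), 1)
  }
  list(tMap = matrix(tt, d[2L], d[3L]),
       pMap = matrix(pp, d[2L], d[3L]),
       df   = df)
}

#' Cluster-size permutation contrast of two PAI map stacks
#'
#' Controls for multiple comparisons over a time-frequency map whose adjacent
#' points are highly dependent: observed clusters are the connected components
#' (4-adjacency: time and frequency neighbours, no diagonals; positive and
#' negative t clustered separately) of points with pointwise p below
#' \code{alpha}; condition labels are then reassigned at random within each
#' participant (a sign flip of the paired differences) \code{nPermutations}
#' times, the largest cluster size over both signs recorded each time, and
#' each observed cluster's size compared against that null with the
#' add-one estimator p = (1 + #{null >= size}) / (1 + nPermutations).
#'
#' @param paiSE,paiUE as in [pointwiseTMap()].
#' @param nPermutations default 1000; below 100 a warning is issued.
#' @param alpha pointwise threshold in (0, 1); default 0.05.
#' @param seed integer seed for the permutations.
#' @param freqs,times optional axis grids carried into the result (defaults
#'   are grid indices).
#' @return a [ClusterTestResult-class].
#' @export
clusterSizePermutation <- function(paiSE, paiUE, nPermutations = 1000L,
                                   alpha = 0.05, seed = 1L,
                                   freqs = NULL, times = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)", call. = FALSE)
  if (nPermutations < 100L)
    warning("fewer than 100 permutations gives a coarse null")
  obs <- pointwiseTMap(paiSE, paiUE, paired = TRUE)
  d   <- dim(paiSE); nP <- d[1L]; nF <- d[2L]; nT <- d[3L]
  if (is.null(freqs)) freqs <- seq_len(nF)
  if (is.null(times)) times <- seq_len(nT)

  sig <- obs$pMap < alpha
  clusterList <- list()
  for (sgn in c(1, -1)) {
    mask <- sig & (sgn * obs$tMap > 0)
    lab  <- label_clusters(mask)
    for (id in seq_len(max(lab))) {
      pts <- which(lab == id, arr.ind = TRUE)
      colnames(pts) <- c("freq", "time")
      clusterList[[length(clusterList) + 1L]] <-
        list(points = pts, size = nrow(pts), sign = sgn)
    }
  }
  # order clusters by decreasing size for readability
  if (length(clusterList)) {
    ord <- order(vapply(clusterList, `[[`, integer(1), "size"),
                 decreasing = TRUE)
    clusterList <- clusterList[ord]
  }

  # permutation null of the largest suprathreshold cluster size; a paired
  # label swap is a sign flip of the per-participant difference maps
  D    <- matrix(paiSE - paiUE, nP, nF * nT)
  SS   <- colSums(D^2)
  crit <- stats::qt(1 - alpha / 2, nP - 1)
  nullMax <- integer(nPermutations)
  withSeed(seed, {
    for (b in seq_len(nPermutations)) {
      sgns <- sample(c(-1, 1), nP, replace = TRUE)
      S  <- as.numeric(sgns %*% D)
      v  <- (SS - S^2 / nP) / (nP - 1)
      tt <- ifelse(v > 0, (S / nP) / sqrt(v / nP), 0)
      nullMax[b] <- max_cluster_size(matrix(tt, nF, nT), crit)
    }
  })
  sizes <- vapply(clusterList, `[[`, integer(1), "size")
  cp <- vapply(sizes, function(s)
    (1 + sum(nullMax >= s)) / (1 + nPermutations), numeric(1))
  new("ClusterTestResult",
      tMap = obs$tMap, pMap = obs$pMap, clusters = clusterList,
      nullMaxSizes = nullMax, clusterP = cp,
      freqs = as.numeric(freqs), times = as.numeric(times), alpha = alpha)
}

#' Pearson correlation with its t-test
#'
#' Sample Pearson correlation with the exact two-sided test
#' t = r sqrt(n-2) / sqrt(1-r^2) on n-2 degrees of freedom (delegated to
#' \code{stats::cor.test}).
#'
#' @param x,y numeric vectors of equal length n >= 3 with nonzero variance.
#' @param label optional description carried in the result.
#' @return a [CorrelationResult-class].
#' @examples
#' # the two-sided p for r = 0.78 with n = 7 scalars is 0.039
#' @export
pearsonR <- function(x, y, label = "") {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  new("CorrelationResult",
      r = unname(ct$estimate), n = as.integer(n),
      tStat = unname(ct$statistic),
      p = max(unname(ct$p.value), .Machine$double.xmin),
      pFDR = NA_real_, label = label)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (adjusted_i = min over j with rank >= rank(i) of
#' m p_(j) / j, capped at 1; delegated to \code{stats::p.adjust}) and the
#' rejection decisions at level q.
#'
#' @param pValues numeric vector of raw p-values in (0, 1].
#' @param q FDR level; default 0.05.
#' @return list with \code{adjusted} and logical \code{reject}.
#' @export
bhFDR <- function(pValues, q = 0.05) {
  if (any(!is.finite(pValues)) || any(pValues <= 0 | pValues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  adj <- stats::p.adjust(pValues, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}

#' Adjust a family of correlations for multiple testing
#'
#' Applies [bhFDR()] to a list of [CorrelationResult-class] objects and fills
#' their \code{pFDR} slot.
#'
#' @param corrs list of [CorrelationResult-class].
#' @param q FDR level.
#' @return the list with \code{pFDR} set.
#' @export
adjustCorrelationFamily <- function(corrs, q = 0.05) {
  adj <- bhFDR(vapply(corrs, function(cr) cr@p, numeric(1)), q)$adjusted
  for (i in seq_along(corrs)) corrs[[i]]@pFDR <- adj[i]
  corrs
}

#' Fisher z comparison of two correlations
#'
#' Tests whether two independent Pearson correlations differ: each r is
#' Fisher-z transformed (atanh) and the difference, scaled by
#' sqrt(1/(n1-3) + 1/(n2-3)), is referred to the unit normal distribution
#' (two-sided).
#'
#' @param r1,r2 correlations with |r| < 1.
#' @param n1,n2 sample sizes, >= 4.
#' @return a [FisherComparison-class].
#' @export
fisherZCompare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| = 1 has an infinite Fisher transform", call. = FALSE)
  if (n1 < 4L || n2 < 4L)
    stop("sample sizes must be >= 4", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  new("FisherComparison",
      z = z, p = 2 * stats::pnorm(-abs(z)),
      r1 = r1, n1 = as.integer(n1), r2 = r2, n2 = as.integer(n2))
}
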