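test_that("pointwiseTMap matches stats::t.test cell by cell", {
  set.seed(20)
  nP <- 8L
  se <- array(rnorm(nP * 3 * 4, mean = 0.4), dim = c(nP, 3, 4))
  ue <- array(rnorm(nP * 3 * 4), dim = c(nP, 3, 4))
  res <- pointwiseTMap(se, ue, paired = TRUE)
  for (f in 1:3) for (t in 1:4) {
    tt <- t.test(se[, f, t], ue[, f, t], paired = TRUE)
    expect_equal(res$tMap[f, t], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$pMap[f, t], tt$p.value, tolerance = 1e-10)
  }
  resW <- pointwiseTMap(se, ue, paired = FALSE)
  tw <- t.test(se[, 2, 3], ue[, 2, 3], paired = FALSE)
  expect_equal(resW$tMap[2, 3], unname(tw$statistic), tolerance = 1e-10)
  expect_equal(resW$pMap[2, 3], tw$p.value, tolerance = 1e-10)
})

test_that("pointwiseTMap reproduces the worked paired-t example", {
  # differences 0.1, 0.2, 0.3 -> t = 0.2 / (0.1/sqrt(3)) = 3.4641
  se <- array(c(1.1, 1.2, 1.3), dim = c(3, 1, 1))
  ue <- array(c(1.0, 1.0, 1.0), dim = c(3, 1, 1))
  res <- pointwiseTMap(se, ue)
  expect_equal(res$tMap[1, 1], sqrt(12), tolerance = 1e-9)
})

test_that("zero-variance differences yield t = 0, p = 1 with a warning", {
  se <- array(1, dim = c(5, 2, 2))
  ue <- array(0.5, dim = c(5, 2, 2))
  expect_warning(res <- pointwiseTMap(se, ue), "variance")
  expect_true(all(res$tMap == 0))
  expect_true(all(res$pMap == 1))
})

test_that("cluster labelling matches a brute-force component search", {
  set.seed(21)
  for (rep in 1:20) {
    mask <- matrix(runif(12 * 15) < 0.4, 12, 15)
    lab <- thetaPLF:::label_clusters(mask)
    expect_true(all((lab > 0) == mask))
    sizes <- sort(as.integer(table(lab[lab > 0])))
    expect_equal(sizes, componentSizesBrute(mask))
    # labelled components are internally 4-connected: every labelled cell
    # shares its label with at least one 4-neighbour (unless a singleton)
    if (any(mask)) {
      crit <- 1.5
      tmap <- matrix(ifelse(mask, 2, 0), 12, 15)
      expect_equal(thetaPLF:::max_cluster_size(tmap, crit),
                   max(c(0L, componentSizesBrute(mask))))
    }
  }
})

test_that("max_cluster_size treats signs separately", {
  tmap <- rbind(c(3, 3, -3), c(-3, 3, -3))
  # positive component {(1,1),(1,2),(2,2)} size 3; negative column size 2
  expect_equal(thetaPLF:::max_cluster_size(tmap, 2), 3L)
  expect_equal(thetaPLF:::max_cluster_size(-tmap, 2), 3L)
  # a bridge of opposite sign does not join clusters
  tmap2 <- matrix(c(3, -3, 3), 1, 3)
  expect_equal(thetaPLF:::max_cluster_size(tmap2, 2), 1L)
})

test_that("clusterSizePermutation finds a strong localised effect", {
  set.seed(22)
  nP <- 9L; nF <- 8L; nT <- 20L
  se <- array(rnorm(nP * nF * nT, 0, 0.05), dim = c(nP, nF, nT))
  ue <- array(rnorm(nP * nF * nT, 0, 0.05), dim = c(nP, nF, nT))
  se[, 3:5, 8:14] <- se[, 3:5, 8:14] + 0.4
  ct <- clusterSizePermutation(se, ue, nPermutations = 500L, seed = 3L,
                               freqs = 1:nF, times = (1:nT) / 10)
  expect_s4_class(ct, "ClusterTestResult")
  expect_gt(length(clusters(ct)), 0L)
  top <- which.max(vapply(clusters(ct), `[[`, integer(1), "size"))
  # sign-flip permutations retain the effect under unbalanced flips, so the
  # null is effect-contaminated and p stays above its 1/(B+1) floor
  expect_lt(clusterP(ct)[top], 0.05)
  expect_equal(clusters(ct)[[top]]$sign, 1)
  pts <- clusters(ct)[[top]]$points
  expect_true(all(pts[, "freq"] %in% 3:5))
  expect_true(all(pts[, "time"] %in% 8:14))
  expect_length(nullMaxSizes(ct), 500L)
  # determinism
  ct2 <- clusterSizePermutation(se, ue, nPermutations = 500L, seed = 3L,
                                freqs = 1:nF, times = (1:nT) / 10)
  expect_identical(clusterP(ct), clusterP(ct2))
  expect_identical(nullMaxSizes(ct), nullMaxSizes(ct2))
})

test_that("cluster p-values use the add-one permutation convention", {
  set.seed(23)
  se <- array(rnorm(6 * 4 * 5), dim = c(6, 4, 5))
  ue <- array(rnorm(6 * 4 * 5), dim = c(6, 4, 5))
  ct <- clusterSizePermutation(se, ue, nPermutations = 200L, seed = 1L)
  for (i in seq_along(clusters(ct))) {
    sz <- clusters(ct)[[i]]$size
    expect_equal(clusterP(ct)[i],
                 (1 + sum(nullMaxSizes(ct) >= sz)) / (1 + 200))
  }
  expect_true(all(clusterP(ct) > 0 & clusterP(ct) <= 1))
})

test_that("pearsonR wraps cor.test faithfully", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  cr <- pearsonR(x, y, label = "worked example")
  expect_equal(cr@r, 0.6, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(cr@p, ct$p.value, tolerance = 1e-12)
  expect_equal(cr@tStat, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(cr@n, 4L)
  expect_equal(cr@label, "worked example")
  expect_error(pearsonR(1:5, 1:4), "equal length")
  expect_error(pearsonR(rep(1, 5), 1:5), "zero variance")
})

test_that("bhFDR agrees with stats::p.adjust and the brute oracle", {
  set.seed(24)
  p <- runif(37)
  res <- bhFDR(p, q = 0.1)
  expect_equal(res$adjusted, p.adjust(p, "BH"), tolerance = 1e-12)
  expect_equal(res$adjusted, bhBrute(p), tolerance = 1e-12)
  expect_identical(res$reject, res$adjusted <= 0.1)
  # worked example: 0.01, 0.02, 0.03, 0.04 all adjust to 0.04
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04))$adjusted, rep(0.04, 4),
               tolerance = 1e-12)
  expect_error(bhFDR(c(0.5, 0)), "0, 1")
  expect_error(bhFDR(c(0.5, NA)), "0, 1")
})

test_that("adjustCorrelationFamily fills pFDR consistently", {
  set.seed(25)
  corrs <- lapply(1:5, function(i) {
    d <- exactCorPair(0.1 * i, 10, seed = i)
    pearsonR(d$x, d$y, label = paste0("c", i))
  })
  adj <- adjustCorrelationFamily(corrs, q = 0.05)
  ps <- vapply(corrs, function(cr) cr@p, numeric(1))
  expect_equal(vapply(adj, function(cr) cr@pFDR, numeric(1)),
               p.adjust(ps, "BH"), tolerance = 1e-12)
  expect_true(all(vapply(adj, function(cr) cr@pFDR >= cr@p, logical(1))))
})

test_that("fisherZCompare matches its closed form and is antisymmetric", {
  fz <- fisherZCompare(0.8, 20, 0.3, 25)
  zManual <- (atanh(0.8) - atanh(0.3)) / sqrt(1 / 17 + 1 / 22)
  expect_equal(fz@z, zManual, tolerance = 1e-12)
  expect_equal(fz@p, 2 * pnorm(-abs(zManual)), tolerance = 1e-12)
  rev <- fisherZCompare(0.3, 25, 0.8, 20)
  expect_equal(rev@z, -fz@z, tolerance = 1e-12)
  expect_equal(rev@p, fz@p, tolerance = 1e-12)
  expect_equal(fisherZCompare(0.5, 10, 0.5, 10)@z, 0)
  expect_error(fisherZCompare(1, 10, 0.5, 10), "Fisher")
  expect_error(fisherZCompare(0.5, 3, 0.5, 10), ">= 4")
})
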