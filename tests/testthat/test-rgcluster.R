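test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhAdjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bhAdjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    p <- runif(n, .Machine$double.eps, 1)
    expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("adjusted values are monotone in the raw p-values", {
  set.seed(17)
  p <- runif(100)
  q <- bhAdjust(p)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
})

test_that("significance is strict at the FDR threshold", {
  pairs <- data.frame(pheno_a_id = c("a", "a"), pheno_b_id = c("b", "c"),
                      p = c(0.01, 0.9), fdr = c(0.05, 0.9))
  expect_identical(nrow(suppressMessages(significantPairs(pairs, 0.05))), 0L)
  expect_identical(nrow(suppressMessages(significantPairs(pairs, 1.0))), 2L)
})

test_that("the FDR-significant fraction is controlled under the null", {
  set.seed(211)
  fracs <- replicate(50, {
    p <- runif(200)
    mean(bhAdjust(p) < 0.05)
  })
  expect_lte(mean(fracs), 0.05)
})

test_that("rg matrix assembly is symmetric, clamped and validated", {
  pairs <- data.frame(pheno_a_id = "a", pheno_b_id = "b", rg = 0.5)
  m <- buildRgMatrix(pairs, c("a", "b"))
  expect_equal(unname(m), matrix(c(1, 0.5, 0.5, 1), 2))

  over <- data.frame(pheno_a_id = "a", pheno_b_id = "b", rg = 1.07)
  expect_warning(m2 <- buildRgMatrix(over, c("a", "b")), "clamped 1")
  expect_equal(m2["a", "b"], 1.0)

  expect_error(buildRgMatrix(pairs, c("a", "b", "b")), "unique")
  expect_error(buildRgMatrix(pairs, c("a", "x")), "unknown phenotype")
})

test_that("rg matrix assembly equals a brute-force fill", {
  set.seed(23)
  ph <- sprintf("p%02d", 1:12)
  all <- t(combn(ph, 2))
  take <- sample(nrow(all), 40)
  pairs <- data.frame(pheno_a_id = all[take, 1], pheno_b_id = all[take, 2],
                      rg = runif(40, -1, 1), stringsAsFactors = FALSE)
  m <- buildRgMatrix(pairs, ph)
  brute <- matrix(NA_real_, 12, 12, dimnames = list(ph, ph))
  diag(brute) <- 1
  for (i in seq_len(nrow(pairs))) {
    brute[pairs$pheno_a_id[i], pairs$pheno_b_id[i]] <- pairs$rg[i]
    brute[pairs$pheno_b_id[i], pairs$pheno_a_id[i]] <- pairs$rg[i]
  }
  expect_identical(m, brute)
})

test_that("distance transform maps rg = 1/-1 to 0/2 and imputes missing", {
  m <- matrix(c(1, 1, -1, 1, 1, NA, -1, NA, 1), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  d <- rgToDistance(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  expect_equal(d["b", "c"], 2)  # missing -> missingDistance
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  set.seed(3)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    mm <- matrix(runif(n * n, -1, 1), n)
    mm[lower.tri(mm)] <- t(mm)[lower.tri(mm)]
    diag(mm) <- 1
    dimnames(mm) <- list(seq_len(n), seq_len(n))
    dd <- rgToDistance(mm)
    expect_true(isSymmetric(dd))
    expect_true(all(diag(dd) == 0))
  }
})

test_that("agglomeration reproduces hand-executed complete linkage", {
  d2 <- matrix(c(0, 0.7, 0.7, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  hc <- agglomerativeCluster(d2)
  expect_equal(hc$height, 0.7)

  d3 <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- agglomerativeCluster(d3, "complete")
  expect_equal(hc$height, c(1, 5))      # (A,B)@1 then (AB,C)@5
  expect_identical(sort(hc$labels[-hc$merge[1, ]]), c("A", "B"))

  expect_error(agglomerativeCluster(matrix(1, 2, 3)), "square")
  asym <- matrix(c(0, 1, 2, 0), 2)
  expect_error(agglomerativeCluster(asym), "symmetric")
})

test_that("merge heights equal a naive O(n^3) agglomeration oracle", {
  set.seed(47)
  for (i in 1:40) {
    n <- sample(3:7, 1)
    d <- randomDistanceMatrix(n)
    for (linkage in c("complete", "average", "single")) {
      hc <- agglomerativeCluster(d, linkage)
      expect_equal(hc$height, naiveAgglomerationHeights(d, linkage),
                   tolerance = 1e-10)
    }
  }
})

test_that("tree cut reduces to the static cut for clean two-branch trees", {
  ## two tight groups merged at height 1.8 > cutHeight
  d <- as.matrix(dist(c(a1 = 0, a2 = 0.05, a3 = 0.1,
                        b1 = 2, b2 = 2.05, b3 = 2.1)))
  hc <- agglomerativeCluster(d)
  cl <- dynamicTreeCut(hc, cutParams(cutHeight = 0.99, minClusterSize = 3L))
  expect_identical(length(unique(cl)), 2L)
  static <- stats::cutree(hc, h = 0.99)
  expect_equal(ariOracle(cl, static), 1.0)
  expect_true(all(cl > 0))
})

test_that("a tree entirely below the cut is one cluster", {
  d <- as.matrix(dist(c(a = 0, b = 0.1, c = 0.2, d = 0.3)))
  hc <- agglomerativeCluster(d)
  cl <- dynamicTreeCut(hc, cutParams(cutHeight = 5, minClusterSize = 3L))
  expect_identical(unname(cl), rep(1L, 4))
})

test_that("a cut below the lowest merge unassigns every leaf, warning", {
  d <- as.matrix(dist(c(a = 0, b = 1, c = 2, d = 3)))
  hc <- agglomerativeCluster(d)
  expect_warning(
    cl <- dynamicTreeCut(hc, cutParams(cutHeight = 0.5,
                                       minClusterSize = 2L)),
    "unassigned")
  expect_identical(unname(cl), rep(0L, 4))
})

test_that("small branches merge into the nearest qualifying branch", {
  ## one tight trio plus one straggler that joins above the cut
  d <- as.matrix(dist(c(a1 = 0, a2 = 0.1, a3 = 0.2, stray = 1.5,
                        b1 = 9, b2 = 9.1, b3 = 9.2)))
  hc <- agglomerativeCluster(d)
  cl <- dynamicTreeCut(hc, cutParams(cutHeight = 0.99, minClusterSize = 3L))
  expect_identical(length(unique(cl[cl > 0])), 2L)
  expect_identical(unname(cl["stray"]), unname(cl["a1"]))
})

test_that("planted 3-block distances are recovered exactly", {
  set.seed(7)
  n <- 30
  blocks <- rep(1:3, each = 10)
  d <- matrix(1.9, n, n)
  for (b in 1:3) d[blocks == b, blocks == b] <- 0.1
  diag(d) <- 0
  d <- d + matrix(runif(n * n, 0, 0.01), n, n)  # tiny jitter, symmetrized
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  dimnames(d) <- list(sprintf("x%02d", 1:n), sprintf("x%02d", 1:n))
  hc <- agglomerativeCluster(d)
  cl <- dynamicTreeCut(hc)
  expect_identical(length(unique(cl[cl > 0])), 3L)
  expect_equal(ariOracle(cl, blocks), 1.0)
})

test_that("no nonzero cluster is smaller than minClusterSize", {
  set.seed(71)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    d <- randomDistanceMatrix(n)
    params <- cutParams(cutHeight = runif(1, 0.3, 2.5),
                        minClusterSize = sample(2:4, 1))
    cl <- suppressWarnings(dynamicTreeCut(agglomerativeCluster(d), params))
    expect_length(cl, n)                      # every leaf gets exactly one id
    sizes <- table(cl[cl > 0])
    if (length(sizes))
      expect_true(all(sizes >= params@minClusterSize))
    ## ids are numbered by decreasing size
    if (length(sizes) > 1)
      expect_true(all(diff(as.integer(sizes[order(as.integer(
        names(sizes)))])) <= 0))
  }
})

test_that("leaf order is a permutation, stable under relabelling", {
  set.seed(83)
  d <- randomDistanceMatrix(9)
  hc <- agglomerativeCluster(d)
  ord <- leafOrder(hc)
  expect_setequal(ord, rownames(d))
  expect_identical(length(ord), 9L)
  rev <- d[9:1, 9:1]
  ord2 <- leafOrder(agglomerativeCluster(rev))
  expect_setequal(ord2, rownames(d))
})

test_that("heatmap TSVs hold the reordered matrix and mask", {
  set.seed(29)
  ph <- sprintf("p%d", 1:6)
  m <- matrix(runif(36, -1, 1), 6, dimnames = list(ph, ph))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  mask <- matrix(FALSE, 6, 6, dimnames = list(ph, ph))
  mask["p1", "p3"] <- mask["p3", "p1"] <- TRUE
  mask["p2", "p5"] <- mask["p5", "p2"] <- TRUE
  ord <- c("p3", "p1", "p6", "p2", "p4", "p5")
  png <- withr::local_tempfile(fileext = ".png")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  res <- renderHeatmap(m, ord, mask, png, tsv)
  expect_true(file.exists(png))
  back <- readTsv(tsv)
  expect_identical(back$phenotype, ord)
  expect_equal(as.matrix(back[, -1]), m[ord, ord],
               ignore_attr = TRUE)                 # permutation oracle
  maskBack <- readTsv(sub("\\.tsv$", "_mask.tsv", tsv))
  expect_identical(sum(as.matrix(maskBack[, -1]) == TRUE), 4L)  # 2 pairs x 2

  ## identity order reproduces the input matrix
  res2 <- renderHeatmap(m, ph, mask, png, tsv)
  expect_identical(res2$matrix, m)
  expect_error(renderHeatmap(m, ph[-1], mask, png, tsv), "permutation")
})

test_that("planted two-block rg structure yields two exact clusters", {
  spec <- synthSpec(seed = 1)
  rg <- genRgPairs(spec)
  pairs <- rg$pairs
  pairs$fdr <- bhAdjust(pairs$p)
  ph <- sort(unique(c(pairs$pheno_a_id, pairs$pheno_b_id)))
  m <- buildRgMatrix(pairs, ph)
  cl <- dynamicTreeCut(agglomerativeCluster(rgToDistance(m)))
  expect_identical(length(unique(cl[cl > 0])), 2L)
  expect_equal(ariOracle(cl[rg$labels$pheno_id], rg$labels$block), 1.0)
})
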