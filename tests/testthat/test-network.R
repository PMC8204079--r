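test_that("edge reading dedupes pairs, keeps max score, drops loops", {
  tmp <- withr::local_tempfile(fileext = ".tsv", lines = c(
    "disease_a\tdisease_b\tsimilarity",
    "A\tB\t0.4",
    "B\tA\t0.6",          # duplicate unordered pair, higher score
    "C\tC\t0.9",          # self-loop
    "A\tC\t0.3"))
  edges <- suppressMessages(readSimilarityEdges(tmp))
  expect_identical(nrow(edges), 2L)
  expect_equal(edges$similarity[edges$disease_a == "A" &
                                edges$disease_b == "B"], 0.6)
})

test_that("hand-counted fixture: 10 rows, 2 duplicates, 1 loop -> 7 edges", {
  rows <- data.frame(
    disease_a = c("A", "B", "C", "D", "E", "A", "B", "F", "G", "H"),
    disease_b = c("B", "C", "D", "E", "F", "B", "A", "G", "H", "H"),
    similarity = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95))
  ## A-B appears twice (rows 1, 7); A-B row 6? no: row 6 is A-B? A,B -> yes
  ## duplicates: rows 1/6/7 collapse to one A-B; row 10 H-H is a loop
  edges <- suppressMessages(similarityEdges(rows))
  expect_identical(nrow(edges), 7L)
  expect_equal(max(edges$similarity[edges$disease_a == "A" &
                                    edges$disease_b == "B"]), 0.7)
})

test_that("non-numeric similarity raises a parse error with line number", {
  tmp <- withr::local_tempfile(fileext = ".tsv", lines = c(
    "disease_a\tdisease_b\tsimilarity",
    "A\tB\t0.4",
    "B\tC\toops"))
  expect_error(readSimilarityEdges(tmp), "line 3")
})

test_that("similarity scores outside [0, 1] are rejected", {
  bad <- data.frame(disease_a = "A", disease_b = "B", similarity = 1.2)
  expect_error(similarityEdges(bad), "\\[0, 1\\]")
})

test_that("induction is strict at the threshold and on membership", {
  edges <- data.frame(disease_a = c("A", "A", "A"),
                      disease_b = c("B", "C", "D"),
                      similarity = c(0.55, 0.56, 0.9))
  kept <- induceAndThreshold(edges, c("A", "B", "C"), 0.55)
  expect_identical(nrow(kept), 1L)        # 0.55 excluded; D outside
  expect_identical(kept$disease_b, "C")
  expect_error(induceAndThreshold(edges, character(0)), "non-empty")
})

test_that("thresholding agrees with a brute-force filter on random graphs", {
  set.seed(31)
  edges <- randomEdgeList(25, 0.35)
  ard <- sprintf("N%02d", sample(25, 15))
  for (thr in c(0.2, 0.55, 0.8)) {
    kept <- induceAndThreshold(edges, ard, thr)
    manual <- edges[edges$disease_a %in% ard & edges$disease_b %in% ard &
                    edges$similarity > thr, ]
    rownames(manual) <- NULL
    expect_identical(kept, manual)
  }
})

test_that("components match a depth-first-search oracle on random graphs", {
  set.seed(97)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    edges <- randomEdgeList(n, runif(1, 0.05, 0.3))
    if (nrow(edges) == 0) next
    sn <- connectedComponents(edges)
    expect_identical(canonicalPartition(sn$members), dfsComponents(edges))
  }
})

test_that("component numbering is by size with lexical tie-break", {
  edges <- data.frame(disease_a = c("x1", "x2", "b1", "a1"),
                      disease_b = c("x2", "x3", "b2", "a2"),
                      similarity = 1)
  sn <- connectedComponents(edges, minPrimarySize = 3L)
  expect_identical(sn$summary$size, c(3L, 2L, 2L))
  expect_identical(sn$summary$is_primary, c(TRUE, FALSE, FALSE))
  ## the two 2-node components order by smallest member: a1 before b1
  expect_identical(sn$members$term[sn$members$subnetwork_id == 2],
                   c("a1", "a2"))
})

test_that("empty and single-edge graphs decompose sensibly", {
  empty <- connectedComponents(data.frame(disease_a = character(),
                                          disease_b = character(),
                                          similarity = numeric()))
  expect_identical(nrow(empty$summary), 0L)
  one <- connectedComponents(data.frame(disease_a = "A", disease_b = "B",
                                        similarity = 0.9))
  expect_identical(one$summary$size, 2L)
})

test_that("component partition is invariant to edge order and swaps", {
  set.seed(13)
  edges <- randomEdgeList(20, 0.15)
  sn1 <- connectedComponents(edges)
  shuffled <- edges[sample(nrow(edges)), ]
  swapped <- data.frame(disease_a = shuffled$disease_b,
                        disease_b = shuffled$disease_a,
                        similarity = shuffled$similarity)
  sn2 <- connectedComponents(swapped)
  expect_identical(canonicalPartition(sn1$members),
                   canonicalPartition(sn2$members))
})

test_that("raising the threshold never grows any component", {
  set.seed(41)
  edges <- randomEdgeList(25, 0.25)
  ard <- sprintf("N%02d", 1:25)
  thresholds <- c(0.2, 0.4, 0.6, 0.8)
  maxSizes <- vapply(thresholds, function(thr) {
    sn <- connectedComponents(induceAndThreshold(edges, ard, thr))
    if (nrow(sn$summary) == 0) 0L else max(sn$summary$size)
  }, integer(1))
  expect_true(all(diff(maxSizes) <= 0))
})

test_that("member counts over components equal non-isolated node count", {
  set.seed(59)
  edges <- randomEdgeList(30, 0.1)
  sn <- connectedComponents(edges)
  expect_identical(sum(sn$summary$size),
                   length(unique(c(edges$disease_a, edges$disease_b))))
})

test_that("subnetwork labels take the plurality category, ties lexical", {
  edges <- data.frame(disease_a = c("a", "a", "a", "p", "p", "q"),
                      disease_b = c("b", "c", "d", "q", "r", "s"),
                      similarity = 1)
  sn <- connectedComponents(edges)
  catg <- c(a = "Neoplasms", b = "Neoplasms", c = "Neoplasms",
            d = "Cardiovascular Diseases",
            p = "Eye Diseases", q = "Eye Diseases",
            r = "Digestive System Diseases",
            s = "Digestive System Diseases")
  sn <- labelSubnetworks(sn, catg)
  expect_identical(sn$summary$label[1], "Neoplasms")        # 3 vs 1
  expect_identical(sn$summary$label[2], "Digestive System Diseases")  # 2-2 tie
})

test_that("planted module labels are recovered from the generator", {
  spec <- synthSpec(seed = 2, networkModuleSizes = c(6L, 5L, 4L))
  net <- genNetwork(spec)
  kept <- induceAndThreshold(net$edges, net$labels$term, 0.55)
  sn <- connectedComponents(kept)
  sn <- labelSubnetworks(sn,
                         setNames(net$labels$category, net$labels$term))
  planted <- vapply(sn$summary$subnetwork_id, function(id) {
    terms <- sn$members$term[sn$members$subnetwork_id == id]
    unique(net$labels$category[net$labels$term %in% terms])
  }, character(1))
  expect_identical(sn$summary$label, planted)
})

test_that("GraphML export round-trips node and edge attributes", {
  spec <- synthSpec(seed = 4, networkModuleSizes = c(4L, 3L, 3L))
  net <- genNetwork(spec)
  kept <- induceAndThreshold(net$edges, net$labels$term, 0.55)
  sn <- connectedComponents(kept)
  sn <- labelSubnetworks(sn, setNames(net$labels$category,
                                      net$labels$term))
  gml <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(sn, kept, "graphml", gml,
                categoryOf = setNames(net$labels$category,
                                      net$labels$term),
                tissueOf = setNames(net$labels$tissue, net$labels$term))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g)$name, sn$members$term)
  expect_setequal(round(igraph::E(g)$similarity, 10),
                  round(kept$similarity, 10))
  expect_setequal(igraph::V(g)$category,
                  unique(net$labels$category[net$labels$term %in%
                                             sn$members$term]))

  sif <- withr::local_tempfile(fileext = ".sif")
  exportNetwork(sn, kept, "sif", sif)
  expect_identical(length(readLines(sif)), nrow(kept))
  expect_true(file.exists(paste0(sif, ".attrs.tsv")))

  expect_error(exportNetwork(sn, kept, "dot", gml), "unknown")
})

test_that("an empty network exports to a valid empty document", {
  empty <- connectedComponents(data.frame(disease_a = character(),
                                          disease_b = character(),
                                          similarity = numeric()))
  gml <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(empty, data.frame(disease_a = character(),
                                  disease_b = character(),
                                  similarity = numeric()),
                "graphml", gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 0)
})
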