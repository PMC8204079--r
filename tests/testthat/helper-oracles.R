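## Independent brute-force oracles used to cross-check the implementation.
## Each is written directly from the mathematical definition and shares no
## code with the package internals.

## Benjamini-Hochberg step-up, literal definition
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

## connected components by explicit depth-first search
dfsComponents <- function(edges) {
  nodes <- sort(unique(c(edges$disease_a, edges$disease_b)))
  adj <- lapply(setNames(nodes, nodes), function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges$disease_a[i]; b <- edges$disease_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (start in nodes) {
    if (seen[start]) next
    stack <- start
    members <- character(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      members <- c(members, v)
      stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  ## canonical form: sorted members, components sorted by first member
  comps[order(vapply(comps, `[`, character(1), 1L))]
}

## mode count by exhaustive plateau enumeration: every maximal run of equal
## values is tested against both neighbouring runs
plateauScanModes <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  n <- 0L
  for (i in seq_len(k)) {
    left <- i == 1L || r$values[i] > r$values[i - 1L]
    right <- i == k || r$values[i] > r$values[i + 1L]
    if (left && right) n <- n + 1L
  }
  n
}

## naive O(n^3) agglomeration; returns the sorted merge heights
naiveAgglomerationHeights <- function(d, linkage) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  linkFun <- switch(linkage, complete = max, average = mean, single = min)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA_integer_
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        dv <- linkFun(d[clusters[[i]], clusters[[j]]])
        if (dv < best) { best <- dv; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

## random symmetric distance matrix with labelled dimnames
randomDistanceMatrix <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.05, 3)
  m <- m + t(m)
  dimnames(m) <- list(sprintf("L%02d", seq_len(n)),
                      sprintf("L%02d", seq_len(n)))
  m
}

## random undirected edge list over n nodes
randomEdgeList <- function(n, pEdge = 0.15) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < pEdge
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(disease_a = sprintf("N%02d", pairs[, 1]),
             disease_b = sprintf("N%02d", pairs[, 2]),
             similarity = runif(nrow(pairs)),
             stringsAsFactors = FALSE)
}

## membership table -> canonical list-of-sorted-sets partition
canonicalPartition <- function(members) {
  comps <- split(members$term, members$subnetwork_id)
  comps <- lapply(comps, sort)
  unname(comps[order(vapply(comps, `[`, character(1), 1L))])
}

## adjusted Rand index from the contingency table (closed form)
ariOracle <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sumIj <- sum(ch2(tab))
  sumI <- sum(ch2(rowSums(tab)))
  sumJ <- sum(ch2(colSums(tab)))
  nTot <- ch2(sum(tab))
  expected <- sumI * sumJ / nTot
  (sumIj - expected) / ((sumI + sumJ) / 2 - expected)
}
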