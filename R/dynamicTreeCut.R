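## Top-down dynamic tree cut ("tree" variant), implemented from scratch on
## the hclust merge structure.
##
## The dendrogram is severed at cutHeight: a *branch* is a maximal subtree
## all of whose internal merge heights are at or below the cut (a leaf whose
## parent merges above the cut is a singleton branch). Branches with at
## least minClusterSize leaves become clusters. Each smaller branch then
## walks up the tree and joins the nearest qualifying branch - the first
## ancestor on whose other side a qualifying branch exists; if several
## qualify at that ancestor, the largest wins, with ties broken by the
## lexically smallest member label. Branches that reach the root without
## finding a qualifying neighbour stay unassigned (cluster id 0). Final
## cluster ids are renumbered by decreasing cluster size.

#' Decompose a dendrogram with a dynamic tree cut
#'
#' @param hc An [stats::hclust] dendrogram with leaf labels.
#' @param params A [CutParams-class]; `cutHeight` is interpreted on the raw
#'   merge heights and `minClusterSize` is the minimum branch size that can
#'   seed a cluster.
#' @param normalizeHeights If `TRUE`, merge heights are rescaled so the
#'   highest merge is 1 before cutting (for matching conventions that state
#'   the cut as a fraction of tree height); default `FALSE`.
#' @return A named integer vector: one cluster id per leaf (0 =
#'   unassigned), names = leaf labels, ids numbered by decreasing cluster
#'   size.
#' @examples
#' d <- as.matrix(dist(c(a1 = 0, a2 = 0.1, a3 = 0.2, b1 = 5, b2 = 5.1,
#'                       b3 = 5.2)))
#' hc <- agglomerativeCluster(d)
#' dynamicTreeCut(hc, cutParams(cutHeight = 1, minClusterSize = 3L))
#' @export
dynamicTreeCut <- function(hc, params = cutParams(),
                           normalizeHeights = FALSE) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$labels)
  labels <- hc$labels
  heights <- hc$height
  if (normalizeHeights && max(heights) > 0)
    heights <- heights / max(heights)
  cutHeight <- params@cutHeight
  minSize <- params@minClusterSize
  nm <- nrow(hc$merge)

  ## tree bookkeeping: nodes are leaves (-1..-n) and merges (1..nm)
  parent <- new.env(hash = TRUE)
  for (k in seq_len(nm)) {
    assign(as.character(hc$merge[k, 1L]), k, envir = parent)
    assign(as.character(hc$merge[k, 2L]), k, envir = parent)
  }
  getParent <- function(node) {
    key <- as.character(node)
    if (exists(key, envir = parent, inherits = FALSE))
      get(key, envir = parent, inherits = FALSE) else NA_integer_
  }
  ## leaves under each merge node
  leavesUnder <- vector("list", nm)
  for (k in seq_len(nm)) {
    kids <- hc$merge[k, ]
    leavesUnder[[k]] <- unlist(lapply(kids, function(ch)
      if (ch < 0) -ch else leavesUnder[[ch]]))
  }

  ## branch roots: maximal subtrees severed at cutHeight
  isBranchRootMerge <- vapply(seq_len(nm), function(k) {
    if (heights[k] > cutHeight) return(FALSE)
    p <- getParent(k)
    is.na(p) || heights[p] > cutHeight
  }, logical(1))
  leafIsBranch <- vapply(seq_len(n), function(i) {
    p <- getParent(-i)
    is.na(p) || heights[p] > cutHeight
  }, logical(1))
  branches <- c(lapply(which(isBranchRootMerge), function(k)
                  list(node = k, leaves = leavesUnder[[k]])),
                lapply(which(leafIsBranch), function(i)
                  list(node = -i, leaves = i)))
  qualifies <- vapply(branches, function(b)
    length(b$leaves) >= minSize, logical(1))

  assignment <- integer(n)  # 0 = unassigned
  if (!any(qualifies)) {
    warning("no branch reaches minClusterSize below cutHeight = ",
            cutHeight, "; all leaves unassigned", call. = FALSE)
    names(assignment) <- labels
    return(assignment)
  }

  ## qualifying branch roots beneath (or at) every node
  branchNodeOf <- vapply(branches, `[[`, numeric(1), "node")
  qualNodes <- branchNodeOf[qualifies]
  qualUnder <- function(node) {
    if (node %in% qualNodes) return(node)
    if (node < 0) return(numeric(0))
    kids <- hc$merge[node, ]
    c(qualUnder(kids[1L]), qualUnder(kids[2L]))
  }

  ## seed clusters from qualifying branches
  clusterOfBranchNode <- new.env(hash = TRUE)
  for (j in which(qualifies))
    assign(as.character(branches[[j]]$node), j,
           envir = clusterOfBranchNode)
  clusterLeaves <- vector("list", length(branches))
  for (j in which(qualifies)) {
    clusterLeaves[[j]] <- branches[[j]]$leaves
    assignment[branches[[j]]$leaves] <- j
  }

  ## merge small branches upward into the nearest qualifying branch
  for (j in which(!qualifies)) {
    node <- branches[[j]]$node
    target <- NA_integer_
    cameFrom <- node
    a <- getParent(node)
    while (!is.na(a)) {
      kids <- hc$merge[a, ]
      other <- kids[kids != cameFrom][1L]
      cands <- qualUnder(other)
      if (length(cands)) {
        sizes <- vapply(cands, function(q)
          length(branches[[get(as.character(q),
                               envir = clusterOfBranchNode)]]$leaves),
          numeric(1))
        best <- cands[sizes == max(sizes)]
        if (length(best) > 1L) {
          anchors <- vapply(best, function(q) {
            b <- branches[[get(as.character(q),
                               envir = clusterOfBranchNode)]]
            .lexMin(labels[b$leaves])
          }, character(1))
          best <- best[order(anchors, method = "radix")]
        }
        target <- get(as.character(best[1L]),
                      envir = clusterOfBranchNode)
        break
      }
      cameFrom <- a
      a <- getParent(a)
    }
    if (!is.na(target)) {
      clusterLeaves[[target]] <- c(clusterLeaves[[target]],
                                   branches[[j]]$leaves)
      assignment[branches[[j]]$leaves] <- target
    }
  }

  ## renumber by decreasing final size, ties by smallest lexical member
  used <- sort(unique(assignment[assignment > 0]))
  finalSizes <- vapply(used, function(j) sum(assignment == j), integer(1))
  anchors <- vapply(used, function(j) .lexMin(labels[assignment == j]),
                    character(1))
  ord <- used[order(-finalSizes, anchors, method = "radix")]
  renum <- integer(max(used))
  renum[ord] <- seq_along(ord)
  assignment[assignment > 0] <- renum[assignment[assignment > 0]]
  names(assignment) <- labels
  assignment
}
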