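## Symptom-shared disease subnetworks.
##
## The similarity input is an HSDN-style edge list (two MeSH disease terms
## plus a symptom-similarity score in [0, 1]). The analysis induces the
## graph on the age-related disease set, keeps edges with similarity
## strictly above the threshold (0.55 by default), and decomposes the result
## into connected components ("subnetworks"), numbered by decreasing size.

#' Read a disease-similarity edge list
#'
#' Expects a TSV whose first two columns are MeSH disease terms and whose
#' third column is a numeric similarity score in \[0, 1\]. Self-loops are
#' dropped (and counted in a message); duplicate unordered pairs are
#' collapsed keeping the maximum score.
#'
#' @param file Path to the TSV.
#' @return A `data.frame` with columns `disease_a`, `disease_b`,
#'   `similarity`.
#' @export
readSimilarityEdges <- function(file) {
  df <- readTsv(file)
  if (ncol(df) < 3L)
    stop("similarity TSV needs two term columns and a score column",
         call. = FALSE)
  raw <- df[[3L]]
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(num) & !is.na(raw))
  if (length(bad))
    stop("non-numeric similarity score at line ", bad[1L] + 1L, ": '",
         raw[bad[1L]], "'", call. = FALSE)
  edges <- data.frame(disease_a = as.character(df[[1L]]),
                      disease_b = as.character(df[[2L]]),
                      similarity = num, stringsAsFactors = FALSE)
  similarityEdges(edges)
}

#' Canonicalize an in-memory similarity edge table
#'
#' Applies the same cleanup as [readSimilarityEdges()]: drops self-loops,
#' collapses duplicate unordered pairs keeping the maximum score, and
#' validates the score range.
#'
#' @param edges `data.frame` with columns `disease_a`, `disease_b`,
#'   `similarity`.
#' @return The cleaned `data.frame`.
#' @export
similarityEdges <- function(edges) {
  if (any(edges$similarity < 0 | edges$similarity > 1, na.rm = TRUE))
    stop("similarity scores must lie in [0, 1]", call. = FALSE)
  loops <- edges$disease_a == edges$disease_b
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s)")
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) == 0L) { rownames(edges) <- NULL; return(edges) }
  a <- pmin(edges$disease_a, edges$disease_b)
  b <- pmax(edges$disease_a, edges$disease_b)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    message("collapsed ", sum(duplicated(key)),
            " duplicate pair(s), keeping the maximum score")
    sim <- tapply(edges$similarity, key, max)
    ord <- !duplicated(key)
    edges <- data.frame(disease_a = a[ord], disease_b = b[ord],
                        similarity = as.numeric(sim[key[ord]]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(disease_a = a, disease_b = b,
                        similarity = edges$similarity,
                        stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  edges
}

#' Induce the similarity graph on a disease set and threshold it
#'
#' Keeps edges whose endpoints are both in `ardTerms` and whose similarity
#' is strictly greater than `minSimilarity` (an edge at exactly the
#' threshold is excluded).
#'
#' @param edges Similarity edge `data.frame`.
#' @param ardTerms Character vector of age-related disease MeSH terms.
#' @param minSimilarity Strict lower bound on similarity; default 0.55.
#' @return The filtered edge `data.frame`.
#' @export
induceAndThreshold <- function(edges, ardTerms, minSimilarity = 0.55) {
  if (length(ardTerms) == 0L)
    stop("ardTerms must be non-empty", call. = FALSE)
  keep <- edges$disease_a %in% ardTerms &
          edges$disease_b %in% ardTerms &
          edges$similarity > minSimilarity
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decompose a thresholded edge list into subnetworks
#'
#' Connected components of the undirected graph, numbered by decreasing
#' member count with ties broken by the lexically smallest member. A
#' component is "primary" when it has at least `minPrimarySize` members.
#' Only non-isolated nodes appear (every component has >= 2 members).
#'
#' @param edges Thresholded similarity edge `data.frame`.
#' @param minPrimarySize Minimum size for a component to be flagged
#'   primary; default 5.
#' @return A list with `members` (`data.frame`: term, subnetwork_id) and
#'   `summary` (`data.frame`: subnetwork_id, size, is_primary, label —
#'   label `NA` until [labelSubnetworks()] is applied).
#' @export
connectedComponents <- function(edges, minPrimarySize = 5L) {
  if (nrow(edges) == 0L) {
    return(list(
      members = data.frame(term = character(), subnetwork_id = integer(),
                           stringsAsFactors = FALSE),
      summary = data.frame(subnetwork_id = integer(), size = integer(),
                           is_primary = logical(), label = character(),
                           stringsAsFactors = FALSE)))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("disease_a", "disease_b")], directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  ## order by decreasing size, ties by smallest lexical member
  sizes <- lengths(groups)
  anchors <- vapply(groups, .lexMin, character(1))
  ord <- order(-sizes, anchors, method = "radix")
  groups <- groups[ord]
  members <- do.call(rbind, lapply(seq_along(groups), function(i) {
    data.frame(term = sort(groups[[i]], method = "radix"),
               subnetwork_id = i, stringsAsFactors = FALSE)
  }))
  rownames(members) <- NULL
  summary <- data.frame(subnetwork_id = seq_along(groups),
                        size = as.integer(lengths(groups)),
                        is_primary = lengths(groups) >= minPrimarySize,
                        label = NA_character_, stringsAsFactors = FALSE)
  list(members = members, summary = summary)
}

#' Label subnetworks by plurality disease category and tissue
#'
#' Each subnetwork's label is the plurality MeSH disease category among its
#' members, suffixed with the plurality tissue; ties are broken by lexical
#' order, and members missing an annotation count as `"unspecified"`.
#'
#' @param subnetworks Result of [connectedComponents()].
#' @param categoryOf Named character vector: term -> disease category.
#' @param tissueOf Named character vector: term -> tissue, or `NULL`.
#' @return `subnetworks` with `summary$label` filled in.
#' @export
labelSubnetworks <- function(subnetworks, categoryOf, tissueOf = NULL) {
  lookup <- function(map, terms) {
    if (is.null(map)) return(rep("unspecified", length(terms)))
    v <- unname(map[terms])
    v[is.na(v)] <- "unspecified"
    v
  }
  labels <- vapply(subnetworks$summary$subnetwork_id, function(id) {
    terms <- subnetworks$members$term[
      subnetworks$members$subnetwork_id == id]
    catg <- .pluralityLabel(lookup(categoryOf, terms))
    if (is.null(tissueOf)) return(catg)
    paste0(catg, " / ", .pluralityLabel(lookup(tissueOf, terms)))
  }, character(1))
  subnetworks$summary$label <- labels
  subnetworks
}

#' Export a labeled subnetwork graph
#'
#' GraphML carries node attributes (`category`, `tissue`, `subnetwork_id`)
#' and the `similarity` edge attribute in one file. SIF carries the
#' topology (`A sim B` lines) with a sidecar `<file>.attrs.tsv` holding the
#' node attributes.
#'
#' @param subnetworks Labeled subnetworks from [labelSubnetworks()].
#' @param edges The thresholded edge `data.frame` the components were built
#'   from.
#' @param format `"graphml"` or `"sif"`.
#' @param file Output path.
#' @param categoryOf,tissueOf Named character vectors annotating member
#'   terms (missing entries become `"unspecified"`).
#' @return `file`, invisibly.
#' @export
exportNetwork <- function(subnetworks, edges, format = c("graphml", "sif"),
                          file, categoryOf = NULL, tissueOf = NULL) {
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       stop("unknown export format", call. = FALSE))
  mem <- subnetworks$members
  ann <- function(map, terms) {
    if (is.null(map)) return(rep("unspecified", length(terms)))
    v <- unname(map[terms]); v[is.na(v)] <- "unspecified"; v
  }
  nodes <- data.frame(name = mem$term,
                      category = ann(categoryOf, mem$term),
                      tissue = ann(tissueOf, mem$term),
                      subnetwork_id = mem$subnetwork_id,
                      stringsAsFactors = FALSE)
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      edges[, c("disease_a", "disease_b", "similarity")],
      directed = FALSE, vertices = nodes)
    igraph::write_graph(g, file, format = "graphml")
  } else {
    lines <- sprintf("%s\tsim\t%s", edges$disease_a, edges$disease_b)
    writeLines(lines, file)
    writeTsv(nodes, paste0(file, ".attrs.tsv"))
  }
  invisible(file)
}
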