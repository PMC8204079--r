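## Vocabulary harmonization: trait names -> MeSH disease/anatomy terms,
## phecode -> ICD code annotation, and category/tissue summaries.
##
## The trait->MeSH mapping itself is curated data, not code: the package
## consumes a deposited mapping table (trait_name, catalog, phecode,
## mesh_disease_id, mesh_anatomy_id, mapping_rule) and never invents a
## match. Five mapping rules are recognised: exact, parental (a specific
## trait mapped to its parent term, e.g. a hand/wrist fracture to
## "fracture"), alternate_category (non-disease traits mapped to anatomy/
## chemical/diagnosis/phenomena terms), causal (co-morbidity traits mapped
## to the shared causal disease, e.g. hypertensive heart/renal disease to
## "hypertension") and pick_one (ambiguous co-morbidities resolved to the
## single curated target).

.MAPPING_RULES <- c("exact", "parental", "alternate_category", "causal",
                    "pick_one")

## MeSH top-level headings for the branches the compendium uses.
.MESH_BRANCHES <- c(A = "Anatomy", C = "Diseases", D = "Chemicals and Drugs",
                    E = "Analytical, Diagnostic and Therapeutic Techniques",
                    F = "Psychiatry and Psychology",
                    G = "Phenomena and Processes")

.MESH_TOP <- c(
  C01 = "Infections",
  C04 = "Neoplasms",
  C05 = "Musculoskeletal Diseases",
  C06 = "Digestive System Diseases",
  C07 = "Stomatognathic Diseases",
  C08 = "Respiratory Tract Diseases",
  C09 = "Otorhinolaryngologic Diseases",
  C10 = "Nervous System Diseases",
  C11 = "Eye Diseases",
  C12 = "Male Urogenital Diseases",
  C13 = "Female Urogenital Diseases and Pregnancy Complications",
  C14 = "Cardiovascular Diseases",
  C15 = "Hemic and Lymphatic Diseases",
  C16 = "Congenital, Hereditary, and Neonatal Diseases and Abnormalities",
  C17 = "Skin and Connective Tissue Diseases",
  C18 = "Nutritional and Metabolic Diseases",
  C19 = "Endocrine System Diseases",
  C20 = "Immune System Diseases",
  C21 = "Disorders of Environmental Origin",
  C22 = "Animal Diseases",
  C23 = "Pathological Conditions, Signs and Symptoms",
  C24 = "Occupational Diseases",
  C25 = "Chemically-Induced Disorders",
  C26 = "Wounds and Injuries",
  A01 = "Body Regions",
  A02 = "Musculoskeletal System",
  A03 = "Digestive System",
  A04 = "Respiratory System",
  A05 = "Urogenital System",
  A06 = "Endocrine System",
  A07 = "Cardiovascular System",
  A08 = "Nervous System",
  A09 = "Sense Organs",
  A10 = "Tissues",
  A11 = "Cells",
  A12 = "Fluids and Secretions",
  A13 = "Animal Structures",
  A14 = "Stomatognathic System",
  A15 = "Hemic and Immune Systems",
  A16 = "Embryonic Structures",
  A17 = "Skin"
)

#' Normalize a trait or MeSH term for matching
#'
#' Lowercases, collapses internal whitespace and strips punctuation, so
#' "Hypertensive heart and/or renal disease" and "hypertensive heart and or
#' renal disease" compare equal.
#'
#' @param x Character vector of term names.
#' @return Normalized character vector.
#' @export
normalizeTerm <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:punct:]]+", " ", x)
  gsub("[[:space:]]+", " ", trimws(x))
}

#' Determine the top-level MeSH category of a node
#'
#' The category is derived deterministically from the first component of the
#' lexically smallest tree number (ties between tree numbers are broken by
#' lexical order). Unknown or absent tree numbers yield `"unspecified"`.
#'
#' @param treeNumbers Character vector of semicolon-separated dotted MeSH
#'   tree numbers, one string per node (e.g. `"C14.280;C16.131"`).
#' @return Character vector of top-level category names.
#' @export
meshTopCategory <- function(treeNumbers) {
  vapply(treeNumbers, function(tn) {
    if (is.na(tn) || !nzchar(tn)) return("unspecified")
    parts <- sort(trimws(strsplit(tn, ";", fixed = TRUE)[[1L]]),
                  method = "radix")
    first <- strsplit(parts[1L], ".", fixed = TRUE)[[1L]][1L]
    hit <- unname(.MESH_TOP[first])
    if (is.na(hit)) "unspecified" else hit
  }, character(1), USE.NAMES = FALSE)
}

## branch letter (A/C/D/E/F/G) of a node's first tree number
.meshBranch <- function(treeNumbers) {
  vapply(treeNumbers, function(tn) {
    if (is.na(tn) || !nzchar(tn)) return("unspecified")
    parts <- sort(trimws(strsplit(tn, ";", fixed = TRUE)[[1L]]),
                  method = "radix")
    letter <- substr(parts[1L], 1L, 1L)
    hit <- unname(.MESH_BRANCHES[letter])
    if (is.na(hit)) "unspecified" else hit
  }, character(1), USE.NAMES = FALSE)
}

#' Read a MeSH node table
#'
#' Expects columns `mesh_id`, `term` and `tree_numbers`
#' (semicolon-separated dotted tree codes). Adds derived `top_category` and
#' `branch` columns; nodes without tree numbers are categorized as
#' `"unspecified"` with a warning.
#'
#' @param file Path to the TSV.
#' @return A `data.frame` of MeSH nodes.
#' @export
readMeshNodes <- function(file) {
  df <- readTsv(file)
  need <- c("mesh_id", "term", "tree_numbers")
  if (!all(need %in% names(df)))
    stop("MeSH node TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$top_category <- meshTopCategory(df$tree_numbers)
  df$branch <- .meshBranch(df$tree_numbers)
  bad <- is.na(df$tree_numbers) | !nzchar(df$tree_numbers)
  if (any(bad))
    warning(sum(bad), " MeSH node(s) lack tree numbers; categorized as ",
            "'unspecified'", call. = FALSE)
  df
}

#' Map one trait name to its curated MeSH node
#'
#' Lookup is case-insensitive on whitespace/punctuation-normalized names; if
#' the exact normalized name is absent, a trailing "s" is stripped and the
#' lookup retried (so "Dementias" finds the "Dementia" entry).
#'
#' @param traitName Trait name to map.
#' @param mappingTable Curated `data.frame` with columns `trait_name`,
#'   `mesh_disease_id`, `mesh_anatomy_id`, `mapping_rule` (and typically
#'   `catalog`, `phecode`).
#' @param meshNodes MeSH node `data.frame` from [readMeshNodes()].
#' @return A list with `diseaseNode` and `anatomyNode` (each a one-row
#'   `data.frame` or `NULL`) and `rule`, or `NULL` when the trait is absent
#'   from the table (the caller records it in the rejects report).
#' @export
mapTraitToMesh <- function(traitName, mappingTable, meshNodes) {
  key <- normalizeTerm(traitName)
  tabKeys <- normalizeTerm(mappingTable$trait_name)
  hit <- which(tabKeys == key)
  if (length(hit) == 0L && endsWith(key, "s"))
    hit <- which(tabKeys == sub("s$", "", key))
  if (length(hit) == 0L)
    hit <- which(sub("s$", "", tabKeys) == key)
  if (length(hit) == 0L) return(NULL)
  row <- mappingTable[hit[1L], , drop = FALSE]
  findNode <- function(id) {
    if (is.na(id) || !nzchar(id)) return(NULL)
    m <- meshNodes[meshNodes$mesh_id == id, , drop = FALSE]
    if (nrow(m) == 0L) return(NULL)
    m <- m[1L, , drop = FALSE]
    if (is.null(m$top_category))
      m$top_category <- meshTopCategory(m$tree_numbers)
    m
  }
  rule <- row$mapping_rule
  if (!(rule %in% .MAPPING_RULES)) rule <- "exact"
  list(diseaseNode = findNode(row$mesh_disease_id),
       anatomyNode = findNode(row$mesh_anatomy_id),
       rule = rule)
}

#' Map a table of traits to MeSH, keeping a rejects report
#'
#' Every input trait appears exactly once in either the mapped records or
#' the rejects report; nothing is silently dropped. Mapping is deterministic
#' and idempotent.
#'
#' @param artTable `data.frame` with at least `trait_name` and `catalog`
#'   columns (typically also `phecode`).
#' @param mappingTable Curated trait->MeSH table (see [mapTraitToMesh()]).
#' @param meshNodes MeSH node `data.frame` from [readMeshNodes()].
#' @return A list with `records` (mapped rows: trait_name, catalog, phecode,
#'   mesh ids/terms/categories, mapping_rule) and `rejects` (trait_name,
#'   reason).
#' @export
mapArts <- function(artTable, mappingTable, meshNodes) {
  rec <- list(); rej <- list()
  for (i in seq_len(nrow(artTable))) {
    nm <- artTable$trait_name[i]
    m <- mapTraitToMesh(nm, mappingTable, meshNodes)
    if (is.null(m) || (is.null(m$diseaseNode) && is.null(m$anatomyNode))) {
      rej[[length(rej) + 1L]] <- data.frame(
        trait_name = nm,
        reason = if (is.null(m)) "unmapped: not in mapping table"
                 else "unmapped: no resolvable MeSH id",
        stringsAsFactors = FALSE)
      next
    }
    d <- m$diseaseNode; a <- m$anatomyNode
    rec[[length(rec) + 1L]] <- data.frame(
      trait_name = nm,
      catalog = if ("catalog" %in% names(artTable))
                  artTable$catalog[i] else NA_character_,
      phecode = if ("phecode" %in% names(artTable))
                  as.character(artTable$phecode[i]) else NA_character_,
      mesh_disease_id = if (is.null(d)) NA_character_ else d$mesh_id,
      mesh_disease_term = if (is.null(d)) NA_character_ else d$term,
      disease_category = if (is.null(d)) NA_character_ else d$top_category,
      mesh_anatomy_id = if (is.null(a)) NA_character_ else a$mesh_id,
      mesh_anatomy_term = if (is.null(a)) NA_character_ else a$term,
      anatomy_category = if (is.null(a)) NA_character_ else a$top_category,
      mapping_rule = m$rule,
      stringsAsFactors = FALSE)
  }
  records <- if (length(rec)) do.call(rbind, rec) else
    data.frame(trait_name = character(), catalog = character(),
               phecode = character(), mesh_disease_id = character(),
               mesh_disease_term = character(),
               disease_category = character(),
               mesh_anatomy_id = character(),
               mesh_anatomy_term = character(),
               anatomy_category = character(),
               mapping_rule = character(), stringsAsFactors = FALSE)
  rejects <- if (length(rej)) do.call(rbind, rej) else
    data.frame(trait_name = character(), reason = character(),
               stringsAsFactors = FALSE)
  message("mapped ", nrow(records), "/", nrow(artTable), " traits (",
          nrow(rejects), " rejects)")
  list(records = records, rejects = rejects)
}

#' Reduce mapped records to the unique MeSH node set
#'
#' Collects all disease and anatomy MeSH ids referenced by the records,
#' deduplicates by `mesh_id` and returns the nodes in stable order by term
#' name. Counts per MeSH branch are emitted as a message.
#'
#' @param records Mapped records from [mapArts()].
#' @param meshNodes MeSH node `data.frame` from [readMeshNodes()].
#' @return A `data.frame` of unique MeSH nodes, ordered by term.
#' @export
dedupeToUniqueMesh <- function(records, meshNodes) {
  ids <- unique(stats::na.omit(c(records$mesh_disease_id,
                                 records$mesh_anatomy_id)))
  nodes <- meshNodes[meshNodes$mesh_id %in% ids, , drop = FALSE]
  nodes <- nodes[!duplicated(nodes$mesh_id), , drop = FALSE]
  nodes <- nodes[order(nodes$term, method = "radix"), , drop = FALSE]
  rownames(nodes) <- NULL
  if (nrow(nodes)) {
    per <- table(nodes$branch)
    message("unique MeSH terms: ", nrow(nodes), " (",
            paste(sprintf("%s=%d", names(per), as.integer(per)),
                  collapse = ", "), ")")
  }
  nodes
}

#' Attach ICD-9 / ICD-10 / ICD-10-CM code lists by phecode
#'
#' Joins each record's phecode against the three phecode->ICD tables; one
#' phecode may map to many codes, stored comma-separated. Records without a
#' phecode pass through unchanged with empty code lists; phecodes that do
#' not parse as numeric codes go to the rejects report.
#'
#' @param records Mapped records (must have a `phecode` column).
#' @param phecodeIcd9,phecodeIcd10,phecodeIcd10cm `data.frame`s with columns
#'   `phecode` and `icd`.
#' @return A list with `records` (ICD columns `icd9`, `icd10`, `icd10cm`
#'   attached) and `rejects` (malformed phecodes).
#' @export
annotateIcd <- function(records, phecodeIcd9, phecodeIcd10, phecodeIcd10cm) {
  joinCodes <- function(phecode, tab) {
    if (is.na(phecode) || !nzchar(phecode)) return("")
    paste(sort(unique(tab$icd[as.character(tab$phecode) == phecode]),
               method = "radix"), collapse = ",")
  }
  ph <- as.character(records$phecode)
  present <- !is.na(ph) & nzchar(ph)
  malformed <- present & !grepl("^[0-9]+(\\.[0-9]+)?$", ph)
  rejects <- data.frame(trait_name = records$trait_name[malformed],
                        reason = sprintf("malformed phecode: %s",
                                         ph[malformed]),
                        stringsAsFactors = FALSE)
  use <- ifelse(malformed, NA_character_, ph)
  records$icd9 <- vapply(use, joinCodes, character(1), tab = phecodeIcd9,
                         USE.NAMES = FALSE)
  records$icd10 <- vapply(use, joinCodes, character(1), tab = phecodeIcd10,
                          USE.NAMES = FALSE)
  records$icd10cm <- vapply(use, joinCodes, character(1),
                            tab = phecodeIcd10cm, USE.NAMES = FALSE)
  list(records = records, rejects = rejects)
}

#' Summarize disease categories and anatomy/tissue distributions
#'
#' @param diseaseNodes Unique disease-branch MeSH nodes (`data.frame` with
#'   `top_category`).
#' @param anatomyNodes Unique anatomy-branch MeSH nodes, or `NULL`.
#' @param tissueOf Optional named character vector mapping disease term ->
#'   tissue term, for the cross-tabulated disease x tissue table.
#' @return A list with `diseaseCounts` (`data.frame`: category, n, ordered
#'   by decreasing n then name; plus a `tissue` cross-tab column when
#'   `tissueOf` is given) and `anatomyCounts`. Totals are conserved: the
#'   category counts sum to the number of input nodes.
#' @export
summarizeCategories <- function(diseaseNodes, anatomyNodes = NULL,
                                tissueOf = NULL) {
  countTab <- function(nodes) {
    if (is.null(nodes) || nrow(nodes) == 0L)
      return(data.frame(category = character(), n = integer(),
                        stringsAsFactors = FALSE))
    if (any(nodes$top_category == "unspecified"))
      warning("nodes without a known top-level category counted as ",
              "'unspecified'", call. = FALSE)
    tab <- table(nodes$top_category)
    out <- data.frame(category = names(tab), n = as.integer(tab),
                      stringsAsFactors = FALSE)
    out[order(-out$n, out$category, method = "radix"), , drop = FALSE]
  }
  diseaseCounts <- countTab(diseaseNodes)
  rownames(diseaseCounts) <- NULL
  if (!is.null(tissueOf) && nrow(diseaseCounts)) {
    tis <- vapply(diseaseCounts$category, function(catg) {
      terms <- diseaseNodes$term[diseaseNodes$top_category == catg]
      t <- tissueOf[terms]
      t <- t[!is.na(t)]
      if (!length(t)) NA_character_ else .pluralityLabel(t)
    }, character(1), USE.NAMES = FALSE)
    diseaseCounts$tissue <- tis
  }
  anatomyCounts <- countTab(anatomyNodes)
  rownames(anatomyCounts) <- NULL
  list(diseaseCounts = diseaseCounts, anatomyCounts = anatomyCounts)
}

## most frequent value; ties broken lexically
.pluralityLabel <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  best <- names(tab)[tab == max(tab)]
  .lexMin(best)
}
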