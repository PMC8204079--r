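## Synthetic inputs with known ground truth for every pipeline stage.
##
## Each generator consumes a SynthSpec and derives its own RNG stream from
## the SynthSpec master seed, so the five inputs are independently and
## jointly reproducible. The shapes emulate the real inputs structurally: late-peak
## unimodal prevalence curves against early-peak / bimodal / flat
## non-age-related ones; a similarity network with dense planted modules
## above the 0.55 threshold and sparse background below it; a pairwise rg
## table whose p-values follow z = rg/se; and a mortality table with a
## planted overlap fraction.

.AGE_BINS <- seq(0, 85, by = 5)

## categories cycled over planted network modules
.SYNTH_CATEGORIES <- c("Neoplasms", "Cardiovascular Diseases",
                       "Nervous System Diseases",
                       "Musculoskeletal Diseases", "Eye Diseases",
                       "Digestive System Diseases")
.SYNTH_TISSUES <- c("blood cells", "heart", "brain", "joint", "eye",
                    "intestine")

#' Generate prevalence profiles with planted labels
#'
#' Age-related profiles are smooth unimodal bumps peaking between 62 and 82
#' years (so they satisfy the classifier's criteria by construction at zero
#' noise); non-age-related profiles rotate through early-peak unimodal,
#' bimodal and flat shapes. Gaussian noise with s.d. `noiseSd` times the
#' profile peak is added and truncated at zero.
#'
#' @param spec A [SynthSpec-class].
#' @return A list with `profiles` (list of [PrevalenceProfile-class]) and
#'   `labels` (`data.frame`: trait_id, source, is_art, shape).
#' @export
genProfiles <- function(spec) {
  set.seed(.subSeed(spec@seed, 1L))
  ages <- .AGE_BINS
  gauss <- function(p, w) exp(-0.5 * ((ages - p) / w)^2)
  profiles <- list(); labs <- list()
  mk <- function(id, source, v) {
    peak <- max(v)
    if (spec@noiseSd > 0)
      v <- pmax(v + stats::rnorm(length(v), 0, spec@noiseSd * peak), 0)
    PrevalenceProfile(id, ages, pmin(v, 1), source = source,
                      valueKind = "proportion")
  }
  for (i in seq_len(spec@nArt)) {
    h <- stats::runif(1, 0.1, 0.6)
    v <- h * (0.02 + 0.98 * gauss(stats::runif(1, 62, 82),
                                  stats::runif(1, 10, 15)))
    id <- sprintf("ART_%03d", i)
    src <- if (i %% 2L == 0L) "GWAS" else "PheWAS"
    profiles[[length(profiles) + 1L]] <- mk(id, src, v)
    labs[[length(labs) + 1L]] <- data.frame(
      trait_id = id, source = src, is_art = TRUE, shape = "late_unimodal",
      stringsAsFactors = FALSE)
  }
  shapes <- c("early_unimodal", "bimodal", "flat")
  for (i in seq_len(spec@nNonArt)) {
    h <- stats::runif(1, 0.1, 0.6)
    shape <- shapes[(i - 1L) %% 3L + 1L]
    v <- switch(shape,
      early_unimodal = h * gauss(stats::runif(1, 15, 35),
                                 stats::runif(1, 8, 12)),
      bimodal = h * gauss(stats::runif(1, 10, 25),
                          stats::runif(1, 5, 8)) +
                0.85 * h * gauss(stats::runif(1, 65, 80),
                                 stats::runif(1, 5, 8)),
      flat = rep(h, length(ages)))
    id <- sprintf("NON_%03d", i)
    src <- if (i %% 2L == 0L) "GWAS" else "PheWAS"
    profiles[[length(profiles) + 1L]] <- mk(id, src, v)
    labs[[length(labs) + 1L]] <- data.frame(
      trait_id = id, source = src, is_art = FALSE, shape = shape,
      stringsAsFactors = FALSE)
  }
  labels <- if (length(labs)) do.call(rbind, labs) else
    data.frame(trait_id = character(), source = character(),
               is_art = logical(), shape = character(),
               stringsAsFactors = FALSE)
  list(profiles = profiles, labels = labels)
}

#' Generate a similarity network with planted modules
#'
#' Every within-module pair receives an edge with similarity drawn from
#' `intraScoreRange` (by default strictly above the 0.55 threshold); a
#' sparse 5% of between-module pairs receive scores from
#' `interScoreRange` (by default below it), so thresholding recovers the
#' planted modules exactly under the defaults. A warning is emitted when
#' either range straddles 0.55.
#'
#' @param spec A [SynthSpec-class].
#' @return A list with `edges` (similarity edge `data.frame`), `labels`
#'   (`data.frame`: term, mesh_id, module, category, tissue) and
#'   `nInterEdges`.
#' @export
genNetwork <- function(spec) {
  set.seed(.subSeed(spec@seed, 2L))
  sizes <- spec@networkModuleSizes
  if (any(sizes < 2L))
    stop("network module sizes must be >= 2", call. = FALSE)
  lo <- spec@intraScoreRange[1L]; hi <- spec@intraScoreRange[2L]
  lo2 <- spec@interScoreRange[1L]; hi2 <- spec@interScoreRange[2L]
  if (lo <= 0.55 || hi2 > 0.55)
    warning("score ranges straddle the 0.55 threshold; planted modules ",
            "may not be recoverable", call. = FALSE)
  n <- sum(sizes)
  terms <- sprintf("Disease_%03d", seq_len(n))
  module <- rep(seq_along(sizes), sizes)
  labels <- data.frame(
    term = terms,
    mesh_id = sprintf("M%03d", seq_len(n)),
    module = module,
    category = .SYNTH_CATEGORIES[(module - 1L) %%
                                 length(.SYNTH_CATEGORIES) + 1L],
    tissue = .SYNTH_TISSUES[(module - 1L) %% length(.SYNTH_TISSUES) + 1L],
    stringsAsFactors = FALSE)
  intra <- do.call(rbind, lapply(seq_along(sizes), function(mi) {
    idx <- which(module == mi)
    if (length(idx) < 2L) return(NULL)
    pr <- t(utils::combn(idx, 2L))
    data.frame(disease_a = terms[pr[, 1L]], disease_b = terms[pr[, 2L]],
               similarity = stats::runif(nrow(pr), lo, hi),
               stringsAsFactors = FALSE)
  }))
  crossPairs <- t(utils::combn(n, 2L))
  crossPairs <- crossPairs[module[crossPairs[, 1L]] !=
                           module[crossPairs[, 2L]], , drop = FALSE]
  if (nrow(crossPairs) > 0L) {
    nInter <- max(1L, round(0.05 * nrow(crossPairs)))
    pick <- sample(nrow(crossPairs), nInter)
    inter <- data.frame(disease_a = terms[crossPairs[pick, 1L]],
                        disease_b = terms[crossPairs[pick, 2L]],
                        similarity = stats::runif(nInter, lo2, hi2),
                        stringsAsFactors = FALSE)
  } else {
    nInter <- 0L
    inter <- intra[0, , drop = FALSE]
  }
  edges <- similarityEdges(rbind(intra, inter))
  list(edges = edges, labels = labels, nInterEdges = nInter)
}

#' Generate a pairwise genetic-correlation table with planted blocks
#'
#' Within-block pairs draw rg around the block's `within_rg`; between-block
#' pairs around `betweenRg` (s.d. 0.05, truncated to \[-1, 1\]). The
#' standard error is the block `se` (mean of the two for cross-block
#' pairs) and p = two-sided normal tail of rg/se, so the significance
#' structure follows the planted blocks.
#'
#' @param spec A [SynthSpec-class].
#' @return A list with `pairs` (UKBB-schema `data.frame`) and `labels`
#'   (`data.frame`: pheno_id, block).
#' @export
genRgPairs <- function(spec) {
  set.seed(.subSeed(spec@seed, 3L))
  blocks <- spec@rgBlocks
  if (any(blocks$se <= 0))
    stop("rg block se must be positive", call. = FALSE)
  n <- sum(blocks$size)
  ids <- sprintf("pheno_%03d", seq_len(n))
  block <- rep(seq_len(nrow(blocks)), blocks$size)
  labels <- data.frame(pheno_id = ids, block = block,
                       stringsAsFactors = FALSE)
  if (n < 2L)
    return(list(pairs = data.frame(), labels = labels))
  pr <- t(utils::combn(n, 2L))
  same <- block[pr[, 1L]] == block[pr[, 2L]]
  mu <- ifelse(same, blocks$within_rg[block[pr[, 1L]]], spec@betweenRg)
  se <- (blocks$se[block[pr[, 1L]]] + blocks$se[block[pr[, 2L]]]) / 2
  rg <- pmin(pmax(stats::rnorm(nrow(pr), mu, 0.05), -1), 1)
  p <- pmax(2 * stats::pnorm(-abs(rg / se)), .Machine$double.xmin)
  pairs <- data.frame(
    pheno_a_id = ids[pr[, 1L]], pheno_a_name = ids[pr[, 1L]],
    pheno_b_id = ids[pr[, 2L]], pheno_b_name = ids[pr[, 2L]],
    rg = rg, se = se, p = p, stringsAsFactors = FALSE)
  list(pairs = pairs, labels = labels)
}

#' Generate a leading-causes-of-death table with a planted overlap
#'
#' `round(overlapFraction * mortalityN)` causes are mapped into `ardTerms`;
#' the rest receive MeSH ids outside the set. Death counts are drawn
#' log-uniformly between 100 and 100,000 and ranks follow decreasing
#' deaths.
#'
#' @param spec A [SynthSpec-class].
#' @param ardTerms Character vector of age-related MeSH ids the overlap is
#'   planted into.
#' @return A list with `records` (mortality `data.frame`) and
#'   `plantedCoverage` (the generated death-coverage percentage).
#' @export
genMortality <- function(spec, ardTerms) {
  set.seed(.subSeed(spec@seed, 4L))
  n <- spec@mortalityN
  k <- round(spec@overlapFraction * n)
  inArd <- if (k > 0) {
    if (k <= length(ardTerms)) sample(ardTerms, k)
    else sample(ardTerms, k, replace = TRUE)
  } else character(0)
  mesh <- c(inArd, sprintf("NONARD_%03d", seq_len(n - k)))
  isOverlap <- c(rep(TRUE, k), rep(FALSE, n - k))
  deaths <- round(exp(stats::runif(n, log(100), log(1e5))))
  ord <- order(-deaths)
  records <- data.frame(
    rank = seq_len(n),
    icd10_code = sprintf("%s%02d.%d", LETTERS[(seq_len(n) - 1L) %% 20L + 1L],
                         seq_len(n) %% 100L, seq_len(n) %% 10L),
    cause_name = sprintf("cause_%03d", seq_len(n)),
    deaths = deaths[ord],
    mesh_id = mesh[ord],
    stringsAsFactors = FALSE)
  planted <- 100 * sum(records$deaths[isOverlap[ord]]) /
    sum(records$deaths)
  list(records = records, plantedCoverage = planted)
}

#' Write the full set of synthetic pipeline inputs
#'
#' Generates all five inputs (plus the MeSH node table, the trait->MeSH
#' mapping table and three phecode->ICD tables) into `dir`, together with a
#' `ground_truth.json` recording every planted label. The mapping table
#' maps each synthetic trait to a network disease term, so the pipeline
#' stages compose end-to-end.
#'
#' @param spec A [SynthSpec-class].
#' @param dir Output directory (created if absent).
#' @return Invisible named list of the written file paths.
#' @export
writeSyntheticInputs <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)

  prof <- genProfiles(spec)
  long <- do.call(rbind, lapply(prof$profiles, function(p) {
    data.frame(trait_id = traitId(p), source = p@source,
               age_bin_start = ageBins(p), value = profileValues(p),
               value_kind = valueKind(p), stringsAsFactors = FALSE)
  }))
  writeTsv(long, pth("profiles.tsv"))

  net <- genNetwork(spec)
  writeTsv(net$edges, pth("similarity_edges.tsv"))

  ## MeSH node table: one disease node per network term + anatomy nodes
  catCode <- names(.MESH_TOP)[match(net$labels$category, .MESH_TOP)]
  nNodes <- nrow(net$labels)
  anat <- data.frame(
    mesh_id = sprintf("A%03d", seq_along(.SYNTH_TISSUES)),
    term = .SYNTH_TISSUES,
    tree_numbers = sprintf("A%02d.%03d",
                           seq_along(.SYNTH_TISSUES) %% 15L + 1L,
                           seq_along(.SYNTH_TISSUES)),
    stringsAsFactors = FALSE)
  meshNodes <- rbind(
    data.frame(mesh_id = net$labels$mesh_id, term = net$labels$term,
               tree_numbers = sprintf("%s.%03d", catCode, seq_len(nNodes)),
               stringsAsFactors = FALSE),
    anat)
  writeTsv(meshNodes, pth("mesh_nodes.tsv"))

  ## trait -> MeSH mapping: every synthetic trait maps onto a network term
  labs <- prof$labels
  nTraits <- nrow(labs)
  target <- net$labels$mesh_id[(seq_len(nTraits) - 1L) %% nNodes + 1L]
  artMap <- data.frame(
    trait_name = labs$trait_id,
    catalog = labs$source,
    phecode = sprintf("%03d.%d", seq_len(nTraits),
                      seq_len(nTraits) %% 10L),
    mesh_disease_id = target,
    mesh_anatomy_id = anat$mesh_id[(seq_len(nTraits) - 1L) %%
                                   nrow(anat) + 1L],
    mapping_rule = "exact",
    stringsAsFactors = FALSE)
  writeTsv(artMap, pth("art_mesh_map.tsv"))

  ## phecode -> ICD tables with known multiplicities (1, 2, 3 cycling)
  icdTab <- function(prefix) {
    mult <- (seq_len(nTraits) - 1L) %% 3L + 1L
    data.frame(
      phecode = rep(artMap$phecode, mult),
      icd = sprintf("%s%03d.%d", prefix,
                    sequence(mult) + rep(seq_len(nTraits), mult) * 10L,
                    sequence(mult)),
      stringsAsFactors = FALSE)
  }
  writeTsv(icdTab("I9-"), pth("phecode_icd9.tsv"))
  writeTsv(icdTab("I10-"), pth("phecode_icd10.tsv"))
  writeTsv(icdTab("CM-"), pth("phecode_icd10cm.tsv"))

  rg <- genRgPairs(spec)
  writeTsv(rg$pairs, pth("rg_pairs.tsv"))

  ## ARD MeSH ids = targets of the planted age-related traits
  ardIds <- unique(target[labs$is_art])
  mort <- genMortality(spec, ardIds)
  writeTsv(mort$records, pth("mortality.tsv"))

  truth <- list(
    seed = spec@seed,
    profile_labels = prof$labels,
    network_labels = net$labels,
    n_inter_edges = net$nInterEdges,
    rg_block_labels = rg$labels,
    ard_mesh_ids = ardIds,
    planted_death_coverage = mort$plantedCoverage)
  jsonlite::write_json(truth, pth("ground_truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    profiles = pth("profiles.tsv"),
    edges = pth("similarity_edges.tsv"),
    meshNodes = pth("mesh_nodes.tsv"),
    artMap = pth("art_mesh_map.tsv"),
    phecodeIcd9 = pth("phecode_icd9.tsv"),
    phecodeIcd10 = pth("phecode_icd10.tsv"),
    phecodeIcd10cm = pth("phecode_icd10cm.tsv"),
    rgPairs = pth("rg_pairs.tsv"),
    mortality = pth("mortality.tsv"),
    groundTruth = pth("ground_truth.json")))
}
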