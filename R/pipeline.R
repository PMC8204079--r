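## End-to-end orchestration: classify -> map -> network -> rgcluster ->
## mortality, driven by a single config, with a machine-readable run
## report. Stages are skippable; the report records per-stage row counts,
## parameter echo, warnings and timings and is written even when a stage
## fails (the error is then re-thrown tagged with the stage name).

#' Read a pipeline run configuration
#'
#' YAML or JSON by file extension. See [runPipeline()] for the recognised
#' fields.
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` config.
#' @return A named list.
#' @export
readRunConfig <- function(file) {
  if (!file.exists(file)) stop("config not found: ", file, call. = FALSE)
  if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
  else jsonlite::read_json(file, simplifyVector = TRUE)
}

#' Run the full compendium pipeline
#'
#' Executes the requested stages in the fixed order classify, map, network,
#' rgcluster, mortality. Later stages consume earlier stage outputs where
#' available (the network and mortality stages need the mapped disease set
#' from the map stage).
#'
#' @param config A named list (or path read with [readRunConfig()]) with
#'   fields: input paths `profiles`, `artMap`, `meshNodes`, `edges`,
#'   `rgPairs`, `mortality` (optionally `phecodeIcd9`, `phecodeIcd10`,
#'   `phecodeIcd10cm`); `outDir`; `seed` (default 1); `stages` (character
#'   subset of the five stage names, default all); and parameter blocks
#'   `classifier` (args of [artClassifierParams()]), `cut` (args of
#'   [cutParams()]), plus scalars `minSimilarity` (default 0.55),
#'   `minPrimarySize` (default 5) and `alpha` (default 0.05).
#' @return The run report, invisibly (also written to
#'   `<outDir>/run_report.json`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stages <- config$stages %||%
    c("classify", "map", "network", "rgcluster", "mortality")
  outDir <- config$outDir %||% stop("config$outDir is required")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  set.seed(seed)

  needed <- c(classify = "profiles", map = "artMap", network = "edges",
              rgcluster = "rgPairs", mortality = "mortality")
  for (st in stages) {
    p <- config[[needed[[st]]]]
    if (is.null(p) || !file.exists(p))
      stop("config error: stage '", st, "' needs existing input '",
           needed[[st]], "' (got: ", p %||% "NULL", ")", call. = FALSE)
  }

  cparams <- do.call(artClassifierParams, config$classifier %||% list())
  ctparams <- do.call(cutParams, config$cut %||% list())
  minSimilarity <- config$minSimilarity %||% 0.55
  minPrimarySize <- config$minPrimarySize %||% 5L
  alpha <- config$alpha %||% 0.05

  report <- list(
    seed = seed,
    config = config[setdiff(names(config), "stages")],
    stages = list(),
    versions = list(R = as.character(getRversion()),
                    ageTraits = as.character(
                      utils::packageVersion("ageTraits"))))
  artNames <- NULL; ardTerms <- NULL; ardMeshIds <- NULL
  categoryOf <- NULL; tissueOf <- NULL; idCategoryOf <- NULL

  runStage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    warnings <- character()
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) e),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    entry <- list(seconds = round(proc.time()[["elapsed"]] - t0, 3),
                  warnings = warnings)
    if (inherits(res, "error")) {
      entry$error <- conditionMessage(res)
      report$stages[[name]] <<- entry
      .writeReport(report, outDir)
      stop("stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    entry <- c(entry, res$counts)
    report$stages[[name]] <<- entry
    res$value
  }

  if ("classify" %in% stages) {
    cls <- runStage("classify", function() {
      profiles <- readProfiles(config$profiles)
      out <- classifyTable(profiles, cparams)
      writeTsv(out, file.path(outDir, "classification.tsv"))
      list(value = out,
           counts = list(n_in = length(profiles), n_out = nrow(out),
                         n_art = sum(out$is_art)))
    })
    artNames <- cls$trait_id[cls$is_art]
  }

  if ("map" %in% stages) {
    uniqueNodes <- runStage("map", function() {
      artMap <- readTsv(config$artMap)
      meshNodes <- readMeshNodes(config$meshNodes)
      traits <- if (is.null(artNames)) artMap$trait_name else artNames
      artTable <- data.frame(trait_name = traits,
                             stringsAsFactors = FALSE)
      keep <- intersect(c("catalog", "phecode"), names(artMap))
      artTable[keep] <- artMap[match(traits, artMap$trait_name), keep]
      mapped <- mapArts(artTable, artMap, meshNodes)
      if (!is.null(config$phecodeIcd9)) {
        icd <- annotateIcd(mapped$records,
                           readTsv(config$phecodeIcd9),
                           readTsv(config$phecodeIcd10),
                           readTsv(config$phecodeIcd10cm))
        mapped$records <- icd$records
        mapped$rejects <- rbind(mapped$rejects, icd$rejects)
      }
      uniq <- dedupeToUniqueMesh(mapped$records, meshNodes)
      summ <- summarizeCategories(
        uniq[uniq$branch == "Diseases", , drop = FALSE],
        uniq[uniq$branch == "Anatomy", , drop = FALSE])
      writeTsv(mapped$records, file.path(outDir, "compendium.tsv"))
      writeTsv(mapped$rejects, file.path(outDir, "rejects.tsv"))
      writeTsv(uniq, file.path(outDir, "unique_mesh.tsv"))
      writeTsv(summ$diseaseCounts,
               file.path(outDir, "disease_categories.tsv"))
      writeTsv(summ$anatomyCounts,
               file.path(outDir, "anatomy_categories.tsv"))
      list(value = uniq,
           counts = list(n_in = length(traits),
                         n_mapped = nrow(mapped$records),
                         n_rejects = nrow(mapped$rejects),
                         n_unique_mesh = nrow(uniq)))
    })
    disease <- uniqueNodes[uniqueNodes$branch == "Diseases", ,
                           drop = FALSE]
    ardTerms <- disease$term
    ardMeshIds <- disease$mesh_id
    categoryOf <- stats::setNames(disease$top_category, disease$term)
    idCategoryOf <- stats::setNames(disease$top_category, disease$mesh_id)
  }

  if ("network" %in% stages) {
    if (is.null(ardTerms)) {
      if (is.null(config$ardTerms))
        stop("network stage needs the map stage or config$ardTerms",
             call. = FALSE)
      ardTerms <- readTsv(config$ardTerms)[[1L]]
    }
    runStage("network", function() {
      edges <- readSimilarityEdges(config$edges)
      kept <- induceAndThreshold(edges, ardTerms, minSimilarity)
      sn <- connectedComponents(kept, minPrimarySize)
      sn <- labelSubnetworks(sn, categoryOf, tissueOf)
      writeTsv(sn$members, file.path(outDir, "subnetwork_members.tsv"))
      writeTsv(sn$summary, file.path(outDir, "subnetwork_summary.tsv"))
      exportNetwork(sn, kept, "graphml",
                    file.path(outDir, "ard_network.graphml"),
                    categoryOf = categoryOf, tissueOf = tissueOf)
      list(value = sn,
           counts = list(n_in = nrow(edges), n_kept = nrow(kept),
                         n_subnetworks = nrow(sn$summary),
                         n_primary = sum(sn$summary$is_primary),
                         n_members = nrow(sn$members)))
    })
  }

  if ("rgcluster" %in% stages) {
    runStage("rgcluster", function() {
      pairs <- readTsv(config$rgPairs)
      pairs$fdr <- bhAdjust(pairs$p)
      sig <- significantPairs(pairs, alpha)
      phenotypes <- sort(unique(c(pairs$pheno_a_id, pairs$pheno_b_id)),
                         method = "radix")
      m <- buildRgMatrix(pairs, phenotypes)
      d <- rgToDistance(m, ctparams)
      hc <- agglomerativeCluster(d, ctparams@linkage)
      cl <- dynamicTreeCut(hc, ctparams)
      mask <- matrix(FALSE, length(phenotypes), length(phenotypes),
                     dimnames = dimnames(m))
      if (nrow(sig)) {
        ia <- match(sig$pheno_a_id, phenotypes)
        ib <- match(sig$pheno_b_id, phenotypes)
        mask[cbind(ia, ib)] <- TRUE
        mask[cbind(ib, ia)] <- TRUE
      }
      renderHeatmap(m, leafOrder(hc), mask,
                    file.path(outDir, "rg_heatmap.png"),
                    file.path(outDir, "rg_matrix_reordered.tsv"))
      writeTsv(sig, file.path(outDir, "significant_pairs.tsv"))
      writeTsv(data.frame(pheno_id = names(cl), cluster = as.integer(cl),
                          stringsAsFactors = FALSE),
               file.path(outDir, "clusters.tsv"))
      list(value = cl,
           counts = list(n_pairs = nrow(pairs), n_significant = nrow(sig),
                         n_phenotypes = length(phenotypes),
                         n_clusters = length(unique(cl[cl > 0]))))
    })
  }

  if ("mortality" %in% stages) {
    if (is.null(ardMeshIds)) {
      if (is.null(config$ardTerms))
        stop("mortality stage needs the map stage or config$ardTerms",
             call. = FALSE)
      ardMeshIds <- readTsv(config$ardTerms)[[1L]]
    }
    runStage("mortality", function() {
      records <- readMortality(config$mortality)
      ov <- overlapCauses(records, ardMeshIds, idCategoryOf)
      coverage <- deathCoverage(ov$overlap, records)
      writeTsv(ov$overlap, file.path(outDir, "mortality_overlap.tsv"))
      writeTsv(ov$perCategory,
               file.path(outDir, "mortality_categories.tsv"))
      list(value = coverage,
           counts = list(n_causes = nrow(records),
                         n_overlap = nrow(ov$overlap),
                         death_coverage_pct = coverage))
    })
  }

  .writeReport(report, outDir)
  invisible(report)
}

.writeReport <- function(report, outDir) {
  jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}
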