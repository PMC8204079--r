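#' PrevalenceProfile: one trait's prevalence by age bin
#'
#' Container for a single trait's prevalence-versus-age curve, the input to
#' the age-related trait classifier. Values may be prevalence proportions in
#' \[0, 1\] or raw patient counts; the classifier is invariant to the choice
#' because every internal comparison is scale-free.
#'
#' @slot traitId Character scalar, unique trait identifier.
#' @slot source Character scalar: `"GWAS"`, `"PheWAS"` or `"other"` —
#'   the catalog the trait was taken from.
#' @slot ageBins Numeric vector of bin-start ages in years, strictly
#'   increasing. The last bin is interpreted as open-ended (e.g. "85+").
#' @slot values Numeric vector, one non-negative value per age bin.
#' @slot valueKind Character scalar: `"proportion"` or `"count"`.
#'
#' @seealso [classifyART()], [smoothProfile()], [countModes()]
#' @export
setClass("PrevalenceProfile",
  slots = c(
    traitId   = "character",
    source    = "character",
    ageBins   = "numeric",
    values    = "numeric",
    valueKind = "character"
  )
)

setValidity("PrevalenceProfile", function(object) {
  msg <- character()
  if (length(object@traitId) != 1L || !nzchar(object@traitId))
    msg <- c(msg, "traitId must be a non-empty character scalar")
  if (!(object@source %in% c("GWAS", "PheWAS", "other")))
    msg <- c(msg, "source must be one of GWAS, PheWAS, other")
  if (!(object@valueKind %in% c("proportion", "count")))
    msg <- c(msg, "valueKind must be 'proportion' or 'count'")
  if (length(object@values) != length(object@ageBins))
    msg <- c(msg, "values and ageBins must have equal length")
  if (length(object@ageBins) > 1L && any(diff(object@ageBins) <= 0))
    msg <- c(msg, "ageBins must be strictly increasing")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and non-negative")
  if (identical(object@valueKind, "proportion") && any(object@values > 1))
    msg <- c(msg, "proportion values must not exceed 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PrevalenceProfile
#'
#' @param traitId Trait identifier.
#' @param ageBins Numeric vector of strictly increasing bin-start ages
#'   (years).
#' @param values Numeric vector of non-negative prevalences or counts, one
#'   per bin.
#' @param source Source catalog: `"GWAS"`, `"PheWAS"` or `"other"`.
#' @param valueKind `"proportion"` or `"count"`.
#' @return A [PrevalenceProfile-class] object.
#' @examples
#' p <- PrevalenceProfile("hypertension", seq(0, 85, 5),
#'                        c(rep(0.01, 8), seq(0.02, 0.5, length.out = 10)),
#'                        source = "PheWAS", valueKind = "proportion")
#' p
#' @export
PrevalenceProfile <- function(traitId, ageBins, values,
                              source = "other", valueKind = "count") {
  methods::new("PrevalenceProfile",
               traitId = as.character(traitId),
               source = as.character(source),
               ageBins = as.numeric(ageBins),
               values = as.numeric(values),
               valueKind = as.character(valueKind))
}

#' @describeIn PrevalenceProfile-class display a short summary
#' @param object A `PrevalenceProfile`.
#' @export
setMethod("show", "PrevalenceProfile", function(object) {
  cat("PrevalenceProfile '", object@traitId, "' (", object@source, ")\n",
      sep = "")
  cat("  ", length(object@ageBins), " age bins [",
      object@ageBins[1L], "-", object@ageBins[length(object@ageBins)],
      "], ", object@valueKind, "\n", sep = "")
  invisible(NULL)
})

#' ARTClassifierParams: tunable thresholds of the ART classifier
#'
#' The classifier declares a trait age-related when its (smoothed) prevalence
#' profile is unimodal, rises after mid-life, and peaks late. These
#' parameters hold the operational thresholds: mid-life at 40 years and the
#' minimum peak age of 60 years are the criteria's published anchors; the
#' remaining knobs control how noise and the qualitative word "around" are
#' handled.
#'
#' @slot midlifeAge Age (years) after which the profile must rise;
#'   default 40.
#' @slot minPeakAge Minimum age (years) of the global prevalence peak;
#'   default 60.
#' @slot peakTolerance Slack (years) subtracted from `minPeakAge`, exposing
#'   the qualitative "around 60"; default 0.
#' @slot smoothWindow Odd moving-average window (bins) applied before
#'   classification; default 3.
#' @slot modeTolerance Minimum prominence of a countable mode, as a fraction
#'   of the profile maximum; default 0.02.
#' @slot minRiseFraction Minimum fraction of non-decreasing steps between the
#'   first post-mid-life bin and the peak; default 0.8.
#' @export
setClass("ARTClassifierParams",
  slots = c(
    midlifeAge      = "numeric",
    minPeakAge      = "numeric",
    peakTolerance   = "numeric",
    smoothWindow    = "integer",
    modeTolerance   = "numeric",
    minRiseFraction = "numeric"
  )
)

setValidity("ARTClassifierParams", function(object) {
  msg <- character()
  if (object@midlifeAge >= object@minPeakAge)
    msg <- c(msg, "midlifeAge must be < minPeakAge")
  if (object@smoothWindow < 1L || object@smoothWindow %% 2L == 0L)
    msg <- c(msg, "smoothWindow must be odd and >= 1")
  if (object@modeTolerance < 0 || object@modeTolerance >= 1)
    msg <- c(msg, "modeTolerance must be in [0, 1)")
  if (object@minRiseFraction < 0 || object@minRiseFraction > 1)
    msg <- c(msg, "minRiseFraction must be in [0, 1]")
  if (object@peakTolerance < 0)
    msg <- c(msg, "peakTolerance must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct classifier parameters
#'
#' @param midlifeAge,minPeakAge,peakTolerance,smoothWindow,modeTolerance,minRiseFraction
#'   See [ARTClassifierParams-class] for meanings and defaults.
#' @return An [ARTClassifierParams-class] object.
#' @export
artClassifierParams <- function(midlifeAge = 40, minPeakAge = 60,
                                peakTolerance = 0, smoothWindow = 3L,
                                modeTolerance = 0.02,
                                minRiseFraction = 0.8) {
  methods::new("ARTClassifierParams",
               midlifeAge = midlifeAge, minPeakAge = minPeakAge,
               peakTolerance = peakTolerance,
               smoothWindow = as.integer(smoothWindow),
               modeTolerance = modeTolerance,
               minRiseFraction = minRiseFraction)
}

setMethod("show", "ARTClassifierParams", function(object) {
  cat("ARTClassifierParams: midlife >", object@midlifeAge,
      "y, peak >=", object@minPeakAge, "-", object@peakTolerance,
      "y, window", object@smoothWindow,
      ", mode tol", object@modeTolerance,
      ", rise fraction", object@minRiseFraction, "\n")
  invisible(NULL)
})

#' CutParams: distance and tree-cut settings for correlation clustering
#'
#' Phenotypes are clustered on the distance d = 1 - rg, so perfectly
#' correlated phenotypes are at distance 0 and perfectly anti-correlated ones
#' at 2. Missing pairs are imputed at the maximal distance so absent
#' evidence never binds phenotypes together. The dendrogram is decomposed
#' with a top-down tree cut severed at `cutHeight` (on raw merge heights),
#' keeping branches of at least `minClusterSize` leaves.
#'
#' @slot cutHeight Height at which the dendrogram is severed; default 0.99.
#' @slot minClusterSize Minimum leaves for a branch to become a cluster;
#'   default 3.
#' @slot linkage Agglomeration rule: `"complete"` (default), `"average"` or
#'   `"single"`.
#' @slot distance Distance transform; only `"one_minus_rg"` is defined.
#' @slot missingDistance Distance imputed for phenotype pairs with no
#'   correlation estimate; default 2 (the maximum of 1 - rg).
#' @export
setClass("CutParams",
  slots = c(
    cutHeight       = "numeric",
    minClusterSize  = "integer",
    linkage         = "character",
    distance        = "character",
    missingDistance = "numeric"
  )
)

setValidity("CutParams", function(object) {
  msg <- character()
  if (object@cutHeight <= 0) msg <- c(msg, "cutHeight must be > 0")
  if (object@minClusterSize < 1L)
    msg <- c(msg, "minClusterSize must be >= 1")
  if (!(object@linkage %in% c("complete", "average", "single")))
    msg <- c(msg, "linkage must be complete, average or single")
  if (!identical(object@distance, "one_minus_rg"))
    msg <- c(msg, "distance must be 'one_minus_rg'")
  if (length(msg)) msg else TRUE
})

#' Construct tree-cut parameters
#'
#' @param cutHeight,minClusterSize,linkage,distance,missingDistance See
#'   [CutParams-class].
#' @return A [CutParams-class] object.
#' @export
cutParams <- function(cutHeight = 0.99, minClusterSize = 3L,
                      linkage = "complete", distance = "one_minus_rg",
                      missingDistance = 2.0) {
  methods::new("CutParams", cutHeight = cutHeight,
               minClusterSize = as.integer(minClusterSize),
               linkage = linkage, distance = distance,
               missingDistance = missingDistance)
}

setMethod("show", "CutParams", function(object) {
  cat("CutParams: cutHeight", object@cutHeight,
      ", minClusterSize", object@minClusterSize,
      ", linkage", object@linkage, "\n")
  invisible(NULL)
})

#' SynthSpec: parameters of the synthetic-data generator
#'
#' One object fixes every synthetic input of the pipeline: prevalence
#' profiles with planted age-related/non-age-related labels, a
#' disease-similarity network with planted dense modules, a pairwise genetic
#' correlation table with planted correlation blocks, and a
#' leading-causes-of-death table with a planted overlap fraction. All
#' randomness derives from `seed`; two generators built from equal specs are
#' bit-identical.
#'
#' Defaults mirror the structure of the study the pipeline reproduces:
#' six similarity modules of sizes 41, 24, 10, 8, 7 and 32; two genetic
#' correlation blocks of 29 and 25 phenotypes; 100 mortality causes of which
#' a fraction 0.54 overlaps the disease set.
#'
#' @slot seed Integer master seed.
#' @slot nArt,nNonArt Number of planted age-related / non-age-related
#'   profiles.
#' @slot noiseSd Gaussian noise s.d. as a fraction of each profile's peak.
#' @slot networkModuleSizes Integer sizes of planted similarity modules.
#' @slot intraScoreRange,interScoreRange Similarity ranges for within- and
#'   between-module edges; the defaults sit strictly above and below the
#'   0.55 network threshold.
#' @slot rgBlocks data.frame with columns `size`, `within_rg`, `se` — one
#'   row per planted correlation block.
#' @slot betweenRg Mean genetic correlation between blocks.
#' @slot mortalityN Number of causes in the mortality table.
#' @slot overlapFraction Fraction of causes planted inside the disease set.
#' @export
setClass("SynthSpec",
  slots = c(
    seed               = "integer",
    nArt               = "integer",
    nNonArt            = "integer",
    noiseSd            = "numeric",
    networkModuleSizes = "integer",
    intraScoreRange    = "numeric",
    interScoreRange    = "numeric",
    rgBlocks           = "data.frame",
    betweenRg          = "numeric",
    mortalityN         = "integer",
    overlapFraction    = "numeric"
  )
)

setValidity("SynthSpec", function(object) {
  msg <- character()
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (any(object@networkModuleSizes < 1L))
    msg <- c(msg, "network module sizes must be >= 1")
  rng <- c(object@intraScoreRange, object@interScoreRange)
  if (any(rng < 0) || any(rng > 1))
    msg <- c(msg, "score ranges must lie within [0, 1]")
  if (!all(c("size", "within_rg", "se") %in% names(object@rgBlocks)))
    msg <- c(msg, "rgBlocks needs columns size, within_rg, se")
  else {
    if (any(object@rgBlocks$size < 1)) msg <- c(msg, "rg block sizes >= 1")
    if (any(object@rgBlocks$se <= 0)) msg <- c(msg, "rg block se must be > 0")
  }
  if (object@overlapFraction < 0 || object@overlapFraction > 1)
    msg <- c(msg, "overlapFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic-data specification
#'
#' @param seed Integer master seed driving all generators.
#' @param nArt,nNonArt Planted age-related / non-age-related profile counts.
#' @param noiseSd Profile noise s.d. as a fraction of the peak value.
#' @param networkModuleSizes Sizes of planted similarity modules.
#' @param intraScoreRange,interScoreRange Similarity score ranges for
#'   within- and between-module edges.
#' @param rgBlocks data.frame (`size`, `within_rg`, `se`) of planted
#'   correlation blocks.
#' @param betweenRg Mean between-block genetic correlation.
#' @param mortalityN Number of leading causes of death to generate.
#' @param overlapFraction Fraction of causes mapped into the disease set.
#' @return A [SynthSpec-class] object.
#' @examples
#' spec <- synthSpec(seed = 1, noiseSd = 0)
#' prof <- genProfiles(spec)
#' table(prof$labels$is_art)
#' @export
synthSpec <- function(seed = 1L, nArt = 50L, nNonArt = 50L, noiseSd = 0.05,
                      networkModuleSizes = c(41L, 24L, 10L, 8L, 7L, 32L),
                      intraScoreRange = c(0.6, 1.0),
                      interScoreRange = c(0.0, 0.5),
                      rgBlocks = data.frame(size = c(29L, 25L),
                                            within_rg = c(0.7, 0.7),
                                            se = c(0.1, 0.1)),
                      betweenRg = -0.3,
                      mortalityN = 100L, overlapFraction = 0.54) {
  methods::new("SynthSpec",
               seed = as.integer(seed), nArt = as.integer(nArt),
               nNonArt = as.integer(nNonArt), noiseSd = noiseSd,
               networkModuleSizes = as.integer(networkModuleSizes),
               intraScoreRange = as.numeric(intraScoreRange),
               interScoreRange = as.numeric(interScoreRange),
               rgBlocks = rgBlocks, betweenRg = betweenRg,
               mortalityN = as.integer(mortalityN),
               overlapFraction = overlapFraction)
}

setMethod("show", "SynthSpec", function(object) {
  cat("SynthSpec (seed ", object@seed, "): ",
      object@nArt, " ART + ", object@nNonArt, " non-ART profiles, ",
      length(object@networkModuleSizes), " network modules, ",
      nrow(object@rgBlocks), " rg blocks, ",
      object@mortalityN, " mortality causes\n", sep = "")
  invisible(NULL)
})
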