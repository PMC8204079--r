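## Age-related trait classification from prevalence-versus-age profiles.
##
## A trait is called age-related when its (smoothed) profile
##   (1) is unimodal and rises after mid-life (> 40 years), and
##   (2) peaks at around 60 years of age or later.
## Every comparison is scale-free, so proportions, rates per 100k and raw
## patient counts classify identically.

#' Smooth a prevalence profile with a centred moving average
#'
#' Edges use truncated windows, so the output has the same length and the
#' same age bins as the input; a window of 1 is the identity.
#'
#' @param profile A [PrevalenceProfile-class].
#' @param window Odd positive integer window width in bins, at most the
#'   number of bins.
#' @return A smoothed [PrevalenceProfile-class].
#' @examples
#' p <- PrevalenceProfile("t", c(40, 50, 60, 70, 80), c(0, 0, 3, 0, 0))
#' profileValues(smoothProfile(p, 3))  # 0 1 1 1 0
#' @export
setMethod("smoothProfile", "PrevalenceProfile", function(profile,
                                                         window = 3L) {
  v <- profile@values
  sm <- .movingAverage(v, window)
  methods::initialize(profile, values = sm)
})

.movingAverage <- function(v, window) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("smoothing window must be a positive odd integer", call. = FALSE)
  if (window > length(v))
    stop("smoothing window exceeds the number of age bins", call. = FALSE)
  if (window == 1L) return(v)
  half <- (window - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(v[lo:hi])
  }, numeric(1))
}

#' Count prevalence modes and locate the peak age
#'
#' Counts strict local maxima of the profile after merging plateaus (runs of
#' equal values count once); boundary bins can be maxima. A secondary
#' maximum is only counted when it is separated from the global maximum by a
#' valley at least `modeTolerance * max(values)` below it — shallow wiggles
#' do not create modes. The peak age is the bin-start age of the global
#' maximum, taking the earliest bin on exact ties.
#'
#' @param profile A [PrevalenceProfile-class] with at least 3 bins and not
#'   all-zero values.
#' @param modeTolerance Minimum mode prominence as a fraction of the profile
#'   maximum; 0 counts every strict local maximum.
#' @return A list with elements `nModes` (integer) and `peakAge` (years).
#' @examples
#' p <- PrevalenceProfile("t", c(40, 50, 60, 70, 80), c(1, 2, 5, 3, 1))
#' countModes(p)  # one mode, peak at 60
#' @export
setMethod("countModes", "PrevalenceProfile", function(profile,
                                                      modeTolerance = 0.02) {
  v <- profile@values
  if (length(v) < 3L)
    stop("mode counting needs at least 3 age bins", call. = FALSE)
  if (all(v == 0))
    stop("empty profile: all values are zero", call. = FALSE)
  res <- .scanModes(v, modeTolerance)
  list(nModes = res$nModes, peakAge = profile@ageBins[res$peakIndex])
})

## plateau-merging local-maximum scan on a numeric vector
.scanModes <- function(v, modeTolerance = 0) {
  r <- rle(v)
  rv <- r$values
  k <- length(rv)
  ## a run is a candidate mode if strictly above both existing neighbours
  isMax <- vapply(seq_len(k), function(i) {
    leftOk  <- i == 1L || rv[i] > rv[i - 1L]
    rightOk <- i == k  || rv[i] > rv[i + 1L]
    leftOk && rightOk
  }, logical(1))
  cand <- which(isMax)
  ## run-start index in the original vector
  starts <- cumsum(c(1L, r$lengths[-k]))
  globalRun <- cand[which.max(rv[cand])]  # earliest on ties (which.max)
  keep <- vapply(cand, function(i) {
    if (i == globalRun) return(TRUE)
    path <- if (i < globalRun) rv[i:globalRun] else rv[globalRun:i]
    (rv[i] - min(path)) >= modeTolerance * max(v)
  }, logical(1))
  list(nModes = sum(keep), peakIndex = starts[globalRun])
}

#' Does prevalence rise after mid-life?
#'
#' True when the value at the global peak is at least the value at the first
#' bin starting at or after `midlifeAge`, and the fraction of non-decreasing
#' consecutive steps between that bin and the peak is at least
#' `minRiseFraction`. A peak before mid-life — or at the first post-mid-life
#' bin, where no step ever rose — returns `FALSE` (a classification outcome,
#' not an error).
#'
#' @param profile A [PrevalenceProfile-class].
#' @param params An [ARTClassifierParams-class].
#' @return Logical scalar.
#' @export
setMethod("risesAfterMidlife", "PrevalenceProfile",
          function(profile, params = artClassifierParams()) {
  v <- profile@values
  ages <- profile@ageBins
  peakIdx <- .scanModes(v)$peakIndex
  if (ages[peakIdx] < params@midlifeAge) return(FALSE)
  startIdx <- which(ages >= params@midlifeAge)[1L]
  if (is.na(startIdx)) return(FALSE)
  if (v[peakIdx] < v[startIdx]) return(FALSE)
  ## a peak at (or before) the first post-mid-life bin means nothing rose
  if (peakIdx <= startIdx) return(FALSE)
  steps <- diff(v[startIdx:peakIdx])
  mean(steps >= 0) >= params@minRiseFraction
})

#' Classify one prevalence profile as age-related or not
#'
#' Applies [smoothProfile()], [countModes()] and [risesAfterMidlife()] with
#' the thresholds in `params`. The verdict is age-related iff the smoothed
#' profile is unimodal, rises after mid-life, and peaks at
#' `minPeakAge - peakTolerance` years or later.
#'
#' @param profile A [PrevalenceProfile-class].
#' @param params An [ARTClassifierParams-class].
#' @return A one-row `data.frame` with columns `trait_id`, `source`,
#'   `is_art`, `peak_age`, `n_modes`, `rises_after_midlife` and `reasons`
#'   (semicolon-separated rule outcomes; empty when age-related).
#' @examples
#' ages <- seq(0, 85, 5)
#' vals <- exp(-0.5 * ((ages - 75) / 12)^2)
#' classifyART(PrevalenceProfile("late", ages, vals))
#' @export
setMethod("classifyART", "PrevalenceProfile",
          function(profile, params = artClassifierParams()) {
  sm <- smoothProfile(profile, params@smoothWindow)
  modes <- countModes(sm, params@modeTolerance)
  rises <- risesAfterMidlife(sm, params)
  peakOk <- modes$peakAge >= params@minPeakAge - params@peakTolerance
  reasons <- character()
  if (modes$nModes != 1L)
    reasons <- c(reasons, sprintf("not unimodal (%d modes)", modes$nModes))
  if (!rises)
    reasons <- c(reasons, sprintf("not rising after %g", params@midlifeAge))
  if (!peakOk)
    reasons <- c(reasons,
                 sprintf("peak at %g before %g", modes$peakAge,
                         params@minPeakAge - params@peakTolerance))
  data.frame(
    trait_id = profile@traitId,
    source = profile@source,
    is_art = modes$nModes == 1L && rises && peakOk,
    peak_age = modes$peakAge,
    n_modes = modes$nModes,
    rises_after_midlife = rises,
    reasons = paste(reasons, collapse = "; "),
    stringsAsFactors = FALSE
  )
})

#' Classify a batch of prevalence profiles
#'
#' @param profiles A list of [PrevalenceProfile-class] objects with unique
#'   trait ids.
#' @param params An [ARTClassifierParams-class].
#' @return A `data.frame`, one row per profile, in input order, with the
#'   columns of [classifyART()]. Per-catalog counts of age-related calls are
#'   emitted as a message.
#' @export
classifyTable <- function(profiles, params = artClassifierParams()) {
  cols <- c("trait_id", "source", "is_art", "peak_age", "n_modes",
            "rises_after_midlife", "reasons")
  if (length(profiles) == 0L) {
    out <- data.frame(trait_id = character(), source = character(),
                      is_art = logical(), peak_age = numeric(),
                      n_modes = integer(), rises_after_midlife = logical(),
                      reasons = character(), stringsAsFactors = FALSE)
    return(out[cols])
  }
  ids <- vapply(profiles, traitId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate trait_id in profile list: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  out <- do.call(rbind, lapply(profiles, classifyART, params = params))
  rownames(out) <- NULL
  counts <- tapply(out$is_art, out$source, sum)
  message("classified ", nrow(out), " profiles; age-related by source: ",
          paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                collapse = ", "))
  out
}

#' Read prevalence profiles from a tidy TSV
#'
#' Expects columns `trait_id`, `source`, `age_bin_start`, `value`,
#' `value_kind`, one row per (trait, bin). Bins are sorted by age within
#' trait.
#'
#' @param file Path to the TSV.
#' @return A list of [PrevalenceProfile-class] objects, in first-appearance
#'   order of `trait_id`.
#' @export
readProfiles <- function(file) {
  df <- readTsv(file)
  need <- c("trait_id", "source", "age_bin_start", "value", "value_kind")
  if (!all(need %in% names(df)))
    stop("profile TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- unique(df$trait_id)
  lapply(ids, function(id) {
    d <- df[df$trait_id == id, , drop = FALSE]
    d <- d[order(d$age_bin_start), , drop = FALSE]
    PrevalenceProfile(id, d$age_bin_start, d$value,
                      source = d$source[1L], valueKind = d$value_kind[1L])
  })
}
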