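## Mortality overlap: how much of the death burden in a leading-causes
## table falls on the age-related disease set.

#' Read a leading-causes-of-death table
#'
#' Expects columns `rank`, `icd10_code`, `cause_name`, `deaths` and
#' `mesh_id` (the MeSH translation of the cause; empty when unmapped).
#'
#' @param file Path to the TSV.
#' @return A `data.frame` of mortality records.
#' @export
readMortality <- function(file) {
  df <- readTsv(file)
  need <- c("rank", "icd10_code", "cause_name", "deaths", "mesh_id")
  if (!all(need %in% names(df)))
    stop("mortality TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$rank))
    stop("ranks must be unique", call. = FALSE)
  if (any(df$deaths < 0))
    stop("death counts must be non-negative", call. = FALSE)
  df
}

#' Overlap causes of death with the age-related disease set
#'
#' A cause overlaps when its MeSH translation is in `ardTerms`. Causes with
#' no MeSH mapping are excluded from the overlap (and counted in a message)
#' but remain part of the death denominator used by [deathCoverage()].
#'
#' @param records Mortality `data.frame` (see [readMortality()]).
#' @param ardTerms Character vector of age-related disease MeSH ids/terms.
#' @param categoryOf Optional named character vector mapping MeSH id ->
#'   disease category for the per-category breakdown.
#' @return A list with `overlap` (the overlapping records) and
#'   `perCategory` (`data.frame`: category, n).
#' @export
overlapCauses <- function(records, ardTerms, categoryOf = NULL) {
  mapped <- !is.na(records$mesh_id) & nzchar(records$mesh_id)
  if (any(!mapped))
    message(sum(!mapped), " cause(s) without MeSH mapping excluded from ",
            "the overlap")
  overlap <- records[mapped & records$mesh_id %in% ardTerms, ,
                     drop = FALSE]
  rownames(overlap) <- NULL
  perCategory <- if (is.null(categoryOf) || nrow(overlap) == 0L) {
    data.frame(category = character(), n = integer(),
               stringsAsFactors = FALSE)
  } else {
    catg <- unname(categoryOf[overlap$mesh_id])
    catg[is.na(catg)] <- "unspecified"
    tab <- table(catg)
    out <- data.frame(category = names(tab), n = as.integer(tab),
                      stringsAsFactors = FALSE)
    out[order(-out$n, out$category, method = "radix"), , drop = FALSE]
  }
  rownames(perCategory) <- NULL
  list(overlap = overlap, perCategory = perCategory)
}

#' Death coverage of the overlapping causes
#'
#' The percentage of all deaths in the table that fall on overlapping
#' causes: 100 * sum(deaths of overlap) / sum(deaths of all records).
#' Unmapped causes stay in the denominator. No rounding is applied.
#'
#' @param overlap Overlapping records from [overlapCauses()].
#' @param records The full mortality table.
#' @return Numeric percentage in \[0, 100\].
#' @examples
#' tab <- data.frame(rank = 1:3, icd10_code = c("I21", "C34", "X99"),
#'                   cause_name = c("a", "b", "c"),
#'                   deaths = c(30, 20, 50),
#'                   mesh_id = c("M1", "M2", "M3"))
#' deathCoverage(tab[1:2, ], tab)  # 50
#' @export
deathCoverage <- function(overlap, records) {
  total <- sum(records$deaths)
  if (total <= 0)
    stop("total death count is zero; coverage undefined", call. = FALSE)
  100 * sum(overlap$deaths) / total
}
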