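## Genetic-correlation significance and clustering.
##
## Input is a pairwise genetic-correlation table in the public UK Biobank
## release schema (pheno_a_id, pheno_a_name, pheno_b_id, pheno_b_name, rg,
## se, p). Raw p-values are corrected to FDR by Benjamini-Hochberg;
## significance uses strict FDR < alpha. Phenotypes are clustered on the
## distance 1 - rg with agglomerative clustering, and the dendrogram is
## decomposed with a top-down dynamic tree cut (see dynamicTreeCutTree).

#' Benjamini-Hochberg false discovery rates
#'
#' The step-up adjustment: sort p ascending, q_i = p_i * m / i, enforce
#' monotonicity by a running minimum from the largest rank, cap at 1 and
#' return in input order. Computation is delegated to
#' [stats::p.adjust()] with `method = "BH"` after validating the input.
#'
#' @param p Numeric vector of raw p-values in (0, 1\].
#' @return Numeric vector of FDR-adjusted values, same order as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Select significantly correlated phenotype pairs
#'
#' Applies strict `fdr < alpha`. If the table has no `fdr` column it is
#' computed from `p` with [bhAdjust()] first.
#'
#' @param pairs `data.frame` of correlation pairs with a `p` (and
#'   optionally `fdr`) column.
#' @param alpha Significance threshold on FDR; default 0.05.
#' @return The significant subset, with the `fdr` column populated.
#' @export
significantPairs <- function(pairs, alpha = 0.05) {
  if (!("fdr" %in% names(pairs))) pairs$fdr <- bhAdjust(pairs$p)
  out <- pairs[pairs$fdr < alpha, , drop = FALSE]
  rownames(out) <- NULL
  message(nrow(out), "/", nrow(pairs), " pairs significant at FDR < ",
          alpha)
  out
}

#' Assemble a symmetric genetic-correlation matrix
#'
#' The diagonal is 1; pairs absent from the table are `NA`; rg estimates
#' outside \[-1, 1\] (LD-score estimates may slightly overshoot) are clamped
#' with a warning reporting how many.
#'
#' @param pairs `data.frame` with `pheno_a_id`, `pheno_b_id`, `rg`.
#' @param phenotypes Ordered character vector of unique phenotype ids
#'   defining the matrix rows/columns.
#' @return A symmetric numeric matrix with `phenotypes` as dimnames.
#' @export
buildRgMatrix <- function(pairs, phenotypes) {
  if (anyDuplicated(phenotypes))
    stop("phenotypes must be unique", call. = FALSE)
  unknown <- setdiff(unique(c(pairs$pheno_a_id, pairs$pheno_b_id)),
                     phenotypes)
  if (length(unknown))
    stop("pair references unknown phenotype(s): ",
         paste(utils::head(unknown, 3L), collapse = ", "), call. = FALSE)
  n <- length(phenotypes)
  m <- matrix(NA_real_, n, n, dimnames = list(phenotypes, phenotypes))
  diag(m) <- 1
  rg <- pairs$rg
  nClamped <- sum(rg < -1 | rg > 1, na.rm = TRUE)
  if (nClamped > 0)
    warning("clamped ", nClamped, " rg value(s) to [-1, 1]", call. = FALSE)
  rg <- pmin(pmax(rg, -1), 1)
  ia <- match(pairs$pheno_a_id, phenotypes)
  ib <- match(pairs$pheno_b_id, phenotypes)
  m[cbind(ia, ib)] <- rg
  m[cbind(ib, ia)] <- rg
  m
}

#' Transform a correlation matrix into clustering distances
#'
#' d = 1 - rg, ranging over \[0, 2\]; missing entries are imputed at
#' `params@missingDistance` so that absent evidence never binds phenotypes;
#' the diagonal is 0.
#'
#' @param m Symmetric rg matrix with unit diagonal (see [buildRgMatrix()]).
#' @param params A [CutParams-class].
#' @return A symmetric distance matrix with zero diagonal.
#' @export
rgToDistance <- function(m, params = cutParams()) {
  d <- 1 - m
  d[is.na(d)] <- params@missingDistance
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Standard agglomeration under complete, average or single linkage,
#' delegated to [stats::hclust()] (which breaks merge ties by smallest
#' cluster index).
#'
#' @param d Square symmetric numeric distance matrix with labels as
#'   dimnames.
#' @param linkage `"complete"`, `"average"` or `"single"`.
#' @return An [stats::hclust] dendrogram.
#' @export
agglomerativeCluster <- function(d, linkage = c("complete", "average",
                                                "single")) {
  linkage <- match.arg(linkage)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance input must be a square matrix", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Left-to-right leaf order of a dendrogram
#'
#' @param hc An [stats::hclust] object.
#' @return Character vector of leaf labels in display order.
#' @export
leafOrder <- function(hc) {
  hc$labels[hc$order]
}

#' Render a clustered genetic-correlation heatmap
#'
#' Writes a PNG of the reordered correlation matrix on a diverging scale
#' (-1 blue, 0 white, +1 red) with significant cells outlined, plus the
#' testable artifacts: a TSV of the reordered matrix and a TSV of the
#' reordered significance mask.
#'
#' @param m Symmetric rg matrix.
#' @param order Character vector (a permutation of the matrix labels)
#'   giving the display order, typically [leafOrder()].
#' @param mask Logical matrix, same dimnames as `m`, `TRUE` where the pair
#'   is significant.
#' @param file PNG output path.
#' @param tsvFile Path for the reordered-matrix TSV; the mask is written
#'   next to it with suffix `_mask.tsv`.
#' @return Invisible list with the reordered `matrix` and `mask`.
#' @export
renderHeatmap <- function(m, order, mask, file, tsvFile) {
  if (!setequal(order, rownames(m)) || length(order) != nrow(m))
    stop("order must be a permutation of the matrix labels", call. = FALSE)
  mo <- m[order, order, drop = FALSE]
  ko <- mask[order, order, drop = FALSE]
  writeTsv(data.frame(phenotype = rownames(mo), mo, check.names = FALSE),
           tsvFile)
  writeTsv(data.frame(phenotype = rownames(ko), ko, check.names = FALSE),
           sub("\\.tsv$", "_mask.tsv", tsvFile))
  pal <- grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))
  n <- nrow(mo)
  grDevices::png(file, width = 900, height = 900)
  on.exit(grDevices::dev.off(), add = TRUE)
  z <- mo; z[is.na(z)] <- 0
  graphics::image(seq_len(n), seq_len(n), t(z[n:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal(101), axes = FALSE,
                  xlab = "", ylab = "", main = "genetic correlation (rg)")
  graphics::axis(1, at = seq_len(n), labels = colnames(mo), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(mo)), las = 2,
                 cex.axis = 0.6)
  sig <- which(ko[n:1, , drop = FALSE], arr.ind = TRUE)
  if (nrow(sig))
    graphics::rect(sig[, 2] - 0.5, sig[, 1] - 0.5, sig[, 2] + 0.5,
                   sig[, 1] + 0.5, border = "black", lwd = 0.6)
  invisible(list(matrix = mo, mask = ko))
}
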