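# Stage 2 statistics: splicing indices, the MIDAS-style ANOVA on
# gene-normalized values, and the exon-to-junction threshold mapping.

# Row-wise one-way ANOVA F-test p-values for a two-condition design.
# nv: matrix of gene-normalized per-sample values. Degenerate rows with
# zero within-group variance get p = 1 when the group means also agree
# and p = 0 otherwise.
.rowAnovaP <- function(nv, condition) {
  conds <- sort(unique(condition))
  a <- which(condition == conds[1L])
  b <- which(condition == conds[2L])
  nA <- length(a); nB <- length(b); n <- nA + nB
  if (nA < 2L || nB < 2L)
    return(rep(NA_real_, nrow(nv)))
  mA <- rowMeans(nv[, a, drop = FALSE])
  mB <- rowMeans(nv[, b, drop = FALSE])
  gm <- (nA * mA + nB * mB) / n
  ssw <- rowSums((nv[, a, drop = FALSE] - mA)^2) +
    rowSums((nv[, b, drop = FALSE] - mB)^2)
  ssb <- nA * (mA - gm)^2 + nB * (mB - gm)^2
  f <- (ssb / 1) / (ssw / (n - 2L))
  p <- pf(f, 1, n - 2L, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1
  p[ssw == 0 & ssb > 0] <- 0
  unname(p)
}

#' MIDAS-style test for one probeset
#'
#' One-way ANOVA across the two conditions on the gene-normalized
#' values `nv[s] = probesetValues[s] - geneValues[s]`; returns the
#' F-test p-value. Normalizing by the per-sample gene index makes the
#' test invariant to any sample-wise shift shared by probeset and gene.
#' With fewer than two samples in either condition the probeset is
#' untestable and `NA` is returned. When the within-group variance is
#' zero, the p-value is 1 if the group means agree and 0 otherwise.
#'
#' @param probesetValues numeric per-sample log2 index of the probeset.
#' @param geneValues numeric per-sample log2 index of its gene.
#' @param condition character vector of condition labels per sample
#'   (exactly two distinct values).
#' @return p-value in `[0, 1]`, or `NA` if untestable.
#' @export
midasTest <- function(probesetValues, geneValues, condition) {
  if (length(probesetValues) != length(geneValues) ||
      length(probesetValues) != length(condition))
    stop("'probesetValues', 'geneValues' and 'condition' must align")
  if (length(unique(condition)) != 2L)
    stop("exactly two conditions are required")
  nv <- matrix(probesetValues - geneValues, nrow = 1L)
  .rowAnovaP(nv, condition)
}

#' Splicing indices of probesets relative to their gene
#'
#' The splicing index is the probeset's between-condition log2 fold
#' change minus the fold change of its gene; its sign is the direction
#' of the splicing change. Probesets whose gene has no expression index
#' (gene excluded by stage 1) get `NA` and are marked untestable.
#'
#' @param probesetExprs probeset index matrix (exons and/or junctions).
#' @param geneValues gene index matrix as from [geneExpressionIndex()]
#'   (`$values`).
#' @param geneOf named character vector mapping probeset id to gene id.
#' @param condition sample-to-condition vector or design `data.frame`.
#' @return `data.frame` with `probeset_id`, `gene_id`, `si`,
#'   `direction` (-1, 0, 1 or `NA`) and `testable`.
#' @export
splicingIndex <- function(probesetExprs, geneValues, geneOf, condition) {
  if (is.data.frame(condition))
    condition <- setNames(condition$condition, condition$sample_id)
  ids <- rownames(probesetExprs)
  g <- geneOf[ids]
  fc <- foldChanges(probesetExprs, condition)
  gfc <- .foldChanges(geneValues, as.character(condition[colnames(geneValues)]))
  si <- unname(fc) - unname(gfc[match(g, rownames(geneValues))])
  testable <- g %in% rownames(geneValues)
  si[!testable] <- NA_real_
  data.frame(probeset_id = ids, gene_id = unname(g), si = si,
             direction = sign(si), testable = testable,
             stringsAsFactors = FALSE)
}

#' Adjusted junction significance threshold by quantile mapping
#'
#' Junction probesets are fewer-probed and noisier than exon probesets,
#' so their p-value distribution differs systematically. The exon
#' threshold `p` is mapped to the junction scale through the empirical
#' quantile level it attains on the exon p-values:
#' `f = (# exon p <= p) / N_exon`, `k = ceiling(f * N_junc)`, and the
#' adjusted threshold `p'` is the k-th smallest junction p-value (0 when
#' `k = 0`). By construction the fraction of junctions passing `p'`
#' equals `k / N_junc`, the smallest achievable fraction at or above
#' `f`.
#'
#' @param exonPvalues,junctionPvalues nonempty numeric p-value vectors.
#' @param p exon significance threshold (default 0.01).
#' @return list with `p`, `p_prime`, `f` and `k`.
#' @examples
#' adjustJunctionThreshold(c(0.001, 0.005, 0.02, 0.2, 0.5, 0.9),
#'                         c(0.002, 0.03, 0.04, 0.3, 0.6, 0.8), p = 0.01)
#' @export
adjustJunctionThreshold <- function(exonPvalues, junctionPvalues, p = 0.01) {
  exonPvalues <- exonPvalues[!is.na(exonPvalues)]
  junctionPvalues <- junctionPvalues[!is.na(junctionPvalues)]
  if (!length(exonPvalues) || !length(junctionPvalues))
    stop("empty p-value list")
  cnt <- sum(exonPvalues <= p)
  nE <- length(exonPvalues)
  nJ <- length(junctionPvalues)
  f <- cnt / nE
  # k = ceiling(f * nJ), computed on exact integers (cnt * nJ / nE)
  k <- as.integer(ceiling((as.numeric(cnt) * nJ) / nE))
  p_prime <- if (k == 0L) 0 else sort(junctionPvalues)[k]
  list(p = p, p_prime = p_prime, f = f, k = k)
}
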