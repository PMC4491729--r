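# Stage 1: putatively constitutive exon selection and the gene
# expression index computed from the selected exons.

.foldChanges <- function(m, condition) {
  conds <- sort(unique(condition))
  if (length(conds) != 2L)
    stop("fold changes require exactly two conditions")
  a <- which(condition == conds[1L])
  b <- which(condition == conds[2L])
  if (!length(a) || !length(b)) stop("condition with zero samples")
  rowMeans(m[, b, drop = FALSE]) - rowMeans(m[, a, drop = FALSE])
}

#' Between-condition log2 fold changes
#'
#' Per-row difference of condition means, second condition minus first
#' in lexicographic order of the condition labels (override by passing a
#' factor-ordered character vector is not supported; relabel instead).
#'
#' @param m numeric matrix (rows x samples), log2 scale.
#' @param condition named character vector mapping sample id to
#'   condition, or a design `data.frame`.
#' @return named numeric vector of log2 fold changes.
#' @export
foldChanges <- function(m, condition) {
  if (is.data.frame(condition))
    condition <- setNames(condition$condition, condition$sample_id)
  if (!is.null(colnames(m))) {
    miss <- setdiff(colnames(m), names(condition))
    if (length(miss))
      stop("samples missing from the design: ", paste(miss, collapse = ", "))
    condition <- condition[colnames(m)]
  }
  .foldChanges(m, as.character(condition))
}

#' Iterative selection of putatively constitutive exons for one gene
#'
#' Exons absent in either condition are labeled `absent`. Among the
#' remaining exons the mean `m` and sample standard deviation `s` of the
#' log2 fold changes are computed, exons with fold change strictly
#' outside `[m - d*s, m + d*s]` are flagged as outliers (the boundary is
#' inclusive, so identical fold changes with `s = 0` are all kept), and
#' the process repeats on the retained exons until no new exon is
#' flagged. Removal is monotone: a flagged exon is never re-admitted,
#' which guarantees termination in at most one iteration per exon.
#'
#' @param fc named numeric vector of exon log2 fold changes (names are
#'   exon probeset ids or indices).
#' @param presentBoth logical vector parallel to `fc`: present in both
#'   conditions (see [groupDabg()]). Default: all present.
#' @param d outlier sensitivity; fold changes farther than `d` standard
#'   deviations from the mean are trimmed (default 2).
#' @param maxIterations safety cap (default: number of exons).
#' @return list with `label` (per exon: `constitutive`, `absent` or
#'   `outlier`), `m`, `s`, `n_iterations` and `fallback` (`TRUE` when no
#'   exon was retained).
#' @examples
#' fc <- c(rep(0, 9), 3)
#' selectConstitutiveExons(fc, d = 2)  # 9 constitutive, 1 outlier
#' @export
selectConstitutiveExons <- function(fc, presentBoth = NULL, d = 2,
                                    maxIterations = length(fc)) {
  if (!length(fc)) stop("gene has no exons")
  if (d <= 0) stop("'d' must be positive")
  if (is.null(presentBoth)) presentBoth <- rep(TRUE, length(fc))
  label <- ifelse(presentBoth, NA_character_, "absent")
  retained <- which(presentBoth)
  if (!length(retained))
    return(list(label = setNames(label, names(fc)), m = NA_real_,
                s = NA_real_, n_iterations = 0L, fallback = TRUE))
  m <- s <- NA_real_
  it <- 0L
  repeat {
    it <- it + 1L
    m <- mean(fc[retained])
    s <- if (length(retained) > 1L) sd(fc[retained]) else 0
    out <- retained[fc[retained] < m - d * s | fc[retained] > m + d * s]
    if (!length(out) || it >= maxIterations) break
    label[out] <- "outlier"
    retained <- setdiff(retained, out)
    if (!length(retained)) break
  }
  label[retained] <- "constitutive"
  if (length(retained)) {
    m <- mean(fc[retained])
    s <- if (length(retained) > 1L) sd(fc[retained]) else 0
  } else {
    m <- s <- NA_real_
  }
  list(label = setNames(label, names(fc)), m = m, s = s,
       n_iterations = it, fallback = length(retained) == 0L)
}

#' Constitutive/absent/outlier partition for every gene
#'
#' Applies [selectConstitutiveExons()] gene by gene using exon fold
#' changes and group DABG presence calls.
#'
#' @param exonExprs numeric matrix of exon probeset indices (rows named
#'   by probeset id).
#' @param annotation validated design annotation (see
#'   [readAnnotation()]).
#' @param condition named sample-to-condition vector or design
#'   `data.frame`.
#' @param presence result of [groupDabg()], or `NULL` to treat every
#'   exon as present.
#' @param d outlier sensitivity (default 2).
#' @return list with `exons` (`data.frame`: `probeset_id`, `gene_id`,
#'   `exon_index`, `fc`, `label`, `present_A`, `present_B`) and `genes`
#'   (`data.frame`: `gene_id`, `m`, `s`, `n_iterations`,
#'   `n_constitutive`, `fallback`).
#' @export
constitutivePartition <- function(exonExprs, annotation, condition,
                                  presence = NULL, d = 2) {
  ann <- annotation[annotation$kind == "exon", , drop = FALSE]
  ann <- ann[ann$probeset_id %in% rownames(exonExprs), , drop = FALSE]
  if (!nrow(ann)) stop("no exon probesets found in the expression matrix")
  fc <- foldChanges(exonExprs[ann$probeset_id, , drop = FALSE], condition)
  if (is.null(presence)) {
    presA <- presB <- rep(TRUE, nrow(ann))
  } else {
    pm <- presence$present[ann$probeset_id, , drop = FALSE]
    presA <- pm[, 1L]
    presB <- pm[, 2L]
  }
  presBoth <- presA & presB
  genes <- unique(ann$gene_id)
  exonRows <- split(seq_len(nrow(ann)), factor(ann$gene_id, levels = genes))
  labels <- character(nrow(ann))
  gsum <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    rows <- exonRows[[i]]
    sel <- selectConstitutiveExons(setNames(fc[rows], ann$probeset_id[rows]),
                                   presBoth[rows], d = d)
    labels[rows] <- sel$label
    gsum[[i]] <- data.frame(
      gene_id = genes[i], m = sel$m, s = sel$s,
      n_iterations = sel$n_iterations,
      n_constitutive = sum(sel$label == "constitutive"),
      fallback = sel$fallback, stringsAsFactors = FALSE)
  }
  list(
    exons = data.frame(probeset_id = ann$probeset_id, gene_id = ann$gene_id,
                       exon_index = ann$exon_index, fc = unname(fc),
                       label = labels, present_A = presA, present_B = presB,
                       stringsAsFactors = FALSE),
    genes = do.call(rbind, gsum)
  )
}

#' Gene expression index from the selected exons
#'
#' Summarizes each gene's expression per sample from its putatively
#' constitutive exons. With probeset-level input the constitutive exon
#' index rows are median-polished; when probe-level data are supplied
#' (`probes` + `probeMap`) the pooled probes of the constitutive exons
#' are median-polished instead. Genes with fewer than `minConstitutive`
#' constitutive exons fall back to all exons present in both conditions
#' (and are flagged); genes with no present exon are excluded.
#'
#' @param exonExprs exon probeset index matrix.
#' @param partition result of [constitutivePartition()].
#' @param minConstitutive minimum number of constitutive exons before
#'   the all-present-exon fallback engages (default 1).
#' @param probes,probeMap optional probe-level matrix and probe map; when
#'   given, gene indices are polished from pooled probes.
#' @return list with `values` (genes x samples matrix), `sourceExons`
#'   (named list of exon probesets used per gene), `fallback` (named
#'   logical) and `excluded` (gene ids with no usable exon).
#' @export
geneExpressionIndex <- function(exonExprs, partition, minConstitutive = 1L,
                                probes = NULL, probeMap = NULL) {
  exdf <- partition$exons
  genes <- unique(exdf$gene_id)
  sourceExons <- vector("list", length(genes))
  names(sourceExons) <- genes
  fallback <- setNames(logical(length(genes)), genes)
  excluded <- character(0)
  vals <- vector("list", length(genes))
  useProbes <- !is.null(probes) && !is.null(probeMap)
  if (useProbes)
    psOfProbe <- setNames(probeMap$probeset_id, probeMap$probe_id)
  for (i in seq_along(genes)) {
    rows <- exdf[exdf$gene_id == genes[i], , drop = FALSE]
    cons <- rows$probeset_id[rows$label == "constitutive"]
    if (length(cons) >= minConstitutive) {
      src <- cons
    } else {
      src <- rows$probeset_id[rows$present_A & rows$present_B]
      fallback[i] <- TRUE
      if (!length(src)) {
        excluded <- c(excluded, genes[i])
        sourceExons[[i]] <- character(0)
        next
      }
    }
    sourceExons[[i]] <- src
    if (useProbes) {
      pr <- probes[psOfProbe[rownames(probes)] %in% src, , drop = FALSE]
      vals[[i]] <- if (nrow(pr) == 1L) pr[1L, ] else medianPolish(pr)$index
    } else {
      block <- exonExprs[src, , drop = FALSE]
      vals[[i]] <- if (nrow(block) == 1L) block[1L, ] else
        medianPolish(block)$index
    }
  }
  keep <- setdiff(genes, excluded)
  if (length(keep)) {
    values <- do.call(rbind, vals[match(keep, genes)])
    rownames(values) <- keep
  } else {
    values <- matrix(numeric(0), nrow = 0L, ncol = ncol(exonExprs),
                     dimnames = list(NULL, colnames(exonExprs)))
  }
  list(values = values, sourceExons = sourceExons,
       fallback = fallback, excluded = excluded)
}
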