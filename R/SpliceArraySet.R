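#' Construct a SpliceArraySet
#'
#' Bundles a probeset-level log2 expression matrix, the exon/junction
#' design annotation, the sample-to-condition design and (optionally) a
#' matrix of per-sample DABG p-values into one validated container.
#'
#' DABG p-values are clamped to `[1e-16, 1]` on ingest so geometric means
#' are always defined.
#'
#' @param exprs numeric matrix, probesets x samples, log2 expression
#'   indices; rownames are probeset ids, colnames sample ids.
#' @param annotation `data.frame` with columns `probeset_id`, `gene_id`,
#'   `kind` (`"exon"`/`"junction"`), `exon_index`, `exon5`, `exon3`,
#'   `n_probes`; must cover every row of `exprs`.
#' @param design `data.frame` with columns `sample_id` and `condition`;
#'   every column of `exprs` must appear exactly once, and there must be
#'   exactly two conditions (comparisons are pairwise).
#' @param dabg optional numeric matrix of DABG p-values with the same
#'   dimnames as `exprs`.
#' @return a [SpliceArraySet-class] object.
#' @seealso [runRasa()], [simulateSpliceArray()]
#' @export
SpliceArraySet <- function(exprs, annotation, design, dabg = NULL) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("'exprs' must be a numeric matrix")
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("'exprs' must have probeset rownames and sample colnames")
  annotation <- .checkAnnotation(annotation)
  design <- .checkDesign(design, colnames(exprs))

  miss <- setdiff(rownames(exprs), annotation$probeset_id)
  if (length(miss))
    stop("probesets missing from annotation: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
  ann <- annotation[match(rownames(exprs), annotation$probeset_id), ,
                    drop = FALSE]
  rownames(ann) <- ann$probeset_id

  assays <- list(exprs = exprs)
  if (!is.null(dabg)) {
    if (!identical(dim(dabg), dim(exprs)))
      stop("'dabg' must have the same dimensions as 'exprs'")
    dabg <- dabg[rownames(exprs), colnames(exprs), drop = FALSE]
    if (any(!is.finite(dabg)) || any(dabg < 0) || any(dabg > 1))
      stop("'dabg' values must lie in [0, 1]")
    assays$dabg <- pmin(pmax(dabg, 1e-16), 1)
  }
  cd <- DataFrame(condition = design$condition[match(colnames(exprs),
                                                     design$sample_id)],
                  row.names = colnames(exprs))
  se <- SummarizedExperiment(assays = assays, rowData = DataFrame(ann),
                             colData = cd)
  new("SpliceArraySet", se)
}

.checkDesign <- function(design, sampleIds = NULL) {
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% colnames(design)))
    stop("design needs columns 'sample_id' and 'condition'")
  design$sample_id <- as.character(design$sample_id)
  design$condition <- as.character(design$condition)
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "))
  conds <- sort(unique(design$condition))
  if (length(conds) != 2L)
    stop("runs are pairwise: the design must have exactly two conditions, ",
         "found ", length(conds), " (", paste(conds, collapse = ", "), ")")
  if (!is.null(sampleIds)) {
    miss <- setdiff(sampleIds, design$sample_id)
    if (length(miss))
      stop("samples present in the matrix but missing from the design: ",
           paste(miss, collapse = ", "))
  }
  design
}

#' Accessors for SpliceArraySet
#'
#' `expressionIndex()` returns the log2 expression matrix,
#' `dabgMatrix()` the DABG p-value matrix (or `NULL`),
#' `sampleConditions()` a named character vector mapping sample id to
#' condition, `annotationTable()` the full design annotation and
#' `exonAnnotation()`/`junctionAnnotation()` its two kinds of rows.
#'
#' @param x a [SpliceArraySet-class].
#' @name SpliceArraySet-accessors
NULL

#' @rdname SpliceArraySet-accessors
#' @export
setMethod("expressionIndex", "SpliceArraySet", function(x) assay(x, "exprs"))

#' @rdname SpliceArraySet-accessors
#' @export
setMethod("dabgMatrix", "SpliceArraySet", function(x) {
  if ("dabg" %in% assayNames(x)) assay(x, "dabg") else NULL
})

#' @rdname SpliceArraySet-accessors
#' @export
setMethod("sampleConditions", "SpliceArraySet", function(x)
  setNames(as.character(colData(x)$condition), colnames(x)))

#' @rdname SpliceArraySet-accessors
#' @export
setMethod("annotationTable", "SpliceArraySet", function(x) {
  df <- as.data.frame(rowData(x))
  rownames(df) <- df$probeset_id
  df
})

#' @rdname SpliceArraySet-accessors
#' @export
setMethod("exonAnnotation", "SpliceArraySet", function(x) {
  df <- annotationTable(x)
  df[df$kind == "exon", , drop = FALSE]
})

#' @rdname SpliceArraySet-accessors
#' @export
setMethod("junctionAnnotation", "SpliceArraySet", function(x) {
  df <- annotationTable(x)
  df[df$kind == "junction", , drop = FALSE]
})

setMethod("show", "SpliceArraySet", function(object) {
  ann <- annotationTable(object)
  cond <- table(sampleConditions(object))
  cat("SpliceArraySet:", sum(ann$kind == "exon"), "exon and",
      sum(ann$kind == "junction"), "junction probesets,",
      length(unique(ann$gene_id)), "genes\n")
  cat("  samples:", paste(sprintf("%s (%d)", names(cond), cond),
                          collapse = ", "), "\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})
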