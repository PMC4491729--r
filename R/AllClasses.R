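#' SpliceArraySet: probeset-level expression on an exon-junction array
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding log2
#' probeset expression indices (`assay "exprs"`), an optional matrix of
#' per-sample detection-above-background (DABG) p-values (`assay "dabg"`),
#' the exon/junction design annotation as `rowData`, and the sample to
#' condition design as `colData` (column `condition`).
#'
#' Row annotation columns are `probeset_id`, `gene_id`, `kind`
#' (`"exon"` or `"junction"`), `exon_index` (1-based ordinal position of
#' exon probesets along the gene, 5' to 3'), `exon5`/`exon3` (the exon
#' indices a junction connects, `exon5 < exon3`) and `n_probes`. A
#' junction is an *inclusion* junction for exon `e` when `exon5 == e` or
#' `exon3 == e`, and an *exclusion* junction for `e` when
#' `exon5 < e < exon3`.
#'
#' @slot .  See [SummarizedExperiment::SummarizedExperiment].
#' @seealso [SpliceArraySet()] for the validating constructor.
#' @export
setClass("SpliceArraySet", contains = "SummarizedExperiment")

#' SplicingCalls: results of an alternative-splicing run
#'
#' Holds the per-exon call table, the junction statistics table, the
#' per-gene constitutive-selection summary, the gene expression index and
#' the thresholds/report of a [runRasa()] run.
#'
#' Exon categories are `junction_supported` (significant exon with at
#' least one significant, direction-consistent junction),
#' `unreliable_junction_candidate` (significant exon whose exon-junction
#' fold-change difference exceeds the empirical-null cutoff),
#' `exon_only_not_called`, `not_significant` and `absent` (below the
#' presence threshold in both conditions).
#'
#' @slot calls per-exon `data.frame`: `gene_id`, `probeset_id`,
#'   `exon_index`, `category`, `p_value`, `si`, `supporting_junctions`
#'   (comma-joined ids), `best_junction_id`, `fc_difference`,
#'   `presence_flag` (exon absent in exactly one condition).
#' @slot junctions per-junction `data.frame` with `p_value`, `si` and the
#'   significance flag at the adjusted threshold.
#' @slot genes per-gene `data.frame` with the trimming summary (`m`, `s`,
#'   `n_iterations`, `n_constitutive`, `fallback`).
#' @slot geneIndex numeric matrix of per-sample gene expression indices
#'   (genes x samples, log2).
#' @slot thresholds list with `p`, `p_prime`, `f`, `q`, `cutoff`,
#'   `null_size`, `step3_enabled` and bookkeeping counts.
#' @export
setClass("SplicingCalls",
  slots = c(
    calls      = "data.frame",
    junctions  = "data.frame",
    genes      = "data.frame",
    geneIndex  = "matrix",
    thresholds = "list"
  )
)

.CALL_CATEGORIES <- c("junction_supported", "unreliable_junction_candidate",
                      "exon_only_not_called", "not_significant", "absent")

setValidity("SpliceArraySet", function(object) {
  msg <- character(0)
  if (!"exprs" %in% assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    ex <- assay(object, "exprs")
    if (!is.numeric(ex) || any(!is.finite(ex)))
      msg <- c(msg, "assay 'exprs' must be finite numeric")
  }
  if ("dabg" %in% assayNames(object)) {
    dp <- assay(object, "dabg")
    if (any(!is.finite(dp)) || any(dp < 0) || any(dp > 1))
      msg <- c(msg, "assay 'dabg' must lie in [0, 1]")
  }
  rd <- as.data.frame(rowData(object))
  need <- c("probeset_id", "gene_id", "kind", "exon_index", "exon5",
            "exon3", "n_probes")
  if (!all(need %in% colnames(rd))) {
    msg <- c(msg, paste0("rowData must contain columns: ",
                         paste(need, collapse = ", ")))
  } else {
    ann <- try(.checkAnnotation(rd), silent = TRUE)
    if (inherits(ann, "try-error"))
      msg <- c(msg, paste("invalid annotation:",
                          conditionMessage(attr(ann, "condition"))))
  }
  if (!"condition" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'condition' column")
  if (length(msg)) msg else TRUE
})

setValidity("SplicingCalls", function(object) {
  msg <- character(0)
  bad <- setdiff(unique(object@calls$category), .CALL_CATEGORIES)
  if (length(bad))
    msg <- c(msg, paste("unknown call categories:", paste(bad, collapse = ", ")))
  pv <- object@calls$p_value
  if (any(pv < 0 | pv > 1, na.rm = TRUE))
    msg <- c(msg, "p_value outside [0, 1]")
  if (length(msg)) msg else TRUE
})
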