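#' Accessors for SplicingCalls
#'
#' `callTable()` returns the per-exon call table, `junctionStats()` the
#' junction-level statistics, `geneSummary()` the per-gene
#' constitutive-selection summary, `geneIndex()` the gene expression
#' index matrix and `callThresholds()` the thresholds and run report.
#'
#' @param x a [SplicingCalls-class].
#' @name SplicingCalls-accessors
NULL

#' @rdname SplicingCalls-accessors
#' @export
setMethod("callTable", "SplicingCalls", function(x) x@calls)

#' @rdname SplicingCalls-accessors
#' @export
setMethod("junctionStats", "SplicingCalls", function(x) x@junctions)

#' @rdname SplicingCalls-accessors
#' @export
setMethod("geneSummary", "SplicingCalls", function(x) x@genes)

#' @rdname SplicingCalls-accessors
#' @export
setMethod("geneIndex", "SplicingCalls", function(x) x@geneIndex)

#' @rdname SplicingCalls-accessors
#' @export
setMethod("callThresholds", "SplicingCalls", function(x) x@thresholds)

setMethod("show", "SplicingCalls", function(object) {
  th <- object@thresholds
  counts <- table(factor(object@calls$category, levels = .CALL_CATEGORIES))
  cat("SplicingCalls:", nrow(object@calls), "exons across",
      nrow(object@genes), "genes\n")
  for (nm in names(counts))
    cat(sprintf("  %-30s %d\n", nm, counts[[nm]]))
  cat(sprintf("  p = %g, p' = %g (f = %.4f)\n", th$p, th$p_prime, th$f))
  if (isTRUE(th$step3_enabled))
    cat(sprintf("  null cutoff = %.4f (q = %g, null size = %d)\n",
                th$cutoff, th$q, th$null_size))
  else
    cat("  unreliable-junction rescue disabled (null too small)\n")
})
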