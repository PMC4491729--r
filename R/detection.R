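# Stages 2-3: junction-supported calling, empirical-null rescue of
# exons with unreliable junctions, classification, orchestration.

#' Junctions supporting a significant exon
#'
#' A junction supports the exon when it is significant at the adjusted
#' threshold `pPrime` and changes in a consistent direction: inclusion
#' junctions (one endpoint at the exon) must share the exon's splicing
#' direction, exclusion junctions (spanning across the exon) must change
#' in the opposite direction. Probesets with splicing index exactly 0
#' have no direction and can neither support nor be supported.
#'
#' @param exonId exon probeset id.
#' @param stats `data.frame` with columns `probeset_id`, `p_value`,
#'   `si` covering at least the exon and its junctions.
#' @param p exon significance threshold (the exon itself must satisfy
#'   `p_value <= p`; checked).
#' @param pPrime adjusted junction threshold (see
#'   [adjustJunctionThreshold()]).
#' @param annotation design annotation `data.frame` or [SpliceArraySet].
#' @return `data.frame` of supporting junctions with columns
#'   `junction_id` and `support_type` (`"inclusion"`/`"exclusion"`);
#'   zero rows when unsupported (such exons route to the
#'   unreliable-junction stage).
#' @export
findSupportingJunctions <- function(exonId, stats, p, pPrime, annotation) {
  if (is(annotation, "SpliceArraySet"))
    annotation <- annotationTable(annotation)
  row <- stats[stats$probeset_id == exonId, , drop = FALSE]
  if (nrow(row) != 1L) stop("exon not found in stats: ", exonId)
  ann <- annotation[annotation$probeset_id == exonId, , drop = FALSE]
  if (nrow(ann) != 1L || ann$kind != "exon")
    stop("not an exon probeset: ", exonId)
  empty <- data.frame(junction_id = character(0),
                      support_type = character(0), stringsAsFactors = FALSE)
  exSign <- sign(row$si)
  if (is.na(row$p_value) || row$p_value > p || is.na(exSign) || exSign == 0)
    return(empty)
  jn <- junctionsForExon(annotation, ann$gene_id, ann$exon_index)
  .sig <- function(ids, wantSign) {
    st <- stats[match(ids, stats$probeset_id), , drop = FALSE]
    ids[!is.na(st$p_value) & st$p_value <= pPrime &
          !is.na(st$si) & sign(st$si) == wantSign & st$si != 0]
  }
  inc <- .sig(jn$inclusion, exSign)
  exc <- .sig(jn$exclusion, -exSign)
  rbind(
    data.frame(junction_id = inc, support_type = rep("inclusion", length(inc)),
               stringsAsFactors = FALSE),
    data.frame(junction_id = exc, support_type = rep("exclusion", length(exc)),
               stringsAsFactors = FALSE)
  )
}

#' Best-junction fold-change difference for an exon
#'
#' The best junction is the one with the largest absolute splicing index
#' among the exon's junctions changing in the same direction as the
#' exon. The fold-change difference is `|exon si| - |best junction si|`;
#' when no junction changes in the same direction the junction change is
#' truncated to 0 and the difference is `|exon si|`. A negative
#' difference means the junction responds more strongly than the exon.
#'
#' @param exonSi nonzero splicing index of the exon.
#' @param junctionSis named numeric vector of the exon's junction
#'   splicing indices (names are junction ids); may be empty.
#' @return list with `best_junction_id` (`NA` for the truncation case)
#'   and `fc_difference`.
#' @export
bestJunctionDifference <- function(exonSi, junctionSis) {
  if (is.na(exonSi) || exonSi == 0)
    stop("'exonSi' must be a nonzero splicing index")
  junctionSis <- junctionSis[!is.na(junctionSis)]
  same <- junctionSis[sign(junctionSis) == sign(exonSi)]
  if (!length(same))
    return(list(best_junction_id = NA_character_,
                fc_difference = abs(exonSi)))
  best <- which.max(abs(same))
  list(best_junction_id = names(same)[best],
       fc_difference = abs(exonSi) - abs(same[[best]]))
}

#' Empirical-null cutoff for unreliable-junction detection
#'
#' The null sample is the set of fold-change differences of exons that
#' were supported by significant junctions (exon and junction both
#' behaving properly). The cutoff is the top-`q` quantile of this null,
#' taken as the k-th smallest value with `k = ceiling((1 - q) * N)`.
#' Exons whose difference is strictly greater than the cutoff are
#' declared to have unreliable junctions (ties fall inside the null).
#' With fewer than `minNullSize` values the stage is disabled (with a
#' warning) because the quantile would be meaningless.
#'
#' @param nullDiffs numeric vector of fold-change differences from
#'   supported exons.
#' @param q quantile level (default 0.05).
#' @param minNullSize minimum null size before the stage activates
#'   (default 20).
#' @return list with `cutoff`, `q`, `null_size` and `enabled`.
#' @export
estimateNullThreshold <- function(nullDiffs, q = 0.05, minNullSize = 20L) {
  if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
  nullDiffs <- nullDiffs[!is.na(nullDiffs)]
  n <- length(nullDiffs)
  if (n < minNullSize) {
    warning("null sample too small (", n, " < ", minNullSize,
            "); unreliable-junction detection disabled")
    return(list(cutoff = NA_real_, q = q, null_size = n, enabled = FALSE))
  }
  k <- max(1L, as.integer(ceiling((1 - q) * n)))
  list(cutoff = sort(nullDiffs)[k], q = q, null_size = n, enabled = TRUE)
}

#' Final category per exon
#'
#' Assigns each testable exon exactly one category: `absent` (below the
#' presence threshold in both conditions), `not_significant`,
#' `junction_supported` (significant with at least one supporting
#' junction), `unreliable_junction_candidate` (significant, unsupported,
#' fold-change difference strictly above the null cutoff) or
#' `exon_only_not_called` (significant, unsupported, at or below the
#' cutoff, or the rescue stage disabled).
#'
#' @param exonTable `data.frame` with columns `p_value`, `n_support`,
#'   `fc_difference` and `absent_both` (logical).
#' @param p exon significance threshold.
#' @param nullThreshold result of [estimateNullThreshold()].
#' @return character vector of categories, parallel to `exonTable`.
#' @export
classifyExons <- function(exonTable, p, nullThreshold) {
  sig <- !is.na(exonTable$p_value) & exonTable$p_value <= p
  cat <- rep("not_significant", nrow(exonTable))
  cat[sig & exonTable$n_support > 0L] <- "junction_supported"
  rescue <- sig & exonTable$n_support == 0L
  if (isTRUE(nullThreshold$enabled)) {
    over <- rescue & !is.na(exonTable$fc_difference) &
      exonTable$fc_difference > nullThreshold$cutoff
    cat[over] <- "unreliable_junction_candidate"
    cat[rescue & !over] <- "exon_only_not_called"
  } else {
    cat[rescue] <- "exon_only_not_called"
  }
  cat[exonTable$absent_both] <- "absent"
  cat
}

#' Run the full splicing-detection workflow
#'
#' Orchestrates the three stages on a probeset-level
#' [SpliceArraySet-class]: group DABG presence calls, iterative
#' constitutive-exon selection and gene index calculation, MIDAS-style
#' testing of exons and junctions with the quantile-mapped junction
#' threshold, junction-supported calling, and empirical-null rescue of
#' significant exons whose junctions are unreliable. Deterministic:
#' identical inputs and parameters give identical output.
#'
#' Exons absent in both conditions are categorized `absent` and excluded
#' from testing; exons absent in exactly one condition are tested
#' normally (presence-based splicing) and flagged with `presence_flag`.
#' Exons of genes with no usable expression index are untestable and are
#' omitted from the call table (counted in the thresholds report).
#'
#' @param x a [SpliceArraySet-class] (assays `exprs` and optionally
#'   `dabg`).
#' @param p exon significance threshold (default 0.01).
#' @param d outlier sensitivity of the constitutive selection
#'   (default 2).
#' @param q quantile level of the unreliable-junction null
#'   (default 0.05).
#' @param presenceThreshold group DABG presence threshold
#'   (default 0.01).
#' @param minNullSize minimum null size for the rescue stage
#'   (default 20).
#' @param minConstitutive minimum constitutive exons before the gene
#'   index falls back to all present exons (default 1).
#' @param probes,probeMap optional probe-level matrix and map; when
#'   supplied the gene index is polished from pooled probes of the
#'   selected exons.
#' @return a [SplicingCalls-class] object.
#' @export
runRasa <- function(x, p = 0.01, d = 2, q = 0.05, presenceThreshold = 0.01,
                    minNullSize = 20L, minConstitutive = 1L,
                    probes = NULL, probeMap = NULL) {
  stopifnot(is(x, "SpliceArraySet"))
  ann <- annotationTable(x)
  cond <- sampleConditions(x)
  if (length(unique(cond)) != 2L)
    stop("stage design: exactly two conditions are required")
  ex <- expressionIndex(x)
  dp <- dabgMatrix(x)
  presence <- if (is.null(dp)) NULL else
    groupDabg(dp, cond, threshold = presenceThreshold)

  # stage 1: constitutive selection and gene index
  exonIds <- ann$probeset_id[ann$kind == "exon"]
  part <- constitutivePartition(ex[exonIds, , drop = FALSE], ann, cond,
                                presence = presence, d = d)
  gi <- geneExpressionIndex(ex[exonIds, , drop = FALSE], part,
                            minConstitutive = minConstitutive,
                            probes = probes, probeMap = probeMap)

  # stage 2 statistics on gene-normalized values
  geneOf <- setNames(ann$gene_id, ann$probeset_id)
  testable <- ann$probeset_id[geneOf %in% rownames(gi$values)]
  gvals <- gi$values[geneOf[testable], , drop = FALSE]
  nv <- ex[testable, colnames(gi$values), drop = FALSE] - gvals
  pvals <- setNames(.rowAnovaP(nv, cond[colnames(gi$values)]), testable)
  siTab <- splicingIndex(ex[testable, , drop = FALSE], gi$values,
                         geneOf, cond)
  si <- setNames(siTab$si, siTab$probeset_id)

  exdf <- part$exons
  exdf <- exdf[exdf$probeset_id %in% testable, , drop = FALSE]
  exdf$absent_both <- !exdf$present_A & !exdf$present_B
  exdf$p_value <- pvals[exdf$probeset_id]
  exdf$si <- si[exdf$probeset_id]
  exdf$p_value[exdf$absent_both] <- NA_real_
  exdf$si[exdf$absent_both] <- NA_real_

  juncIds <- intersect(ann$probeset_id[ann$kind == "junction"], testable)
  jdf <- data.frame(probeset_id = juncIds,
                    gene_id = unname(geneOf[juncIds]),
                    exon5 = ann[juncIds, "exon5"],
                    exon3 = ann[juncIds, "exon3"],
                    p_value = unname(pvals[juncIds]),
                    si = unname(si[juncIds]),
                    stringsAsFactors = FALSE)

  thr <- adjustJunctionThreshold(exdf$p_value[!exdf$absent_both],
                                 jdf$p_value, p = p)
  jdf$significant <- !is.na(jdf$p_value) & jdf$p_value <= thr$p_prime

  # stage 2: junction support; stage 3: best-junction differences
  stats <- data.frame(probeset_id = c(exdf$probeset_id, jdf$probeset_id),
                      p_value = c(exdf$p_value, jdf$p_value),
                      si = c(exdf$si, jdf$si), stringsAsFactors = FALSE)
  n <- nrow(exdf)
  nSupport <- integer(n)
  supportIds <- character(n)
  bestId <- rep(NA_character_, n)
  fcDiff <- rep(NA_real_, n)
  sig <- !exdf$absent_both & !is.na(exdf$p_value) & exdf$p_value <= p &
    !is.na(exdf$si) & exdf$si != 0
  jsi <- setNames(jdf$si, jdf$probeset_id)
  for (i in which(sig)) {
    sup <- findSupportingJunctions(exdf$probeset_id[i], stats, p,
                                   thr$p_prime, ann)
    nSupport[i] <- nrow(sup)
    supportIds[i] <- paste(sup$junction_id, collapse = ",")
    jn <- junctionsForExon(ann, exdf$gene_id[i], exdf$exon_index[i])
    allj <- c(jn$inclusion, jn$exclusion)
    bd <- bestJunctionDifference(exdf$si[i],
                                 jsi[intersect(allj, names(jsi))])
    bestId[i] <- bd$best_junction_id
    fcDiff[i] <- bd$fc_difference
  }
  exdf$n_support <- nSupport
  exdf$supporting_junctions <- supportIds
  exdf$best_junction_id <- bestId
  exdf$fc_difference <- fcDiff

  nullDiffs <- fcDiff[sig & nSupport > 0L]
  nt <- withCallingHandlers(
    estimateNullThreshold(nullDiffs, q = q, minNullSize = minNullSize),
    warning = function(w) {
      message("unreliable-junction stage: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  exdf$category <- classifyExons(exdf, p, nt)
  exdf$presence_flag <- xor(exdf$present_A, exdf$present_B)

  calls <- exdf[order(exdf$gene_id, exdf$exon_index),
                .CALL_COLUMNS, drop = FALSE]
  rownames(calls) <- NULL
  counts <- table(factor(calls$category, levels = .CALL_CATEGORIES))
  thresholds <- list(
    p = p, p_prime = thr$p_prime, f = thr$f, q = q,
    cutoff = nt$cutoff, null_size = nt$null_size,
    step3_enabled = nt$enabled, d = d,
    presence_threshold = presenceThreshold,
    n_untestable_exons = sum(ann$kind == "exon") -
      sum(exdf$probeset_id %in% ann$probeset_id),
    category_counts = as.list(counts))
  new("SplicingCalls", calls = calls, junctions = jdf, genes = part$genes,
      geneIndex = gi$values, thresholds = thresholds)
}

#' Run the workflow from a YAML configuration of file paths
#'
#' Reads the inputs named in the configuration (either a probeset-level
#' matrix `exprs`, or probe-level `probes` + `probe_map` which are
#' median-scaled and summarized first), runs [runRasa()] and writes
#' `calls.tsv`, `gene_index.tsv`, `partition.tsv` and `report.yaml` to
#' `outdir`. Running twice on identical inputs produces byte-identical
#' outputs.
#'
#' @param config path to a YAML file or a configuration list (see
#'   [readRasaConfig()]).
#' @param outdir output directory (created if needed).
#' @return the [SplicingCalls-class] object, invisibly.
#' @export
runRasaFiles <- function(config, outdir) {
  if (is.character(config)) config <- readRasaConfig(config)
  ann <- readAnnotation(config$annotation)
  design <- readSampleDesign(config$design)
  dabg <- if (!is.null(config$dabg)) readDabgMatrix(config$dabg) else NULL
  probes <- probeMap <- NULL
  if (!is.null(config$exprs)) {
    exprs <- readExpressionMatrix(config$exprs, "probeset")
  } else if (!is.null(config$probes) && !is.null(config$probe_map)) {
    probes <- readExpressionMatrix(config$probes, "probe")
    probeMap <- readProbeMap(config$probe_map)
    probes <- medianScaleNormalize(probes)
    exprs <- summarizeProbesets(probes, probeMap)
  } else {
    stop("config must name either 'exprs' or 'probes' + 'probe_map'")
  }
  sas <- SpliceArraySet(exprs, ann, design, dabg = dabg)
  res <- runRasa(sas, p = config$p, d = config$d, q = config$q,
                 presenceThreshold = config$presence_threshold,
                 minNullSize = config$min_null_size,
                 minConstitutive = config$min_constitutive,
                 probes = probes, probeMap = probeMap)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeSplicingCalls(res, file.path(outdir, "calls.tsv"))
  writeTsvMatrix(geneIndex(res), file.path(outdir, "gene_index.tsv"),
                 idColumn = "gene_id")
  part <- geneSummary(res)
  write.table(part, file.path(outdir, "partition.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  th <- callThresholds(res)
  th$category_counts <- lapply(th$category_counts, as.integer)
  yaml::write_yaml(th, file.path(outdir, "report.yaml"))
  invisible(res)
}
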