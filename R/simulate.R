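# Synthetic exon-junction array data with known ground truth.
#
# Genes are linear chains of exons with adjacent junctions (i, i+1);
# each planted spliced internal exon e additionally gets the skip
# junction (e-1, e+1) that an exon-skipping isoform would produce.
# Probe-level log2 values are gene abundance + probeset offset +
# splicing shift (condition B only) + probe affinity + noise. Junction
# probesets are fewer-probed and noisier than exon probesets, failed
# junction probesets and absent exons sit flat at the background level,
# and DABG p-values follow a seeded logistic model of
# signal-above-background.

#' Simulation parameters
#'
#' Builds and validates the parameter list for
#' [simulateSpliceArray()]. The defaults emulate a small two-tissue
#' array study: 200 genes of 10 exons, three replicates per condition,
#' 5% of internal exons spliced with a log2 splicing-index magnitude of
#' 2, 8 probes per exon probeset and 4 per junction probeset, with
#' junction probes noisier than exon probes.
#'
#' @param nGenes number of genes (default 200).
#' @param exonsPerGene exons per gene (default 10; minimum 3 so internal
#'   exons exist).
#' @param nReplicates samples per condition (default 3).
#' @param fracSplicedExons fraction of eligible internal exons planted
#'   as spliced (default 0.05); the planted count is
#'   `round(frac * n_eligible)`.
#' @param splicingEffect log2 splicing-index magnitude of planted events
#'   (default 2).
#' @param geneFcSd sd of the between-condition gene-level log2 fold
#'   change (default 0.5).
#' @param baseMean,baseSd mean and sd of baseline gene abundance (log2;
#'   defaults 8 and 1).
#' @param exonNoiseSd,junctionNoiseSd per-measurement log2 noise for
#'   exon and junction probes (defaults 0.25 and 0.4).
#' @param probeAffinitySd sd of per-probe affinity offsets
#'   (default 0.3).
#' @param unitOffsetSd sd of per-probeset baseline offsets
#'   (default 0.3).
#' @param junctionFailureRate fraction of junction probesets emitting
#'   flat background signal, sampled independently (default 0).
#' @param failedExonFraction fraction of planted spliced exons whose
#'   junction probesets are *all* failed (default 0); models the
#'   junctions of a region failing together, the scenario the
#'   unreliable-junction rescue stage exists for.
#' @param fracAbsentExons fraction of (non-spliced) exons absent in both
#'   conditions (default 0.05).
#' @param probesPerExon,probesPerJunction probes per probeset (defaults
#'   8 and 4).
#' @param background log2 background level (default 4).
#' @param dabgSlope,dabgNoiseSd slope and logit-scale noise of the DABG
#'   generative model (defaults 1.5 and 0.5).
#' @param conditions two condition labels (default `c("A", "B")`; fold
#'   changes are second minus first in lexicographic order).
#' @param seed RNG seed (default 1).
#' @return validated parameter list of class `"rasaSimParams"`.
#' @export
simulationParams <- function(nGenes = 200L, exonsPerGene = 10L,
                             nReplicates = 3L, fracSplicedExons = 0.05,
                             splicingEffect = 2, geneFcSd = 0.5,
                             baseMean = 8, baseSd = 1,
                             exonNoiseSd = 0.25, junctionNoiseSd = 0.4,
                             probeAffinitySd = 0.3, unitOffsetSd = 0.3,
                             junctionFailureRate = 0,
                             failedExonFraction = 0,
                             fracAbsentExons = 0.05,
                             probesPerExon = 8L, probesPerJunction = 4L,
                             background = 4, dabgSlope = 1.5,
                             dabgNoiseSd = 0.5,
                             conditions = c("A", "B"), seed = 1L) {
  p <- list(nGenes = as.integer(nGenes),
            exonsPerGene = as.integer(exonsPerGene),
            nReplicates = as.integer(nReplicates),
            fracSplicedExons = fracSplicedExons,
            splicingEffect = splicingEffect, geneFcSd = geneFcSd,
            baseMean = baseMean, baseSd = baseSd,
            exonNoiseSd = exonNoiseSd, junctionNoiseSd = junctionNoiseSd,
            probeAffinitySd = probeAffinitySd, unitOffsetSd = unitOffsetSd,
            junctionFailureRate = junctionFailureRate,
            failedExonFraction = failedExonFraction,
            fracAbsentExons = fracAbsentExons,
            probesPerExon = as.integer(probesPerExon),
            probesPerJunction = as.integer(probesPerJunction),
            background = background, dabgSlope = dabgSlope,
            dabgNoiseSd = dabgNoiseSd, conditions = as.character(conditions),
            seed = as.integer(seed))
  if (p$nGenes < 1L || p$nReplicates < 1L)
    stop("need at least one gene and one replicate per condition")
  if (p$exonsPerGene < 3L)
    stop("'exonsPerGene' must be >= 3 so internal exons exist")
  for (nm in c("fracSplicedExons", "junctionFailureRate",
               "failedExonFraction", "fracAbsentExons"))
    if (p[[nm]] < 0 || p[[nm]] > 1) stop("'", nm, "' must lie in [0, 1]")
  for (nm in c("geneFcSd", "exonNoiseSd", "junctionNoiseSd",
               "probeAffinitySd", "unitOffsetSd", "dabgNoiseSd"))
    if (p[[nm]] < 0) stop("'", nm, "' must be non-negative")
  if (length(p$conditions) != 2L || anyDuplicated(p$conditions))
    stop("'conditions' must be two distinct labels")
  class(p) <- "rasaSimParams"
  p
}

.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit(if (had) assign(".Random.seed", old, envir = env)
          else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env))
  set.seed(seed)
  expr
}

#' Simulate an exon-junction array dataset with ground truth
#'
#' Generates probe-level log2 expression, per-probeset DABG p-values,
#' the design annotation, the sample design and a truth table, fully
#' reproducible from the seed in `params`.
#'
#' @param params a parameter list from [simulationParams()].
#' @param noiseSeed optional separate seed for the measurement noise
#'   (probe noise and DABG noise). The gene/exon structure, planted
#'   events, offsets and probe affinities are always drawn from
#'   `params$seed`, so varying `noiseSeed` at a fixed `params$seed`
#'   replicates fresh measurements of the same truth — the layout needed
#'   to estimate estimator bias rather than single-realization error.
#' @return list with elements `probes` (matrix), `probeMap`
#'   (`data.frame` probe_id/probeset_id), `dabg` (probeset x sample
#'   matrix), `annotation`, `design`, `truth` (list with `exons`,
#'   `junctions`, `genes`) and `params`.
#' @examples
#' sim <- simulateSpliceArray(simulationParams(nGenes = 5, seed = 42))
#' sim$truth$exons[sim$truth$exons$is_spliced, ]
#' @export
simulateSpliceArray <- function(params = simulationParams(),
                                noiseSeed = NULL) {
  stopifnot(inherits(params, "rasaSimParams"))
  .withSeed(params$seed, .simulateImpl(params, noiseSeed))
}

.simulateImpl <- function(p, noiseSeed = NULL) {
  G <- p$nGenes; E <- p$exonsPerGene; nr <- p$nReplicates
  geneIds <- sprintf("g%04d", seq_len(G))

  # exon units
  exGene <- rep(seq_len(G), each = E)
  exIdx <- rep(seq_len(E), times = G)
  exPs <- sprintf("%s_e%02d", geneIds[exGene], exIdx)
  nEx <- length(exPs)
  eligible <- which(exIdx >= 2L & exIdx <= E - 1L)
  nSpliced <- round(p$fracSplicedExons * length(eligible))
  splicedRows <- sort(sample(eligible, nSpliced))
  direction <- integer(nEx)
  direction[splicedRows] <- sample(c(-1L, 1L), nSpliced, replace = TRUE)
  absCand <- setdiff(seq_len(nEx), splicedRows)
  nAbsent <- min(round(p$fracAbsentExons * nEx), length(absCand))
  absentRows <- sort(sample(absCand, nAbsent))
  isSpliced <- seq_len(nEx) %in% splicedRows
  isAbsent <- seq_len(nEx) %in% absentRows

  # junction units: adjacent chain plus skip junctions for spliced exons
  adjGene <- rep(seq_len(G), each = E - 1L)
  adj5 <- rep(seq_len(E - 1L), times = G)
  jGene <- c(adjGene, exGene[splicedRows])
  j5 <- c(adj5, exIdx[splicedRows] - 1L)
  j3 <- c(adj5 + 1L, exIdx[splicedRows] + 1L)
  jPs <- sprintf("%s_j%02d_%02d", geneIds[jGene], j5, j3)
  nJc <- length(jPs)
  isFailed <- runif(nJc) < p$junctionFailureRate
  # targeted failures: all junctions of a fraction of the planted exons
  nTargeted <- round(p$failedExonFraction * nSpliced)
  targetRows <- if (nTargeted > 0L)
    sort(sample(splicedRows, nTargeted)) else integer(0)
  for (r in targetRows) {
    g <- exGene[r]; e <- exIdx[r]
    hit <- jGene == g & ((j5 == e | j3 == e) | (j5 < e & j3 > e))
    isFailed[hit] <- TRUE
  }

  # gene truth
  baseA <- rnorm(G, p$baseMean, p$baseSd)
  geneFc <- rnorm(G, 0, p$geneFcSd)

  # per-unit condition means
  exOff <- rnorm(nEx, 0, p$unitOffsetSd)
  jcOff <- rnorm(nJc, 0, p$unitOffsetSd)
  exMuA <- baseA[exGene] + exOff
  exMuB <- baseA[exGene] + geneFc[exGene] + exOff +
    direction * p$splicingEffect
  exMuA[isAbsent] <- p$background
  exMuB[isAbsent] <- p$background

  jShift <- numeric(nJc)
  for (r in splicedRows) {
    g <- exGene[r]; e <- exIdx[r]; d <- direction[r]
    samegene <- which(jGene == g)
    inc <- samegene[j5[samegene] == e | j3[samegene] == e]
    exc <- samegene[j5[samegene] < e & j3[samegene] > e]
    jShift[inc] <- jShift[inc] + d * p$splicingEffect
    jShift[exc] <- jShift[exc] - d * p$splicingEffect
  }
  jcMuA <- baseA[jGene] + jcOff
  jcMuB <- baseA[jGene] + geneFc[jGene] + jcOff + jShift
  jcMuA[isFailed] <- p$background
  jcMuB[isFailed] <- p$background

  # samples (condition labels sorted so fold change = second - first)
  conds <- sort(p$conditions)
  sampleIds <- c(paste0(conds[1L], seq_len(nr)), paste0(conds[2L], seq_len(nr)))
  condition <- rep(conds, each = nr)
  nS <- length(sampleIds)

  unitMuA <- c(exMuA, jcMuA)
  unitMuB <- c(exMuB, jcMuB)
  unitPs <- c(exPs, jPs)
  unitKind <- rep(c("exon", "junction"), c(nEx, nJc))
  unitNoise <- ifelse(unitKind == "exon", p$exonNoiseSd, p$junctionNoiseSd)
  nProbes <- ifelse(unitKind == "exon", p$probesPerExon, p$probesPerJunction)
  muMat <- cbind(matrix(unitMuA, nrow = length(unitPs), ncol = nr),
                 matrix(unitMuB, nrow = length(unitPs), ncol = nr))

  probeUnit <- rep(seq_along(unitPs), times = nProbes)
  probeIds <- sprintf("%s_p%02d", unitPs[probeUnit],
                      sequence(nProbes))
  affinity <- rnorm(length(probeIds), 0, p$probeAffinitySd)
  # everything above is structure (fixed truth); measurement noise below
  if (!is.null(noiseSeed)) set.seed(noiseSeed)
  noise <- matrix(rnorm(length(probeIds) * nS, 0,
                        unitNoise[probeUnit]),
                  nrow = length(probeIds), ncol = nS)
  probes <- muMat[probeUnit, , drop = FALSE] + affinity + noise
  dimnames(probes) <- list(probeIds, sampleIds)

  # DABG: logistic in standardized signal-above-background + seeded noise
  z <- (muMat - p$background) / unitNoise
  dabg <- plogis(-p$dabgSlope * z +
                   matrix(rnorm(length(unitPs) * nS, 0, p$dabgNoiseSd),
                          nrow = length(unitPs), ncol = nS))
  dabg <- pmin(pmax(dabg, 1e-16), 1)
  dimnames(dabg) <- list(unitPs, sampleIds)

  annotation <- data.frame(
    probeset_id = unitPs,
    gene_id = geneIds[c(exGene, jGene)],
    kind = unitKind,
    exon_index = c(exIdx, rep(NA_integer_, nJc)),
    exon5 = c(rep(NA_integer_, nEx), j5),
    exon3 = c(rep(NA_integer_, nEx), j3),
    n_probes = nProbes, stringsAsFactors = FALSE)

  design <- data.frame(sample_id = sampleIds, condition = condition,
                       stringsAsFactors = FALSE)
  # per exon: do all of its junction probesets emit failed signal?
  junctionsFailed <- logical(nEx)
  for (g in seq_len(G)) {
    jIn <- which(jGene == g)
    eIn <- which(exGene == g)
    for (i in eIn) {
      e <- exIdx[i]
      hit <- jIn[(j5[jIn] == e | j3[jIn] == e) |
                   (j5[jIn] < e & j3[jIn] > e)]
      junctionsFailed[i] <- length(hit) > 0L && all(isFailed[hit])
    }
  }
  truth <- list(
    exons = data.frame(probeset_id = exPs, gene_id = geneIds[exGene],
                       exon_index = exIdx, is_spliced = isSpliced,
                       direction = direction, is_absent = isAbsent,
                       junctions_failed = junctionsFailed,
                       stringsAsFactors = FALSE),
    junctions = data.frame(probeset_id = jPs, gene_id = geneIds[jGene],
                           exon5 = j5, exon3 = j3, is_failed = isFailed,
                           shift = jShift, stringsAsFactors = FALSE),
    genes = data.frame(gene_id = geneIds, abundance_A = baseA,
                       abundance_B = baseA + geneFc, fc = geneFc,
                       stringsAsFactors = FALSE))
  list(probes = probes,
       probeMap = data.frame(probe_id = probeIds,
                             probeset_id = unitPs[probeUnit],
                             stringsAsFactors = FALSE),
       dabg = dabg, annotation = annotation, design = design,
       truth = truth, params = p)
}

#' Summarize a simulated dataset into a SpliceArraySet
#'
#' Applies median-scaling normalization and median-polish summarization
#' to the simulated probe matrix and bundles the result with the
#' simulated annotation, design and DABG p-values.
#'
#' @param sim result of [simulateSpliceArray()].
#' @param normalize apply [medianScaleNormalize()] first
#'   (default `TRUE`).
#' @return a [SpliceArraySet-class].
#' @export
simulatedSpliceArraySet <- function(sim, normalize = TRUE) {
  probes <- sim$probes
  if (normalize) probes <- medianScaleNormalize(probes)
  exprs <- summarizeProbesets(probes, sim$probeMap)
  SpliceArraySet(exprs, sim$annotation, sim$design, dabg = sim$dabg)
}

#' Write a simulated dataset to TSV files
#'
#' Writes `probes.tsv`, `probe_map.tsv`, `dabg.tsv`, `annotation.tsv`,
#' `design.tsv` and the truth tables (`truth_exons.tsv`,
#' `truth_junctions.tsv`, `truth_genes.tsv`) in the formats the pipeline
#' reads.
#'
#' @param sim result of [simulateSpliceArray()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulatedData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTsvMatrix(sim$probes, file.path(dir, "probes.tsv"), "probe_id")
  writeTsvMatrix(sim$dabg, file.path(dir, "dabg.tsv"), "probeset_id")
  .wt <- function(df, nm) write.table(df, file.path(dir, nm), sep = "\t",
                                      quote = FALSE, row.names = FALSE)
  .wt(sim$probeMap, "probe_map.tsv")
  .wt(sim$annotation, "annotation.tsv")
  .wt(sim$design, "design.tsv")
  .wt(sim$truth$exons, "truth_exons.tsv")
  .wt(sim$truth$junctions, "truth_junctions.tsv")
  .wt(sim$truth$genes, "truth_genes.tsv")
  invisible(dir)
}

#' Evaluate splicing calls against simulated truth
#'
#' An exon counts as called positive when its category is one of
#' `positiveCategories` (by default the two confident-candidate
#' categories). Precision is computed over called exons, recall over all
#' planted spliced exons in the truth table (exons dropped as
#' untestable count as misses). With zero positive calls precision is
#' reported as `NA`, not 0.
#'
#' @param calls a [SplicingCalls-class] or call `data.frame`.
#' @param truth truth list from [simulateSpliceArray()] (`$truth`), or
#'   its `exons` `data.frame`.
#' @param positiveCategories categories counted as positive calls.
#' @return list with `confusion` (TP, FP, FN, TN), `precision`,
#'   `recall`, `f1`, `direction_agreement` (fraction of true positives
#'   whose splicing-index sign matches the planted direction) and
#'   `by_category` (per-category TP/FP/precision).
#' @export
evaluateCalls <- function(calls, truth,
                          positiveCategories = c("junction_supported",
                                                 "unreliable_junction_candidate")) {
  if (is(calls, "SplicingCalls")) calls <- callTable(calls)
  tx <- if (is.data.frame(truth)) truth else truth$exons
  if (!all(calls$probeset_id %in% tx$probeset_id))
    stop("calls contain exons unknown to the truth table: mismatched annotation")
  m <- match(calls$probeset_id, tx$probeset_id)
  spliced <- tx$is_spliced[m]
  pos <- calls$category %in% positiveCategories
  TP <- sum(pos & spliced)
  FP <- sum(pos & !spliced)
  TN <- sum(!pos & !spliced)
  nPlanted <- sum(tx$is_spliced)
  FN <- nPlanted - TP
  precision <- if (TP + FP == 0L) NA_real_ else TP / (TP + FP)
  recall <- if (nPlanted == 0L) NA_real_ else TP / nPlanted
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  tpRows <- which(pos & spliced)
  dirAgree <- if (length(tpRows))
    mean(sign(calls$si[tpRows]) == tx$direction[m][tpRows]) else NA_real_
  byCat <- lapply(split(seq_len(nrow(calls)), calls$category), function(i) {
    tp <- sum(spliced[i]); n <- length(i)
    list(n = n, tp = tp, precision = if (n) tp / n else NA_real_)
  })
  list(confusion = list(TP = TP, FP = FP, FN = FN, TN = TN),
       precision = precision, recall = recall, f1 = f1,
       direction_agreement = dirAgree, by_category = byCat)
}
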