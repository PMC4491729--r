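test_that("simulation is reproducible from its seed", {
  p <- simulationParams(nGenes = 10, seed = 77, junctionFailureRate = 0.2,
                        failedExonFraction = 0.5)
  s1 <- simulateSpliceArray(p)
  s2 <- simulateSpliceArray(p)
  expect_identical(s1, s2)
  s3 <- simulateSpliceArray(simulationParams(nGenes = 10, seed = 78))
  expect_false(identical(s1$probes, s3$probes))
  # a noise seed changes measurements but not the truth
  s4 <- simulateSpliceArray(p, noiseSeed = 123)
  expect_identical(s4$truth, s1$truth)
  expect_false(identical(s4$probes, s1$probes))
})

test_that("planted event counts follow the configured fractions", {
  p <- simulationParams(nGenes = 100, exonsPerGene = 10,
                        fracSplicedExons = 0.05, seed = 5)
  sim <- simulateSpliceArray(p)
  tx <- sim$truth$exons
  nEligible <- sum(tx$exon_index >= 2 & tx$exon_index <= 9)
  expect_identical(sum(tx$is_spliced), as.integer(round(0.05 * nEligible)))
  # spliced exons are internal and carry a direction
  sp <- tx[tx$is_spliced, ]
  expect_true(all(sp$exon_index >= 2 & sp$exon_index <= 9))
  expect_true(all(sp$direction %in% c(-1L, 1L)))
  expect_true(all(tx$direction[!tx$is_spliced] == 0L))
  # absent exons never coincide with spliced ones
  expect_false(any(tx$is_spliced & tx$is_absent))
  expect_identical(sum(tx$is_absent), as.integer(round(0.05 * nrow(tx))))
  # every planted exon has its skip junction in the annotation
  ann <- sim$annotation
  for (i in seq_len(nrow(sp))) {
    jn <- junctionsForExon(ann, sp$gene_id[i], sp$exon_index[i])
    expect_length(jn$exclusion, 1)
  }
})

test_that("targeted junction failure marks whole exon neighbourhoods", {
  p <- simulationParams(nGenes = 60, seed = 19, fracSplicedExons = 0.1,
                        failedExonFraction = 0.5)
  sim <- simulateSpliceArray(p)
  tx <- sim$truth$exons
  tj <- sim$truth$junctions
  sp <- tx[tx$is_spliced, ]
  nTargeted <- sum(sp$junctions_failed)
  expect_identical(nTargeted, as.integer(round(0.5 * nrow(sp))))
  failed <- tj$probeset_id[tj$is_failed]
  for (i in which(sp$junctions_failed)) {
    jn <- junctionsForExon(sim$annotation, sp$gene_id[i], sp$exon_index[i])
    expect_true(all(c(jn$inclusion, jn$exclusion) %in% failed))
  }
})

test_that("absent exons and failed junctions sit at background", {
  p <- simulationParams(nGenes = 50, seed = 23, fracAbsentExons = 0.1,
                        junctionFailureRate = 0.3)
  sim <- simulateSpliceArray(p)
  tx <- sim$truth$exons; tj <- sim$truth$junctions
  psOf <- sim$probeMap$probeset_id
  absent <- tx$probeset_id[tx$is_absent]
  mAbs <- mean(sim$probes[psOf %in% absent, ])
  mPres <- mean(sim$probes[psOf %in% tx$probeset_id[!tx$is_absent], ])
  expect_lt(abs(mAbs - p$background), 0.2)
  expect_gt(mPres - mAbs, 2)
  # absent exons are called absent by group DABG, present exons present
  gc <- groupDabg(sim$dabg, sim$design)
  expect_gt(mean(!gc$present[absent, 1] & !gc$present[absent, 2]), 0.95)
  pres <- tx$probeset_id[!tx$is_absent]
  expect_gt(mean(gc$present[pres, 1] & gc$present[pres, 2]), 0.9)
})

test_that("call evaluation computes the confusion arithmetic", {
  truth <- data.frame(probeset_id = paste0("e", 1:14),
                      is_spliced = rep(c(TRUE, FALSE), c(10, 4)),
                      direction = rep(c(1L, 0L), c(10, 4)))
  calls <- data.frame(
    probeset_id = paste0("e", 1:14),
    category = c(rep("junction_supported", 8),      # 8 TP
                 rep("exon_only_not_called", 2),    # 2 FN
                 rep("unreliable_junction_candidate", 2),  # 2 FP
                 rep("not_significant", 2)),
    si = c(rep(1, 8), rep(1, 2), rep(-1, 2), rep(0, 2)))
  ev <- evaluateCalls(calls, truth)
  expect_identical(ev$confusion, list(TP = 8L, FP = 2L, FN = 2L, TN = 2L))
  expect_equal(ev$precision, 0.8)
  expect_equal(ev$recall, 0.8)
  expect_equal(ev$direction_agreement, 1)

  # calls identical to truth: perfect scores
  perfect <- data.frame(probeset_id = truth$probeset_id,
                        category = ifelse(truth$is_spliced,
                                          "junction_supported",
                                          "not_significant"),
                        si = truth$direction)
  evp <- evaluateCalls(perfect, truth)
  expect_equal(evp$precision, 1)
  expect_equal(evp$recall, 1)

  # zero positive calls: precision NA, not zero
  none <- data.frame(probeset_id = truth$probeset_id,
                     category = "not_significant", si = 0)
  evn <- evaluateCalls(none, truth)
  expect_true(is.na(evn$precision))
  expect_equal(evn$recall, 0)

  # mismatched annotation is an error
  bad <- data.frame(probeset_id = "zz", category = "absent", si = 0)
  expect_error(evaluateCalls(bad, truth), "mismatched annotation")
})

test_that("recall rises with effect size and replication", {
  recallAt <- function(effect, nrep, seed) {
    sim <- simulateSpliceArray(simulationParams(
      nGenes = 60, nReplicates = nrep, splicingEffect = effect,
      fracSplicedExons = 0.1, seed = seed))
    ev <- evaluateCalls(runRasa(simulatedSpliceArraySet(sim)), sim$truth)
    ev$recall
  }
  r_small <- recallAt(0.7, 3L, 71)
  r_big <- recallAt(2.5, 3L, 71)
  expect_gte(r_big, r_small)
  r_more <- recallAt(0.7, 6L, 71)
  expect_gte(r_more, r_small)
  expect_gt(r_big, 0.8)
})
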