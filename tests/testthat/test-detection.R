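make_stats <- function(...) {
  rows <- list(...)
  data.frame(probeset_id = vapply(rows, `[[`, "", 1),
             p_value = as.numeric(vapply(rows, `[[`, "", 2)),
             si = as.numeric(vapply(rows, `[[`, "", 3)),
             stringsAsFactors = FALSE)
}

test_that("junction support requires significance and direction agreement", {
  ann <- tinyAnnotation()
  # inclusion junction co-directional and significant at p' = 0.007
  st <- make_stats(c("gA_e2", "0.001", "2"),
                   c("gA_j12", "0.002", "1.5"),
                   c("gA_j23", "0.5", "0.1"),
                   c("gA_j13", "0.9", "0"))
  sup <- findSupportingJunctions("gA_e2", st, p = 0.01, pPrime = 0.007, ann)
  expect_identical(sup$junction_id, "gA_j12")
  expect_identical(sup$support_type, "inclusion")

  # exclusion junction in the opposite direction also supports
  st2 <- make_stats(c("gA_e2", "0.001", "2"),
                    c("gA_j12", "0.5", "0.2"),
                    c("gA_j23", "0.6", "0.1"),
                    c("gA_j13", "0.003", "-1.2"))
  sup2 <- findSupportingJunctions("gA_e2", st2, 0.01, 0.007, ann)
  expect_identical(sup2$junction_id, "gA_j13")
  expect_identical(sup2$support_type, "exclusion")

  # right direction but p above p': unsupported
  st3 <- make_stats(c("gA_e2", "0.001", "2"),
                    c("gA_j12", "0.02", "1.5"),
                    c("gA_j23", "0.6", "0.1"),
                    c("gA_j13", "0.9", "0"))
  expect_identical(nrow(findSupportingJunctions("gA_e2", st3, 0.01, 0.007,
                                                ann)), 0L)

  # exon with no junctions at all: empty support set
  st4 <- make_stats(c("gB_e1", "0.001", "2"))
  expect_identical(nrow(findSupportingJunctions("gB_e1", st4, 0.01, 0.007,
                                                ann)), 0L)
})

test_that("best-junction difference follows the truncation rule", {
  bd <- bestJunctionDifference(2, c(j1 = 1.5, j2 = -0.3))
  expect_identical(bd$best_junction_id, "j1")
  expect_equal(bd$fc_difference, 0.5)

  # no same-direction junction: truncate the junction change to zero
  bd2 <- bestJunctionDifference(2, c(j1 = -0.3, j2 = -1.0))
  expect_true(is.na(bd2$best_junction_id))
  expect_equal(bd2$fc_difference, 2)

  # junction stronger than the exon gives a negative difference
  bd3 <- bestJunctionDifference(-2, c(j1 = -3, j2 = 1))
  expect_identical(bd3$best_junction_id, "j1")
  expect_equal(bd3$fc_difference, -1)

  # empty junction list is the truncation case too
  expect_equal(bestJunctionDifference(-1.2, numeric(0))$fc_difference, 1.2)
})

test_that("the null cutoff is the top-q order statistic with strict ties", {
  diffs <- seq(0.05, 1, by = 0.05)  # 20 evenly spaced values
  nt <- estimateNullThreshold(diffs, q = 0.05)
  expect_equal(nt$cutoff, 0.95)     # k = ceiling(0.95 * 20) = 19
  expect_true(nt$enabled)

  # q near 1 collapses to the smallest difference
  expect_equal(estimateNullThreshold(diffs, q = 0.99)$cutoff, 0.05)

  # all differences equal: cutoff = c, and ties do not exceed it
  nt2 <- estimateNullThreshold(rep(0.4, 25), q = 0.05)
  expect_equal(nt2$cutoff, 0.4)
  expect_false(any(rep(0.4, 25) > nt2$cutoff))

  # too small a null disables the stage
  expect_warning(nt3 <- estimateNullThreshold(diffs[1:5], q = 0.05),
                 "too small")
  expect_false(nt3$enabled)
})

test_that("classification composes significance, support and the cutoff", {
  tab <- data.frame(
    p_value = c(0.001, 0.001, 0.001, 0.5, NA),
    n_support = c(2L, 0L, 0L, 0L, 0L),
    fc_difference = c(-0.1, 2.0, 0.3, NA, NA),
    absent_both = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  nt <- list(cutoff = 0.95, enabled = TRUE)
  expect_identical(classifyExons(tab, p = 0.01, nt),
                   c("junction_supported", "unreliable_junction_candidate",
                     "exon_only_not_called", "not_significant", "absent"))
  # disabled rescue folds candidates into exon_only_not_called
  ntOff <- list(cutoff = NA_real_, enabled = FALSE)
  expect_identical(classifyExons(tab, 0.01, ntOff)[2], "exon_only_not_called")
})

test_that("the pipeline run is deterministic and partitions every exon", {
  sim <- simulateSpliceArray(simulationParams(nGenes = 40, seed = 3,
                                              failedExonFraction = 0.3))
  sas <- simulatedSpliceArraySet(sim)
  res1 <- runRasa(sas)
  res2 <- runRasa(sas)
  expect_identical(callTable(res1), callTable(res2))

  ct <- callTable(res1)
  # every testable exon gets exactly one category; counts add up
  expect_false(any(is.na(ct$category)))
  th <- callThresholds(res1)
  expect_identical(sum(unlist(th$category_counts)), nrow(ct))
  expect_identical(nrow(ct) + th$n_untestable_exons,
                   sum(annotationTable(sas)$kind == "exon"))
  # supported exons always list at least one junction
  js <- ct[ct$category == "junction_supported", ]
  expect_true(all(nchar(js$supporting_junctions) > 0))
  # rescued exons have an empty support set and exceed the cutoff
  uj <- ct[ct$category == "unreliable_junction_candidate", ]
  expect_true(all(uj$supporting_junctions == ""))
  expect_true(all(uj$fc_difference > th$cutoff))
})

test_that("file-level runs are byte-identical and round-trip", {
  sim <- simulateSpliceArray(simulationParams(nGenes = 25, seed = 9,
                                              junctionFailureRate = 0.1))
  dir <- withr::local_tempdir()
  writeSimulatedData(sim, file.path(dir, "data"))
  cfg <- list(probes = file.path(dir, "data", "probes.tsv"),
              probe_map = file.path(dir, "data", "probe_map.tsv"),
              annotation = file.path(dir, "data", "annotation.tsv"),
              design = file.path(dir, "data", "design.tsv"),
              dabg = file.path(dir, "data", "dabg.tsv"))
  cfgFile <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, cfgFile)
  res1 <- runRasaFiles(readRasaConfig(cfgFile), file.path(dir, "out1"))
  res2 <- runRasaFiles(readRasaConfig(cfgFile), file.path(dir, "out2"))
  for (f in c("calls.tsv", "gene_index.tsv", "partition.tsv", "report.yaml"))
    expect_identical(readLines(file.path(dir, "out1", f)),
                     readLines(file.path(dir, "out2", f)))
  back <- readSplicingCalls(file.path(dir, "out1", "calls.tsv"))
  expect_equal(back, callTable(res1), tolerance = 1e-12)
})
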