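# Independent reference implementations used as oracles. These are
# deliberately written apply/loop style, independent of the package
# internals they check.

# Reference Tukey median polish: rows first, stopping on the largest
# absolute sweep adjustment.
refMedianPolish <- function(x, tol = 1e-9, maxSweeps = 100L) {
  overall <- 0
  rowe <- rep(0, nrow(x))
  cole <- rep(0, ncol(x))
  z <- x
  for (s in seq_len(maxSweeps)) {
    rd <- apply(z, 1, stats::median)
    z <- sweep(z, 1, rd)
    rowe <- rowe + rd
    dl <- stats::median(cole)
    cole <- cole - dl
    overall <- overall + dl
    cd <- apply(z, 2, stats::median)
    z <- sweep(z, 2, cd)
    cole <- cole + cd
    dl <- stats::median(rowe)
    rowe <- rowe - dl
    overall <- overall + dl
    if (max(abs(rd), abs(cd)) < tol) break
  }
  list(overall = overall, row = rowe, col = cole, index = overall + cole)
}

# Brute-force k-th order-statistic threshold: smallest value t in the
# list such that the fraction of values <= t is >= f.
refQuantileThreshold <- function(values, f) {
  if (f <= 0) return(0)
  s <- sort(values)
  fr <- vapply(s, function(t) mean(values <= t), 0)
  s[which(fr >= f)[1L]]
}

refGeometricMean <- function(p) prod(p)^(1 / length(p))

# Smallest junction count k with k/nJ >= cnt/nE, by exact integer
# comparison (k * nE >= cnt * nJ), i.e. ceiling((cnt/nE) * nJ) without
# floating-point error.
refPassCount <- function(cnt, nE, nJ) {
  k <- 0L
  while (k * nE < cnt * nJ) k <- k + 1L
  k
}

# Small hand-built two-gene annotation used across io/detection tests.
tinyAnnotation <- function() {
  data.frame(
    probeset_id = c("gA_e1", "gA_e2", "gA_e3", "gA_j12", "gA_j23", "gA_j13",
                    "gB_e1", "gB_e2"),
    gene_id = c(rep("gA", 6), "gB", "gB"),
    kind = c(rep("exon", 3), rep("junction", 3), "exon", "exon"),
    exon_index = c(1L, 2L, 3L, NA, NA, NA, 1L, 2L),
    exon5 = c(NA, NA, NA, 1L, 2L, 1L, NA, NA),
    exon3 = c(NA, NA, NA, 2L, 3L, 3L, NA, NA),
    n_probes = 4L,
    stringsAsFactors = FALSE
  )
}

tinyDesign <- function(nrep = 3L) {
  data.frame(
    sample_id = c(paste0("A", seq_len(nrep)), paste0("B", seq_len(nrep))),
    condition = rep(c("A", "B"), each = nrep),
    stringsAsFactors = FALSE
  )
}
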