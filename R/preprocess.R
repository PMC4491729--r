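#' Median-scaling normalization of a log2 probe matrix
#'
#' Shifts each sample (column) by a constant so that its median equals
#' `target`. With `target = "auto"` the target is the mean of the
#' original column medians. On the log2 scale this is the usual
#' median-scaling step applied before probeset summarization.
#'
#' @param m numeric matrix, probes x samples, log2 scale.
#' @param target numeric scalar or `"auto"`.
#' @return matrix of the same shape; column medians equal `target`.
#' @export
medianScaleNormalize <- function(m, target = "auto") {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) < 1L || ncol(m) < 1L)
    stop("'m' must be a non-empty numeric matrix")
  meds <- colMedians(m)
  if (identical(target, "auto")) target <- mean(meds)
  if (!is.numeric(target) || length(target) != 1L)
    stop("'target' must be a single number or \"auto\"")
  sweep(m, 2L, meds - target, "-")
}

#' Tukey median polish of one probe block
#'
#' Alternates row and column median sweeps (rows first) until the
#' largest absolute adjustment applied to the residuals in a full sweep
#' is below `tol` or `maxSweeps` full sweeps have run. The even-length median is the mean
#' of the two central values. The per-sample expression index is
#' `overall + col`.
#'
#' @param block numeric matrix, probes x samples (one probeset).
#' @param tol convergence tolerance on the residual change (default
#'   `1e-6`).
#' @param maxSweeps maximum number of full sweeps (default 30).
#' @return list with `overall`, `row`, `col`, `residuals`, `index`
#'   (named per-sample vector `overall + col`) and `sweeps`.
#' @export
medianPolish <- function(block, tol = 1e-6, maxSweeps = 30L) {
  if (!is.matrix(block) || !is.numeric(block) ||
      nrow(block) < 1L || ncol(block) < 1L)
    stop("'block' must be a non-empty numeric matrix")
  z <- block
  nr <- nrow(z)
  overall <- 0
  rowe <- numeric(nr)
  cole <- numeric(ncol(z))
  sweeps <- 0L
  # plain sort-based median (mean of the two central values when even);
  # avoids S3 dispatch in the hot loop
  med <- function(v) {
    n <- length(v)
    s <- sort.int(v, method = "quick")
    h <- n %/% 2L
    if (n %% 2L) s[h + 1L] else (s[h] + s[h + 1L]) / 2
  }
  repeat {
    rdelta <- rowMedians(z)
    z <- z - rdelta         # recycles down columns
    rowe <- rowe + rdelta
    delta <- med(cole)
    cole <- cole - delta
    overall <- overall + delta
    cdelta <- colMedians(z)
    z <- z - rep(cdelta, each = nr)
    cole <- cole + cdelta
    delta <- med(rowe)
    rowe <- rowe - delta
    overall <- overall + delta
    sweeps <- sweeps + 1L
    if (max(abs(rdelta), abs(cdelta)) < tol || sweeps >= maxSweeps) break
  }
  index <- overall + cole
  names(index) <- colnames(block)
  list(overall = overall, row = setNames(rowe, rownames(block)),
       col = setNames(cole, colnames(block)), residuals = z,
       index = index, sweeps = sweeps)
}

#' Summarize probe-level signal into probeset expression indices
#'
#' Runs a median polish per probeset over its probe rows and returns the
#' per-sample indices as a probeset x sample matrix. Probeset order is
#' the order of first appearance in `probeMap`.
#'
#' @param probes numeric matrix, probes x samples, log2 scale (usually
#'   after [medianScaleNormalize()]).
#' @param probeMap `data.frame` with columns `probe_id`, `probeset_id`;
#'   every row of `probes` must be mapped.
#' @param tol,maxSweeps passed to [medianPolish()].
#' @return numeric matrix, probesets x samples.
#' @export
summarizeProbesets <- function(probes, probeMap, tol = 1e-6, maxSweeps = 30L) {
  if (is.null(rownames(probes)))
    stop("'probes' must have probe_id rownames")
  ps <- probeMap$probeset_id[match(rownames(probes), probeMap$probe_id)]
  if (any(is.na(ps)))
    stop("probes missing from the probe map: ",
         paste(utils::head(rownames(probes)[is.na(ps)], 5), collapse = ", "))
  sets <- unique(ps)
  idx <- split(seq_len(nrow(probes)), factor(ps, levels = sets))
  out <- matrix(NA_real_, nrow = length(sets), ncol = ncol(probes),
                dimnames = list(sets, colnames(probes)))
  for (i in seq_along(idx)) {
    block <- probes[idx[[i]], , drop = FALSE]
    if (nrow(block) == 1L) {
      out[i, ] <- block[1L, ]
    } else {
      out[i, ] <- medianPolish(block, tol = tol, maxSweeps = maxSweeps)$index
    }
  }
  out
}

#' Group-level detection-above-background calls
#'
#' Aggregates per-sample DABG p-values into one p-value per probeset and
#' condition as the geometric mean of the sample p-values, and flags a
#' probeset as present in a condition when the group p-value is at or
#' below `threshold` (default 0.01).
#'
#' @param dabg numeric matrix of per-sample DABG p-values (probesets x
#'   samples), values in `[0, 1]`; zeros are clamped to `1e-16`.
#' @param condition named character vector mapping sample id to
#'   condition (as from [sampleConditions()]), or a design `data.frame`
#'   with `sample_id`/`condition` columns.
#' @param threshold presence threshold on the group p-value.
#' @return list with matrices `group_p` and `present` (probesets x
#'   conditions) and the `threshold` used.
#' @export
groupDabg <- function(dabg, condition, threshold = 0.01) {
  if (is.data.frame(condition))
    condition <- setNames(condition$condition, condition$sample_id)
  if (is.null(colnames(dabg)) || !all(colnames(dabg) %in% names(condition)))
    stop("every DABG column must appear in the design")
  condition <- condition[colnames(dabg)]
  dabg <- pmin(pmax(dabg, 1e-16), 1)
  conds <- sort(unique(condition))
  gp <- vapply(conds, function(cc) {
    cols <- which(condition == cc)
    if (!length(cols)) stop("condition with zero samples: ", cc)
    exp(rowMeans(log(dabg[, cols, drop = FALSE])))
  }, numeric(nrow(dabg)))
  gp <- matrix(gp, nrow = nrow(dabg),
               dimnames = list(rownames(dabg), conds))
  list(group_p = gp, present = gp <= threshold, threshold = threshold)
}
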