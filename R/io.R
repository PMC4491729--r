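# TSV readers/writers. All files are tab-separated, UTF-8, with a header
# row; matrices carry row identifiers in the first column.

.readTsvMatrix <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(what, " file '", path, "' has no data rows")
  if (ncol(df) < 2L) stop(what, " file '", path, "' has no sample columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated row identifier in ", what, " '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cols <- colnames(df)[-1L]
  if (anyDuplicated(cols))
    stop("duplicated column identifier in ", what, " '", path, "': ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    badcol <- cols[which(!vapply(df[-1L], is.numeric, logical(1)))[1L]]
    stop("non-numeric values in ", what, " '", path, "', column '",
         badcol, "'")
  }
  dimnames(m) <- list(ids, cols)
  m
}

#' Read a log2 expression matrix from TSV
#'
#' The first column holds probe or probeset identifiers, the remaining
#' header names are sample ids. Duplicate identifiers, non-numeric cells
#' and non-finite values are rejected with an error naming the offender.
#'
#' @param path TSV file path.
#' @param rowKind `"probeset"` (default) or `"probe"`; recorded as the
#'   `"row_kind"` attribute of the result.
#' @return numeric matrix with dimnames.
#' @export
readExpressionMatrix <- function(path, rowKind = c("probeset", "probe")) {
  rowKind <- match.arg(rowKind)
  m <- .readTsvMatrix(path, "expression matrix")
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop("non-finite value in expression matrix at row '",
         rownames(m)[bad[1L]], "', column '", colnames(m)[bad[2L]], "'")
  }
  attr(m, "row_kind") <- rowKind
  m
}

#' Read a DABG p-value matrix from TSV
#'
#' Values must lie in `[0, 1]`; they are clamped to `[1e-16, 1]` so that
#' log-scale geometric means are defined.
#'
#' @param path TSV file path.
#' @return numeric matrix of p-values.
#' @export
readDabgMatrix <- function(path) {
  m <- .readTsvMatrix(path, "DABG matrix")
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop("DABG p-values must lie in [0, 1]: ", path)
  pmin(pmax(m, 1e-16), 1)
}

#' Read the exon/junction design annotation from TSV
#'
#' Expected columns: `probeset_id`, `gene_id`, `kind` (`exon` or
#' `junction`), `exon_index` (exon rows), `exon5` and `exon3` (junction
#' rows), `n_probes`. All structural invariants are checked: unique
#' probeset ids, unique exon ordinals per gene, `exon5 < exon3`, and
#' junction endpoints that exist in the same gene.
#'
#' @param path TSV file path.
#' @return validated annotation `data.frame`.
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("annotation file '", path, "' has no data rows")
  .checkAnnotation(df)
}

#' Read the sample-to-condition design from TSV
#'
#' Expected columns: `sample_id`, `condition`. Exactly two conditions are
#' required; multi-group studies are analyzed pairwise.
#'
#' @param path TSV file path.
#' @return `data.frame` with columns `sample_id`, `condition`.
#' @export
readSampleDesign <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("design file '", path, "' has no data rows")
  .checkDesign(df)
}

#' Read a probe-to-probeset map from TSV
#'
#' Expected columns: `probe_id`, `probeset_id`.
#'
#' @param path TSV file path.
#' @return `data.frame` with columns `probe_id`, `probeset_id`.
#' @export
readProbeMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("probe_id", "probeset_id") %in% colnames(df)))
    stop("probe map needs columns 'probe_id' and 'probeset_id'")
  df$probe_id <- as.character(df$probe_id)
  df$probeset_id <- as.character(df$probeset_id)
  if (anyDuplicated(df$probe_id))
    stop("duplicated probe_id in probe map: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  df
}

.CALL_COLUMNS <- c("gene_id", "probeset_id", "exon_index", "category",
                   "p_value", "si", "supporting_junctions",
                   "best_junction_id", "fc_difference", "presence_flag")

#' Write and read splicing call tables
#'
#' `writeSplicingCalls()` writes one row per exon, ordered by `gene_id`
#' then `exon_index`, with columns `gene_id`, `probeset_id`,
#' `exon_index`, `category`, `p_value`, `si`, `supporting_junctions`
#' (comma-joined), `best_junction_id`, `fc_difference` and
#' `presence_flag`. `readSplicingCalls()` reads the same schema back;
#' the round trip is the identity on all fields (numeric columns are
#' written at full precision).
#'
#' @param calls a [SplicingCalls-class] or a call `data.frame` with the
#'   schema above.
#' @param path output (input) TSV path.
#' @return `writeSplicingCalls()` returns `path` invisibly;
#'   `readSplicingCalls()` returns the call `data.frame`.
#' @export
writeSplicingCalls <- function(calls, path) {
  if (is(calls, "SplicingCalls")) calls <- callTable(calls)
  miss <- setdiff(.CALL_COLUMNS, colnames(calls))
  if (length(miss))
    stop("call table is missing columns: ", paste(miss, collapse = ", "))
  calls <- calls[order(calls$gene_id, calls$exon_index), .CALL_COLUMNS,
                 drop = FALSE]
  num <- c("p_value", "si", "fc_difference")
  out <- calls
  for (col in num)
    out[[col]] <- formatC(calls[[col]], digits = 17, format = "g")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname writeSplicingCalls
#' @export
readSplicingCalls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE,
                   colClasses = c(gene_id = "character",
                                  probeset_id = "character",
                                  exon_index = "integer",
                                  category = "character",
                                  p_value = "numeric", si = "numeric",
                                  supporting_junctions = "character",
                                  best_junction_id = "character",
                                  fc_difference = "numeric",
                                  presence_flag = "logical"))
  miss <- setdiff(.CALL_COLUMNS, colnames(df))
  if (length(miss))
    stop("call file is missing columns: ", paste(miss, collapse = ", "))
  df$supporting_junctions[is.na(df$supporting_junctions)] <- ""
  df
}

#' Write a matrix as TSV with an identifier column
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param idColumn name for the identifier column.
#' @return `path`, invisibly.
#' @export
writeTsvMatrix <- function(m, path, idColumn = "probeset_id") {
  df <- data.frame(id = rownames(m),
                   formatC(m, digits = 17, format = "g"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(idColumn, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Recognized keys: input paths (`exprs`, `probes`, `probe_map`,
#' `annotation`, `design`, `dabg`) and parameters (`p`, `d`, `q`,
#' `presence_threshold`, `min_null_size`, `min_constitutive`, `seed`).
#' Missing parameters fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return named list of configuration values.
#' @export
readRasaConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(p = 0.01, d = 2, q = 0.05, presence_threshold = 0.01,
                   min_null_size = 20L, min_constitutive = 1L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg
}
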