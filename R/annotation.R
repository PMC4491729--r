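# Design annotation: one row per probeset, two kinds.
#   exon rows:     probeset_id, gene_id, kind = "exon", exon_index, n_probes
#   junction rows: probeset_id, gene_id, kind = "junction", exon5, exon3,
#                  n_probes  (exon5 < exon3; both must exist in the gene)

.checkAnnotation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("probeset_id", "gene_id", "kind", "n_probes")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  for (col in c("exon_index", "exon5", "exon3"))
    if (!col %in% colnames(df)) df[[col]] <- NA_integer_
  if (nrow(df) == 0L) stop("annotation has no rows")

  df$probeset_id <- as.character(df$probeset_id)
  df$gene_id <- as.character(df$gene_id)
  df$kind <- as.character(df$kind)
  for (col in c("exon_index", "exon5", "exon3", "n_probes"))
    df[[col]] <- as.integer(df[[col]])

  dup <- df$probeset_id[duplicated(df$probeset_id)]
  if (length(dup))
    stop("duplicated probeset_id in annotation: ",
         paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$kind), c("exon", "junction"))
  if (length(bad))
    stop("annotation 'kind' must be 'exon' or 'junction', found: ",
         paste(bad, collapse = ", "))
  if (any(is.na(df$n_probes)) || any(df$n_probes < 1L))
    stop("n_probes must be a positive integer for every probeset")

  is_ex <- df$kind == "exon"
  ex <- df[is_ex, ]
  jc <- df[!is_ex, ]

  if (any(is.na(ex$exon_index)) || any(ex$exon_index < 1L))
    stop("exon rows need a positive integer exon_index; offending probesets: ",
         paste(ex$probeset_id[is.na(ex$exon_index) | ex$exon_index < 1L],
               collapse = ", "))
  key <- paste(ex$gene_id, ex$exon_index)
  if (anyDuplicated(key))
    stop("exon_index duplicated within a gene for probesets: ",
         paste(ex$probeset_id[duplicated(key) | duplicated(key, fromLast = TRUE)],
               collapse = ", "))

  if (nrow(jc)) {
    bad <- is.na(jc$exon5) | is.na(jc$exon3) | jc$exon5 >= jc$exon3
    if (any(bad))
      stop("junction rows need exon5 < exon3; offending probesets: ",
           paste(jc$probeset_id[bad], collapse = ", "))
    ref5 <- paste(jc$gene_id, jc$exon5) %in% key
    ref3 <- paste(jc$gene_id, jc$exon3) %in% key
    bad <- !(ref5 & ref3)
    if (any(bad))
      stop("junctions referencing exons missing from their gene: ",
           paste(jc$probeset_id[bad], collapse = ", "))
  }
  df
}

#' Junctions connected to or skipping an exon
#'
#' For exon `exonIndex` of `geneId`, returns the junction probesets that
#' include the exon (one of their endpoints is the exon) and those that
#' exclude it (they span across it, `exon5 < exonIndex < exon3`).
#'
#' @param annotation design annotation `data.frame` (see
#'   [readAnnotation()]) or a [SpliceArraySet].
#' @param geneId gene identifier.
#' @param exonIndex 1-based ordinal exon position within the gene.
#' @return list with character vectors `inclusion` and `exclusion` of
#'   junction probeset ids.
#' @examples
#' ann <- data.frame(
#'   probeset_id = c("e1", "e2", "e3", "j12", "j23", "j13"),
#'   gene_id = "g", kind = rep(c("exon", "junction"), each = 3),
#'   exon_index = c(1:3, NA, NA, NA),
#'   exon5 = c(NA, NA, NA, 1, 2, 1), exon3 = c(NA, NA, NA, 2, 3, 3),
#'   n_probes = 4)
#' junctionsForExon(ann, "g", 2)
#' @export
junctionsForExon <- function(annotation, geneId, exonIndex) {
  if (is(annotation, "SpliceArraySet"))
    annotation <- annotationTable(annotation)
  jc <- annotation[annotation$kind == "junction" &
                     annotation$gene_id == geneId, , drop = FALSE]
  list(
    inclusion = jc$probeset_id[jc$exon5 == exonIndex | jc$exon3 == exonIndex],
    exclusion = jc$probeset_id[jc$exon5 < exonIndex & jc$exon3 > exonIndex]
  )
}
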