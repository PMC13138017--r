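# Export of annotations and reports: JSON-lines, BED (0-based half-open per
# BED convention), dot-plot JSON for interactive inspection.

#' Write per-read annotations as JSON lines
#'
#' One JSON object per read: read id, length, chromosome/haplotype call, RU
#' count and structure, spanning flag, segment and feature tables, and motif
#' counts — the schema consumed by dot-plot style interactive viewers.
#'
#' @param annotations named list of \linkS4class{ReadAnnotation}.
#' @param calls named list of \linkS4class{HaplotypeCall} (optional).
#' @param path output path.
#' @return invisibly, \code{path}
#' @export
writeAnnotationJsonl <- function(annotations, path, calls = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(annotations)) {
    ann <- annotations[[id]]
    cl <- if (!is.null(calls)) calls[[id]] else NULL
    rec <- list(
      read = ann@read_id, length = ann@read_length,
      chrom = if (is.null(cl)) NA else cl@chrom,
      haplotype = if (is.null(cl)) NA else haplotypeLabel(cl),
      conflict = if (is.null(cl)) NA else cl@conflict,
      RU = sum(ruStructure(ann)),
      structure = .structure_label(ruStructure(ann)),
      spanning = isSpanning(ann),
      distal_partial_len = distalPartialLength(ann),
      inverted_upstream = !is.na(ann@inverted_upstream),
      segments = ann@segments,
      features = ann@features[, c("feature", "read_start", "read_end",
                                  "strand", "identity")],
      motif_counts = lapply(ann@motif_sites, nrow))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 6,
                                dataframe = "rows", na = "null"), con)
  }
  invisible(path)
}

#' Write read-space annotation intervals as BED
#'
#' Unit and feature intervals in read space, 0-based half-open, score =
#' identity x 1000, for genome-browser-style inspection of single reads.
#'
#' @param annotations named list of \linkS4class{ReadAnnotation}.
#' @param path output path.
#' @return invisibly, \code{path}
#' @export
writeAnnotationBed <- function(annotations, path) {
  rows <- list()
  for (id in names(annotations)) {
    ann <- annotations[[id]]
    u <- ann@units
    if (nrow(u))
      rows[[paste0(id, "_u")]] <- data.frame(
        chrom = ann@read_id, start = u$read_start - 1L, end = u$read_end,
        name = paste0("D4Z4_", u$completeness),
        score = as.integer(round(u$identity * 1000)), strand = u$strand)
    f <- ann@features
    if (nrow(f))
      rows[[paste0(id, "_f")]] <- data.frame(
        chrom = ann@read_id, start = f$read_start - 1L, end = f$read_end,
        name = f$feature, score = as.integer(round(f$identity * 1000)),
        strand = f$strand)
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), name = character(0),
                        score = integer(0), strand = character(0))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Dot-plot JSON export
#'
#' The compact per-read export for the interactive dot view: one dot per read
#' with x = haplotype group, y = RU count, spanning flag.
#'
#' @param annotations named list of \linkS4class{ReadAnnotation}.
#' @param calls named list of \linkS4class{HaplotypeCall}.
#' @param path output path.
#' @return invisibly, \code{path}
#' @export
writeDotJson <- function(annotations, calls, path) {
  dots <- lapply(names(annotations), function(id) {
    list(read = id, chrom = calls[[id]]@chrom,
         haplotype = haplotypeLabel(calls[[id]]),
         RU = sum(ruStructure(annotations[[id]])),
         spanning = isSpanning(annotations[[id]]))
  })
  jsonlite::write_json(dots, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write the allele report table as TSV
#' @param tab data.frame from [reportTable()].
#' @param path output path.
#' @return invisibly, \code{path}
#' @export
writeReportTsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
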