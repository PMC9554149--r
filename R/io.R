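# Plain-text readers/writers for the pipeline's interchange formats:
# expression TSV (genes x samples), sample label TSV, membrane-topology TSV,
# FASTA (via Biostrings), and GMT gene-set files.

#' Read / write an expression matrix as TSV
#'
#' Genes as rows (first column `gene_id`), samples as columns.
#'
#' @param path File path.
#' @param scale Expression scale tag, `"count"` or `"tpm"`.
#' @return [read_expression_tsv()]: an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, scale = c("count", "tpm")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, scale = match.arg(scale))
}

#' @rdname read_expression_tsv
#' @param expr Expression matrix to write.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample label table
#'
#' Columns: `sample_id`, `class` (e.g. BMP / NBMP), `subgroup`.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_labels_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_labels_tsv
#' @param labels Label data.frame to write.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein topology records from TSV + FASTA
#'
#' The topology TSV has columns `protein_id`, `gene_id`, `segment_type`,
#' `start`, `end` (1-based inclusive); sequences come from a FASTA file
#' keyed by `protein_id`.
#'
#' @param topology_path Topology TSV path.
#' @param fasta_path FASTA path.
#' @return List of [protein_record] objects.
#' @export
read_protein_records <- function(topology_path, fasta_path) {
  topo <- utils::read.delim(topology_path, stringsAsFactors = FALSE)
  seqs <- Biostrings::readAAStringSet(fasta_path)
  seq_by_id <- stats::setNames(as.character(seqs), names(seqs))
  lapply(split(topo, topo$protein_id), function(tp) {
    pid <- tp$protein_id[1]
    if (!pid %in% names(seq_by_id)) stop("no sequence for protein ", pid)
    protein_record(pid, tp$gene_id[1], seq_by_id[[pid]],
                   tp[, c("segment_type", "start", "end")])
  })
}

#' Write protein records to TSV + FASTA
#'
#' @param records List of [protein_record] objects.
#' @inheritParams read_protein_records
#' @export
write_protein_records <- function(records, topology_path, fasta_path) {
  topo <- do.call(rbind, lapply(records, function(r) {
    data.frame(protein_id = r$protein_id, gene_id = r$gene_id,
               r$segments, stringsAsFactors = FALSE)
  }))
  utils::write.table(topo, topology_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(records, `[[`, character(1), "protein_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(list(topology = topology_path, fasta = fasta_path))
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated `name`, `description`, members.
#'
#' @param path File path.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
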