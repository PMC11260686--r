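#' Default MAF column mapping
#'
#' Maps internal record fields onto the tab-delimited MAF-like header.
#' Real MAF dialects vary; pass a modified copy to [read_maf()] to adapt.
#'
#' @return named character vector (internal field -> file column).
#' @export
maf_columns <- function() {
  c(donor_id = "Tumor_Sample_Barcode",
    tissue = "Project_Code",
    gene = "Hugo_Symbol",
    variant_class = "Variant_Classification",
    position = "Position",
    ref_allele = "Reference_Allele",
    alt_allele = "Tumor_Seq_Allele2")
}

#' Read a MAF-like mutation table
#'
#' Tab-delimited with a header naming the required columns in any order;
#' extra columns are ignored. Rows missing required fields are rejected
#' with line-numbered errors.
#'
#' @param path file path.
#' @param columns column mapping, see [maf_columns()].
#' @return mutation record data frame.
#' @export
read_maf <- function(path, columns = maf_columns()) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  missing <- setdiff(unname(columns), names(df))
  if (length(missing))
    stop("MAF header is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rec <- df[, unname(columns)]
  names(rec) <- names(columns)
  rec$position <- suppressWarnings(as.integer(rec$position))
  bad <- which(is.na(rec$donor_id) | !nzchar(rec$donor_id) |
               is.na(rec$tissue) | !nzchar(rec$tissue) |
               is.na(rec$gene) | !nzchar(rec$gene) |
               is.na(rec$position) | rec$position < 1)
  if (length(bad))
    stop("malformed MAF rows at line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "),
         " (header is line 1)", call. = FALSE)
  rownames(rec) <- NULL
  rec
}

#' Write a mutation table in MAF-like format
#'
#' @param records mutation table.
#' @param path file path.
#' @param columns column mapping, see [maf_columns()].
#' @export
write_maf <- function(records, path, columns = maf_columns()) {
  check_records(records)
  out <- records[, names(columns)]
  names(out) <- unname(columns)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a census membership list
#'
#' Plain text, one gene per line; blank lines ignored.
#'
#' @param path file path.
#' @return character vector of gene names.
#' @export
read_census <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname read_census
#' @param genes character vector of census gene names.
#' @export
write_census <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Write a gene catalog as FASTA plus census list
#'
#' @param catalog a [generate_catalog()] data frame.
#' @param fasta_path,census_path output paths.
#' @export
write_catalog <- function(catalog, fasta_path, census_path) {
  seqs <- Biostrings::DNAStringSet(
    stats::setNames(catalog$sequence, catalog$gene))
  Biostrings::writeXStringSet(seqs, fasta_path)
  write_census(catalog$gene[catalog$is_census], census_path)
  invisible(fasta_path)
}

#' Read a gene catalog from FASTA plus census list
#'
#' @param fasta_path,census_path input paths.
#' @return `gene_catalog` data frame.
#' @export
read_catalog <- function(fasta_path, census_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  census <- read_census(census_path)
  structure(
    data.frame(gene = names(seqs),
               is_census = names(seqs) %in% census,
               sequence = as.character(seqs),
               stringsAsFactors = FALSE),
    class = c("gene_catalog", "data.frame"))
}

#' Write sample sequences and the reference as FASTA
#'
#' Record ids are donor ids; the reference is written under id `WT`.
#'
#' @param samples list of `sample_sequence` objects.
#' @param reference a [build_reference()] result.
#' @param path output path.
#' @export
write_sample_fasta <- function(samples, reference, path) {
  seqs <- c(stats::setNames(
    vapply(samples, `[[`, character(1), "sequence"),
    vapply(samples, `[[`, character(1), "donor_id")),
    WT = reference$sequence)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

collapse_counts <- function(x) {
  if (!length(x)) return("")
  paste(sprintf("%s:%d", names(x), as.integer(unlist(x))), collapse = "|")
}

#' Write a sequence-node table as TSV
#'
#' @param nodes a `sequence_nodes` data frame.
#' @param path output path.
#' @export
write_node_table <- function(nodes, path) {
  out <- data.frame(
    node_id = nodes$node_id,
    count = nodes$count,
    dominant_tissue = ifelse(is.na(nodes$dominant_tissue), "",
                             nodes$dominant_tissue),
    is_wildtype = nodes$is_wildtype,
    tissue_counts = vapply(nodes$tissue_counts, collapse_counts,
                           character(1)),
    genes = vapply(nodes$genes, paste, character(1), collapse = ";"),
    donors = vapply(nodes$donors, paste, character(1), collapse = ";"),
    sequence = nodes$sequence,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a graph as a weighted TSV edge list
#'
#' Columns `source_id`, `target_id`, `weight`, in deterministic
#' (source, target) order.
#'
#' @param graph an igraph with edge attribute `weight`.
#' @param path output path.
#' @export
write_edge_list <- function(graph, path) {
  e <- edge_table(graph)
  names(e) <- c("source_id", "target_id", "weight")
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a graph as GraphML
#'
#' Node attributes (occurrence count, dominant tissue, wild-type flag,
#' census membership) travel with the graph.
#'
#' @param graph an igraph.
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
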