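# shared fixtures: all built in code, no stored data

`%||%` <- function(a, b) if (is.null(a)) b else a

rec <- function(donor, tissue, gene, class, pos, ref, alt) {
  data.frame(donor_id = donor, tissue = tissue, gene = gene,
             variant_class = class, position = as.integer(pos),
             ref_allele = ref, alt_allele = alt, stringsAsFactors = FALSE)
}

# small catalog with known sequences for hand-checkable transforms
toy_catalog <- function() {
  structure(data.frame(
    gene = c("G1", "G2"),
    is_census = c(TRUE, FALSE),
    sequence = c("ACGTACG", "TTAA"),
    stringsAsFactors = FALSE), class = c("gene_catalog", "data.frame"))
}

random_seqs <- function(n, len_range = c(5, 100)) {
  vapply(seq_len(n), function(i) {
    L <- sample(seq(len_range[1], len_range[2]), 1)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

distinct_random_seqs <- function(n, len_range = c(5, 100)) {
  s <- unique(random_seqs(2 * n, len_range))
  while (length(s) < n) s <- unique(c(s, random_seqs(n, len_range)))
  s[seq_len(n)]
}

small_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_samples = 60, n_census_genes = 3, n_noncensus_genes = 6,
                   gene_length_range = c(60L, 120L),
                   planted_recurrent_sites = 2, passenger_rate = 1,
                   indel_fraction = 0, seed = 42)
  do.call(synthetic_spec, utils::modifyList(defaults, args))
}

expect_same_edges <- function(g1, g2) {
  expect_identical(edge_table(g1), edge_table(g2))
}

# independent oracle: distinct-donor count per (gene,position,ref,alt)
oracle_donor_counts <- function(records) {
  key <- paste(records$gene, records$position, records$ref_allele,
               records$alt_allele, sep = "\t")
  tab <- unique(data.frame(key = key, donor = records$donor_id))
  table(tab$key)
}
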