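#' Variant classes excluded by default
#'
#' The non-coding classes removed before any frequency-based filtering:
#' intergenic region, intron, 5' flank and lincRNA calls.
#'
#' @return character vector of class names.
#' @export
default_excluded_classes <- function() {
  c("IGR", "Intron", "5'Flank", "lincRNA")
}

check_records <- function(records) {
  req <- c("donor_id", "tissue", "gene", "variant_class", "position",
           "ref_allele", "alt_allele")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("mutation table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(records)
}

#' Remove non-coding variant classes
#'
#' Keeps exactly the records whose variant class is not in `excluded`,
#' preserving input order. Class strings are compared after trimming
#' whitespace; `class_synonyms` maps dialect spellings onto canonical
#' names before matching (e.g. a curly-quote `5'Flank`).
#'
#' @param records mutation table (see [generate_cohort()] for columns).
#' @param excluded character vector of classes to drop.
#' @param class_synonyms named character vector, `names` are dialect
#'   spellings and values the canonical class they stand for.
#' @return filtered mutation table.
#' @export
filter_variant_classes <- function(records,
                                   excluded = default_excluded_classes(),
                                   class_synonyms = NULL) {
  check_records(records)
  cls <- trimws(records$variant_class)
  if (!is.null(class_synonyms)) {
    hit <- match(cls, names(class_synonyms))
    cls[!is.na(hit)] <- unname(class_synonyms[hit[!is.na(hit)]])
  }
  out <- records[!(cls %in% trimws(excluded)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# distinct-donor count per mutation identity
distinct_donor_counts <- function(records) {
  key <- mut_key(records)
  first <- !duplicated(paste(key, records$donor_id, sep = "\r"))
  table(key[first])
}

#' Keep recurrent mutations in census genes
#'
#' Among records in census genes, a record survives iff its mutation
#' identity (gene, position, ref, alt) is carried by at least two distinct
#' donors; duplicate calls within one donor do not count. Records in
#' non-census genes pass through untouched for the next stage.
#'
#' @param records class-filtered mutation table.
#' @param census_genes character vector of census gene names.
#' @return filtered mutation table.
#' @export
recurrent_census_filter <- function(records, census_genes) {
  check_records(records)
  if (nrow(records) == 0) return(records)
  is_cen <- records$gene %in% census_genes
  cnt <- distinct_donor_counts(records)
  keep <- !is_cen | as.vector(cnt[mut_key(records)]) >= 2L
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep the top-frequency non-census mutations per cancer type
#'
#' For each tissue independently, the distinct gene-mutation pairs of
#' non-census genes are ranked by distinct-donor count (descending) and the
#' top `ceiling(fraction * P_t)` pairs are kept, where `P_t` is the number
#' of distinct non-census pairs in that tissue; pairs tied with the
#' last-kept pair's count are all kept, so the result is
#' permutation-invariant. A record is retained if its pair is kept in any
#' tissue. Census-gene records pass through untouched.
#'
#' @param records class-filtered mutation table.
#' @param census_genes character vector of census gene names.
#' @param fraction fraction of pairs to keep per tissue, in (0, 1].
#' @return filtered mutation table.
#' @export
top_frequency_filter <- function(records, census_genes, fraction = 0.04) {
  check_records(records)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  if (nrow(records) == 0) return(records)
  is_cen <- records$gene %in% census_genes
  nc <- records[!is_cen, , drop = FALSE]
  kept_keys <- character(0)
  for (t in unique(nc$tissue)) {
    rt <- nc[nc$tissue == t, , drop = FALSE]
    cnt <- distinct_donor_counts(rt)
    k <- ceiling(fraction * length(cnt))
    cutoff <- sort(as.integer(cnt), decreasing = TRUE)[k]
    kept_keys <- union(kept_keys, names(cnt)[as.integer(cnt) >= cutoff])
  }
  keep <- is_cen | mut_key(records) %in% kept_keys
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full data-reduction pipeline
#'
#' Composes the three filters in order -- variant-class exclusion,
#' census-gene recurrence, non-census per-tissue top-frequency -- and
#' returns the surviving records together with a count report. Donors
#' (and tissues, genes) with zero surviving mutations are absent from the
#' report's final counts.
#'
#' @inheritParams top_frequency_filter
#' @param excluded variant classes to drop first.
#' @return list with elements `records` (filtered table) and `report`
#'   (a `filter_report`).
#' @export
run_filter_pipeline <- function(records, census_genes,
                                excluded = default_excluded_classes(),
                                fraction = 0.04) {
  check_records(records)
  a <- filter_variant_classes(records, excluded)
  b <- recurrent_census_filter(a, census_genes)
  fin <- top_frequency_filter(b, census_genes, fraction)
  genes <- unique(fin$gene)
  report <- structure(list(
    n_input = nrow(records),
    n_after_class_filter = nrow(a),
    n_final_mutations = nrow(fin),
    n_genes_final = length(genes),
    n_donors_final = length(unique(fin$donor_id)),
    n_tissues_final = length(unique(fin$tissue)),
    census_genes_kept = sum(genes %in% census_genes),
    noncensus_genes_kept = sum(!genes %in% census_genes)
  ), class = "filter_report")
  list(records = fin, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Mutation filter report\n")
  cat(sprintf("  input mutations:       %d\n", x$n_input))
  cat(sprintf("  after class filter:    %d\n", x$n_after_class_filter))
  cat(sprintf("  final mutations:       %d\n", x$n_final_mutations))
  cat(sprintf("  genes kept:            %d (%d census + %d non-census)\n",
              x$n_genes_final, x$census_genes_kept, x$noncensus_genes_kept))
  cat(sprintf("  donors kept:           %d\n", x$n_donors_final))
  cat(sprintf("  tissues kept:          %d\n", x$n_tissues_final))
  invisible(x)
}
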