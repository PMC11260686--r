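#' Build the transformed reference sequence
#'
#' Concatenates the wild-type base at every distinct recurrently mutated
#' locus (gene, position) present in the filtered mutation table, in a
#' fixed order (genes in `gene_order`, positions ascending within gene).
#' The order is identical for every sample, so downstream edit distances
#' are unaffected by it. SNV and deletion reference alleles are checked
#' against the catalog sequence; a disagreement is a data inconsistency
#' and raises an error.
#'
#' @param records filtered mutation table.
#' @param catalog gene catalog (`gene`, `sequence` columns).
#' @param gene_order optional character vector fixing the gene
#'   concatenation order; defaults to lexicographic.
#' @return object of class `transformed_reference` with fields `loci`
#'   (data frame `gene`, `position`, `wildtype_base`), `sequence`, and
#'   `index` (named offsets into `sequence`).
#' @export
build_reference <- function(records, catalog, gene_order = NULL) {
  check_records(records)
  genes_present <- unique(records$gene)
  unknown <- setdiff(genes_present, catalog$gene)
  if (length(unknown))
    stop("genes absent from catalog: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  gene_order <- gene_order %||% sort(genes_present)
  if (!all(genes_present %in% gene_order))
    stop("gene_order does not cover all genes present", call. = FALSE)

  loci <- unique(records[, c("gene", "position")])
  loci <- loci[order(match(loci$gene, gene_order), loci$position), ,
               drop = FALSE]
  rownames(loci) <- NULL
  gseq <- stats::setNames(catalog$sequence, catalog$gene)
  glen <- nchar(gseq)
  bad <- loci$position > glen[loci$gene] | loci$position < 1
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("position %d outside gene %s (length %d)",
                 loci$position[i], loci$gene[i], glen[[loci$gene[i]]]),
         call. = FALSE)
  }
  loci$wildtype_base <- substr(gseq[loci$gene], loci$position, loci$position)

  # reference alleles (SNV or deletion) must match the catalog
  chk <- records[records$ref_allele != "-", , drop = FALSE]
  if (nrow(chk)) {
    obs <- substr(gseq[chk$gene], chk$position,
                  chk$position + nchar(chk$ref_allele) - 1L)
    bad <- obs != chk$ref_allele
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf(
        "ref allele '%s' at %s:%d disagrees with catalog sequence ('%s')",
        chk$ref_allele[i], chk$gene[i], chk$position[i], obs[i]),
        call. = FALSE)
    }
  }

  structure(list(
    loci = loci,
    sequence = paste(loci$wildtype_base, collapse = ""),
    index = stats::setNames(seq_len(nrow(loci)),
                            locus_key(loci$gene, loci$position))
  ), class = "transformed_reference")
}

#' @export
print.transformed_reference <- function(x, ...) {
  cat(sprintf("Transformed reference: %d tracked loci over %d genes\n",
              nrow(x$loci), length(unique(x$loci$gene))))
  invisible(x)
}

#' Apply one donor's mutations to the transformed reference
#'
#' Starting from the reference string, an SNV replaces the base at its
#' tracked offset, a deletion drops every tracked locus its span covers,
#' and an insertion places the alternate bases immediately after its
#' tracked offset. Edits are resolved per locus (mark-and-build), which is
#' equivalent to splicing in descending-offset order; at most one edit
#' applies per tracked locus, conflicting SNV alternates for one donor at
#' one locus raise an error, and a locus that is both substituted and
#' deleted resolves to deleted.
#'
#' @param reference a [build_reference()] result.
#' @param donor_records mutation records of a single donor; every
#'   (gene, position) must be a tracked locus.
#' @return `sample_sequence` list: `donor_id`, `tissue`, `sequence`,
#'   `mutated_genes`.
#' @export
apply_mutations <- function(reference, donor_records) {
  check_records(donor_records)
  stopifnot(inherits(reference, "transformed_reference"))
  if (nrow(donor_records) == 0)  # wild-type donor
    return(structure(list(donor_id = NA_character_, tissue = NA_character_,
                          sequence = reference$sequence,
                          mutated_genes = character(0)),
                     class = "sample_sequence"))
  if (length(unique(donor_records$donor_id)) != 1)
    stop("donor_records must belong to a single donor", call. = FALSE)
  r <- unique(donor_records[, c("gene", "position", "ref_allele",
                                "alt_allele")])
  off <- reference$index[locus_key(r$gene, r$position)]
  if (anyNA(off)) {
    i <- which(is.na(off))[1]
    stop(sprintf("mutation at %s:%d is not a tracked locus",
                 r$gene[i], r$position[i]), call. = FALSE)
  }
  type <- ifelse(r$ref_allele == "-", "ins",
                 ifelse(r$alt_allele == "-", "del", "snv"))
  snv <- which(type == "snv")
  if (anyDuplicated(off[snv])) {
    dup <- off[snv][duplicated(off[snv])][1]
    alts <- unique(r$alt_allele[snv][off[snv] == dup])
    if (length(alts) > 1)
      stop(sprintf("conflicting SNVs at locus %s for donor %s: %s",
                   names(reference$index)[dup], donor_records$donor_id[1],
                   paste(alts, collapse = " vs ")), call. = FALSE)
  }

  L <- nrow(reference$loci)
  keep <- rep(TRUE, L)
  repl <- strsplit(reference$sequence, "")[[1]]
  ins_after <- vector("list", L)
  ord <- order(off, match(type, c("del", "snv", "ins")), r$alt_allele)
  for (i in ord) {
    o <- off[[i]]
    switch(type[i],
      snv = { repl[o] <- r$alt_allele[i] },
      del = {
        span <- r$position[i] + seq_len(nchar(r$ref_allele[i])) - 1L
        cov <- reference$index[locus_key(r$gene[i], span)]
        keep[cov[!is.na(cov)]] <- FALSE
      },
      ins = {
        ins_after[[o]] <- c(ins_after[[o]], r$alt_allele[i])
      })
  }
  parts <- ifelse(keep, repl, "")
  for (o in seq_len(L)) {
    if (!is.null(ins_after[[o]]))
      parts[o] <- paste0(parts[o], paste(ins_after[[o]], collapse = ""))
  }
  structure(list(
    donor_id = donor_records$donor_id[1],
    tissue = donor_records$tissue[1],
    sequence = paste(parts, collapse = ""),
    mutated_genes = sort(unique(r$gene))
  ), class = "sample_sequence")
}

#' Apply mutations for every donor in a filtered table
#'
#' @param reference a [build_reference()] result.
#' @param records filtered mutation table.
#' @return list of `sample_sequence` objects, one per donor, in donor-id
#'   order.
#' @export
apply_mutations_all <- function(reference, records) {
  check_records(records)
  donors <- sort(unique(records$donor_id))
  lapply(donors, function(d) {
    apply_mutations(reference, records[records$donor_id == d, , drop = FALSE])
  })
}

#' Collapse identical sample sequences into weighted nodes
#'
#' One node per distinct sequence string, carrying its occurrence count,
#' per-tissue counts, the dominant tissue (ties broken lexicographically),
#' the union of causative genes, and the donor list.
#'
#' @param samples list of `sample_sequence` objects.
#' @return `sequence_nodes` data frame with list columns `tissue_counts`,
#'   `genes`, `donors`.
#' @export
collapse_duplicates <- function(samples) {
  stopifnot(length(samples) > 0)
  seqs <- vapply(samples, `[[`, character(1), "sequence")
  tissues <- vapply(samples, `[[`, character(1), "tissue")
  donors <- vapply(samples, `[[`, character(1), "donor_id")
  uniq <- unique(seqs)
  idx <- split(seq_along(seqs), factor(seqs, levels = uniq))
  rows <- lapply(seq_along(uniq), function(i) {
    j <- idx[[i]]
    tc <- sort(table(tissues[j]), decreasing = TRUE)
    # dominant tissue: max count, tie broken by lexicographic order
    top <- names(tc)[tc == max(tc)]
    list(sequence = uniq[i],
         count = length(j),
         tissue_counts = as.list(tc)[order(names(tc))],
         dominant_tissue = sort(top)[1],
         genes = sort(unique(unlist(lapply(samples[j], `[[`,
                                           "mutated_genes")))),
         donors = sort(donors[j]))
  })
  structure(data.frame(
    node_id = sprintf("N%04d", seq_along(rows)),
    sequence = vapply(rows, `[[`, character(1), "sequence"),
    count = vapply(rows, `[[`, integer(1), "count"),
    dominant_tissue = vapply(rows, `[[`, character(1), "dominant_tissue"),
    is_wildtype = FALSE,
    tissue_counts = I(lapply(rows, `[[`, "tissue_counts")),
    genes = I(lapply(rows, `[[`, "genes")),
    donors = I(lapply(rows, `[[`, "donors")),
    stringsAsFactors = FALSE
  ), class = c("sequence_nodes", "data.frame"))
}

#' Add the wild-type reference node
#'
#' If the unmutated reference string is already among the nodes it is
#' flagged; otherwise a zero-occurrence wild-type node is appended (the
#' one node allowed an occurrence count of 0). The wild-type node serves
#' as the pivot sequence of the DiWANN construction.
#'
#' @param nodes a [collapse_duplicates()] result.
#' @param reference a [build_reference()] result.
#' @return `sequence_nodes` data frame including the wild-type node.
#' @export
add_wildtype_node <- function(nodes, reference) {
  stopifnot(inherits(reference, "transformed_reference"))
  hit <- which(nodes$sequence == reference$sequence)
  if (length(hit)) {
    nodes$is_wildtype[hit] <- TRUE
    return(nodes)
  }
  wt <- data.frame(
    node_id = "WT", sequence = reference$sequence, count = 0L,
    dominant_tissue = NA_character_, is_wildtype = TRUE,
    tissue_counts = I(list(list())), genes = I(list(character(0))),
    donors = I(list(character(0))), stringsAsFactors = FALSE)
  out <- rbind(nodes, wt)
  rownames(out) <- NULL
  class(out) <- c("sequence_nodes", "data.frame")
  out
}
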