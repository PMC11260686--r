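#' Default tissue mix for synthetic cohorts
#'
#' Twenty-five cancer types with geometrically skewed proportions, so one
#' type (here pancreatic) dominates the cohort the way a real pan-cancer
#' consensus callset is dominated by its largest projects, while the tail
#' types contribute only a handful of donors.
#'
#' @param n_tissues number of cancer types (at most 25).
#' @param skew geometric decay applied to successive types; 1 gives a
#'   uniform mix.
#' @return named numeric vector of proportions summing to 1.
#' @export
default_tissue_proportions <- function(n_tissues = 25, skew = 0.82) {
  labels <- c("Pancreatic", "Lymph", "Prostate", "Liver", "Skin", "Breast",
              "Esophageal", "Myeloid", "Ovary", "Stomach", "Biliary", "CNS",
              "Kidney", "Bone", "Head", "Lung", "Colorectal", "Uterine",
              "Bladder", "Thyroid", "Cervical", "Sarcoma", "Testicular",
              "Mesothelial", "Glioma")
  stopifnot(n_tissues >= 1, n_tissues <= length(labels))
  p <- skew^(seq_len(n_tissues) - 1)
  stats::setNames(p / sum(p), labels[seq_len(n_tissues)])
}

#' Default variant-class mix for synthetic cohorts
#'
#' Dominated by the non-coding classes the variant-class filter removes
#' (intergenic calls being the single largest class), with a coding
#' remainder split across missense, nonsense, silent, splice and
#' frameshift classes.
#'
#' @return named numeric vector of class probabilities summing to 1.
#' @export
default_variant_class_mix <- function() {
  c("IGR" = 0.45, "Intron" = 0.20, "5'Flank" = 0.05, "lincRNA" = 0.05,
    "Missense_Mutation" = 0.14, "Nonsense_Mutation" = 0.03,
    "Silent" = 0.04, "Splice_Site" = 0.02,
    "Frame_Shift_Del" = 0.01, "Frame_Shift_Ins" = 0.01)
}

#' Specification of a synthetic somatic-mutation cohort
#'
#' Bundles every tunable of the generator: cohort size, tissue mix, gene
#' catalog shape, planted recurrent driver sites, passenger noise, and the
#' variant-class mix. The defaults describe a desk-scale cohort with the
#' statistical structure the filtering and network stages assume: a skewed
#' pan-cancer tissue mix, a census-gene subset carrying recurrent planted
#' mutations, non-census genes with a hotspot frequency gradient, and
#' donor-private passenger mutations.
#'
#' @param n_samples number of donors.
#' @param tissue_proportions named probability vector over cancer types;
#'   must sum to 1.
#' @param n_census_genes,n_noncensus_genes catalog composition.
#' @param gene_length_range integer `(min, max)` cDNA lengths, drawn
#'   uniformly.
#' @param planted_recurrent_sites recurrent driver sites planted per
#'   census gene.
#' @param recurrence_depth minimum number of distinct donors sharing each
#'   planted mutation (at least 2).
#' @param passenger_rate expected number of private passenger SNVs per
#'   donor (Poisson).
#' @param variant_class_mix named probability vector over variant classes,
#'   including the excluded non-coding classes; must sum to 1.
#' @param indel_fraction fraction of planted census sites emitted as 1-3 bp
#'   insertions or deletions rather than SNVs.
#' @param seed integer seed; every generator operation derives its own
#'   stream from it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 200,
                           tissue_proportions = default_tissue_proportions(),
                           n_census_genes = 8,
                           n_noncensus_genes = 30,
                           gene_length_range = c(400L, 1200L),
                           planted_recurrent_sites = 3,
                           recurrence_depth = 2,
                           passenger_rate = 2,
                           variant_class_mix = default_variant_class_mix(),
                           indel_fraction = 0.05,
                           seed = 1) {
  spec <- structure(list(
    n_samples = as.integer(n_samples),
    tissue_proportions = tissue_proportions,
    n_census_genes = as.integer(n_census_genes),
    n_noncensus_genes = as.integer(n_noncensus_genes),
    gene_length_range = as.integer(gene_length_range),
    planted_recurrent_sites = as.integer(planted_recurrent_sites),
    recurrence_depth = as.integer(recurrence_depth),
    passenger_rate = passenger_rate,
    variant_class_mix = variant_class_mix,
    indel_fraction = indel_fraction,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  err <- function(field, msg) {
    stop(sprintf("invalid synthetic_spec: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (!isTRUE(spec$n_samples >= 1)) err("n_samples", "must be >= 1")
  tp <- spec$tissue_proportions
  if (is.null(names(tp)) || any(!nzchar(names(tp))))
    err("tissue_proportions", "must be a named vector")
  if (any(tp < 0 | tp > 1)) err("tissue_proportions", "must lie in [0,1]")
  if (abs(sum(tp) - 1) > 1e-9) err("tissue_proportions", "must sum to 1")
  if (!isTRUE(spec$n_census_genes >= 1)) err("n_census_genes", "must be >= 1")
  if (!isTRUE(spec$n_noncensus_genes >= 1))
    err("n_noncensus_genes", "must be >= 1")
  glr <- spec$gene_length_range
  if (length(glr) != 2 || any(glr < 1) || glr[1] > glr[2])
    err("gene_length_range", "must be increasing positive (min, max)")
  if (!isTRUE(spec$planted_recurrent_sites >= 0))
    err("planted_recurrent_sites", "must be >= 0")
  if (!isTRUE(spec$recurrence_depth >= 2)) err("recurrence_depth", "must be >= 2")
  if (!isTRUE(spec$passenger_rate >= 0)) err("passenger_rate", "must be >= 0")
  mix <- spec$variant_class_mix
  if (is.null(names(mix)) || any(!nzchar(names(mix))))
    err("variant_class_mix", "must be a named vector")
  if (any(mix < 0 | mix > 1)) err("variant_class_mix", "must lie in [0,1]")
  if (abs(sum(mix) - 1) > 1e-9) err("variant_class_mix", "must sum to 1")
  if (spec$indel_fraction < 0 || spec$indel_fraction > 1)
    err("indel_fraction", "must lie in [0,1]")
  if (!is.finite(spec$seed)) err("seed", "must be a finite integer")
  invisible(spec)
}

random_dna <- function(length) {
  paste(sample(BASES, length, replace = TRUE), collapse = "")
}

#' Generate a synthetic gene catalog
#'
#' Random cDNA sequences for census (`CGxx`) and non-census (`NGxx`) genes,
#' with lengths drawn uniformly from `spec$gene_length_range`. Deterministic
#' for a fixed spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return `gene_catalog` data frame with columns `gene`, `is_census`,
#'   `sequence`.
#' @export
generate_catalog <- function(spec) {
  validate_spec(spec)
  withr::with_seed(op_seed(spec$seed, "generate_catalog"), {
    n <- spec$n_census_genes + spec$n_noncensus_genes
    genes <- c(sprintf("CG%02d", seq_len(spec$n_census_genes)),
               sprintf("NG%02d", seq_len(spec$n_noncensus_genes)))
    lo <- spec$gene_length_range[1]
    hi <- spec$gene_length_range[2]
    lens <- lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
    seqs <- vapply(lens, random_dna, character(1))
    structure(
      data.frame(gene = genes,
                 is_census = rep(c(TRUE, FALSE),
                                 c(spec$n_census_genes, spec$n_noncensus_genes)),
                 sequence = seqs,
                 stringsAsFactors = FALSE),
      class = c("gene_catalog", "data.frame"))
  })
}

new_records <- function(donor_id, tissue, gene, variant_class, position,
                        ref_allele, alt_allele) {
  data.frame(donor_id = donor_id, tissue = tissue, gene = gene,
             variant_class = variant_class, position = as.integer(position),
             ref_allele = ref_allele, alt_allele = alt_allele,
             stringsAsFactors = FALSE)
}

# alternate base different from each reference base
random_alt <- function(ref) {
  vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1),
         USE.NAMES = FALSE)
}

#' Generate a synthetic mutation cohort
#'
#' Emits a MAF-like mutation table with three layers: (i) planted recurrent
#' sites in census genes, each shared by at least `recurrence_depth`
#' distinct donors with an identical (gene, position, ref, alt) identity
#' (a small fraction become 1-3 bp indels); (ii) non-census hotspot sites
#' whose carrier counts follow a geometric frequency gradient concentrated
#' in a per-gene home tissue, giving the top-frequency filter real
#' structure; and (iii) Poisson passenger SNVs at uniformly random
#' positions, donor-private with probability approaching 1 as the position
#' space grows. Variant classes are drawn from `spec$variant_class_mix` --
#' per site for planted/hotspot mutations (so a recurrent site survives or
#' fails the class filter as a unit) and per record for passengers.
#'
#' At most one mutation is emitted per (donor, gene, position); later
#' colliding draws are dropped deterministically.
#'
#' @param spec a [synthetic_spec()].
#' @param catalog catalog from [generate_catalog()] with a compatible spec.
#' @return data frame of mutation records (`donor_id`, `tissue`, `gene`,
#'   `variant_class`, `position`, `ref_allele`, `alt_allele`), with the
#'   donor table (all donors, including mutation-free ones) attached as
#'   attribute `donors`.
#' @export
generate_cohort <- function(spec, catalog) {
  validate_spec(spec)
  stopifnot(inherits(catalog, "data.frame"),
            all(c("gene", "is_census", "sequence") %in% names(catalog)))
  withr::with_seed(op_seed(spec$seed, "generate_cohort"), {
    donors <- sprintf("DO%04d", seq_len(spec$n_samples))
    tp <- spec$tissue_proportions
    donor_tissue <- stats::setNames(
      sample(names(tp), spec$n_samples, replace = TRUE, prob = tp), donors)
    mix <- spec$variant_class_mix
    draw_class <- function(n) sample(names(mix), n, replace = TRUE, prob = mix)
    out <- list()

    # planted recurrent sites in census genes
    for (gi in which(catalog$is_census)) {
      g <- catalog$gene[gi]
      gseq <- catalog$sequence[gi]
      L <- nchar(gseq)
      k <- spec$planted_recurrent_sites
      if (k == 0) next
      if (k > L)
        stop(sprintf("planted sites (%d) exceed length of gene %s (%d)",
                     k, g, L), call. = FALSE)
      pos <- sort(sample.int(L, k))
      for (p in pos) {
        cls <- draw_class(1)
        depth <- min(spec$recurrence_depth + rpois(1, 1), spec$n_samples)
        carriers <- sample(donors, depth)
        if (runif(1) < spec$indel_fraction) {
          if (runif(1) < 0.5) {  # insertion after p
            ref <- "-"
            alt <- random_dna(sample.int(3, 1))
          } else {               # deletion starting at p
            dl <- min(sample.int(3, 1), L - p + 1L)
            ref <- substr(gseq, p, p + dl - 1L)
            alt <- "-"
          }
        } else {
          ref <- substr(gseq, p, p)
          alt <- random_alt(ref)
        }
        out[[length(out) + 1L]] <- new_records(
          carriers, donor_tissue[carriers], g, cls, p, ref, alt)
      }
    }

    # non-census hotspots: geometric carrier-count gradient, home tissue
    nc <- which(!catalog$is_census)
    for (r in seq_along(nc)) {
      gi <- nc[r]
      g <- catalog$gene[gi]
      gseq <- catalog$sequence[gi]
      L <- nchar(gseq)
      p <- sample.int(L, 1)
      cls <- draw_class(1)
      home <- sample(names(tp), 1, prob = tp)
      m <- min(max(1L, rpois(1, 8 * 0.85^(r - 1))), spec$n_samples)
      w <- ifelse(donor_tissue == home, 4, 1)
      carriers <- sample(donors, m, prob = w)
      ref <- substr(gseq, p, p)
      out[[length(out) + 1L]] <- new_records(
        carriers, donor_tissue[carriers], g, cls, p, ref, random_alt(ref))
    }

    # passenger noise: donor-private SNVs at uniform random positions
    k <- rpois(spec$n_samples, spec$passenger_rate)
    if (sum(k) > 0) {
      d <- rep(donors, k)
      gi <- sample.int(nrow(catalog), length(d), replace = TRUE)
      L <- nchar(catalog$sequence)[gi]
      p <- as.integer(floor(runif(length(d)) * L)) + 1L
      ref <- substr(catalog$sequence[gi], p, p)
      out[[length(out) + 1L]] <- new_records(
        d, donor_tissue[d], catalog$gene[gi], draw_class(length(d)),
        p, ref, random_alt(ref))
    }

    records <- do.call(rbind, out)
    rownames(records) <- NULL
    # one mutation per (donor, gene, position): drop later colliding draws
    records <- records[!duplicated(paste(records$donor_id, records$gene,
                                         records$position, sep = "\t")), ,
                       drop = FALSE]
    rownames(records) <- NULL
    attr(records, "donors") <- data.frame(
      donor_id = donors, tissue = unname(donor_tissue),
      stringsAsFactors = FALSE)
    records
  })
}
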