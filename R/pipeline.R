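#' Pipeline configuration
#'
#' Exactly one input source must be given: a [synthetic_spec()] (the
#' cohort is generated and written alongside the outputs), or paths to a
#' MAF-like table, a catalog FASTA and a census list.
#'
#' @param spec optional [synthetic_spec()].
#' @param maf,catalog_fasta,census optional input file paths.
#' @param excluded_classes variant classes removed first.
#' @param top_fraction non-census top-frequency fraction per tissue.
#' @param threshold_ssn also build the threshold similarity network.
#' @param ssn_threshold edit-distance cutoff for the threshold network.
#' @param resolutions Louvain resolutions to sweep.
#' @param louvain_seed seed for the clustering heuristic.
#' @param alpha enrichment significance level.
#' @param cutoffs list of projection weight cutoffs for the top-weight
#'   tables: `tissue_projection`, `gene_projection`,
#'   `cooccurrence_projection`, `per_type`.
#' @param outdir output directory (created if needed).
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(spec = NULL, maf = NULL, catalog_fasta = NULL,
                            census = NULL,
                            excluded_classes = default_excluded_classes(),
                            top_fraction = 0.04,
                            threshold_ssn = TRUE, ssn_threshold = 2,
                            resolutions = c(0.5, 1, 1.5),
                            louvain_seed = 1, alpha = 0.05,
                            cutoffs = list(tissue_projection = 6,
                                           gene_projection = 7,
                                           cooccurrence_projection = 9,
                                           per_type = 3),
                            outdir = "diwann_output") {
  have_spec <- !is.null(spec)
  have_files <- !is.null(maf) || !is.null(catalog_fasta) || !is.null(census)
  if (have_spec == have_files)
    stop("give exactly one input source: a synthetic spec, or ",
         "maf + catalog_fasta + census paths", call. = FALSE)
  if (have_files && (is.null(maf) || is.null(catalog_fasta) ||
                     is.null(census)))
    stop("file input needs all of maf, catalog_fasta and census",
         call. = FALSE)
  if (have_spec) validate_spec(spec)
  stopifnot(top_fraction > 0, top_fraction <= 1, ssn_threshold >= 1,
            all(resolutions > 0), alpha > 0, alpha < 1)
  structure(list(
    spec = spec, maf = maf, catalog_fasta = catalog_fasta, census = census,
    excluded_classes = excluded_classes, top_fraction = top_fraction,
    threshold_ssn = isTRUE(threshold_ssn),
    ssn_threshold = as.integer(ssn_threshold),
    resolutions = resolutions, louvain_seed = as.integer(louvain_seed),
    alpha = alpha, cutoffs = cutoffs, outdir = outdir
  ), class = "pipeline_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

res_tag <- function(r) sprintf("res%g", r)

#' Run the full analysis pipeline
#'
#' Executes filter -> transformed reference -> per-sample sequences ->
#' DiWANN network (plus optional threshold network) -> structural
#' summary, per-tissue edge statistics, Louvain sweep with enrichment and
#' cluster profiles; and, in parallel, filter -> tissue-gene and
#' sample-gene bipartite networks -> degree tables and weighted one-mode
#' projections (global and per cancer type). All artifacts are written
#' under `config$outdir` and indexed, with their MD5 checksums, in
#' `manifest.json`. Identical config and seeds yield byte-identical
#' artifacts.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out, ...)
  files <- character(0)
  add <- function(path) files <<- c(files, path)

  if (!is.null(config$spec)) {
    catalog <- generate_catalog(config$spec)
    records <- generate_cohort(config$spec, catalog)
    add(write_maf(records, p("cohort.maf.tsv")))
    add(write_catalog(catalog, p("genes.fasta"), p("census.txt")))
    add(p("census.txt"))
    census <- catalog$gene[catalog$is_census]
  } else {
    for (f in c(config$maf, config$catalog_fasta, config$census))
      if (!file.exists(f)) stop("input not found: ", f, call. = FALSE)
    records <- read_maf(config$maf)
    catalog <- read_catalog(config$catalog_fasta, config$census)
    census <- read_census(config$census)
  }

  fil <- run_filter_pipeline(records, census,
                             excluded = config$excluded_classes,
                             fraction = config$top_fraction)
  add(write_maf(fil$records, p("filtered.maf.tsv")))
  add(write_json_file(unclass(fil$report), p("filter_report.json")))

  manifest <- list(
    package = "diwann",
    version = as.character(packageVersion("diwann")),
    config = list(
      synthetic_seed = if (!is.null(config$spec)) config$spec$seed,
      excluded_classes = config$excluded_classes,
      top_fraction = config$top_fraction,
      ssn_threshold = if (config$threshold_ssn) config$ssn_threshold,
      resolutions = config$resolutions,
      louvain_seed = config$louvain_seed,
      alpha = config$alpha,
      cutoffs = config$cutoffs),
    filter_report = unclass(fil$report),
    stages = list("filter")
  )

  if (nrow(fil$records) == 0) {
    manifest$halted <- "no mutations survived filtering"
    manifest$files <- file_index(files, out)
    write_json_file(manifest, p("manifest.json"))
    return(invisible(manifest))
  }

  # sequence similarity branch
  ref <- build_reference(fil$records, catalog)
  samples <- apply_mutations_all(ref, fil$records)
  nodes <- add_wildtype_node(collapse_duplicates(samples), ref)
  add(write_sample_fasta(samples, ref, p("sample_sequences.fasta")))
  add(write_node_table(nodes, p("sequence_nodes.tsv")))

  g <- build_diwann(nodes)
  add(write_edge_list(g, p("diwann_edges.tsv")))
  add(write_graphml(g, p("diwann.graphml")))
  summ <- structural_summary(g)
  add(write_json_file(unclass(summ), p("structural_summary.json")))
  tes <- tissue_edge_stats(g)
  write.table(tes, p("tissue_edge_stats.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  add(p("tissue_edge_stats.tsv"))
  manifest$structural_summary <- unclass(summ)
  manifest$diwann_pruning <- list(
    n_computed = igraph::graph_attr(g, "n_computed"),
    n_avoided = igraph::graph_attr(g, "n_avoided"))
  manifest$stages <- c(manifest$stages, "transform", "diwann")

  if (config$threshold_ssn) {
    ssn <- build_threshold_ssn(nodes, config$ssn_threshold)
    add(write_edge_list(ssn, p("threshold_ssn_edges.tsv")))
    manifest$threshold_ssn <- list(threshold = config$ssn_threshold,
                                   n_nodes = igraph::vcount(ssn),
                                   n_edges = igraph::ecount(ssn))
    manifest$stages <- c(manifest$stages, "threshold_ssn")
  }

  ann <- node_annotations(nodes)
  manifest$clustering <- list()
  for (r in config$resolutions) {
    part <- louvain_clusters(g, r, seed = config$louvain_seed)
    tag <- res_tag(r)
    ptab <- data.frame(node_id = names(part$assignment),
                       cluster = unname(part$assignment),
                       stringsAsFactors = FALSE)
    write.table(ptab, p(sprintf("clusters_%s.tsv", tag)), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add(p(sprintf("clusters_%s.tsv", tag)))
    enr <- fisher_enrichment(part, ann, alpha = config$alpha)
    write.table(enr, p(sprintf("enrichment_%s.tsv", tag)), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add(p(sprintf("enrichment_%s.tsv", tag)))
    prof <- cluster_profiles(part, nodes, fil$records)
    prof$tissue_counts <- vapply(prof$tissue_counts, collapse_counts,
                                 character(1))
    write.table(prof, p(sprintf("cluster_profiles_%s.tsv", tag)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    add(p(sprintf("cluster_profiles_%s.tsv", tag)))
    manifest$clustering[[tag]] <- list(
      resolution = r, n_clusters = part$n_clusters,
      n_enriched = sum(enr$enriched))
  }
  manifest$stages <- c(manifest$stages, "clustering")

  # bipartite branch
  bt <- build_bipartite(fil$records, "tissue")
  bs <- build_bipartite(fil$records, "donor_id")
  add(write_edge_list_unweighted(bt, p("tissue_gene_bipartite.tsv")))
  add(write_edge_list_unweighted(bs, p("sample_gene_bipartite.tsv")))
  for (side in c("left", "right")) {
    for (nm in c("tissue_gene", "sample_gene")) {
      gg <- if (nm == "tissue_gene") bt else bs
      dt <- degree_table(gg, side)
      f <- p(sprintf("degrees_%s_%s.tsv", nm, side))
      write.table(dt, f, sep = "\t", quote = FALSE, row.names = FALSE)
      add(f)
    }
  }
  proj_t <- one_mode_projection(bt, "left")
  proj_g <- one_mode_projection(bt, "right", census)
  proj_sg <- one_mode_projection(bs, "right", census)
  add(write_edge_list(proj_t, p("tissue_projection.tsv")))
  add(write_edge_list(proj_g, p("gene_projection.tsv")))
  add(write_edge_list(proj_sg, p("gene_cooccurrence_projection.tsv")))
  tops <- list(
    tissue_projection_top = top_weight_table(
      proj_t, config$cutoffs$tissue_projection),
    gene_projection_top = top_weight_table(
      proj_g, config$cutoffs$gene_projection),
    gene_cooccurrence_top = top_weight_table(
      proj_sg, config$cutoffs$cooccurrence_projection))
  for (nm in names(tops)) {
    f <- p(paste0(nm, ".tsv"))
    write.table(tops[[nm]], f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    add(f)
  }
  per_type <- per_type_projections(fil$records, census)
  pt_rows <- do.call(rbind, lapply(names(per_type), function(t) {
    tab <- top_weight_table(per_type[[t]], 1)
    if (nrow(tab) == 0) return(NULL)
    cbind(tissue = t, tab)
  }))
  if (is.null(pt_rows))
    pt_rows <- data.frame(tissue = character(0), node1 = character(0),
                          node2 = character(0), weight = integer(0))
  write.table(pt_rows, p("per_type_cooccurrence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  add(p("per_type_cooccurrence.tsv"))
  pt_top <- pt_rows[pt_rows$weight >= config$cutoffs$per_type, ,
                    drop = FALSE]
  write.table(pt_top, p("per_type_cooccurrence_top.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  add(p("per_type_cooccurrence_top.tsv"))
  manifest$bipartite <- list(
    tissue_gene = list(n_nodes = igraph::vcount(bt),
                       n_edges = igraph::ecount(bt)),
    sample_gene = list(n_nodes = igraph::vcount(bs),
                       n_edges = igraph::ecount(bs)))
  manifest$stages <- c(manifest$stages, "bipartite")

  manifest$files <- file_index(files, out)
  write_json_file(manifest, p("manifest.json"))
  invisible(manifest)
}

write_edge_list_unweighted <- function(graph, path) {
  e <- igraph::as_data_frame(graph, what = "edges")
  e <- e[order(e$from, e$to), , drop = FALSE]
  names(e) <- c("source_id", "target_id")
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

file_index <- function(files, outdir) {
  files <- sort(unique(files))
  idx <- lapply(files, function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f))))
  idx
}
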