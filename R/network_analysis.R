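#' Structural summary of a similarity network
#'
#' Node and edge counts, degree statistics (degrees count in- plus
#' out-edges on a directed graph, so the mean degree is exactly `2m/n`),
#' the number of weak components, and the global clustering coefficient
#' (transitivity) computed on the undirected simple view. A graph with no
#' connected triple reports a clustering coefficient of 0.
#'
#' @param graph an igraph.
#' @return `structural_summary` list.
#' @export
structural_summary <- function(graph) {
  if (igraph::vcount(graph) == 0) stop("empty graph", call. = FALSE)
  deg <- igraph::degree(graph, mode = "all")
  und <- igraph::as_undirected(graph, mode = "collapse",
                               edge.attr.comb = list(weight = "min",
                                                     "ignore"))
  tr <- igraph::transitivity(und, type = "global")
  structure(list(
    n_nodes = igraph::vcount(graph),
    n_edges = igraph::ecount(graph),
    max_degree = max(deg),
    min_degree = min(deg),
    avg_degree = 2 * igraph::ecount(graph) / igraph::vcount(graph),
    n_weak_components = igraph::components(graph, mode = "weak")$no,
    global_clustering = if (is.nan(tr)) 0 else tr
  ), class = "structural_summary")
}

#' @export
print.structural_summary <- function(x, ...) {
  cat("Structural summary\n")
  cat(sprintf("  nodes: %d  edges: %d\n", x$n_nodes, x$n_edges))
  cat(sprintf("  degree: max %d, min %d, mean %.3f\n",
              x$max_degree, x$min_degree, x$avg_degree))
  cat(sprintf("  weak components: %d\n", x$n_weak_components))
  cat(sprintf("  global clustering: %.4f\n", x$global_clustering))
  invisible(x)
}

#' Per-tissue edge statistics
#'
#' For each tissue: the number of edges whose source node carries that
#' dominant tissue, and the subset of those whose target shares it. On the
#' DiWANN network this quantifies how connected each cancer type's samples
#' are among themselves.
#'
#' @param graph igraph whose vertices carry a `dominant_tissue` attribute.
#' @return data frame `tissue`, `edges_from`, `edges_within`.
#' @export
tissue_edge_stats <- function(graph) {
  tis <- igraph::vertex_attr(graph, "dominant_tissue")
  if (is.null(tis)) stop("vertices lack a dominant_tissue attribute",
                         call. = FALSE)
  names(tis) <- igraph::V(graph)$name
  ends <- igraph::as_data_frame(graph, what = "edges")
  src <- tis[ends$from]
  dst <- tis[ends$to]
  tissues <- sort(unique(tis[nzchar(tis) & !is.na(tis)]))
  out <- data.frame(
    tissue = tissues,
    edges_from = vapply(tissues, function(t) sum(src == t, na.rm = TRUE),
                        integer(1)),
    edges_within = vapply(tissues, function(t)
      sum(src == t & dst == t, na.rm = TRUE), integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Louvain community detection with a resolution parameter
#'
#' Runs Louvain modularity optimization on the undirected collapsed view
#' of the similarity graph. Edit-distance weights encode dissimilarity, so
#' edges are re-weighted as similarity `1/d` before clustering (the
#' dominant distance-1 edges keep weight 1 and rank order is preserved).
#' Deterministic for a fixed seed. An edgeless graph yields singleton
#' clusters.
#'
#' @param graph igraph with edge attribute `weight` (edit distances).
#' @param resolution positive resolution parameter; larger values favor
#'   more, smaller communities.
#' @param seed integer seed for the heuristic.
#' @return `cluster_partition` list: `resolution`, `seed`, `assignment`
#'   (named vector of 0-based contiguous cluster ids), `n_clusters`.
#' @export
louvain_clusters <- function(graph, resolution = 1, seed = 1) {
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("resolution must be > 0", call. = FALSE)
  und <- igraph::as_undirected(graph, mode = "collapse",
                               edge.attr.comb = list(weight = "min",
                                                     "ignore"))
  if (igraph::ecount(und) == 0) {
    memb <- seq_len(igraph::vcount(und))
  } else {
    w <- 1 / igraph::E(und)$weight
    memb <- withr::with_seed(as.integer(seed), {
      igraph::membership(igraph::cluster_louvain(
        und, weights = w, resolution = resolution))
    })
  }
  ids <- as.integer(factor(memb)) - 1L
  structure(list(
    resolution = resolution,
    seed = as.integer(seed),
    assignment = stats::setNames(ids, igraph::V(und)$name),
    n_clusters = length(unique(ids))
  ), class = "cluster_partition")
}

#' Node annotation table for enrichment tests
#'
#' One row per (node, term): every tissue a node's collapsed samples came
#' from (`cancer_type` terms) and every causative gene mutated in them
#' (`causative_gene` terms). A zero-occurrence wild-type node contributes
#' no annotations.
#'
#' @param nodes a `sequence_nodes` data frame.
#' @return data frame `node`, `term`, `type`.
#' @export
node_annotations <- function(nodes) {
  rows <- lapply(seq_len(nrow(nodes)), function(i) {
    tis <- names(nodes$tissue_counts[[i]])
    gen <- nodes$genes[[i]]
    if (length(tis) + length(gen) == 0) return(NULL)
    data.frame(
      node = nodes$node_id[i],
      term = c(tis, gen),
      type = rep(c("cancer_type", "causative_gene"),
                 c(length(tis), length(gen))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fisher-exact enrichment of cluster annotations
#'
#' For every (cluster, term) pair, the one-sided (greater) Fisher exact
#' test on the 2x2 table splitting all network nodes by cluster membership
#' and term annotation; the p-value is the hypergeometric upper tail.
#' Benjamini-Hochberg adjustment is applied across all tests of a term
#' type, and a pair is called enriched when the adjusted p falls below
#' `alpha`.
#'
#' @param partition a [louvain_clusters()] partition.
#' @param annotations a [node_annotations()] table.
#' @param alpha significance level for the adjusted p-values.
#' @return data frame with one row per (cluster, term): the 2x2 counts
#'   `a` (in cluster, with term), `b`, `c`, `d`, `p_raw`, `p_adjusted`,
#'   `enriched`.
#' @export
fisher_enrichment <- function(partition, annotations, alpha = 0.05) {
  stopifnot(inherits(partition, "cluster_partition"))
  assign <- partition$assignment
  N <- length(assign)
  ann <- unique(annotations[, c("node", "term", "type")])
  unknown <- !(ann$node %in% names(assign))
  if (any(unknown)) {
    warning(sum(unknown), " annotation rows reference nodes outside the ",
            "partition and were dropped")
    ann <- ann[!unknown, , drop = FALSE]
  }
  sizes <- table(assign)
  out <- list()
  for (ty in unique(ann$type)) {
    at <- ann[ann$type == ty, , drop = FALSE]
    term_tot <- table(at$term)
    empty <- names(term_tot)[term_tot == 0]
    if (length(empty))
      warning("terms absent from all nodes omitted: ",
              paste(empty, collapse = ", "))
    at$cluster <- assign[at$node]
    a_tab <- table(factor(at$cluster, levels = names(sizes)), at$term)
    grid <- expand.grid(cluster = names(sizes),
                        term = colnames(a_tab),
                        stringsAsFactors = FALSE)
    a <- a_tab[cbind(grid$cluster, grid$term)]
    size <- as.integer(sizes[grid$cluster])
    tot <- as.integer(term_tot[grid$term])
    b <- size - a
    cc <- tot - a
    d <- N - a - b - cc
    # one-sided (greater) Fisher exact p = hypergeometric upper tail
    p <- phyper(a - 1, tot, N - tot, size, lower.tail = FALSE)
    out[[ty]] <- data.frame(
      cluster = as.integer(grid$cluster), term = grid$term, type = ty,
      a = as.integer(a), b = as.integer(b), c = as.integer(cc),
      d = as.integer(d), p_raw = p,
      p_adjusted = p.adjust(p, method = "BH"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$enriched <- res$p_adjusted < alpha
  res <- res[order(res$type, res$cluster, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-cluster sample profiles
#'
#' Expands each cluster's collapsed nodes back into samples and reports,
#' per cluster: node and sample counts, sample counts per cancer type,
#' the dominant genes (mutated in the most member samples), and the mean
#' mutational load (filtered mutations per member sample).
#'
#' @param partition a [louvain_clusters()] partition.
#' @param nodes the `sequence_nodes` the network was built from.
#' @param records the filtered mutation table.
#' @return data frame with one row per cluster; `tissue_counts` is a list
#'   column of named sample counts.
#' @export
cluster_profiles <- function(partition, nodes, records) {
  stopifnot(inherits(partition, "cluster_partition"))
  check_records(records)
  assign <- partition$assignment
  donor_tissue <- stats::setNames(records$tissue, records$donor_id)
  donor_tissue <- donor_tissue[!duplicated(names(donor_tissue))]
  load <- table(records$donor_id)
  dg <- unique(records[, c("donor_id", "gene")])
  clusters <- sort(unique(assign))
  rows <- lapply(clusters, function(cl) {
    ids <- names(assign)[assign == cl]
    sel <- nodes$node_id %in% ids
    donors <- unlist(nodes$donors[sel], use.names = FALSE)
    gtab <- table(dg$gene[dg$donor_id %in% donors])
    top <- if (length(gtab)) sort(names(gtab)[gtab == max(gtab)]) else
      character(0)
    data.frame(
      cluster = cl,
      n_nodes = sum(sel),
      n_samples = length(donors),
      mean_mutational_load = if (length(donors))
        mean(as.integer(load[donors])) else NA_real_,
      dominant_genes = paste(top, collapse = ";"),
      dominant_gene_samples = if (length(gtab)) max(gtab) else 0L,
      tissue_counts = I(list(as.list(table(donor_tissue[donors])))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
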