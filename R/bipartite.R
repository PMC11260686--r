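#' Build a tissue-gene or sample-gene bipartite network
#'
#' Left nodes are the distinct values of `left_key` (tissues or donors),
#' right nodes the distinct genes; an unweighted edge joins a pair iff at
#' least one mutation record links them (a gene mutated repeatedly in one
#' tissue or sample still yields a single edge).
#'
#' @param records filtered mutation table (non-empty).
#' @param left_key `"tissue"` or `"donor_id"`.
#' @return undirected bipartite igraph; vertex attribute `type` is FALSE
#'   for the left set, TRUE for genes.
#' @export
build_bipartite <- function(records, left_key = c("tissue", "donor_id")) {
  check_records(records)
  left_key <- match.arg(left_key)
  if (nrow(records) == 0) stop("empty mutation table", call. = FALSE)
  pairs <- unique(data.frame(from = records[[left_key]],
                             to = records$gene, stringsAsFactors = FALSE))
  lnodes <- sort(unique(pairs$from))
  rnodes <- sort(unique(pairs$to))
  clash <- intersect(lnodes, rnodes)
  if (length(clash))
    stop("left and gene node names clash: ", paste(clash, collapse = ", "),
         call. = FALSE)
  verts <- data.frame(name = c(lnodes, rnodes),
                      type = rep(c(FALSE, TRUE),
                                 c(length(lnodes), length(rnodes))),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE,
                                     vertices = verts)
  igraph::set_graph_attr(g, "left_key", left_key)
}

#' Degree table of one side of a bipartite network
#'
#' Degrees within the bipartite graph, sorted descending (ties by node
#' name ascending) and filtered at `min_degree`. On the tissue-gene
#' network a gene's degree counts the tissues it mutates in, and a
#' tissue's degree counts its mutated genes.
#'
#' @param graph a [build_bipartite()] graph.
#' @param side `"left"` or `"right"` (genes).
#' @param min_degree drop nodes below this degree.
#' @return data frame `node`, `degree`.
#' @export
degree_table <- function(graph, side = c("left", "right"), min_degree = 0) {
  side <- match.arg(side)
  type <- igraph::V(graph)$type
  sel <- if (side == "left") !type else type
  d <- igraph::degree(graph)[sel]
  out <- data.frame(node = names(d), degree = as.integer(d),
                    stringsAsFactors = FALSE)
  out <- out[out$degree >= min_degree, , drop = FALSE]
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted one-mode projection of a bipartite network
#'
#' Projects onto one side; the weight of an edge (u, v) is the number of
#' shared neighbors of u and v in the other side (e.g. the number of
#' genes through which two tissues are connected). Zero-weight pairs are
#' absent and there are no self-loops.
#'
#' @param graph a [build_bipartite()] graph.
#' @param onto `"left"` or `"right"` (genes).
#' @param census_genes optional census membership; when projecting onto
#'   genes, attaches a logical `is_census` vertex attribute.
#' @return undirected igraph with edge attribute `weight`.
#' @export
one_mode_projection <- function(graph, onto = c("left", "right"),
                                census_genes = NULL) {
  onto <- match.arg(onto)
  pr <- igraph::bipartite_projection(graph, multiplicity = TRUE)
  g <- if (onto == "left") pr$proj1 else pr$proj2
  if (!is.null(census_genes) && onto == "right")
    g <- igraph::set_vertex_attr(g, "is_census",
                                 value = igraph::V(g)$name %in% census_genes)
  g
}

#' Per-cancer-type gene co-occurrence projections
#'
#' For each tissue, restricts the records to that tissue, builds the
#' sample-gene bipartite network and projects onto genes; the weight of
#' (g1, g2) is the number of that tissue's samples mutated in both genes.
#'
#' @param records filtered mutation table.
#' @param census_genes optional census membership for node annotation.
#' @return named list of projection graphs, one per tissue.
#' @export
per_type_projections <- function(records, census_genes = NULL) {
  check_records(records)
  out <- list()
  for (t in sort(unique(records$tissue))) {
    rt <- records[records$tissue == t, , drop = FALSE]
    if (length(unique(rt$donor_id)) < 1) {
      warning("tissue ", t, " has no samples; omitted")
      next
    }
    bg <- build_bipartite(rt, "donor_id")
    out[[t]] <- one_mode_projection(bg, "right", census_genes)
  }
  out
}

#' Restrict a projection to heavy edges
#'
#' Keeps edges with weight at least `min_weight`, then drops nodes left
#' without edges.
#'
#' @param projection a [one_mode_projection()] graph.
#' @param min_weight positive integer cutoff.
#' @return filtered igraph.
#' @export
subset_by_weight <- function(projection, min_weight) {
  if (!is.numeric(min_weight) || length(min_weight) != 1 || min_weight < 1)
    stop("min_weight must be >= 1", call. = FALSE)
  g <- igraph::delete_edges(projection,
                            which(igraph::E(projection)$weight < min_weight))
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))
}

#' Top projection weights as a sorted table
#'
#' @param projection a [one_mode_projection()] graph.
#' @param min_weight report edges with weight at least this.
#' @return data frame `node1`, `node2`, `weight`, sorted by descending
#'   weight then node names.
#' @export
top_weight_table <- function(projection, min_weight = 1) {
  e <- igraph::as_data_frame(projection, what = "edges")
  if (nrow(e) == 0)
    return(data.frame(node1 = character(0), node2 = character(0),
                      weight = integer(0)))
  swap <- e$from > e$to
  tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
  e <- e[e$weight >= min_weight, , drop = FALSE]
  e <- e[order(-e$weight, e$from, e$to), , drop = FALSE]
  out <- data.frame(node1 = e$from, node2 = e$to,
                    weight = as.integer(e$weight), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
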