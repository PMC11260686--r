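#' Edit distance with optional early abandon
#'
#' Unit-cost Levenshtein distance (substitution, insertion, deletion each
#' cost 1). With `abandon_above = k` the banded computation returns
#' `NA_integer_` as soon as the true distance provably exceeds `k`; any
#' distance `<= k` is still returned exactly.
#'
#' @param a,b character strings.
#' @param abandon_above optional non-negative integer bound.
#' @return integer distance, or `NA_integer_` if abandoned.
#' @export
edit_distance <- function(a, b, abandon_above = NULL) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1, length(b) == 1)
  band <- if (is.null(abandon_above)) -1L else as.integer(abandon_above)
  if (band < -1L) stop("abandon_above must be >= 0", call. = FALSE)
  d <- .edit_distance_cpp(a, b, band)
  if (d < 0) NA_integer_ else d
}

as_sequence_nodes <- function(nodes) {
  if (is.character(nodes)) {
    nodes <- data.frame(
      node_id = sprintf("N%04d", seq_along(nodes)), sequence = nodes,
      count = 1L, dominant_tissue = NA_character_, is_wildtype = FALSE,
      stringsAsFactors = FALSE)
  }
  stopifnot(inherits(nodes, "data.frame"),
            all(c("node_id", "sequence") %in% names(nodes)))
  if (is.null(nodes$count)) nodes$count <- 1L
  if (is.null(nodes$dominant_tissue)) nodes$dominant_tissue <- NA_character_
  if (is.null(nodes$is_wildtype)) nodes$is_wildtype <- FALSE
  bad <- !grepl("^[ACGT]*$", nodes$sequence)
  if (any(bad))
    stop("sequences must be over {A,C,G,T}; offending node: ",
         nodes$node_id[which(bad)[1]], call. = FALSE)
  nodes
}

ann_graph <- function(nodes, edges, directed = TRUE) {
  verts <- data.frame(
    name = nodes$node_id,
    count = nodes$count,
    dominant_tissue = ifelse(is.na(nodes$dominant_tissue), "",
                             nodes$dominant_tissue),
    is_wildtype = nodes$is_wildtype,
    sequence = nodes$sequence,
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = directed,
                                vertices = verts)
}

#' Build the DiWANN all-nearest-neighbor network
#'
#' Directed graph on unique sequence nodes in which every node points to
#' all sequences at its minimum edit distance, with that distance as the
#' edge weight. The construction avoids the full distance matrix: the
#' wild-type (reference) node, when present, is used as the pivot whose
#' complete distance row seeds a triangle-inequality lower bound and a
#' per-node current best, after which candidates are pruned by admissible
#' bounds or abandoned early by the banded dynamic program. The edge set
#' is exactly that of the brute-force construction.
#'
#' @param nodes a `sequence_nodes` data frame, or a character vector of
#'   distinct sequences.
#' @return directed igraph with edge attribute `weight` and graph
#'   attributes `n_computed`, `n_pruned`, `n_abandoned`, `n_avoided`
#'   (distance computations saved relative to the full matrix).
#' @export
build_diwann <- function(nodes) {
  nodes <- as_sequence_nodes(nodes)
  n <- nrow(nodes)
  if (n < 2) stop("need at least two sequence nodes", call. = FALSE)
  if (anyDuplicated(nodes$sequence))
    stop("duplicate sequences; collapse them first with collapse_duplicates()",
         call. = FALSE)
  pivot <- which(nodes$is_wildtype)[1]
  if (is.na(pivot)) pivot <- 1L
  res <- .diwann_core_cpp(nodes$sequence, pivot - 1L)
  edges <- data.frame(from = nodes$node_id[res$from],
                      to = nodes$node_id[res$to],
                      weight = res$weight, stringsAsFactors = FALSE)
  g <- ann_graph(nodes, edges, directed = TRUE)
  total_pairs <- n * (n - 1)
  g <- igraph::set_graph_attr(g, "n_computed", res$n_computed)
  g <- igraph::set_graph_attr(g, "n_pruned", res$n_pruned)
  g <- igraph::set_graph_attr(g, "n_abandoned", res$n_abandoned)
  g <- igraph::set_graph_attr(g, "n_avoided", total_pairs - res$n_computed)
  g
}

#' Brute-force all-nearest-neighbor network
#'
#' Ground-truth construction via the full pairwise distance matrix
#' (computed with `utils::adist`, an implementation independent of the
#' pruned search). Used as the oracle that [build_diwann()] must match.
#'
#' @inheritParams build_diwann
#' @return directed igraph with edge attribute `weight`.
#' @export
brute_force_ann <- function(nodes) {
  nodes <- as_sequence_nodes(nodes)
  n <- nrow(nodes)
  if (n < 2) stop("need at least two sequence nodes", call. = FALSE)
  D <- utils::adist(nodes$sequence)
  diag(D) <- NA
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    m <- min(D[i, ], na.rm = TRUE)
    data.frame(from = nodes$node_id[i],
               to = nodes$node_id[which(D[i, ] == m)],
               weight = m, stringsAsFactors = FALSE)
  }))
  ann_graph(nodes, edges, directed = TRUE)
}

#' Build a threshold sequence-similarity network
#'
#' Undirected graph keeping every pair at edit distance at most
#' `threshold`, with the distance as edge weight. Isolated nodes are
#' retained (unlike the all-nearest-neighbor graph, a threshold network
#' can contain singletons).
#'
#' @inheritParams build_diwann
#' @param threshold positive integer distance cutoff.
#' @return undirected igraph with edge attribute `weight`.
#' @export
build_threshold_ssn <- function(nodes, threshold) {
  nodes <- as_sequence_nodes(nodes)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 1)
    stop("threshold must be a positive integer", call. = FALSE)
  threshold <- as.integer(threshold)
  if (anyDuplicated(nodes$sequence))
    stop("duplicate sequences; collapse them first with collapse_duplicates()",
         call. = FALSE)
  n <- nrow(nodes)
  from <- integer(0); to <- integer(0); w <- integer(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d <- .edit_distance_cpp(nodes$sequence[i], nodes$sequence[j],
                                threshold)
        if (d >= 0) {
          from <- c(from, i); to <- c(to, j); w <- c(w, d)
        }
      }
    }
  }
  edges <- data.frame(from = nodes$node_id[from], to = nodes$node_id[to],
                      weight = w, stringsAsFactors = FALSE)
  g <- ann_graph(nodes, edges, directed = FALSE)
  igraph::set_graph_attr(g, "threshold", threshold)
}

#' Canonical edge table of a similarity graph
#'
#' Sorted (source, target, weight) data frame; for undirected graphs the
#' endpoint pair is ordered lexicographically. Two graphs are
#' edge-equivalent iff their canonical tables are identical.
#'
#' @param graph an igraph.
#' @return data frame with columns `from`, `to`, `weight`.
#' @export
edge_table <- function(graph) {
  e <- igraph::as_data_frame(graph, what = "edges")
  if (nrow(e) == 0)
    return(data.frame(from = character(0), to = character(0),
                      weight = integer(0)))
  if (!igraph::is_directed(graph)) {
    swap <- e$from > e$to
    tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
  }
  e <- e[order(e$from, e$to), c("from", "to", "weight")]
  e$weight <- as.numeric(e$weight)
  rownames(e) <- NULL
  e
}
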