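test_that("structural summary matches an independent recomputation", {
  g <- withr::with_seed(201, igraph::sample_gnm(100, 180, directed = TRUE))
  igraph::V(g)$name <- sprintf("N%03d", 1:100)
  s <- structural_summary(g)
  # recompute from the raw edge list
  e <- igraph::as_data_frame(g)
  deg <- table(factor(c(e$from, e$to), levels = igraph::V(g)$name))
  expect_equal(s$n_nodes, 100)
  expect_equal(s$n_edges, 180)
  expect_equal(s$max_degree, max(deg))
  expect_equal(s$min_degree, min(deg))
  expect_equal(s$avg_degree, 2 * 180 / 100)
  expect_equal(s$avg_degree, mean(deg))
  expect_equal(s$n_weak_components,
               igraph::components(igraph::as_undirected(g))$no)

  # a directed 3-cycle closes one triangle on the undirected view
  tri <- igraph::graph_from_literal(A -+ B, B -+ C, C -+ A)
  expect_equal(structural_summary(tri)$global_clustering, 1.0)

  # no connected triple -> clustering reported as 0
  pair <- igraph::make_graph(c("A", "B"), directed = TRUE)
  expect_equal(structural_summary(pair)$global_clustering, 0)
  expect_error(structural_summary(igraph::make_empty_graph(0)), "empty")
})

test_that("tissue edge statistics match a brute-force edge scan", {
  seqs <- withr::with_seed(202, distinct_random_seqs(60, c(8, 20)))
  tissues <- withr::with_seed(203,
    sample(c("Panc", "Liver", "Skin"), 60, replace = TRUE))
  nodes <- data.frame(node_id = sprintf("N%04d", 1:60), sequence = seqs,
                      count = 1L, dominant_tissue = tissues,
                      is_wildtype = FALSE, stringsAsFactors = FALSE)
  g <- build_diwann(nodes)
  st <- tissue_edge_stats(g)
  e <- igraph::as_data_frame(g)
  tmap <- setNames(tissues, nodes$node_id)
  for (t in st$tissue) {
    expect_equal(st$edges_from[st$tissue == t], sum(tmap[e$from] == t))
    expect_equal(st$edges_within[st$tissue == t],
                 sum(tmap[e$from] == t & tmap[e$to] == t))
  }
  expect_true(all(st$edges_within <= st$edges_from))

  # single-tissue graph: within = from
  nodes$dominant_tissue <- "Panc"
  st1 <- tissue_edge_stats(build_diwann(nodes))
  expect_equal(st1$edges_within, st1$edges_from)
})

test_that("Louvain recovers planted cliques and respects the seed", {
  # two 10-cliques joined by a single bridge edge
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(10))
  g <- igraph::add_edges(g, c(1, 11))
  igraph::V(g)$name <- sprintf("V%02d", 1:20)
  igraph::E(g)$weight <- 1
  part <- louvain_clusters(g, resolution = 1, seed = 4)
  expect_equal(part$n_clusters, 2)
  expect_length(unique(part$assignment[1:10]), 1)
  expect_length(unique(part$assignment[11:20]), 1)
  expect_identical(part$assignment,
                   louvain_clusters(g, resolution = 1, seed = 4)$assignment)

  # partition is total with contiguous ids from 0
  expect_setequal(unique(part$assignment), 0:1)
  expect_length(part$assignment, 20)

  single <- igraph::make_empty_graph(1)
  igraph::V(single)$name <- "V1"
  expect_equal(louvain_clusters(single, 1, 1)$n_clusters, 1)
  expect_error(louvain_clusters(g, resolution = 0), "resolution")
})

test_that("cluster count grows with resolution on a fixed graph", {
  seqs <- withr::with_seed(204, distinct_random_seqs(80, c(8, 16)))
  g <- build_diwann(seqs)
  res <- c(0.25, 0.5, 1, 1.5, 2)
  ok <- 0; total <- 0
  for (s in 1:5) {
    k <- vapply(res, function(r)
      louvain_clusters(g, r, seed = s)$n_clusters, integer(1))
    ok <- ok + sum(diff(k) >= 0)
    total <- total + length(res) - 1
  }
  expect_gte(ok / total, 0.9)
})

test_that("Fisher enrichment p-values are the hypergeometric tail", {
  part <- structure(list(resolution = 1, seed = 1,
                         assignment = c(n1 = 0L, n2 = 1L),
                         n_clusters = 2L), class = "cluster_partition")
  ann <- data.frame(node = "n1", term = "Panc", type = "cancer_type")
  res <- fisher_enrichment(part, ann)
  # 2x2 = [1,0;0,1]: one-sided p = 0.5
  r <- res[res$cluster == 0 & res$term == "Panc", ]
  expect_equal(r$a, 1); expect_equal(r$d, 1)
  expect_equal(r$p_raw, 0.5)
  expect_equal(stats::fisher.test(matrix(c(1, 0, 0, 1), 2),
                                  alternative = "greater")$p.value, 0.5)
  # cluster with zero term members: p = 1, not enriched
  r0 <- res[res$cluster == 1 & res$term == "Panc", ]
  expect_equal(r0$a, 0)
  expect_equal(r0$p_raw, 1)
  expect_false(r0$enriched)
})

test_that("enrichment 2x2 margins and BH adjustment are coherent", {
  spec <- small_spec(seed = 51)
  cat_ <- generate_catalog(spec)
  fil <- run_filter_pipeline(generate_cohort(spec, cat_),
                             cat_$gene[cat_$is_census])
  ref <- build_reference(fil$records, cat_)
  nodes <- add_wildtype_node(
    collapse_duplicates(apply_mutations_all(ref, fil$records)), ref)
  g <- build_diwann(nodes)
  part <- louvain_clusters(g, 1, 1)
  ann <- node_annotations(nodes)
  res <- fisher_enrichment(part, ann)
  N <- length(part$assignment)
  sizes <- table(part$assignment)
  expect_true(all(res$a + res$b + res$c + res$d == N))
  expect_equal(res$a + res$b, as.integer(sizes[as.character(res$cluster)]),
               ignore_attr = TRUE)
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_true(all(res$p_raw >= 0 & res$p_raw <= 1))
  # BH is monotone: identical p ordering after adjustment within a type
  for (ty in unique(res$type)) {
    rt <- res[res$type == ty, ]
    expect_true(all(diff(rt$p_adjusted[order(rt$p_raw)]) >= -1e-12))
  }
})

test_that("a planted 100%-pure cluster is flagged as enriched", {
  # one cluster entirely tissue A where A is 10% of nodes overall
  assign <- c(rep(0L, 10), rep(1L, 90))
  names(assign) <- sprintf("n%03d", 1:100)
  part <- structure(list(resolution = 1, seed = 1, assignment = assign,
                         n_clusters = 2L), class = "cluster_partition")
  ann <- data.frame(node = names(assign),
                    term = c(rep("A", 10), rep("B", 90)),
                    type = "cancer_type", stringsAsFactors = FALSE)
  res <- fisher_enrichment(part, ann, alpha = 0.05)
  hit <- res[res$cluster == 0 & res$term == "A", ]
  expect_equal(hit$p_raw, 1 / choose(100, 10))
  expect_true(hit$enriched)
  expect_false(res$enriched[res$cluster == 1 & res$term == "A"])
})

test_that("cluster profiles expand collapsed nodes back into samples", {
  # one node collapsing 3 samples with loads 2, 3 and 4
  r <- rbind(
    rec("d1", "Panc", "G1", "Missense_Mutation", c(1, 2), "A", "T"),
    rec("d2", "Panc", "G1", "Missense_Mutation", c(1, 2, 3), "A", "T"),
    rec("d3", "Liver", "G1", "Missense_Mutation", c(1, 2, 3, 4), "A", "T"))
  nodes <- data.frame(node_id = "N0001", sequence = "AAAA", count = 3L,
                      dominant_tissue = "Panc", is_wildtype = FALSE,
                      tissue_counts = I(list(list(Panc = 2L, Liver = 1L))),
                      genes = I(list("G1")),
                      donors = I(list(c("d1", "d2", "d3"))),
                      stringsAsFactors = FALSE)
  part <- structure(list(resolution = 1, seed = 1,
                         assignment = c(N0001 = 0L), n_clusters = 1L),
                    class = "cluster_partition")
  prof <- cluster_profiles(part, nodes, r)
  expect_equal(prof$n_samples, 3)
  expect_equal(prof$mean_mutational_load, 3.0)
  expect_equal(prof$dominant_genes, "G1")
  expect_equal(prof$tissue_counts[[1]]$Panc, 2L)
  # cluster sizes sum to the node count
  expect_equal(sum(prof$n_nodes), 1)
})

test_that("per-cluster tissue counts match brute-force expansion", {
  spec <- small_spec(n_samples = 100, seed = 61)
  cat_ <- generate_catalog(spec)
  fil <- run_filter_pipeline(generate_cohort(spec, cat_),
                             cat_$gene[cat_$is_census])
  ref <- build_reference(fil$records, cat_)
  nodes <- add_wildtype_node(
    collapse_duplicates(apply_mutations_all(ref, fil$records)), ref)
  part <- louvain_clusters(build_diwann(nodes), 1, 1)
  prof <- cluster_profiles(part, nodes, fil$records)
  expect_equal(sum(prof$n_nodes), length(part$assignment))
  dt <- setNames(fil$records$tissue, fil$records$donor_id)
  dt <- dt[!duplicated(names(dt))]
  for (i in seq_len(nrow(prof))) {
    ids <- names(part$assignment)[part$assignment == prof$cluster[i]]
    donors <- unlist(nodes$donors[nodes$node_id %in% ids])
    expect_equal(sort(unlist(prof$tissue_counts[[i]])),
                 sort(as.vector(table(dt[donors]))), ignore_attr = TRUE)
  }
})
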