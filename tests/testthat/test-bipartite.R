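complete_bipartite_records <- function(tissues, genes) {
  do.call(rbind, lapply(tissues, function(t)
    rec(paste0("d_", t), t, genes, "Missense_Mutation", 1, "A", "T")))
}

test_that("bipartite construction deduplicates and counts nodes", {
  r <- complete_bipartite_records(c("T1", "T2"), c("g1", "g2", "g3"))
  g <- build_bipartite(r, "tissue")
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 6)
  expect_true(igraph::is_bipartite(g))

  # a gene mutated 5 times in one tissue yields a single edge
  r5 <- do.call(rbind, replicate(5, rec("d1", "T1", "g1",
                                        "Missense_Mutation", 1, "A", "T"),
                                 simplify = FALSE))
  expect_equal(igraph::ecount(build_bipartite(r5, "tissue")), 1)
  expect_error(build_bipartite(r5[0, ], "tissue"), "empty")
})

test_that("bipartite node counts equal distinct left + distinct genes", {
  spec <- small_spec(seed = 71)
  cat_ <- generate_catalog(spec)
  fil <- run_filter_pipeline(generate_cohort(spec, cat_),
                             cat_$gene[cat_$is_census])
  for (key in c("tissue", "donor_id")) {
    g <- build_bipartite(fil$records, key)
    expect_equal(igraph::vcount(g),
                 length(unique(fil$records[[key]])) +
                 length(unique(fil$records$gene)))
    # edges only run across the two sets
    e <- igraph::as_data_frame(g)
    type <- setNames(igraph::V(g)$type, igraph::V(g)$name)
    expect_true(all(type[e$from] != type[e$to]))
  }
})

test_that("degree tables sort, tie-break and filter correctly", {
  r <- complete_bipartite_records(c("T1", "T2"), c("g1", "g2", "g3"))
  g <- build_bipartite(r, "tissue")
  dl <- degree_table(g, "left")
  expect_equal(dl$degree, c(3, 3))
  expect_equal(dl$node, c("T1", "T2"))  # tie broken by name
  dr <- degree_table(g, "right")
  expect_equal(dr$degree, rep(2, 3))
  expect_equal(nrow(degree_table(g, "right", min_degree = 5)), 0)

  # degrees equal brute-force neighbor counts on a synthetic graph
  spec <- small_spec(seed = 72)
  cat_ <- generate_catalog(spec)
  fil <- run_filter_pipeline(generate_cohort(spec, cat_),
                             cat_$gene[cat_$is_census])
  gb <- build_bipartite(fil$records, "tissue")
  dt <- degree_table(gb, "right")
  pairs <- unique(fil$records[, c("tissue", "gene")])
  expect_equal(dt$degree, as.integer(table(pairs$gene)[dt$node]))
})

test_that("projection weights count shared neighbors exactly", {
  r <- complete_bipartite_records(c("T1", "T2"), c("g1", "g2", "g3"))
  g <- build_bipartite(r, "tissue")
  pt <- one_mode_projection(g, "left")
  et <- edge_table(pt)
  expect_equal(nrow(et), 1)
  expect_equal(et$weight, 3)

  # complete bipartite K_{a,b} projects onto the a-side as K_a, weight b
  r2 <- complete_bipartite_records(paste0("T", 1:4), paste0("g", 1:6))
  p2 <- one_mode_projection(build_bipartite(r2, "tissue"), "left")
  e2 <- edge_table(p2)
  expect_equal(nrow(e2), choose(4, 2))
  expect_true(all(e2$weight == 6))

  # census annotation lands on gene projections
  pg <- one_mode_projection(g, "right", census_genes = "g1")
  expect_equal(igraph::V(pg)$is_census, c(TRUE, FALSE, FALSE))
})

test_that("projection weights match brute-force pairwise intersections", {
  withr::with_seed(301, {
    for (i in 1:5) {
      nl <- sample(10:50, 1); nr <- sample(10:80, 1)
      rows <- data.frame(
        donor_id = paste0("s", sample(nl, 400, replace = TRUE)),
        gene = paste0("g", sample(nr, 400, replace = TRUE)),
        stringsAsFactors = FALSE)
      rows$tissue <- "T1"
      rows$variant_class <- "Missense_Mutation"
      rows$position <- 1L; rows$ref_allele <- "A"; rows$alt_allele <- "T"
      g <- build_bipartite(rows, "donor_id")
      for (onto in c("left", "right")) {
        pr <- one_mode_projection(g, onto)
        nbr <- if (onto == "left")
          split(rows$gene, rows$donor_id) else split(rows$donor_id, rows$gene)
        nbr <- lapply(nbr, unique)
        et <- edge_table(pr)
        # every reported weight equals the intersection size
        for (k in seq_len(nrow(et)))
          expect_length(intersect(nbr[[et$from[k]]], nbr[[et$to[k]]]),
                        et$weight[k])
        # every positive intersection is reported
        nm <- names(nbr)
        npos <- sum(vapply(seq_along(nm), function(a)
          sum(vapply(seq_len(a - 1), function(b)
            length(intersect(nbr[[nm[a]]], nbr[[nm[b]]])) > 0, logical(1))),
          integer(1)))
        expect_equal(nrow(et), npos)
        # symmetry and weight bound
        deg <- vapply(nbr, length, integer(1))
        expect_true(all(et$weight <= pmin(deg[et$from], deg[et$to])))
      }
    }
  })
})

test_that("per-type projections count within-tissue co-occurrence", {
  r <- rbind(rec("s1", "Panc", c("A1", "B1"), "Missense_Mutation", 1, "A", "T"),
             rec("s2", "Panc", c("A1", "B1"), "Missense_Mutation", 1, "A", "T"),
             rec("s3", "Panc", "A1", "Missense_Mutation", 1, "A", "T"))
  pp <- per_type_projections(r)
  et <- edge_table(pp$Panc)
  expect_equal(nrow(et), 1)
  expect_equal(et$weight, 2)

  # every sample mutated in exactly one gene -> edgeless projection
  r1 <- rec(paste0("s", 1:5), "Liver", paste0("g", 1:5),
            "Missense_Mutation", 1, "A", "T")
  expect_equal(igraph::ecount(per_type_projections(r1)$Liver), 0)
})

test_that("per-type weights add up to the global projection", {
  # tissues partition samples, so per-type co-occurrence sums to global
  spec <- small_spec(seed = 73)
  cat_ <- generate_catalog(spec)
  fil <- run_filter_pipeline(generate_cohort(spec, cat_),
                             cat_$gene[cat_$is_census])
  global <- edge_table(one_mode_projection(
    build_bipartite(fil$records, "donor_id"), "right"))
  per <- per_type_projections(fil$records)
  acc <- list()
  for (t in names(per)) {
    et <- edge_table(per[[t]])
    for (k in seq_len(nrow(et))) {
      key <- paste(et$from[k], et$to[k])
      acc[[key]] <- (acc[[key]] %||% 0) + et$weight[k]
    }
  }
  expect_equal(length(acc), nrow(global))
  gkey <- paste(global$from, global$to)
  expect_equal(unlist(acc)[gkey], setNames(global$weight, gkey))
})

test_that("weight-cutoff subgraphs filter edges then orphaned nodes", {
  r <- complete_bipartite_records(paste0("T", 1:3), paste0("g", 1:4))
  pr <- one_mode_projection(build_bipartite(r, "tissue"), "left")
  expect_equal(edge_table(subset_by_weight(pr, 1)), edge_table(pr))
  gone <- subset_by_weight(pr, 99)
  expect_equal(igraph::vcount(gone), 0)
  expect_error(subset_by_weight(pr, 0), "min_weight")

  withr::with_seed(302, {
    rows <- rec(paste0("s", sample(20, 200, replace = TRUE)), "T1",
                paste0("g", sample(15, 200, replace = TRUE)),
                "Missense_Mutation", 1, "A", "T")
    pr2 <- one_mode_projection(build_bipartite(rows, "donor_id"), "right")
    for (w in 2:4) {
      sub <- subset_by_weight(pr2, w)
      et_all <- edge_table(pr2)
      expect_equal(edge_table(sub), et_all[et_all$weight >= w, ],
                   ignore_attr = TRUE)
      expect_true(all(igraph::degree(sub) > 0))
    }
  })
})
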