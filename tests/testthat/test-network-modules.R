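shared_tbl <- function(genes) {
  A <- quick_dgs("a", setNames(rep(list("text_mining"), length(genes)),
                               genes))
  shared_gene_table(A, A, genes)
}

test_that("network building restricts edges to shared genes and allowed types", {
  genes <- c("G1", "G2", "G3", "G4", "G5")
  edges <- data.frame(
    gene1 = c("G1", "G2", "G1", "G1", "G9", "G3"),
    gene2 = c("G2", "G3", "G2", "G1", "G1", "G3"),
    type = c("coexpression", "physical", "pathway", "physical",
             "coexpression", "pathway"),
    weight = round(runif(6), 2))
  net <- build_network(shared_tbl(genes), tmp_tsv(edges))
  expect_equal(length(net$nodes), 5)           # isolated nodes retained
  expect_equal(igraph::ecount(net$graph), 2)   # dedup, self-loop + G9 dropped
  expect_equal(net$n_connected, 3)
  expect_equal(net$connectivity, 3 / 5)
  # duplicate edge with two types collapses to one edge with a type set
  e <- igraph::as_data_frame(net$graph)
  expect_equal(sort(e$types[e$from == "G1" | e$to == "G1"]),
               "coexpression;pathway")
  bad <- edges; bad$type[1] <- "regulatory"
  expect_error(build_network(shared_tbl(genes), tmp_tsv(bad)), "regulatory")
})

test_that("maximal cliques match hand enumeration on canonical graphs", {
  tri <- network_from_edges(data.frame(gene1 = c("a", "b", "c"),
                                       gene2 = c("b", "c", "a")))
  expect_equal(maximal_cliques(tri), list(c("a", "b", "c")))
  path <- network_from_edges(data.frame(gene1 = c("a", "b"),
                                        gene2 = c("b", "c")))
  expect_equal(maximal_cliques(path), list(c("a", "b"), c("b", "c")))
  # two 4-cliques sharing one vertex
  m1 <- c("a", "b", "c", "x"); m2 <- c("x", "d", "e", "f")
  pr <- cbind(utils::combn(m1, 2), utils::combn(m2, 2))
  two <- network_from_edges(data.frame(gene1 = pr[1, ], gene2 = pr[2, ]))
  cl <- maximal_cliques(two)
  expect_equal(lengths(cl), c(4L, 4L))
  expect_setequal(vapply(cl, paste, character(1), collapse = ","),
                  c(paste(sort(m1), collapse = ","),
                    paste(sort(m2), collapse = ",")))
})

test_that("maximal cliques agree with brute-force subset enumeration", {
  for (seed in 1:40) {
    g <- random_network(sample(4:10, 1), runif(1, 0.2, 0.7), seed)
    got <- maximal_cliques(g$net)
    expect_identical(got, oracle_max_cliques(g$adj))
  }
})

test_that("extended modularity reproduces its closed-form identities", {
  # all nodes in one community covering a connected graph: EQ = 0
  g <- random_network(8, 0.5, 99)$net
  expect_equal(extended_modularity(g, list(g$nodes)), 0, tolerance = 1e-12)
  # two disjoint triangles as two modules: EQ = 1/2 exactly
  t2 <- network_from_edges(data.frame(
    gene1 = c("a", "b", "c", "x", "y", "z"),
    gene2 = c("b", "c", "a", "y", "z", "x")))
  expect_equal(extended_modularity(t2, list(c("a", "b", "c"),
                                            c("x", "y", "z"))),
               0.5, tolerance = 1e-12)
  # edgeless network: EQ = 0 by convention
  e0 <- network_from_edges(data.frame(gene1 = character(0),
                                      gene2 = character(0)),
                           nodes = c("u", "v"))
  expect_equal(extended_modularity(e0, list(c("u", "v"))), 0)
  expect_error(extended_modularity(t2, list(c("a", "nope"))), "nope")
})

test_that("extended modularity matches a naive pairwise-sum oracle", {
  oracle_eq <- function(adj, modules, nodes) {
    m <- sum(adj) / 2
    if (m == 0) return(0)
    deg <- rowSums(adj)
    ov <- setNames(rep(1, length(nodes)), nodes)
    counts <- table(unlist(modules))
    ov[names(counts)] <- pmax(counts, 1)
    total <- 0
    for (mod in modules) {
      for (v in mod) for (w in mod) {
        total <- total + (adj[v, w] - deg[v] * deg[w] / (2 * m)) /
          (ov[[v]] * ov[[w]])
      }
    }
    unname(total / (2 * m))
  }
  for (seed in 1:10) {
    g <- random_network(9, 0.4, 100 + seed)
    set.seed(seed)
    mods <- list(sample(g$net$nodes, 4), sample(g$net$nodes, 5))
    expect_equal(extended_modularity(g$net, mods),
                 oracle_eq(g$adj, mods, g$net$nodes), tolerance = 1e-12)
  }
})

test_that("clique-seeded agglomeration recovers planted disjoint cliques", {
  # two disjoint 4-cliques: the maximal-EQ cover is exactly the two cliques
  m1 <- c("a1", "a2", "a3", "a4"); m2 <- c("b1", "b2", "b3", "b4")
  pr <- cbind(utils::combn(m1, 2), utils::combn(m2, 2))
  net <- network_from_edges(data.frame(gene1 = pr[1, ], gene2 = pr[2, ]))
  cov <- eagle(net, min_clique = 3, min_complex = 3)
  expect_equal(cov$modules, list(m1, m2))
  expect_equal(cov$eq, 0.5, tolerance = 1e-12)
  expect_equal(cov$eq, extended_modularity(net, cov$all_modules),
               tolerance = 1e-12)
  # a single k-clique yields one module equal to the clique
  k <- utils::combn(sprintf("k%d", 1:5), 2)
  one <- network_from_edges(data.frame(gene1 = k[1, ], gene2 = k[2, ]))
  cov1 <- eagle(one, min_clique = 3, min_complex = 3)
  expect_equal(cov1$modules, list(sprintf("k%d", 1:5)))
})

test_that("overlapping cliques keep the shared vertex in both modules", {
  m1 <- c("a1", "a2", "a3", "a4", "xx"); m2 <- c("xx", "b1", "b2", "b3", "b4")
  pr <- cbind(utils::combn(m1, 2), utils::combn(m2, 2))
  net <- network_from_edges(data.frame(gene1 = pr[1, ], gene2 = pr[2, ]))
  cov <- eagle(net, min_clique = 4, min_complex = 4)
  expect_equal(length(cov$modules), 2)
  expect_true(all(vapply(cov$modules, function(m) "xx" %in% m, logical(1))))
  ov <- module_overlap_genes(cov)
  expect_equal(names(ov), "xx")
  expect_equal(sort(ov$xx), c(1L, 2L))
})

test_that("module overlap reporting handles disjoint and triple membership", {
  cov <- structure(list(modules = list(c("a", "b"), c("c", "d"))),
                   class = "module_cover")
  expect_length(module_overlap_genes(cov), 0)
  cov3 <- structure(list(modules = list(c("a", "b"), c("a", "c"),
                                        c("a", "d"))),
                    class = "module_cover")
  expect_equal(module_overlap_genes(cov3), list(a = c(1L, 2L, 3L)))
})

test_that("eagle is deterministic and robust to degenerate inputs", {
  g <- planted_clique_graph(3, 6, 0.05, 17)
  c1 <- eagle(g$net, 4, 4)
  c2 <- eagle(g$net, 4, 4)
  expect_identical(c1$modules, c2$modules)
  expect_identical(c1$dendrogram, c2$dendrogram)
  empty <- network_from_edges(data.frame(gene1 = character(0),
                                         gene2 = character(0)))
  cov0 <- eagle(empty, 3, 3)
  expect_length(cov0$modules, 0)
  expect_equal(cov0$eq, 0)
  expect_error(eagle(g$net, min_clique = 1), "min_clique")
  expect_error(eagle(g$net, min_complex = 0), "min_complex")
})

test_that("planted modules survive inter-module noise", {
  for (seed in 1:5) {
    g <- planted_clique_graph(4, 12, 0.02, 400 + seed)
    cov <- eagle(g$net, 10, 10)
    for (m in g$modules) {
      best <- max(vapply(cov$modules, jaccard, numeric(1), y = m), 0)
      expect_gte(best, 0.9)
    }
  }
})

test_that("module annotation counts channels and finds the planted term", {
  genes <- sprintf("G%02d", 1:12)
  la <- setNames(c(rep(list("eqtl"), 6), rep(list("text_mining"), 6)), genes)
  tbl <- shared_gene_table(quick_dgs("a", la), quick_dgs("b", la), genes)
  mod1 <- genes[1:6]; mod2 <- genes[7:12]
  cov <- structure(list(modules = list(mod1, mod2)), class = "module_cover")
  coll <- list(sets = list(PLANTED = mod1, OTHER = genes[5:9]))
  ann <- annotate_modules(cov, tbl, coll)
  expect_equal(unname(ann[[1]]$channel_counts["eqtl"]), 6L)
  expect_equal(unname(ann[[1]]$channel_counts["text_mining"]), 0L)
  expect_equal(ann[[1]]$enrichment$term[1], "PLANTED")
  expect_equal(ann[[1]]$enrichment$p[1], oracle_fisher_p(6, 0, 0, 6),
               tolerance = 1e-12)
  # empty collection: annotations carry empty enrichment frames
  ann0 <- annotate_modules(cov, tbl, list())
  expect_equal(nrow(ann0[[1]]$enrichment), 0)
})
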