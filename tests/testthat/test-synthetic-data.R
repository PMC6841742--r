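test_that("fixture specs are validated before any file is written", {
  expect_error(fixture_spec(planted_shared = 10, module_sizes = c(12)),
               "module")
  expect_error(fixture_spec(planted_eqtl_excess = 100, planted_shared = 60),
               "excess")
  expect_error(fixture_spec(planted_cross_drugs = 99), "group_size")
  expect_error(fixture_spec(noise_edge_p = 1), "noise_edge_p")
  expect_error(fixture_spec(diseases = c("x", "x")), "distinct")
  bad_dir <- file.path(tempfile(), "sub")
  expect_error(gen_fixture(structure(
    utils::modifyList(unclass(demo_fixture_spec()),
                      list(planted_shared = 1000000L)),
    class = "fixture_spec"), bad_dir), "planted|pool|infeasible")
})

test_that("zero-noise fixtures contain exactly the planted structure", {
  dir <- tempfile("fx0")
  spec <- demo_fixture_spec(noise = FALSE, seed = 5)
  m <- gen_fixture(spec, dir)
  # edge list is exactly the union of the planted cliques
  edges <- read.delim(file.path(dir, "edges.tsv"))
  expect_equal(nrow(edges), sum(choose(spec$module_sizes, 2)))
  within_planted <- mapply(function(g1, g2) {
    any(vapply(m$modules, function(mod) g1 %in% mod && g2 %in% mod,
               logical(1)))
  }, edges$gene1, edges$gene2)
  expect_true(all(within_planted))
  # manifest shared set equals the planted pool (no collisions possible)
  expect_setequal(m$genes$shared, m$genes$planted_shared)
  expect_length(m$genes$shared, spec$planted_shared)
  expect_length(m$genes$eqtl_shared, spec$planted_eqtl_excess)
})

test_that("generated bundles are byte-identical given the same spec", {
  d1 <- tempfile("fxa"); d2 <- tempfile("fxb")
  spec <- demo_fixture_spec(noise = TRUE, seed = 42)
  gen_fixture(spec, d1)
  gen_fixture(spec, d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the bundle
  d3 <- tempfile("fxc")
  gen_fixture(demo_fixture_spec(noise = TRUE, seed = 43), d3)
  expect_false(identical(readLines(file.path(d1, "gwas_associations.tsv")),
                         readLines(file.path(d3, "gwas_associations.tsv"))))
})

test_that("every generated table parses through its reader without loss", {
  dir <- tempfile("fxp")
  spec <- demo_fixture_spec(noise = TRUE, seed = 3)
  m <- gen_fixture(spec, dir)
  tm <- read.delim(file.path(dir, "trait_map.tsv"))
  gwas_raw <- read.delim(file.path(dir, "gwas_associations.tsv"))
  gwas <- parse_gwas_table(file.path(dir, "gwas_associations.tsv"),
                           setNames(tm$disease, tm$trait))
  expect_equal(nrow(gwas), nrow(gwas_raw))       # zero dropped rows
  expect_equal(attr(gwas, "n_dropped"), 0)
  for (f in m$files$eqtl) {
    expect_silent(parse_eqtl_table(file.path(dir, f), f))
  }
  expect_silent(parse_hpo_table(file.path(dir, m$files$hpo)))
  expect_silent(parse_expression_table(file.path(dir, m$files$expression)))
  expect_silent(parse_drug_tables(file.path(dir, "drugs.tsv"),
                                  file.path(dir, "drug_targets.tsv")))
  gmt <- read_gmt(file.path(dir, m$files$gmt))
  expect_true(all(m$planted_gmt_terms %in% names(gmt)))
  expect_silent(read_alias_table(file.path(dir, "aliases.tsv")))
})

test_that("null-world pairs satisfy the forced-intersection contract", {
  spec <- fixture_spec()
  for (i in 1:5) {
    nw <- gen_null_eqtl_pair(spec, seed = i)
    expect_length(nw$snpsA, spec$null_set_size)
    expect_length(nw$snpsB, spec$null_set_size)
    expect_length(intersect(nw$snpsA, nw$snpsB), spec$null_overlap)
    expect_true(all(c(nw$snpsA, nw$snpsB) %in% nw$links$snp_id))
    # SNPs regulated by the shared core appear in both gene sets
    core <- intersect(nw$snpsA, nw$snpsB)
    core_genes <- unique(nw$links$gene[nw$links$snp_id %in% core])
    gA <- unique(nw$links$gene[nw$links$snp_id %in% nw$snpsA])
    gB <- unique(nw$links$gene[nw$links$snp_id %in% nw$snpsB])
    expect_true(all(core_genes %in% gA) && all(core_genes %in% gB))
  }
})

test_that("unit fan-out over disjoint gene blocks shares nothing", {
  # fanout 1 and no forced overlap: each SNP has its own gene, so two
  # disjoint SNP sets regulate disjoint gene sets
  spec <- fixture_spec(eqtl_fanout_mean = 1, null_overlap = 0,
                       null_hub_snps = 0)
  nw <- gen_null_eqtl_pair(spec, seed = 8)
  links <- nw$links
  expect_equal(nrow(links), length(unique(links$snp_id)))
  links$gene <- paste0(links$gene, "_", links$snp_id)  # force disjoint blocks
  r <- matched_permutation(links, nw$snpsA, nw$snpsB, n_perm = 20, seed = 1)
  expect_equal(r$observed, 0)
})
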