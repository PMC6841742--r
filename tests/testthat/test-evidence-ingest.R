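gwas_fixture <- function() {
  data.frame(snp_id = c("rs1", "rs2", "rs3"),
             trait = c("asthma", "asthma", "unrelated trait"),
             p_value = c("1e-6", "2e-8", "1e-9"),
             consequence = c("missense_variant", "intergenic_variant",
                             "missense_variant"),
             mapped_gene = c("GA", "", "GC"))
}

test_that("GWAS parsing maps traits and logs dropped rows", {
  tm <- c(asthma = "asthma")
  expect_message(v <- parse_gwas_table(tmp_tsv(gwas_fixture()), tm),
                 "dropped 1")
  expect_equal(nrow(v), 2)
  expect_equal(attr(v, "n_dropped"), 1)
  expect_equal(v$disease, c("asthma", "asthma"))
  expect_true(is.na(v$mapped_gene[2]))
  # all mapped: identity case
  tm2 <- c(asthma = "asthma", `unrelated trait` = "asthma")
  expect_equal(nrow(parse_gwas_table(tmp_tsv(gwas_fixture()), tm2)), 3)
  # header-only file
  empty <- gwas_fixture()[0, ]
  expect_equal(nrow(parse_gwas_table(tmp_tsv(empty), tm)), 0)
})

test_that("GWAS parsing errors name the defect", {
  df <- gwas_fixture()[, c("snp_id", "trait", "consequence")]
  expect_error(parse_gwas_table(tmp_tsv(df), c(asthma = "asthma")),
               "p_value")
  df2 <- gwas_fixture(); df2$p_value[2] <- "not-a-number"
  expect_error(parse_gwas_table(tmp_tsv(df2), c(asthma = "asthma")),
               "row\\(s\\) 2")
})

test_that("coding-variant filter is strict at the p threshold", {
  cfg <- ingest_config()
  mk <- function(p, cons) data.frame(snp_id = "rs", trait = "t",
                                     disease = "d", p_value = p,
                                     consequence = cons,
                                     mapped_gene = "G")
  expect_equal(nrow(filter_coding_variants(mk(1e-6, "missense_variant"),
                                           cfg)), 1)
  expect_equal(nrow(filter_coding_variants(mk(1e-9, "intergenic_variant"),
                                           cfg)), 0)
  # boundary: exactly 1e-5 fails the strict inequality
  expect_equal(nrow(filter_coding_variants(mk(1e-5, "missense_variant"),
                                           cfg)), 0)
  expect_equal(nrow(filter_coding_variants(mk(0.99e-5, "missense_variant"),
                                           cfg)), 1)
})

eqtl_fixture <- function() {
  data.frame(snp_id = c("rs1", "rs1", "rs2"),
             gene = c("G1", "G2", "G3"),
             tissue = "blood",
             kind = c("cis", "trans", "cis"),
             fdr = c("0.01", "0.02", "0.03"))
}

test_that("eQTL parsing validates kinds, range and uniqueness", {
  li <- parse_eqtl_table(tmp_tsv(eqtl_fixture()), "st1")
  expect_equal(nrow(li), 3)
  expect_equal(li$kind, c("cis", "trans", "cis"))
  expect_equal(li$study, rep("st1", 3))
  bad <- eqtl_fixture(); bad$kind[1] <- "weird"
  expect_error(parse_eqtl_table(tmp_tsv(bad), "s"), "weird")
  bad2 <- eqtl_fixture(); bad2$fdr[2] <- "1.5"
  expect_error(parse_eqtl_table(tmp_tsv(bad2), "s"), "\\[0, 1\\]")
  dup <- eqtl_fixture()[c(1, 1, 2), ]
  expect_error(parse_eqtl_table(tmp_tsv(dup), "s"), "duplicate.*rs1")
})

test_that("FDR filter is inclusive at the threshold", {
  cfg <- ingest_config()
  li <- data.frame(snp_id = c("a", "b", "c"), gene = "G", study = "s",
                   tissue = "t", kind = "cis", fdr = c(0.049, 0.05, 0.051))
  kept <- filter_eqtl_fdr(li, cfg)
  expect_equal(kept$snp_id, c("a", "b"))
  expect_equal(nrow(filter_eqtl_fdr(li[0, ], cfg)), 0)
  # idempotence
  expect_identical(filter_eqtl_fdr(kept, cfg), kept)
})

test_that("eQTL-regulated genes equal the brute-force variant-link scan", {
  gwas <- data.frame(snp_id = c("rs1", "rs9"))
  links <- data.frame(snp_id = c("rs1", "rs1", "rs1", "rs2"),
                      gene = c("G1", "G2", "G3", "G4"),
                      study = "s", tissue = "t", kind = "trans", fdr = 0.01)
  reg <- eqtl_regulated_genes(gwas, links)
  expect_equal(sort(unique(reg$gene)), c("G1", "G2", "G3"))  # fan-out kept
  expect_equal(nrow(eqtl_regulated_genes(data.frame(snp_id = "rsX"), links)),
               0)
  set.seed(3)
  for (i in 1:10) {
    g <- data.frame(snp_id = sample(sprintf("rs%d", 1:30), 10))
    l <- data.frame(snp_id = sample(sprintf("rs%d", 1:30), 50, TRUE),
                    gene = sample(sprintf("G%d", 1:20), 50, TRUE),
                    study = sample(c("s1", "s2"), 50, TRUE),
                    tissue = "t", kind = "cis", fdr = 0.01)
    got <- eqtl_regulated_genes(g, l)
    brute <- unique(do.call(rbind, lapply(seq_len(nrow(l)), function(j) {
      if (l$snp_id[j] %in% g$snp_id)
        data.frame(gene = l$gene[j], snp_id = l$snp_id[j], study = l$study[j])
    })))
    expect_setequal(paste(got$gene, got$snp_id, got$study),
                    paste(brute$gene, brute$snp_id, brute$study))
  }
})

test_that("phenotype selection honours frequency labels and term-level exclusion", {
  cfg <- ingest_config(hpo_include_terms = "HP:0000822",
                       hpo_exclude_terms = "HP:0007906")
  ann <- data.frame(
    gene = c("KEEP", "OCULAR", "OCC", "BOTH", "BOTH"),
    term_id = c("HP:0000822", "HP:0007906", "HP:0000822", "HP:0007906",
                "HP:0000822"),
    frequency_label = c("frequent", "frequent", "occasional", "frequent",
                        "frequent"))
  got <- select_hpo_genes(ann, cfg)
  expect_true("KEEP" %in% got)
  expect_false("OCULAR" %in% got)   # only an excluded term
  expect_false("OCC" %in% got)      # label outside the allowed set
  expect_true("BOTH" %in% got)      # kept through the included annotation
  expect_error(select_hpo_genes(ann, ingest_config()), "include")
  expect_error(ingest_config(hpo_include_terms = "HP:1",
                             hpo_exclude_terms = "HP:1"), "overlap")
})

test_that("phenotype table parsing enforces the ontology prefix", {
  df <- data.frame(gene = "G", term_id = "GO:0001", frequency_label = "frequent")
  expect_error(parse_hpo_table(tmp_tsv(df)), "prefix")
})

test_that("differential expression needs two distinct sources unless trusted", {
  cfg <- ingest_config()
  rep1 <- data.frame(gene = c("T1", "S1", "S1", "M1", "M1"),
                     disease = "d", direction = "up",
                     source = c("big", "db1", "db1", "db1", "db2"),
                     trusted = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  got <- de_genes_min_support(rep1, cfg)
  expect_true("T1" %in% got)    # single trusted signature suffices
  expect_false("S1" %in% got)   # two rows of the same source do not
  expect_true("M1" %in% got)    # two distinct sources do
  expect_identical(de_genes_min_support(rep1[0, ], cfg), character(0))
})

test_that("text-mining lists respect the study-support threshold", {
  cfg <- ingest_config()
  lst <- curated_gene_list("d", "text_mining",
                           c(A = 2, B = 1, C = 100))
  expect_equal(text_mined_genes(lst, cfg), c("A", "C"))
  empty <- curated_gene_list("d", "text_mining", integer(0))
  expect_identical(text_mined_genes(empty, cfg), character(0))
  mono <- curated_gene_list("d", "monogenic", c(A = 1))
  expect_error(text_mined_genes(mono, cfg), "text_mining")
  expect_error(curated_gene_list("d", "text_mining", c(A = 0)), ">= 1")
})

test_that("assembly unions channels with exact per-gene channel sets", {
  out <- assemble_disease_gene_set("d", list(
    monogenic = c("G1"), text_mining = c("G1")))
  expect_equal(out$genes$G1, c("monogenic", "text_mining"))
  out2 <- assemble_disease_gene_set("d", list(
    monogenic = "G1", text_mining = "G2"))
  expect_equal(lengths(out2$genes), c(G1 = 1L, G2 = 1L))

  # engineered 10-gene fixture across all six channels, hand-tallied
  sets <- list(
    monogenic = c("G01", "G02"),
    coding_gwas = c("G02", "G03", "G04"),
    eqtl = c("G04", "G05", "G06"),
    diff_expr = c("G01", "G06"),
    text_mining = c("G07", "G08", "G09", "G01"),
    drug_target = c("G10", "G01"))
  out3 <- assemble_disease_gene_set("d", sets)
  tally <- c(G01 = 4, G02 = 2, G03 = 1, G04 = 2, G05 = 1, G06 = 2,
             G07 = 1, G08 = 1, G09 = 1, G10 = 1)
  expect_equal(lengths(out3$genes)[names(tally)], tally)
  # channel-count conservation
  expect_equal(sum(lengths(out3$genes)), sum(lengths(sets)))
  expect_equal(length(out3$genes), length(unique(unlist(sets))))
  expect_error(assemble_disease_gene_set("d", list(bogus = "G1")), "bogus")
})

test_that("gene namespace is normalized and never silently mixed", {
  out <- assemble_disease_gene_set("d", list(text_mining = c("abc", "ABC")))
  expect_equal(names(out$genes), "ABC")
  expect_error(assemble_disease_gene_set("d", list(text_mining = c("ABC",
                                                                   "1234"))),
               "numeric")
  expect_equal(normalize_genes("55", "numeric"), "55")
  expect_error(normalize_genes("TP53", "numeric"), "non-numeric")
  expect_equal(normalize_genes("old1", "symbol", alias = c(old1 = "NEW1")),
               "NEW1")
})

test_that("filters are order-independent and idempotent", {
  cfg <- ingest_config()
  set.seed(11)
  vars <- data.frame(snp_id = sprintf("rs%d", 1:40), trait = "t",
                     disease = "d",
                     p_value = 10^-runif(40, 3, 8),
                     consequence = sample(c("missense_variant", "intergenic",
                                            "synonymous_variant"), 40, TRUE),
                     mapped_gene = sprintf("G%d", 1:40))
  f1 <- filter_coding_variants(vars, cfg)
  expect_identical(filter_coding_variants(f1, cfg), f1)
  perm <- vars[sample(nrow(vars)), ]
  f2 <- filter_coding_variants(perm, cfg)
  expect_setequal(f2$snp_id, f1$snp_id)
})
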