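test_that("one-sided Fisher p matches the hypergeometric tail oracle", {
  # hand-derived: among C(4,2)=6 tables with margins (2,2)/(2,2), only one
  # has a=2, so P(X >= 2) = 1/6
  expect_equal(fisher_one_sided(2, 0, 0, 2)$p, 1 / 6, tolerance = 1e-12)
  # a = 0 covers the whole upper tail
  expect_equal(fisher_one_sided(0, 3, 4, 5)$p, 1)

  set.seed(42)
  for (i in 1:200) {
    cells <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(1 / 4, 4)))
    got <- fisher_one_sided(cells[1], cells[2], cells[3], cells[4])$p
    expect_equal(got, oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
  # agreement with the standard exact test implementation
  tab <- matrix(c(8, 2, 3, 17), 2, byrow = TRUE)
  expect_equal(fisher_one_sided(8, 2, 3, 17)$p,
               stats::fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-12)
  # large totals stay finite and in range
  p_big <- fisher_one_sided(5000, 1000, 1000, 993000)$p
  expect_true(is.finite(p_big) && p_big >= 0 && p_big <= 1)
})

test_that("Fisher result reports odds ratio, side and degeneracy", {
  r <- fisher_one_sided(6, 2, 1, 8)
  expect_equal(r$odds_ratio, 6 * 8 / (2 * 1))
  expect_identical(r$side, "greater")
  expect_false(r$degenerate)
  expect_identical(fisher_one_sided(3, 0, 2, 0)$degenerate, TRUE)
  expect_equal(fisher_one_sided(3, 0, 2, 0)$p, 1)
  expect_true(is.infinite(fisher_one_sided(2, 0, 0, 3)$odds_ratio))
  expect_error(fisher_one_sided(-1, 1, 1, 1), "non-negative")
  expect_error(fisher_one_sided(0, 0, 0, 0), "total")
})

test_that("p is monotone non-increasing in the joint cell with margins fixed", {
  # margins (10, 20) x (12, 18), vary a along the feasible range
  r1 <- 10; c1 <- 12; n <- 30
  ps <- vapply(max(0, c1 - (n - r1)):min(r1, c1), function(a) {
    fisher_one_sided(a, r1 - a, c1 - a, n - r1 - c1 + a)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("BH adjustment matches the definitional oracle and its properties", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(7)
  for (i in 1:50) {
    m <- sample(1:60, 1)
    p <- round(runif(m), 3)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    # order preservation: adjustment never reorders the evidence
    o <- order(p)
    expect_true(!is.unsorted(q[o]))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})

test_that("gene-set overrepresentation matches the oracle and degenerates safely", {
  bg <- sprintf("G%03d", 1:100)
  term <- bg[1:20]
  query <- bg[1:10]
  res <- gene_set_overrep(query, list(hit = term), bg)
  expect_equal(res$p, oracle_fisher_p(10, 0, 10, 80), tolerance = 1e-12)
  expect_equal(res$k, 10)
  # term = query = background is a zero-margin table
  res2 <- gene_set_overrep(bg, list(all = bg), bg)
  expect_equal(res2$p, 1)
  expect_true(all(res$q >= res$p))
  expect_error(gene_set_overrep("X1", list(t = "X1"), character(0)),
               "background")
  expect_error(gene_set_overrep("ZZZ", list(t = bg[1]), bg), "outside")
})

test_that("set-overlap test recovers planted co-membership", {
  bg <- sprintf("D%04d", 1:1000)
  x <- bg[1:10]
  y <- c(bg[1:8], bg[101:102])
  r <- group_overlap_test(x, y, bg)
  expect_equal(r$a, 8)
  expect_equal(r$p, oracle_fisher_p(8, 2, 2, 988), tolerance = 1e-12)
  expect_lt(r$p, 1e-10)
  # disjoint small sets in a large background carry no signal
  r2 <- group_overlap_test(bg[1:5], bg[6:10], bg)
  expect_gt(r2$p, 0.9)
  # half-overlapping halves match the oracle
  r3 <- group_overlap_test(bg[1:500], bg[251:750], bg)
  expect_equal(r3$p, oracle_fisher_p(250, 250, 250, 250), tolerance = 1e-12)
})

test_that("drug-target overrepresentation counts drugs, not actions", {
  grp_ids <- sprintf("DG%02d", 1:10)
  bg_ids <- sprintf("DB%03d", 1:190)
  drugs <- data.frame(drug_id = c(grp_ids, bg_ids),
                      name = "x", indicated = c(rep("dis", 10), rep("", 190)),
                      contraindicated = "", adverse_inducing = "")
  targets <- rbind(
    data.frame(drug_id = grp_ids[1:6], gene = "TGT1",
               action_raw = "agonist", organism = "Human"),
    # a second action row for the same (drug, gene) must not double-count
    data.frame(drug_id = grp_ids[1], gene = "TGT1",
               action_raw = "inhibitor", organism = "Human"),
    data.frame(drug_id = bg_ids[1:5], gene = "TGT1",
               action_raw = "inhibitor", organism = "Human"),
    data.frame(drug_id = c(grp_ids, bg_ids), gene = "FILLER",
               action_raw = "binder", organism = "Human"))
  dt <- quick_drug_table(drugs, targets)
  grp <- build_drug_groups(dt, "dis")$beneficial
  res <- drug_target_overrep(grp, dt)
  row <- res[res$term == "TGT1", ]
  expect_equal(row$k, 6)
  expect_equal(row$p, oracle_fisher_p(6, 4, 5, 185), tolerance = 1e-12)
  # genes with no group drug are not tested
  expect_false("UNTOUCHED" %in% res$term)
  # a group drug outside the human-target background is refused
  drugs2 <- rbind(drugs, data.frame(drug_id = "DNOTGT", name = "x",
                                    indicated = "dis", contraindicated = "",
                                    adverse_inducing = ""))
  dt2 <- quick_drug_table(drugs2, targets)
  expect_error(drug_target_overrep(build_drug_groups(dt2, "dis")$beneficial,
                                   dt2), "DNOTGT")
})

test_that("matched pair sampler preserves sizes and intersection exactly", {
  set.seed(99)
  for (i in 1:300) {
    nU <- sample(10:60, 1)
    nA <- sample(1:8, 1); nB <- sample(1:8, 1)
    core <- sample(0:min(nA, nB), 1)
    if (nA + nB - core > nU) next
    pr <- sample_matched_pair(nU, nA, nB, core)
    expect_length(pr$A, nA)
    expect_length(pr$B, nB)
    expect_length(intersect(pr$A, pr$B), core)
    expect_false(anyDuplicated(pr$A) > 0 || anyDuplicated(pr$B) > 0)
  }
  expect_error(sample_matched_pair(5, 4, 4, 0), "infeasible")
})

test_that("matched permutation handles edge cases and is reproducible", {
  links0 <- data.frame(snp_id = character(0), gene = character(0))
  r0 <- matched_permutation(links0, character(0), character(0), n_perm = 50)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p_empirical, 1)

  links <- data.frame(snp_id = rep(sprintf("rs%d", 1:10), each = 2),
                      gene = sprintf("g%d", 1:20))
  A <- sprintf("rs%d", 1:3); B <- sprintf("rs%d", 3:5)
  r1 <- matched_permutation(links, A, B, n_perm = 200, seed = 5)
  r2 <- matched_permutation(links, A, B, n_perm = 200, seed = 5)
  expect_identical(r1$null, r2$null)
  expect_gte(r1$p_empirical, 1 / 201)
  expect_equal(r1$p_empirical, (r1$null_ge_observed + 1) / 201)
  expect_error(matched_permutation(links, c(A, "rsX"), B, 10), "universe")
  expect_error(
    matched_permutation(links, sprintf("rs%d", 1:6), sprintf("rs%d", 7:10),
                        10),
    NA)
  expect_error(
    matched_permutation(data.frame(snp_id = "rs1", gene = "g"),
                        "rs1", "rs1", 0), "n_perm")
})

test_that("planted excess sharing is detected at the estimator floor", {
  # A and B regulate the same 30 genes; 200 decoy SNPs regulate others
  shared_genes <- sprintf("S%02d", 1:30)
  links <- rbind(
    data.frame(snp_id = rep(sprintf("ra%d", 1:5), each = 6),
               gene = shared_genes),
    data.frame(snp_id = rep(sprintf("rb%d", 1:5), each = 6),
               gene = shared_genes),
    data.frame(snp_id = sprintf("rx%d", 1:200),
               gene = sprintf("O%03d", 1:200)))
  r <- matched_permutation(links, sprintf("ra%d", 1:5), sprintf("rb%d", 1:5),
                           n_perm = 999, seed = 1)
  expect_equal(r$observed, 30)
  expect_equal(r$p_empirical, 1 / 1000)
  expect_lt(r$null_mean, 5)
})
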