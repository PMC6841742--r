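#' Specification of a synthetic comorbidity fixture
#'
#' Describes the planted structure of a full synthetic input bundle:
#' how many genes and SNPs exist, how many genes carry evidence for both
#' diseases, which evidence channels fire at random in the background,
#' how eQTL fan-out is distributed, and what network modules, drug groups
#' and cross-disease drug overlaps are planted. The generator emulates
#' the statistical shape of versioned database extracts (variant
#' association catalogs, eQTL link tables, phenotype annotations,
#' expression reports, curated lists, drug/target tables, typed edge
#' lists, GMT collections) without reproducing any real content.
#'
#' Noise rates of zero give a fully deterministic "planted truth only"
#' bundle in which the pipeline's outputs must equal the manifest
#' exactly; positive rates add realistic random evidence that can create
#' additional shared genes by collision.
#'
#' @param n_genes,n_snps Pool sizes for gene and SNP identifiers.
#' @param diseases Pair of disease labels.
#' @param planted_shared Number of genes planted with evidence for both
#'   diseases.
#' @param per_disease_only Number of genes planted with evidence for
#'   exactly one disease (each disease).
#' @param per_channel_rates Named numeric: per-gene, per-disease
#'   probability that a channel fires at random in the background.
#' @param eqtl_fanout_mean Mean genes per eQTL SNP (1 + geometric).
#' @param planted_eqtl_excess Number of shared genes regulated by eQTL
#'   SNPs of both diseases (through different SNPs).
#' @param n_background_drugs Drugs with human targets but no disease
#'   relation (the overrepresentation background).
#' @param group_size Drugs per planted disease group.
#' @param planted_cross_drugs Drugs beneficial for disease 1 and harmful
#'   for disease 2.
#' @param targets_per_group Planted overrepresented target genes per group.
#' @param n_paradoxical Drugs planted as both indicated and
#'   contraindicated for disease 1 (the paradoxical-reaction case).
#' @param module_sizes Integer vector of planted clique sizes on the
#'   shared-gene network.
#' @param noise_edge_p Edge probability between shared genes outside a
#'   common planted module.
#' @param null_universe_snps,null_gene_pool,null_set_size,null_overlap,
#'   null_hub_snps,null_hub_fanout Parameters of the null-world eQTL
#'   generator ([gen_null_eqtl_pair()]): pooled SNP universe size, gene
#'   pool, the two set sizes and their forced intersection, and the
#'   number and mean fan-out of high-fan-out trans hub SNPs.
#' @param seed Integer seed; the whole bundle is a pure function of the
#'   spec including the seed.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 600,
                         n_snps = 500,
                         diseases = c("asthma", "hypertension"),
                         planted_shared = 60,
                         per_disease_only = 120,
                         per_channel_rates = c(monogenic = 0.005,
                                               coding_gwas = 0.01,
                                               eqtl = 0.02,
                                               diff_expr = 0.03,
                                               text_mining = 0.06,
                                               drug_target = 0.005),
                         eqtl_fanout_mean = 2,
                         planted_eqtl_excess = 20,
                         n_background_drugs = 150,
                         group_size = 10,
                         planted_cross_drugs = 3,
                         targets_per_group = 3,
                         n_paradoxical = 1,
                         module_sizes = c(12, 12, 12, 12),
                         noise_edge_p = 0.02,
                         null_universe_snps = 300,
                         null_gene_pool = 400,
                         null_set_size = 60,
                         null_overlap = 8,
                         null_hub_snps = 10,
                         null_hub_fanout = 25,
                         seed = 1) {
  spec <- list(n_genes = n_genes, n_snps = n_snps, diseases = diseases,
               planted_shared = planted_shared,
               per_disease_only = per_disease_only,
               per_channel_rates = per_channel_rates,
               eqtl_fanout_mean = eqtl_fanout_mean,
               planted_eqtl_excess = planted_eqtl_excess,
               n_background_drugs = n_background_drugs,
               group_size = group_size,
               planted_cross_drugs = planted_cross_drugs,
               targets_per_group = targets_per_group,
               n_paradoxical = n_paradoxical,
               module_sizes = as.integer(module_sizes),
               noise_edge_p = noise_edge_p,
               null_universe_snps = null_universe_snps,
               null_gene_pool = null_gene_pool,
               null_set_size = null_set_size,
               null_overlap = null_overlap,
               null_hub_snps = null_hub_snps,
               null_hub_fanout = null_hub_fanout,
               seed = as.integer(seed))
  class(spec) <- "fixture_spec"
  validate_fixture_spec(spec)
  spec
}

validate_fixture_spec <- function(spec) {
  with(spec, {
    if (length(diseases) != 2 || diseases[1] == diseases[2]) {
      stop("diseases must be two distinct labels", call. = FALSE)
    }
    if (any(per_channel_rates < 0) || any(per_channel_rates > 1)) {
      stop("per_channel_rates must lie in [0, 1]", call. = FALSE)
    }
    if (noise_edge_p < 0 || noise_edge_p >= 1) {
      stop("noise_edge_p must lie in [0, 1)", call. = FALSE)
    }
    if (sum(module_sizes) > planted_shared) {
      stop("planted module sizes exceed the planted shared gene pool",
           call. = FALSE)
    }
    if (sum(module_sizes) + 2 * targets_per_group > planted_shared) {
      stop("planted modules plus target genes exceed the shared pool",
           call. = FALSE)
    }
    if (planted_eqtl_excess > planted_shared) {
      stop("planted_eqtl_excess exceeds planted_shared", call. = FALSE)
    }
    if (planted_cross_drugs > group_size) {
      stop("planted_cross_drugs exceeds group_size", call. = FALSE)
    }
    if (planted_shared + 2 * per_disease_only + n_background_drugs + 50 >
        n_genes) {
      stop("n_genes too small for the planted structure", call. = FALSE)
    }
    if (null_overlap > null_set_size ||
        2 * null_set_size - null_overlap > null_universe_snps) {
      stop("null-world set sizes infeasible for the SNP universe",
           call. = FALSE)
    }
    if (eqtl_fanout_mean < 1) stop("eqtl_fanout_mean must be >= 1",
                                   call. = FALSE)
  })
  invisible(spec)
}

# 1 + geometric fan-out with the given mean, truncated at `max`.
draw_fanout <- function(n, mean, max) {
  extra <- if (mean > 1) rgeom(n, prob = 1 / mean) else rep(0L, n)
  pmin(1L + extra, max)
}

#' Generate a complete synthetic input bundle
#'
#' Writes every input table the pipeline consumes into `out_dir`, plus a
#' ready-to-run `config.yaml` and a `manifest.json` recording the planted
#' truth (shared genes, per-disease gene sets, eQTL-shared genes, network
#' modules, drug groups, paradoxical and cross-disease drugs, planted
#' overrepresented targets, and a Monte-Carlo estimate of the expected
#' eQTL sharing under independence). Byte-identical output for identical
#' specs. Infeasible specs fail before any file is written.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly.
#' @export
gen_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  validate_fixture_spec(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  dA <- spec$diseases[1]; dB <- spec$diseases[2]
  genes <- sprintf("GX%04d", seq_len(spec$n_genes))
  snps <- sprintf("rs%06d", seq_len(spec$n_snps))
  snp_cursor <- 0L
  take_snps <- function(k) {
    if (snp_cursor + k > length(snps)) {
      stop("fixture spec infeasible: SNP pool exhausted", call. = FALSE)
    }
    out <- snps[snp_cursor + seq_len(k)]
    snp_cursor <<- snp_cursor + k
    out
  }

  ps <- spec$planted_shared
  pdo <- spec$per_disease_only
  shared_idx <- seq_len(ps)
  a_only_idx <- ps + seq_len(pdo)
  b_only_idx <- ps + pdo + seq_len(pdo)
  filler_idx <- seq(ps + 2 * pdo + 1, spec$n_genes)
  filler_cursor <- 0L
  take_filler <- function(k) {
    if (filler_cursor + k > length(filler_idx)) {
      stop("fixture spec infeasible: filler gene pool exhausted",
           call. = FALSE)
    }
    out <- genes[filler_idx[filler_cursor + seq_len(k)]]
    filler_cursor <<- filler_cursor + k
    out
  }

  chans <- evidence_channels()
  chA <- matrix(FALSE, spec$n_genes, length(chans),
                dimnames = list(genes, chans))
  chB <- chA

  # planted structure: every shared gene is text-mined for both diseases,
  # the tail of the shared pool is eQTL-regulated from both sides, and
  # disease-only genes cycle through the non-drug channels
  chA[shared_idx, "text_mining"] <- TRUE
  chB[shared_idx, "text_mining"] <- TRUE
  excess_idx <- if (spec$planted_eqtl_excess)
    shared_idx[seq(ps - spec$planted_eqtl_excess + 1, ps)] else integer(0)
  chA[excess_idx, "eqtl"] <- TRUE
  chB[excess_idx, "eqtl"] <- TRUE
  cycle <- c("monogenic", "coding_gwas", "eqtl", "diff_expr", "text_mining")
  chA[cbind(a_only_idx, match(rep_len(cycle, pdo), chans))] <- TRUE
  chB[cbind(b_only_idx, match(rep_len(cycle, pdo), chans))] <- TRUE

  # background noise: channels fire independently per gene and disease
  for (ch in chans) {
    r <- spec$per_channel_rates[[ch]] %||% 0
    if (r > 0) {
      noise_pool <- seq_len(ps + 2 * pdo)
      chA[noise_pool, ch] <- chA[noise_pool, ch] |
        (runif(length(noise_pool)) < r)
      chB[noise_pool, ch] <- chB[noise_pool, ch] |
        (runif(length(noise_pool)) < r)
    }
  }

  # ---- phenotype ontology channel -----------------------------------
  include_terms <- c("HP:0002099", "HP:0000822")
  names(include_terms) <- c(dA, dB)
  exclude_term <- "HP:0007906"
  hpo_rows <- list()
  mono_A <- genes[chA[, "monogenic"]]
  mono_B <- genes[chB[, "monogenic"]]
  if (length(mono_A)) {
    hpo_rows$a <- data.frame(gene = mono_A, term_id = include_terms[[dA]],
                             frequency_label = "frequent")
  }
  if (length(mono_B)) {
    hpo_rows$b <- data.frame(gene = mono_B, term_id = include_terms[[dB]],
                             frequency_label = "frequent")
  }
  decoy_excl <- take_filler(2)
  decoy_occ <- take_filler(2)
  hpo_rows$decoys <- data.frame(
    gene = c(decoy_excl, decoy_occ),
    term_id = c(rep(exclude_term, 2), rep(include_terms[[dB]], 2)),
    frequency_label = c("frequent", "frequent", "occasional", "occasional"))
  hpo <- do.call(rbind, hpo_rows)
  write_tsv(hpo, file.path(out_dir, "hpo_annotations.tsv"))

  # curated monogenic lists (redundant with the ontology annotations,
  # exercising the curated-list entry path)
  for (d in c(dA, dB)) {
    mono <- if (d == dA) mono_A else mono_B
    cur <- data.frame(gene = utils::head(mono, 2),
                      support_count = rep(1L, min(2L, length(mono))))
    write_tsv(cur, file.path(out_dir, sprintf("monogenic_%s.tsv", d)))
  }

  # ---- GWAS + eQTL channels -----------------------------------------
  traits <- setNames(list(c(dA, paste(dA, "related trait")),
                          c(dB, paste(dB, "related trait"))), c(dA, dB))
  trait_map <- data.frame(trait = unlist(traits),
                          disease = rep(c(dA, dB), each = 2),
                          row.names = NULL)
  write_tsv(trait_map, file.path(out_dir, "trait_map.tsv"))

  coding_cons <- c("missense_variant", "splice_region_variant",
                   "synonymous_variant", "non_coding_transcript_exon_variant")
  gwas_rows <- list()
  gwas_snps <- list(character(0), character(0))
  names(gwas_snps) <- c(dA, dB)
  for (d in c(dA, dB)) {
    cg <- genes[if (d == dA) chA[, "coding_gwas"] else chB[, "coding_gwas"]]
    if (length(cg)) {
      s <- take_snps(length(cg))
      gwas_snps[[d]] <- c(gwas_snps[[d]], s)
      gwas_rows[[paste0("coding_", d)]] <- data.frame(
        snp_id = s,
        trait = rep_len(traits[[d]], length(cg)),
        p_value = signif(10^(-runif(length(cg), 6, 12)), 3),
        consequence = rep_len(coding_cons, length(cg)),
        mapped_gene = cg)
    }
  }

  # eQTL links: each disease's regulated genes are covered by fresh SNPs
  # with geometric fan-out; shared regulated genes are reached from both
  # diseases through different SNPs (no shared GWAS hit is needed)
  link_rows <- list()
  add_links <- function(snp, gene_vec, fdr) {
    data.frame(snp_id = snp, gene = gene_vec,
               tissue = "whole_blood",
               kind = c("cis", rep("trans", length(gene_vec) - 1)),
               fdr = fdr)
  }
  for (d in c(dA, dB)) {
    eg <- genes[if (d == dA) chA[, "eqtl"] else chB[, "eqtl"]]
    remaining <- eg
    while (length(remaining)) {
      fo <- draw_fanout(1, spec$eqtl_fanout_mean, length(remaining))
      s <- take_snps(1)
      gwas_snps[[d]] <- c(gwas_snps[[d]], s)
      gwas_rows[[paste0("eqtl_", d, s)]] <- data.frame(
        snp_id = s, trait = traits[[d]][1],
        p_value = signif(10^(-runif(1, 5.5, 9)), 3),
        consequence = "intergenic_variant", mapped_gene = "")
      link_rows[[length(link_rows) + 1L]] <-
        add_links(s, remaining[seq_len(fo)],
                  round(runif(fo, 0.001, 0.049), 4))
      remaining <- remaining[-seq_len(fo)]
    }
  }
  # decoy links: GWAS SNPs whose links fail the FDR filter
  decoy_fdr_genes <- take_filler(3)
  s <- take_snps(1)
  gwas_snps[[dA]] <- c(gwas_snps[[dA]], s)
  gwas_rows$decoy_fdr_gwas <- data.frame(
    snp_id = s, trait = traits[[dA]][1], p_value = 1e-6,
    consequence = "intergenic_variant", mapped_gene = "")
  link_rows[[length(link_rows) + 1L]] <-
    add_links(s, decoy_fdr_genes, round(runif(3, 0.2, 0.9), 4))
  # widen the pooled SNP universe with non-GWAS eQTL SNPs, including a
  # couple of high-fan-out trans hubs
  n_extra <- 60
  extra_snps <- take_snps(n_extra)
  fo <- draw_fanout(n_extra, spec$eqtl_fanout_mean, 20)
  fo[seq_len(2)] <- pmin(spec$null_hub_fanout, spec$n_genes)
  for (i in seq_len(n_extra)) {
    g <- genes[sample.int(spec$n_genes, fo[i])]
    link_rows[[length(link_rows) + 1L]] <-
      add_links(extra_snps[i], g, round(runif(fo[i], 0.001, 0.049), 4))
  }
  links <- do.call(rbind, link_rows)
  # split links across two pseudo-studies by row parity
  study_of <- rep_len(c("bloodstudy1", "bloodstudy2"), nrow(links))
  for (st in c("bloodstudy1", "bloodstudy2")) {
    write_tsv(links[study_of == st, ],
              file.path(out_dir, sprintf("eqtl_%s.tsv", st)))
  }
  # GWAS decoys failing the p filter (boundary row is dropped by strict <)
  pd <- take_filler(2)
  gwas_rows$decoy_p <- data.frame(
    snp_id = take_snps(2), trait = traits[[dA]][1],
    p_value = c(1e-5, 2e-4),
    consequence = "missense_variant", mapped_gene = pd)
  gwas <- do.call(rbind, gwas_rows)
  rownames(gwas) <- NULL
  write_tsv(gwas, file.path(out_dir, "gwas_associations.tsv"))

  # ---- differential expression channel -------------------------------
  expr_rows <- list()
  for (d in c(dA, dB)) {
    de <- genes[if (d == dA) chA[, "diff_expr"] else chB[, "diff_expr"]]
    if (length(de)) {
      trusted <- de[seq_along(de) %% 2 == 1]
      mined <- setdiff(de, trusted)
      if (length(trusted)) {
        expr_rows[[paste0("tr", d)]] <- data.frame(
          gene = trusted, disease = d,
          direction = rep_len(c("up", "down"), length(trusted)),
          source = paste0("big_profiling_", d), trusted = "TRUE")
      }
      if (length(mined)) {
        expr_rows[[paste0("tm", d)]] <- data.frame(
          gene = rep(mined, 2), disease = d,
          direction = "unspecified",
          source = rep(c("expr_textdb1", "expr_textdb2"), each = length(mined)),
          trusted = "FALSE")
      }
    }
    expr_rows[[paste0("decoy", d)]] <- data.frame(
      gene = take_filler(1), disease = d, direction = "up",
      source = "expr_textdb1", trusted = "FALSE")
  }
  write_tsv(do.call(rbind, expr_rows),
            file.path(out_dir, "expression_reports.tsv"))

  # ---- text mining channel ------------------------------------------
  for (d in c(dA, dB)) {
    tm <- genes[if (d == dA) chA[, "text_mining"] else chB[, "text_mining"]]
    tbl <- data.frame(gene = c(tm, take_filler(1)),
                      support_count = c(2L + stats::rpois(length(tm), 1),
                                        1L))
    write_tsv(tbl, file.path(out_dir, sprintf("text_mining_%s.tsv", d)))
  }

  # ---- drugs and targets --------------------------------------------
  gs <- spec$group_size
  tpg <- spec$targets_per_group
  module_total <- sum(spec$module_sizes)
  tg1 <- genes[module_total + seq_len(tpg)]          # A-beneficial & B-harmful
  tg2 <- genes[module_total + tpg + seq_len(tpg)]    # A-harmful & B-beneficial
  drug_id <- function(prefix, k) sprintf("%s%03d", prefix, seq_len(k))
  ben_A <- drug_id("DBA", gs)       # first planted_cross_drugs also harm B
  harm_A <- drug_id("DHA", gs)
  ben_B <- drug_id("DBB", gs)
  harm_B <- drug_id("DHB", gs)      # dedicated; cross drugs join via ben_A
  par_A <- drug_id("DPX", spec$n_paradoxical)
  cross <- utils::head(ben_A, spec$planted_cross_drugs)
  bg <- drug_id("DBG", spec$n_background_drugs)
  no_target <- drug_id("DNT", 2)    # background drugs without human targets

  rel <- function(ids, ind = "", contra = "", adv = "") {
    if (!length(ids)) return(NULL)
    data.frame(drug_id = ids, name = paste0("drug_", tolower(ids)),
               indicated = ind, contraindicated = contra,
               adverse_inducing = adv)
  }
  drugs <- rbind(
    rel(setdiff(ben_A, cross), ind = dA),
    rel(cross, ind = dA, contra = dB),
    rel(harm_A[seq_len(gs) %% 2 == 1], contra = dA),
    rel(harm_A[seq_len(gs) %% 2 == 0], adv = dA),
    rel(ben_B, ind = dB),
    rel(harm_B, contra = dB),
    rel(par_A, ind = dA, contra = dA),
    rel(bg), rel(no_target))

  actions <- c("agonist", "antagonist", "inhibitor", "activator")
  # rotation pattern: planted target j is hit by ~70% of the group drugs,
  # starting at drug j (mod group size) — deterministic, and extreme
  # enough that every planted target is overrepresented
  plant_targets <- function(group_ids, target_genes) {
    k <- length(group_ids)
    nh <- max(1L, ceiling(0.7 * k))
    step <- max(1L, k %/% length(target_genes))
    do.call(rbind, lapply(seq_along(target_genes), function(j) {
      hit <- group_ids[(seq_len(nh) + (j - 1) * step - 1) %% k + 1]
      data.frame(drug_id = hit, gene = target_genes[j],
                 action_raw = rep_len(actions, nh), organism = "Human")
    }))
  }
  target_rows <- list(
    plant_targets(ben_A, tg1), plant_targets(harm_B, tg1),
    plant_targets(harm_A, tg2), plant_targets(ben_B, tg2))
  if (tpg == 0) {
    # no planted overrepresentation: every group drug still needs a human
    # target with a defined action, so each gets a private filler target
    for (d in c(dA, dB)) {
      ids <- if (d == dA) c(ben_A, harm_A) else c(ben_B, harm_B)
      fg <- take_filler(length(ids))
      target_rows[[paste0("grpfill_", d)]] <- data.frame(
        drug_id = ids, gene = fg, action_raw = "modifier",
        organism = "Human")
      if (d == dA) chA[match(fg, genes), "drug_target"] <- TRUE
      else chB[match(fg, genes), "drug_target"] <- TRUE
      # cross drugs sit in disease B's harmful group as well, so their
      # targets carry the drug_target channel for both diseases
      cross_fg <- fg[ids %in% cross]
      if (length(cross_fg)) chB[match(cross_fg, genes), "drug_target"] <- TRUE
    }
  }
  # background drugs target filler genes thinly; a few also touch tg1[1]
  bg_genes <- take_filler(spec$n_background_drugs)
  target_rows$bg <- data.frame(drug_id = bg, gene = bg_genes,
                               action_raw = rep_len(actions, length(bg)),
                               organism = "Human")
  if (length(tg1)) {
    target_rows$bg_tg <- data.frame(drug_id = utils::head(bg, 3),
                                    gene = tg1[1],
                                    action_raw = "inhibitor",
                                    organism = "Human")
  }
  # non-human target of a group drug (must never be emitted) and
  # human-target-free background drugs
  target_rows$nonhuman <- data.frame(drug_id = ben_A[1],
                                     gene = take_filler(1),
                                     action_raw = "agonist",
                                     organism = "Mouse")
  target_rows$nt <- data.frame(drug_id = no_target, gene = take_filler(2),
                               action_raw = "binder",
                               organism = "Rattus norvegicus")
  # paradoxical drugs target the first planted A-beneficial target (or a
  # filler gene when no targets are planted)
  if (length(par_A)) {
    target_rows$par <- data.frame(
      drug_id = par_A,
      gene = if (length(tg1)) tg1[1] else take_filler(1),
      action_raw = "agonist", organism = "Human")
  }
  # noise drug_target channel: one singleton indicated drug per noise gene
  noise_tg <- list(genes[chA[, "drug_target"]], genes[chB[, "drug_target"]])
  names(noise_tg) <- c(dA, dB)
  for (d in c(dA, dB)) {
    ng <- setdiff(noise_tg[[d]], c(tg1, tg2))
    if (length(ng)) {
      ids <- sprintf("DZ%d%03d", match(d, c(dA, dB)), seq_along(ng))
      drugs <- rbind(drugs, rel(ids, ind = d))
      target_rows[[paste0("noise", d)]] <- data.frame(
        drug_id = ids, gene = ng, action_raw = "binder", organism = "Human")
    }
  }
  targets <- do.call(rbind, target_rows)
  rownames(targets) <- NULL
  write_tsv(drugs, file.path(out_dir, "drugs.tsv"))
  write_tsv(targets, file.path(out_dir, "drug_targets.tsv"))

  # drug-target evidence channel implied by the tables just written
  chA[match(c(tg1, tg2), genes), "drug_target"] <- TRUE
  chB[match(c(tg1, tg2), genes), "drug_target"] <- TRUE

  # ---- network edges -------------------------------------------------
  shared_genes <- genes[rowSums(chA) > 0 & rowSums(chB) > 0]
  modules <- list()
  off <- 0L
  for (sz in spec$module_sizes) {
    modules[[length(modules) + 1L]] <- genes[off + seq_len(sz)]
    off <- off + sz
  }
  edge_types <- c("coexpression", "physical", "pathway")
  edge_rows <- list()
  for (mod in modules) {
    pr <- utils::combn(mod, 2)
    edge_rows[[length(edge_rows) + 1L]] <- data.frame(
      gene1 = pr[1, ], gene2 = pr[2, ],
      type = rep_len(edge_types, ncol(pr)),
      weight = round(runif(ncol(pr), 0.4, 1), 3))
  }
  if (spec$noise_edge_p > 0 && length(shared_genes) > 1) {
    pr <- utils::combn(shared_genes, 2)
    mod_of <- lapply(modules, function(m) pr[1, ] %in% m & pr[2, ] %in% m)
    same_mod <- Reduce(`|`, mod_of, rep(FALSE, ncol(pr)))
    keep <- !same_mod & runif(ncol(pr)) < spec$noise_edge_p
    if (any(keep)) {
      edge_rows$noise <- data.frame(
        gene1 = pr[1, keep], gene2 = pr[2, keep],
        type = sample(edge_types, sum(keep), replace = TRUE),
        weight = round(runif(sum(keep), 0.4, 1), 3))
    }
  }
  edges <- do.call(rbind, edge_rows)
  if (is.null(edges)) {
    edges <- data.frame(gene1 = character(0), gene2 = character(0),
                        type = character(0), weight = numeric(0))
  }
  rownames(edges) <- NULL
  write_tsv(edges, file.path(out_dir, "edges.tsv"))

  # ---- gene-set collection (GMT) ------------------------------------
  gmt_path <- file.path(out_dir, "genesets.gmt")
  gmt_lines <- c(
    vapply(seq_along(modules), function(i) {
      paste(c(sprintf("PLANTED_MODULE_%d", i), "planted clique",
              modules[[i]]), collapse = "\t")
    }, character(1)),
    vapply(1:3, function(i) {
      paste(c(sprintf("RANDOM_SET_%d", i), "random genes",
              sample(shared_genes, min(15, length(shared_genes)))),
            collapse = "\t")
    }, character(1)))
  writeLines(gmt_lines, gmt_path)

  # ---- alias table and reference sets -------------------------------
  al <- take_filler(2)
  write_tsv(data.frame(alias = paste0("ALIAS_", al), canonical = al),
            file.path(out_dir, "aliases.tsv"))
  # reference gene-disease resource: a subset of the planted shared genes
  ref <- data.frame(gene = genes[shared_idx[seq_len(floor(ps / 2))]])
  write_tsv(ref, file.path(out_dir, "reference_knownsets.tsv"))

  # ---- manifest ------------------------------------------------------
  genes_A <- genes[rowSums(chA) > 0]
  genes_B <- genes[rowSums(chB) > 0]
  eqtl_shared <- genes[chA[, "eqtl"] & chB[, "eqtl"]]
  flinks <- links[links$fdr <= 0.05, c("snp_id", "gene")]
  snpsA <- intersect(gwas_snps[[dA]], flinks$snp_id)
  snpsB <- intersect(gwas_snps[[dB]], flinks$snp_id)
  null_est <- matched_permutation(flinks, snpsA, snpsB, n_perm = 200,
                                  seed = spec$seed + 1L)
  manifest <- list(
    diseases = c(dA, dB),
    seed = spec$seed,
    genes = list(shared = sort_c(shared_genes),
                 planted_shared = sort_c(genes[shared_idx]),
                 disease_A = sort_c(genes_A),
                 disease_B = sort_c(genes_B),
                 eqtl_shared = sort_c(eqtl_shared)),
    modules = lapply(modules, sort_c),
    eqtl = list(observed_shared = null_est$observed,
                expected_null_shared = null_est$null_mean,
                snpsA = sort_c(snpsA), snpsB = sort_c(snpsB)),
    drugs = list(beneficial_A = sort_c(c(ben_A, par_A)),
                 harmful_A = sort_c(harm_A),
                 beneficial_B = sort_c(ben_B),
                 harmful_B = sort_c(c(harm_B, cross)),
                 paradoxical_A = sort_c(par_A),
                 cross_A_ben_B_harm = sort_c(cross),
                 significant_targets = list(
                   beneficial_A = sort_c(tg1), harmful_B = sort_c(tg1),
                   harmful_A = sort_c(tg2), beneficial_B = sort_c(tg2))),
    hpo = list(include = as.list(include_terms),
               exclude = list(exclude_term)),
    planted_gmt_terms = sprintf("PLANTED_MODULE_%d", seq_along(modules)),
    files = list(gwas = "gwas_associations.tsv",
                 trait_map = "trait_map.tsv",
                 eqtl = c("eqtl_bloodstudy1.tsv", "eqtl_bloodstudy2.tsv"),
                 hpo = "hpo_annotations.tsv",
                 expression = "expression_reports.tsv",
                 edges = "edges.tsv", gmt = "genesets.gmt"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # ---- pipeline config ----------------------------------------------
  config <- list(
    diseases = c(dA, dB),
    inputs = list(
      gwas = "gwas_associations.tsv",
      trait_map = "trait_map.tsv",
      eqtl = list(bloodstudy1 = "eqtl_bloodstudy1.tsv",
                  bloodstudy2 = "eqtl_bloodstudy2.tsv"),
      hpo = "hpo_annotations.tsv",
      expression = "expression_reports.tsv",
      text_mining = setNames(
        list(sprintf("text_mining_%s.tsv", dA),
             sprintf("text_mining_%s.tsv", dB)), c(dA, dB)),
      monogenic = setNames(
        list(sprintf("monogenic_%s.tsv", dA),
             sprintf("monogenic_%s.tsv", dB)), c(dA, dB)),
      drugs = "drugs.tsv",
      drug_targets = "drug_targets.tsv",
      edges = "edges.tsv",
      gene_sets = "genesets.gmt",
      aliases = "aliases.tsv",
      references = list(knownsets = "reference_knownsets.tsv")),
    hpo_terms = setNames(list(
      list(include = as.list(unname(include_terms[dA])), exclude = list()),
      list(include = as.list(unname(include_terms[dB])),
           exclude = list(exclude_term))), c(dA, dB)),
    params = list(min_clique = 10L, min_complex = 10L, n_perm = 1000L),
    seed = spec$seed,
    out_dir = "results")
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  invisible(manifest)
}

#' Demonstration fixture specifications
#'
#' Two ready-made study conditions: the noiseless "planted truth only"
#' bundle, on which every pipeline output must equal the manifest
#' exactly, and the realistic noisy bundle, in which background evidence
#' rates create additional shared genes by collision and random edges
#' perturb the planted modules.
#'
#' @param noise If `FALSE`, all background channel rates and the noise
#'   edge probability are zero.
#' @param seed Fixture seed.
#' @return A [fixture_spec()].
#' @export
demo_fixture_spec <- function(noise = TRUE, seed = 20) {
  if (noise) {
    fixture_spec(seed = seed)
  } else {
    fixture_spec(per_channel_rates = c(monogenic = 0, coding_gwas = 0,
                                       eqtl = 0, diff_expr = 0,
                                       text_mining = 0, drug_target = 0),
                 noise_edge_p = 0, seed = seed)
  }
}

#' Generate a null-world eQTL set pair
#'
#' Draws a SNP-to-gene link table with geometric fan-out plus a few
#' high-fan-out trans hub SNPs, and two SNP sets A and B sampled
#' uniformly from the universe with the requested sizes and forced
#' intersection — exactly the null the matched permutation resamples, so
#' p-values computed on these worlds are calibration checks.
#'
#' @param spec A [fixture_spec()] (fields `null_*` are used).
#' @param seed Optional integer seed.
#' @return List with `snpsA`, `snpsB` and `links` (data.frame `snp_id`,
#'   `gene`, `study`, `tissue`, `kind`, `fdr`).
#' @export
gen_null_eqtl_pair <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(seed)) set.seed(seed)
  nU <- spec$null_universe_snps
  snps <- sprintf("ns%06d", seq_len(nU))
  pool <- sprintf("NG%04d", seq_len(spec$null_gene_pool))
  fo <- draw_fanout(nU, spec$eqtl_fanout_mean, spec$null_gene_pool)
  if (spec$null_hub_snps > 0) {
    hubs <- sample.int(nU, spec$null_hub_snps)
    fo[hubs] <- pmin(1L + stats::rpois(spec$null_hub_snps,
                                       spec$null_hub_fanout - 1),
                     spec$null_gene_pool)
  }
  links <- do.call(rbind, lapply(seq_len(nU), function(i) {
    g <- pool[sample.int(spec$null_gene_pool, fo[i])]
    data.frame(snp_id = snps[i], gene = g, study = "nullstudy",
               tissue = "whole_blood",
               kind = c("cis", rep("trans", fo[i] - 1)),
               fdr = 0.01)
  }))
  rownames(links) <- NULL
  core <- sample(snps, spec$null_overlap)
  rest <- setdiff(snps, core)
  extra <- sample(rest, 2 * (spec$null_set_size - spec$null_overlap))
  nx <- spec$null_set_size - spec$null_overlap
  list(snpsA = c(core, extra[seq_len(nx)]),
       snpsB = c(core, extra[nx + seq_len(nx)]),
       links = links)
}
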