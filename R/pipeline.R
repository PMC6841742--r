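known_param_defaults <- function() {
  list(gwas_p_max = 1e-5, eqtl_fdr_max = 0.05, de_min_sources = 2L,
       text_min_studies = 2L, min_clique = 10L, min_complex = 10L,
       alpha = 0.05, n_perm = 10000L)
}

#' Validate and load a pipeline run configuration
#'
#' Reads a YAML configuration, refuses unknown keys (no silent typo
#' tolerance), fills parameter defaults (GWAS p < 1e-5, eQTL FDR <= 0.05,
#' two-source support minima, clique/complex thresholds 10, alpha 0.05,
#' 10000 permutations), resolves input paths relative to the config file
#' and checks that every mandatory path exists. The seed is mandatory:
#' silent nondeterminism is refused.
#'
#' @param path Path to the YAML config.
#' @return A validated config list of class `run_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  known_top <- c("diseases", "inputs", "hpo_terms", "params", "seed",
                 "out_dir")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(cfg$diseases %||% character(0)) != 2) {
    stop("config must declare exactly two diseases", call. = FALSE)
  }
  cfg$diseases <- as.character(cfg$diseases)
  if (is.null(cfg$seed)) stop("config key 'seed' is mandatory", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)

  known_inputs <- c("gwas", "trait_map", "eqtl", "hpo", "expression",
                    "text_mining", "monogenic", "drugs", "drug_targets",
                    "edges", "gene_sets", "aliases", "references")
  unknown <- setdiff(names(cfg$inputs), known_inputs)
  if (length(unknown)) {
    stop("unknown config key(s) under inputs: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  resolve <- function(p) {
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  }
  mandatory <- c("gwas", "trait_map", "eqtl", "hpo", "expression",
                 "text_mining", "drugs", "drug_targets", "edges")
  missing <- mandatory[!mandatory %in% names(cfg$inputs)]
  if (length(missing)) {
    stop("missing mandatory input path(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (k in names(cfg$inputs)) {
    v <- cfg$inputs[[k]]
    if (is.list(v)) {
      cfg$inputs[[k]] <- lapply(v, function(p) resolve(as.character(p)))
    } else {
      cfg$inputs[[k]] <- resolve(as.character(v))
    }
  }
  flat <- unlist(cfg$inputs)
  absent <- flat[!file.exists(flat)]
  if (length(absent)) {
    stop("input file(s) not found: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  for (d in cfg$diseases) {
    if (is.null(cfg$hpo_terms[[d]]$include) ||
        !length(cfg$hpo_terms[[d]]$include)) {
      stop("hpo_terms for '", d, "' must declare include terms",
           call. = FALSE)
    }
  }

  defaults <- known_param_defaults()
  unknown <- setdiff(names(cfg$params), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s) under params: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg$params <- utils::modifyList(defaults, cfg$params %||% list())
  if (cfg$params$min_clique < 2) stop("min_clique must be >= 2",
                                      call. = FALSE)
  if (cfg$params$min_complex < 1) stop("min_complex must be >= 1",
                                       call. = FALSE)
  if (cfg$params$n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  cfg$out_dir <- cfg$out_dir %||% file.path(base, "results")
  if (!startsWith(cfg$out_dir, "/")) cfg$out_dir <- file.path(base, cfg$out_dir)
  cfg$config_hash <- unname(tools::md5sum(path))
  class(cfg) <- "run_config"
  cfg
}

write_tsv_stamped <- function(df, path, hash) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Run the full comorbidity analysis pipeline
#'
#' Executes the stages of the analysis in order: evidence ingestion per
#' disease, drug group construction, shared-gene intersection, network
#' construction and overlapping module detection, module annotation,
#' drug-target and group-overlap tests, evidence-channel enrichment and
#' the matched eQTL permutation. Every stage logs its input/output
#' counts; stage outputs are flushed to the output directory as they are
#' produced, so a failing stage leaves the earlier results on disk
#' (`summary.json` then records `complete: false` before the error is
#' re-signalled).
#'
#' @param cfg A `run_config` from [validate_config()].
#' @return The report bundle (a list of the stage results), invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- cfg$config_hash
  log_lines <- character(0)
  counts <- list()
  bundle <- list(config = cfg)
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  flush_meta <- function(complete) {
    writeLines(log_lines, file.path(out, "log.txt"))
    jsonlite::write_json(
      list(config_hash = hash, complete = complete, seed = cfg$seed,
           params = cfg$params, counts = counts),
      file.path(out, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  run <- function() {
    dA <- cfg$diseases[1]; dB <- cfg$diseases[2]
    p <- cfg$params
    alias <- if (!is.null(cfg$inputs$aliases))
      read_alias_table(cfg$inputs$aliases) else NULL

    # ---- stage: parse shared inputs ---------------------------------
    tm_df <- read_evidence_tsv(cfg$inputs$trait_map, c("trait", "disease"),
                               "trait map")
    trait_map <- setNames(tm_df$disease, tm_df$trait)
    gwas <- parse_gwas_table(cfg$inputs$gwas, trait_map)
    links <- do.call(rbind, lapply(names(cfg$inputs$eqtl), function(st) {
      parse_eqtl_table(cfg$inputs$eqtl[[st]], st)
    }))
    hpo <- parse_hpo_table(cfg$inputs$hpo)
    expr <- parse_expression_table(cfg$inputs$expression)
    drug_table <- parse_drug_tables(cfg$inputs$drugs,
                                    cfg$inputs$drug_targets)
    edges_df <- read_evidence_tsv(cfg$inputs$edges,
                                  c("gene1", "gene2", "type"), "edge list")
    logf("parsed: %d GWAS rows (%d dropped), %d eQTL links, %d HPO rows, %d expression rows, %d drugs, %d edges",
         nrow(gwas), attr(gwas, "n_dropped"), nrow(links), nrow(hpo),
         nrow(expr), nrow(drug_table$drugs), nrow(edges_df))
    counts$parsed <<- list(gwas = nrow(gwas), eqtl_links = nrow(links),
                           hpo = nrow(hpo), expression = nrow(expr),
                           drugs = nrow(drug_table$drugs),
                           edges = nrow(edges_df))

    # ---- stage: evidence ingestion per disease ----------------------
    flinks <- NULL
    dgs <- list(); groups <- list()
    curated_genes <- character(0)
    for (d in cfg$diseases) {
      icfg <- ingest_config(
        gwas_p_max = p$gwas_p_max, eqtl_fdr_max = p$eqtl_fdr_max,
        hpo_include_terms = unlist(cfg$hpo_terms[[d]]$include),
        hpo_exclude_terms = unlist(cfg$hpo_terms[[d]]$exclude %||% list()),
        de_min_sources = p$de_min_sources,
        text_min_studies = p$text_min_studies)
      if (is.null(flinks)) flinks <- filter_eqtl_fdr(links, icfg)
      gw <- gwas[gwas$disease == d, , drop = FALSE]
      coding <- filter_coding_variants(gw, icfg)
      coding <- coding[!is.na(coding$mapped_gene), , drop = FALSE]
      reg <- eqtl_regulated_genes(gw, flinks)
      mono_hpo <- select_hpo_genes(hpo, icfg)
      mono_cur <- if (!is.null(cfg$inputs$monogenic[[d]]))
        names(parse_curated_table(cfg$inputs$monogenic[[d]], d,
                                  "monogenic")$entries) else character(0)
      de <- de_genes_min_support(expr[expr$disease == d, , drop = FALSE],
                                 icfg)
      tm_list <- parse_curated_table(cfg$inputs$text_mining[[d]], d,
                                     "text_mining")
      tm <- text_mined_genes(tm_list, icfg)
      curated_genes <- c(curated_genes, names(tm_list$entries), mono_cur)
      groups[[d]] <- build_drug_groups(drug_table, d)
      tgt <- rbind(group_target_genes(groups[[d]]$beneficial, drug_table),
                   group_target_genes(groups[[d]]$harmful, drug_table))
      dgs[[d]] <- assemble_disease_gene_set(d, list(
        monogenic = union(mono_hpo, mono_cur),
        coding_gwas = data.frame(gene = coding$mapped_gene,
                                 detail = coding$snp_id),
        eqtl = data.frame(gene = reg$gene,
                          detail = paste(reg$snp_id, reg$study, sep = "/")),
        diff_expr = de,
        text_mining = tm,
        drug_target = data.frame(gene = tgt$gene,
                                 detail = paste(tgt$drug_id, tgt$effect,
                                                sep = "/"))),
        namespace = "symbol", alias = alias)
      logf("%s: %d genes (%d coding GWAS, %d eQTL, %d monogenic, %d DE, %d text-mined, %d drug-target); %d beneficial / %d harmful drugs (%d paradoxical)",
           d, length(dgs[[d]]$genes), length(unique(coding$mapped_gene)),
           length(unique(reg$gene)),
           length(union(mono_hpo, mono_cur)), length(de), length(tm),
           length(unique(tgt$gene)),
           length(groups[[d]]$beneficial$drugs),
           length(groups[[d]]$harmful$drugs),
           length(groups[[d]]$paradoxical))
      counts[[paste0("genes_", d)]] <<- length(dgs[[d]]$genes)
      write_tsv_stamped(as_association_table(dgs[[d]]),
                        file.path(out, sprintf("associations_%s.tsv", d)),
                        hash)
    }
    bundle$disease_gene_sets <<- dgs
    bundle$drug_groups <<- groups

    # ---- stage: shared genes ----------------------------------------
    norm <- function(g) normalize_genes(g, "symbol", alias)
    universe <- unique(c(
      norm(gwas$mapped_gene[!is.na(gwas$mapped_gene)]),
      norm(links$gene), norm(hpo$gene), norm(expr$gene),
      norm(drug_table$targets$gene[drug_table$targets$human]),
      norm(edges_df$gene1), norm(edges_df$gene2), norm(curated_genes),
      unlist(lapply(dgs, gene_ids))))
    tbl <- shared_gene_table(dgs[[dA]], dgs[[dB]], universe)
    refs <- list()
    for (nm in names(cfg$inputs$references %||% list())) {
      refs[[nm]] <- norm(read_evidence_tsv(cfg$inputs$references[[nm]],
                                           "gene", "reference set")$gene)
    }
    nov <- novelty_flags(tbl, refs)
    logf("shared genes: %d of universe %d; %d novel vs %d reference set(s)",
         nrow(tbl), length(universe), sum(nov$novel), length(refs))
    counts$shared <<- nrow(tbl)
    counts$universe <<- length(universe)
    counts$novel <<- sum(nov$novel)
    shared_out <- merge(as.data.frame(tbl), nov, by = "gene", sort = FALSE)
    shared_out <- shared_out[order_c(-shared_out$evidence_count,
                                     shared_out$gene), , drop = FALSE]
    write_tsv_stamped(shared_out, file.path(out, "shared_genes.tsv"), hash)
    bundle$shared <<- tbl
    bundle$novelty <<- nov
    if (nrow(tbl) == 0) {
      warning("the two disease gene sets are disjoint; network and module ",
              "stages will be empty", call. = FALSE)
    }

    # ---- stage: channel enrichment ----------------------------------
    enr <- lapply(evidence_channels(), function(ch) {
      r <- channel_enrichment(tbl, ch, dgs[[dA]], dgs[[dB]])
      data.frame(channel = ch, a = r$a, b = r$b, c = r$c, d = r$d,
                 p = r$p, odds_ratio = r$odds_ratio,
                 degenerate = r$degenerate, stringsAsFactors = FALSE)
    })
    enr <- do.call(rbind, enr)
    write_tsv_stamped(enr, file.path(out, "channel_enrichment.tsv"), hash)
    bundle$channel_enrichment <<- enr

    # ---- stage: network and modules ---------------------------------
    net <- build_network(tbl, cfg$inputs$edges)
    cover <- eagle(net, min_clique = p$min_clique,
                   min_complex = p$min_complex)
    overlaps <- module_overlap_genes(cover)
    logf("network: %d nodes, %d edges, %.0f%% connected; %d modules (EQ %.4f), %d overlap genes",
         length(net$nodes), igraph::ecount(net$graph),
         100 * (net$connectivity %||% 0), length(cover$modules), cover$eq,
         length(overlaps))
    counts$network <<- list(nodes = length(net$nodes),
                            edges = igraph::ecount(net$graph),
                            connected = net$n_connected)
    counts$modules <<- length(cover$modules)
    write_network_graphml(net, file.path(out, "network.graphml"))
    if (length(cover$modules)) {
      mod_df <- data.frame(
        module_id = rep(seq_along(cover$modules), lengths(cover$modules)),
        gene = unlist(cover$modules))
    } else {
      mod_df <- data.frame(module_id = integer(0), gene = character(0))
    }
    write_tsv_stamped(mod_df, file.path(out, "modules.tsv"), hash)
    collections <- list()
    if (!is.null(cfg$inputs$gene_sets)) {
      collections$gene_sets <- read_gmt(cfg$inputs$gene_sets)
    }
    ann <- annotate_modules(cover, tbl, collections, alpha = p$alpha)
    jsonlite::write_json(
      list(config_hash = hash, eq = cover$eq,
           sizes = lengths(cover$modules),
           overlap_genes = overlaps, unassigned = cover$unassigned,
           annotations = lapply(ann, function(a) {
             list(module_id = a$module_id, size = a$size,
                  channel_counts = as.list(a$channel_counts),
                  top_terms = utils::head(a$enrichment[
                    a$enrichment$significant,
                    c("collection", "term", "k", "K", "p", "q")], 10))
           })),
      file.path(out, "modules_summary.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
    bundle$network <<- net
    bundle$cover <<- cover
    bundle$annotations <<- ann

    # ---- stage: drug statistics -------------------------------------
    cross_AB <- cross_disease_harm_overlap(groups[[dA]]$beneficial,
                                           groups[[dB]]$harmful)
    cross_BA <- cross_disease_harm_overlap(groups[[dB]]$beneficial,
                                           groups[[dA]]$harmful)
    drug_bg <- drug_table$drugs$drug_id
    ov_AB <- group_overlap_test(groups[[dA]]$beneficial$drugs,
                                groups[[dB]]$harmful$drugs, drug_bg)
    ov_BA <- group_overlap_test(groups[[dB]]$beneficial$drugs,
                                groups[[dA]]$harmful$drugs, drug_bg)
    logf("cross-disease drugs: %d beneficial-%s/harmful-%s (p=%.3g), %d beneficial-%s/harmful-%s (p=%.3g)",
         length(cross_AB), dA, dB, ov_AB$p, length(cross_BA), dB, dA,
         ov_BA$p)
    counts$cross_drugs <<- list(A_ben_B_harm = length(cross_AB),
                                B_ben_A_harm = length(cross_BA))
    overrep <- list()
    for (d in cfg$diseases) {
      for (pol in c("beneficial", "harmful")) {
        tag <- paste(pol, d, sep = "_")
        res <- drug_target_overrep(groups[[d]][[pol]], drug_table,
                                   alpha = p$alpha)
        res <- cbind(group = tag, res)
        overrep[[tag]] <- res
      }
    }
    overrep_df <- do.call(rbind, overrep)
    rownames(overrep_df) <- NULL
    write_tsv_stamped(overrep_df, file.path(out, "drug_target_overrep.tsv"),
                      hash)
    grp_df <- do.call(rbind, lapply(cfg$diseases, function(d) {
      rbind(data.frame(disease = d, polarity = "beneficial",
                       drug_id = groups[[d]]$beneficial$drugs),
            data.frame(disease = d, polarity = "harmful",
                       drug_id = groups[[d]]$harmful$drugs))
    }))
    write_tsv_stamped(grp_df, file.path(out, "drug_groups.tsv"), hash)
    jsonlite::write_json(
      list(config_hash = hash,
           cross_A_ben_B_harm = cross_AB, cross_B_ben_A_harm = cross_BA,
           overlap_tests = list(
             A_ben_B_harm = list(a = ov_AB$a, b = ov_AB$b, c = ov_AB$c,
                                 d = ov_AB$d, p = ov_AB$p),
             B_ben_A_harm = list(a = ov_BA$a, b = ov_BA$b, c = ov_BA$c,
                                 d = ov_BA$d, p = ov_BA$p)),
           paradoxical = lapply(groups, function(g) g$paradoxical)),
      file.path(out, "drug_overlap.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    bundle$cross_drugs <<- list(A_ben_B_harm = cross_AB,
                                B_ben_A_harm = cross_BA,
                                test_AB = ov_AB, test_BA = ov_BA)
    bundle$drug_target_overrep <<- overrep

    # ---- stage: matched eQTL permutation ----------------------------
    snpsA <- intersect(unique(gwas$snp_id[gwas$disease == dA]),
                       unique(flinks$snp_id))
    snpsB <- intersect(unique(gwas$snp_id[gwas$disease == dB]),
                       unique(flinks$snp_id))
    perm <- matched_permutation(flinks, snpsA, snpsB, n_perm = p$n_perm,
                                seed = cfg$seed)
    logf("eQTL sharing: observed %d genes, null mean %.2f, empirical p = %.4g (%d permutations)",
         perm$observed, perm$null_mean, perm$p_empirical, perm$n_perm)
    counts$eqtl_sharing <<- list(observed = perm$observed,
                                 null_mean = perm$null_mean,
                                 p = perm$p_empirical)
    writeLines(as.character(perm$null),
               file.path(out, "permutation_null.txt"))
    jsonlite::write_json(
      list(config_hash = hash, observed = perm$observed,
           n_perm = perm$n_perm, null_mean = perm$null_mean,
           null_ge_observed = perm$null_ge_observed,
           p_empirical = perm$p_empirical),
      file.path(out, "permutation.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    bundle$permutation <<- perm
    invisible(NULL)
  }
  ok <- FALSE
  tryCatch({
    run()
    ok <- TRUE
  }, error = function(e) {
    logf("ERROR: %s", conditionMessage(e))
    flush_meta(complete = FALSE)
    stop(e)
  })
  flush_meta(complete = TRUE)
  logf("pipeline complete: outputs in %s", out)
  invisible(bundle)
}
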