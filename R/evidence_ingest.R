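#' Ingestion configuration
#'
#' Bundles the scalar thresholds of the evidence filters. Defaults follow
#' the conventions of the underlying resources: GWAS associations are
#' suggestive below 1e-5 (strict `<`), eQTL links pass at FDR <= 0.05
#' (inclusive), phenotype annotations count when labelled "frequent"
#' (manifested in at least half of the patients), and differential
#' expression or text-mining support requires at least two independent
#' sources or studies.
#'
#' @param gwas_p_max GWAS association p-value upper bound (strict).
#' @param eqtl_fdr_max eQTL link FDR upper bound (inclusive).
#' @param allowed_consequences Consequence classes counted as coding /
#'   transcript-affecting.
#' @param hpo_include_terms Phenotype term ids that define the disease.
#' @param hpo_exclude_terms Term ids removed before gene selection
#'   (term-level exclusion; must be disjoint from the include set).
#' @param hpo_frequency_labels Frequency labels that qualify an annotation.
#' @param de_min_sources Minimum distinct non-trusted sources for a
#'   differential-expression call.
#' @param text_min_studies Minimum supporting studies for a text-mining call.
#' @return A list of class `ingest_config`.
#' @export
ingest_config <- function(gwas_p_max = 1e-5,
                          eqtl_fdr_max = 0.05,
                          allowed_consequences = c("splice_region_variant",
                                                   "missense_variant",
                                                   "synonymous_variant",
                                                   "non_coding_transcript_exon_variant"),
                          hpo_include_terms = character(0),
                          hpo_exclude_terms = character(0),
                          hpo_frequency_labels = "frequent",
                          de_min_sources = 2L,
                          text_min_studies = 2L) {
  if (gwas_p_max <= 0 || eqtl_fdr_max <= 0) {
    stop("thresholds must be strictly positive", call. = FALSE)
  }
  if (de_min_sources < 1 || text_min_studies < 1) {
    stop("minimum support counts must be >= 1", call. = FALSE)
  }
  clash <- intersect(hpo_include_terms, hpo_exclude_terms)
  if (length(clash)) {
    stop("HPO include and exclude term sets overlap: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  structure(list(gwas_p_max = gwas_p_max,
                 eqtl_fdr_max = eqtl_fdr_max,
                 allowed_consequences = allowed_consequences,
                 hpo_include_terms = hpo_include_terms,
                 hpo_exclude_terms = hpo_exclude_terms,
                 hpo_frequency_labels = hpo_frequency_labels,
                 de_min_sources = as.integer(de_min_sources),
                 text_min_studies = as.integer(text_min_studies)),
            class = "ingest_config")
}

#' Parse a GWAS association table
#'
#' Reads variant-trait associations (TSV columns `snp_id`, `trait`,
#' `p_value`, `consequence`, optional `mapped_gene`) and maps each trait
#' to a disease label. Rows whose trait is absent from `trait_map` are
#' dropped; the number of dropped rows is attached as attribute
#' `n_dropped` and reported with a message.
#'
#' @param path Path to the GWAS TSV.
#' @param trait_map Named character vector, trait -> disease label.
#'   Related traits (e.g. blood-pressure or eosinophil-count phenotypes)
#'   are mapped to the disease with full weight.
#' @return data.frame with columns `snp_id`, `trait`, `disease`,
#'   `p_value` (numeric), `consequence`, `mapped_gene` (`NA` when absent).
#' @export
parse_gwas_table <- function(path, trait_map) {
  df <- read_evidence_tsv(path, c("snp_id", "trait", "p_value", "consequence"),
                          "GWAS table")
  df$p_value <- parse_numeric_col(df$p_value, "p_value", "GWAS table")
  if (nrow(df) && any(df$p_value <= 0 | df$p_value > 1)) {
    stop("GWAS table: p_value out of (0, 1] at data row(s) ",
         paste(which(df$p_value <= 0 | df$p_value > 1), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) && any(!nzchar(df$snp_id))) {
    stop("GWAS table: empty snp_id", call. = FALSE)
  }
  if (!"mapped_gene" %in% names(df)) df$mapped_gene <- NA_character_
  df$mapped_gene[!nzchar(df$mapped_gene) | is.na(df$mapped_gene)] <- NA_character_
  mapped <- df$trait %in% names(trait_map)
  n_dropped <- sum(!mapped)
  if (n_dropped) {
    message(sprintf("parse_gwas_table: dropped %d row(s) with unmapped traits",
                    n_dropped))
  }
  out <- df[mapped, , drop = FALSE]
  out$disease <- unname(trait_map[out$trait])
  out <- out[, c("snp_id", "trait", "disease", "p_value", "consequence",
                 "mapped_gene")]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Filter GWAS variants to coding / transcript-affecting hits
#'
#' Keeps rows with `p_value` strictly below `cfg$gwas_p_max` and a
#' consequence in the allowed set. Input order is preserved.
#'
#' @param vars data.frame from [parse_gwas_table()].
#' @param cfg An [ingest_config()].
#' @return Filtered data.frame.
#' @export
filter_coding_variants <- function(vars, cfg) {
  stopifnot(inherits(cfg, "ingest_config"))
  if (!length(cfg$allowed_consequences)) {
    stop("allowed_consequences must be non-empty", call. = FALSE)
  }
  keep <- vars$p_value < cfg$gwas_p_max &
    vars$consequence %in% cfg$allowed_consequences
  out <- vars[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse one eQTL study's SNP-gene link table
#'
#' Columns: `snp_id`, `gene`, `tissue`, `kind` (`cis`/`trans`), `fdr`.
#' Links are labelled with the given study name. Duplicate
#' (snp, gene, study, tissue) keys and out-of-range FDR values are
#' refused.
#'
#' @param path Path to the eQTL TSV.
#' @param study Study label attached to every link.
#' @return data.frame with columns `snp_id`, `gene`, `study`, `tissue`,
#'   `kind`, `fdr`.
#' @export
parse_eqtl_table <- function(path, study) {
  df <- read_evidence_tsv(path, c("snp_id", "gene", "tissue", "kind", "fdr"),
                          "eQTL table")
  bad_kind <- setdiff(unique(df$kind), c("cis", "trans"))
  if (length(bad_kind)) {
    stop("eQTL table: kind outside {cis, trans}: ",
         paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  df$fdr <- parse_numeric_col(df$fdr, "fdr", "eQTL table")
  if (nrow(df) && any(df$fdr < 0 | df$fdr > 1)) {
    stop("eQTL table: fdr out of [0, 1] at data row(s) ",
         paste(which(df$fdr < 0 | df$fdr > 1), collapse = ", "),
         call. = FALSE)
  }
  df$study <- study
  key <- paste(df$snp_id, df$gene, df$study, df$tissue, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- df[which(dup)[1], ]
    stop(sprintf("eQTL table: duplicate link (%s, %s, %s, %s)",
                 first$snp_id, first$gene, first$study, first$tissue),
         call. = FALSE)
  }
  out <- df[, c("snp_id", "gene", "study", "tissue", "kind", "fdr")]
  rownames(out) <- NULL
  out
}

#' Keep eQTL links passing the FDR threshold
#'
#' The threshold is inclusive: a link with FDR exactly at the cutoff has
#' passed it.
#'
#' @param links data.frame from [parse_eqtl_table()] (possibly several
#'   studies row-bound).
#' @param cfg An [ingest_config()].
#' @return Filtered data.frame.
#' @export
filter_eqtl_fdr <- function(links, cfg) {
  stopifnot(inherits(cfg, "ingest_config"))
  out <- links[links$fdr <= cfg$eqtl_fdr_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes regulated by disease-associated eQTL SNPs
#'
#' Overlaps the disease's GWAS SNPs with the eQTL SNP-gene links and
#' returns every gene regulated by at least one overlapping SNP, with the
#' supporting (snp, study) pairs as provenance. No p-value or consequence
#' filter is applied here: all GWAS hits of the disease feed the eQTL
#' channel, not only the coding ones.
#'
#' @param gwas data.frame of the disease's GWAS variants (column `snp_id`).
#' @param links FDR-filtered link data.frame.
#' @return data.frame with columns `gene`, `snp_id`, `study`, one row per
#'   distinct supporting pair, sorted by (gene, snp_id, study).
#' @export
eqtl_regulated_genes <- function(gwas, links) {
  hit <- links[links$snp_id %in% unique(gwas$snp_id),
               c("gene", "snp_id", "study"), drop = FALSE]
  hit <- unique(hit)
  hit <- hit[order_c(hit$gene, hit$snp_id, hit$study), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

#' Select genes from phenotype-ontology annotations
#'
#' A gene qualifies when it carries at least one annotation whose term is
#' in the include set, whose frequency label qualifies (by default
#' "frequent", i.e. manifested in at least 50% of patients), and whose
#' term is not in the exclude set. Exclusion is term-level, not
#' gene-level: a gene annotated to both an included and an excluded term
#' through distinct annotations is kept through the included one.
#'
#' @param ann data.frame with columns `gene`, `term_id`, `frequency_label`.
#' @param cfg An [ingest_config()] with non-empty `hpo_include_terms`.
#' @return Sorted character vector of qualifying genes.
#' @export
select_hpo_genes <- function(ann, cfg) {
  stopifnot(inherits(cfg, "ingest_config"))
  if (!length(cfg$hpo_include_terms)) {
    stop("hpo_include_terms must be non-empty", call. = FALSE)
  }
  keep <- ann$term_id %in% cfg$hpo_include_terms &
    !(ann$term_id %in% cfg$hpo_exclude_terms) &
    ann$frequency_label %in% cfg$hpo_frequency_labels
  sort_c(unique(ann$gene[keep]))
}

#' Parse a phenotype-annotation table
#'
#' @param path TSV with columns `gene`, `term_id`, `frequency_label`.
#' @param term_prefix Expected ontology prefix (default `"HP:"`); rows
#'   with another prefix are refused.
#' @return data.frame of the three columns.
#' @export
parse_hpo_table <- function(path, term_prefix = "HP:") {
  df <- read_evidence_tsv(path, c("gene", "term_id", "frequency_label"),
                          "phenotype annotation table")
  bad <- !startsWith(df$term_id, term_prefix)
  if (any(bad)) {
    stop("phenotype annotation table: term id(s) outside the declared ",
         "ontology prefix: ",
         paste(utils::head(unique(df$term_id[bad]), 5), collapse = ", "),
         call. = FALSE)
  }
  df[, c("gene", "term_id", "frequency_label")]
}

#' Parse a differential-expression report table
#'
#' @param path TSV with columns `gene`, `disease`, `direction`
#'   (`up`/`down`/`unspecified`), `source`, `trusted` (`TRUE`/`FALSE`).
#' @return data.frame with `trusted` as logical.
#' @export
parse_expression_table <- function(path) {
  df <- read_evidence_tsv(path, c("gene", "disease", "direction", "source",
                                  "trusted"), "expression report table")
  bad_dir <- setdiff(unique(df$direction), c("up", "down", "unspecified"))
  if (length(bad_dir)) {
    stop("expression report table: direction outside {up, down, unspecified}: ",
         paste(bad_dir, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) && any(!nzchar(df$source))) {
    stop("expression report table: empty source", call. = FALSE)
  }
  df$trusted <- toupper(df$trusted) %in% c("TRUE", "T", "1")
  df
}

#' Differentially expressed genes with minimum source support
#'
#' A gene qualifies if it appears in at least one trusted report (a
#' signature from a single large profiling study is taken at face value),
#' or in reports from at least `cfg$de_min_sources` distinct non-trusted
#' sources (text-mining collections of expression claims). Distinctness is
#' counted on source labels, not rows.
#'
#' @param reports data.frame from [parse_expression_table()] (already
#'   restricted to one disease).
#' @param cfg An [ingest_config()].
#' @return Sorted character vector of qualifying genes.
#' @export
de_genes_min_support <- function(reports, cfg) {
  stopifnot(inherits(cfg, "ingest_config"))
  if (!nrow(reports)) return(character(0))
  trusted_genes <- unique(reports$gene[reports$trusted])
  untr <- unique(reports[!reports$trusted, c("gene", "source"), drop = FALSE])
  n_src <- table(untr$gene)
  multi <- names(n_src)[n_src >= cfg$de_min_sources]
  sort_c(unique(c(trusted_genes, multi)))
}

#' Build a curated gene list
#'
#' @param disease Disease label.
#' @param channel Evidence channel of the list (`text_mining` or
#'   `monogenic`).
#' @param entries Named integer vector, gene -> supporting study count
#'   (all counts >= 1).
#' @return List of class `curated_gene_list`.
#' @export
curated_gene_list <- function(disease, channel, entries) {
  assert_channels(channel)
  entries <- setNames(as.integer(entries), names(entries))
  if (length(entries) && any(entries < 1)) {
    stop("support counts must be >= 1", call. = FALSE)
  }
  structure(list(disease = disease, channel = channel, entries = entries),
            class = "curated_gene_list")
}

#' Parse a curated gene list table
#'
#' @param path TSV with columns `gene`, `support_count`.
#' @inheritParams curated_gene_list
#' @return A `curated_gene_list`.
#' @export
parse_curated_table <- function(path, disease, channel) {
  df <- read_evidence_tsv(path, c("gene", "support_count"),
                          "curated gene list")
  counts <- parse_numeric_col(df$support_count, "support_count",
                              "curated gene list")
  curated_gene_list(disease, channel, setNames(as.integer(counts), df$gene))
}

#' Text-mined genes with minimum study support
#'
#' @param lst A `curated_gene_list` with channel `text_mining`.
#' @param cfg An [ingest_config()].
#' @return Sorted character vector of genes supported by at least
#'   `cfg$text_min_studies` independent studies.
#' @export
text_mined_genes <- function(lst, cfg) {
  stopifnot(inherits(lst, "curated_gene_list"), inherits(cfg, "ingest_config"))
  if (lst$channel != "text_mining") {
    stop("list channel must be text_mining", call. = FALSE)
  }
  sort_c(names(lst$entries)[lst$entries >= cfg$text_min_studies])
}

#' Assemble a disease gene set from per-channel contributions
#'
#' Unions the genes contributed by each evidence channel into one
#' evidence-labelled set. Each element of `channel_sets` is either a
#' character vector of genes or a data.frame with columns `gene` and
#' `detail` (provenance, e.g. the supporting SNP/study pair). Gene
#' identifiers are normalized into the declared namespace; a mix of
#' namespaces is refused rather than silently merged.
#'
#' @param disease Disease label.
#' @param channel_sets Named list, channel -> genes (character vector or
#'   data.frame(gene, detail)); names must be evidence channels.
#' @param namespace Gene namespace, `"symbol"` or `"numeric"`.
#' @param alias Optional alias mapping (see [normalize_genes()]).
#' @return Object of class `disease_gene_set`: list with `disease`,
#'   `genes` (named list, gene -> sorted character vector of channels) and
#'   `provenance` (data.frame gene/channel/detail).
#' @export
assemble_disease_gene_set <- function(disease, channel_sets,
                                      namespace = "symbol", alias = NULL) {
  assert_channels(names(channel_sets))
  prov <- list()
  for (ch in names(channel_sets)) {
    x <- channel_sets[[ch]]
    if (is.data.frame(x)) {
      if (!all(c("gene", "detail") %in% names(x))) {
        stop("channel data.frame needs columns gene, detail", call. = FALSE)
      }
      g <- as.character(x$gene); detail <- as.character(x$detail)
    } else {
      g <- as.character(x); detail <- rep("", length(g))
    }
    if (!length(g)) next
    g <- normalize_genes(g, namespace, alias)
    prov[[ch]] <- data.frame(gene = g, channel = ch, detail = detail,
                             stringsAsFactors = FALSE)
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(gene = character(0), channel = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  prov <- unique(prov)
  prov <- prov[order_c(prov$gene, prov$channel, prov$detail), , drop = FALSE]
  rownames(prov) <- NULL
  genes <- lapply(split(prov$channel, prov$gene),
                  function(ch) sort_c(unique(ch)))
  genes <- genes[order_c(names(genes))]
  structure(list(disease = disease, genes = genes, provenance = prov),
            class = "disease_gene_set")
}

#' @export
print.disease_gene_set <- function(x, ...) {
  tab <- table(unlist(x$genes, use.names = FALSE))
  cat(sprintf("disease gene set '%s': %d genes\n", x$disease, length(x$genes)))
  for (ch in names(tab)) cat(sprintf("  %-12s %d\n", ch, tab[[ch]]))
  invisible(x)
}

#' Genes of a disease gene set
#' @param x A `disease_gene_set`.
#' @return Sorted character vector of gene identifiers.
#' @export
gene_ids <- function(x) {
  stopifnot(inherits(x, "disease_gene_set"))
  names(x$genes)
}

#' Export a disease gene set as a tidy association table
#'
#' @param x A `disease_gene_set`.
#' @return data.frame with columns `gene`, `channels` (';'-joined sorted
#'   labels) and `provenance` (JSON-encoded list of channel/detail pairs).
#' @export
as_association_table <- function(x) {
  stopifnot(inherits(x, "disease_gene_set"))
  genes <- names(x$genes)
  prov_by_gene <- split(x$provenance[, c("channel", "detail")],
                        x$provenance$gene)
  data.frame(
    gene = genes,
    channels = vapply(x$genes, paste, character(1), collapse = ";"),
    provenance = vapply(genes, function(g) {
      as.character(jsonlite::toJSON(prov_by_gene[[g]], dataframe = "rows"))
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
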