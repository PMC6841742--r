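#' Evidence-labelled table of genes shared by two diseases
#'
#' Intersects two disease gene sets. Each row records the gene, the
#' evidence channels supporting it in each disease, and the total number
#' of distinct channels (`evidence_count`). Rows are sorted by
#' (evidence_count descending, gene ascending), a total deterministic
#' order. The gene universe (all genes attested in any input source of
#' the run) is stored for downstream enrichment tests.
#'
#' @param A,B `disease_gene_set` objects in the same gene namespace.
#' @param universe Character vector: all genes attested anywhere in the
#'   run's inputs. Must be non-empty and contain the genes of A and B.
#' @return Object of class `shared_gene_table`: a data.frame with columns
#'   `gene`, `channels_A`, `channels_B` (';'-joined sorted labels),
#'   `evidence_count`, with attributes `universe` and `diseases`.
#' @export
shared_gene_table <- function(A, B, universe) {
  stopifnot(inherits(A, "disease_gene_set"), inherits(B, "disease_gene_set"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty", call. = FALSE)
  out_of_u <- setdiff(union(gene_ids(A), gene_ids(B)), universe)
  if (length(out_of_u)) {
    stop("disease gene(s) outside the declared universe: ",
         paste(utils::head(out_of_u, 5), collapse = ", "), call. = FALSE)
  }
  shared <- intersect(gene_ids(A), gene_ids(B))
  rows <- data.frame(
    gene = shared,
    channels_A = vapply(shared, function(g) paste(A$genes[[g]], collapse = ";"),
                        character(1)),
    channels_B = vapply(shared, function(g) paste(B$genes[[g]], collapse = ";"),
                        character(1)),
    evidence_count = vapply(shared, function(g) {
      length(union(A$genes[[g]], B$genes[[g]]))
    }, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  rows <- rows[order_c(-rows$evidence_count, rows$gene), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, class = c("shared_gene_table", "data.frame"),
            universe = universe, diseases = c(A$disease, B$disease))
}

#' @export
print.shared_gene_table <- function(x, ...) {
  d <- attr(x, "diseases")
  cat(sprintf("%d genes shared by %s and %s (universe: %d genes)\n",
              nrow(x), d[1], d[2], length(attr(x, "universe"))))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

# channel membership of a disease gene set, as a character vector of genes
channel_genes <- function(dgs, channel) {
  names(dgs$genes)[vapply(dgs$genes, function(ch) channel %in% ch, logical(1))]
}

#' Flag shared genes absent from reference gene-disease resources
#'
#' A shared gene is novel when no supplied reference set (e.g. local
#' extracts of large gene-disease association databases) contains it.
#'
#' @param tbl A `shared_gene_table`.
#' @param references Named list of character vectors (resource name ->
#'   gene set). May be empty, in which case every shared gene is novel.
#' @return data.frame with columns `gene`, `novel`, plus one logical
#'   `in_<name>` column per reference.
#' @export
novelty_flags <- function(tbl, references = list()) {
  stopifnot(inherits(tbl, "shared_gene_table"))
  out <- data.frame(gene = tbl$gene, stringsAsFactors = FALSE)
  novel <- rep(TRUE, nrow(tbl))
  for (nm in names(references)) {
    hit <- tbl$gene %in% references[[nm]]
    out[[paste0("in_", nm)]] <- hit
    novel <- novel & !hit
  }
  out$novel <- novel
  out
}

#' Enrichment of one evidence channel between the two diseases
#'
#' Tests whether carrying the channel for disease A and carrying it for
#' disease B co-occur in the same genes more often than chance predicts,
#' by a one-sided Fisher test on the 2x2 table over the declared gene
#' universe (rows: gene carries the channel for A yes/no; columns: same
#' for B). The universe defaults to the one stored in the shared-gene
#' table and is always part of the result, since the p-value is
#' background-dependent.
#'
#' @param tbl A `shared_gene_table`.
#' @param channel One evidence channel label.
#' @param A,B The two `disease_gene_set` objects.
#' @param universe Optional override of the background universe.
#' @return A `fisher_result` with an additional `universe_size` element;
#'   degenerate tables (a zero margin) return `p = 1` flagged degenerate.
#' @export
channel_enrichment <- function(tbl, channel, A, B, universe = NULL) {
  stopifnot(inherits(tbl, "shared_gene_table"))
  assert_channels(channel)
  universe <- unique(universe %||% attr(tbl, "universe"))
  x <- intersect(channel_genes(A, channel), universe)
  y <- intersect(channel_genes(B, channel), universe)
  a <- length(intersect(x, y))
  b <- length(x) - a
  c <- length(y) - a
  d <- length(universe) - a - b - c
  res <- fisher_one_sided(a, b, c, d)
  res$universe_size <- length(universe)
  res$channel <- channel
  res
}
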