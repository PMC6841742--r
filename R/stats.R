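#' One-sided Fisher's exact test for a 2x2 table
#'
#' Computes the exact upper-tail p-value `P(X >= a)` of the hypergeometric
#' distribution of the top-left cell with all margins fixed, i.e. the
#' one-sided (greater) Fisher's exact test used throughout the pipeline
#' for co-occurrence and overrepresentation questions. Evaluation goes
#' through the log-space hypergeometric tail, so totals up to about 1e6
#' are handled without under- or overflow.
#'
#' @param a,b,c,d Non-negative integer cell counts of the 2x2 table,
#'   laid out as rows = condition 1 (yes/no), columns = condition 2
#'   (yes/no); `a` is the joint-positive cell whose excess is tested.
#' @return An object of class `fisher_result`: a list with the four cells,
#'   `p` (upper-tail p-value), `odds_ratio` (sample odds ratio, `Inf` when
#'   `b*c == 0` and `a*d > 0`, `NaN` for 0/0), `side = "greater"` and
#'   `degenerate` (TRUE when a margin is zero or full, in which case
#'   `p = 1` carries no signal).
#' @examples
#' fisher_one_sided(8, 2, 2, 988)$p
#' @export
fisher_one_sided <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  n <- a + b + c + d
  if (n < 1) stop("table total must be >= 1", call. = FALSE)
  # X ~ Hypergeometric(white = a + b, black = c + d, drawn = a + c)
  p <- phyper(a - 1, m = a + b, n = c + d, k = a + c, lower.tail = FALSE)
  p <- min(max(p, 0), 1)
  num <- a * d
  den <- b * c
  odds <- if (den == 0) {
    if (num == 0) NaN else Inf
  } else {
    num / den
  }
  degenerate <- (a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)
  structure(list(a = a, b = b, c = c, d = d, p = p, odds_ratio = odds,
                 side = "greater", degenerate = degenerate),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("2x2 table [%d %d; %d %d], one-sided Fisher p = %.4g, OR = %.4g%s\n",
              x$a, x$b, x$c, x$d, x$p, x$odds_ratio,
              if (x$degenerate) " (degenerate margins)" else ""))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns BH-adjusted p-values in input order. This is the standard
#' step-up FDR control: sort ascending, take running minima of
#' `p(j) * m / j` from the largest rank down, cap at 1.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

# Shared worker: one-sided Fisher per term over a fixed background, BH
# across the family, tidy sorted data.frame out.
overrep_frame <- function(items, k, K, n, N, alpha) {
  p <- vapply(seq_along(items), function(i) {
    fisher_one_sided(k[i], n - k[i], K[i] - k[i], N - n - K[i] + k[i])$p
  }, numeric(1))
  q <- bh_adjust(p)
  out <- data.frame(term = items, k = k, K = K, n = n, N = N,
                    p = p, q = q, significant = q <= alpha,
                    stringsAsFactors = FALSE)
  out[order_c(out$q, out$p, out$term), , drop = FALSE]
}

#' Gene-set overrepresentation by one-sided Fisher tests
#'
#' Tests each term of a collection for overrepresentation in a query set
#' against a declared background, with BH correction across all terms of
#' the collection. Terms are intersected with the background before
#' testing, mirroring the convention that all genes of the annotation
#' resource form the background universe.
#'
#' @param query Character vector of query genes (must be a subset of
#'   `background`).
#' @param collection Named list of character vectors (term -> member genes),
#'   e.g. from [read_gmt()].
#' @param background Character vector: the background gene universe.
#' @param alpha Significance threshold applied to BH-adjusted values.
#' @return A data.frame with one row per term: `term`, `k` (query hits),
#'   `K` (term size in background), `n` (query size), `N` (background
#'   size), `p`, `q`, `significant`; sorted by (q, p, term).
#' @export
gene_set_overrep <- function(query, collection, background, alpha = 0.05) {
  background <- unique(background)
  if (!length(background)) stop("background must be non-empty", call. = FALSE)
  query <- unique(query)
  out_of_bg <- setdiff(query, background)
  if (length(out_of_bg)) {
    stop("query gene(s) outside the background: ",
         paste(utils::head(out_of_bg, 5), collapse = ", "), call. = FALSE)
  }
  if (!length(collection)) {
    return(overrep_frame(character(0), integer(0), integer(0),
                         length(query), length(background), alpha))
  }
  terms <- sort_c(names(collection))
  K <- integer(length(terms))
  k <- integer(length(terms))
  for (i in seq_along(terms)) {
    members <- intersect(unique(collection[[terms[i]]]), background)
    K[i] <- length(members)
    k[i] <- length(intersect(members, query))
  }
  overrep_frame(terms, k, K, length(query), length(background), alpha)
}

#' Drug-target overrepresentation within a drug group
#'
#' For each gene targeted by at least one drug of the group, tests whether
#' the group hits that target more often than the drug-wide background
#' does. The counting unit is the drug: `a` = group drugs targeting the
#' gene, `b` = group drugs not targeting it, `c` = background non-group
#' drugs targeting it, `d` = the remainder. The background is every drug
#' with at least one human target carrying a defined action. BH correction
#' is applied across the genes tested within the group.
#'
#' @param group A `drug_group` (see [build_drug_groups()]).
#' @param drug_table A `drug_table` (see [parse_drug_tables()]).
#' @param alpha Significance threshold on BH-adjusted values.
#' @return A data.frame as in [gene_set_overrep()] with `term` = gene.
#' @export
drug_target_overrep <- function(group, drug_table, alpha = 0.05) {
  stopifnot(inherits(group, "drug_group"), inherits(drug_table, "drug_table"))
  tg <- drug_table$targets
  tg <- tg[tg$human & nzchar(tg$action_raw), , drop = FALSE]
  background <- sort_c(unique(tg$drug_id))
  missing <- setdiff(group$drugs, background)
  if (length(missing)) {
    stop("group drug(s) outside the background of drugs with human targets: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # one (drug, gene) pair counts once regardless of action multiplicity
  pair <- unique(tg[, c("drug_id", "gene")])
  pair$in_group <- pair$drug_id %in% group$drugs
  genes <- sort_c(unique(pair$gene[pair$in_group]))
  n <- length(group$drugs)
  N <- length(background)
  a <- vapply(genes, function(g) sum(pair$in_group & pair$gene == g), integer(1))
  hits <- vapply(genes, function(g) sum(pair$gene == g), integer(1))
  overrep_frame(genes, a, hits, n, N, alpha)
}

#' One-sided overlap test between two sets over a background
#'
#' Tests whether two sets (e.g. drugs beneficial for one disease and
#' harmful for the other) co-occur more than chance predicts over a
#' declared background, via the one-sided Fisher test on the 2x2
#' membership table.
#'
#' @param setX,setY Character vectors, subsets of `background`.
#' @param background Character vector: the common universe.
#' @return A `fisher_result`.
#' @export
group_overlap_test <- function(setX, setY, background) {
  background <- unique(background)
  if (!length(background)) stop("background must be non-empty", call. = FALSE)
  setX <- unique(setX); setY <- unique(setY)
  bad <- c(setdiff(setX, background), setdiff(setY, background))
  if (length(bad)) {
    stop("set member(s) outside the background: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  a <- length(intersect(setX, setY))
  b <- length(setX) - a
  c <- length(setY) - a
  d <- length(background) - a - b - c
  fisher_one_sided(a, b, c, d)
}

#' Matched permutation test for eQTL-mediated gene sharing
#'
#' Tests whether two diseases' eQTL SNP sets regulate more genes in common
#' than expected by chance. The observed statistic is
#' `|genes(A) intersect genes(B)|`, where `genes(S)` is the set of genes
#' regulated by at least one SNP of `S` according to the (already
#' FDR-filtered) link table. Each of `n_perm` replicates draws a random
#' pair of SNP sets from the pooled eQTL SNP universe that preserves the
#' sizes and the intersection size of the observed pair exactly — a shared
#' core of size `|A ∩ B|` plus disjoint remainders — and recomputes the
#' statistic. Resampling SNPs (not genes) preserves the many-to-many
#' SNP-to-gene fan-out that inflates sharing under the null. The empirical
#' p-value uses the add-one estimator `(r + 1) / (n_perm + 1)`, which is
#' never zero.
#'
#' @param links A data.frame with columns `snp_id` and `gene` (one row per
#'   regulatory link; extra columns are ignored).
#' @param snpsA,snpsB Character vectors of SNP ids, subsets of the SNP
#'   universe `unique(links$snp_id)`.
#' @param n_perm Number of permutation replicates (default 10000).
#' @param seed Integer seed for the replicate draws.
#' @return An object of class `permutation_result`: list with `observed`,
#'   `n_perm`, `null_mean`, `null_ge_observed`, `p_empirical`, and `null`
#'   (the integer null distribution, for audit).
#' @export
matched_permutation <- function(links, snpsA, snpsB, n_perm = 10000,
                                seed = NULL) {
  stopifnot(is.data.frame(links), all(c("snp_id", "gene") %in% names(links)))
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  snpsA <- unique(as.character(snpsA))
  snpsB <- unique(as.character(snpsB))
  universe <- unique(as.character(links$snp_id))
  bad <- c(setdiff(snpsA, universe), setdiff(snpsB, universe))
  if (length(bad)) {
    stop("SNP(s) outside the eQTL universe: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  nA <- length(snpsA); nB <- length(snpsB)
  core <- length(intersect(snpsA, snpsB))
  extraA <- nA - core
  extraB <- nB - core
  if (core + extraA + extraB > length(universe)) {
    stop("cannot sample: |A| + |B| - |A n B| exceeds the SNP universe",
         call. = FALSE)
  }

  # integer-indexed SNP -> genes lookup for fast replicate evaluation
  snp_idx <- match(links$snp_id, universe)
  gene_ids <- match(links$gene, unique(links$gene))
  by_snp <- vector("list", length(universe))
  if (length(universe)) {
    spl <- split(gene_ids, snp_idx)
    by_snp[as.integer(names(spl))] <- spl
  }
  genes_of <- function(idx) {
    if (!length(idx)) return(integer(0))
    unique(unlist(by_snp[idx], use.names = FALSE))
  }
  observed <- length(intersect(genes_of(match(snpsA, universe)),
                               genes_of(match(snpsB, universe))))

  if (!is.null(seed)) set.seed(seed)
  nU <- length(universe)
  null <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    pair <- sample_matched_pair(nU, nA, nB, core)
    null[i] <- length(intersect(genes_of(pair$A), genes_of(pair$B)))
  }
  r <- sum(null >= observed)
  structure(list(observed = observed, n_perm = n_perm,
                 null_mean = mean(null), null_ge_observed = r,
                 p_empirical = (r + 1) / (n_perm + 1), null = null),
            class = "permutation_result")
}

#' Draw one size- and intersection-matched pair of index sets
#'
#' The elementary step of the matched permutation null: draws, uniformly
#' without replacement from `1:n_universe`, a shared core of size
#' `n_core` and two disjoint remainders, so that the returned pair
#' satisfies `|A| = nA`, `|B| = nB` and `|A intersect B| = n_core` by
#' construction. Uses the current RNG state.
#'
#' @param n_universe Size of the index universe.
#' @param nA,nB Target set sizes.
#' @param n_core Target intersection size.
#' @return List with integer vectors `A` and `B`.
#' @export
sample_matched_pair <- function(n_universe, nA, nB, n_core) {
  if (n_core > min(nA, nB) || nA + nB - n_core > n_universe) {
    stop("infeasible matched-pair sizes", call. = FALSE)
  }
  extraA <- nA - n_core
  extraB <- nB - n_core
  draw <- sample.int(n_universe, n_core + extraA + extraB, replace = FALSE)
  coreS <- draw[seq_len(n_core)]
  list(A = c(coreS, draw[n_core + seq_len(extraA)]),
       B = c(coreS, draw[n_core + extraA + seq_len(extraB)]))
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "matched permutation: observed %d shared genes, null mean %.2f over %d replicates, p = %.4g\n",
    x$observed, x$null_mean, x$n_perm, x$p_empirical))
  invisible(x)
}
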