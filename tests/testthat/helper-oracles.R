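# Independent oracles and fixture builders shared across the test files.
# Every oracle here is written from the definition, not from the package
# implementation it checks.

# Brute-force one-sided Fisher p: sum hypergeometric point masses over the
# upper tail of the top-left cell, margins fixed.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  xs <- a:hi
  if (a > hi) return(0)
  logp <- lchoose(r1, xs) + lchoose(n - r1, c1 - xs) - lchoose(n, c1)
  sum(exp(logp))
}

# Definitional O(m^2) BH: q(i) = min(1, min over j with p(j) >= p(i) of
# p(j) * m / rank(p(j))).
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(1, min(p[js] * m / r[js]))
  }, numeric(1))
}

# Brute-force maximal clique enumeration by subset scan (n <= 15).
oracle_max_cliques <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  subsets <- lapply(seq_len(2^n - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
  })
  is_clique <- vapply(subsets, function(s) {
    length(s) < 2 || all(adj[s, s][upper.tri(diag(length(s)))] == 1)
  }, logical(1))
  cl <- subsets[is_clique]
  keys <- vapply(cl, paste, character(1), collapse = ",")
  maximal <- vapply(seq_along(cl), function(i) {
    !any(vapply(cl, function(o) {
      length(o) > length(cl[[i]]) && all(cl[[i]] %in% o)
    }, logical(1)))
  }, logical(1))
  out <- lapply(cl[maximal], function(s) sort(nodes[s], method = "radix"))
  keys <- vapply(out, paste, character(1), collapse = "\r")
  out[order(-lengths(out), keys, method = "radix")]
}

# Random simple graph as a gene_network plus its adjacency matrix.
random_network <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("V%02d", seq_len(n))
  adj <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  }
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edges <- data.frame(gene1 = nodes[idx[, 1]], gene2 = nodes[idx[, 2]],
                      stringsAsFactors = FALSE)
  list(net = network_from_edges(edges, nodes), adj = adj)
}

# c disjoint q-cliques plus Erdos-Renyi noise between modules.
planted_clique_graph <- function(n_cliques, q, noise_p, seed) {
  set.seed(seed)
  nodes <- sprintf("P%03d", seq_len(n_cliques * q))
  mods <- split(nodes, rep(seq_len(n_cliques), each = q))
  ed <- do.call(rbind, lapply(mods, function(m) {
    pr <- utils::combn(m, 2)
    data.frame(gene1 = pr[1, ], gene2 = pr[2, ], stringsAsFactors = FALSE)
  }))
  pr <- utils::combn(nodes, 2)
  same <- Reduce(`|`, lapply(mods, function(m) {
    pr[1, ] %in% m & pr[2, ] %in% m
  }))
  keep <- !same & runif(ncol(pr)) < noise_p
  ed <- rbind(ed, data.frame(gene1 = pr[1, keep], gene2 = pr[2, keep],
                             stringsAsFactors = FALSE))
  list(net = network_from_edges(ed, nodes), modules = mods)
}

jaccard <- function(x, y) length(intersect(x, y)) / length(union(x, y))

# Write a data.frame as a TSV in a temp file.
tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Minimal disease gene set from a named list gene -> channels.
quick_dgs <- function(disease, gene_channels) {
  channels <- unique(unlist(gene_channels))
  sets <- lapply(channels, function(ch) {
    names(gene_channels)[vapply(gene_channels, function(x) ch %in% x,
                                logical(1))]
  })
  names(sets) <- channels
  assemble_disease_gene_set(disease, sets)
}

# Tiny in-memory drug table via temp TSVs.
quick_drug_table <- function(drugs_df, targets_df) {
  parse_drug_tables(tmp_tsv(drugs_df), tmp_tsv(targets_df))
}
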