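#' Build the shared-gene functional network
#'
#' Reads a typed gene-gene edge list (TSV columns `gene1`, `gene2`,
#' `type`, optional `weight`) and restricts it to the shared genes:
#' an edge is kept iff both endpoints are shared genes and its type is
#' allowed (co-expression, physical interaction, or pathway sharing by
#' default). Parallel typed edges between the same pair collapse into one
#' simple edge carrying the set of types; self-loops are dropped.
#' Isolated shared genes stay in the node set, and the connected fraction
#' of nodes is reported.
#'
#' @param tbl A `shared_gene_table` providing the node set.
#' @param edge_file Path to the edge-list TSV.
#' @param allowed_types Edge types kept in the network.
#' @return Object of class `gene_network`: list with `graph` (igraph),
#'   `nodes` (sorted), `n_connected` and `connectivity` (fraction of
#'   nodes with at least one edge).
#' @export
build_network <- function(tbl, edge_file,
                          allowed_types = c("coexpression", "physical",
                                            "pathway")) {
  stopifnot(inherits(tbl, "shared_gene_table"))
  nodes <- sort_c(unique(tbl$gene))
  df <- read_evidence_tsv(edge_file, c("gene1", "gene2", "type"), "edge list")
  unknown <- setdiff(unique(df$type), allowed_types)
  if (length(unknown)) {
    stop("unknown edge type(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  df <- df[df$gene1 %in% nodes & df$gene2 %in% nodes, , drop = FALSE]
  df <- df[df$gene1 != df$gene2, , drop = FALSE]
  if (nrow(df)) {
    a <- pmin(df$gene1, df$gene2)
    b <- pmax(df$gene1, df$gene2)
    key <- paste(a, b, sep = "\r")
    types <- vapply(split(df$type, key), function(t) {
      paste(sort_c(unique(t)), collapse = ";")
    }, character(1))
    uk <- sort_c(unique(key))
    ends <- strsplit(uk, "\r", fixed = TRUE)
    edges <- data.frame(gene1 = vapply(ends, `[`, character(1), 1),
                        gene2 = vapply(ends, `[`, character(1), 2),
                        types = unname(types[uk]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(gene1 = character(0), gene2 = character(0),
                        types = character(0), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  deg <- igraph::degree(g)
  structure(list(graph = g, nodes = nodes,
                 n_connected = sum(deg > 0),
                 connectivity = if (length(nodes)) sum(deg > 0) / length(nodes)
                                else NA_real_),
            class = "gene_network")
}

#' Construct a gene network from an in-memory edge table
#'
#' Lower-level companion of [build_network()] for programmatic use:
#' takes a data.frame of undirected edges (columns `gene1`, `gene2`,
#' optional `types`), collapses duplicates and self-loops, and keeps any
#' extra isolated nodes passed in `nodes`.
#'
#' @param edges data.frame with columns `gene1`, `gene2` and optionally
#'   `types`.
#' @param nodes Optional character vector of nodes (defaults to the edge
#'   endpoints); endpoints outside `nodes` are an error.
#' @return A `gene_network`.
#' @export
network_from_edges <- function(edges, nodes = NULL) {
  ep <- unique(c(edges$gene1, edges$gene2))
  nodes <- sort_c(unique(nodes %||% ep))
  if (length(setdiff(ep, nodes))) {
    stop("edge endpoint(s) outside the node set", call. = FALSE)
  }
  edges <- edges[edges$gene1 != edges$gene2, , drop = FALSE]
  if (nrow(edges)) {
    a <- pmin(edges$gene1, edges$gene2)
    b <- pmax(edges$gene1, edges$gene2)
    keep <- !duplicated(paste(a, b, sep = "\r"))
    el <- data.frame(gene1 = a[keep], gene2 = b[keep],
                     stringsAsFactors = FALSE)
  } else {
    el <- data.frame(gene1 = character(0), gene2 = character(0))
  }
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  deg <- igraph::degree(g)
  structure(list(graph = g, nodes = nodes, n_connected = sum(deg > 0),
                 connectivity = if (length(nodes)) sum(deg > 0) / length(nodes)
                                else NA_real_),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene network: %d nodes, %d edges, %d (%.0f%%) connected\n",
              length(x$nodes), igraph::ecount(x$graph), x$n_connected,
              100 * x$connectivity))
  invisible(x)
}

#' Enumerate maximal cliques
#'
#' Returns every maximal clique of the (simple, undirected) network
#' exactly once, members sorted, cliques ordered deterministically by
#' (size descending, lexicographic member list). Isolated nodes appear as
#' singleton cliques.
#'
#' @param net A `gene_network`.
#' @param min_size Minimum clique size to return (default 1).
#' @return List of character vectors.
#' @export
maximal_cliques <- function(net, min_size = 1) {
  stopifnot(inherits(net, "gene_network"))
  if (!length(net$nodes)) return(list())
  cl <- igraph::max_cliques(net$graph, min = min_size)
  cl <- lapply(cl, function(v) sort_c(names(v)))
  if (!length(cl)) return(list())
  keys <- vapply(cl, paste, character(1), collapse = "\r")
  sizes <- lengths(cl)
  cl[order_c(-sizes, keys)]
}

# Dense adjacency + degrees for the EAGLE / EQ internals.
net_matrices <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  el <- igraph::as_edgelist(net$graph)
  if (nrow(el)) {
    i <- match(el[, 1], net$nodes)
    j <- match(el[, 2], net$nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  list(A = A, deg = rowSums(A), m = nrow(el))
}

# EQ contribution of one module (integer indices) given weights w = 1/O.
eq_contrib <- function(A, deg, m2, idx, Ov) {
  w <- 1 / Ov[idx]
  aw <- as.numeric(A[idx, idx, drop = FALSE] %*% w)
  sum(w * aw) - (sum(deg[idx] * w))^2 / m2
}

#' Extended modularity of an overlapping cover
#'
#' Computes EQ, the generalization of Newman modularity to overlapping
#' covers: every vertex pair's contribution `A_vw - k_v k_w / 2m` is
#' down-weighted by the product of the two vertices' membership counts
#' `O_v O_w`, summed within modules and normalized by `2m`. Vertices
#' outside every module count as singleton communities for the `O_v`
#' accounting (`O_v = 1`) but contribute no module term. An edgeless
#' network has EQ 0 by convention.
#'
#' @param net A `gene_network`.
#' @param modules List of character vectors (overlap allowed); all
#'   members must be network nodes.
#' @return A single numeric EQ value.
#' @export
extended_modularity <- function(net, modules) {
  stopifnot(inherits(net, "gene_network"))
  unknown <- setdiff(unique(unlist(modules)), net$nodes)
  if (length(unknown)) {
    stop("module member(s) not in the network: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  mats <- net_matrices(net)
  if (mats$m == 0) return(0)
  n <- length(net$nodes)
  Ov <- rep(1L, n)
  midx <- lapply(modules, function(mod) match(unique(mod), net$nodes))
  counts <- tabulate(unlist(midx), nbins = n)
  Ov <- pmax(counts, 1L)
  m2 <- 2 * mats$m
  total <- sum(vapply(midx, function(idx) {
    eq_contrib(mats$A, mats$deg, m2, idx, Ov)
  }, numeric(1)))
  total / m2
}

#' Overlapping module detection by clique-seeded agglomeration (EAGLE)
#'
#' Detects possibly-overlapping modules: (1) enumerate maximal cliques
#' and keep those of size at least `min_clique` as seed communities;
#' (2) every node in no retained clique becomes a singleton community;
#' (3) repeatedly merge the pair of communities with maximal similarity
#' `S(C1, C2) = (1/2m) * sum over v in C1\\C2, w in C2\\C1 of
#' (A_vw - k_v k_w / 2m)`, recording the dendrogram, until one community
#' remains per connected component (cross-component merges are forbidden);
#' (4) return the dendrogram level with maximal extended modularity EQ;
#' (5) drop modules smaller than `min_complex` from the reported cover
#' (they remain in the dendrogram). Ties in similarity are broken by
#' lexicographic comparison of the communities' sorted member lists
#' (smaller first); a community fully contained in another is absorbed
#' immediately. The procedure is fully deterministic; `seed` is accepted
#' for interface uniformity but unused.
#'
#' @param net A `gene_network`.
#' @param min_clique Minimum seed clique size (>= 2).
#' @param min_complex Minimum reported module size (>= 1).
#' @param seed Ignored (the algorithm is deterministic).
#' @return Object of class `module_cover`: list with `modules` (list of
#'   sorted character vectors, ordered by size desc then lexicographic),
#'   `eq` (EQ of the selected cover), `dendrogram` (data.frame `step`,
#'   `left`, `right`, `similarity`), `all_modules` (the selected cover
#'   before the size filter, whose EQ is `eq`), `unassigned` (nodes in no
#'   reported module), and `params`.
#' @export
eagle <- function(net, min_clique = 10, min_complex = 10, seed = NULL) {
  stopifnot(inherits(net, "gene_network"))
  if (min_clique < 2) stop("min_clique must be >= 2", call. = FALSE)
  if (min_complex < 1) stop("min_complex must be >= 1", call. = FALSE)
  empty_dendro <- data.frame(step = integer(0), left = character(0),
                             right = character(0), similarity = numeric(0),
                             stringsAsFactors = FALSE)
  finish <- function(modules, eq, dendro, nodes) {
    keep <- lengths(modules) >= min_complex
    mods <- modules[keep]
    if (length(mods)) {
      keys <- vapply(mods, paste, character(1), collapse = "\r")
      mods <- mods[order_c(-lengths(mods), keys)]
    }
    assigned <- unique(unlist(mods))
    structure(list(modules = mods, eq = eq, dendrogram = dendro,
                   all_modules = modules,
                   unassigned = sort_c(setdiff(nodes, assigned)),
                   params = list(min_clique = min_clique,
                                 min_complex = min_complex)),
              class = "module_cover")
  }
  if (!length(net$nodes)) {
    return(finish(list(), 0, empty_dendro, character(0)))
  }
  mats <- net_matrices(net)
  A <- mats$A; deg <- mats$deg; m <- mats$m
  n <- length(net$nodes)
  m2 <- 2 * m

  cliques <- maximal_cliques(net)
  seeds <- cliques[lengths(cliques) >= min_clique]
  covered <- unique(unlist(seeds))
  singletons <- as.list(sort_c(setdiff(net$nodes, covered)))
  members <- c(lapply(seeds, function(s) match(s, net$nodes)),
               lapply(singletons, function(s) match(s, net$nodes)))
  if (!length(members)) return(finish(list(), 0, empty_dendro, net$nodes))

  comp <- igraph::components(net$graph)$membership
  comm_comp <- vapply(members, function(idx) comp[[idx[1]]], numeric(1))
  keys <- vapply(members, function(idx) {
    paste(net$nodes[sort(idx)], collapse = "\r")
  }, character(1))
  # per-community adjacency row-sums, used for O(size) similarity updates
  av <- lapply(members, function(idx) colSums(A[idx, , drop = FALSE]))
  kd <- vapply(members, function(idx) sum(deg[idx]), numeric(1))

  sim <- function(i, j) {
    ii <- members[[i]]; jj <- members[[j]]
    I <- intersect(ii, jj)
    e2 <- setdiff(jj, ii)
    e1 <- setdiff(ii, jj)
    if (!length(e1) || !length(e2)) return(Inf)
    Tsum <- sum(av[[i]][e2])
    if (length(I)) Tsum <- Tsum - sum(A[I, e2, drop = FALSE])
    (Tsum - sum(deg[e1]) * sum(deg[e2]) / m2) / m2
  }

  nc <- length(members)
  S <- matrix(NA_real_, nc, nc)
  if (m > 0) {
    for (i in seq_len(nc - 1)) {
      for (j in seq(i + 1, nc)) {
        if (comm_comp[i] == comm_comp[j]) S[i, j] <- sim(i, j)
      }
    }
  }

  cover_eq <- function() {
    counts <- tabulate(unlist(members), nbins = n)
    Ov <- pmax(counts, 1L)
    if (m == 0) return(0)
    sum(vapply(members, function(idx) eq_contrib(A, deg, m2, idx, Ov),
               numeric(1))) / m2
  }

  best_eq <- cover_eq()
  best_members <- members
  dendro <- empty_dendro
  step <- 0L
  while (any(!is.na(S))) {
    smax <- max(S, na.rm = TRUE)
    cand <- which(S == smax, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      # tie-break: lexicographically smallest (minor key, major key) pair
      pk1 <- pmin(keys[cand[, 1]], keys[cand[, 2]])
      pk2 <- pmax(keys[cand[, 1]], keys[cand[, 2]])
      cand <- cand[order_c(pk1, pk2)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    step <- step + 1L
    dendro <- rbind(dendro, data.frame(
      step = step,
      left = min(keys[i], keys[j]), right = max(keys[i], keys[j]),
      similarity = smax, stringsAsFactors = FALSE))
    merged <- sort(union(members[[i]], members[[j]]))
    I <- intersect(members[[i]], members[[j]])
    av_new <- av[[i]] + av[[j]] -
      if (length(I)) colSums(A[I, , drop = FALSE]) else 0
    keep <- setdiff(seq_along(members), c(i, j))
    members <- c(members[keep], list(merged))
    av <- c(av[keep], list(av_new))
    kd <- c(kd[keep], sum(deg[merged]))
    keys <- c(keys[keep],
              paste(net$nodes[merged], collapse = "\r"))
    comm_comp <- c(comm_comp[keep], comp[[merged[1]]])
    nc <- length(members)
    S <- S[keep, keep, drop = FALSE]
    newS <- rep(NA_real_, nc)
    for (k in seq_len(nc - 1)) {
      if (comm_comp[k] == comm_comp[nc]) newS[k] <- sim(k, nc)
    }
    S <- rbind(cbind(S, newS[seq_len(nc - 1)]), rep(NA_real_, nc))
    eq_now <- cover_eq()
    if (eq_now > best_eq + 1e-12) {
      best_eq <- eq_now
      best_members <- members
    }
  }
  modules <- lapply(best_members, function(idx) net$nodes[sort(idx)])
  finish(modules, best_eq, dendro, net$nodes)
}

#' @export
print.module_cover <- function(x, ...) {
  cat(sprintf("module cover: %d modules (sizes %s), EQ = %.4f, %d unassigned\n",
              length(x$modules),
              paste(lengths(x$modules), collapse = ", "), x$eq,
              length(x$unassigned)))
  invisible(x)
}

#' Genes belonging to more than one module
#'
#' @param cover A `module_cover`.
#' @return Named list, gene -> integer vector of module ids (1-based,
#'   in the cover's module order), containing exactly the genes with two
#'   or more memberships.
#' @export
module_overlap_genes <- function(cover) {
  stopifnot(inherits(cover, "module_cover"))
  if (!length(cover$modules)) return(setNames(list(), character(0)))
  df <- data.frame(
    gene = unlist(cover$modules),
    module = rep(seq_along(cover$modules), lengths(cover$modules)),
    stringsAsFactors = FALSE)
  by_gene <- split(df$module, df$gene)
  multi <- by_gene[lengths(by_gene) >= 2]
  multi[order_c(names(multi))]
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file (term, description, member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Annotate modules with evidence channels and gene-set enrichment
#'
#' For each module of the cover, counts how many member genes carry each
#' evidence channel (union over the two diseases) and tests the module for
#' overrepresentation of every term in the supplied collections, with the
#' network node set as background and BH correction applied jointly across
#' all (module, term) pairs.
#'
#' @param cover A `module_cover`.
#' @param tbl The `shared_gene_table` the network was built from.
#' @param collections Named list of gene-set collections, each a named
#'   list of character vectors (e.g. from [read_gmt()]). May be empty.
#' @param background Character vector; defaults to the genes of `tbl`.
#' @param alpha Significance threshold on BH-adjusted values.
#' @return List of per-module annotations: `module_id`, `size`,
#'   `channel_counts` (named integer vector over the channel vocabulary)
#'   and `enrichment` (data.frame with `collection`, `term`, counts, `p`,
#'   `q`, `significant`, sorted by (q, p, term)).
#' @export
annotate_modules <- function(cover, tbl, collections = list(),
                             background = NULL, alpha = 0.05) {
  stopifnot(inherits(cover, "module_cover"),
            inherits(tbl, "shared_gene_table"))
  background <- unique(background %||% tbl$gene)
  chans <- lapply(seq_len(nrow(tbl)), function(i) {
    union(strsplit(tbl$channels_A[i], ";", fixed = TRUE)[[1]],
          strsplit(tbl$channels_B[i], ";", fixed = TRUE)[[1]])
  })
  names(chans) <- tbl$gene

  flat <- list()
  for (coll in names(collections)) {
    for (term in names(collections[[coll]])) {
      flat[[paste(coll, term, sep = "\r")]] <-
        intersect(unique(collections[[coll]][[term]]), background)
    }
  }
  rows <- list()
  for (mid in seq_along(cover$modules)) {
    q <- intersect(cover$modules[[mid]], background)
    for (key in names(flat)) {
      members <- flat[[key]]
      k <- length(intersect(members, q))
      p <- fisher_one_sided(k, length(q) - k, length(members) - k,
                            length(background) - length(q) -
                              length(members) + k)$p
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = mid, collection = parts[1], term = parts[2],
        k = k, K = length(members), n = length(q), N = length(background),
        p = p, stringsAsFactors = FALSE)
    }
  }
  enr <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module_id = integer(0), collection = character(0),
               term = character(0), k = integer(0), K = integer(0),
               n = integer(0), N = integer(0), p = numeric(0),
               stringsAsFactors = FALSE)
  enr$q <- bh_adjust(enr$p)
  enr$significant <- enr$q <= alpha

  lapply(seq_along(cover$modules), function(mid) {
    mod <- cover$modules[[mid]]
    cc <- vapply(evidence_channels(), function(ch) {
      sum(vapply(mod, function(g) ch %in% (chans[[g]] %||% character(0)),
                 logical(1)))
    }, integer(1))
    e <- enr[enr$module_id == mid, , drop = FALSE]
    e <- e[order_c(e$q, e$p, e$term), , drop = FALSE]
    rownames(e) <- NULL
    list(module_id = mid, size = length(mod), channel_counts = cc,
         enrichment = e)
  })
}

#' Export a network as GraphML
#'
#' @param net A `gene_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
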