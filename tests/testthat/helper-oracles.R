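# Independent oracles and small graph/sequence fixtures used across tests.

# Build a minimal coexpression_network object from an edge list (and
# optionally extra isolated nodes), for topology tests that do not need
# expression data.
make_net <- function(edges, extra_nodes = character(), condition = "test") {
  nodes <- sort(unique(c(edges$node_a, edges$node_b, extra_nodes)))
  deg <- table(factor(c(edges$node_a, edges$node_b), levels = nodes))
  structure(list(
    nodes = data.frame(node = nodes, mean_expression = 1,
                       degree = as.integer(deg),
                       isolated = as.integer(deg) == 0L,
                       stringsAsFactors = FALSE),
    edges = edges[order(edges$node_a, edges$node_b), , drop = FALSE],
    condition = condition, pcc_min = 0.7,
    dropped_zero_variance = character(), n_samples = 0L),
    class = "coexpression_network")
}

edges_df <- function(a, b, pcc = 1) {
  sw <- a > b
  data.frame(node_a = ifelse(sw, b, a), node_b = ifelse(sw, a, b),
             pcc = rep_len(pcc, length(a)), stringsAsFactors = FALSE)
}

random_graph <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  edges_df(pairs[keep, 1], pairs[keep, 2])
}

# Principal-eigenvector hub oracle: dense eigendecomposition per connected
# component, each edged component max-normalized to 1; isolated nodes 0.
eigen_hub_oracle <- function(net) {
  nodes <- net$nodes$node
  scores <- stats::setNames(rep(0, length(nodes)), nodes)
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(net$edges))) {
    A[net$edges$node_a[i], net$edges$node_b[i]] <- 1
    A[net$edges$node_b[i], net$edges$node_a[i]] <- 1
  }
  # connected components by repeated reachability on the adjacency matrix
  remaining <- nodes
  while (length(remaining)) {
    comp <- remaining[1]
    repeat {
      grown <- unique(c(comp, nodes[colSums(A[comp, , drop = FALSE]) > 0]))
      if (length(grown) == length(comp)) break
      comp <- grown
    }
    if (length(comp) > 1 && sum(A[comp, comp]) > 0) {
      ev <- eigen(A[comp, comp], symmetric = TRUE)
      v <- abs(ev$vectors[, 1])
      scores[comp] <- v / max(v)
    }
    remaining <- setdiff(remaining, comp)
  }
  scores
}

# Brute-force edge betweenness: enumerate every geodesic of every unordered
# node pair and split one unit fractionally across a pair's geodesics.
bf_edge_betweenness <- function(net) {
  nodes <- net$nodes$node
  adj <- stats::setNames(lapply(nodes, function(n) character()), nodes)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$node_a[i]; b <- net$edges$node_b[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  eb <- stats::setNames(rep(0, nrow(net$edges)),
                        key(net$edges$node_a, net$edges$node_b))
  bfs_dist <- function(s) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes); d[[s]] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (is.infinite(d[[w]])) {
        d[[w]] <- d[[v]] + 1; q <- c(q, w)
      }
    }
    d
  }
  all_geodesics <- function(s, t, d) {
    if (t == s) return(list(s))
    out <- list()
    for (v in adj[[t]]) if (d[[v]] == d[[t]] - 1)
      out <- c(out, lapply(all_geodesics(s, v, d), function(p) c(p, t)))
    out
  }
  for (i in seq_along(nodes)) {
    d <- bfs_dist(nodes[i])
    for (j in seq_along(nodes)) {
      if (j <= i || is.infinite(d[[nodes[j]]])) next
      paths <- all_geodesics(nodes[i], nodes[j], d)
      for (p in paths)
        for (k in seq_len(length(p) - 1))
          eb[[key(p[k], p[k + 1])]] <-
            eb[[key(p[k], p[k + 1])]] + 1 / length(paths)
    }
  }
  eb
}

# Vectorized pH-grid scan oracle for the isoelectric point (independent of
# the package's bisection; same EMBOSS-style pKa constants).
grid_pi_oracle <- function(sequence, step = 1e-4) {
  chars <- strsplit(sequence, "")[[1]]
  ph <- seq(0, 14, by = step)
  q <- 1 / (1 + 10^(ph - 8.6)) - 1 / (1 + 10^(3.6 - ph))
  pos <- c(K = 10.8, R = 12.5, H = 6.5)
  neg <- c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  for (aa in names(pos)) q <- q + sum(chars == aa) / (1 + 10^(ph - pos[[aa]]))
  for (aa in names(neg)) q <- q - sum(chars == aa) / (1 + 10^(neg[[aa]] - ph))
  ph[which.min(abs(q))]
}

# BFS two-coloring bipartiteness check on a connected node set
is_bipartite_component <- function(members, edges) {
  adj <- stats::setNames(lapply(members, function(n) character()), members)
  for (i in seq_len(nrow(edges))) {
    a <- edges$node_a[i]; b <- edges$node_b[i]
    if (!(a %in% members)) next
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  colour <- stats::setNames(rep(NA_integer_, length(members)), members)
  colour[[members[1]]] <- 0L
  queue <- members[1]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.na(colour[[w]])) {
        colour[[w]] <- 1L - colour[[v]]
        queue <- c(queue, w)
      } else if (colour[[w]] == colour[[v]]) return(FALSE)
    }
  }
  TRUE
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

substitute_at <- function(seq, pos, alphabet) {
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
  paste(chars, collapse = "")
}

# gene coordinate table for duplication/TE tests
gene_table <- function(ids, chrom, start, end, subfamily = "S1") {
  data.frame(gene_id = ids, chromosome = chrom, start = start, end = end,
             strand = "+", subfamily = subfamily, group = "G",
             stringsAsFactors = FALSE)
}

pairs_table <- function(a, b, identity, coverage = 1, evalue = 1e-50) {
  data.frame(gene_id_a = a, gene_id_b = b, identity = identity,
             coverage = coverage, evalue = evalue, score = 100,
             stringsAsFactors = FALSE)
}
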