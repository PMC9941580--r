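# Subfamily coexpression networks: thresholded Pearson correlation graphs,
# Kleinberg (HITS) hub scores via per-component power iteration, Brandes
# edge betweenness, and control-vs-stress topology comparison.

edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Build a subfamily coexpression network
#'
#' Nodes are subfamilies; an undirected edge joins two subfamilies iff the
#' Pearson correlation of their expression profiles across the given
#' samples is at least `pcc_min` (positive correlations only). Node weight
#' is the mean expression across those samples; edge weight is the
#' correlation. Zero-variance subfamilies are dropped before correlation
#' and flagged.
#'
#' @param subfam_expr Matrix, subfamilies x samples (e.g. mean TPM from
#'   [aggregate_subfamily()], typically replicate-averaged and restricted
#'   to one condition's samples).
#' @param pcc_min Minimum Pearson correlation for an edge (default 0.7).
#' @param condition Label stored on the network.
#' @return Object of class `coexpression_network`: `nodes` (node,
#'   mean_expression, degree, isolated), `edges` (node_a, node_b, pcc;
#'   node_a < node_b), `condition`, `pcc_min`, `dropped_zero_variance`,
#'   `n_samples`.
#' @export
build_network <- function(subfam_expr, pcc_min = 0.7, condition = "all") {
  stopifnot(is.matrix(subfam_expr))
  if (ncol(subfam_expr) < 3)
    stop("need at least 3 samples to build a coexpression network",
         call. = FALSE)
  stop_if_not_scalar_fraction(pcc_min, "pcc_min")
  v <- apply(subfam_expr, 1, stats::var)
  dropped <- rownames(subfam_expr)[v == 0]
  mat <- subfam_expr[v > 0, , drop = FALSE]
  nodes <- rownames(mat)
  edges <- data.frame(node_a = character(), node_b = character(),
                      pcc = numeric(), stringsAsFactors = FALSE)
  if (length(nodes) >= 2) {
    r <- stats::cor(t(mat))
    idx <- which(upper.tri(r) & r >= pcc_min, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(node_a = nodes[idx[, 1]], node_b = nodes[idx[, 2]],
                          pcc = r[idx], stringsAsFactors = FALSE)
      swap <- edges$node_a > edges$node_b
      tmp <- edges$node_a[swap]
      edges$node_a[swap] <- edges$node_b[swap]
      edges$node_b[swap] <- tmp
      edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  deg <- table(factor(c(edges$node_a, edges$node_b), levels = nodes))
  nodes_df <- data.frame(node = nodes,
                         mean_expression = unname(rowMeans(mat)),
                         degree = as.integer(deg),
                         isolated = as.integer(deg) == 0L,
                         stringsAsFactors = FALSE)
  structure(list(nodes = nodes_df, edges = edges, condition = condition,
                 pcc_min = pcc_min, dropped_zero_variance = dropped,
                 n_samples = ncol(subfam_expr)),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network [%s]: %d nodes, %d edges (PCC >= %.2f over %d samples), %d isolated\n",
              x$condition, nrow(x$nodes), nrow(x$edges), x$pcc_min,
              x$n_samples, sum(x$nodes$isolated)))
  invisible(x)
}

adjacency_list <- function(net) {
  nodes <- net$nodes$node
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$node_a[i]; b <- net$edges$node_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

connected_components <- function(adj) {
  nodes <- names(adj)
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (n in nodes) {
    if (seen[[n]]) next
    queue <- n; seen[[n]] <- TRUE; comp <- character()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (!seen[[w]]) { seen[[w]] <- TRUE
        queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

#' Kleinberg hub scores
#'
#' HITS on the symmetric unweighted adjacency: on an undirected graph hub
#' and authority scores coincide with the principal eigenvector of the
#' adjacency matrix. Scores are computed per connected component by power
#' iteration on `A + I` (L2 change < 1e-12 or 10,000 iterations); the
#' diagonal shift leaves the eigenvectors unchanged but makes the principal
#' eigenvalue strictly dominant, so the iteration converges even on
#' bipartite components (where iterating `A` or `A^2` stalls in the
#' two-dimensional eigenspace of the `+/- lambda` pair). Each component
#' with at least one edge is scaled to a maximum of 1 (so the global
#' maximum is also 1); isolated nodes score 0.
#'
#' @param net A `coexpression_network`.
#' @return Named numeric vector of hub scores in `[0, 1]`, one per node.
#' @export
hub_scores <- function(net, tol = 1e-12, max_iter = 10000L) {
  adj <- adjacency_list(net)
  scores <- stats::setNames(rep(0, length(adj)), names(adj))
  for (comp in connected_components(adj)) {
    if (length(comp) < 2 || !length(unlist(adj[comp]))) next
    A <- matrix(0, length(comp), length(comp), dimnames = list(comp, comp))
    for (v in comp) A[v, adj[[v]]] <- 1
    diag(A) <- 1   # shift: same eigenvectors, strictly dominant lambda_1
    x <- rep(1, length(comp))
    for (it in seq_len(max_iter)) {
      x_new <- as.numeric(A %*% x)
      x_new <- x_new / sqrt(sum(x_new^2))
      if (sqrt(sum((x_new - x)^2)) < tol) { x <- x_new; break }
      x <- x_new
    }
    scores[comp] <- x / max(x)
  }
  scores
}

#' Edge betweenness centrality
#'
#' Brandes' algorithm on the unweighted, undirected graph: each unordered
#' node pair is counted once, and when several geodesics tie, each
#' contributes its fractional share to the edges it traverses.
#'
#' @param net A `coexpression_network`.
#' @return Named numeric vector keyed `"a|b"` (lexicographic node order),
#'   one value per edge.
#' @export
edge_betweenness <- function(net) {
  adj <- adjacency_list(net)
  nodes <- names(adj)
  eb <- stats::setNames(rep(0, nrow(net$edges)),
                        edge_key(net$edges$node_a, net$edges$node_b))
  for (s in nodes) {
    # BFS from s
    sigma <- stats::setNames(rep(0, length(nodes)), nodes); sigma[[s]] <- 1
    dist <- stats::setNames(rep(-1L, length(nodes)), nodes); dist[[s]] <- 0L
    preds <- stats::setNames(vector("list", length(nodes)), nodes)
    queue <- s; order_visited <- character()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[[w]] < 0) { dist[[w]] <- dist[[v]] + 1L
          queue <- c(queue, w) }
        if (dist[[w]] == dist[[v]] + 1L) {
          sigma[[w]] <- sigma[[w]] + sigma[[v]]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- stats::setNames(rep(0, length(nodes)), nodes)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        c_share <- sigma[[v]] / sigma[[w]] * (1 + delta[[w]])
        eb[[edge_key(v, w)]] <- eb[[edge_key(v, w)]] + c_share
        delta[[v]] <- delta[[v]] + c_share
      }
    }
  }
  eb / 2  # each unordered pair was counted from both endpoints
}

#' Compare control and stress coexpression networks
#'
#' @param control,stress `coexpression_network`s over the same node
#'   universe.
#' @return list of class `network_comparison`: per-network edge counts,
#'   shared and per-network unique edge keys, isolated-node lists, percent
#'   edge loss `100 * (1 - |E_stress| / |E_control|)`, and per-node hub
#'   rank shift (control rank minus stress rank; positive means the node
#'   rose under stress).
#' @export
compare_networks <- function(control, stress) {
  if (!setequal(control$nodes$node, stress$nodes$node))
    stop("networks must share the same node universe", call. = FALSE)
  ec <- edge_key(control$edges$node_a, control$edges$node_b)
  es <- edge_key(stress$edges$node_a, stress$edges$node_b)
  hub_c <- hub_scores(control); hub_s <- hub_scores(stress)
  nodes <- sort(control$nodes$node)
  rank_c <- rank(-hub_c[nodes], ties.method = "min")
  rank_s <- rank(-hub_s[nodes], ties.method = "min")
  structure(list(
    n_edges_control = length(ec), n_edges_stress = length(es),
    shared_edges = sort(intersect(ec, es)),
    unique_control = sort(setdiff(ec, es)),
    unique_stress = sort(setdiff(es, ec)),
    isolated_control = control$nodes$node[control$nodes$isolated],
    isolated_stress = stress$nodes$node[stress$nodes$isolated],
    pct_edge_loss = if (length(ec))
      100 * (1 - length(es) / length(ec)) else NA_real_,
    hub_rank_shift = stats::setNames(as.integer(rank_c - rank_s), nodes)),
    class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("network_comparison: %d control edges, %d stress edges (%.1f%% loss), %d shared\n",
              x$n_edges_control, x$n_edges_stress, x$pct_edge_loss,
              length(x$shared_edges)))
  invisible(x)
}

#' Full topology report for a network
#'
#' @param net A `coexpression_network`.
#' @return list of class `topology_report` with `nodes` (node, hub_score,
#'   mean_expression, degree, isolated), `edges` (node_a, node_b, pcc,
#'   betweenness), `n_edges`, `isolated` node ids.
#' @export
topology_report <- function(net) {
  hubs <- hub_scores(net)
  eb <- edge_betweenness(net)
  edges <- net$edges
  edges$betweenness <- unname(eb[edge_key(edges$node_a, edges$node_b)])
  nodes <- net$nodes
  nodes$hub_score <- unname(hubs[nodes$node])
  structure(list(nodes = nodes[, c("node", "hub_score", "mean_expression",
                                   "degree", "isolated")],
                 edges = edges, n_edges = nrow(edges),
                 isolated = nodes$node[nodes$isolated]),
            class = "topology_report")
}

#' Export a network as an edge-list TSV
#'
#' @param net A `coexpression_network`.
#' @param path Output path.
#' @export
write_network_edges <- function(net, path) {
  write_tsv(net$edges, path)
}
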