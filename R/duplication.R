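# Duplication analysis: all-vs-all CDS similarity search (word-seeded local
# alignment with Karlin-Altschul E-values), tandem-duplication clusters
# (same chromosome, boundary gap <= 25 kb, single linkage) and tiered
# segmental correspondences (> 100 kb apart or trans-chromosomal).

# Karlin-Altschul ungapped constants for the +1/-2 nucleotide scheme
# (approximate; E-values here only gate pass/fail at thresholds orders of
# magnitude away from the decision boundary).
KA_LAMBDA <- 1.28
KA_K <- 0.46

shared_word_count <- function(a, b, word_size) {
  if (nchar(a) < word_size || nchar(b) < word_size) return(0L)
  wa <- unique(substring(a, seq_len(nchar(a) - word_size + 1),
                         word_size:nchar(a)))
  wb <- unique(substring(b, seq_len(nchar(b) - word_size + 1),
                         word_size:nchar(b)))
  length(intersect(wa, wb))
}

#' All-vs-all CDS similarity search
#'
#' Seed-and-extend style search: candidate pairs must share at least one
#' exact `word_size`-mer (mirroring a nucleotide word seed, so highly
#' diverged pairs without an exact seed word are not reported); candidates
#' are then aligned locally and reported with identity (matches per
#' alignment column), coverage (aligned fraction of the shorter CDS) and a
#' Karlin-Altschul E-value `E = K m n exp(-lambda S)`. Self-pairs are
#' excluded; each unordered pair is reported once.
#'
#' @param cds Named character vector or `DNAStringSet`, one CDS per gene.
#' @param id_min,cov_min,evalue_max Reporting thresholds (defaults 0.5,
#'   0.75, 1e-10).
#' @param word_size Exact-match seed length (default 11).
#' @return data.frame with columns gene_id_a, gene_id_b (a < b), identity,
#'   coverage, evalue, score.
#' @export
similarity_search <- function(cds, id_min = 0.5, cov_min = 0.75,
                              evalue_max = 1e-10, word_size = 11L) {
  if (!is.character(cds))
    cds <- stats::setNames(as.character(cds), names(cds))
  stopifnot(length(cds) >= 2, !is.null(names(cds)))
  ids <- sort(names(cds))
  rows <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      a <- cds[[ids[i]]]; b <- cds[[ids[j]]]
      if (shared_word_count(a, b, word_size) < 1L) next
      pi <- pairwise_identity(a, b, type = "dna")
      evalue <- KA_K * nchar(a) * nchar(b) * exp(-KA_LAMBDA * pi$score)
      if (pi$identity >= id_min && pi$coverage >= cov_min &&
          evalue <= evalue_max) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id_a = ids[i], gene_id_b = ids[j],
          identity = pi$identity, coverage = pi$coverage,
          evalue = evalue, score = pi$score, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(gene_id_a = character(), gene_id_b = character(),
                      identity = numeric(), coverage = numeric(),
                      evalue = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# boundary gap (bp between nearest gene boundaries; 0 when overlapping),
# NA across chromosomes
pair_geometry <- function(pairs, genes) {
  rownames(genes) <- genes$gene_id
  missing <- setdiff(c(pairs$gene_id_a, pairs$gene_id_b), genes$gene_id)
  if (length(missing))
    stop("pair references unknown gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  a <- genes[pairs$gene_id_a, ]; b <- genes[pairs$gene_id_b, ]
  same <- a$chromosome == b$chromosome
  gap <- ifelse(same, pmax(0, pmax(b$start - a$end, a$start - b$end) - 1),
                NA_real_)
  pairs$same_chromosome <- same
  pairs$boundary_gap_bp <- gap
  pairs
}

#' Detect tandem duplication clusters
#'
#' Qualifying edges are similarity pairs on the same chromosome with a
#' boundary gap of at most `max_gap` that also meet the identity, coverage
#' and E-value thresholds. Clusters are the single-linkage connected
#' components of size >= 2, so chains of qualifying neighbours merge even
#' when the outermost genes are farther apart than `max_gap`.
#'
#' @param kinome A `kinome` data.frame (or any data.frame with gene_id,
#'   chromosome, start, end, subfamily).
#' @param pairs data.frame from [similarity_search()].
#' @param max_gap Maximum boundary gap in bp (default 25,000).
#' @param id_min,cov_min,evalue_max Edge thresholds (defaults 0.95, 0.75,
#'   1e-10).
#' @return list of class `tandem_clusters`: `clusters` (cluster_id,
#'   chromosome, size, genes, subfamilies), `membership` (named gene ->
#'   cluster vector), `edges` (qualifying pairs), `per_chromosome` counts,
#'   and `proximal_unclassified` (same-chromosome qualifying-similarity
#'   pairs in the `max_gap`..100 kb dead zone, reported separately).
#' @export
detect_tandem_clusters <- function(kinome, pairs, max_gap = 25000,
                                   id_min = 0.95, cov_min = 0.75,
                                   evalue_max = 1e-10) {
  pairs <- pair_geometry(pairs, kinome)
  sim_ok <- pairs$identity >= id_min & pairs$coverage >= cov_min &
    pairs$evalue <= evalue_max
  edges <- pairs[sim_ok & pairs$same_chromosome &
                   pairs$boundary_gap_bp <= max_gap, , drop = FALSE]
  proximal <- pairs[sim_ok & pairs$same_chromosome &
                      pairs$boundary_gap_bp > max_gap &
                      pairs$boundary_gap_bp <= 1e5, , drop = FALSE]

  membership <- character()
  clusters <- NULL
  if (nrow(edges)) {
    nodes <- sort(unique(c(edges$gene_id_a, edges$gene_id_b)))
    # union-find over node indices (single linkage)
    parent <- seq_along(nodes)
    findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in seq_len(nrow(edges))) {
      i <- findp(match(edges$gene_id_a[e], nodes))
      j <- findp(match(edges$gene_id_b[e], nodes))
      if (i != j) parent[max(i, j)] <- min(i, j)
    }
    root <- vapply(seq_along(nodes), findp, integer(1))
    sub_of <- stats::setNames(kinome$subfamily, kinome$gene_id)
    chr_of <- stats::setNames(kinome$chromosome, kinome$gene_id)
    comp_ids <- split(nodes, root)
    comp_ids <- comp_ids[order(vapply(comp_ids, min, character(1)))]
    clusters <- do.call(rbind, lapply(seq_along(comp_ids), function(k) {
      g <- sort(comp_ids[[k]])
      data.frame(cluster_id = sprintf("TD%03d", k),
                 chromosome = unname(chr_of[g[1]]), size = length(g),
                 genes = paste(g, collapse = ","),
                 subfamilies = paste(sort(unique(sub_of[g])), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    for (k in seq_along(comp_ids))
      membership[comp_ids[[k]]] <- sprintf("TD%03d", k)
  }
  per_chr <- if (!is.null(clusters))
    stats::aggregate(cbind(n_clusters = 1, n_genes = clusters$size) ~
                       chromosome, data = clusters, FUN = sum)
  else data.frame(chromosome = character(), n_clusters = integer(),
                  n_genes = integer())
  structure(list(clusters = clusters, membership = membership,
                 edges = edges, per_chromosome = per_chr,
                 proximal_unclassified = proximal),
            class = "tandem_clusters")
}

#' @export
print.tandem_clusters <- function(x, ...) {
  n <- if (is.null(x$clusters)) 0L else nrow(x$clusters)
  cat(sprintf("tandem_clusters: %d clusters, %d genes\n", n,
              length(x$membership)))
  invisible(x)
}

#' Tier segmental duplication correspondences
#'
#' A similarity pair enters tier `t` iff its identity exceeds `t` and the
#' genes are either on different chromosomes or separated by more than
#' `min_separation` on the same chromosome. Tiers are nested: every pair in
#' a higher-identity tier is present in all lower tiers.
#'
#' @param kinome Gene table (gene_id, chromosome, start, end).
#' @param pairs data.frame from [similarity_search()].
#' @param thresholds Descending identity thresholds (default 0.90, 0.75,
#'   0.50).
#' @param min_separation Minimum same-chromosome boundary gap in bp
#'   (default 100,000).
#' @return list of class `segmental_tiers`: per-threshold data.frames of
#'   qualifying pairs plus a `counts` data.frame (threshold, n_pairs).
#' @export
tier_segmental <- function(kinome, pairs, thresholds = c(0.90, 0.75, 0.50),
                           min_separation = 1e5) {
  stopifnot(all(diff(thresholds) < 0))
  pairs <- pair_geometry(pairs, kinome)
  segmental <- pairs[!pairs$same_chromosome |
                       pairs$boundary_gap_bp > min_separation, , drop = FALSE]
  tiers <- lapply(thresholds, function(t)
    segmental[segmental$identity > t, , drop = FALSE])
  names(tiers) <- sprintf("%.2f", thresholds)
  counts <- data.frame(threshold = thresholds,
                       n_pairs = vapply(tiers, nrow, integer(1)),
                       row.names = NULL)
  structure(list(tiers = tiers, counts = counts), class = "segmental_tiers")
}

#' @export
print.segmental_tiers <- function(x, ...) {
  cat("segmental_tiers:\n")
  for (i in seq_len(nrow(x$counts)))
    cat(sprintf("  identity > %.2f: %d pairs\n", x$counts$threshold[i],
                x$counts$n_pairs[i]))
  invisible(x)
}
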