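# Cross-assembly kinome merging: greedy incremental identity clustering
# (CD-HIT style: sequences processed longest-first, each joining the first
# cluster whose representative it matches) followed by per-cluster
# retention rules for sequences called on two assemblies.

aa_match_matrix <- function(match = 2, mismatch = -1) {
  letters <- c(AA_ALPHABET, "X", "*")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

#' Pairwise local identity and coverage of two sequences
#'
#' Aligns the two sequences locally (Smith-Waterman via
#' [Biostrings::pairwiseAlignment()]) and reports identity as matches per
#' alignment column and coverage as the aligned length of the shorter
#' sequence over its full length. Symmetric in its arguments.
#'
#' @param seq_a,seq_b Non-empty character scalars (amino-acid by default).
#' @param type `"protein"` or `"dna"` (chooses the scoring scheme:
#'   match 2 / mismatch -1 for protein, match 1 / mismatch -2 for DNA; gap
#'   opening 4, extension 1).
#' @return list with `identity` and `coverage`, both fractions in `[0, 1]`
#'   (0 when no positive-scoring local alignment exists),
#'   `identity_shorter` (matches over the shorter sequence's full length,
#'   the CD-HIT-style global identity), and `score`.
#' @export
pairwise_identity <- function(seq_a, seq_b, type = c("protein", "dna")) {
  type <- match.arg(type)
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  if (type == "protein") {
    sm <- aa_match_matrix()
    pa <- Biostrings::AAString(seq_a); sb <- Biostrings::AAString(seq_b)
  } else {
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                   baseOnly = TRUE)
    pa <- Biostrings::DNAString(seq_a); sb <- Biostrings::DNAString(seq_b)
  }
  aln <- Biostrings::pairwiseAlignment(pa, sb, type = "local",
                                       substitutionMatrix = sm,
                                       gapOpening = 4, gapExtension = 1)
  cols <- Biostrings::nchar(aln)
  if (!length(cols) || cols == 0 || Biostrings::nmatch(aln) == 0)
    return(list(identity = 0, coverage = 0, identity_shorter = 0, score = 0))
  shorter_len <- min(nchar(seq_a), nchar(seq_b))
  aligned_short <- min(
    Biostrings::width(Biostrings::pattern(aln)),
    Biostrings::width(Biostrings::subject(aln)))
  list(identity = Biostrings::nmatch(aln) / cols,
       coverage = min(1, aligned_short / shorter_len),
       identity_shorter = Biostrings::nmatch(aln) / shorter_len,
       score = Biostrings::score(aln))
}

#' Greedy incremental identity clustering
#'
#' Sequences are processed in decreasing length order (ties broken by id);
#' each sequence joins the first existing cluster whose representative (the
#' cluster's founding, hence longest, member) it matches at global identity
#' (aligned matches over the shorter sequence's full length, the CD-HIT
#' convention) >= `id_min` with length ratio (shorter/longer) >=
#' `len_ratio_min`; otherwise it founds a new cluster. Global identity is
#' used for the join decision because per-column local identity alone would
#' merge unrelated sequences sharing any short perfect match. Deterministic.
#'
#' @param sequences Named character vector or `AAStringSet`.
#' @param id_min Minimum representative identity (default 0.95).
#' @param len_ratio_min Minimum shorter/longer length ratio (default 0.75).
#' @param type Passed to [pairwise_identity()].
#' @return data.frame with columns cluster_id, member, length,
#'   is_representative, in input-cluster order.
#' @export
greedy_cluster <- function(sequences, id_min = 0.95, len_ratio_min = 0.75,
                           type = "protein") {
  stop_if_not_scalar_fraction(id_min, "id_min", open_left = TRUE)
  stop_if_not_scalar_fraction(len_ratio_min, "len_ratio_min", open_left = TRUE)
  if (!is.character(sequences))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  stopifnot(!is.null(names(sequences)), !anyDuplicated(names(sequences)))
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  reps <- character()      # representative ids in cluster order
  assign <- integer(length(sequences))
  names(assign) <- names(sequences)
  for (i in seq_along(sequences)) {
    placed <- 0L
    for (ci in seq_along(reps)) {
      rep_seq <- sequences[[reps[ci]]]
      if (nchar(sequences[[i]]) / nchar(rep_seq) < len_ratio_min) next
      pi <- pairwise_identity(sequences[[i]], rep_seq, type = type)
      if (pi$identity_shorter >= id_min) { placed <- ci; break }
    }
    if (placed == 0L) {
      reps <- c(reps, names(sequences)[i])
      placed <- length(reps)
    }
    assign[i] <- placed
  }
  data.frame(cluster_id = sprintf("MC%03d", assign),
             member = names(sequences),
             length = unname(nchar(sequences)),
             is_representative = names(sequences) %in% reps,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Merge kinase protein sets from two assemblies
#'
#' Clusters the union of both sets with [greedy_cluster()] and applies the
#' retention rules: (i) clusters holding a single copy from each source keep
#' only the longest member; (ii) clusters holding putative duplications
#' (more than one member from either source) keep *all* members of the
#' source contributing more members and drop the other source's members
#' (tie in member count: the source containing the longest member wins);
#' singleton clusters are kept as-is.
#'
#' @param set_a,set_b Named character vectors or `AAStringSet`s of protein
#'   sequences, one per candidate kinase.
#' @param source_labels Length-2 labels recorded for the two sets.
#' @param id_min,len_ratio_min Clustering thresholds (defaults 0.95 / 0.75).
#' @return list of class `kinome_merge`: `retained` (data.frame member,
#'   source, cluster_id, rule), `clusters` (full report with retained
#'   flags), and `composition` (retained count and percentage per source,
#'   percentages rounded half-up to 2 decimals).
#' @export
merge_kinomes <- function(set_a, set_b, source_labels = c("A", "B"),
                          id_min = 0.95, len_ratio_min = 0.75) {
  if (!is.character(set_a))
    set_a <- stats::setNames(as.character(set_a), names(set_a))
  if (!is.character(set_b))
    set_b <- stats::setNames(as.character(set_b), names(set_b))
  src <- c(stats::setNames(rep(source_labels[1], length(set_a)), names(set_a)),
           stats::setNames(rep(source_labels[2], length(set_b)), names(set_b)))
  # ids may repeat across sets; make the union unambiguous
  all_ids <- c(names(set_a), names(set_b))
  uniq <- make.unique(all_ids, sep = "#")
  seqs <- stats::setNames(c(set_a, set_b), uniq)
  src <- stats::setNames(unname(src), uniq)
  orig <- stats::setNames(all_ids, uniq)

  cl <- greedy_cluster(seqs, id_min = id_min, len_ratio_min = len_ratio_min)
  cl$source <- unname(src[cl$member])
  cl$retained <- FALSE
  cl$rule <- NA_character_
  for (cid in unique(cl$cluster_id)) {
    idx <- which(cl$cluster_id == cid)
    n_a <- sum(cl$source[idx] == source_labels[1])
    n_b <- sum(cl$source[idx] == source_labels[2])
    if (length(idx) == 1L) {
      cl$retained[idx] <- TRUE
      cl$rule[idx] <- "unique"
    } else if (n_a == 1L && n_b == 1L) {
      len <- cl$length[idx]
      win <- idx[order(-len, cl$member[idx])][1]
      cl$retained[win] <- TRUE
      cl$rule[idx] <- "singleton-both"
    } else {
      winner <- if (n_a > n_b) source_labels[1]
        else if (n_b > n_a) source_labels[2]
        else cl$source[idx[which.max(cl$length[idx])]]
      keep <- idx[cl$source[idx] == winner]
      cl$retained[keep] <- TRUE
      cl$rule[idx] <- "duplicated"
    }
  }
  retained <- cl[cl$retained, c("cluster_id", "member", "source", "rule"),
                 drop = FALSE]
  retained$member <- unname(orig[retained$member])
  cl$member <- unname(orig[cl$member])
  rownames(retained) <- NULL
  comp <- as.data.frame(table(source = retained$source),
                        stringsAsFactors = FALSE)
  names(comp)[2] <- "n"
  comp$percent <- vapply(comp$n, percent_half_up, numeric(1),
                         denominator = nrow(retained), digits = 2)
  structure(list(retained = retained, clusters = cl, composition = comp),
            class = "kinome_merge")
}

#' @export
print.kinome_merge <- function(x, ...) {
  cat(sprintf("kinome_merge: %d retained of %d input proteins in %d clusters\n",
              nrow(x$retained), nrow(x$clusters),
              length(unique(x$clusters$cluster_id))))
  for (i in seq_len(nrow(x$composition)))
    cat(sprintf("  %s: %d (%.2f%%)\n", x$composition$source[i],
                x$composition$n[i], x$composition$percent[i]))
  invisible(x)
}
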