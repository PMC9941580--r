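# Subfamily profile scoring. Kinase subfamilies are recognised with
# position-specific score matrices (log-odds over aligned family members),
# scored by the best ungapped placement of the query against the matrix.
# A profile set is a plain list so externally derived profiles (e.g. built
# from curated family alignments) plug in through the same structure.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Build a subfamily profile set from family alignments
#'
#' Each subfamily is summarised as a position-specific score matrix (PSSM) of
#' natural-log odds `log(p_residue / background)` with a symmetric
#' pseudocount, computed from an ungapped alignment (equal-length sequences)
#' of family members.
#'
#' @param alignments Named list; each element a character vector of
#'   equal-length amino-acid sequences for one subfamily.
#' @param groups Named character vector mapping subfamily name to kinase
#'   group (e.g. `"RLK-Pelle_DLSV"` to `"RLK-Pelle"`).
#' @param threshold Minimum best-placement score (nats) to accept an
#'   assignment; below it the query is labelled `"Unknown"`.
#' @param margin Minimum gap between best and second-best subfamily scores;
#'   ambiguous queries fall back to `"Unknown"`.
#' @param pseudocount Total pseudocount mass per alignment column.
#' @return An object of class `profile_set`: a list with `profiles` (named
#'   list of 20 x L score matrices), `groups`, `threshold`, `margin`.
#' @export
build_profile_set <- function(alignments, groups, threshold = 30,
                              margin = 5, pseudocount = 1) {
  stopifnot(length(alignments) > 0, !is.null(names(alignments)),
            all(names(alignments) %in% names(groups)))
  if (anyDuplicated(names(alignments)))
    stop("subfamily names must be unique", call. = FALSE)
  bg <- 1 / length(AA_ALPHABET)
  profiles <- lapply(alignments, function(seqs) {
    L <- unique(nchar(seqs))
    if (length(L) != 1L)
      stop("alignment sequences must have equal length", call. = FALSE)
    chars <- do.call(rbind, strsplit(seqs, ""))
    n <- nrow(chars)
    mat <- vapply(seq_len(L), function(j) {
      counts <- table(factor(chars[, j], levels = AA_ALPHABET))
      p <- (as.numeric(counts) + pseudocount / length(AA_ALPHABET)) /
        (n + pseudocount)
      log(p / bg)
    }, numeric(length(AA_ALPHABET)))
    rownames(mat) <- AA_ALPHABET
    mat
  })
  structure(list(profiles = profiles,
                 groups = groups[names(alignments)],
                 threshold = threshold, margin = margin),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("profile_set: %d subfamilies (%d groups), threshold %.1f, margin %.1f\n",
              length(x$profiles), length(unique(x$groups)),
              x$threshold, x$margin))
  invisible(x)
}

# Best ungapped placement of `sequence` against a PSSM: the maximal column
# sum over all shifts with full overlap of the shorter side. Unknown residues
# score 0 at their column.
score_profile <- function(sequence, pssm) {
  q <- strsplit(sequence, "")[[1]]
  nq <- length(q)
  L <- ncol(pssm)
  idx <- match(q, rownames(pssm))
  col_score <- function(qpos, cols) {
    ii <- idx[qpos]
    ok <- !is.na(ii)
    sum(pssm[cbind(ii[ok], cols[ok])])
  }
  best <- -Inf
  if (nq >= L) {
    for (off in 0:(nq - L))
      best <- max(best, col_score(off + seq_len(L), seq_len(L)))
  } else {
    for (off in 0:(L - nq))
      best <- max(best, col_score(seq_len(nq), off + seq_len(nq)))
  }
  best
}

#' Classify a kinase domain sequence into a subfamily
#'
#' Scores the sequence against every profile in the set and assigns the
#' best-scoring subfamily if (a) its score reaches the set's threshold and
#' (b) it beats the runner-up by at least the set's margin. Queries failing
#' either rule are assigned to the `"Unknown"` category, mirroring kinases
#' that cluster with no recognised subfamily.
#'
#' @param sequence Non-empty amino-acid sequence (character scalar).
#' @param profiles A `profile_set` from [build_profile_set()].
#' @return list with elements `subfamily`, `group`, `score` (best score in
#'   nats, reported even for Unknown assignments).
#' @export
classify_subfamily <- function(sequence, profiles) {
  stopifnot(inherits(profiles, "profile_set"))
  if (!length(profiles$profiles)) stop("empty profile set", call. = FALSE)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a non-empty character scalar", call. = FALSE)
  scores <- vapply(profiles$profiles, function(p) score_profile(sequence, p),
                   numeric(1))
  ord <- order(scores, decreasing = TRUE)
  best <- scores[ord[1]]
  second <- if (length(scores) > 1L) scores[ord[2]] else -Inf
  if (best >= profiles$threshold && (best - second) >= profiles$margin) {
    name <- names(scores)[ord[1]]
    list(subfamily = name, group = unname(profiles$groups[name]), score = best)
  } else {
    list(subfamily = "Unknown", group = "Unknown", score = best)
  }
}
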