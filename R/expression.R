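# Expression stage: TPM normalization, sample QC, replicate averaging and
# subfamily-level aggregation.

#' Normalize counts to transcripts per million (TPM)
#'
#' Per sample: `rate_i = count_i / length_i`, `TPM_i = 1e6 * rate_i /
#' sum(rate)`. Columns of the result sum to 1e6 (relative tolerance 1e-6);
#' all-zero samples come back all-zero and are flagged in the
#' `"zero_samples"` attribute.
#'
#' @param counts Non-negative numeric matrix, transcripts x samples.
#' @param lengths Positive lengths (bp) named by transcript; every counted
#'   transcript must have one.
#' @return TPM matrix with the same dimnames; attribute `zero_samples`
#'   lists flagged all-zero samples.
#' @export
compute_tpm <- function(counts, lengths) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stop("missing length for transcript(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  len <- lengths[rownames(counts)]
  stopifnot(all(len > 0))
  rate <- counts / len
  totals <- colSums(rate)
  zero <- totals == 0
  totals[zero] <- 1   # leaves those columns all-zero
  tpm <- sweep(rate, 2, totals, "/") * 1e6
  attr(tpm, "zero_samples") <- colnames(counts)[zero]
  tpm
}

#' Exclude samples with too few detected transcripts
#'
#' A sample is excluded iff the fraction of transcripts with TPM > 0 falls
#' below `min_detected_fraction` — the quantitative stand-in for dropping
#' samples with abnormally low quantifications.
#'
#' @param tpm TPM matrix (transcripts x samples).
#' @param min_detected_fraction Threshold in `[0, 1]` (default 0.1).
#' @return list with `matrix` (kept samples) and `excluded` (data.frame
#'   sample, detected_fraction for each dropped sample).
#' @export
qc_filter_samples <- function(tpm, min_detected_fraction = 0.1) {
  stop_if_not_scalar_fraction(min_detected_fraction, "min_detected_fraction")
  frac <- colMeans(tpm > 0)
  drop <- frac < min_detected_fraction
  list(matrix = tpm[, !drop, drop = FALSE],
       excluded = data.frame(sample = colnames(tpm)[drop],
                             detected_fraction = unname(frac[drop]),
                             stringsAsFactors = FALSE))
}

#' Average replicate samples
#'
#' Collapses columns to one per replicate group by the arithmetic mean.
#' Metadata is collapsed alongside; conflicting condition labels within a
#' group are an error.
#'
#' @param tpm Matrix, transcripts x samples.
#' @param samples Metadata data.frame with columns sample, tissue,
#'   condition, replicate_group covering every column of `tpm`.
#' @return list with `matrix` (transcripts x replicate groups) and
#'   `samples` (collapsed metadata, one row per group).
#' @export
average_replicates <- function(tpm, samples) {
  stopifnot(all(colnames(tpm) %in% samples$sample))
  samples <- samples[match(colnames(tpm), samples$sample), , drop = FALSE]
  groups <- split(seq_len(ncol(tpm)), samples$replicate_group)
  meta <- do.call(rbind, lapply(names(groups), function(g) {
    idx <- groups[[g]]
    cond <- unique(samples$condition[idx])
    if (length(cond) != 1L)
      stop(sprintf("replicate group '%s' mixes conditions: %s", g,
                   paste(cond, collapse = ", ")), call. = FALSE)
    data.frame(sample = g, tissue = samples$tissue[idx[1]],
               condition = cond, replicate_group = g,
               n_replicates = length(idx), stringsAsFactors = FALSE)
  }))
  avg <- matrix(vapply(names(groups), function(g)
    rowMeans(tpm[, groups[[g]], drop = FALSE]), numeric(nrow(tpm))),
    nrow = nrow(tpm), dimnames = list(rownames(tpm), names(groups)))
  list(matrix = avg, samples = meta)
}

#' Aggregate transcript expression to subfamily level
#'
#' Subfamily value per sample is the arithmetic mean TPM over member
#' transcripts. Transcripts without a subfamily assignment are ignored;
#' subfamilies with no quantified member are absent from the result and
#' listed in the `"unquantified"` attribute.
#'
#' @param tpm Matrix, transcripts x samples.
#' @param subfamily_of Named character vector mapping transcript (or gene)
#'   id to subfamily; names must match `rownames(tpm)`.
#' @return Matrix subfamilies x samples with attributes `member_counts`
#'   (named integer vector) and `unquantified` (assigned subfamilies with
#'   zero quantified members).
#' @export
aggregate_subfamily <- function(tpm, subfamily_of) {
  keep <- rownames(tpm) %in% names(subfamily_of)
  sub <- subfamily_of[rownames(tpm)[keep]]
  groups <- split(which(keep), sub)
  out <- t(matrix(vapply(groups, function(idx)
    colMeans(tpm[idx, , drop = FALSE]), numeric(ncol(tpm))),
    nrow = ncol(tpm), dimnames = list(colnames(tpm), names(groups))))
  attr(out, "member_counts") <- vapply(groups, length, integer(1))
  attr(out, "unquantified") <- setdiff(unique(subfamily_of), rownames(out))
  out
}
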