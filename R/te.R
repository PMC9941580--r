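# Transposable-element association: windowed gene/TE proximity via the
# GenomicRanges interval index, and summary of overlap with tandem
# duplication status.

#' Associate kinase genes with nearby transposable elements
#'
#' A gene is associated with a TE iff both lie on the same chromosome and
#' the interval distance between them (0 when overlapping, otherwise the
#' gap between nearest boundaries) is at most `window`. The query runs on a
#' GenomicRanges interval index and is symmetric in the gene/TE roles.
#'
#' @param genes data.frame with gene_id, chromosome, start, end (1-based
#'   inclusive), e.g. a `kinome`.
#' @param tes data.frame from [read_te_bed()] (chromosome, start, end,
#'   te_class, 1-based inclusive).
#' @param window Maximum distance in bp (default 100,000).
#' @return data.frame with one row per (gene, TE) association: gene_id,
#'   te_index (row in `tes`), te_class, distance. Zero rows when `tes` is
#'   empty. TE chromosomes absent from the gene set trigger a warning and
#'   are skipped.
#' @export
associate_tes <- function(genes, tes, window = 1e5) {
  stopifnot(window >= 0)
  empty <- data.frame(gene_id = character(), te_index = integer(),
                      te_class = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(tes) || !nrow(tes) || !nrow(genes)) return(empty)
  orphan <- setdiff(unique(tes$chromosome), unique(genes$chromosome))
  if (length(orphan)) {
    warning("TE chromosome(s) absent from the gene annotation, skipped: ",
            paste(orphan, collapse = ", "))
    tes <- tes[!tes$chromosome %in% orphan, , drop = FALSE]
    if (!nrow(tes)) return(empty)
  }
  gr_genes <- GenomicRanges::GRanges(
    genes$chromosome, IRanges::IRanges(genes$start, genes$end))
  gr_tes <- GenomicRanges::GRanges(
    tes$chromosome, IRanges::IRanges(tes$start, tes$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_tes, maxgap = window,
                                      ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(gr_genes[qi], gr_tes[si])
  keep <- !is.na(d) & d <= window
  out <- data.frame(gene_id = genes$gene_id[qi[keep]],
                    te_index = si[keep],
                    te_class = tes$te_class[si[keep]],
                    distance = as.numeric(d[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$te_index), , drop = FALSE]
}

#' Summarize TE association across the kinome
#'
#' Counts TE-associated kinase genes, their overlap with tandem duplication
#' clusters, the TE class composition among associated elements, and the
#' per-group breakdown. Fractions follow the reporting convention
#' (`100 * numerator / denominator`, half-up, 1 decimal).
#'
#' @param associations data.frame from [associate_tes()].
#' @param kinome A `kinome` data.frame.
#' @param tandem A `tandem_clusters` object (or NULL when the tandem stage
#'   was not run).
#' @return list with n_associated, pct_of_kinome, n_associated_tandem,
#'   pct_of_associated, te_class_composition (per-class counts and percent
#'   of associated TE records), per_group (associated gene counts per
#'   kinase group).
#' @export
summarize_te_overlap <- function(associations, kinome, tandem = NULL) {
  assoc_genes <- unique(associations$gene_id)
  n_assoc <- length(assoc_genes)
  tandem_genes <- if (!is.null(tandem)) names(tandem$membership) else character()
  n_assoc_tandem <- length(intersect(assoc_genes, tandem_genes))
  cls <- if (nrow(associations)) table(associations$te_class) else table(character())
  cls_df <- data.frame(te_class = names(cls), n = as.integer(cls),
                       stringsAsFactors = FALSE)
  cls_df$percent <- vapply(cls_df$n, percent_half_up, numeric(1),
                           denominator = max(1L, nrow(associations)))
  grp <- stats::setNames(kinome$group, kinome$gene_id)
  per_group <- if (n_assoc) as.data.frame(table(group = grp[assoc_genes]),
                                          stringsAsFactors = FALSE)
    else data.frame(group = character(), Freq = integer())
  names(per_group)[2] <- "n_associated"
  list(
    n_associated = n_assoc,
    pct_of_kinome = if (nrow(kinome)) percent_half_up(n_assoc, nrow(kinome))
      else 0,
    n_associated_tandem = n_assoc_tandem,
    pct_of_associated = if (n_assoc) percent_half_up(n_assoc_tandem, n_assoc)
      else 0,
    te_class_composition = cls_df,
    per_group = per_group)
}
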