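# Kinome identification: filter typical protein kinases from domain hits,
# keep one (longest) isoform per gene, classify into subfamilies, and
# assemble the per-gene kinome table.

KINASE_DOMAINS <- c("Pkinase", "Pkinase_Tyr")

#' Filter typical protein kinases from domain hits
#'
#' A protein is retained as a typical kinase iff it carries at least one hit
#' to a kinase domain model (Pkinase or Pkinase_Tyr) that passes *both* the
#' E-value cutoff and the minimum domain-model coverage. Proteins whose best
#' kinase hits fail either criterion are atypical (treated downstream as
#' probable pseudogenes and excluded). The number of kinase domains per
#' retained protein is counted over non-overlapping passing hits, selected
#' greedily by ascending E-value on protein (envelope) coordinates.
#'
#' @param hits data.frame from [parse_domain_hits()].
#' @param evalue_max Maximum per-domain E-value (default 1e-10).
#' @param coverage_min Minimum fraction of the domain model covered
#'   (default 0.5).
#' @param kinase_domains Domain model names treated as kinase domains.
#' @return data.frame with columns `protein_id` and `n_kinase_domains`
#'   (>= 1), one row per retained protein, ordered by protein_id.
#' @export
filter_kinases <- function(hits, evalue_max = 1e-10, coverage_min = 0.5,
                           kinase_domains = KINASE_DOMAINS) {
  stopifnot(evalue_max > 0)
  stop_if_not_scalar_fraction(coverage_min, "coverage_min")
  pass <- hits[hits$domain_name %in% kinase_domains &
                 hits$evalue <= evalue_max &
                 hits$model_coverage >= coverage_min, , drop = FALSE]
  if (!nrow(pass))
    return(data.frame(protein_id = character(), n_kinase_domains = integer(),
                      stringsAsFactors = FALSE))
  counts <- vapply(split(pass, pass$protein_id), function(h) {
    h <- h[order(h$evalue), , drop = FALSE]
    taken <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(h))) {
      if (!nrow(taken) ||
          all(h$env_to[i] < taken[, 1] | h$env_from[i] > taken[, 2]))
        taken <- rbind(taken, c(h$env_from[i], h$env_to[i]))
    }
    nrow(taken)
  }, integer(1))
  out <- data.frame(protein_id = names(counts),
                    n_kinase_domains = unname(counts),
                    stringsAsFactors = FALSE)
  out[order(out$protein_id), , drop = FALSE]
}

#' Keep the longest isoform per gene
#'
#' @param protein_lengths Named numeric vector of residue lengths, one per
#'   protein/transcript.
#' @param isoform_groups Named list mapping gene id to the character vector
#'   of its isoform ids; every retained protein must belong to exactly one
#'   group. Isoforms absent from `protein_lengths` are ignored.
#' @return Character vector of retained protein ids (one per gene, the
#'   longest; ties broken by lexicographically smallest id).
#' @export
select_longest_isoform <- function(protein_lengths, isoform_groups) {
  stopifnot(!is.null(names(protein_lengths)))
  kept <- vapply(isoform_groups, function(ids) {
    ids <- ids[ids %in% names(protein_lengths)]
    if (!length(ids)) return(NA_character_)
    len <- protein_lengths[ids]
    cand <- sort(ids[len == max(len)])
    cand[1]
  }, character(1))
  unname(kept[!is.na(kept)])
}

#' Identify and classify a kinome from pipeline inputs
#'
#' Runs the full identification stage: parse domain hits, filter typical
#' kinases, keep the longest isoform per gene, classify each kinase into a
#' subfamily (with the `"Unknown"` fallback), and attach gene coordinates
#' and intron counts from the annotation.
#'
#' @param hits Path to a domain-hit table, or a parsed data.frame.
#' @param proteins Path to protein FASTA or an `AAStringSet`.
#' @param annotation Path to GFF3 or a list from [read_gff3_genes()].
#' @param profiles A `profile_set` for subfamily classification.
#' @param cds Optional path to CDS FASTA or `DNAStringSet`; when given, the
#'   kinase's CDS sequence is carried in the result.
#' @param source_assembly Label recorded for every gene (e.g. `"chr"` or
#'   `"scaf"` for chromosome- vs scaffold-level assemblies).
#' @param evalue_max,coverage_min Passed to [filter_kinases()].
#' @return data.frame of class `kinome` with one row per kinase gene:
#'   gene_id, protein_id, source_assembly, chromosome, start, end, strand,
#'   n_kinase_domains, subfamily, group, classification_score, intron_count,
#'   protein_length and (optionally) cds_sequence.
#' @export
identify_kinome <- function(hits, proteins, annotation, profiles,
                            cds = NULL, source_assembly = "assembly",
                            evalue_max = 1e-10, coverage_min = 0.5) {
  if (is.character(hits)) hits <- parse_domain_hits(hits)
  if (is.character(proteins)) proteins <- read_protein_fasta(proteins)
  if (is.character(annotation)) annotation <- read_gff3_genes(annotation)
  if (is.character(cds)) cds <- read_cds_fasta(cds)

  typical <- filter_kinases(hits, evalue_max = evalue_max,
                            coverage_min = coverage_min)
  lens <- stats::setNames(Biostrings::width(proteins), names(proteins))
  lens <- lens[names(lens) %in% typical$protein_id]
  iso_groups <- split(annotation$transcripts$transcript_id,
                      annotation$transcripts$gene_id)
  kept <- select_longest_isoform(lens, iso_groups)
  if (!length(kept))
    return(empty_kinome())

  tx2gene <- stats::setNames(annotation$transcripts$gene_id,
                             annotation$transcripts$transcript_id)
  exon_counts <- table(annotation$exons$transcript_id)
  genes <- annotation$genes
  rownames(genes) <- genes$gene_id

  rows <- lapply(sort(kept), function(pid) {
    gid <- tx2gene[[pid]]
    g <- genes[gid, ]
    cls <- classify_subfamily(as.character(proteins[[pid]]), profiles)
    data.frame(
      gene_id = gid, protein_id = pid, source_assembly = source_assembly,
      chromosome = g$chromosome, start = g$start, end = g$end,
      strand = g$strand,
      n_kinase_domains =
        typical$n_kinase_domains[typical$protein_id == pid],
      subfamily = cls$subfamily, group = cls$group,
      classification_score = cls$score,
      intron_count = as.integer(exon_counts[[pid]]) - 1L,
      protein_length = unname(lens[pid]),
      cds_sequence = if (!is.null(cds) && pid %in% names(cds))
        as.character(cds[[pid]]) else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("kinome", "data.frame")
  out
}

empty_kinome <- function() {
  out <- data.frame(gene_id = character(), protein_id = character(),
                    source_assembly = character(), chromosome = character(),
                    start = integer(), end = integer(), strand = character(),
                    n_kinase_domains = integer(), subfamily = character(),
                    group = character(), classification_score = numeric(),
                    intron_count = integer(), protein_length = integer(),
                    cds_sequence = character(), stringsAsFactors = FALSE)
  class(out) <- c("kinome", "data.frame")
  out
}

#' @export
print.kinome <- function(x, ...) {
  cat(sprintf("kinome: %d genes, %d subfamilies (%d groups), %d chromosomes\n",
              nrow(x), length(unique(x$subfamily)),
              length(unique(x$group)), length(unique(x$chromosome))))
  if (nrow(x)) {
    tab <- sort(table(x$group), decreasing = TRUE)
    cat("  groups: ", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.kinome <- function(object, ...) {
  list(n_genes = nrow(object),
       n_subfamilies = length(unique(object$subfamily)),
       n_groups = length(unique(object$group)),
       pct_unknown = percent_half_up(sum(object$subfamily == "Unknown"),
                                     max(1L, nrow(object))),
       pct_intronless = percent_half_up(sum(object$intron_count == 0),
                                        max(1L, nrow(object))),
       n_multi_domain = sum(object$n_kinase_domains > 1))
}
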