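# Readers and writers for the interchange formats the pipeline consumes:
# FASTA (Biostrings), GFF3/BED (rtracklayer), TSV matrices, and the
# whitespace-delimited hmmsearch per-domain table ("domtblout") dialect.

#' Read protein or nucleotide FASTA
#'
#' Thin wrappers over [Biostrings::readAAStringSet()] /
#' [Biostrings::readDNAStringSet()] that strip FASTA descriptions so that
#' names are bare sequence identifiers.
#'
#' @param path Path to a FASTA file.
#' @return An `AAStringSet` (`read_protein_fasta`) or `DNAStringSet`
#'   (`read_cds_fasta`) named by sequence id.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname read_protein_fasta
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

write_fasta <- function(x, path, width = 60L) {
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 file (1-based inclusive coordinates) and returns tidy
#' tables for genes, transcripts (mRNA) and exons, linked by `ID`/`Parent`
#' attributes.
#'
#' @param path Path to a GFF3 file with `gene`, `mRNA` and `exon` records.
#' @return A list with data.frames `genes` (gene_id, chromosome, start, end,
#'   strand), `transcripts` (transcript_id, gene_id, start, end) and `exons`
#'   (transcript_id, start, end).
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  parent <- vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  tx <- df[df$type == "mRNA", , drop = FALSE]
  ex <- df[df$type == "exon", , drop = FALSE]
  list(
    genes = data.frame(
      gene_id = genes$ID, chromosome = as.character(genes$seqnames),
      start = genes$start, end = genes$end,
      strand = as.character(genes$strand), stringsAsFactors = FALSE),
    transcripts = data.frame(
      transcript_id = tx$ID, gene_id = parent[df$type == "mRNA"],
      start = tx$start, end = tx$end, stringsAsFactors = FALSE),
    exons = data.frame(
      transcript_id = parent[df$type == "exon"],
      start = ex$start, end = ex$end, stringsAsFactors = FALSE)
  )
}

#' Read transposable-element annotations from BED
#'
#' BED input is 0-based half-open; the returned table is 1-based inclusive,
#' matching the gene coordinate convention used everywhere else in the
#' package.
#'
#' @param path Path to a BED file whose name column holds the TE class.
#' @return data.frame with columns chromosome, start, end (1-based
#'   inclusive) and te_class.
#' @export
read_te_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), te_class = character(),
                      stringsAsFactors = FALSE))
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    te_class = if (!is.null(gr$name)) gr$name else NA_character_,
    stringsAsFactors = FALSE)
}

# ---- hmmsearch per-domain table ("domtblout") dialect --------------------
#
# Whitespace-delimited, '#'-comment lines ignored. Fields (in order):
#  1 target name   2 target acc   3 tlen        4 query name  5 query acc
#  6 qlen          7 seq E-value  8 seq score   9 seq bias   10 dom #
# 11 ndom         12 c-Evalue    13 i-Evalue   14 dom score  15 dom bias
# 16 hmm from     17 hmm to      18 ali from   19 ali to     20 env from
# 21 env to       22 acc         23+ free-text description
# target = protein, query = domain model; coordinates 1-based inclusive.

#' Parse a domain-hit table
#'
#' Reads one record per domain alignment from an hmmsearch per-domain table
#' (see the dialect documented in the package source). The per-domain
#' independent E-value (i-Evalue) is used as the hit E-value, and coverage is
#' measured on the domain model: `(hmm_to - hmm_from + 1) / model_length`.
#'
#' @param path Path to a domtblout-style file.
#' @return data.frame with columns protein_id, domain_name, model_length,
#'   evalue, score, hmm_from, hmm_to, env_from, env_to, model_coverage.
#'   Empty file (or comments only) yields zero rows.
#' @export
parse_domain_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  empty <- data.frame(
    protein_id = character(), domain_name = character(),
    model_length = integer(), evalue = numeric(), score = numeric(),
    hmm_from = integer(), hmm_to = integer(), env_from = integer(),
    env_to = integer(), model_coverage = numeric(), stringsAsFactors = FALSE)
  if (!length(keep)) return(empty)
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22)
      stop(sprintf("malformed domain-hit row at line %d: expected >= 22 fields, got %d",
                   i, length(f)), call. = FALSE)
    num <- suppressWarnings(as.numeric(f[c(6, 13, 14, 16, 17, 20, 21)]))
    if (anyNA(num))
      stop(sprintf("malformed domain-hit row at line %d: non-numeric field", i),
           call. = FALSE)
    if (num[5] < num[4])
      stop(sprintf("malformed domain-hit row at line %d: hmm_to < hmm_from", i),
           call. = FALSE)
    if (num[7] < num[6])
      stop(sprintf("malformed domain-hit row at line %d: env_to < env_from", i),
           call. = FALSE)
    data.frame(protein_id = f[1], domain_name = f[4],
               model_length = as.integer(num[1]), evalue = num[2],
               score = num[3], hmm_from = as.integer(num[4]),
               hmm_to = as.integer(num[5]), env_from = as.integer(num[6]),
               env_to = as.integer(num[7]),
               model_coverage = (num[5] - num[4] + 1) / num[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Write hits in the same dialect (used by the synthetic-data module).
# `hits` needs the columns produced by parse_domain_hits plus protein_length.
write_domain_hits <- function(hits, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# synthetic per-domain hits; whitespace-delimited domtblout dialect",
             con)
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      writeLines(paste(
        h$protein_id, "-", h$protein_length, h$domain_name, "-",
        h$model_length,
        format(h$evalue, scientific = TRUE, digits = 3), "0.0", "0.0",
        "1", "1",
        format(h$evalue, scientific = TRUE, digits = 3),
        format(h$evalue, scientific = TRUE, digits = 3),
        format(h$score, nsmall = 1), "0.0",
        h$hmm_from, h$hmm_to, h$env_from, h$env_to, h$env_from, h$env_to,
        "0.95", "-", sep = " "), con)
    }
  }
  invisible(path)
}
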