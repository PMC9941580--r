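# Per-kinase protein properties (molecular weight, isoelectric point,
# intron counts) and the kinome summary report with its percentage
# conventions.

# Average (not monoisotopic) residue masses in Daltons, ExPASy-style table.
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

# EMBOSS-style pKa table: termini plus ionizable side chains. Different
# published tables shift pI by ~0.1-0.5 pH; the table is an argument of
# isoelectric_point() for that reason.
PKA_EMBOSS <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

check_protein_alphabet <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty character scalar", call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(AA_RESIDUE_MASS))
  if (length(bad))
    stop(sprintf("illegal amino-acid character '%s' at position %d",
                 chars[bad[1]], bad[1]), call. = FALSE)
  chars
}

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water mass, using an ExPASy-style
#' average-mass table. Additive up to water:
#' `MW(ab) = MW(a) + MW(b) - 18.01524`.
#'
#' @param sequence Protein sequence over the 20-letter amino-acid alphabet;
#'   ambiguity codes are rejected with the offending position named.
#' @return Molecular weight in Daltons.
#' @examples
#' molecular_weight("G")   # 75.07 Da
#' @export
molecular_weight <- function(sequence) {
  chars <- check_protein_alphabet(sequence)
  sum(AA_RESIDUE_MASS[chars]) + WATER_MASS
}

net_charge <- function(chars, pH, pka) {
  pos <- 1 / (1 + 10^(pH - pka$nterm))
  neg <- -1 / (1 + 10^(pka$cterm - pH))
  for (aa in names(pka$positive)) {
    n <- sum(chars == aa)
    if (n) pos <- pos + n / (1 + 10^(pH - pka$positive[[aa]]))
  }
  for (aa in names(pka$negative)) {
    n <- sum(chars == aa)
    if (n) neg <- neg - n / (1 + 10^(pka$negative[[aa]] - pH))
  }
  pos + neg
}

#' Protein isoelectric point
#'
#' Finds the pH at which the Henderson-Hasselbalch net charge (N/C termini
#' plus ionizable side chains under the given pKa table) vanishes, by
#' bisection on `[0, 14]`. The charge function is strictly decreasing in
#' pH, so the root is unique; iteration stops when |charge| < 1e-4 or the
#' bracket is narrower than 1e-4 pH.
#'
#' @inheritParams molecular_weight
#' @param pka pKa table: list with `nterm`, `cterm` scalars and named
#'   vectors `positive`, `negative` (defaults to an EMBOSS-style table).
#' @return pI in pH units, inside (0, 14).
#' @export
isoelectric_point <- function(sequence, pka = PKA_EMBOSS) {
  chars <- check_protein_alphabet(sequence)
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(chars, mid, pka)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-4) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Count introns of a gene's selected transcript
#'
#' Introns = exon count - 1 on the given transcript (by convention the
#' longest-protein isoform chosen during identification).
#'
#' @param annotation list from [read_gff3_genes()].
#' @param gene_id Gene identifier.
#' @param transcript_id Optional; defaults to the gene's transcript with
#'   the most exons being ambiguous, so pass the selected isoform. When
#'   omitted and the gene has one transcript, that one is used.
#' @return Integer intron count (0 flags an intronless gene).
#' @export
count_introns <- function(annotation, gene_id, transcript_id = NULL) {
  tx <- annotation$transcripts[annotation$transcripts$gene_id == gene_id, ]
  if (!nrow(tx)) stop("gene has no transcripts: ", gene_id, call. = FALSE)
  if (is.null(transcript_id)) {
    if (nrow(tx) > 1L)
      stop("gene has several transcripts; pass the selected isoform",
           call. = FALSE)
    transcript_id <- tx$transcript_id[1]
  }
  n_ex <- sum(annotation$exons$transcript_id == transcript_id)
  if (n_ex == 0) stop("transcript has no exon records: ", transcript_id,
                      call. = FALSE)
  n_ex - 1L
}

#' Per-kinase protein property table
#'
#' @param kinome A `kinome` data.frame.
#' @param proteins `AAStringSet` (or named character) holding the kinome's
#'   protein sequences.
#' @return data.frame: gene_id, protein_id, molecular_weight,
#'   isoelectric_point, intron_count, n_kinase_domains, intronless,
#'   multi_domain.
#' @export
protein_properties <- function(kinome, proteins) {
  if (!is.character(proteins))
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  data.frame(
    gene_id = kinome$gene_id, protein_id = kinome$protein_id,
    molecular_weight = vapply(proteins[kinome$protein_id],
                              molecular_weight, numeric(1)),
    isoelectric_point = vapply(proteins[kinome$protein_id],
                               isoelectric_point, numeric(1)),
    intron_count = kinome$intron_count,
    n_kinase_domains = kinome$n_kinase_domains,
    intronless = kinome$intron_count == 0L,
    multi_domain = kinome$n_kinase_domains > 1L,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble the kinome summary report
#'
#' Pure function of the persisted stage outputs. All fractions are
#' `100 * numerator / denominator` rounded half-up — 2 decimals for the
#' assembly composition, 1 decimal elsewhere; zero denominators omit the
#' field with a warning.
#'
#' @param kinome A `kinome` data.frame.
#' @param tandem Optional `tandem_clusters`.
#' @param te_summary Optional list from [summarize_te_overlap()].
#' @param merge Optional `kinome_merge` (for source-assembly composition).
#' @param networks Optional list with elements `control`, `stress`
#'   (`coexpression_network`s) and `comparison` (`network_comparison`).
#' @return list of class `kinome_report`.
#' @export
summary_report <- function(kinome, tandem = NULL, te_summary = NULL,
                           merge = NULL, networks = NULL) {
  n <- nrow(kinome)
  rep_list <- list(
    n_kinases = n,
    per_group = as.data.frame(table(group = kinome$group),
                              stringsAsFactors = FALSE),
    per_subfamily = as.data.frame(table(subfamily = kinome$subfamily),
                                  stringsAsFactors = FALSE),
    n_unknown = sum(kinome$subfamily == "Unknown"),
    pct_unknown = percent_half_up(sum(kinome$subfamily == "Unknown"), n),
    n_intronless = sum(kinome$intron_count == 0),
    pct_intronless = percent_half_up(sum(kinome$intron_count == 0), n),
    n_multi_domain = sum(kinome$n_kinase_domains > 1))
  if (!is.null(tandem)) {
    n_tandem <- length(tandem$membership)
    rep_list$n_tandem_genes <- n_tandem
    rep_list$n_tandem_clusters <- if (is.null(tandem$clusters)) 0L
      else nrow(tandem$clusters)
    rep_list$pct_tandem <- percent_half_up(n_tandem, n)
  }
  if (!is.null(te_summary)) rep_list$te <- te_summary
  if (!is.null(merge)) rep_list$assembly_composition <- merge$composition
  if (!is.null(networks)) {
    rep_list$network <- list(
      n_edges_control = nrow(networks$control$edges),
      n_edges_stress = nrow(networks$stress$edges),
      n_shared_edges = length(networks$comparison$shared_edges),
      pct_edge_loss = round(networks$comparison$pct_edge_loss, 1),
      isolated_control = networks$comparison$isolated_control,
      isolated_stress = networks$comparison$isolated_stress)
  }
  structure(rep_list, class = "kinome_report")
}

#' @export
print.kinome_report <- function(x, ...) {
  cat(sprintf("kinome_report: %d kinases", x$n_kinases))
  if (!is.null(x$pct_tandem))
    cat(sprintf(", %d tandem (%.1f%%)", x$n_tandem_genes, x$pct_tandem))
  if (!is.null(x$te))
    cat(sprintf(", %d TE-associated (%.1f%%)", x$te$n_associated,
                x$te$pct_of_kinome))
  cat("\n")
  invisible(x)
}

#' Write a kinome report as canonical JSON
#'
#' Serialization is deterministic (fixed field order, full precision), so a
#' fixed-seed pipeline run writes a byte-identical report.
#'
#' @param report A `kinome_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
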