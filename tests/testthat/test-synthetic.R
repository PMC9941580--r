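# Synthetic-data generators: determinism, planted structure, degenerate
# settings, and round-tripping through the package's own readers.

test_that("genome generation is byte-identical for a fixed seed", {
  g1 <- generate_genome(n_genes = 6, seed = 7, te_density = 5,
                        dir = tempfile())
  g2 <- generate_genome(n_genes = 6, seed = 7, te_density = 5,
                        dir = tempfile())
  for (f in names(g1$paths)) {
    expect_identical(readLines(g1$paths[[f]]), readLines(g2$paths[[f]]),
                     info = f)
  }
  expect_identical(g1$truth, g2$truth)
})

test_that("planted tandem arrays appear in truth with the requested gaps", {
  g <- generate_genome(n_genes = 4, tandem_spec = list(c(3, 5000, 0.98)),
                       te_density = 0, seed = 11)
  tc <- g$truth$tandem_clusters
  expect_equal(nrow(tc), 1)
  expect_equal(tc$size, 3)
  members <- strsplit(tc$genes, ",")[[1]]
  coords <- g$genes[match(members, g$genes$gene_id), ]
  coords <- coords[order(coords$start), ]
  gaps <- coords$start[-1] - coords$end[-nrow(coords)] - 1
  expect_equal(gaps, c(5000, 5000))
  # planted pairwise CDS identity >= the requested identity
  cds <- read_cds_fasta(g$paths$cds)
  tx <- paste0(members, ".t1")
  for (i in 1:2) for (j in (i + 1):3) {
    pi <- pairwise_identity(as.character(cds[[tx[i]]]),
                            as.character(cds[[tx[j]]]), type = "dna")
    expect_gte(pi$identity, 0.98)
  }
})

test_that("zero TE density yields an empty BED and no TE-associated genes", {
  g <- generate_genome(n_genes = 3, tandem_spec = list(), te_density = 0,
                       seed = 3)
  expect_equal(file.size(g$paths$te_bed), 0)
  expect_length(g$truth$te_associated_genes, 0)
  expect_equal(nrow(read_te_bed(g$paths$te_bed)), 0)
})

test_that("oversized tandem arrays and bad specs are rejected", {
  expect_error(generate_genome(tandem_spec = list(c(3, 6e5, 0.97)),
                               seed = 1),
               "cannot fit")
  expect_error(generate_genome(tandem_spec = list(c(1, 100, 0.97)), seed = 1),
               "size >= 2")
  expect_error(generate_genome(tandem_spec = list(c(2, 100, 1.5)), seed = 1),
               "identity")
})

test_that("emitted files round-trip through the package readers", {
  g <- shared_genome()
  prot <- read_protein_fasta(g$paths$proteins)
  cds <- read_cds_fasta(g$paths$cds)
  expect_setequal(names(prot), g$transcripts$transcript_id)
  expect_equal(unname(Biostrings::width(prot)[match(g$transcripts$transcript_id,
                                                    names(prot))]),
               g$transcripts$protein_length)
  expect_setequal(names(cds), g$transcripts$transcript_id)
  ann <- read_gff3_genes(g$paths$gff)
  expect_setequal(ann$genes$gene_id, g$genes$gene_id)
  m <- match(g$genes$gene_id, ann$genes$gene_id)
  expect_equal(ann$genes$start[m], g$genes$start)
  expect_equal(ann$genes$end[m], g$genes$end)
  te <- read_te_bed(g$paths$te_bed)
  expect_equal(te[order(te$chromosome, te$start), c("chromosome", "start", "end")],
               g$tes[, c("chromosome", "start", "end")],
               ignore_attr = TRUE)
  # GFF3 internal consistency: exons within their mRNA within their gene
  for (i in seq_len(nrow(ann$transcripts))) {
    tx <- ann$transcripts[i, ]
    gene <- ann$genes[ann$genes$gene_id == tx$gene_id, ]
    ex <- ann$exons[ann$exons$transcript_id == tx$transcript_id, ]
    expect_true(all(ex$start >= tx$start & ex$end <= tx$end))
    expect_true(tx$start >= gene$start && tx$end <= gene$end)
  }
  # TEs stay within chromosome bounds
  expect_true(all(g$tes$start >= 1 & g$tes$end <= 1e6))
})

test_that("noise-free domain hits cover exactly the planted proteins", {
  g <- shared_genome()
  h <- generate_domain_hits(g, noise_spec = 0, seed = 5)
  hits <- parse_domain_hits(h$hits_path)
  typical <- filter_kinases(hits)
  expect_setequal(typical$protein_id, g$transcripts$transcript_id)
  expect_true(all(hits$evalue <= 1e-10))
  expect_true(all(hits$model_coverage >= 0.5))
})

test_that("decoy proteins only carry threshold-violating hits", {
  g <- shared_genome()
  h <- generate_domain_hits(g, noise_spec = 0.3, seed = 6)
  expect_gt(length(h$decoy_ids), 0)
  hits <- parse_domain_hits(h$hits_path)
  decoy_hits <- hits[hits$protein_id %in% h$decoy_ids, ]
  expect_true(all(decoy_hits$evalue > 1e-10 |
                    decoy_hits$model_coverage < 0.5))
  typical <- filter_kinases(hits)
  expect_length(intersect(typical$protein_id, h$decoy_ids), 0)
  # decoys are present in the emitted protein FASTA
  expect_true(all(h$decoy_ids %in%
                    names(read_protein_fasta(h$proteins_path))))
})

test_that("expression TSVs are deterministic per seed", {
  g <- shared_genome()
  e1 <- generate_expression(g, seed = 9)
  l1 <- lapply(e1$paths, readLines)
  e2 <- generate_expression(g, seed = 9)
  for (f in names(e1$paths))
    expect_identical(l1[[f]], readLines(e2$paths[[f]]), info = f)
})

test_that("planted blocks reach the target correlation with many samples", {
  # gentle-noise settings: a large gene set stabilizes the TPM denominator
  # and a small signal amplitude limits lognormal attenuation, so the
  # planted block correlation survives to the subfamily TPM level
  g <- generate_genome(n_chromosomes = 2, n_genes = 60, tandem_spec = list(),
                       te_density = 0, seed = 13)
  spec <- data.frame(tissue = sprintf("t%02d", 1:60), condition = "control",
                     n_replicates = 1, stringsAsFactors = FALSE)
  e <- generate_expression(g, samples_spec = spec, block_correlation = 0.95,
                           noise_sd = 0.02, signal_sd = 0.25,
                           base_log_mean = 7, base_log_sd = 0.3, seed = 13)
  tpm <- compute_tpm(e$counts, e$lengths)
  sub_of <- stats::setNames(g$truth$subfamily_of_gene[g$transcripts$gene_id],
                            g$transcripts$transcript_id)
  se <- aggregate_subfamily(tpm, sub_of)
  for (block in g$truth$correlated_blocks) {
    cc <- stats::cor(t(se[block, , drop = FALSE]))
    # all three mutual edges of the planted block pass the 0.7 threshold
    expect_true(all(cc[upper.tri(cc)] > 0.7))
  }
  # latent subfamily profiles realize the analytic correlation r = v/(v+s2)
  spec_big <- data.frame(tissue = sprintf("t%03d", 1:500),
                         condition = "control", n_replicates = 1)
  e2 <- generate_expression(g, samples_spec = spec_big,
                            block_correlation = 0.9, seed = 14)
  for (block in g$truth$correlated_blocks) {
    cc <- stats::cor(t(e2$latent[block, , drop = FALSE]))
    expect_equal(mean(cc[upper.tri(cc)]), 0.9, tolerance = 0.05)
  }
})

test_that("noise-free expression makes same-subfamily genes exactly proportional", {
  g <- shared_genome()
  e <- generate_expression(g, block_correlation = 0.9, noise_sd = 0,
                           seed = 21)
  tpm <- compute_tpm(e$counts, e$lengths)
  gene_of <- stats::setNames(g$transcripts$gene_id,
                             g$transcripts$transcript_id)
  sub_of <- g$truth$subfamily_of_gene
  by_sub <- split(rownames(tpm), sub_of[gene_of[rownames(tpm)]])
  checked <- 0L
  for (txs in by_sub) {
    if (length(txs) < 2) next
    cc <- stats::cor(t(tpm[txs, , drop = FALSE]))
    expect_equal(min(cc), 1, tolerance = 1e-6)
    checked <- checked + 1L
  }
  expect_gt(checked, 0)
})

test_that("empty or invalid expression designs are rejected", {
  g <- shared_genome()
  expect_error(generate_expression(g, samples_spec = data.frame()), "empty")
  bad <- data.frame(tissue = "leaf", condition = "control", n_replicates = 0)
  expect_error(generate_expression(g, samples_spec = bad), "n_replicates")
  expect_error(generate_expression(g, block_correlation = 1), "< 1")
})
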