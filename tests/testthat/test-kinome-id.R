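# Domain-hit parsing, typical-kinase filtering, isoform selection and
# subfamily classification.

write_domtbl_line <- function(path, protein = "p1", domain = "Pkinase",
                              qlen = 264, evalue = 1e-30, hmm = c(10, 150),
                              env = c(5, 160)) {
  line <- paste(protein, "-", 400, domain, "-", qlen, evalue, 80, 0, 1, 1,
                evalue, evalue, 80, 0, hmm[1], hmm[2], env[1], env[2],
                env[1], env[2], 0.9, "desc text")
  writeLines(line, path)
  path
}

test_that("model coverage is measured on the domain model", {
  f <- write_domtbl_line(tempfile(), qlen = 264, hmm = c(10, 150))
  hits <- parse_domain_hits(f)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$model_coverage, (150 - 10 + 1) / 264, tolerance = 1e-12)
  expect_equal(hits$model_coverage, 0.534, tolerance = 1e-3)
})

test_that("empty and malformed hit tables are handled", {
  empty <- tempfile(); writeLines("# only a comment", empty)
  expect_equal(nrow(parse_domain_hits(empty)), 0)
  short <- tempfile(); writeLines(c("# header", "p1 Pkinase 1e-30"), short)
  expect_error(parse_domain_hits(short), "line 2")
  rev <- write_domtbl_line(tempfile(), hmm = c(150, 10))
  expect_error(parse_domain_hits(rev), "hmm_to < hmm_from")
  expect_error(parse_domain_hits(tempfile()), "no such file")
})

test_that("kinase filtering demands both E-value and coverage", {
  mk <- function(protein, evalue, cov, env = c(1, 100), domain = "Pkinase") {
    data.frame(protein_id = protein, domain_name = domain, model_length = 264,
               evalue = evalue, score = 50, hmm_from = 1,
               hmm_to = round(cov * 264), env_from = env[1], env_to = env[2],
               model_coverage = cov, stringsAsFactors = FALSE)
  }
  hits <- rbind(
    mk("keep", 1e-12, 0.6),
    mk("fail_cov", 1e-20, 0.49),
    mk("fail_e", 1e-9, 0.9),
    mk("other_domain", 1e-40, 0.9)[, ])
  hits$domain_name[4] <- "WD40"
  out <- filter_kinases(hits)
  expect_equal(out$protein_id, "keep")
  expect_equal(out$n_kinase_domains, 1L)
})

test_that("non-overlapping passing hits count as separate kinase domains", {
  mk <- function(evalue, env) {
    data.frame(protein_id = "p", domain_name = "Pkinase", model_length = 264,
               evalue = evalue, score = 50, hmm_from = 1, hmm_to = 200,
               env_from = env[1], env_to = env[2], model_coverage = 0.75,
               stringsAsFactors = FALSE)
  }
  two <- rbind(mk(1e-30, c(1, 150)), mk(1e-25, c(200, 350)))
  expect_equal(filter_kinases(two)$n_kinase_domains, 2L)
  overlapping <- rbind(mk(1e-30, c(1, 150)), mk(1e-25, c(100, 250)))
  expect_equal(filter_kinases(overlapping)$n_kinase_domains, 1L)
})

test_that("filtering is monotone in both thresholds", {
  set.seed(101)
  hits <- data.frame(protein_id = sprintf("p%02d", sample(30, 80, TRUE)),
                     domain_name = sample(c("Pkinase", "Pkinase_Tyr"), 80, TRUE),
                     model_length = 264, evalue = 10^-runif(80, 0, 30),
                     score = 50, hmm_from = 1, hmm_to = 100,
                     env_from = 1, env_to = 100,
                     model_coverage = runif(80), stringsAsFactors = FALSE)
  base <- filter_kinases(hits, evalue_max = 1e-5, coverage_min = 0.3)
  for (em in c(1e-10, 1e-20)) for (cm in c(0.5, 0.7)) {
    tight <- filter_kinases(hits, evalue_max = em, coverage_min = cm)
    expect_true(all(tight$protein_id %in% base$protein_id))
    m <- match(tight$protein_id, base$protein_id)
    expect_true(all(tight$n_kinase_domains <= base$n_kinase_domains[m]))
  }
})

test_that("longest-isoform selection keeps one protein per gene", {
  lens <- c(gA.t1 = 300, gA.t2 = 310, gB.t1 = 200,
            gC.t1 = 150, gC.t2 = 150)
  groups <- list(gA = c("gA.t1", "gA.t2"), gB = "gB.t1",
                 gC = c("gC.t2", "gC.t1"))
  kept <- select_longest_isoform(lens, groups)
  expect_setequal(kept, c("gA.t2", "gB.t1", "gC.t1"))  # tie -> lexicographic
  # idempotent: reapplying to the kept subset changes nothing
  kept2 <- select_longest_isoform(lens[kept],
                                  lapply(groups, intersect, kept))
  expect_setequal(kept2, kept)
})

test_that("classification recovers planted subfamilies and falls back to Unknown", {
  prof <- shared_profiles()
  cons <- kinomer:::synthetic_domain_consensus()
  hit <- classify_subfamily(cons[["RLK-Pelle_DLSV"]], prof)
  expect_equal(hit$subfamily, "RLK-Pelle_DLSV")
  expect_equal(hit$group, "RLK-Pelle")
  set.seed(55)
  rnd <- classify_subfamily(random_aa(150), prof)
  expect_equal(rnd$subfamily, "Unknown")
  expect_equal(rnd$group, "Unknown")
  # margin rule: two identical profiles tie -> Unknown
  aln <- list(S1 = c("ACDEF", "ACDEF"), S2 = c("ACDEF", "ACDEF"))
  twin <- build_profile_set(aln, c(S1 = "G1", S2 = "G2"), threshold = 0,
                            margin = 1)
  expect_equal(classify_subfamily("ACDEF", twin)$subfamily, "Unknown")
  expect_error(classify_subfamily("ACDEF",
                                  structure(list(profiles = list()),
                                            class = "profile_set")),
               "empty profile set")
  expect_error(classify_subfamily("", prof), "non-empty")
})

test_that("identification recovers exactly the planted kinome with decoy noise", {
  g <- shared_genome()
  h <- generate_domain_hits(g, noise_spec = 0.3, seed = 8)
  kin <- identify_kinome(h$hits_path, h$proteins_path, g$paths$gff,
                         shared_profiles(), cds = g$paths$cds,
                         source_assembly = "synthetic")
  expect_s3_class(kin, "kinome")
  expect_setequal(kin$gene_id, g$genes$gene_id)
  # one protein per gene, the longest isoform
  expect_false(anyDuplicated(kin$gene_id) > 0)
  iso <- g$truth$isoform_groups
  lens <- stats::setNames(g$transcripts$protein_length,
                          g$transcripts$transcript_id)
  for (i in seq_len(nrow(kin))) {
    ids <- iso[[kin$gene_id[i]]]
    expect_equal(unname(lens[kin$protein_id[i]]), max(lens[ids]))
  }
  # classification agrees with the planted subfamily labels
  expect_equal(kin$subfamily,
               unname(g$truth$subfamily_of_gene[kin$gene_id]))
  expect_true(all(kin$start <= kin$end))
  expect_true(all(kin$n_kinase_domains >= 1))
  # intron counts match the GFF exon structure of the selected isoform
  ann <- read_gff3_genes(g$paths$gff)
  for (i in seq_len(nrow(kin)))
    expect_equal(kin$intron_count[i],
                 count_introns(ann, kin$gene_id[i], kin$protein_id[i]))
})
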