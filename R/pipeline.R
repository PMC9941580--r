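# End-to-end synthetic pipeline: generate a genome, identify and classify
# the kinome, detect duplications, associate TEs, aggregate expression and
# build/compare condition networks, writing every stage output as
# deterministic text so fixed-seed runs are byte-identical.

#' Run the full pipeline on synthetic data
#'
#' Executes every stage in order on a seeded synthetic genome and writes
#' the stage outputs (kinome table, tandem clusters, similarity pairs, TE
#' associations, subfamily expression, per-condition network edge lists and
#' topology, JSON summary report) into `out_dir`. With a fixed seed two
#' runs produce byte-identical files.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param out_dir Output directory (created; stage files overwritten).
#' @param n_chromosomes,n_genes,tandem_spec,te_density,samples_spec,block_correlation,noise_sd
#'   Generator settings, passed through to [generate_genome()] and
#'   [generate_expression()].
#' @param noise_spec Decoy fraction for [generate_domain_hits()].
#' @param pcc_min Network edge threshold (default 0.7).
#' @return Invisibly, a list with all intermediate objects (`genome`,
#'   `kinome`, `pairs`, `tandem`, `tiers`, `te_summary`, `subfam_expr`,
#'   `networks`, `report`) plus `out_dir`.
#' @export
run_kinome_pipeline <- function(seed = 1L, out_dir = tempfile("kinome_run"),
                                n_chromosomes = 3L, n_genes = 20L,
                                tandem_spec = list(c(3, 5000, 0.97),
                                                   c(2, 8000, 0.98)),
                                te_density = 20,
                                samples_spec = default_samples_spec(),
                                block_correlation = 0.9, noise_sd = 0.25,
                                noise_spec = 0.2, pcc_min = 0.7) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(n_chromosomes = n_chromosomes, n_genes = n_genes,
                            tandem_spec = tandem_spec,
                            te_density = te_density, seed = seed,
                            dir = file.path(out_dir, "genome"))
  hits <- generate_domain_hits(genome, noise_spec = noise_spec, seed = seed)
  profiles <- synthetic_profile_set()
  kinome <- identify_kinome(hits$hits_path, hits$proteins_path,
                            genome$paths$gff, profiles,
                            cds = genome$paths$cds,
                            source_assembly = "synthetic")
  write_tsv(as.data.frame(kinome)[, setdiff(names(kinome), "cds_sequence")],
            file.path(out_dir, "kinome.tsv"))

  cds <- stats::setNames(kinome$cds_sequence, kinome$gene_id)
  pairs <- similarity_search(cds)
  tandem <- detect_tandem_clusters(kinome, pairs)
  tiers <- tier_segmental(kinome, pairs)
  write_tsv(pair_geometry(pairs, kinome), file.path(out_dir, "pairs.tsv"))
  if (!is.null(tandem$clusters))
    write_tsv(tandem$clusters, file.path(out_dir, "tandem_clusters.tsv"))

  tes <- read_te_bed(genome$paths$te_bed)
  assoc <- associate_tes(kinome, tes)
  te_summary <- summarize_te_overlap(assoc, kinome, tandem)
  write_tsv(assoc, file.path(out_dir, "te_associations.tsv"))

  expr <- generate_expression(genome, samples_spec = samples_spec,
                              block_correlation = block_correlation,
                              noise_sd = noise_sd, seed = seed)
  tpm <- compute_tpm(expr$counts, expr$lengths)
  qc <- qc_filter_samples(tpm)
  kept_samples <- expr$samples[expr$samples$sample %in% colnames(qc$matrix), ]
  avg <- average_replicates(qc$matrix, kept_samples)
  sub_of_tx <- stats::setNames(kinome$subfamily, kinome$protein_id)
  subfam_expr <- aggregate_subfamily(avg$matrix, sub_of_tx)
  write_matrix_tsv(subfam_expr, file.path(out_dir, "subfamily_expression.tsv"),
                   id_col = "subfamily")

  is_control <- avg$samples$condition == "control"
  networks <- list(
    control = build_network(subfam_expr[, avg$samples$sample[is_control],
                                        drop = FALSE],
                            pcc_min = pcc_min, condition = "control"),
    stress = build_network(subfam_expr[, avg$samples$sample[!is_control],
                                       drop = FALSE],
                           pcc_min = pcc_min, condition = "stress"))
  networks$comparison <- compare_networks(networks$control, networks$stress)
  for (cond in c("control", "stress")) {
    topo <- topology_report(networks[[cond]])
    write_tsv(topo$edges, file.path(out_dir, paste0("network_", cond,
                                                    "_edges.tsv")))
    write_tsv(topo$nodes, file.path(out_dir, paste0("network_", cond,
                                                    "_nodes.tsv")))
  }

  report <- summary_report(kinome, tandem = tandem, te_summary = te_summary,
                           networks = networks)
  write_report_json(report, file.path(out_dir, "report.json"))

  invisible(list(genome = genome, kinome = kinome, pairs = pairs,
                 tandem = tandem, tiers = tiers, te_summary = te_summary,
                 subfam_expr = subfam_expr, networks = networks,
                 report = report, out_dir = out_dir))
}
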