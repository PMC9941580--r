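# Synthetic-data module: seeded generators for genomes (proteins, CDS, GFF3
# gene models, TE BED), domain-hit tables and expression matrices, with
# planted ground truth (tandem arrays, subfamily labels, TE associations,
# correlated subfamily blocks). The generators emulate the statistical
# structure the analysis assumes — multi-chromosome gene sets with tandem
# arrays of near-identical paralogs, LTR-dominated interspersed TEs, and
# multi-tissue/multi-condition expression with replicate groups — so every
# pipeline stage can be validated against known truth.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Built-in synthetic kinase subfamilies
#'
#' Twelve subfamily labels drawn from the standard plant kinase
#' classification (RLK-Pelle, CMGC, CAMK, CK1, STE, TKL, AGC, NEK groups),
#' used to label synthetic genes and to name the built-in profile set.
#'
#' @return data.frame with columns `subfamily` and `group`.
#' @export
synthetic_subfamilies <- function() {
  data.frame(
    subfamily = c("RLK-Pelle_DLSV", "RLK-Pelle_LRR-XII-1",
                  "RLK-Pelle_RLCK-XVI", "RLK-Pelle_LysM",
                  "CMGC_CDK", "CMGC_MAPK", "CAMK_CDPK", "CK1_CK1",
                  "STE_STE7", "TKL-Pl-1", "AGC_PKA-PKG", "NEK"),
    group = c("RLK-Pelle", "RLK-Pelle", "RLK-Pelle", "RLK-Pelle",
              "CMGC", "CMGC", "CAMK", "CK1",
              "STE", "TKL", "AGC", "NEK"),
    stringsAsFactors = FALSE)
}

# Fixed-seed 120-residue consensus per subfamily. The internal seed is a
# package constant (not user-facing): the consensus identities must be
# stable so profile sets built in one session classify genomes generated in
# another.
synthetic_domain_consensus <- function(length = 120L) {
  subf <- synthetic_subfamilies()$subfamily
  with_seed(900001L, {
    out <- vapply(seq_along(subf), function(i)
      paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = ""),
      character(1))
    names(out) <- subf
    out
  })
}

#' Built-in profile set matching the synthetic subfamilies
#'
#' Builds one PSSM per synthetic subfamily from a small family alignment
#' obtained by mutating the subfamily consensus, so that kinases emitted by
#' [generate_genome()] are classifiable out of the box.
#'
#' @param n_train Family members per alignment.
#' @param divergence Per-residue substitution rate within the training
#'   family.
#' @param threshold,margin Passed to [build_profile_set()].
#' @return A `profile_set`.
#' @export
synthetic_profile_set <- function(n_train = 8L, divergence = 0.1,
                                  threshold = 30, margin = 5) {
  cons <- synthetic_domain_consensus()
  subf <- synthetic_subfamilies()
  with_seed(900002L, {
    alignments <- lapply(cons, function(cs)
      vapply(seq_len(n_train), function(i) mutate_protein(cs, divergence),
             character(1)))
  })
  groups <- stats::setNames(subf$group, subf$subfamily)
  build_profile_set(alignments, groups, threshold = threshold, margin = margin)
}

mutate_protein <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  n_mut <- round(length(chars) * rate)
  if (n_mut > 0) {
    pos <- sample.int(length(chars), n_mut)
    for (p in pos) {
      chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1)
    }
  }
  paste(chars, collapse = "")
}

# random codon per residue (uniform over synonymous codons)
reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  codons_by_aa <- split(names(gc), gc)
  chars <- strsplit(protein, "")[[1]]
  out <- character(length(chars))
  for (a in unique(chars)) {
    cs <- codons_by_aa[[a]]
    at <- chars == a
    out[at] <- if (length(cs) == 1L) cs else sample(cs, sum(at), replace = TRUE)
  }
  paste(out, collapse = "")
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

# Mutate a CDS at `positions` (1-based), choosing substitutions that never
# create a stop codon; returns the mutated character vector.
mutate_cds_at <- function(chars, positions) {
  for (p in positions) {
    cod_i <- (p - 1L) %/% 3L
    cod_pos <- cod_i * 3L + 1:3
    old <- chars[p]
    for (b in sample(setdiff(c("A", "C", "G", "T"), old))) {
      trial <- chars
      trial[p] <- b
      if (!paste(trial[cod_pos], collapse = "") %in% STOP_CODONS) {
        chars <- trial
        break
      }
    }
  }
  chars
}

random_protein <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                                    collapse = "")

# ---------------------------------------------------------------------------

#' Generate a synthetic kinase genome with planted ground truth
#'
#' Emits protein FASTA, CDS FASTA, a GFF3 gene annotation and a TE BED file
#' for a multi-chromosome genome containing `n_genes` singleton kinase genes
#' plus the tandem arrays requested in `tandem_spec`. Tandem paralogs are
#' produced by copy-and-mutate of a seed CDS with per-copy substitutions at
#' disjoint sites, so that pairwise CDS identity within an array is at least
#' the planted identity. Transposable elements (LTR-retrotransposon
#' dominated) are interspersed at `te_density` per Mbp.
#'
#' @param n_chromosomes,n_genes Positive counts; `n_genes` singleton genes
#'   are distributed across chromosomes in addition to array members.
#' @param tandem_spec List of numeric triples `c(size, gap_bp, identity)`:
#'   array size (>= 2), boundary gap between consecutive members (bp >= 0)
#'   and planted pairwise CDS identity in (0, 1].
#' @param te_density TEs per Mbp (>= 0); 0 yields an empty BED.
#' @param seed Integer seed; fixed seed gives byte-identical output files.
#' @param chromosome_length Length of every chromosome (bp).
#' @param isoform_fraction Fraction of singleton genes receiving a second,
#'   shorter mRNA isoform.
#' @param dir Output directory (created if missing).
#' @param correlated_blocks Optional list of subfamily-name vectors planted
#'   as coexpressed blocks; by default the first six represented subfamilies
#'   are split into two blocks of three.
#' @return Object of class `synthetic_genome`: paths to the four files plus
#'   `genes`, `transcripts` tables and a `truth` list (tandem cluster
#'   membership and metadata, TE-associated gene set under a 100 kb window,
#'   subfamily map, isoform groups, correlated blocks).
#' @export
generate_genome <- function(n_chromosomes = 3L, n_genes = 24L,
                            tandem_spec = list(c(3, 5000, 0.97)),
                            te_density = 20, seed = 1L,
                            chromosome_length = 1e6,
                            isoform_fraction = 0.25,
                            dir = tempfile("synthgenome"),
                            correlated_blocks = NULL) {
  stopifnot(n_chromosomes >= 1, n_genes >= 1, te_density >= 0,
            chromosome_length > 0)
  for (ts in tandem_spec) {
    if (length(ts) != 3 || ts[1] < 2 || ts[2] < 0 || ts[3] <= 0 || ts[3] > 1)
      stop("tandem_spec entries must be c(size >= 2, gap >= 0, identity in (0,1])",
           call. = FALSE)
    if ((ts[1] - 1) * ts[2] + ts[1] * 1000 > chromosome_length)
      stop("tandem array cannot fit on the shortest chromosome", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subf <- synthetic_subfamilies()
  cons <- synthetic_domain_consensus()

  with_seed(sub_seed(seed, 1L), {
    # ---- build gene units (singletons and arrays) -----------------------
    units <- list()
    sf_i <- 0L
    next_sf <- function() {
      sf_i <<- sf_i + 1L
      subf$subfamily[(sf_i - 1L) %% nrow(subf) + 1L]
    }
    new_gene_unit <- function(sf, with_isoform) {
      nt <- sample(20:40, 1)
      ct <- sample(20:40, 1)
      prot <- paste0("M", random_protein(nt),
                     mutate_protein(cons[[sf]], 0.05), random_protein(ct))
      cds <- reverse_translate(prot)
      n_exons <- sample(1:6, 1)
      list(subfamily = sf, cds = cds, n_exons = n_exons,
           isoform = with_isoform)
    }
    for (g in seq_len(n_genes)) {
      units[[length(units) + 1L]] <- list(
        type = "singleton",
        genes = list(new_gene_unit(next_sf(),
                                   stats::runif(1) < isoform_fraction)))
    }
    for (ai in seq_along(tandem_spec)) {
      ts <- tandem_spec[[ai]]
      k <- as.integer(ts[1]); gap <- as.integer(ts[2]); ident <- ts[3]
      seedg <- new_gene_unit(next_sf(), FALSE)
      L <- nchar(seedg$cds)
      m <- floor(L * (1 - ident) / 2)
      if (k * m > L) stop("planting identity too low for CDS length",
                          call. = FALSE)
      pool <- sample.int(L)
      chars0 <- strsplit(seedg$cds, "")[[1]]
      members <- lapply(seq_len(k), function(i) {
        pos <- if (m > 0) pool[((i - 1) * m + 1):(i * m)] else integer()
        g <- seedg
        g$cds <- paste(mutate_cds_at(chars0, pos), collapse = "")
        g
      })
      units[[length(units) + 1L]] <- list(
        type = "array", gap = gap, identity = ident, genes = members)
    }

    # ---- place units on chromosomes ------------------------------------
    chrom_of_unit <- rep(seq_len(n_chromosomes), length.out = length(units))
    # arrays last in `units`; shuffle assignment so arrays land on varied
    # chromosomes across seeds
    chrom_of_unit <- sample(chrom_of_unit)
    genes <- list(); transcripts <- list(); gff <- character()
    tandem_membership <- character(); tandem_meta <- list()
    gidx <- 0L; cluster_idx <- 0L
    for (ci in seq_len(n_chromosomes)) {
      chrom <- sprintf("chr%02d", ci)
      pos <- sample(2000:20000, 1)
      for (ui in which(chrom_of_unit == ci)) {
        unit <- units[[ui]]
        if (unit$type == "array") {
          cluster_idx <- cluster_idx + 1L
          cid <- sprintf("TDC%03d", cluster_idx)
          member_ids <- character()
        }
        for (mi in seq_along(unit$genes)) {
          gu <- unit$genes[[mi]]
          gidx <- gidx + 1L
          gene_id <- sprintf("g%04d", gidx)
          cds_len <- nchar(gu$cds)
          introns <- if (gu$n_exons > 1)
            sample(100:800, gu$n_exons - 1, replace = TRUE) else integer()
          span <- cds_len + sum(introns)
          gstart <- pos; gend <- pos + span - 1L
          if (gend > chromosome_length)
            stop(sprintf("genes do not fit on %s (need %d bp)", chrom, gend),
                 call. = FALSE)
          strand <- sample(c("+", "-"), 1)
          # exon lengths: split the CDS at interior points (>= 3 bp pieces)
          if (gu$n_exons > 1) {
            cuts <- sort(sample(seq(3, cds_len - 3, by = 3),
                                gu$n_exons - 1))
            exon_len <- diff(c(0L, cuts, cds_len))
          } else exon_len <- cds_len
          tx_id <- paste0(gene_id, ".t1")
          gff <- c(gff, paste(chrom, "synth", "gene", gstart, gend, ".",
                              strand, ".", paste0("ID=", gene_id), sep = "\t"))
          gff <- c(gff, paste(chrom, "synth", "mRNA", gstart, gend, ".",
                              strand, ".",
                              paste0("ID=", tx_id, ";Parent=", gene_id),
                              sep = "\t"))
          epos <- gstart
          for (e in seq_along(exon_len)) {
            eend <- epos + exon_len[e] - 1L
            gff <- c(gff, paste(chrom, "synth", "exon", epos, eend, ".",
                                strand, ".",
                                paste0("ID=", tx_id, ".e", e, ";Parent=", tx_id),
                                sep = "\t"))
            epos <- eend + (if (e <= length(introns)) introns[e] else 0L) + 1L
          }
          prot <- translate_cds(gu$cds)
          transcripts[[tx_id]] <- list(transcript_id = tx_id, gene_id = gene_id,
                                       protein = prot, cds = gu$cds,
                                       n_exons = gu$n_exons)
          iso_ids <- tx_id
          if (isTRUE(gu$isoform)) {
            # second, shorter isoform: first ~60% of codons, fewer exons
            keep <- max(1L, floor(cds_len / 3 * 0.6)) * 3L
            tx2 <- paste0(gene_id, ".t2")
            cds2 <- substr(gu$cds, 1, keep)
            n_ex2 <- max(1L, gu$n_exons - 1L)
            gff <- c(gff, paste(chrom, "synth", "mRNA", gstart, gend, ".",
                                strand, ".",
                                paste0("ID=", tx2, ";Parent=", gene_id),
                                sep = "\t"))
            gff <- c(gff, paste(chrom, "synth", "exon", gstart,
                                gstart + keep - 1L, ".", strand, ".",
                                paste0("ID=", tx2, ".e1;Parent=", tx2),
                                sep = "\t"))
            transcripts[[tx2]] <- list(transcript_id = tx2, gene_id = gene_id,
                                       protein = translate_cds(cds2),
                                       cds = cds2, n_exons = n_ex2)
            iso_ids <- c(iso_ids, tx2)
          }
          genes[[gene_id]] <- list(gene_id = gene_id, chromosome = chrom,
                                   start = gstart, end = gend,
                                   strand = strand, subfamily = gu$subfamily,
                                   transcripts = iso_ids)
          if (unit$type == "array") {
            member_ids <- c(member_ids, gene_id)
            tandem_membership[gene_id] <- cid
            pos <- gend + unit$gap + 1L
          } else {
            pos <- gend + sample(2000:20000, 1) + 1L
          }
        }
        if (unit$type == "array") {
          tandem_meta[[cid]] <- data.frame(
            cluster_id = cid, chromosome = chrom,
            size = length(member_ids), gap = unit$gap,
            identity = unit$identity,
            genes = paste(member_ids, collapse = ","),
            stringsAsFactors = FALSE)
          pos <- pos - unit$gap + sample(30000:60000, 1)
        }
      }
    }

    # ---- transposable elements -----------------------------------------
    te <- NULL
    n_te_per_chr <- round(te_density * chromosome_length / 1e6)
    if (n_te_per_chr > 0) {
      te <- do.call(rbind, lapply(seq_len(n_chromosomes), function(ci) {
        len <- sample(300:5000, n_te_per_chr, replace = TRUE)
        start <- vapply(len, function(l)
          sample.int(chromosome_length - l, 1), integer(1))
        data.frame(chromosome = sprintf("chr%02d", ci), start = start,
                   end = start + len - 1L,
                   te_class = sample(c("LTR_retrotransposon", "LINE", "SINE",
                                       "DNA_transposon"), n_te_per_chr,
                                     replace = TRUE,
                                     prob = c(0.88, 0.05, 0.03, 0.04)),
                   stringsAsFactors = FALSE)
      }))
      te <- te[order(te$chromosome, te$start), , drop = FALSE]
    }
  })

  genes_df <- do.call(rbind, lapply(genes, function(g)
    data.frame(g[c("gene_id", "chromosome", "start", "end", "strand",
                   "subfamily")], stringsAsFactors = FALSE)))
  rownames(genes_df) <- NULL
  tx_df <- do.call(rbind, lapply(transcripts, function(t)
    data.frame(transcript_id = t$transcript_id, gene_id = t$gene_id,
               protein_length = nchar(t$protein), cds_length = nchar(t$cds),
               n_exons = t$n_exons, stringsAsFactors = FALSE)))
  rownames(tx_df) <- NULL

  # TE-associated genes under the 100 kb convention (brute force; the
  # pipeline's interval-index implementation is validated against this)
  te_assoc <- character()
  if (!is.null(te) && nrow(te)) {
    for (gi in seq_len(nrow(genes_df))) {
      g <- genes_df[gi, ]
      same <- te[te$chromosome == g$chromosome, , drop = FALSE]
      if (!nrow(same)) next
      gap <- pmax(0, pmax(same$start - g$end, g$start - same$end) - 1)
      if (any(gap <= 1e5)) te_assoc <- c(te_assoc, g$gene_id)
    }
  }

  present <- unique(genes_df$subfamily)
  if (is.null(correlated_blocks)) {
    ordered <- subf$subfamily[subf$subfamily %in% present]
    correlated_blocks <- if (length(ordered) >= 6)
      list(ordered[1:3], ordered[4:6]) else list(ordered)
  } else {
    for (b in correlated_blocks)
      if (!all(b %in% present))
        stop("correlated block names a subfamily absent from the genome",
             call. = FALSE)
  }

  paths <- list(proteins = file.path(dir, "proteins.faa"),
                cds = file.path(dir, "cds.fna"),
                gff = file.path(dir, "genes.gff3"),
                te_bed = file.path(dir, "tes.bed"))
  prot_set <- Biostrings::AAStringSet(vapply(transcripts, `[[`, "",
                                             "protein"))
  cds_set <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, "", "cds"))
  write_fasta(prot_set, paths$proteins)
  write_fasta(cds_set, paths$cds)
  writeLines(c("##gff-version 3", gff), paths$gff)
  if (is.null(te) || !nrow(te)) {
    file.create(paths$te_bed)
  } else {
    writeLines(sprintf("%s\t%d\t%d\t%s", te$chromosome, te$start - 1L,
                       te$end, te$te_class), paths$te_bed)
  }

  truth <- list(
    tandem_cluster_membership = tandem_membership,
    tandem_clusters = if (length(tandem_meta))
      do.call(rbind, tandem_meta) else NULL,
    te_associated_genes = te_assoc,
    subfamily_of_gene = stats::setNames(genes_df$subfamily, genes_df$gene_id),
    correlated_blocks = correlated_blocks,
    isoform_groups = lapply(genes, `[[`, "transcripts"))
  structure(list(dir = dir, paths = paths, genes = genes_df,
                 transcripts = tx_df, tes = te, truth = truth, seed = seed),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d genes (%d transcripts) on %d chromosomes, %d TEs, %d planted tandem clusters\n",
              nrow(x$genes), nrow(x$transcripts),
              length(unique(x$genes$chromosome)),
              if (is.null(x$tes)) 0L else nrow(x$tes),
              if (is.null(x$truth$tandem_clusters)) 0L
              else nrow(x$truth$tandem_clusters)))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Generate a synthetic domain-hit table
#'
#' Every planted kinase protein receives at least one kinase-domain hit
#' passing the identification thresholds (E <= 1e-10, model coverage >=
#' 0.5); a `noise_spec` fraction of decoy proteins is appended to the
#' protein FASTA and receives only hits that violate at least one threshold
#' (half fail coverage at good E-values, half fail the E-value at good
#' coverage).
#'
#' @param genome A `synthetic_genome`.
#' @param noise_spec Decoy fraction (relative to the number of planted
#'   proteins) in `[0, 1]`.
#' @param seed Integer seed.
#' @param multi_domain_fraction Fraction of planted proteins given a second
#'   non-overlapping passing hit.
#' @return list with `hits_path` (domtblout dialect), `proteins_path`
#'   (planted proteins plus decoys), `hits` data.frame and `decoy_ids`.
#' @export
generate_domain_hits <- function(genome, noise_spec = 0, seed = 1L,
                                 multi_domain_fraction = 0.1) {
  stopifnot(inherits(genome, "synthetic_genome"),
            noise_spec >= 0, noise_spec <= 1)
  prots <- read_protein_fasta(genome$paths$proteins)
  models <- c(Pkinase = 264L, Pkinase_Tyr = 258L)
  with_seed(sub_seed(seed, 2L), {
    rows <- list()
    add_hit <- function(id, plen, domain, evalue, cov, env_from) {
      mlen <- models[[domain]]
      span <- max(1L, round(cov * mlen))
      hfrom <- sample.int(mlen - span + 1L, 1)
      alen <- min(span, plen - env_from + 1L)
      rows[[length(rows) + 1L]] <<- data.frame(
        protein_id = id, protein_length = plen, domain_name = domain,
        model_length = mlen, evalue = evalue,
        score = max(5, round(-log10(evalue) * 2.2, 1)),
        hmm_from = hfrom, hmm_to = hfrom + span - 1L,
        env_from = env_from, env_to = env_from + alen - 1L,
        stringsAsFactors = FALSE)
    }
    for (i in seq_along(prots)) {
      id <- names(prots)[i]; plen <- nchar(as.character(prots[[i]]))
      dom <- sample(names(models), 1)
      add_hit(id, plen, dom, 10^-stats::runif(1, 15, 60),
              stats::runif(1, 0.6, 1.0), sample.int(max(1L, plen - 140L), 1))
      if (stats::runif(1) < multi_domain_fraction && plen > 160) {
        # second passing hit on a disjoint protein region
        add_hit(id, plen, dom, 10^-stats::runif(1, 12, 30), 0.55,
                env_from = plen - 60L)
      }
    }
    n_decoy <- ceiling(noise_spec * length(prots))
    decoy_ids <- character()
    decoys <- NULL
    if (n_decoy > 0) {
      decoy_ids <- sprintf("decoy%03d", seq_len(n_decoy))
      decoys <- Biostrings::AAStringSet(stats::setNames(
        vapply(seq_len(n_decoy), function(i)
          random_protein(sample(150:400, 1)), character(1)), decoy_ids))
      for (i in seq_len(n_decoy)) {
        plen <- nchar(as.character(decoys[[i]]))
        if (i %% 2 == 0) {
          add_hit(decoy_ids[i], plen, sample(names(models), 1),
                  10^-stats::runif(1, 15, 40), stats::runif(1, 0.2, 0.45), 1L)
        } else {
          add_hit(decoy_ids[i], plen, sample(names(models), 1),
                  10^-stats::runif(1, 2, 9), stats::runif(1, 0.6, 0.9), 1L)
        }
      }
    }
  })
  hits <- do.call(rbind, rows)
  hits_path <- file.path(genome$dir, "hits.domtbl")
  proteins_path <- file.path(genome$dir, "proteins_with_decoys.faa")
  write_domain_hits(hits, hits_path)
  all_prots <- if (is.null(decoys)) prots else c(prots, decoys)
  write_fasta(all_prots, proteins_path)
  list(hits_path = hits_path, proteins_path = proteins_path, hits = hits,
       decoy_ids = decoy_ids)
}

# ---------------------------------------------------------------------------

#' Generate a synthetic expression experiment
#'
#' Simulates transcript counts for the genome's transcripts across a design
#' of tissue/condition replicate groups. Subfamily latent profiles follow a
#' shared-factor model: for subfamilies in the same planted block,
#' `eta_s = sqrt(r) f_block + sqrt(1 - r) u_s` per sample, so the latent
#' subfamily-level Pearson correlation equals `block_correlation = r`
#' (`r = v / (v + sigma^2)` with factor variance `v = r` and
#' subfamily-specific variance `1 - r`). Gene log-means add observation
#' noise of standard deviation `noise_sd`; exponentiated means are sampled
#' as Poisson counts. When `noise_sd = 0` the expected counts are emitted
#' unrounded (a non-integer, noise-free diagnostic mode), so the noiseless
#' contract — exactly proportional expression profiles, hence Pearson
#' correlation 1, within a subfamily — holds exactly.
#'
#' @param genome A `synthetic_genome`.
#' @param samples_spec data.frame with columns `tissue`, `condition`,
#'   `n_replicates` (>= 1). Conditions use the labels `control` and
#'   `stress:<type>`.
#' @param block_correlation Target within-block subfamily correlation in
#'   `[0, 1)`.
#' @param noise_sd Gene-level log-scale noise standard deviation (>= 0).
#' @param seed Integer seed; fixed seed gives byte-identical TSVs.
#' @param signal_sd Log-scale amplitude of the subfamily latent profile.
#' @param base_log_mean,base_log_sd Log-normal baseline abundance per
#'   transcript.
#' @return list with `counts` (transcripts x samples integer matrix),
#'   `lengths` (named CDS lengths), `samples` metadata data.frame and
#'   `paths` of the three TSVs written next to the genome.
#' @export
generate_expression <- function(genome,
                                samples_spec = default_samples_spec(),
                                block_correlation = 0.9, noise_sd = 0.25,
                                seed = 1L, signal_sd = 0.5,
                                base_log_mean = 5, base_log_sd = 1) {
  stopifnot(inherits(genome, "synthetic_genome"),
            block_correlation >= 0, block_correlation < 1, noise_sd >= 0)
  if (!nrow(samples_spec)) stop("empty samples_spec", call. = FALSE)
  if (any(samples_spec$n_replicates < 1))
    stop("n_replicates must be >= 1", call. = FALSE)

  samples <- do.call(rbind, lapply(seq_len(nrow(samples_spec)), function(i) {
    s <- samples_spec[i, ]
    grp <- paste(s$tissue, gsub("[^A-Za-z0-9]", "_", s$condition), sep = "_")
    data.frame(sample = paste0(grp, "_rep", seq_len(s$n_replicates)),
               tissue = s$tissue, genotype = "synthetic",
               condition = s$condition, replicate_group = grp,
               stringsAsFactors = FALSE)
  }))
  n_samp <- nrow(samples)
  tx <- genome$transcripts
  sub_of_gene <- genome$truth$subfamily_of_gene
  subfamilies <- unique(sub_of_gene)
  blocks <- genome$truth$correlated_blocks
  block_of <- stats::setNames(rep(NA_integer_, length(subfamilies)),
                              subfamilies)
  for (b in seq_along(blocks)) block_of[blocks[[b]]] <- b
  r <- block_correlation

  with_seed(sub_seed(seed, 3L), {
    f <- matrix(stats::rnorm(length(blocks) * n_samp), length(blocks), n_samp)
    eta <- matrix(NA_real_, length(subfamilies), n_samp,
                  dimnames = list(subfamilies, samples$sample))
    for (s in subfamilies) {
      u <- stats::rnorm(n_samp)
      b <- block_of[[s]]
      eta[s, ] <- if (!is.na(b)) sqrt(r) * f[b, ] + sqrt(1 - r) * u else u
    }
    base <- exp(stats::rnorm(nrow(tx), base_log_mean, base_log_sd))
    counts <- matrix(0L, nrow(tx), n_samp,
                     dimnames = list(tx$transcript_id, samples$sample))
    for (i in seq_len(nrow(tx))) {
      sfam <- sub_of_gene[[tx$gene_id[i]]]
      logmu <- log(base[i]) + signal_sd * eta[sfam, ]
      if (noise_sd > 0) logmu <- logmu + stats::rnorm(n_samp, 0, noise_sd)
      mu <- exp(logmu)
      counts[i, ] <- if (noise_sd > 0) stats::rpois(n_samp, mu) else mu
    }
  })
  lengths <- stats::setNames(tx$cds_length, tx$transcript_id)
  paths <- list(counts = file.path(genome$dir, "counts.tsv"),
                lengths = file.path(genome$dir, "lengths.tsv"),
                samples = file.path(genome$dir, "samples.tsv"))
  write_matrix_tsv(counts, paths$counts, id_col = "transcript")
  write_tsv(data.frame(transcript = names(lengths), length = lengths),
            paths$lengths)
  write_tsv(samples, paths$samples)
  list(counts = counts, lengths = lengths, samples = samples, paths = paths,
       latent = eta)
}

#' Default synthetic experiment design
#'
#' Four tissues under control and cold-stress conditions with three
#' replicates each (24 samples), a desk-scale stand-in for a multi-tissue,
#' multi-condition expression compendium.
#'
#' @return data.frame with columns tissue, condition, n_replicates.
#' @export
default_samples_spec <- function() {
  expand.grid(tissue = c("leaf", "bark", "latex", "root"),
              condition = c("control", "stress:cold"),
              n_replicates = 3, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}
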