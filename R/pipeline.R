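#' End-to-end small RNA pipeline on synthetic data
#'
#' Generates (or loads) a genome and annotations, simulates small RNA
#' libraries for a wild-type and a mutant condition, then runs the full
#' analysis chain per replicate — collapse, exact multi-map alignment,
#' structural filtering, class calling, per-gene quantification —
#' followed by differential 22G analysis between conditions and gene-set
#' enrichment of the down-regulated list against the simulated depletion
#' set. All outputs land in `out_dir`: gene tables, DE table, enrichment
#' table, length/first-nt profile, a machine-readable `summary.json` and
#' a `manifest.json` recording parameters.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param de a [de_config()] used for the differential calls.
#' @param gff,genome_fasta optional paths to an existing annotation /
#'   genome; when given they are loaded instead of simulated (both are
#'   required together).
#' @param write_fastq also write the simulated libraries as FASTQ.
#' @return Invisibly, a list with the DE table, enrichment row, per-sample
#'   gene tables, and the summary list.
#' @export
run_smallrna <- function(config = sim_config(), out_dir,
                         de = de_config(), gff = NULL, genome_fasta = NULL,
                         write_fastq = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(gff) || !is.null(genome_fasta)) {
    if (is.null(gff) || !file.exists(gff)) {
      .stopf("annotation GFF not found: %s",
             if (is.null(gff)) "(not given)" else gff)
    }
    if (is.null(genome_fasta) || !file.exists(genome_fasta)) {
      .stopf("genome FASTA not found: %s",
             if (is.null(genome_fasta)) "(not given)" else genome_fasta)
    }
    annots <- read_gff(gff)
    genome <- Biostrings::readDNAStringSet(genome_fasta)
    names(genome) <- sub("\\s.*", "", names(genome))
  } else {
    gen <- make_genome(config)
    genome <- gen$genome
    annots <- gen$annots
    write_genome_fasta(genome, file.path(out_dir, "genome.fa"))
    write_gff(annots, file.path(out_dir, "annotations.gff3"))
  }
  index <- build_feature_index(annots)

  sims <- list(
    wildtype = simulate_small_rna_reads(genome, annots, config, "wildtype"),
    mutant = simulate_small_rna_reads(genome, annots, config, "mutant")
  )
  tables <- list(wildtype = list(), mutant = list())
  class_counts <- list()
  profile <- NULL
  for (cond in names(sims)) {
    reads <- sims[[cond]]$reads
    for (r in sort(unique(reads$replicate))) {
      d <- reads[reads$replicate == r, , drop = FALSE]
      sample_id <- sprintf("%s_rep%d", cond, r)
      if (write_fastq) {
        write_reads_fastq(reads, file.path(out_dir, paste0(sample_id, ".fq")),
                          replicate = r)
      }
      collapsed <- collapse_reads(rep(d$sequence, d$count))
      aln <- align_reads(collapsed, genome)
      parts <- filter_structural(aln, index)
      depth <- attr(parts$retained, "depth")
      cls <- classify_all(collapsed, parts$retained, index)
      tab <- quantify_genes(cls, depth, sample_id)
      utils::write.table(
        tab, file.path(out_dir, paste0("genes_", sample_id, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      tables[[cond]][[r]] <- tab
      lev <- factor(cls$assignments$class,
                    levels = c("piRNA", "22G", "26G", "unassigned"))
      cc <- tapply(cls$assignments$count, lev, sum, default = 0L)
      class_counts[[sample_id]] <- as.list(cc)
      if (is.null(profile)) profile <- length_firstnt_profile(collapsed)
    }
  }
  utils::write.table(cbind(length = rownames(profile), as.data.frame(profile)),
                     file.path(out_dir, "length_firstnt_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  de_tab <- differential_22g(tables$wildtype, tables$mutant, de)
  utils::write.table(de_tab, file.path(out_dir, "de_22g.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  down <- de_tab$gene[de_tab$call == "down"]
  truth <- sims$mutant$truth
  enr <- set_enrichment(down, truth$depleted_set, de_tab$gene,
                        set_name = "depleted_truth_set")
  utils::write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  recovery <- if (length(truth$depleted_set)) {
    mean(truth$depleted_set %in% down)
  } else {
    NA_real_
  }
  summary <- list(
    seed = config$seed,
    n_samples = length(class_counts),
    reads_per_sample = config$reads_per_sample,
    class_read_counts = class_counts,
    n_de_genes = nrow(de_tab),
    n_up = sum(de_tab$call == "up"),
    n_down = sum(de_tab$call == "down"),
    depleted_set_size = length(truth$depleted_set),
    down_recovery = recovery,
    down_log2_enrichment = enr$log2_enrichment,
    down_fisher_p = enr$p
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(out_dir, "smallrna", config,
                  list(de = unclass(de)))
  invisible(list(de = de_tab, enrichment = enr, tables = tables,
                 summary = summary))
}

#' ChIP target-calling pipeline on synthetic peaks
#'
#' Generates annotations, plants target genes, simulates replicate peak
#' sets as BED, calls targets with the both-replicate promoter rule, and
#' compares against the planted truth.
#'
#' @param config a [sim_config()] (genome shape; seeds all randomness).
#' @param out_dir output directory.
#' @param n_targets number of planted target genes.
#' @param q_cutoff q-value cutoff for [call_targets()].
#' @return Invisibly, a list with calls, targets, truth and the summary.
#' @export
run_chip <- function(config = sim_config(), out_dir, n_targets = 20L,
                     q_cutoff = 0.1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- make_genome(config)
  promoters <- derive_promoters(gen$annots)
  set.seed(.derive_seed(config$seed, "chip_targets"))
  plantable <- plantable_chip_targets(gen$annots)
  targets_true <- sort(sample(plantable, n_targets))
  peaks <- simulate_chip_peaks(gen$annots, targets_true, seed = config$seed)
  write_peaks_bed(peaks$rep1, file.path(out_dir, "peaks_rep1.bed"))
  write_peaks_bed(peaks$rep2, file.path(out_dir, "peaks_rep2.bed"))
  rep1 <- peaks_from_bed(file.path(out_dir, "peaks_rep1.bed"), replicate = "1")
  rep2 <- peaks_from_bed(file.path(out_dir, "peaks_rep2.bed"), replicate = "2")
  res <- call_targets(rep1, rep2, promoters, q_cutoff = q_cutoff)
  utils::write.table(res$calls, file.path(out_dir, "target_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(res$targets, file.path(out_dir, "targets.txt"))
  ov <- intersect_targets_with_set(res$targets, peaks$truth)
  summary <- list(
    seed = config$seed, n_planted = length(peaks$truth),
    n_called = length(res$targets), n_recovered = ov$n_overlap,
    recovery = ov$n_overlap / max(1L, length(peaks$truth))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(out_dir, "chip", config,
                  list(n_targets = n_targets, q_cutoff = q_cutoff))
  invisible(c(res, list(truth = peaks$truth, summary = summary)))
}

#' Granule volumetry pipeline on synthetic stacks
#'
#' Simulates wild-type and mutant nuclear stacks (and a rachis stack) of
#' blurred, noisy spheres, derives the consensus Li threshold from the
#' wild-type nuclei projections, segments every stack in 3D, and writes
#' per-granule volumes plus group summaries with fold changes.
#'
#' @param out_dir output directory.
#' @param seed RNG seed.
#' @param n_nuclei stacks per nuclear group (default 15, the study's
#'   reference-nucleus count).
#' @param mean_radius_wt,mean_radius_mut mean sphere radius in um for
#'   wild-type and mutant nuclear granules.
#' @return Invisibly, a list with granule records, the volume summary and
#'   the consensus threshold.
#' @export
run_volumes <- function(out_dir, seed = 1L, n_nuclei = 15L,
                        mean_radius_wt = 0.48, mean_radius_mut = 0.35) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(.derive_seed(seed, "volumes"))
  make_group <- function(n_stacks, mean_r, tag) {
    lapply(seq_len(n_stacks), function(i) {
      n_sph <- sample(2:4, 1L)
      spheres <- data.frame(
        z = runif(n_sph, 2, 6), y = runif(n_sph, 1.5, 4.9),
        x = runif(n_sph, 1.5, 4.9),
        r = pmax(0.2, rnorm(n_sph, mean_r, 0.08)),
        amplitude = 120
      )
      sim <- simulate_granule_stack(
        spheres, dim_vox = c(40L, 64L, 64L), voxel_size = c(0.2, 0.1, 0.1),
        blur_sigma_um = 0.05, poisson_noise = TRUE, background = 4,
        seed = seed + i, id = sprintf("%s_%02d", tag, i))
      sim
    })
  }
  groups_sim <- list(
    wt_nucleus = make_group(n_nuclei, mean_radius_wt, "wt"),
    mut_nucleus = make_group(n_nuclei, mean_radius_mut, "mut"),
    mut_rachis = make_group(4L, mean_radius_wt * 1.3, "rachis")
  )
  wt_stacks <- lapply(groups_sim$wt_nucleus, function(s)
    subtract_background(s$stack, 4))
  thr <- consensus_threshold(wt_stacks)
  records <- lapply(groups_sim, function(group) {
    do.call(rbind, lapply(group, function(s) {
      segment_granules(subtract_background(s$stack, 4), thr)
    }))
  })
  summ <- summarize_volumes(records)
  for (g in names(records)) {
    utils::write.table(records[[g]],
                       file.path(out_dir, paste0("granules_", g, ".csv")),
                       sep = ",", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(summ$summary, file.path(out_dir, "volume_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summ$folds, file.path(out_dir, "volume_folds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(seed = seed, consensus_threshold = as.numeric(thr),
                  groups = summ$summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(records = records, summary = summ, threshold = thr))
}

.write_manifest <- function(out_dir, subcommand, config, extra = list()) {
  manifest <- c(
    list(tool = "granulite",
         version = as.character(utils::packageVersion("granulite")),
         subcommand = subcommand,
         config = unclass(config)),
    extra
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
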