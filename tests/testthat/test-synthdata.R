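test_that("generators are byte-identical under a fixed seed", {
  cfg <- small_cfg()
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g1$genome, f1)
  write_genome_fasta(g2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  a1 <- withr::local_tempfile(fileext = ".gff3")
  a2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff(g1$annots, a1)
  write_gff(g2$annots, a2)
  skip_lines <- function(p) grep("^##(date|source)", readLines(p),
                                 invert = TRUE, value = TRUE)
  expect_identical(skip_lines(a1), skip_lines(a2))

  s1 <- simulate_small_rna_reads(g1$genome, g1$annots, cfg, "wildtype")
  s2 <- simulate_small_rna_reads(g2$genome, g2$annots, cfg, "wildtype")
  q1 <- withr::local_tempfile(fileext = ".fq")
  q2 <- withr::local_tempfile(fileext = ".fq")
  write_reads_fastq(s1$reads, q1, 1L)
  write_reads_fastq(s2$reads, q2, 1L)
  expect_identical(readLines(q1), readLines(q2))
})

test_that("the genome carries the deliberate constructs", {
  w <- small_world()
  f <- w$annots$features
  # at least one operon with >= 2 members
  expect_gte(length(unique(w$annots$operons$operon_id)), 1L)
  expect_true(all(table(w$annots$operons$operon_id) >= 2L))
  # an rRNA overlapping a protein-coding gene (non-empty intersection)
  rr <- f[f$biotype == "rRNA", ]
  pc <- f[f$biotype == "protein_coding", ]
  overlaps <- outer(seq_len(nrow(rr)), seq_len(nrow(pc)),
                    Vectorize(function(i, j) {
                      rr$contig[i] == pc$contig[j] &&
                        rr$start[i] < pc$end[j] && rr$end[i] > pc$start[j]
                    }))
  expect_true(any(overlaps))
  # every gene has strand, exons, biotype and a 5' UTR start
  expect_true(all(pc$id %in% w$annots$exons$feature_id))
  expect_false(anyNA(pc$utr5_start))
  # piRNA loci start with T at offsets 0-2 (strand-aware)
  gchr <- as.character(w$genome)
  pir <- f[f$biotype == "piRNA_locus", ]
  for (i in seq_len(nrow(pir))) {
    if (pir$strand[i] == "+") {
      expect_equal(substr(gchr[[pir$contig[i]]], pir$start[i] + 1L,
                          pir$start[i] + 3L), "TTT")
    } else {
      expect_equal(substr(gchr[[pir$contig[i]]], pir$end[i] - 2L,
                          pir$end[i]), "AAA")
    }
  }
})

test_that("an oversized feature request fails with a sizing error", {
  cfg <- small_cfg()
  cfg$n_genes <- 5000L
  expect_error(make_genome(cfg), "contigs too short")
})

test_that("a pure piRNA mix yields only 21 nt 5' T reads", {
  cfg <- small_cfg(reads_per_sample = 2000L,
                   class_mix = c(piRNA = 1, g22 = 0, g26 = 0,
                                 structural = 0, background = 0))
  gen <- make_genome(cfg)
  sim <- simulate_small_rna_reads(gen$genome, gen$annots, cfg, "wildtype")
  expect_true(all(nchar(sim$reads$sequence) == 21L))
  expect_true(all(substr(sim$reads$sequence, 1L, 1L) == "T"))
  expect_true(all(sim$reads$methylated))
})

test_that("depletion divides mutant 22G abundance by the configured fold", {
  w <- small_world()
  mut <- simulate_small_rna_reads(w$genome, w$annots, w$cfg, "mutant")
  wt <- simulate_small_rna_reads(w$genome, w$annots, w$cfg, "wildtype")
  m <- mut$truth$gene_multiplier
  expect_true(all(m$multiplier[m$gene %in% mut$truth$depleted_set] == 0.25))
  expect_true(all(m$multiplier[!(m$gene %in% mut$truth$depleted_set)] == 1))
  expect_true(all(wt$truth$gene_multiplier$multiplier == 1))
  # empirical: aggregated counts of depleted genes scale by ~1/4
  count_in <- function(sim, genes) {
    d <- sim$reads[sim$reads$class == "g22" & sim$reads$feature_id %in%
                     genes, ]
    sum(d$count)
  }
  dep <- mut$truth$depleted_set
  ratio <- count_in(mut, dep) / count_in(wt, dep)
  n <- count_in(wt, dep)
  expect_lt(abs(ratio - 0.25), 4 * sqrt(0.25 / n + 0.25^2 / n))
  # the same seed gives identical truth across conditions
  expect_identical(mut$truth$depleted_set, wt$truth$depleted_set)
  expect_identical(mut$truth$templates, wt$truth$templates)
})

test_that("oxidation retains reads by methylation status", {
  reads <- data.frame(
    replicate = 1L,
    template_id = sprintf("t%05d", 1:20000),
    sequence = "ACGT",
    class = rep(c("piRNA", "g22"), each = 10000L),
    feature_id = "x",
    methylated = rep(c(TRUE, FALSE), each = 10000L),
    count = 1L
  )
  # degenerate survival: exactly the methylated reads remain
  only_m <- apply_oxidation(reads, 1, 0, seed = 3L)
  expect_true(all(only_m$methylated))
  expect_equal(sum(only_m$count), 10000L)
  # binomial thinning within 3 SD at 0.95 / 0.05
  ox <- apply_oxidation(reads, 0.95, 0.05, seed = 3L)
  km <- sum(ox$count[ox$methylated])
  ku <- sum(ox$count[!ox$methylated])
  expect_lt(abs(km / 10000 - 0.95), 3 * sqrt(0.95 * 0.05 / 10000))
  expect_lt(abs(ku / 10000 - 0.05), 3 * sqrt(0.95 * 0.05 / 10000))
  # sequences are a subset of the input's
  expect_true(all(ox$sequence %in% reads$sequence))
  expect_true(all(ox$count <= reads$count[match(ox$template_id,
                                                reads$template_id)]))
  # empty in, empty out; bad probabilities refused
  expect_equal(nrow(apply_oxidation(reads[0, ], 0.95, 0.05)), 0L)
  expect_error(apply_oxidation(reads, 1.2, 0), "\\[0, 1\\]")
})

test_that("chip peak simulation plants targets in both replicates", {
  w <- small_world()
  prom <- derive_promoters(w$annots)
  targets <- plantable_chip_targets(w$annots)[1:5]
  sim <- simulate_chip_peaks(w$annots, targets, seed = 2L)
  res <- call_targets(sim$rep1, sim$rep2, prom)
  expect_true(all(targets %in% res$targets))
  # zero decoys and no rep1-only peaks: counts equal the target count
  bare <- simulate_chip_peaks(w$annots, targets, seed = 2L,
                              decoy_fraction = 0, n_rep1_only = 0L)
  expect_equal(nrow(bare$rep1), length(targets))
  expect_equal(nrow(bare$rep2), length(targets))
  # determinism: identical BED bytes
  b1 <- withr::local_tempfile(fileext = ".bed")
  b2 <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(simulate_chip_peaks(w$annots, targets, seed = 2L)$rep1, b1)
  write_peaks_bed(simulate_chip_peaks(w$annots, targets, seed = 2L)$rep1, b2)
  expect_identical(readLines(b1), readLines(b2))
})

test_that("granule stacks record analytic truth volumes", {
  sim <- simulate_granule_stack(data.frame(z = 4, y = 3, x = 3, r = 0.5))
  expect_equal(sim$truth$volume_um3, 4 / 3 * pi * 0.5^3)
  # noise/blur free: occupied voxel volume within a one-voxel surface
  # shell of the analytic volume
  vox <- sum(sim$stack$data > 0)
  vol_vox <- vox * prod(sim$stack$voxel_size)
  r <- 0.5
  shell <- 4 * pi * r^2 * max(sim$stack$voxel_size)
  expect_lt(abs(vol_vox - sim$truth$volume_um3), shell)
  # two spheres, two truth rows
  sim2 <- simulate_granule_stack(
    data.frame(z = c(2, 6), y = c(2, 4), x = c(2, 4), r = c(0.3, 0.5)))
  expect_equal(nrow(sim2$truth), 2L)
  expect_equal(anyDuplicated(sim2$truth$granule_id), 0L)
})

test_that("every simulated read template has exactly one truth class", {
  w <- small_world()
  sim <- simulate_small_rna_reads(w$genome, w$annots, w$cfg, "wildtype")
  tpl <- sim$truth$templates
  expect_equal(anyDuplicated(tpl$template_id), 0L)
  expect_equal(anyDuplicated(tpl$sequence), 0L)
  expect_true(all(sim$reads$template_id %in% tpl$template_id))
  expect_true(all(tpl$class %in% c("piRNA", "g22", "g26", "structural",
                                   "background")))
})
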