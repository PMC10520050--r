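# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

# Desk-scale config: small genome, quick to simulate.
small_cfg <- function(seed = 1L, reads_per_sample = 5000L, ...) {
  sim_config(seed = seed, n_contigs = 2L, contig_length = 60000L,
             n_genes = 40L, n_pirna_loci = 30L, n_structural = 8L,
             n_rrna = 2L, n_transposons = 4L, n_operons = 2L,
             depletion_set_size = 10L,
             reads_per_sample = reads_per_sample, ...)
}

small_world <- function() {
  if (is.null(.fixtures$world)) {
    cfg <- small_cfg()
    gen <- make_genome(cfg)
    .fixtures$world <- list(cfg = cfg, genome = gen$genome,
                            annots = gen$annots,
                            index = build_feature_index(gen$annots))
  }
  .fixtures$world
}

# Hand-built annotation world with fully controlled sequences, for
# classifier unit tests. Layout on one 10 kb contig:
#   pirP [100,130)  + piRNA locus (TTT at 100..102)
#   pirM [300,330)  - piRNA locus (AAA at 327..329)
#   G1   [1000,1600) + protein_coding, exon = full span
#   R1   [1300,1500) + rRNA (overlaps G1's exon)
#   G2   [2000,2600) - protein_coding, exon = full span
#   S1   [3000,3080) + tRNA
#   G3   [5000,5400) + / G4 [5200,5600) + overlapping protein_coding genes
# plus a 22-mer planted at 5250 (inside the G3/G4 overlap, antisense
# read) and again at 7000, 7500, 8000 (intergenic) for the multi-mapping
# weight-split example.
hand_world <- function() {
  if (!is.null(.fixtures$hand)) return(.fixtures$hand)
  set.seed(424242)
  chars <- sample(c("A", "C", "G", "T"), 10000L, replace = TRUE)
  chars[101:103] <- "T"                       # pirP offsets 0-2
  chars[328:330] <- "A"                       # pirM offsets 0-2 (minus)
  motif <- "ATGGACCTAGGACCTTAGGAAC"           # 22 nt; revcomp starts with G
  plant <- function(chars, pos0, seq) {
    s <- strsplit(seq, "", fixed = TRUE)[[1L]]
    chars[(pos0 + 1L):(pos0 + length(s))] <- s
    chars
  }
  chars <- plant(chars, 5250L, motif)
  chars <- plant(chars, 7000L, motif)
  chars <- plant(chars, 7500L, motif)
  chars <- plant(chars, 8000L, motif)
  genome <- Biostrings::DNAStringSet(paste0(chars, collapse = ""))
  names(genome) <- "c1"

  features <- data.frame(
    id = c("pirP", "pirM", "G1", "R1", "G2", "S1", "G3", "G4"),
    contig = "c1",
    start = c(100L, 300L, 1000L, 1300L, 2000L, 3000L, 5000L, 5200L),
    end = c(130L, 330L, 1600L, 1500L, 2600L, 3080L, 5400L, 5600L),
    strand = c("+", "-", "+", "+", "-", "+", "+", "+"),
    biotype = c("piRNA_locus", "piRNA_locus", "protein_coding", "rRNA",
                "protein_coding", "tRNA", "protein_coding",
                "protein_coding"),
    utr5_start = c(NA, NA, 1000L, NA, 2600L, NA, 5000L, 5200L)
  )
  exons <- data.frame(
    feature_id = c("G1", "G2", "G3", "G4"),
    start = c(1000L, 2000L, 5000L, 5200L),
    end = c(1600L, 2600L, 5400L, 5600L)
  )
  annots <- annotation_set(features, exons, NULL,
                           data.frame(contig = "c1", length = 10000L))
  .fixtures$hand <- list(
    genome = genome, annots = annots, index = build_feature_index(annots),
    motif = motif,
    seq_at = function(start0, len) {
      paste0(chars[(start0 + 1L):(start0 + len)], collapse = "")
    },
    revcomp_at = function(start0, len) {
      s <- chars[(start0 + 1L):(start0 + len)]
      paste0(rev(chartr("ACGT", "TGCA", s)), collapse = "")
    }
  )
  .fixtures$hand
}

# Naive both-strand exact aligner: the oracle for align_reads.
naive_align <- function(sequences, genome) {
  genome_chr <- as.character(genome)
  rc <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }
  occurrences <- function(pat, subject) {
    hits <- integer()
    from <- 1L
    repeat {
      i <- regexpr(pat, substr(subject, from, nchar(subject)),
                   fixed = TRUE)
      if (i < 0L) break
      hits <- c(hits, from + i - 1L)
      from <- from + i            # allow overlapping occurrences
    }
    hits
  }
  out <- list()
  for (k in seq_along(sequences)) {
    s <- sequences[k]
    for (ctg in names(genome_chr)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") s else rc(s)
        pos <- occurrences(pat, genome_chr[[ctg]])
        if (length(pos)) {
          out[[length(out) + 1L]] <- data.frame(
            seq_index = k, contig = ctg, start = pos - 1L, strand = strand
          )
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(seq_index = integer(), contig = character(),
               start = integer(), strand = character())
}

# Brute-force two-sided Fisher p: sum of hypergeometric probabilities of
# all tables as or less probable than the observed one.
fisher_p_bruteforce <- function(a, n_de, n_set, n_uni) {
  k_range <- max(0L, n_de + n_set - n_uni):min(n_de, n_set)
  d <- dhyper(k_range, n_set, n_uni - n_set, n_de)
  sum(d[d <= d[k_range == a] * (1 + 1e-7)])
}

# Run the small RNA analysis chain for one replicate's reads; returns all
# intermediates.
analyze_sample <- function(reads_df, genome, index) {
  collapsed <- collapse_reads(rep(reads_df$sequence, reads_df$count))
  aln <- align_reads(collapsed, genome)
  parts <- filter_structural(aln, index)
  cls <- classify_all(collapsed, parts$retained, index)
  depth <- attr(parts$retained, "depth")
  list(collapsed = collapsed, alignments = aln, parts = parts,
       classified = cls, depth = depth,
       table = quantify_genes(cls, depth))
}

# Truth-vs-called confusion for one analyzed sample, weighted by read
# count. Truth classes structural/background map to the structural
# partition / unassigned.
class_confusion <- function(analyzed, truth_templates) {
  collapsed <- analyzed$collapsed
  truth_by_seq <- setNames(truth_templates$class, truth_templates$sequence)
  truth <- unname(truth_by_seq[collapsed$sequence])
  truth[truth == "g22"] <- "22G"
  truth[truth == "g26"] <- "26G"
  called <- analyzed$classified$assignments$class[
    match(collapsed$id, analyzed$classified$assignments$read_id)]
  struct_ids <- unique(analyzed$parts$structural$read_id)
  called[collapsed$id %in% struct_ids] <- "structural"
  called[truth == "background" & called == "unassigned"] <- "background"
  data.frame(truth = truth, called = called, count = collapsed$count)
}

per_class_precision_recall <- function(confusion) {
  classes <- unique(confusion$truth)
  do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(confusion$count[confusion$truth == cl & confusion$called == cl])
    fn <- sum(confusion$count[confusion$truth == cl & confusion$called != cl])
    fp <- sum(confusion$count[confusion$truth != cl & confusion$called == cl])
    data.frame(class = cl,
               precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
               recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
  }))
}
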