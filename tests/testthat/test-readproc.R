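test_that("collapsing counts identical sequences", {
  r <- collapse_reads(rep("ACGTACGTACGTACGTACGTA", 5L))
  expect_equal(nrow(r), 1L)
  expect_equal(r$count, 5L)

  seqs <- c("AAAAACCCCCGGGGGTTTTTA", "CCCCCGGGGGTTTTTAAAAAC",
            "GGGGGTTTTTAAAAACCCCCG")
  r3 <- collapse_reads(rep(seqs, times = c(1L, 2L, 3L)))
  expect_equal(nrow(r3), 3L)
  expect_setequal(r3$count, c(1L, 2L, 3L))
  expect_equal(sum(r3$count), 6L)

  expect_equal(nrow(collapse_reads(character())), 0L)

  withN <- collapse_reads(c(seqs, "ACGTNACGTNACGTNACGTNA"))
  expect_equal(attr(withN, "n_dropped"), 1L)
  expect_equal(sum(withN$count), 3L)

  expect_error(collapse_reads("ACGTXACGT"), "ACGTN")
})

test_that("collapsing reads a FASTQ file", {
  w <- small_world()
  sim <- simulate_small_rna_reads(w$genome, w$annots, w$cfg, "wildtype")
  path <- withr::local_tempfile(fileext = ".fq")
  write_reads_fastq(sim$reads, path, replicate = 1L)
  r <- collapse_reads(path)
  d <- sim$reads[sim$reads$replicate == 1L, ]
  expect_equal(sum(r$count), sum(d$count))
  expect_setequal(r$sequence, unique(d$sequence))
})

test_that("exact aligner matches the naive both-strand scan", {
  set.seed(21)
  genome <- Biostrings::DNAStringSet(c(
    cA = paste0(sample(c("A", "C", "G", "T"), 20000L, TRUE), collapse = ""),
    cB = paste0(sample(c("A", "C", "G", "T"), 15000L, TRUE), collapse = "")
  ))
  gchr <- as.character(genome)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  # sampled substrings (both orientations), plus absent reads
  seqs <- character()
  for (i in 1:20) {
    L <- sample(15:30, 1L)
    ctg <- sample(names(gchr), 1L)
    p <- sample.int(nchar(gchr[[ctg]]) - L, 1L)
    s <- substr(gchr[[ctg]], p, p + L - 1L)
    seqs <- c(seqs, if (i %% 2L) s else rc(s))
  }
  seqs <- c(seqs, replicate(5, paste0(sample(c("A", "C", "G", "T"), 25L,
                                             TRUE), collapse = "")))
  seqs <- unique(seqs)
  collapsed <- data.frame(id = sprintf("q%02d", seq_along(seqs)),
                          sequence = seqs, count = 1L)
  aln <- align_reads(collapsed, genome)
  oracle <- naive_align(seqs, genome)
  oracle$read_id <- collapsed$id[oracle$seq_index]
  key <- function(d) sort(paste(d$read_id, d$contig, d$start, d$strand))
  expect_identical(key(aln), key(oracle))
  # n_hits equals the oracle's per-read totals and is constant per read
  ocount <- table(oracle$read_id)
  expect_true(all(aln$n_hits == as.integer(ocount[aln$read_id])))
  # unaligned accounting
  expect_setequal(attr(aln, "unaligned"),
                  setdiff(collapsed$id, oracle$read_id))
})

test_that("one mismatch anywhere means zero alignments", {
  set.seed(31)
  genome <- Biostrings::DNAStringSet(c(
    c1 = paste0(sample(c("A", "C", "G", "T"), 5000L, TRUE), collapse = "")))
  s <- substr(as.character(genome[[1L]]), 100L, 120L)
  mm <- s
  substr(mm, 10L, 10L) <- setdiff(c("A", "C", "G", "T"),
                                  substr(s, 10L, 10L))[1L]
  stopifnot(length(naive_align(mm, genome)$start) == 0L)  # oracle agrees
  aln <- align_reads(data.frame(id = "m1", sequence = mm, count = 1L),
                     genome)
  expect_equal(nrow(aln), 0L)
  expect_equal(attr(aln, "unaligned"), "m1")
})

test_that("reads exceeding max_hits are dropped entirely and tallied", {
  set.seed(41)
  motif <- paste0(sample(c("A", "C", "G", "T"), 21L, TRUE), collapse = "")
  bg <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  genome <- Biostrings::DNAStringSet(c(c1 = paste0(
    bg(500), motif, bg(500), motif, bg(500), motif, bg(500), motif,
    bg(500), motif, bg(500), motif, bg(500))))
  collapsed <- data.frame(id = "multi", sequence = motif, count = 3L)
  full <- align_reads(collapsed, genome, max_hits = 1000L)
  expect_equal(nrow(full), 6L)
  expect_true(all(full$n_hits == 6L))
  capped <- align_reads(collapsed, genome, max_hits = 5L)
  expect_equal(nrow(capped), 0L)
  expect_equal(attr(capped, "dropped_multi"), "multi")
  expect_equal(attr(capped, "depth"), 0L)
})

test_that("aligning reverse complements swaps strands and nothing else", {
  w <- small_world()
  set.seed(51)
  gchr <- as.character(w$genome)
  seqs <- vapply(1:15, function(i) {
    ctg <- sample(names(gchr), 1L)
    L <- sample(18:26, 1L)
    p <- sample.int(nchar(gchr[[ctg]]) - L, 1L)
    substr(gchr[[ctg]], p, p + L - 1L)
  }, "")
  seqs <- unique(seqs)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  fwd <- align_reads(data.frame(id = seqs, sequence = seqs, count = 1L),
                     w$genome)
  rev <- align_reads(data.frame(id = seqs,
                                sequence = vapply(seqs, rc, ""),
                                count = 1L), w$genome)
  flip <- function(d) {
    d$strand <- ifelse(d$strand == "+", "-", "+")
    d[order(d$read_id, d$contig, d$start, d$strand), ]
  }
  expect_equal(flip(fwd)[, c("read_id", "contig", "start", "strand")],
               rev[order(rev$read_id, rev$contig, rev$start, rev$strand),
                   c("read_id", "contig", "start", "strand")],
               ignore_attr = TRUE)
})

test_that("structural filtering moves whole reads and conserves accounting", {
  h <- hand_world()
  reads <- data.frame(
    id = c("in_trna", "split", "clean"),
    sequence = c(h$seq_at(3005L, 21L),          # inside S1 (tRNA)
                 h$seq_at(3005L, 21L),          # placeholder, replaced below
                 h$seq_at(1020L, 21L)),         # inside G1 exon only
    count = c(2L, 1L, 1L)
  )
  # a read with one tRNA hit and one mRNA hit: plant the same sequence in
  # both S1 and G1 via a fabricated genome
  set.seed(61)
  chars <- strsplit(as.character(h$genome[[1L]]), "")[[1L]]
  motif <- strsplit("ACCGTTAGGCAACCGGTTAAG", "")[[1L]]
  chars[3031:3051] <- motif      # inside S1 [3000,3080)
  chars[1101:1121] <- motif      # inside G1 exon [1000,1600)
  genome2 <- Biostrings::DNAStringSet(paste0(chars, collapse = ""))
  names(genome2) <- "c1"
  reads$sequence[2L] <- paste0(motif, collapse = "")
  collapsed <- collapse_reads(rep(reads$sequence, reads$count))
  aln <- align_reads(collapsed, genome2)
  parts <- filter_structural(aln, h$index)
  seq_of <- function(ids) collapsed$sequence[match(ids, collapsed$id)]
  expect_true(reads$sequence[1L] %in% seq_of(parts$structural$read_id))
  # the split read is entirely structural
  expect_true(reads$sequence[2L] %in% seq_of(parts$structural$read_id))
  expect_false(reads$sequence[2L] %in% seq_of(parts$retained$read_id))
  expect_true(reads$sequence[3L] %in% seq_of(parts$retained$read_id))
  # read-level conservation
  n_struct <- length(unique(parts$structural$read_id))
  n_ret <- length(unique(parts$retained$read_id))
  n_drop <- length(attr(aln, "dropped_multi"))
  n_unaln <- length(attr(aln, "unaligned"))
  expect_equal(n_struct + n_ret + n_drop + n_unaln, nrow(collapsed))
})
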