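# Classifier rule tests on the hand-built world (see helper-fixtures.R).

aln_row <- function(id, start, strand, n_hits, len, count = 1L,
                    contig = "c1") {
  data.frame(read_id = id, contig = contig, start = start, strand = strand,
             n_hits = n_hits, length = len, count = count)
}

test_that("piRNA calling enforces uniqueness, offset, 5' base and length", {
  h <- hand_world()
  # sense read at offset 0/1/2 of the plus-strand locus (starts with T)
  for (off in 0:2) {
    read <- data.frame(id = "p1", sequence = h$seq_at(100L + off, 21L),
                       count = 1L)
    res <- call_pirna(read, aln_row("p1", 100L + off, "+", 1L, 21L),
                      h$index)
    expect_true(res$assigned)
    expect_equal(res$weights$feature_id, "pirP")
    expect_equal(sum(res$weights$weight), 1)
  }
  # offset 3 is outside the window
  read <- data.frame(id = "p2", sequence = h$seq_at(103L, 21L), count = 1L)
  expect_false(call_pirna(read, aln_row("p2", 103L, "+", 1L, 21L),
                          h$index)$assigned)
  # multi-mapping refused even at a perfect offset
  read <- data.frame(id = "p3", sequence = h$seq_at(100L, 21L), count = 1L)
  expect_false(call_pirna(read, aln_row("p3", 100L, "+", 2L, 21L),
                          h$index)$assigned)
  # antisense refused
  expect_false(call_pirna(read, aln_row("p3", 100L, "-", 1L, 21L),
                          h$index)$assigned)
  # too short (14 nt), even with 5' T at offset 0
  read <- data.frame(id = "p4", sequence = h$seq_at(100L, 14L), count = 1L)
  expect_false(call_pirna(read, aln_row("p4", 100L, "+", 1L, 14L),
                          h$index)$assigned)
  # minus-strand locus: 5' end at the feature end side
  for (off in 0:2) {
    read <- data.frame(id = "p5",
                       sequence = h$revcomp_at(330L - 21L - off, 21L),
                       count = 1L)
    res <- call_pirna(read, aln_row("p5", 330L - 21L - off, "-", 1L, 21L),
                      h$index)
    expect_true(res$assigned)
    expect_equal(res$weights$feature_id, "pirM")
  }
})

find_antisense <- function(h, from, to, L, bases = c("G", "A")) {
  for (p in from:to) {
    s <- h$revcomp_at(p, L)
    if (substr(s, 1L, 1L) %in% bases) return(list(p = p, s = s))
  }
  stop("no site found")
}

test_that("22G calling splits weight by location and feature with rRNA precedence", {
  h <- hand_world()
  # 22 nt, 5' G/A, unique, antisense to G1's exon only (clear of R1)
  site <- find_antisense(h, 1000L, 1270L, 22L)
  read <- data.frame(id = "g1", sequence = site$s, count = 3L)
  res <- call_22g(read, aln_row("g1", site$p, "-", 1L, 22L, count = 3L),
                  h$index)
  expect_true(res$assigned)
  expect_equal(res$weights$feature_id, "G1")
  expect_equal(sum(res$weights$weight), 3)
  # location overlapping rRNA and mRNA antisense: rRNA takes it all
  site2 <- find_antisense(h, 1320L, 1470L, 22L)
  read <- data.frame(id = "g2", sequence = site2$s, count = 2L)
  res <- call_22g(read, aln_row("g2", site2$p, "-", 1L, 22L, count = 2L),
                  h$index)
  expect_true(res$assigned)
  expect_equal(res$weights$feature_id, "R1")
  expect_equal(res$weights$biotype, "rRNA")
  expect_equal(sum(res$weights$weight), 2)
  # 24 nt is outside 21-23
  site3 <- find_antisense(h, 1000L, 1270L, 24L)
  read <- data.frame(id = "g3", sequence = site3$s, count = 1L)
  expect_false(call_22g(read, aln_row("g3", site3$p, "-", 1L, 24L),
                        h$index)$assigned)
})

test_that("multi-mapping 22G weight is count / n_hits / n_features", {
  h <- hand_world()
  # motif planted at 4 genomic locations; one lies in the G3/G4 exon
  # overlap (antisense), the other three are intergenic
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(h$motif, "")[[1L]]), collapse = ""))
  collapsed <- data.frame(id = "m1", sequence = rc, count = 1L)
  aln <- align_reads(collapsed, h$genome)
  expect_equal(unique(aln$n_hits), 4L)
  res <- classify_all(collapsed, aln, h$index)
  expect_equal(res$assignments$class, "22G")
  w <- res$weights
  # the feature-bearing location splits 1/4 across two genes
  expect_setequal(w$feature_id[!is.na(w$feature_id)], c("G3", "G4"))
  expect_equal(sort(w$weight[!is.na(w$feature_id)]), c(0.125, 0.125))
  # featureless locations keep their count/n_hits share
  expect_equal(sum(w$weight[is.na(w$feature_id)]), 0.75)
  expect_equal(sum(w$weight), 1)
})

test_that("26G calling uses its default rule and honors overrides", {
  h <- hand_world()
  # find a 26-mer antisense to G2 (minus-strand gene, read on plus) with
  # 5' G, scanning the exon
  found <- NULL
  for (p in 2000:2570) {
    s <- h$seq_at(p, 26L)
    if (substr(s, 1L, 1L) == "G") { found <- list(p = p, s = s); break }
  }
  stopifnot(!is.null(found))
  read <- data.frame(id = "s1", sequence = found$s, count = 1L)
  res <- call_26g(read, aln_row("s1", found$p, "+", 1L, 26L), h$index)
  expect_true(res$assigned)
  expect_equal(res$weights$feature_id, "G2")
  # 5' A refused under the default rule...
  found_a <- NULL
  for (p in 2000:2570) {
    s <- h$seq_at(p, 26L)
    if (substr(s, 1L, 1L) == "A") { found_a <- list(p = p, s = s); break }
  }
  read_a <- data.frame(id = "s2", sequence = found_a$s, count = 1L)
  expect_false(call_26g(read_a, aln_row("s2", found_a$p, "+", 1L, 26L),
                        h$index)$assigned)
  # ...but assigned when the rule is overridden to allow 5' A
  rule_a <- class_rule("26G", c(25L, 27L), c("G", "A"), "antisense",
                       targets = "pc_exons")
  expect_true(call_26g(read_a, aln_row("s2", found_a$p, "+", 1L, 26L),
                       h$index, rule = rule_a)$assigned)
})

test_that("class precedence assigns the first matching rule", {
  h <- hand_world()
  # a 22 nt 5' G read antisense to G1 could only be 22G (piRNA needs 5' T)
  read <- NULL
  for (p in 1000:1500) {
    s <- h$revcomp_at(p, 22L)
    if (substr(s, 1L, 1L) == "G") { read <- list(p = p, s = s); break }
  }
  collapsed <- data.frame(id = "x1", sequence = read$s, count = 1L)
  res <- classify_all(collapsed, aln_row("x1", read$p, "-", 1L, 22L),
                      h$index)
  expect_equal(res$assignments$class, "22G")
  # empty input
  empty <- classify_all(collapsed[0, ],
                        aln_row("x1", read$p, "-", 1L, 22L)[0, ], h$index)
  expect_equal(nrow(empty$assignments), 0L)
  expect_equal(nrow(empty$weights), 0L)
})

test_that("classifier is pure and conserves weights on simulated reads", {
  w <- small_world()
  sim <- simulate_small_rna_reads(w$genome, w$annots, w$cfg, "wildtype")
  d <- sim$reads[sim$reads$replicate == 1L, ]
  a <- analyze_sample(d, w$genome, w$index)
  # purity: identical inputs, identical outputs
  again <- classify_all(a$collapsed, a$parts$retained, w$index)
  expect_identical(a$classified, again)
  # weight conservation per assigned read, 1e-9 relative
  sums <- tapply(a$classified$weights$weight,
                 a$classified$weights$read_id, sum)
  counts <- a$collapsed$count[match(names(sums), a$collapsed$id)]
  expect_true(all(abs(sums - counts) / counts < 1e-9))
  # truth recovery on unambiguous reads
  conf <- class_confusion(a, sim$truth$templates)
  pr <- per_class_precision_recall(conf)
  expect_true(all(pr$precision == 1))
  expect_true(all(pr$recall == 1))
})

test_that("adding an rRNA overlap never decreases the rRNA gene's count", {
  h <- hand_world()
  # read antisense over the R1/G1 overlap
  site <- find_antisense(h, 1320L, 1470L, 22L)
  read <- data.frame(id = "r1", sequence = site$s, count = 4L)
  aln <- aln_row("r1", site$p, "-", 1L, 22L, count = 4L)
  with_pref <- call_22g(read, aln, h$index)
  rrna_with <- sum(with_pref$weights$weight[
    with_pref$weights$feature_id == "R1"])
  # same call under an index lacking the overlapping gene: rRNA alone
  f2 <- h$annots$features[h$annots$features$id != "G1", ]
  e2 <- h$annots$exons[h$annots$exons$feature_id != "G1", ]
  idx2 <- build_feature_index(
    annotation_set(f2, e2, NULL, h$annots$contigs))
  alone <- call_22g(read, aln, idx2)
  rrna_alone <- sum(alone$weights$weight[alone$weights$feature_id == "R1"])
  expect_gte(rrna_with, rrna_alone)
})

test_that("gene tables scale raw weights to RPM and conserve totals", {
  fake <- list(weights = data.frame(
    read_id = c("a", "a", "b"), class = "22G", contig = "c1",
    start = c(0L, 10L, 20L), strand = "-",
    feature_id = c("g1", "g1", "g2"), biotype = "protein_coding",
    weight = c(3, 1, 2)))
  tab <- quantify_genes(fake, depth = 2000)
  expect_equal(tab$raw[tab$feature_id == "g1"], 4)
  expect_equal(tab$rpm[tab$feature_id == "g1"], 2000)  # 4 / 2000 * 1e6
  expect_equal(sum(tab$rpm), 1e6 * sum(tab$raw) / 2000)
  # moving weight between genes leaves the total unchanged
  fake2 <- fake
  fake2$weights$feature_id <- c("g1", "g2", "g2")
  tab2 <- quantify_genes(fake2, depth = 2000)
  expect_equal(sum(tab2$raw), sum(tab$raw))
})

test_that("length/first-nt profile reproduces totals and marginals", {
  d <- data.frame(sequence = c("TTTTTTTTTTTTTTTTTTTTT",   # 21 nt T
                               "GGGGGGGGGGGGGGGGGGGGGG",  # 22 nt G
                               "AAAAAAAAAAAAAAAAAAAAAA"), # 22 nt A
                  count = c(5L, 3L, 2L))
  m <- length_firstnt_profile(d)
  expect_equal(m["21", "T"], 5L)
  expect_equal(m["22", "G"], 3L)
  expect_equal(m["22", "A"], 2L)
  expect_equal(sum(m), 10L)
  pure <- length_firstnt_profile(d[1L, ])
  expect_equal(sum(pure), 5L)
  expect_equal(sum(pure != 0L), 1L)
})
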