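# Template pools: small sets of verified read sequences per class, from
# which replicate libraries are sampled. Building templates once and
# verifying them by exact alignment guarantees unambiguous truth labels.

.revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

# sample() a single element without the scalar-x pitfall
.sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

.substr_genome <- function(genome_chr, contig, start0, len) {
  substr(genome_chr[[contig]], start0 + 1L, start0 + len)
}

# Candidate piRNA templates: one per (locus, offset 0:2), 21 nt, sense.
.pirna_templates <- function(genome_chr, annots) {
  loci <- annots$features[annots$features$biotype == "piRNA_locus", ]
  if (nrow(loci) == 0L) return(NULL)
  off <- rep(0:2, nrow(loci))
  li <- rep(seq_len(nrow(loci)), each = 3L)
  plus <- loci$strand[li] == "+"
  s0 <- ifelse(plus, loci$start[li] + off, loci$end[li] - 21L - off)
  seqs <- vapply(seq_along(s0), function(k) {
    .substr_genome(genome_chr, loci$contig[li[k]], s0[k], 21L)
  }, "")
  seqs[!plus] <- .revcomp(seqs[!plus])
  data.frame(class = "piRNA", feature_id = loci$id[li], offset = off,
             sequence = seqs)
}

# Candidate antisense templates within exons of the given genes, with the
# required 5' base; read strand is opposite to the gene strand.
.antisense_templates <- function(genome_chr, annots, gene_ids, lengths,
                                 first_bases, sites_per_gene, class) {
  ex <- annots$exons
  f <- annots$features
  out <- list()
  ok_plus_base <- first_bases                      # gene "-": read on "+"
  ok_minus_base <- unname(.complement_base[first_bases]) # gene "+": read "-"
  acc_gene <- character(); acc_seq <- character()
  gene_pos <- match(gene_ids, f$id)
  ex_by_gene <- split(seq_len(nrow(ex)), ex$feature_id)
  for (gi in seq_along(gene_ids)) {
    g <- gene_ids[gi]
    strand <- f$strand[gene_pos[gi]]
    contig <- f$contig[gene_pos[gi]]
    rows <- ex_by_gene[[g]]
    if (is.null(rows)) next
    es <- ex$start[rows]; ee <- ex$end[rows]
    found <- 0L; tries <- 0L
    while (found < sites_per_gene && tries < 60L) {
      tries <- tries + 1L
      j <- .sample1(seq_along(rows))
      L <- if (length(lengths) == 1L) lengths else sample(lengths, 1L)
      if (ee[j] - es[j] < L) next
      p <- .sample1(seq(es[j], ee[j] - L))
      if (strand == "+") {
        # read on minus strand; its 5' base complements genome[p + L - 1]
        b <- substr(genome_chr[[contig]], p + L, p + L)
        if (!(b %in% ok_minus_base)) next
        seq <- .revcomp(.substr_genome(genome_chr, contig, p, L))
      } else {
        b <- substr(genome_chr[[contig]], p + 1L, p + 1L)
        if (!(b %in% ok_plus_base)) next
        seq <- .substr_genome(genome_chr, contig, p, L)
      }
      found <- found + 1L
      acc_gene <- c(acc_gene, g); acc_seq <- c(acc_seq, seq)
    }
  }
  if (length(acc_seq) == 0L) return(NULL)
  data.frame(class = class, feature_id = acc_gene, offset = NA_integer_,
             sequence = acc_seq)
}

# Sense templates inside structural RNA features.
.structural_templates <- function(genome_chr, annots, sites_per_feature = 2L) {
  f <- annots$features[annots$features$biotype %in% STRUCTURAL_BIOTYPES, ]
  if (nrow(f) == 0L) return(NULL)
  acc_id <- character(); acc_seq <- character()
  for (i in seq_len(nrow(f))) {
    s <- f[i, ]
    L <- min(22L, s$end - s$start)
    for (k in seq_len(sites_per_feature)) {
      p <- .sample1(seq(s$start, s$end - L))
      seq <- .substr_genome(genome_chr, s$contig, p, L)
      if (s$strand == "-") seq <- .revcomp(seq)
      acc_id <- c(acc_id, s$id); acc_seq <- c(acc_seq, seq)
    }
  }
  data.frame(class = "structural", feature_id = acc_id,
             offset = NA_integer_, sequence = acc_seq)
}

# Intergenic templates (no feature overlap at the drawn site; verified
# globally afterwards).
.background_templates <- function(genome_chr, annots, n_templates) {
  f <- annots$features
  contigs <- annots$contigs
  f_by_ctg <- split(f[, c("start", "end")], f$contig)
  acc_seq <- character(); tries <- 0L
  while (length(acc_seq) < n_templates && tries < n_templates * 50L) {
    tries <- tries + 1L
    ci <- sample.int(nrow(contigs), 1L)
    L <- sample(18:24, 1L)
    p <- sample.int(contigs$length[ci] - L, 1L) - 1L
    ctg <- contigs$contig[ci]
    fc <- f_by_ctg[[ctg]]
    margin <- 5L
    if (!is.null(fc) &&
        any(fc$start < p + L + margin & fc$end > p - margin)) next
    acc_seq <- c(acc_seq, .substr_genome(genome_chr, ctg, p, L))
  }
  if (length(acc_seq) == 0L) return(NULL)
  data.frame(class = "background", feature_id = NA_character_,
             offset = NA_integer_, sequence = acc_seq)
}

# Verify templates by exact alignment and keep only those whose truth
# label is unambiguous under the pipeline's own rules.
.verify_templates <- function(templates, genome, index) {
  templates$template_id <- sprintf("t%05d", seq_len(nrow(templates)))
  uniq <- !duplicated(templates$sequence) &
    !(templates$sequence %in% templates$sequence[duplicated(templates$sequence)])
  templates <- templates[uniq, , drop = FALSE]
  coll <- data.frame(id = templates$template_id,
                     sequence = templates$sequence, count = 1L)
  aln <- align_reads(coll, genome, max_hits = 100L)
  nh <- tapply(aln$n_hits, aln$read_id, `[`, 1L)
  templates$n_hits <- as.integer(nh[templates$template_id])
  templates <- templates[!is.na(templates$n_hits), , drop = FALSE]
  aln <- aln[aln$read_id %in% templates$template_id, , drop = FALSE]

  st <- index_query(index, aln$contig, aln$start, aln$start + aln$length,
                    what = "structural", sense = "any")
  touch_struct <- unique(aln$read_id[unique(st$query)])
  wh <- index_query(index, aln$contig, aln$start, aln$start + aln$length,
                    what = "whole", sense = "any")
  touch_any <- unique(aln$read_id[unique(wh$query)])

  keep <- rep(TRUE, nrow(templates))
  cls <- templates$class
  tid <- templates$template_id
  keep[cls == "piRNA" &
         (templates$n_hits != 1L | tid %in% touch_struct)] <- FALSE
  keep[cls %in% c("g22", "g26") &
         (tid %in% touch_struct | templates$n_hits > 20L)] <- FALSE
  keep[cls == "background" & tid %in% touch_any] <- FALSE
  templates[keep, , drop = FALSE]
}

#' Simulate a small RNA read library with ground truth
#'
#' Draws reads per class according to `class_mix`: piRNA-class reads are
#' 21 nt, 5' T, sense, starting at offset 0--2 of a piRNA locus;
#' 22G-class reads are 21--23 nt with a 5' G or A, antisense to
#' protein-coding exons; 26G-class reads are 26 nt with a 5' G, antisense
#' to protein-coding exons; structural reads are sense within structural
#' RNAs; background reads come from intergenic space. Genes in the
#' depletion set have their 22G abundance divided by `depletion_fold` in
#' the `"mutant"` condition. Per-gene log-normal baselines are shared
#' across replicates and conditions; per-replicate counts are Poisson.
#' Every read carries a methylation flag (piRNA-class reads are
#' 2'-O-methylated). Templates are verified by exact alignment so the
#' recorded truth labels are unambiguous.
#'
#' @param genome named [Biostrings::DNAStringSet] from [make_genome()].
#' @param annots matching [annotation_set()].
#' @param config a [sim_config()].
#' @param condition `"wildtype"` or `"mutant"`.
#' @return list with `reads` (data.frame: `replicate`, `template_id`,
#'   `sequence`, `class`, `feature_id`, `methylated`, `count`) and `truth`
#'   (template classes, per-gene condition multipliers, the depleted gene
#'   set).
#' @export
simulate_small_rna_reads <- function(genome, annots, config,
                                     condition = c("wildtype", "mutant")) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  genome_chr <- as.list(as.character(genome))

  # shared structure: same seed regardless of condition
  set.seed(.derive_seed(config$seed, "pools"))
  index <- build_feature_index(annots)
  genes <- annots$features$id[annots$features$biotype == "protein_coding"]
  mix <- config$class_mix
  for (cl in names(mix)) {
    n_src <- switch(cl,
      piRNA = config$n_pirna_loci, g22 = length(genes),
      g26 = length(genes), structural = config$n_structural,
      background = 1L)
    if (mix[[cl]] > 0 && n_src == 0L) {
      .stopf("class_mix requests '%s' reads but no source loci exist", cl)
    }
  }
  templates <- rbind(
    if (mix[["piRNA"]] > 0) .pirna_templates(genome_chr, annots),
    if (mix[["g22"]] > 0) .antisense_templates(
      genome_chr, annots, genes, 21:23, c("G", "A"), 4L, "g22"),
    if (mix[["g26"]] > 0) .antisense_templates(
      genome_chr, annots, genes, 26L, "G", 2L, "g26"),
    if (mix[["structural"]] > 0) .structural_templates(genome_chr, annots),
    if (mix[["background"]] > 0) .background_templates(
      genome_chr, annots, 120L)
  )
  templates <- .verify_templates(templates, genome, index)

  depleted <- sort(sample(genes, config$depletion_set_size))
  base_gene <- setNames(rlnorm(length(genes), 0, config$lognormal_sigma),
                        genes)
  loci <- annots$features$id[annots$features$biotype == "piRNA_locus"]
  base_locus <- setNames(rlnorm(length(loci), 0, config$lognormal_sigma),
                         loci)
  struct_ids <- annots$features$id[
    annots$features$biotype %in% STRUCTURAL_BIOTYPES]
  base_struct <- setNames(rlnorm(length(struct_ids), 0, 0.3), struct_ids)

  mult <- setNames(rep(1, length(genes)), genes)
  if (condition == "mutant") mult[depleted] <- 1 / config$depletion_fold

  offset_probs <- c(`0` = 0.7, `1` = 0.2, `2` = 0.1)

  draw_feature_counts <- function(tpl, base, lambda_total, multipliers = NULL) {
    # expected reads per feature proportional to its baseline (times any
    # condition multiplier), Poisson per replicate, spread uniformly over
    # the feature's verified templates
    if (is.null(tpl) || nrow(tpl) == 0L || lambda_total <= 0) return(NULL)
    feats <- intersect(names(base), unique(tpl$feature_id))
    if (length(feats) == 0L) return(NULL)
    lam <- lambda_total * (base[feats] / sum(base[feats]))
    if (!is.null(multipliers)) lam <- lam * multipliers[feats]
    counts <- rpois(length(lam), lam)
    names(counts) <- feats
    counts
  }

  sample_reads <- function(tpl, counts, offsets = FALSE) {
    if (is.null(counts)) return(NULL)
    feats <- names(counts)[counts > 0L]
    by_feat <- split(seq_len(nrow(tpl)), tpl$feature_id)
    acc_id <- character(); acc_n <- integer()
    for (ft in feats) {
      ri <- by_feat[[ft]]
      if (is.null(ri)) next
      prob <- if (offsets) offset_probs[as.character(tpl$offset[ri])] else
        NULL
      pick <- ri[sample.int(length(ri), counts[[ft]], replace = TRUE,
                            prob = prob)]
      tab <- table(pick)
      acc_id <- c(acc_id, tpl$template_id[as.integer(names(tab))])
      acc_n <- c(acc_n, as.integer(tab))
    }
    if (length(acc_id) == 0L) return(NULL)
    data.frame(template_id = acc_id, count = acc_n)
  }

  reps <- list()
  for (r in seq_len(config$replicates_per_condition)) {
    set.seed(.derive_seed(config$seed, paste0("reads_", condition), r))
    n <- config$reads_per_sample
    per_rep <- list()

    per_rep$piRNA <- sample_reads(
      templates[templates$class == "piRNA", ],
      draw_feature_counts(templates[templates$class == "piRNA", ],
                          base_locus, n * mix[["piRNA"]]),
      offsets = TRUE)
    per_rep$g22 <- sample_reads(
      templates[templates$class == "g22", ],
      draw_feature_counts(templates[templates$class == "g22", ],
                          base_gene, n * mix[["g22"]], mult))
    per_rep$g26 <- sample_reads(
      templates[templates$class == "g26", ],
      draw_feature_counts(templates[templates$class == "g26", ],
                          base_gene, n * mix[["g26"]]))
    per_rep$structural <- sample_reads(
      templates[templates$class == "structural", ],
      draw_feature_counts(templates[templates$class == "structural", ],
                          base_struct, n * mix[["structural"]]))
    bg <- templates[templates$class == "background", ]
    if (nrow(bg) > 0L && mix[["background"]] > 0) {
      cnt <- rpois(nrow(bg), n * mix[["background"]] / nrow(bg))
      per_rep$background <- data.frame(
        template_id = bg$template_id[cnt > 0L], count = cnt[cnt > 0L]
      )
    }
    dd <- do.call(rbind, per_rep)
    if (is.null(dd) || nrow(dd) == 0L) next
    ti <- match(dd$template_id, templates$template_id)
    reps[[r]] <- data.frame(
      replicate = r, template_id = dd$template_id,
      sequence = templates$sequence[ti],
      class = templates$class[ti],
      feature_id = templates$feature_id[ti],
      methylated = templates$class[ti] == "piRNA",
      count = dd$count
    )
  }
  reads <- do.call(rbind, reps)
  rownames(reads) <- NULL
  truth <- list(
    templates = templates[, c("template_id", "class", "feature_id",
                              "offset", "sequence", "n_hits")],
    gene_multiplier = data.frame(gene = genes,
                                 multiplier = unname(mult[genes])),
    depleted_set = depleted,
    condition = condition
  )
  list(reads = reads, truth = truth)
}

#' Apply periodate oxidation to a simulated read set
#'
#' Binomially thins each collapsed read's count: methylated reads survive
#' with probability `methylated_survival`, unmethylated reads with
#' `unmethylated_survival`. Surviving sequences are a subset of the input
#' sequences.
#'
#' @param reads read data.frame from [simulate_small_rna_reads()] (needs
#'   `methylated` and `count` columns).
#' @param methylated_survival,unmethylated_survival probabilities in
#'   `[0, 1]`.
#' @param seed RNG seed for the thinning.
#' @return The thinned read data.frame (rows with zero surviving count are
#'   dropped).
#' @export
apply_oxidation <- function(reads, methylated_survival = 0.95,
                            unmethylated_survival = 0.05, seed = 1L) {
  probs <- c(methylated_survival, unmethylated_survival)
  if (any(probs < 0 | probs > 1)) {
    .stopf("survival probabilities must be in [0, 1]")
  }
  if (nrow(reads) == 0L) return(reads)
  set.seed(.derive_seed(seed, "oxidation"))
  p <- ifelse(reads$methylated, methylated_survival, unmethylated_survival)
  kept <- rbinom(nrow(reads), reads$count, p)
  out <- reads
  out$count <- kept
  out <- out[out$count > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write simulated reads to FASTQ
#'
#' Expands collapsed counts to individual records with constant quality.
#'
#' @param reads read data.frame (needs `sequence`, `count`, `replicate`).
#' @param path output path.
#' @param replicate which replicate to write.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path, replicate = 1L) {
  d <- reads[reads$replicate == replicate, , drop = FALSE]
  seqs <- rep(d$sequence, d$count)
  n <- length(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  if (n > 0L) {
    ids <- sprintf("@sim_%07d", seq_len(n))
    qual <- vapply(nchar(seqs), function(L) strrep("I", L), "")
    writeLines(paste(ids, seqs, "+", qual, sep = "\n"), con)
  }
  invisible(path)
}
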