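#' Simulate replicate ChIP peak sets over promoters
#'
#' For every target gene, both replicate peak sets receive a peak
#' overlapping the gene's promoter (with replicate-specific jitter). Decoy
#' peaks overlapping non-promoter regions are added to both replicates,
#' and a number of promoter peaks present in replicate 1 only exercise the
#' both-replicate rule. Peak q-values for planted/decoy peaks are drawn
#' below/around the conventional 0.1 cutoff.
#'
#' @param annots an [annotation_set()].
#' @param target_genes character vector of planted target gene ids (must
#'   have derivable promoters).
#' @param seed RNG seed.
#' @param decoy_fraction number of decoy peaks as a fraction of targets.
#' @param n_rep1_only number of rep1-only promoter peaks over non-target
#'   genes.
#' @param min_exclusive minimum width (bp) of a target promoter's segment
#'   not shared with any other promoter; targets below this are refused
#'   (see [plantable_chip_targets()]).
#' @return list with `rep1`, `rep2` (peak data.frames: `contig`, `start`,
#'   `end`, `name`, `q`, `replicate`) and `truth` (planted target ids).
#' @export
simulate_chip_peaks <- function(annots, target_genes, seed = 1L,
                                decoy_fraction = 0.3, n_rep1_only = 5L,
                                min_exclusive = 50L) {
  stopifnot(inherits(annots, "annotation_set"))
  set.seed(.derive_seed(seed, "chip"))
  promoters <- derive_promoters(annots)
  miss <- setdiff(target_genes, promoters$gene_id)
  if (length(miss)) {
    .stopf("no promoter derivable for target gene(s): %s",
           paste(head(miss, 3L), collapse = ", "))
  }
  clen <- setNames(annots$contigs$length, annots$contigs$contig)

  # peaks are placed in the part of each promoter not shared with any
  # other promoter, so a planted peak supports exactly its intended gene;
  # targets whose promoter has no such segment (e.g. non-first operon
  # members, whose promoter is identical to the first gene's) cannot be
  # planted unambiguously and are refused
  exclusive <- .exclusive_promoter_regions(promoters)
  widths <- vapply(exclusive, function(r) {
    if (length(r) == 0L) 0L else max(GenomicRanges::width(r))
  }, integer(1L))
  bad <- target_genes[widths[match(target_genes, promoters$gene_id)] <
                        min_exclusive]
  if (length(bad)) {
    .stopf(paste0("target gene(s) without a distinguishable promoter ",
                  "segment (>= %d bp not shared with another promoter): ",
                  "%s; choose targets from plantable_chip_targets()"),
           min_exclusive, paste(head(bad, 3L), collapse = ", "))
  }

  peak_at_promoter <- function(gene, rep_id, k) {
    i <- match(gene, promoters$gene_id)
    region <- exclusive[[i]]
    region <- region[which.max(GenomicRanges::width(region))]
    s0 <- GenomicRanges::start(region) - 1L
    e0 <- GenomicRanges::end(region)
    w <- min(sample(150:400, 1L), e0 - s0)
    s <- .sample1(seq(s0, e0 - w))
    data.frame(contig = promoters$contig[i], start = s, end = s + w,
               name = sprintf("peak_%s_r%d_%d", gene, rep_id, k),
               q = 10^-runif(1L, 2, 8), replicate = rep_id)
  }

  rep1 <- list(); rep2 <- list()
  for (g in target_genes) {
    rep1[[length(rep1) + 1L]] <- peak_at_promoter(g, 1L, 0L)
    rep2[[length(rep2) + 1L]] <- peak_at_promoter(g, 2L, 0L)
  }

  n_decoys <- round(decoy_fraction * length(target_genes))
  if (n_decoys > 0L) {
    made <- 0L; tries <- 0L
    while (made < n_decoys && tries < n_decoys * 50L) {
      tries <- tries + 1L
      ci <- sample.int(nrow(annots$contigs), 1L)
      w <- sample(150:400, 1L)
      s <- sample.int(annots$contigs$length[ci] - w, 1L) - 1L
      ctg <- annots$contigs$contig[ci]
      if (any(promoters$contig == ctg & promoters$start < s + w &
                promoters$end > s)) {
        next
      }
      made <- made + 1L
      for (rep_id in 1:2) {
        row <- data.frame(contig = annots$contigs$contig[ci], start = s,
                          end = s + w,
                          name = sprintf("decoy_%03d_r%d", made, rep_id),
                          q = 10^-runif(1L, 1.5, 4), replicate = rep_id)
        if (rep_id == 1L) rep1[[length(rep1) + 1L]] <- row else
          rep2[[length(rep2) + 1L]] <- row
      }
    }
  }
  if (n_rep1_only > 0L) {
    plantable <- promoters$gene_id[widths >= min_exclusive]
    others <- setdiff(plantable, target_genes)
    pick <- head(others, n_rep1_only)
    for (k in seq_along(pick)) {
      rep1[[length(rep1) + 1L]] <- peak_at_promoter(pick[k], 1L, k)
    }
  }
  mk <- function(lst) {
    d <- do.call(rbind, lst)
    d <- d[order(d$contig, d$start), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  list(rep1 = mk(rep1), rep2 = mk(rep2), truth = sort(target_genes))
}

#' Write peaks as BED6 with -log10(q) scores
#'
#' @param peaks peak data.frame (see [simulate_chip_peaks()]).
#' @param path output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  write_bed(data.frame(contig = peaks$contig, start = peaks$start,
                       end = peaks$end, name = peaks$name,
                       score = -log10(peaks$q), strand = "*"),
            path)
}

# Per-promoter sub-intervals not covered by any other promoter.
.exclusive_promoter_regions <- function(promoters) {
  prom_gr <- .granges0(promoters)
  lapply(seq_len(nrow(promoters)), function(i) {
    other <- GenomicRanges::reduce(prom_gr[-i], ignore.strand = TRUE)
    GenomicRanges::setdiff(prom_gr[i], other, ignore.strand = TRUE)
  })
}

#' Genes whose promoter can be targeted unambiguously
#'
#' Returns the gene ids whose promoter has at least `min_exclusive` bp not
#' shared with any other promoter, i.e. genes for which a planted ChIP
#' peak can support exactly one target call. Non-first operon members
#' (which share the first gene's promoter) are never plantable.
#'
#' @param annots an [annotation_set()].
#' @param min_exclusive minimum exclusive width in bp.
#' @return character vector of gene ids.
#' @export
plantable_chip_targets <- function(annots, min_exclusive = 50L) {
  promoters <- derive_promoters(annots)
  excl <- .exclusive_promoter_regions(promoters)
  widths <- vapply(excl, function(r) {
    if (length(r) == 0L) 0L else max(GenomicRanges::width(r))
  }, integer(1L))
  promoters$gene_id[widths >= min_exclusive]
}
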