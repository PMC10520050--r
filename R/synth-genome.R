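#' Generate a synthetic genome with annotations
#'
#' Draws random ACGT contigs and places protein-coding genes (with exons,
#' strand and 5' UTR starts), operons, piRNA loci, structural RNAs (tRNA,
#' snRNA, snoRNA, ncRNA), rRNAs and transposons without pathological
#' crowding, but with two deliberate constructs that exercise downstream
#' rules: one rRNA overlapping a protein-coding gene on the same strand
#' (rRNA-precedence path) and at least one operon of two or more genes
#' (operon-aware promoters). piRNA loci are written into the genome with
#' `T` at their first three positions so that reads starting at offsets
#' 0--2 carry a 5' T.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named [Biostrings::DNAStringSet]) and
#'   `annots` (an [annotation_set()]).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, "genome"))
  ctg_names <- sprintf("ctg%02d", seq_len(config$n_contigs))
  contig_chars <- lapply(seq_len(config$n_contigs), function(i) {
    sample(c("A", "C", "G", "T"), config$contig_length, replace = TRUE)
  })
  names(contig_chars) <- ctg_names

  # --- build the slot list -------------------------------------------------
  n_op <- config$n_operons
  op_sizes <- if (n_op > 0L) sample(2:3, n_op, replace = TRUE) else integer()
  n_op_genes <- sum(op_sizes)
  if (n_op_genes > config$n_genes) {
    .stopf("operons require %d genes but n_genes = %d", n_op_genes,
           config$n_genes)
  }
  n_free_genes <- config$n_genes - n_op_genes

  slot <- function(type, lengths) list(type = type, lengths = lengths)
  slots <- c(
    lapply(seq_len(n_free_genes), function(i) {
      slot("gene", sample(600:1200, 1L))
    }),
    lapply(op_sizes, function(k) slot("operon", sample(600:1200, k))),
    lapply(seq_len(config$n_pirna_loci), function(i) {
      slot("piRNA_locus", sample(24:30, 1L))
    }),
    lapply(seq_len(config$n_structural), function(i) slot("structural", sample(70:120, 1L))),
    lapply(seq_len(config$n_rrna), function(i) slot("rRNA", sample(150:300, 1L))),
    lapply(seq_len(config$n_transposons), function(i) slot("transposon", sample(300:500, 1L)))
  )
  slots <- slots[sample.int(length(slots))]
  gap <- function() sample(20:80, 1L)
  need <- sum(vapply(slots, function(s) sum(s$lengths) +
                       60L * length(s$lengths), numeric(1L)))
  cap <- config$n_contigs * (config$contig_length - 200L)
  if (need > cap) {
    .stopf(paste0("contigs too short: placing the requested features needs ",
                  "~%d bp but only %d bp are available ",
                  "(n_contigs * contig_length)"), need, cap)
  }

  feats <- list(); exons <- list(); operons <- list()
  gi <- 0L; pi <- 0L; si <- 0L; ri <- 0L; ti <- 0L; oi <- 0L
  ci <- 1L; cursor <- gap()

  place_gene <- function(contig, start, len, strand, id) {
    end <- start + len
    # 1-3 exons; first exon starts at the gene start, last ends at its end
    k <- if (len < 300L) 1L else sample(1:3, 1L)
    if (k == 1L) {
      ex <- data.frame(feature_id = id, start = start, end = end)
    } else {
      cuts <- sort(sample(seq(start + 100L, end - 100L), 2L * (k - 1L)))
      b <- c(start, cuts, end)
      ex <- data.frame(
        feature_id = id,
        start = b[seq(1L, length(b) - 1L, by = 2L)],
        end = b[seq(2L, length(b), by = 2L)]
      )
    }
    utr5 <- if (strand == "+") start else end
    list(
      feat = data.frame(id = id, contig = contig, start = start, end = end,
                        strand = strand, biotype = "protein_coding",
                        utr5_start = utr5),
      exons = ex
    )
  }

  for (s in slots) {
    total_len <- sum(s$lengths) + 30L * (length(s$lengths) - 1L)
    while (cursor + total_len + 100L > config$contig_length) {
      ci <- ci + 1L
      if (ci > config$n_contigs) {
        .stopf("contigs too short: ran out of space while placing features")
      }
      cursor <- gap()
    }
    contig <- ctg_names[ci]
    strand <- sample(c("+", "-"), 1L)
    if (s$type == "gene") {
      gi <- gi + 1L
      g <- place_gene(contig, cursor, s$lengths, strand,
                      sprintf("gene%04d", gi))
      feats[[length(feats) + 1L]] <- g$feat
      exons[[length(exons) + 1L]] <- g$exons
      cursor <- cursor + s$lengths + gap()
    } else if (s$type == "operon") {
      oi <- oi + 1L
      oid <- sprintf("op%02d", oi)
      member_feats <- list()
      for (len in s$lengths) {
        gi <- gi + 1L
        g <- place_gene(contig, cursor, len, strand, sprintf("gene%04d", gi))
        feats[[length(feats) + 1L]] <- g$feat
        exons[[length(exons) + 1L]] <- g$exons
        member_feats[[length(member_feats) + 1L]] <- g$feat
        cursor <- cursor + len + 30L
      }
      ids <- vapply(member_feats, function(f) f$id, "")
      starts <- vapply(member_feats, function(f) f$start, numeric(1L))
      # first gene = 5'-most on the operon strand
      ord <- if (strand == "+") order(starts) else order(-starts)
      operons[[length(operons) + 1L]] <- data.frame(
        operon_id = oid, gene_id = ids[ord], position = seq_along(ids)
      )
      cursor <- cursor + gap()
    } else {
      len <- s$lengths
      biotype <- switch(s$type,
        piRNA_locus = "piRNA_locus",
        structural = sample(STRUCTURAL_BIOTYPES, 1L),
        rRNA = "rRNA",
        transposon = "transposon"
      )
      if (s$type == "piRNA_locus") {
        pi <- pi + 1L; id <- sprintf("pir%04d", pi)
      } else if (s$type == "structural") {
        si <- si + 1L; id <- sprintf("str%03d", si)
      } else if (s$type == "rRNA") {
        ri <- ri + 1L; id <- sprintf("rrn%02d", ri)
      } else {
        ti <- ti + 1L; id <- sprintf("tsp%03d", ti)
      }
      feats[[length(feats) + 1L]] <- data.frame(
        id = id, contig = contig, start = cursor, end = cursor + len,
        strand = strand, biotype = biotype, utr5_start = NA_integer_
      )
      if (s$type == "piRNA_locus") {
        # force a 5' T at locus offsets 0-2 (strand-aware)
        pos <- if (strand == "+") cursor + 1:3 else cursor + len - (2:0)
        contig_chars[[contig]][pos] <- if (strand == "+") "T" else "A"
      }
      cursor <- cursor + len + gap()
    }
  }

  features <- do.call(rbind, feats)
  exon_df <- do.call(rbind, exons)
  operon_df <- if (length(operons)) do.call(rbind, operons) else NULL

  # deliberate rRNA/protein-coding overlap, same strand, inside an exon
  genes <- features[features$biotype == "protein_coding", ]
  host <- genes[which.max(genes$end - genes$start), ]
  host_ex <- exon_df[exon_df$feature_id == host$id, ]
  big_ex <- host_ex[which.max(host_ex$end - host_ex$start), ]
  ov_len <- min(120L, (big_ex$end - big_ex$start) %/% 2L)
  ri <- ri + 1L
  features <- rbind(features, data.frame(
    id = sprintf("rrn%02d", ri), contig = host$contig,
    start = big_ex$start + 10L, end = big_ex$start + 10L + ov_len,
    strand = host$strand, biotype = "rRNA", utr5_start = NA_integer_
  ))

  genome <- Biostrings::DNAStringSet(
    vapply(contig_chars, paste0, "", collapse = "")
  )
  names(genome) <- ctg_names
  contigs <- data.frame(contig = ctg_names, length = config$contig_length)
  annots <- annotation_set(features, exon_df, operon_df, contigs)
  list(genome = genome, annots = annots)
}

#' Write a genome to FASTA
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
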