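#' Collapse raw small RNA reads
#'
#' Collapses identical sequences into one record with an occurrence count.
#' Input may be a FASTA/FASTQ file path, a [Biostrings::DNAStringSet], or a
#' character vector of sequences (assumed adapter-trimmed). Reads
#' containing `N` are dropped and tallied; any other non-ACGT character is
#' an error.
#'
#' @param reads file path, `DNAStringSet`, or character vector.
#' @return data.frame with columns `id`, `sequence`, `count`, sorted by
#'   decreasing count then sequence. The number of dropped N-containing
#'   reads is in the `n_dropped` attribute; `sum(count)` equals the number
#'   of retained input reads.
#' @export
collapse_reads <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  seqs <- if (methods::is(reads, "DNAStringSet")) {
    as.character(reads)
  } else {
    as.character(reads)
  }
  seqs <- unname(seqs)
  if (length(seqs) && any(grepl("[^ACGTN]", seqs))) {
    .stopf("reads contain characters outside ACGTN")
  }
  has_n <- grepl("N", seqs, fixed = TRUE)
  n_dropped <- sum(has_n)
  seqs <- seqs[!has_n]
  if (length(seqs) == 0L) {
    out <- data.frame(id = character(), sequence = character(),
                      count = integer())
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  out$id <- sprintf("r%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out <- out[, c("id", "sequence", "count")]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Align collapsed reads exactly against a genome
#'
#' Reports all, and only, exact (0-mismatch) occurrences of each read on
#' both strands of the genome. Reads with more than `max_hits` genomic
#' locations are dropped entirely and tallied, mirroring a
#' `-v 0 -m 1000 -a` alignment contract. Every surviving alignment carries
#' `n_hits`, the total number of genomic locations for its read.
#'
#' @param collapsed data.frame from [collapse_reads()] (`id`, `sequence`,
#'   `count`).
#' @param genome a named [Biostrings::DNAStringSet] or named character
#'   vector of contig sequences.
#' @param max_hits maximum allowed genomic locations per read (default
#'   1000).
#' @return data.frame with columns `read_id`, `contig`, `start` (0-based),
#'   `strand`, `n_hits`, `length`, `count`. Attributes: `dropped_multi`
#'   (ids dropped for exceeding `max_hits`), `unaligned` (ids with no
#'   exact occurrence), `depth` (total read count, with multiplicity, of
#'   aligned reads).
#' @export
align_reads <- function(collapsed, genome, max_hits = 1000L) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (is.null(names(genome))) .stopf("genome contigs must be named")
  empty <- data.frame(read_id = character(), contig = character(),
                      start = integer(), strand = character(),
                      n_hits = integer(), length = integer(),
                      count = integer())
  if (nrow(collapsed) == 0L) {
    attr(empty, "dropped_multi") <- character()
    attr(empty, "unaligned") <- character()
    attr(empty, "depth") <- 0L
    return(empty)
  }
  lens <- nchar(collapsed$sequence)
  seqs <- Biostrings::DNAStringSet(collapsed$sequence)
  ids <- collapsed$id
  # one variable-width dictionary with a trusted band over the first
  # min-width bases; matchPDict verifies the remainder at 0 mismatches
  tb <- min(lens)
  pd_fwd <- Biostrings::PDict(seqs, tb.start = 1L, tb.end = tb)
  rc <- Biostrings::reverseComplement(seqs)
  # band the last tb bases of the original read = first tb of the rev comp
  pd_rev <- Biostrings::PDict(rc, tb.start = 1L, tb.end = tb)
  parts <- list()
  for (ci in seq_along(genome)) {
    subject <- genome[[ci]]
    for (strand in c("+", "-")) {
      pd <- if (strand == "+") pd_fwd else pd_rev
      mi <- Biostrings::matchPDict(pd, subject, max.mismatch = 0)
      starts <- Biostrings::startIndex(mi)
      nhit <- lengths(starts)
      if (sum(nhit) == 0L) next
      w <- which(nhit > 0L)
      parts[[length(parts) + 1L]] <- data.frame(
        read_id = rep(ids[w], nhit[w]),
        contig = names(genome)[ci],
        start = unlist(starts[w], use.names = FALSE) - 1L,
        strand = strand,
        length = rep(lens[w], nhit[w])
      )
    }
  }
  aln <- if (length(parts)) do.call(rbind, parts) else
    data.frame(read_id = character(), contig = character(),
               start = integer(), strand = character(), length = integer())
  hit_counts <- table(aln$read_id)
  n_hits <- as.integer(hit_counts[aln$read_id])
  over <- names(hit_counts)[hit_counts > max_hits]
  keep <- !(aln$read_id %in% over)
  aln <- aln[keep, , drop = FALSE]
  aln$n_hits <- n_hits[keep]
  aln$count <- collapsed$count[match(aln$read_id, collapsed$id)]
  aln <- aln[order(aln$read_id, aln$contig, aln$start, aln$strand), ,
             drop = FALSE]
  rownames(aln) <- NULL
  aln <- aln[, c("read_id", "contig", "start", "strand", "n_hits", "length",
                 "count")]
  aligned_ids <- unique(aln$read_id)
  attr(aln, "dropped_multi") <- over
  attr(aln, "unaligned") <- setdiff(collapsed$id,
                                    c(aligned_ids, over))
  attr(aln, "depth") <- sum(collapsed$count[collapsed$id %in% aligned_ids])
  aln
}

#' Partition alignments into structural-RNA and retained reads
#'
#' A read is structural if any of its genomic alignments intersects a
#' structural-RNA feature (tRNA, snRNA, snoRNA or ncRNA), on either
#' strand; all alignments of such a read move to the structural
#' partition. The partition is exhaustive and disjoint at the read level.
#'
#' @param alignments data.frame from [align_reads()].
#' @param index a [build_feature_index()] result.
#' @return list with elements `structural` and `retained`, each an
#'   alignment data.frame; `retained` carries a `depth` attribute (total
#'   count, with multiplicity, of retained reads).
#' @export
filter_structural <- function(alignments, index) {
  stopifnot(inherits(index, "feature_index"))
  if (nrow(alignments) == 0L) {
    retained <- alignments
    attr(retained, "depth") <- 0L
    return(list(structural = alignments, retained = retained))
  }
  hits <- index_query(index, alignments$contig, alignments$start,
                      alignments$start + alignments$length,
                      what = "structural", sense = "any")
  struct_ids <- unique(alignments$read_id[unique(hits$query)])
  is_struct <- alignments$read_id %in% struct_ids
  retained <- alignments[!is_struct, , drop = FALSE]
  rownames(retained) <- NULL
  structural <- alignments[is_struct, , drop = FALSE]
  rownames(structural) <- NULL
  ret_ids <- unique(retained$read_id)
  attr(retained, "depth") <-
    sum(retained$count[match(ret_ids, retained$read_id)])
  list(structural = structural, retained = retained)
}
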