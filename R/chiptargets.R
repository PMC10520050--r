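#' Call transcription-factor target genes from replicate ChIP peak sets
#'
#' Peaks are filtered at `q < q_cutoff` (strict inequality), then
#' intersected with promoter intervals (any >= 1 bp overlap). A gene is a
#' target iff at least one qualifying peak in *each* replicate overlaps
#' its promoter. A peak overlapping two promoters supports both genes.
#'
#' @param peaks_rep1,peaks_rep2 data.frames with columns `contig`,
#'   `start`, `end` (0-based half-open) and `q` (q-value). Peak BED files
#'   whose score column holds -log10(q) can be converted with
#'   [peaks_from_bed()].
#' @param promoters promoter intervals from [derive_promoters()].
#' @param q_cutoff q-value cutoff (default 0.1, strict).
#' @return list with `calls` (per gene: supporting peak counts per
#'   replicate and `is_target`) and `targets` (character vector of target
#'   gene ids).
#' @export
call_targets <- function(peaks_rep1, peaks_rep2, promoters,
                         q_cutoff = 0.1) {
  if (nrow(peaks_rep1) == 0L || nrow(peaks_rep2) == 0L) {
    warning("a replicate peak set is empty: zero targets", call. = FALSE)
  }
  support <- function(peaks) {
    peaks <- peaks[!is.na(peaks$q) & peaks$q < q_cutoff, , drop = FALSE]
    n <- setNames(integer(nrow(promoters)), promoters$gene_id)
    if (nrow(peaks) == 0L || nrow(promoters) == 0L) return(n)
    pg <- .granges0(promoters)
    kg <- .granges0(peaks)
    hits <- GenomicRanges::findOverlaps(pg, kg, ignore.strand = TRUE)
    tab <- table(S4Vectors::queryHits(hits))
    n[as.integer(names(tab))] <- as.integer(tab)
    n
  }
  n1 <- support(peaks_rep1)
  n2 <- support(peaks_rep2)
  calls <- data.frame(
    gene = promoters$gene_id,
    peaks_rep1 = unname(n1),
    peaks_rep2 = unname(n2),
    is_target = unname(n1 > 0L & n2 > 0L)
  )
  list(calls = calls, targets = calls$gene[calls$is_target])
}

#' Convert a BED6 peak file to a peak data.frame
#'
#' @param path BED6 file; the score column is interpreted as -log10(q)
#'   unless `score_is = "q"`.
#' @param score_is `"neglog10q"` (default) or `"q"`.
#' @param replicate optional replicate label.
#' @return data.frame with `contig`, `start`, `end`, `name`, `q`,
#'   `replicate`.
#' @export
peaks_from_bed <- function(path, score_is = c("neglog10q", "q"),
                           replicate = NA_character_) {
  score_is <- match.arg(score_is)
  bed <- read_bed(path)
  q <- if (score_is == "neglog10q") 10^(-bed$score) else bed$score
  data.frame(contig = bed$contig, start = bed$start, end = bed$end,
             name = bed$name, q = q, replicate = replicate)
}

#' Intersect called targets with a gene set
#'
#' @param targets character vector of target gene ids (see
#'   [call_targets()]).
#' @param gene_set character vector.
#' @return list with `n_overlap`, `overlap` (ids), and the input sizes.
#'   Enrichment statistics on such overlaps are available through
#'   [set_enrichment()].
#' @export
intersect_targets_with_set <- function(targets, gene_set) {
  ov <- intersect(unique(targets), unique(gene_set))
  list(n_overlap = length(ov), overlap = sort(ov),
       n_targets = length(unique(targets)),
       n_set = length(unique(gene_set)))
}
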