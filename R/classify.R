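#' Small RNA class rules
#'
#' A `class_rule` captures one small RNA class definition: a length range,
#' allowed 5' bases, orientation relative to the target feature, a
#' uniqueness requirement, the eligible target interval set, and (for
#' piRNA-style rules) the allowed 5'-offset window relative to the locus
#' 5' end.
#'
#' The three built-in rules are:
#' \describe{
#'   \item{piRNA}{unique, perfect, sense to a piRNA locus, 5' T, 15--40 nt,
#'     5' end at offset 0, 1 or 2 from the locus 5' end (strand-aware).}
#'   \item{22G}{21--23 nt, 5' G or A, antisense to protein-coding or
#'     pseudogene exons, lincRNAs, rRNAs or transposons; multi-mapping
#'     allowed. At a location overlapping an rRNA, the rRNA takes the whole
#'     location weight; otherwise the location weight is split equally
#'     among the distinct overlapping eligible features.}
#'   \item{26G}{25--27 nt, 5' G, antisense to protein-coding exons
#'     (configurable; the class definition is not standardized, so every
#'     field can be overridden).}
#' }
#'
#' @param name class label.
#' @param length_range integer vector `c(min, max)` in nt.
#' @param first_bases allowed 5' bases of the read.
#' @param orientation `"sense"` or `"antisense"` to the target feature.
#' @param unique_only require `n_hits == 1`.
#' @param targets name of the target interval set in a `feature_index`:
#'   one of `"pirna"`, `"eligible22g"`, `"pc_exons"`, `"exonic"`,
#'   `"whole"`.
#' @param offset_window allowed 5' offsets from the target's 5' end, or
#'   `NULL` for no positional constraint.
#' @param rrna_preference give rRNA features the whole location weight
#'   when they overlap other eligible features.
#' @return A `class_rule` object.
#' @export
class_rule <- function(name, length_range, first_bases, orientation,
                       unique_only = FALSE, targets = "whole",
                       offset_window = NULL, rrna_preference = FALSE) {
  stopifnot(length(length_range) == 2L, length_range[1L] <= length_range[2L],
            orientation %in% c("sense", "antisense"))
  structure(
    list(name = name, length_range = as.integer(length_range),
         first_bases = first_bases, orientation = orientation,
         unique_only = unique_only, targets = targets,
         offset_window = offset_window, rrna_preference = rrna_preference),
    class = "class_rule"
  )
}

#' @rdname class_rule
#' @export
default_class_rules <- function() {
  list(
    class_rule("piRNA", c(15L, 40L), "T", "sense", unique_only = TRUE,
               targets = "pirna", offset_window = 0:2),
    class_rule("22G", c(21L, 23L), c("G", "A"), "antisense",
               targets = "eligible22g", rrna_preference = TRUE),
    class_rule("26G", c(25L, 27L), "G", "antisense", targets = "pc_exons")
  )
}

# Apply one rule to a set of candidate reads. Returns NULL if nothing is
# assigned, else list(read_ids, weights) where weights has one row per
# (alignment location, feature) pair -- feature NA for locations of an
# assigned read that overlap no eligible feature, so that the per-read
# weight total is conserved at count = sum over locations of count/n_hits.
.apply_rule <- function(rule, collapsed, alignments, index) {
  lens <- nchar(collapsed$sequence)
  first <- substr(collapsed$sequence, 1L, 1L)
  cand <- collapsed$id[
    lens >= rule$length_range[1L] & lens <= rule$length_range[2L] &
      first %in% rule$first_bases
  ]
  if (length(cand) == 0L) return(NULL)
  aln <- alignments[alignments$read_id %in% cand, , drop = FALSE]
  if (rule$unique_only) aln <- aln[aln$n_hits == 1L, , drop = FALSE]
  if (nrow(aln) == 0L) return(NULL)

  sense <- if (rule$orientation == "sense") "same" else "opposite"
  hits <- index_query(index, aln$contig, aln$start, aln$start + aln$length,
                      strand = aln$strand, what = rule$targets,
                      sense = sense)
  if (!is.null(rule$offset_window)) {
    set <- index[[rule$targets]]
    fs <- as.character(GenomicRanges::strand(set))
    f_start0 <- GenomicRanges::start(set) - 1L
    f_end0 <- GenomicRanges::end(set)
    fid <- S4Vectors::mcols(set)$feature_id
    si <- match(hits$feature_id, fid)
    q <- hits$query
    # read 5' end in genome coordinates: start for "+", end - 1 for "-"
    off <- ifelse(aln$strand[q] == "+",
                  aln$start[q] - f_start0[si],
                  (f_end0[si] - 1L) - (aln$start[q] + aln$length[q] - 1L))
    hits <- hits[off %in% rule$offset_window, , drop = FALSE]
  }
  if (nrow(hits) == 0L) return(NULL)

  assigned_reads <- unique(aln$read_id[unique(hits$query)])
  keep_aln <- which(aln$read_id %in% assigned_reads)
  aln_a <- aln[keep_aln, , drop = FALSE]
  hits <- hits[aln$read_id[hits$query] %in% assigned_reads, , drop = FALSE]
  # one (location, feature) pair at most once
  hits <- unique(hits[, c("query", "feature_id", "biotype")])

  if (rule$rrna_preference && any(hits$biotype == "rRNA")) {
    has_rrna <- unique(hits$query[hits$biotype == "rRNA"])
    hits <- hits[!(hits$query %in% has_rrna) | hits$biotype == "rRNA", ,
                 drop = FALSE]
  }

  loc_weight <- aln_a$count / aln_a$n_hits       # per surviving location
  names(loc_weight) <- NULL
  nfeat <- table(hits$query)
  w_hits <- data.frame(
    aln_row = hits$query,
    feature_id = hits$feature_id,
    biotype = hits$biotype,
    weight = loc_weight[match(hits$query, keep_aln)] /
      as.integer(nfeat[as.character(hits$query)])
  )
  # locations of assigned reads with no eligible feature keep their share
  bare <- setdiff(keep_aln, unique(hits$query))
  if (length(bare)) {
    w_hits <- rbind(w_hits, data.frame(
      aln_row = bare, feature_id = NA_character_, biotype = NA_character_,
      weight = loc_weight[match(bare, keep_aln)]
    ))
  }
  ai <- w_hits$aln_row
  weights <- data.frame(
    read_id = aln$read_id[ai],
    class = rule$name,
    contig = aln$contig[ai],
    start = aln$start[ai],
    strand = aln$strand[ai],
    feature_id = w_hits$feature_id,
    biotype = w_hits$biotype,
    weight = w_hits$weight
  )
  list(read_ids = assigned_reads, weights = weights)
}

#' Classify aligned reads into small RNA classes
#'
#' Applies class rules in order (default piRNA, then 22G, then 26G); each
#' read receives the first matching class, or `"unassigned"`. For every
#' assigned read, per-(location, feature) weights are
#' `count x (1 / n_hits) x (1 / n_features_at_location)`, so that the
#' weights of a read sum to its occurrence count (locations overlapping no
#' eligible feature keep their `count / n_hits` share under a missing
#' feature id).
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param alignments data.frame from [align_reads()] (after
#'   [filter_structural()]).
#' @param index a [build_feature_index()] result.
#' @param rules list of [class_rule()] objects in precedence order.
#' @return list with `assignments` (data.frame `read_id`, `class`,
#'   `count`) and `weights` (data.frame `read_id`, `class`, `contig`,
#'   `start`, `strand`, `feature_id`, `biotype`, `weight`).
#' @export
classify_all <- function(collapsed, alignments, index,
                         rules = default_class_rules()) {
  stopifnot(inherits(index, "feature_index"))
  remaining <- collapsed
  out_w <- list()
  classes <- setNames(rep("unassigned", nrow(collapsed)), collapsed$id)
  for (rule in rules) {
    if (nrow(remaining) == 0L) break
    res <- .apply_rule(rule, remaining, alignments, index)
    if (is.null(res)) next
    classes[res$read_ids] <- rule$name
    out_w[[rule$name]] <- res$weights
    remaining <- remaining[!(remaining$id %in% res$read_ids), , drop = FALSE]
  }
  weights <- if (length(out_w)) do.call(rbind, out_w) else
    data.frame(read_id = character(), class = character(),
               contig = character(), start = integer(), strand = character(),
               feature_id = character(), biotype = character(),
               weight = numeric())
  rownames(weights) <- NULL
  assignments <- data.frame(
    read_id = collapsed$id,
    class = unname(classes[collapsed$id]),
    count = collapsed$count
  )
  list(assignments = assignments, weights = weights)
}

#' Call a single read against one class rule
#'
#' Convenience single-read wrappers over the vectorized classifier;
#' refusal is a value (`assigned = FALSE`), not an error.
#'
#' @param read list or one-row data.frame with `id`, `sequence`, `count`.
#' @param alignments alignment rows for this read (see [align_reads()]).
#' @param index a [build_feature_index()] result.
#' @param rule a [class_rule()]; the defaults are the built-in rules.
#' @return list with `assigned` (logical) and `weights` (data.frame, empty
#'   on refusal).
#' @export
call_pirna <- function(read, alignments, index,
                       rule = default_class_rules()[[1L]]) {
  .call_one(read, alignments, index, rule)
}

#' @rdname call_pirna
#' @export
call_22g <- function(read, alignments, index,
                     rule = default_class_rules()[[2L]]) {
  .call_one(read, alignments, index, rule)
}

#' @rdname call_pirna
#' @export
call_26g <- function(read, alignments, index,
                     rule = default_class_rules()[[3L]]) {
  .call_one(read, alignments, index, rule)
}

.call_one <- function(read, alignments, index, rule) {
  read <- as.data.frame(read)
  stopifnot(nrow(read) == 1L)
  aln <- alignments[alignments$read_id == read$id, , drop = FALSE]
  res <- .apply_rule(rule, read, aln, index)
  if (is.null(res)) {
    list(assigned = FALSE, weights = data.frame())
  } else {
    list(assigned = TRUE, weights = res$weights)
  }
}

#' Per-gene, per-class count table
#'
#' Sums classified read weights per feature and class, and scales raw
#' fractional counts to reads per million genome-mapped reads:
#' `RPM = 1e6 * raw / depth`.
#'
#' @param classified result of [classify_all()].
#' @param depth sequencing depth: the number of reads (with multiplicity)
#'   mapping to the genome after structural filtering, e.g. the `depth`
#'   attribute of the retained alignments.
#' @param sample_id optional sample label.
#' @return data.frame with columns `feature_id`, `class`, `raw`, `rpm`,
#'   plus attributes `depth` and `sample_id`.
#' @export
quantify_genes <- function(classified, depth, sample_id = NA_character_) {
  stopifnot(is.numeric(depth), depth > 0)
  w <- classified$weights
  w <- w[!is.na(w$feature_id), , drop = FALSE]
  if (nrow(w) == 0L) {
    out <- data.frame(feature_id = character(), class = character(),
                      raw = numeric(), rpm = numeric())
  } else {
    agg <- stats::aggregate(weight ~ feature_id + class, data = w, FUN = sum)
    out <- data.frame(feature_id = agg$feature_id, class = agg$class,
                      raw = agg$weight, rpm = 1e6 * agg$weight / depth)
    out <- out[order(out$class, out$feature_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "depth") <- depth
  attr(out, "sample_id") <- sample_id
  out
}

#' Length by first-nucleotide profile
#'
#' Tabulates summed read counts over read length (15--40 nt) and 5'
#' nucleotide; margins reproduce the total read count for reads within the
#' length range.
#'
#' @param collapsed data.frame with `sequence` and `count` columns.
#' @param lengths lengths (rows) to tabulate.
#' @return integer matrix with one row per length and columns A, C, G, T.
#' @export
length_firstnt_profile <- function(collapsed, lengths = 15:40) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(0L, nrow = length(lengths), ncol = length(bases),
              dimnames = list(as.character(lengths), bases))
  if (nrow(collapsed) == 0L) return(m)
  len <- nchar(collapsed$sequence)
  first <- substr(collapsed$sequence, 1L, 1L)
  keep <- len %in% lengths & first %in% bases
  if (!any(keep)) return(m)
  tab <- tapply(collapsed$count[keep],
                list(factor(len[keep], levels = lengths),
                     factor(first[keep], levels = bases)),
                sum)
  tab[is.na(tab)] <- 0L
  m[] <- as.integer(tab)
  m
}
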