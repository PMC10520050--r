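#' Genomic feature annotations
#'
#' An `annotation_set` bundles strand-aware genomic features over named
#' contigs: genes and gene-like features with biotypes, their exons, operon
#' membership, and contig lengths. All coordinates are 0-based half-open.
#'
#' @param features data.frame with columns `id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), `biotype`, and optionally
#'   `utr5_start` (the genome coordinate of the transcription start side:
#'   the feature's `start` for plus-strand, its `end` for minus-strand
#'   features; `NA` allowed).
#' @param exons data.frame with columns `feature_id`, `start`, `end`; exons
#'   must lie within their feature, be non-overlapping, and sorted.
#' @param operons data.frame with columns `operon_id`, `gene_id`,
#'   `position` (1 = first gene 5' to 3' on the operon strand). Each operon
#'   needs at least two members on one strand and contig.
#' @param contigs data.frame with columns `contig`, `length`.
#'
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(features, exons = NULL, operons = NULL, contigs) {
  stopifnot(is.data.frame(features), is.data.frame(contigs))
  if (is.null(exons)) {
    exons <- data.frame(feature_id = character(), start = integer(),
                        end = integer())
  }
  if (is.null(operons)) {
    operons <- data.frame(operon_id = character(), gene_id = character(),
                          position = integer())
  }
  need <- c("id", "contig", "start", "end", "strand", "biotype")
  if (!all(need %in% names(features))) {
    .stopf("features must have columns: %s", paste(need, collapse = ", "))
  }
  if (!"utr5_start" %in% names(features)) features$utr5_start <- NA_integer_
  if (anyDuplicated(features$id)) .stopf("duplicated feature ids")
  clen <- setNames(as.integer(contigs$length), contigs$contig)
  if (nrow(features) > 0L) {
    if (!all(features$contig %in% names(clen))) {
      .stopf("feature on unknown contig")
    }
    bad <- which(!(features$start >= 0L & features$start < features$end &
                     features$end <= clen[features$contig]))
    if (length(bad)) {
      .stopf("feature '%s' violates 0 <= start < end <= contig length",
             features$id[bad[1L]])
    }
    if (!all(features$strand %in% c("+", "-"))) .stopf("strand must be + or -")
  }
  if (nrow(exons) > 0L) {
    fidx <- match(exons$feature_id, features$id)
    if (anyNA(fidx)) .stopf("exon refers to unknown feature")
    ok <- exons$start >= features$start[fidx] & exons$end <= features$end[fidx] &
      exons$start < exons$end
    if (!all(ok)) .stopf("exon outside its feature bounds")
    sp <- split(seq_len(nrow(exons)), exons$feature_id)
    for (ii in sp) {
      ii <- ii[order(exons$start[ii])]
      if (length(ii) > 1L &&
          any(exons$start[ii][-1L] < exons$end[ii][-length(ii)])) {
        .stopf("overlapping exons in feature '%s'", exons$feature_id[ii[1L]])
      }
    }
    exons <- exons[order(match(exons$feature_id, features$id), exons$start), ,
                   drop = FALSE]
    rownames(exons) <- NULL
  }
  if (nrow(operons) > 0L) {
    gidx <- match(operons$gene_id, features$id)
    if (anyNA(gidx)) .stopf("operon member is not an annotated feature")
    for (op in split(seq_len(nrow(operons)), operons$operon_id)) {
      if (length(op) < 2L) .stopf("operon with fewer than 2 members")
      if (length(unique(features$strand[gidx[op]])) != 1L ||
          length(unique(features$contig[gidx[op]])) != 1L) {
        .stopf("operon members must share strand and contig")
      }
    }
  }
  structure(
    list(features = features, exons = exons, operons = operons,
         contigs = contigs),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$features), "features on",
      nrow(x$contigs), "contig(s);",
      nrow(x$exons), "exons;",
      length(unique(x$operons$operon_id)), "operon(s)\n")
  print(table(x$features$biotype))
  invisible(x)
}

# Biotypes treated as structural RNA for read filtering. rRNA is not
# filtered: it is an eligible 22G-RNA feature with overlap precedence.
STRUCTURAL_BIOTYPES <- c("tRNA", "snRNA", "snoRNA", "ncRNA")

# Biotypes whose antisense reads are eligible 22G-RNA targets; exon-level
# for the first two, whole-feature for the rest.
ELIGIBLE_22G_EXONIC <- c("protein_coding", "pseudogene")
ELIGIBLE_22G_WHOLE <- c("lincRNA", "rRNA", "transposon")

## ---- GFF3 I/O ------------------------------------------------------------

# Validate raw GFF3 lines before handing to the parser, reporting 1-based
# line numbers for malformed records.
.gff_prescan <- function(path) {
  lines <- readLines(path)
  data_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in data_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) {
      .stopf("GFF line %d: expected 9 tab-separated fields, got %d",
             i, length(f))
    }
    s <- suppressWarnings(as.integer(f[4L]))
    e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e)) {
      .stopf("GFF line %d: non-numeric coordinates", i)
    }
    if (e < s) {
      .stopf("GFF line %d: end (%d) < start (%d)", i, e, s)
    }
  }
  lines
}

#' Read an annotation set from GFF3
#'
#' Reads a GFF3 file written by [write_gff()] (or any file following the
#' same conventions: feature records typed by biotype with `ID` and
#' optional `utr5_start` attributes, `exon` records with `Parent`, and
#' `operon` records with a comma-separated `members` attribute). GFF3
#' coordinates are 1-based inclusive and are converted to the package's
#' 0-based half-open convention on input (`start - 1`, `end`). Contig
#' lengths are taken from `##sequence-region` pragmas.
#'
#' @param path path to a GFF3 file.
#' @return An [annotation_set()].
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) .stopf("GFF file does not exist: %s", path)
  lines <- .gff_prescan(path)
  sr <- lines[startsWith(lines, "##sequence-region")]
  contigs <- data.frame(contig = character(), length = integer())
  if (length(sr)) {
    parts <- strsplit(trimws(sr), "\\s+")
    contigs <- data.frame(
      contig = vapply(parts, `[`, "", 2L),
      length = as.integer(vapply(parts, `[`, "", 4L))
    )
  }
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)
  id <- as.character(m$ID)
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  contig <- as.character(GenomicRanges::seqnames(gr))

  is_exon <- type == "exon"
  is_operon <- type == "operon"
  is_feat <- !is_exon & !is_operon

  utr5 <- rep(NA_integer_, length(gr))
  if ("utr5_start" %in% names(m)) {
    utr5 <- suppressWarnings(as.integer(as.character(m$utr5_start)))
  }
  features <- data.frame(
    id = id[is_feat], contig = contig[is_feat],
    start = start0[is_feat], end = end0[is_feat],
    strand = strand[is_feat], biotype = type[is_feat],
    utr5_start = utr5[is_feat]
  )

  parent <- if ("Parent" %in% names(m)) {
    vapply(m$Parent, function(p) if (length(p)) as.character(p[1L]) else NA_character_, "")
  } else {
    rep(NA_character_, length(gr))
  }
  exons <- data.frame(
    feature_id = parent[is_exon],
    start = start0[is_exon], end = end0[is_exon]
  )

  operons <- data.frame(operon_id = character(), gene_id = character(),
                        position = integer())
  if (any(is_operon)) {
    mem <- m$members[is_operon]
    mem_list <- if (is.list(mem) || methods::is(mem, "List")) {
      lapply(mem, as.character)
    } else {
      strsplit(as.character(mem), ",", fixed = TRUE)
    }
    operons <- do.call(rbind, lapply(seq_along(mem_list), function(k) {
      data.frame(operon_id = id[is_operon][k], gene_id = mem_list[[k]],
                 position = seq_along(mem_list[[k]]))
    }))
  }
  if (nrow(contigs) == 0L) {
    # fall back to the observed extent when pragmas are absent
    contigs <- do.call(rbind, lapply(split(end0, contig), function(e) {
      data.frame(length = max(e))
    }))
    contigs <- data.frame(contig = rownames(contigs), length = contigs$length)
  }
  annotation_set(features, exons, operons, contigs)
}

#' Write an annotation set to GFF3
#'
#' Emits feature records typed by biotype (attributes `ID`, `utr5_start`),
#' `exon` records with `Parent`, and `operon` records carrying their member
#' gene ids in a `members` attribute. Internal 0-based half-open
#' coordinates become 1-based inclusive on output. Contig lengths are
#' recorded as `##sequence-region` pragmas. `read_gff(write_gff(x))`
#' reproduces `x`.
#'
#' @param annots an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(annots, path) {
  stopifnot(inherits(annots, "annotation_set"))
  f <- annots$features
  e <- annots$exons
  o <- annots$operons

  rows <- data.frame(
    contig = f$contig, start = f$start, end = f$end, strand = f$strand,
    type = f$biotype, id = f$id, utr5_start = f$utr5_start,
    parent = NA_character_, members = NA_character_
  )
  if (nrow(e) > 0L) {
    fidx <- match(e$feature_id, f$id)
    rows <- rbind(rows, data.frame(
      contig = f$contig[fidx], start = e$start, end = e$end,
      strand = f$strand[fidx], type = "exon",
      id = paste0(e$feature_id, ".e",
                  stats::ave(seq_len(nrow(e)), e$feature_id, FUN = seq_along)),
      utr5_start = NA_integer_, parent = e$feature_id,
      members = NA_character_
    ))
  }
  if (nrow(o) > 0L) {
    oo <- o[order(o$operon_id, o$position), , drop = FALSE]
    ops <- split(oo, oo$operon_id)
    rows <- rbind(rows, do.call(rbind, lapply(names(ops), function(oid) {
      genes <- ops[[oid]]$gene_id
      gidx <- match(genes, f$id)
      data.frame(
        contig = f$contig[gidx[1L]],
        start = min(f$start[gidx]), end = max(f$end[gidx]),
        strand = f$strand[gidx[1L]], type = "operon", id = oid,
        utr5_start = NA_integer_, parent = NA_character_,
        members = paste(genes, collapse = ",")
      )
    })))
  }
  gr <- .granges0(rows)
  parent_list <- lapply(rows$parent, function(p) {
    if (is.na(p)) character() else p
  })
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "granulite", type = rows$type, ID = rows$id,
    utr5_start = rows$utr5_start,
    Parent = IRanges::CharacterList(parent_list),
    members = rows$members
  )
  rtracklayer::export(gr, path, format = "gff3")
  lines <- readLines(path)
  pragmas <- sprintf("##sequence-region %s 1 %d",
                     annots$contigs$contig, annots$contigs$length)
  writeLines(c(lines[1L], pragmas, lines[-1L]), path)
  invisible(path)
}

## ---- BED I/O -------------------------------------------------------------

#' Read/write BED6 intervals
#'
#' BED is 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged. The score column is carried as-is;
#' for ChIP peak files it conventionally holds -log10(q).
#'
#' @param path file path.
#' @return `read_bed()` returns a data.frame with columns `contig`,
#'   `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) .stopf("BED file does not exist: %s", path)
  gr <- rtracklayer::import(path, format = "bed")
  m <- S4Vectors::mcols(gr)
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if ("name" %in% names(m)) as.character(m$name) else NA_character_,
    score = if ("score" %in% names(m)) as.numeric(m$score) else NA_real_,
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' @rdname read_bed
#' @param intervals data.frame with columns `contig`, `start`, `end` and
#'   optionally `name`, `score`, `strand` (0-based half-open).
#' @export
write_bed <- function(intervals, path) {
  df <- intervals
  if (!"name" %in% names(df)) df$name <- "."
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "*"
  gr <- .granges0(df)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = df$name,
                                               score = df$score)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

## ---- feature index -------------------------------------------------------

#' Build an interval index over an annotation set
#'
#' Precomputes interval sets used throughout the pipeline: whole features,
#' exonic intervals, the structural-RNA sub-index (tRNA/snRNA/snoRNA/ncRNA),
#' the 22G-eligible target intervals (protein-coding and pseudogene exons;
#' whole lincRNA, rRNA and transposon features), protein-coding exons, and
#' piRNA loci. Queries are strand-aware and follow the 0-based half-open
#' convention: a query ending at a feature's start, or starting at its end,
#' does not hit it.
#'
#' @param annots an [annotation_set()].
#' @return A `feature_index` object.
#' @export
build_feature_index <- function(annots) {
  stopifnot(inherits(annots, "annotation_set"))
  f <- annots$features
  e <- annots$exons

  mk <- function(df, ids, biotypes) {
    gr <- .granges0(df)
    if (length(gr)) {
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(feature_id = ids,
                                                   biotype = biotypes)
    }
    gr
  }
  whole <- mk(f, f$id, f$biotype)

  exonic <- GenomicRanges::GRanges()
  if (nrow(e) > 0L) {
    fidx <- match(e$feature_id, f$id)
    exonic <- mk(
      data.frame(contig = f$contig[fidx], start = e$start, end = e$end,
                 strand = f$strand[fidx]),
      e$feature_id, f$biotype[fidx]
    )
  }
  bt_ex <- if (length(exonic)) S4Vectors::mcols(exonic)$biotype else character()
  bt_wh <- f$biotype
  has_exons <- f$id %in% e$feature_id
  # exon-level target intervals where exons exist, else the whole feature
  elig <- suppressWarnings(c(
    exonic[bt_ex %in% ELIGIBLE_22G_EXONIC],
    whole[bt_wh %in% ELIGIBLE_22G_EXONIC & !has_exons],
    whole[bt_wh %in% ELIGIBLE_22G_WHOLE]
  ))
  pc_ex <- suppressWarnings(
    c(exonic[bt_ex == "protein_coding"],
      whole[bt_wh == "protein_coding" & !has_exons]))

  structure(
    list(
      whole = whole,
      exonic = exonic,
      structural = whole[bt_wh %in% STRUCTURAL_BIOTYPES],
      eligible22g = elig,
      pc_exons = pc_ex,
      pirna = whole[bt_wh == "piRNA_locus"],
      annots = annots
    ),
    class = "feature_index"
  )
}

#' @export
print.feature_index <- function(x, ...) {
  cat("feature_index:", length(x$whole), "features (",
      length(x$structural), "structural,",
      length(x$pirna), "piRNA loci,",
      length(x$eligible22g), "22G-eligible intervals )\n")
  invisible(x)
}

#' Query a feature index
#'
#' @param index a `feature_index`.
#' @param contig,start,end query interval(s), 0-based half-open
#'   (vectorized).
#' @param strand optional query strand(s); used with `sense`.
#' @param what which interval set to query: `"whole"`, `"exonic"`,
#'   `"structural"`, `"eligible22g"`, `"pc_exons"` or `"pirna"`.
#' @param sense `"any"` ignores strand; `"same"` keeps hits on the query
#'   strand; `"opposite"` keeps antisense hits.
#' @return data.frame with columns `query` (index of the query interval),
#'   `feature_id`, `biotype`.
#' @export
index_query <- function(index, contig, start, end, strand = NULL,
                        what = "whole", sense = c("any", "same", "opposite")) {
  stopifnot(inherits(index, "feature_index"))
  sense <- match.arg(sense)
  set <- index[[what]]
  n <- length(contig)
  empty <- data.frame(query = integer(), feature_id = character(),
                      biotype = character())
  if (length(set) == 0L || n == 0L) return(empty)
  q <- GenomicRanges::GRanges(contig, .iranges0(start, end))
  hits <- GenomicRanges::findOverlaps(q, set, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (sense != "any") {
    if (is.null(strand)) .stopf("sense-aware query requires strand")
    fs <- as.character(GenomicRanges::strand(set))[si]
    keep <- if (sense == "same") fs == strand[qi] else fs != strand[qi]
    qi <- qi[keep]; si <- si[keep]
  }
  m <- S4Vectors::mcols(set)
  data.frame(query = qi, feature_id = m$feature_id[si],
             biotype = m$biotype[si])
}

## ---- promoters -----------------------------------------------------------

#' Derive operon-aware promoters
#'
#' A gene's promoter is the 1 kb window upstream of its 5' UTR start: for a
#' plus-strand gene with 5' UTR start `s`, the interval `[s - 1000, s)`;
#' for a minus-strand gene, `[s, s + 1000)` where `s` is the feature's end
#' coordinate (the transcription-start side in genome coordinates). Genes
#' lacking an annotated `utr5_start` fall back to their 5'-most coordinate.
#' Every member of an operon receives the promoter computed from the first
#' gene of the operon. Intervals are clipped at contig bounds.
#'
#' @param annots an [annotation_set()].
#' @param length promoter length in bp (default 1000).
#' @param eligible_biotypes biotypes that receive promoters.
#' @return data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `derived_from_operon`; genes that could not be processed are
#'   listed in the `skipped` attribute.
#' @export
derive_promoters <- function(annots, length = 1000L,
                             eligible_biotypes = c("protein_coding",
                                                   "lincRNA", "pseudogene")) {
  stopifnot(inherits(annots, "annotation_set"))
  f <- annots$features
  clen <- setNames(as.integer(annots$contigs$length), annots$contigs$contig)
  g <- f[f$biotype %in% eligible_biotypes, , drop = FALSE]
  skipped <- character()
  if (nrow(g) == 0L) {
    out <- data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      derived_from_operon = logical())
    attr(out, "skipped") <- skipped
    return(out)
  }
  tss <- ifelse(is.na(g$utr5_start),
                ifelse(g$strand == "+", g$start, g$end),
                g$utr5_start)

  # operon members inherit the interval computed from the first gene
  first_of <- setNames(g$id, g$id)
  o <- annots$operons
  if (nrow(o) > 0L) {
    oo <- o[order(o$operon_id, o$position), , drop = FALSE]
    for (sp in split(oo, oo$operon_id)) {
      first_of[sp$gene_id] <- sp$gene_id[1L]
    }
  }
  src <- match(first_of[g$id], g$id)
  in_operon <- first_of[g$id] != g$id | g$id %in% o$gene_id
  na_src <- is.na(src)
  if (any(na_src)) {
    skipped <- c(skipped, g$id[na_src])
    g <- g[!na_src, , drop = FALSE]
    src <- src[!na_src]
    in_operon <- in_operon[!na_src]
  }
  s <- tss[src]
  strand_src <- g$strand[src]
  p_start <- ifelse(strand_src == "+", s - length, s)
  p_end <- ifelse(strand_src == "+", s, s + length)
  contig <- g$contig[src]
  p_start <- pmax(p_start, 0L)
  p_end <- pmin(p_end, clen[contig])
  keep <- p_start < p_end
  skipped <- c(skipped, g$id[!keep])
  out <- data.frame(
    gene_id = g$id[keep], contig = contig[keep],
    start = as.integer(p_start[keep]), end = as.integer(p_end[keep]),
    strand = strand_src[keep],
    derived_from_operon = unname(in_operon[keep])
  )
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
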