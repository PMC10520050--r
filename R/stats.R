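#' Differential-expression configuration
#'
#' @param fold_threshold call threshold on the fold scale (default 4, i.e.
#'   `|log2FC| >= 2`).
#' @param alpha p-value cutoff (default 0.05).
#' @param pseudocount RPM pseudocount added to both condition means before
#'   the log2 ratio (default 0.5).
#' @param var_equal pooled-variance t-test if `TRUE`; Welch otherwise.
#'   Welch is the safer default for real data with unequal dispersion;
#'   note that at n = 2 per group it is conservative by construction, so
#'   calibration studies on homoscedastic simulations should use the
#'   pooled variant.
#' @param adjust multiple-testing adjustment passed to [stats::p.adjust()]
#'   (`"none"` by default: calls are made on raw p-values).
#' @return A `de_config` list.
#' @export
de_config <- function(fold_threshold = 4, alpha = 0.05, pseudocount = 0.5,
                      var_equal = FALSE, adjust = "none") {
  stopifnot(fold_threshold > 1, alpha > 0, alpha < 1, pseudocount >= 0)
  structure(list(fold_threshold = fold_threshold, alpha = alpha,
                 pseudocount = pseudocount, var_equal = var_equal,
                 adjust = adjust),
            class = "de_config")
}

# Extract a gene x replicate RPM matrix for one class from a list of
# GeneCountTables.
.rpm_matrix <- function(tables, class, genes) {
  m <- matrix(0, nrow = length(genes), ncol = length(tables),
              dimnames = list(genes, NULL))
  for (j in seq_along(tables)) {
    t <- tables[[j]]
    t <- t[t$class == class, , drop = FALSE]
    idx <- match(t$feature_id, genes)
    ok <- !is.na(idx)
    m[idx[ok], j] <- t$rpm[ok]
  }
  m
}

# Vectorized two-sample two-tailed t-test on the rows of two matrices.
.row_ttest <- function(a, b, var_equal) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1L, stats::var); v2 <- apply(b, 1L, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate rows: zero variance in both groups
  degen <- !is.finite(se) | se == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  t[degen] <- ifelse(m1[degen] == m2[degen], 0, Inf * sign(m2 - m1)[degen])
  list(t = t, p = p, mean1 = m1, mean2 = m2)
}

#' Differential 22G-RNA analysis between two conditions
#'
#' Per gene, a two-sample two-tailed t-test on replicate RPM values and a
#' log2 fold change of condition means (numerator = `condition_b`,
#' conventionally the mutant). A gene is called `"up"` when
#' `log2FC >= log2(fold_threshold)` and `p < alpha`; `"down"`
#' symmetrically; otherwise `"unchanged"`.
#'
#' @param tables_a,tables_b lists of per-replicate gene count tables (see
#'   [quantify_genes()]), one list per condition; at least two replicates
#'   each.
#' @param cfg a [de_config()].
#' @param class which small RNA class to test (default `"22G"`).
#' @return data.frame with one row per gene: `gene`, `mean_a`, `mean_b`,
#'   `log2fc` (log2 of b over a), `t`, `p`, `padj`, `call`.
#' @export
differential_22g <- function(tables_a, tables_b, cfg = de_config(),
                             class = "22G") {
  stopifnot(inherits(cfg, "de_config"))
  if (length(tables_a) < 2L || length(tables_b) < 2L) {
    .stopf("each condition needs at least 2 replicates for the t-test")
  }
  genes <- sort(unique(unlist(lapply(c(tables_a, tables_b), function(t) {
    t$feature_id[t$class == class]
  }))))
  if (length(genes) == 0L) {
    return(data.frame(gene = character(), mean_a = numeric(),
                      mean_b = numeric(), log2fc = numeric(), t = numeric(),
                      p = numeric(), padj = numeric(), call = character()))
  }
  a <- .rpm_matrix(tables_a, class, genes)
  b <- .rpm_matrix(tables_b, class, genes)
  tt <- .row_ttest(a, b, cfg$var_equal)
  log2fc <- log2((tt$mean2 + cfg$pseudocount) /
                   (tt$mean1 + cfg$pseudocount))
  padj <- stats::p.adjust(tt$p, method = cfg$adjust)
  thr <- log2(cfg$fold_threshold)
  call <- rep("unchanged", length(genes))
  call[log2fc >= thr & padj < cfg$alpha] <- "up"
  call[log2fc <= -thr & padj < cfg$alpha] <- "down"
  data.frame(gene = genes, mean_a = tt$mean1, mean_b = tt$mean2,
             log2fc = log2fc, t = tt$t, p = tt$p, padj = padj, call = call)
}

#' Gene-set fold enrichment with Fisher's exact test
#'
#' Computes `log2((a / |DE|) / (|set ∩ universe| / |universe|))` where `a`
#' is the overlap of the DE list with the gene set — the log2 ratio of the
#' percentage of DE genes in the set to the percentage among all genes —
#' and a Fisher's exact p-value on the 2x2 membership table (two-sided by
#' default).
#'
#' @param de_genes character vector of differential genes (subset of
#'   `universe`).
#' @param target_set character vector, the gene set.
#' @param universe character vector of all genes considered.
#' @param set_name label for the output.
#' @param alternative sidedness passed to [stats::fisher.test()].
#' @return one-row data.frame: `set_name`, `a` (overlap), `n_de`,
#'   `n_set` (set members in the universe), `n_universe`,
#'   `log2_enrichment`, `p`. With an empty DE list or set the enrichment
#'   is undefined (`NA`) and `p = 1`.
#' @export
set_enrichment <- function(de_genes, target_set, universe,
                           set_name = "set",
                           alternative = "two.sided") {
  de_genes <- unique(de_genes)
  universe <- unique(universe)
  if (!all(de_genes %in% universe)) .stopf("de_genes must be in universe")
  set_u <- unique(target_set[target_set %in% universe])
  a <- sum(de_genes %in% set_u)
  n_de <- length(de_genes)
  n_set <- length(set_u)
  n_uni <- length(universe)
  if (n_de == 0L || n_set == 0L) {
    return(data.frame(set_name = set_name, a = a, n_de = n_de,
                      n_set = n_set, n_universe = n_uni,
                      log2_enrichment = NA_real_, p = 1))
  }
  enr <- log2((a / n_de) / (n_set / n_uni))
  tab <- matrix(c(a, n_de - a, n_set - a, n_uni - n_de - n_set + a),
                nrow = 2L)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  data.frame(set_name = set_name, a = a, n_de = n_de, n_set = n_set,
             n_universe = n_uni, log2_enrichment = enr, p = p)
}

#' Fold change of medians between two matched abundance vectors
#'
#' @param a,b numeric vectors of per-locus abundances (e.g. RPM), matched
#'   by locus.
#' @return `median(b) / median(a)`.
#' @export
median_fold <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  ma <- stats::median(a)
  if (ma == 0) .stopf("median of the reference vector is zero")
  stats::median(b) / ma
}

#' Oxidation enrichment analysis
#'
#' Compares RPM-normalized abundances between an untreated and a
#' periodate-oxidized library. Both tables must already be RPM-normalized
#' on their own sequencing depths; oxidation removes reads lacking 3'
#' 2'-O-methylation, shrinking the oxidized library depth, so classes of
#' methylation-protected RNAs (piRNAs) gain RPM share. Loci are grouped by
#' a class labeling (e.g. methylated piRNA loci vs unmethylated
#' background).
#'
#' @param untreated,oxidized gene count tables (see [quantify_genes()]).
#' @param locus_classes data.frame with columns `feature_id` and `group`.
#' @param pseudocount RPM pseudocount for per-locus log2 ratios.
#' @return list with `summary` (per group: locus count, median RPM
#'   untreated and oxidized, median per-locus log2 ratio, RPM share in
#'   each library) and `per_locus` (feature-level RPM and log2 ratio).
#' @export
oxidation_enrichment <- function(untreated, oxidized, locus_classes,
                                 pseudocount = 0.5) {
  if (nrow(oxidized) == 0L) .stopf("oxidized table is empty")
  if (nrow(untreated) == 0L) .stopf("untreated table is empty")
  loci <- unique(locus_classes$feature_id)
  u <- setNames(rep(0, length(loci)), loci)
  o <- u
  uu <- untreated[untreated$feature_id %in% loci, , drop = FALSE]
  oo <- oxidized[oxidized$feature_id %in% loci, , drop = FALSE]
  uu <- stats::aggregate(rpm ~ feature_id, uu, sum)
  oo <- stats::aggregate(rpm ~ feature_id, oo, sum)
  u[uu$feature_id] <- uu$rpm
  o[oo$feature_id] <- oo$rpm
  grp <- locus_classes$group[match(loci, locus_classes$feature_id)]
  per_locus <- data.frame(
    feature_id = loci, group = grp, rpm_untreated = unname(u),
    rpm_oxidized = unname(o),
    log2_ratio = log2((unname(o) + pseudocount) / (unname(u) + pseudocount))
  )
  tot_u <- sum(u); tot_o <- sum(o)
  summ <- do.call(rbind, lapply(split(per_locus, per_locus$group),
                                function(d) {
    data.frame(
      group = d$group[1L], n_loci = nrow(d),
      median_rpm_untreated = stats::median(d$rpm_untreated),
      median_rpm_oxidized = stats::median(d$rpm_oxidized),
      median_log2_ratio = stats::median(d$log2_ratio),
      share_untreated = if (tot_u > 0) sum(d$rpm_untreated) / tot_u else NA,
      share_oxidized = if (tot_o > 0) sum(d$rpm_oxidized) / tot_o else NA
    )
  }))
  rownames(summ) <- NULL
  list(summary = summ, per_locus = per_locus)
}
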