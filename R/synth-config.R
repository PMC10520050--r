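#' Simulation configuration
#'
#' Holds every parameter of the synthetic-data generator. The defaults
#' emulate the study design the pipeline targets: two conditions
#' (wild-type and a granule-defective mutant), two replicates each, a
#' 200-gene set whose 22G-RNAs are four-fold depleted in the mutant, and
#' periodate-oxidation survival probabilities that make methylation
#' enrichment unambiguous (0.95 for 2'-O-methylated piRNAs, 0.05 for
#' unmethylated RNAs). Genome scale is desk-sized: 3 contigs of 300 kb,
#' 500 genes, 300 piRNA loci.
#'
#' Gene abundances follow a log-normal baseline (`sdlog = lognormal_sigma`,
#' default 0.5) shared across replicates and conditions, with Poisson
#' sampling per replicate.
#'
#' @param seed integer RNG seed; identical configurations yield
#'   byte-identical outputs.
#' @param n_contigs,contig_length genome shape (bp).
#' @param n_genes,n_pirna_loci,n_structural,n_rrna,n_transposons,n_operons
#'   feature counts. Operon members are drawn from the genes.
#' @param class_mix named proportions over classes `piRNA`, `g22`, `g26`,
#'   `structural`, `background`; must sum to 1.
#' @param depletion_set_size,depletion_fold number of genes whose 22G-RNA
#'   abundance is divided by `depletion_fold` in the mutant condition.
#' @param replicates_per_condition replicates per condition (>= 2).
#' @param reads_per_sample expected total reads per replicate library.
#' @param methylated_survival,unmethylated_survival periodate-oxidation
#'   survival probabilities by 3' 2'-O-methylation status.
#' @param lognormal_sigma sdlog of the per-gene abundance baseline.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 3L, contig_length = 300000L,
                       n_genes = 500L, n_pirna_loci = 300L,
                       n_structural = 40L, n_rrna = 4L,
                       n_transposons = 20L, n_operons = 10L,
                       class_mix = c(piRNA = 0.25, g22 = 0.55, g26 = 0.05,
                                     structural = 0.05, background = 0.10),
                       depletion_set_size = 200L, depletion_fold = 4,
                       replicates_per_condition = 2L,
                       reads_per_sample = 100000L,
                       methylated_survival = 0.95,
                       unmethylated_survival = 0.05,
                       lognormal_sigma = 0.5) {
  counts <- c(n_contigs = n_contigs, contig_length = contig_length,
              n_genes = n_genes, n_pirna_loci = n_pirna_loci,
              n_structural = n_structural, n_rrna = n_rrna,
              n_transposons = n_transposons,
              replicates_per_condition = replicates_per_condition,
              reads_per_sample = reads_per_sample)
  if (any(counts <= 0)) .stopf("all counts must be positive")
  if (n_operons < 0) .stopf("n_operons must be >= 0")
  need <- c("piRNA", "g22", "g26", "structural", "background")
  if (!setequal(names(class_mix), need)) {
    .stopf("class_mix needs proportions for: %s", paste(need, collapse = ", "))
  }
  if (abs(sum(class_mix) - 1) > 1e-8) .stopf("class_mix must sum to 1")
  if (any(class_mix < 0)) .stopf("class_mix proportions must be >= 0")
  if (depletion_fold <= 0) .stopf("depletion_fold must be > 0")
  if (depletion_set_size > n_genes) {
    .stopf("depletion_set_size cannot exceed n_genes")
  }
  probs <- c(methylated_survival, unmethylated_survival)
  if (any(probs < 0 | probs > 1)) {
    .stopf("survival probabilities must be in [0, 1]")
  }
  structure(
    list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
         contig_length = as.integer(contig_length),
         n_genes = as.integer(n_genes),
         n_pirna_loci = as.integer(n_pirna_loci),
         n_structural = as.integer(n_structural),
         n_rrna = as.integer(n_rrna),
         n_transposons = as.integer(n_transposons),
         n_operons = as.integer(n_operons),
         class_mix = class_mix[need],
         depletion_set_size = as.integer(depletion_set_size),
         depletion_fold = depletion_fold,
         replicates_per_condition = as.integer(replicates_per_condition),
         reads_per_sample = as.integer(reads_per_sample),
         methylated_survival = methylated_survival,
         unmethylated_survival = unmethylated_survival,
         lognormal_sigma = lognormal_sigma),
    class = "sim_config"
  )
}

# Deterministic sub-seed for a labeled RNG stream, kept within 32-bit
# integer range.
.derive_seed <- function(seed, label, k = 0L) {
  h <- sum(utf8ToInt(label)) %% 10000L
  as.integer((as.numeric(seed) * 10007 + h * 131 + k) %% 2147483647)
}
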