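# Assembly-free quantification of AOA core genes in viromes, with the
# gene-length / copy-number host-contamination null (the "would the observed
# profile be expected from contaminating host DNA alone?" comparison).

#' Map virome reads to the core-gene panel
#'
#' Best-gene assignment per read at `min_identity` (nucleotide level);
#' counts are pooled per gene class across clades.  A read counts towards a
#' gene when at least half the read aligns within the gene at the identity
#' floor: with uniform genomic read starts the number of qualifying
#' positions then equals the gene length, which keeps the expected count
#' exactly proportional to gene length times copy number — the property the
#' contamination null model relies on.
#'
#' @param reads Read `data.frame` (`id`, `seq`) or character vector.
#' @param panel_sequences Per-clade gene sequences (`gene_class`, `clade`,
#'   `seq`), e.g. `hosts$panel$sequences` from [generate_hosts()].
#' @param min_identity Identity floor (default 0.90).
#' @return List with `counts` (named per gene class) and `assignments`.
#' @export
map_reads_to_core_genes <- function(reads, panel_sequences, min_identity = 0.90) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  ids <- sprintf("%s|%s", panel_sequences$gene_class, panel_sequences$clade)
  index <- build_kmer_index(setNames(panel_sequences$seq, ids))
  classes <- unique(panel_sequences$gene_class)
  if (!length(seqs)) {
    return(list(counts = setNames(rep(0L, length(classes)), classes),
                assignments = NULL))
  }
  asg <- map_reads(seqs, index, min_identity = min_identity,
                   min_read_frac = 0.5)
  cls <- sub("\\|.*$", "", asg$ref_id)
  counts <- table(factor(cls, levels = classes))
  list(counts = setNames(as.integer(counts), classes), assignments = asg)
}

#' Length-normalize counts and express relative to a reference gene
#'
#' `length_normalized[g] = raw[g] / mean_length[g]`;
#' `relative[g] = length_normalized[g] / length_normalized[reference]`.
#'
#' @param raw_counts Named counts per gene class.
#' @param panel Panel table from [core_gene_panel()].
#' @param reference Reference gene class (default `MCO1`, the most abundant
#'   gene in the observed viromes).
#' @return List of class `amg_profile` with `raw`, `length_normalized`,
#'   `relative`.
#' @export
normalize_profile <- function(raw_counts, panel = core_gene_panel(),
                              reference = "MCO1") {
  raw <- raw_counts[panel$gene_class]
  names(raw) <- panel$gene_class
  raw[is.na(raw)] <- 0
  if (raw[[reference]] <= 0) stop("reference gene unobserved: ", reference)
  ln <- raw / panel$mean_length_bp
  rel <- ln / ln[[reference]]
  structure(list(raw = raw, length_normalized = ln, relative = rel,
                 reference = reference), class = "amg_profile")
}

#' Expected relative profile under host contamination only
#'
#' If reads derive exclusively from contaminating host genomes, expected raw
#' counts are proportional to mean gene length times mean copy number, so
#' the length-normalized profile relative to the reference equals the
#' copy-number ratio.
#'
#' @param panel Panel table from [core_gene_panel()].
#' @param reference Reference gene class (default `MCO1`).
#' @return Named numeric vector of expected relative values (for the default
#'   panel: amoA 1, amoB 1, amoC 2.9, MCO1 1, MCO4 1.25, nirK 1).
#' @export
expected_null_profile <- function(panel = core_gene_panel(), reference = "MCO1") {
  expected_raw <- setNames(panel$mean_length_bp * panel$mean_copies,
                           panel$gene_class)
  normalize_profile(expected_raw, panel, reference)$relative
}

#' Test per-gene deviation from the host-contamination null
#'
#' Computes observed/expected ratios per gene and sample with t-based
#' confidence intervals, and an across-gene comparison of the ratios through
#' [compare_groups()].  Because profiles are expressed relative to the
#' reference gene, a genuine excess of the reference depresses every other
#' ratio uniformly; ratios are therefore centred on their per-sample median
#' so a deviation is attributed to the gene that carries it.  Samples with
#' zero total counts are excluded with a warning.
#'
#' @param profiles_by_sample Named list of `amg_profile` objects (one per
#'   sample; entries that are NULL or have zero counts are dropped).
#' @param null_profile Expected relative profile from
#'   [expected_null_profile()].
#' @param alpha Significance level for the letters.
#' @return List with `per_gene` (`gene_class`, `mean_ratio`, `ci_lo`,
#'   `ci_hi`, `n`), `comparison` (a `group_comparison`), `ratios` (long
#'   table).
#' @export
amg_enrichment_test <- function(profiles_by_sample, null_profile,
                                alpha = 0.05) {
  drop <- vapply(profiles_by_sample, function(p)
    is.null(p) || sum(p$raw) == 0, TRUE)
  if (any(drop)) {
    warning("excluding ", sum(drop), " sample(s) with zero mapped reads")
    profiles_by_sample <- profiles_by_sample[!drop]
  }
  if (length(profiles_by_sample) < 3L) stop("need at least 3 samples")
  genes <- names(null_profile)
  ratios <- do.call(rbind, lapply(names(profiles_by_sample), function(s) {
    rel <- profiles_by_sample[[s]]$relative[genes]
    r <- as.numeric(rel) / as.numeric(null_profile)
    r <- r / median(r[is.finite(r)])
    data.frame(sample_id = s, gene_class = genes, ratio = r,
               stringsAsFactors = FALSE)
  }))
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    x <- ratios$ratio[ratios$gene_class == g]
    x <- x[is.finite(x)]
    m <- mean(x)
    hw <- if (length(x) > 1L) qt(0.975, length(x) - 1L) * sd(x) / sqrt(length(x))
          else NA_real_
    data.frame(gene_class = g, mean_ratio = m, ci_lo = m - hw, ci_hi = m + hw,
               n = length(x), stringsAsFactors = FALSE)
  }))
  ok <- is.finite(ratios$ratio)
  cmp <- compare_groups(ratios$ratio[ok], ratios$gene_class[ok], alpha)
  list(per_gene = per_gene, comparison = cmp, ratios = ratios)
}

#' Identity-threshold sensitivity of core-gene mapping
#'
#' Reports total mapped reads at a descending series of identity floors;
#' the total is non-decreasing as the floor drops.
#'
#' @param reads Read `data.frame` or character vector.
#' @param panel_sequences Per-clade gene sequences.
#' @param identities Identity floors, highest first.
#' @return `data.frame` with `min_identity`, `total_mapped`,
#'   `delta_percent` (increase relative to the first floor).
#' @export
amg_sensitivity <- function(reads, panel_sequences,
                            identities = c(0.90, 0.80, 0.70)) {
  tot <- vapply(identities, function(mi) {
    sum(map_reads_to_core_genes(reads, panel_sequences, mi)$counts)
  }, 1)
  data.frame(min_identity = identities, total_mapped = tot,
             delta_percent = round_half_up(100 * (tot - tot[1]) / max(1, tot[1]), 1))
}
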