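# Shared small fixtures, built once per test run.

.fx <- new.env()

random_seq <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein_fixture <- function(n_aa) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n_aa, replace = TRUE),
        collapse = "")
}

# Substitute exactly `n_sub` positions; returns the mutated string.
substitute_bases <- function(seq, n_sub, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- strsplit(seq, "")[[1]]
  pos <- sample(length(b), n_sub)
  b[pos] <- vapply(b[pos], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  paste(b, collapse = "")
}

small_hosts <- function() {
  if (is.null(.fx$hosts)) {
    .fx$hosts <- generate_hosts(
      n_per_group = 2, seed = 101,
      genome_length = c(AOA = 1e5, AOB = 1e5, Nitrospira = 1.2e5))
  }
  .fx$hosts
}

small_viruses <- function() {
  if (is.null(.fx$viruses)) {
    .fx$viruses <- generate_viruses(
      small_hosts(), n_per_group = 3, n_decoys = 2,
      length_range = c(15000, 30000), frac_with_mco1 = 0.5, seed = 202)
  }
  .fx$viruses
}

# Brute-force single-spacer scan: position-by-position mismatch count on both
# strands, independent of the package's matcher.
brute_spacer_scan <- function(spacer, contig, max_mismatch = 2) {
  hits <- list()
  L <- nchar(spacer)
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") spacer else revcomp(spacer)
    pv <- utf8ToInt(pat)
    for (s in seq_len(nchar(contig) - L + 1)) {
      mm <- sum(utf8ToInt(substr(contig, s, s + L - 1)) != pv)
      if (mm <= max_mismatch) {
        hits[[length(hits) + 1]] <- data.frame(
          position = s - 1L, strand = strand, mismatches = mm)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  do.call(rbind, hits)
}

# Planted variant cohort: `n_species` unrelated genomes, `n_variants` copies
# each at `divergence` substitutions.
planted_cohort <- function(n_species, n_variants, divergence, len = 12000,
                           seed = 1) {
  set.seed(seed)
  ids <- character(0); seqs <- character(0); truth <- integer(0)
  for (sp in seq_len(n_species)) {
    base <- random_seq(len + sp * 10)  # distinct lengths aid determinism
    for (vv in seq_len(n_variants)) {
      s <- if (vv == 1) base else substitute_bases(base, round(divergence * nchar(base)))
      ids <- c(ids, sprintf("sp%02d_v%d", sp, vv))
      seqs <- c(seqs, s)
      truth <- c(truth, sp)
    }
  }
  list(contigs = contig_table(ids, seqs), truth = truth)
}

# Independent transitive-closure clustering oracle over pairwise
# similarities (single-linkage connected components, no greedy path).
transitive_closure_clusters <- function(contigs, id_thr = 0.95, cov_thr = 0.85) {
  n <- nrow(contigs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- pairwise_similarity(contigs[i, ], contigs[j, ])
      if (s$identity >= id_thr && s$coverage >= cov_thr) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

# Planted virus-family cohort for demarcation tests: each family shares an
# exact `shared_bp` block; members carry unique flanking sequence.
planted_families <- function(n_families, members_per_family, shared_bp = 3000,
                             unique_bp = 6000, seed = 1) {
  set.seed(seed)
  ids <- character(0); seqs <- character(0); fam <- integer(0)
  for (f in seq_len(n_families)) {
    core <- random_seq(shared_bp)
    for (m in seq_len(members_per_family)) {
      left <- random_seq(sample(500:unique_bp, 1))
      right <- random_seq(unique_bp - nchar(left) + 500)
      ids <- c(ids, sprintf("fam%02d_m%d", f, m))
      seqs <- c(seqs, paste0(left, core, right))
      fam <- c(fam, f)
    }
  }
  list(contigs = contig_table(ids, seqs), truth = fam)
}
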