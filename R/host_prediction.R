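# Host prediction: shared-homolog calls against a provirus protein database
# (amino-acid identity > 30%, e-value < 1e-5, bit score > 50, query coverage
# > 70%, minimum three homologs to a host group), hallmark-gene matches,
# CRISPR spacer scanning, and a hypergeometric gene-sharing network.

# Karlin-Altschul parameters for BLOSUM62 with gap open 11 / extend 1.
KA_LAMBDA <- 0.267
KA_K <- 0.041

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Call open reading frames on all six frames
#'
#' Maximal start-to-stop ORFs (first ATG after the previous stop, standard
#' genetic code) of at least `min_aa` residues, on both strands.
#'
#' @param contigs Contig `data.frame` (or a single nucleotide string).
#' @param min_aa Minimum protein length in residues (default 60).
#' @return `data.frame` with `protein_id`, `contig_id`, `frame`, `aa_length`,
#'   `seq` (amino acids, stop not included).
#' @export
call_orfs <- function(contigs, min_aa = 60) {
  if (!is.data.frame(contigs)) contigs <- contig_table("contig_1", contigs)
  out <- list()
  for (i in seq_len(nrow(contigs))) {
    id <- contigs$id[i]
    fwd <- contigs$seq[i]
    n <- nchar(fwd)
    k <- 0L
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else revcomp(fwd)
      for (off in 0:2) {
        alen <- floor((n - off) / 3) * 3
        if (alen < 3) next
        sub <- substr(s, off + 1L, off + alen)
        aa <- as.character(suppressWarnings(
          Biostrings::translate(Biostrings::DNAString(sub),
                                if.fuzzy.codon = "solve")))
        stops <- c(0L, which(strsplit(aa, "")[[1]] == "*"))
        for (j in seq_len(length(stops) - 1L)) {
          seg_start <- stops[j] + 1L; seg_end <- stops[j + 1L] - 1L
          if (seg_end - seg_start + 1L < min_aa) next
          seg <- substr(aa, seg_start, seg_end)
          m <- regexpr("M", seg, fixed = TRUE)
          if (m < 0) next
          orf <- substr(seg, m, nchar(seg))
          if (nchar(orf) < min_aa) next
          k <- k + 1L
          out[[length(out) + 1L]] <- data.frame(
            protein_id = sprintf("%s|orf%03d", id, k), contig_id = id,
            frame = paste0(strand, off + 1L), aa_length = nchar(orf),
            seq = orf, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(protein_id = character(0), contig_id = character(0),
                      frame = character(0), aa_length = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

aa_kmers <- function(seq, k = 5L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

# Candidate query/subject pairs sharing at least `min_shared` amino-acid
# k-mers, via an inverted index over the reference.
protein_candidates <- function(query_seqs, ref_seqs, k = 5L, min_shared = 1L) {
  ref_dt <- rbindlist(lapply(seq_along(ref_seqs), function(i) {
    data.table(kmer = aa_kmers(ref_seqs[i], k), ref = i)
  }))
  if (!nrow(ref_dt)) return(data.table(query = integer(0), ref = integer(0)))
  q_dt <- rbindlist(lapply(seq_along(query_seqs), function(i) {
    data.table(kmer = aa_kmers(query_seqs[i], k), query = i)
  }))
  hits <- merge(q_dt, ref_dt, by = "kmer", allow.cartesian = TRUE)
  if (!nrow(hits)) return(data.table(query = integer(0), ref = integer(0)))
  cnt <- hits[, .N, by = c("query", "ref")]
  cnt[cnt$N >= min_shared, c("query", "ref")]
}

# Local BLOSUM62 alignments of queries against one subject, with
# Karlin-Altschul bit scores and e-values.  `db_residues` is the total
# residue count of the search database.
align_protein_batch <- function(query_seqs, subject_seq, db_residues) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(query_seqs), Biostrings::AAString(subject_seq),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1)
  raw <- Biostrings::score(aln)
  bit <- (KA_LAMBDA * raw - log(KA_K)) / log(2)
  qlen <- nchar(query_seqs)
  pat <- Biostrings::pattern(aln)
  qspan <- Biostrings::end(pat) - Biostrings::start(pat) + 1L
  data.frame(
    aa_identity = Biostrings::pid(aln, type = "PID1") / 100,
    bitscore = bit,
    evalue = qlen * db_residues * 2^(-bit),
    query_coverage = qspan / qlen,
    subject_start = Biostrings::start(Biostrings::subject(aln)),
    subject_end = Biostrings::end(Biostrings::subject(aln))
  )
}

#' Best-hit protein search with the four-threshold filter
#'
#' One best hit (highest bit score) is retained per query protein; hits
#' failing any of amino-acid identity > `min_identity`, e-value <
#' `max_evalue`, bit score > `min_bitscore`, query coverage > `min_qcov` are
#' discarded.  Thresholds are strict inequalities.
#'
#' @param query_proteins `data.frame` with `protein_id` and `seq` (amino
#'   acids), e.g. from [call_orfs()]; a `contig_id` column is carried
#'   through.
#' @param reference_db `data.frame` with `protein_id`, `seq`, `host_group`
#'   (and optionally `gene_label`, `hallmark`).
#' @param min_identity,max_evalue,min_bitscore,min_qcov Filter thresholds.
#' @return `data.frame` of retained best hits.
#' @export
protein_best_hits <- function(query_proteins, reference_db,
                              min_identity = 0.30, max_evalue = 1e-5,
                              min_bitscore = 50, min_qcov = 0.70) {
  if (is.null(reference_db) || nrow(reference_db) == 0L) {
    stop("empty reference database")
  }
  if (nrow(query_proteins) == 0L) return(empty_hits())
  db_res <- sum(nchar(reference_db$seq))
  cand <- protein_candidates(query_proteins$seq, reference_db$seq)
  if (!nrow(cand)) return(empty_hits())
  res <- list()
  for (r in unique(cand$ref)) {
    qs <- cand$query[cand$ref == r]
    a <- align_protein_batch(query_proteins$seq[qs], reference_db$seq[r], db_res)
    a$query <- qs; a$ref <- r
    res[[length(res) + 1L]] <- a
  }
  res <- rbindlist(res)
  setorderv(res, c("query", "bitscore"), c(1L, -1L))
  best <- res[res[, .I[1L], by = "query"]$V1]
  keep <- best$aa_identity > min_identity & best$evalue < max_evalue &
    best$bitscore > min_bitscore & best$query_coverage > min_qcov
  best <- best[keep, ]
  out <- data.frame(
    query_protein = query_proteins$protein_id[best$query],
    subject_protein = reference_db$protein_id[best$ref],
    subject_host_group = reference_db$host_group[best$ref],
    aa_identity = best$aa_identity, evalue = best$evalue,
    bitscore = best$bitscore, query_coverage = best$query_coverage,
    stringsAsFactors = FALSE)
  if (!is.null(query_proteins$contig_id)) {
    out$contig_id <- query_proteins$contig_id[best$query]
  }
  if (!is.null(reference_db$gene_label)) {
    out$subject_gene_label <- reference_db$gene_label[best$ref]
  }
  out
}

empty_hits <- function() {
  data.frame(query_protein = character(0), subject_protein = character(0),
             subject_host_group = character(0), aa_identity = numeric(0),
             evalue = numeric(0), bitscore = numeric(0),
             query_coverage = numeric(0), stringsAsFactors = FALSE)
}

#' Predict the host group of each vOTU from retained homolog hits
#'
#' Counts retained best hits per host group and predicts the group with the
#' most homologs when that count reaches `min_homologs`; ties between groups
#' give `none` (logged as a warning).
#'
#' @param hits Retained hits from [protein_best_hits()].  A `votu_id` (or
#'   `contig_id`) column groups hits per vOTU; without one, all hits are
#'   treated as a single vOTU.
#' @param min_homologs Minimum homolog count for a call (default 3).
#' @return `data.frame` with one row per vOTU: `votu_id`, `predicted_group`,
#'   `n_homologs`.
#' @export
predict_host <- function(hits, min_homologs = 3) {
  if (nrow(hits) == 0L) {
    return(data.frame(votu_id = character(0), predicted_group = character(0),
                      n_homologs = integer(0), stringsAsFactors = FALSE))
  }
  key <- hits$votu_id %||% hits$contig_id
  if (is.null(key)) key <- rep("all", nrow(hits))
  ids <- unique(key)
  out <- lapply(ids, function(v) {
    h <- hits[key == v, , drop = FALSE]
    cnt <- table(h$subject_host_group)
    if (!length(cnt) || max(cnt) < min_homologs) {
      return(data.frame(votu_id = v, predicted_group = "none",
                        n_homologs = if (length(cnt)) max(cnt) else 0L,
                        stringsAsFactors = FALSE))
    }
    top <- names(cnt)[cnt == max(cnt)]
    if (length(top) > 1L) {
      warning("ambiguous host for ", v, ": tie between ",
              paste(top, collapse = " and "))
      return(data.frame(votu_id = v, predicted_group = "none",
                        n_homologs = as.integer(max(cnt)),
                        stringsAsFactors = FALSE))
    }
    data.frame(votu_id = v, predicted_group = top,
               n_homologs = as.integer(max(cnt)), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Hallmark-gene association of a vOTU
#'
#' True iff at least one query protein has a retained best hit (same four
#' thresholds as [protein_best_hits()]) against the hallmark
#' structural/replication gene database.
#'
#' @param query_proteins Proteins of one vOTU (as from [call_orfs()]).
#' @param hallmark_db Hallmark protein `data.frame` (`protein_id`, `seq`,
#'   `host_group`).
#' @param ... Threshold overrides passed to [protein_best_hits()].
#' @return List with `hit` (logical) and `n_hits`.
#' @export
hallmark_match <- function(query_proteins, hallmark_db, ...) {
  h <- protein_best_hits(query_proteins, hallmark_db, ...)
  list(hit = nrow(h) > 0L, n_hits = nrow(h))
}

#' Exhaustive CRISPR spacer scan
#'
#' Finds all matches of each spacer, or its reverse complement, with at most
#' `max_mismatch` substitutions (no indels) against each contig.
#'
#' @param spacers `data.frame` with `spacer_id` and `seq` (20-50 nt), or a
#'   character vector.
#' @param contigs Contig `data.frame`.
#' @param max_mismatch Maximum substitutions (default 2).
#' @return `data.frame` with `spacer_id`, `contig_id`, `position` (0-based
#'   start), `strand`, `mismatches`.
#' @export
crispr_spacer_match <- function(spacers, contigs, max_mismatch = 2) {
  if (!is.data.frame(spacers)) {
    spacers <- data.frame(spacer_id = paste0("spacer_", seq_along(spacers)),
                          seq = spacers, stringsAsFactors = FALSE)
  }
  if (any(nchar(spacers$seq) < 20 | nchar(spacers$seq) > 50)) {
    stop("spacers must be 20-50 nt")
  }
  out <- list()
  for (ci in seq_len(nrow(contigs))) {
    subj <- Biostrings::DNAString(contigs$seq[ci])
    for (si in seq_len(nrow(spacers))) {
      sp <- spacers$seq[si]
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") sp else revcomp(sp)
        m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
        if (!length(m)) next
        st <- Biostrings::start(m)
        mm <- vapply(as.character(m), function(w)
          nchar(pat) - str_matches(pat, w), 1L)
        out[[length(out) + 1L]] <- data.frame(
          spacer_id = spacers$spacer_id[si], contig_id = contigs$id[ci],
          position = st - 1L, strand = strand, mismatches = unname(mm),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(spacer_id = character(0), contig_id = character(0),
                      position = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Protein clustering at >= `min_identity` and >= `min_cov` bidirectional
# coverage: single-linkage components over pairs passing both criteria
# (candidate pairs found by shared amino-acid 5-mers).  Single linkage keeps
# diverged copies of one gene in one cluster when a full-length reference
# bridges them, which a greedy representative scheme does not guarantee.
cluster_proteins <- function(seqs, min_identity = 0.5, min_cov = 0.8) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cand <- protein_candidates(seqs, seqs, min_shared = 1L)
  cand <- cand[cand$query < cand$ref, , drop = FALSE]
  for (j in seq_len(nrow(cand))) {
    i1 <- cand$query[j]; i2 <- cand$ref[j]
    if (find(i1) == find(i2)) next
    a <- align_protein_batch(seqs[i1], seqs[i2], 1)
    span_s <- (a$subject_end - a$subject_start + 1) / nchar(seqs[i2])
    if (a$aa_identity >= min_identity && a$query_coverage >= min_cov &&
        span_s >= min_cov) {
      parent[find(i2)] <- find(i1)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

#' Hypergeometric gene-sharing network
#'
#' Proteins are greedily clustered (>= 50% identity, >= 80% bidirectional
#' coverage); for each genome pair sharing `c` of `N` protein clusters with
#' `a` and `b` clusters each, the edge weight is the hypergeometric tail
#' P(X >= c), pair-corrected: significance = -log10(p * n_pairs).  Edges
#' with significance >= `sig_threshold` are kept and connected components
#' reported as network clusters.
#'
#' @param protein_sets Named list: genome id -> character vector of protein
#'   sequences (or `data.frame` with a `seq` column).
#' @param sig_threshold Minimum significance for an edge (default 1).
#' @param cluster_identity,cluster_cov Protein clustering thresholds.
#' @return List with `edges` (`genome_a`, `genome_b`, `shared_clusters`,
#'   `p_hypergeom`, `significance`), `components` (genome -> component id),
#'   and `n_protein_clusters`.
#' @export
build_gene_sharing_network <- function(protein_sets, sig_threshold = 1,
                                       cluster_identity = 0.5,
                                       cluster_cov = 0.8) {
  stopifnot(length(protein_sets) >= 2L)
  seqs <- unlist(lapply(protein_sets, function(x) {
    if (is.data.frame(x)) x$seq else as.character(x)
  }), use.names = FALSE)
  genome <- rep(names(protein_sets),
                vapply(protein_sets, function(x) if (is.data.frame(x)) nrow(x) else length(x), 1L))
  cl <- cluster_proteins(seqs, cluster_identity, cluster_cov)
  N <- length(unique(cl))
  sets <- lapply(split(cl, genome), unique)
  gn <- names(protein_sets)
  pairs <- combn(gn, 2)
  npairs <- ncol(pairs)
  edges <- lapply(seq_len(npairs), function(j) {
    ga <- pairs[1, j]; gb <- pairs[2, j]
    a <- length(sets[[ga]]); b <- length(sets[[gb]])
    cc <- length(intersect(sets[[ga]], sets[[gb]]))
    p <- if (cc == 0) 1 else phyper(cc - 1, a, N - a, b, lower.tail = FALSE)
    data.frame(genome_a = ga, genome_b = gb, shared_clusters = cc,
               p_hypergeom = p,
               significance = max(0, -log10(p * npairs)),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, c(edges, make.row.names = FALSE))
  kept <- edges[edges$significance >= sig_threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(kept[, c("genome_a", "genome_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = gn))
  comp <- igraph::components(g)$membership
  list(edges = edges,
       components = data.frame(genome = names(comp),
                               component = as.integer(comp),
                               stringsAsFactors = FALSE),
       n_protein_clusters = N)
}
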