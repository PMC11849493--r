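# Putative family demarcation from genome-wide translated similarity:
# normalized summed bit scores of translated local alignments, single-linkage
# clustering at the 0.05 normalized-score threshold.

six_frame_translations <- function(seq) {
  out <- character(6)
  n <- nchar(seq)
  i <- 0L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (off in 0:2) {
      i <- i + 1L
      alen <- floor((n - off) / 3) * 3
      out[i] <- if (alen < 3) "" else as.character(suppressWarnings(
        Biostrings::translate(Biostrings::DNAString(substr(s, off + 1L, off + alen)),
                              if.fuzzy.codon = "solve")))
    }
  }
  out
}

# Bit score of a raw BLOSUM62 local score under the gapped Karlin-Altschul
# parameters used throughout the package.
ka_bits <- function(raw) (KA_LAMBDA * raw - log(KA_K)) / log(2)

# Self-score of a protein fragment: the best contiguous run of BLOSUM62
# diagonal scores (what a local alignment of the fragment against itself
# yields).  Stop codons are treated as X, as in the cross-comparison path.
fragment_self_bits <- function(frag) {
  B <- blosum62()
  aa <- strsplit(frag, "")[[1]]
  aa[aa == "*" | !aa %in% rownames(B)] <- "X"
  d <- B[cbind(aa, aa)]
  best <- 0; run <- 0
  for (x in d) {
    run <- max(0, run + x)
    best <- max(best, run)
  }
  ka_bits(best)
}

# Sum of translated-fragment alignment bit scores of `a` against `b`.
# Fragments of a's six translations are placed on b's six translations by
# shared amino-acid 5-mers and verified with local BLOSUM62 alignment;
# alignments below `min_bits` are treated as noise and dropped.
translated_raw_score <- function(frames_a, frames_b, frag = 60L,
                                 min_frag = 30L, min_bits = 40, k = 5L) {
  b_dt <- rbindlist(lapply(seq_along(frames_b), function(fi) {
    s <- frames_b[fi]
    n <- nchar(s)
    if (n < k) return(data.table(kmer = character(0), frame = integer(0),
                                 pos = integer(0)))
    data.table(kmer = substring(s, 1:(n - k + 1L), k:n), frame = fi,
               pos = 1:(n - k + 1L))
  }))
  setkey(b_dt, kmer)
  total <- 0
  for (fa in frames_a) {
    n <- nchar(fa)
    if (n < min_frag) next
    fs_all <- seq(1L, n, by = frag)
    for (fs in fs_all) {
      fe <- min(fs + frag - 1L, n)
      if (fe - fs + 1L < min_frag) next
      fragment <- substr(fa, fs, fe)
      kms <- unique(substring(fragment, 1:(nchar(fragment) - k + 1L),
                              k:nchar(fragment)))
      hits <- b_dt[J(kms), nomatch = NULL]
      if (nrow(hits) < 2L) next
      tab <- hits[, .N, by = "frame"]
      bf <- tab$frame[which.max(tab$N)]
      hpos <- hits$pos[hits$frame == bf]
      if (length(hpos) < 2L) next
      st <- as.integer(median(hpos)) - (fe - fs) %/% 2L
      tgt <- frames_b[bf]
      wa <- max(1L, st - 2L * frag); wb <- min(nchar(tgt), st + 3L * frag)
      if (wb - wa + 1L < min_frag) next
      window <- substr(tgt, wa, wb)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(gsub("\\*", "X", fragment)),
        Biostrings::AAString(gsub("\\*", "X", window)),
        type = "local", substitutionMatrix = blosum62(),
        gapOpening = 11, gapExtension = 1)
      bits <- ka_bits(Biostrings::score(aln))
      if (bits >= min_bits) total <- total + bits
    }
  }
  total
}

# Self raw score: every fragment matches itself perfectly.
translated_self_score <- function(frames, frag = 60L, min_frag = 30L,
                                  min_bits = 40) {
  total <- 0
  for (fa in frames) {
    n <- nchar(fa)
    if (n < min_frag) next
    for (fs in seq(1L, n, by = frag)) {
      fe <- min(fs + frag - 1L, n)
      if (fe - fs + 1L < min_frag) next
      bits <- fragment_self_bits(substr(fa, fs, fe))
      if (bits >= min_bits) total <- total + bits
    }
  }
  total
}

#' Normalized genome-wide translated similarity
#'
#' The raw score is the sum of bit scores of translated local alignments
#' over all frame pairs; the normalized score divides by the smaller
#' self-score (`norm = "min"`, keeping containment at high similarity) or by
#' the geometric mean of the self-scores (`norm = "geometric"`).
#'
#' @param a,b Single-row contig data.frames or nucleotide strings (>= 1 kb).
#' @param norm Normalization rule.
#' @return One-row `data.frame`: `a_id`, `b_id`, `raw_score`, `normalized`.
#' @export
genome_similarity <- function(a, b, norm = c("min", "geometric")) {
  norm <- match.arg(norm)
  sa <- as_seq(a); sb <- as_seq(b)
  stopifnot(nchar(sa) >= 1000, nchar(sb) >= 1000)
  fa <- six_frame_translations(sa)
  fb <- six_frame_translations(sb)
  raw <- translated_raw_score(fa, fb)
  self_a <- translated_self_score(fa)
  self_b <- translated_self_score(fb)
  denom <- if (norm == "min") min(self_a, self_b) else sqrt(self_a * self_b)
  data.frame(a_id = names(sa), b_id = names(sb), raw_score = raw,
             normalized = min(1, raw / denom), stringsAsFactors = FALSE)
}

#' All-pairs genome similarity for a contig set
#'
#' @param contigs Contig `data.frame`.
#' @param norm Normalization rule, see [genome_similarity()].
#' @return `data.frame` of all unordered pairs with `normalized` scores.
#' @export
genome_similarity_matrix <- function(contigs, norm = "min") {
  frames <- lapply(contigs$seq, six_frame_translations)
  selfs <- vapply(frames, translated_self_score, 1)
  n <- nrow(contigs)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      raw <- translated_raw_score(frames[[i]], frames[[j]])
      denom <- if (norm == "min") min(selfs[i], selfs[j]) else
        sqrt(selfs[i] * selfs[j])
      out[[length(out) + 1L]] <- data.frame(
        a_id = contigs$id[i], b_id = contigs$id[j], raw_score = raw,
        normalized = min(1, raw / denom), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Demarcate putative virus families by single linkage
#'
#' Families are connected components over pairs whose normalized similarity
#' reaches the threshold (default 0.05, the proposed family demarcation for
#' normalized translated genome scores).  With
#' `threshold_is_distance = TRUE` the threshold is interpreted as a distance:
#' pairs join when `1 - normalized <= threshold`.
#'
#' @param similarities Pair table from [genome_similarity_matrix()] (columns
#'   `a_id`, `b_id`, `normalized`).
#' @param threshold Demarcation value (default 0.05).
#' @param ids Optional full id universe (to include unpaired singletons).
#' @param threshold_is_distance Interpret `threshold` as a distance.
#' @return `data.frame` with `votu_id`, `family_id`.
#' @export
cluster_families <- function(similarities, threshold = 0.05, ids = NULL,
                             threshold_is_distance = FALSE) {
  keep <- if (threshold_is_distance) {
    (1 - similarities$normalized) <= threshold
  } else {
    similarities$normalized >= threshold
  }
  edges <- similarities[keep, c("a_id", "b_id"), drop = FALSE]
  if (is.null(ids)) ids <- unique(c(similarities$a_id, similarities$b_id))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  data.frame(votu_id = names(comp),
             family_id = sprintf("family_%03d", as.integer(comp)),
             stringsAsFactors = FALSE)
}

#' Neighbour-joining tree from normalized genome similarities
#'
#' BIONJ on the distance `1 - normalized`; a convenience view of the family
#' structure (single-linkage components at 0.05 remain the demarcation).
#'
#' @param similarities Pair table from [genome_similarity_matrix()].
#' @param ids Optional id universe.
#' @return An `ape::phylo` tree.
#' @export
family_tree <- function(similarities, ids = NULL) {
  if (is.null(ids)) ids <- unique(c(similarities$a_id, similarities$b_id))
  d <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  diag(d) <- 0
  for (i in seq_len(nrow(similarities))) {
    v <- 1 - similarities$normalized[i]
    d[similarities$a_id[i], similarities$b_id[i]] <- v
    d[similarities$b_id[i], similarities$a_id[i]] <- v
  }
  ape::bionj(stats::as.dist(d))
}

#' Count vOTUs and families per host group
#'
#' @param assignment Family assignment from [cluster_families()].
#' @param host_predictions Host predictions (`votu_id`, `predicted_group`).
#' @return `data.frame` per group: `group`, `n_votus`, `n_families`,
#'   `n_mixed_families` (families whose members span several groups).
#' @export
count_families_per_group <- function(assignment, host_predictions) {
  grp <- setNames(host_predictions$predicted_group, host_predictions$votu_id)
  assignment$group <- grp[assignment$votu_id]
  fam_groups <- tapply(assignment$group, assignment$family_id,
                       function(g) length(unique(g[!is.na(g)])))
  mixed <- names(fam_groups)[fam_groups > 1]
  groups <- unique(assignment$group[!is.na(assignment$group)])
  out <- lapply(sort(groups), function(g) {
    sel <- assignment[!is.na(assignment$group) & assignment$group == g, ]
    data.frame(group = g, n_votus = nrow(sel),
               n_families = length(unique(sel$family_id)),
               n_mixed_families = length(intersect(unique(sel$family_id), mixed)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
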