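# vOTU clustering at the MIUViG thresholds: species-rank clusters at >= 95%
# average nucleotide identity over >= 85% of the shorter contig, greedy
# centroid clustering processed longest-first.

as_seq <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, "seq" %in% names(x))
    setNames(toupper(x$seq), x$id)
  } else {
    s <- setNames(toupper(as.character(x)), names(x))
    if (is.null(names(s))) names(s) <- NA_character_
    s
  }
}

# Fragment-based merged-local-alignment similarity between two contigs.
# The shorter sequence is cut into `frag`-bp windows; each window is placed on
# the longer sequence by exact 15-mer diagonal vote (both strands) and
# verified ungapped.  Identity is matches over aligned columns summed across
# placed windows; coverage is the placed fraction of the shorter contig.
similarity_engine <- function(sa, sb, k = 15L, frag = 500L,
                              min_frag_identity = 0.3, min_frag_len = 30L) {
  if (nchar(sa) <= nchar(sb)) { s <- sa; l <- sb } else { s <- sb; l <- sa }
  ns <- nchar(s); nl <- nchar(l)
  s_codes <- kmer_codes(s, k)
  l_codes <- kmer_codes(l, k)
  lrc <- revcomp(l)
  lrc_codes <- kmer_codes(lrc, k)
  # N-containing windows must never seed: sentinel out the reference NAs so
  # NA query codes cannot match them.
  l_codes[is.na(l_codes)] <- -1L
  lrc_codes[is.na(lrc_codes)] <- -1L
  m_plus <- match(s_codes, l_codes)
  m_minus <- match(s_codes, lrc_codes)
  tot_match <- 0; tot_cols <- 0; covered <- 0L
  fs_all <- seq(1L, ns, by = frag)
  for (fs in fs_all) {
    fe <- min(fs + frag - 1L, ns)
    flen <- fe - fs + 1L
    if (flen < min_frag_len) next
    kpos <- fs:min(fe - k + 1L, length(s_codes))
    kpos <- kpos[kpos >= 1L]
    if (!length(kpos)) next
    best <- NULL
    for (strand in c("+", "-")) {
      m <- if (strand == "+") m_plus[kpos] else m_minus[kpos]
      hit <- which(!is.na(m))
      if (!length(hit)) next
      startv <- m[hit] - (kpos[hit] - fs)
      tab <- sort(table(startv), decreasing = TRUE)
      st <- as.integer(names(tab)[1L])
      votes <- as.integer(tab[1L])
      tgt <- if (strand == "+") l else lrc
      a <- max(1L, st); b <- min(nl, st + flen - 1L)
      if (b < a) next
      fpart <- substr(s, fs + (a - st), fs + (b - st))
      tpart <- substr(tgt, a, b)
      mt <- str_matches(fpart, tpart)
      cols <- b - a + 1L
      cand <- list(matches = mt, cols = cols, votes = votes)
      if (is.null(best) || cand$matches > best$matches) best <- cand
    }
    if (!is.null(best) && best$matches / best$cols >= min_frag_identity) {
      tot_match <- tot_match + best$matches
      tot_cols <- tot_cols + best$cols
      covered <- covered + best$cols
    }
  }
  list(identity = if (tot_cols > 0) tot_match / tot_cols else 0,
       coverage = min(1, covered / ns))
}

#' Pairwise contig similarity (identity and coverage)
#'
#' Identity is matches over aligned columns summed across merged local
#' alignments on both strands; coverage is the aligned fraction of the
#' shorter contig (MIUViG convention).
#'
#' @param a,b Single-row contig data.frames (as from [read_fasta()]) or
#'   nucleotide strings.
#' @param frag Window size (bp) used for local placement.
#' @return A one-row `data.frame` with `a_id`, `b_id`, `identity`,
#'   `coverage`.
#' @export
pairwise_similarity <- function(a, b, frag = 500L) {
  sa <- as_seq(a); sb <- as_seq(b)
  stopifnot(nchar(sa) > 0, nchar(sb) > 0)
  r <- similarity_engine(sa, sb, frag = frag)
  data.frame(a_id = names(sa), b_id = names(sb),
             identity = r$identity, coverage = r$coverage,
             stringsAsFactors = FALSE)
}

#' Greedy vOTU clustering
#'
#' Contigs are processed longest-first (ties broken lexicographically by id);
#' a contig joins the first existing representative it matches at both
#' thresholds, otherwise it founds a new vOTU.  On transitive inputs the
#' result equals single-linkage connected components.
#'
#' @param contigs Contig `data.frame` from [read_fasta()] or
#'   [contig_table()].
#' @param id_threshold Minimum identity (default 0.95).
#' @param cov_threshold Minimum coverage of the shorter contig (default
#'   0.85).
#' @param min_len Minimum contig length admitted (default 10000 bp).
#' @return A list of class `votu_set` with elements `votus` (one row per
#'   vOTU: `votu_id`, `representative_id`, `n_members`, `length`, `gc`) and
#'   `membership` (`votu_id`, `member_id`).
#' @export
cluster_votus <- function(contigs, id_threshold = 0.95, cov_threshold = 0.85,
                          min_len = 10000) {
  stopifnot(is.data.frame(contigs), nrow(contigs) > 0)
  contigs <- contigs[contigs$length >= min_len, , drop = FALSE]
  if (nrow(contigs) == 0L) stop("no contigs of length >= ", min_len)
  ord <- order(-contigs$length, contigs$id)
  contigs <- contigs[ord, , drop = FALSE]
  reps <- integer(0)          # row indices of representatives
  assign <- integer(nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    placed <- FALSE
    for (r in reps) {
      sim <- similarity_engine(contigs$seq[i], contigs$seq[r])
      if (sim$identity >= id_threshold && sim$coverage >= cov_threshold) {
        assign[i] <- r; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, i); assign[i] <- i }
  }
  rep_ids <- contigs$id[sort(unique(assign))]
  votu_id <- sprintf("vOTU_%04d", seq_along(rep_ids))
  names(votu_id) <- rep_ids
  membership <- data.frame(
    votu_id = votu_id[contigs$id[assign]],
    member_id = contigs$id,
    stringsAsFactors = FALSE
  )
  idx <- sort(unique(assign))
  votus <- data.frame(
    votu_id = votu_id[contigs$id[idx]],
    representative_id = contigs$id[idx],
    n_members = as.integer(table(factor(assign, levels = idx))),
    length = contigs$length[idx],
    gc = contigs$gc[idx],
    stringsAsFactors = FALSE
  )
  structure(list(votus = votus, membership = membership), class = "votu_set")
}

#' @export
print.votu_set <- function(x, ...) {
  cat("votu_set:", nrow(x$votus), "vOTUs from", nrow(x$membership),
      "contigs\n")
  print(head(x$votus, 5), row.names = FALSE)
  invisible(x)
}

#' Flag lysogenic potential from marker annotations
#'
#' A vOTU is flagged lysogenic when at least one protein of its
#' representative carries an integrase, excisionase or CI-like repressor
#' annotation keyword.
#'
#' @param votus A `votu_set` from [cluster_votus()].
#' @param gene_annotations `data.frame` with columns `contig_id` and
#'   `annotation` (free-text labels, e.g. best-hit subject gene names).
#' @return The `votu_set` with a logical `is_lysogenic` column added to
#'   `$votus`.
#' @export
annotate_lifestyle <- function(votus, gene_annotations) {
  stopifnot(inherits(votus, "votu_set"),
            all(c("contig_id", "annotation") %in% names(gene_annotations)))
  marker <- grepl("integrase|excisionase|repressor", gene_annotations$annotation,
                  ignore.case = TRUE)
  lys_contigs <- unique(gene_annotations$contig_id[marker])
  votus$votus$is_lysogenic <- votus$votus$representative_id %in% lys_contigs
  votus
}
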