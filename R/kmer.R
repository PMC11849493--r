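# Seed-and-extend nucleotide engine.
#
# All nucleotide comparison in the package (vOTU similarity, read recruitment,
# core-gene mapping) runs on exact k-mer seeds encoded as base-4 integers
# (k = 15 fits in 30 bits), followed by ungapped verification on the seeded
# diagonal.  The synthetic read and divergence models are substitution-only,
# and the identity/coverage contracts are defined over merged ungapped local
# alignments, so a diagonal extender satisfies them.

# Integer codes of all k-mers of one string; NA where a window contains a
# non-ACGT character.  Overflow-safe: 4^15 - 1 < 2^31 - 1.
kmer_codes <- function(seq, k = 15L) {
  v <- utf8ToInt(seq)
  n <- length(v) - k + 1L
  if (n < 1L) return(integer(0))
  lut <- rep(NA_integer_, 128L)
  lut[c(65L, 67L, 71L, 84L)] <- 0:3
  code <- lut[v]
  out <- code[seq_len(n)]
  for (j in 2:k) out <- out * 4L + code[j:(n + j - 1L)]
  out
}

# Seed index over a set of reference sequences.  Sequences are concatenated
# with k-long N spacers so no k-mer spans two references; duplicate k-mers
# keep their first occurrence.
build_kmer_index <- function(seqs, k = 15L, stride = 1L) {
  seqs <- toupper(seqs)
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  lens <- nchar(seqs)
  cat <- paste(seqs, collapse = strrep("N", k))
  starts <- cumsum(c(1L, head(lens + k, -1L)))  # global start of each seq
  codes <- kmer_codes(cat, k)
  keep <- which(!is.na(codes))
  if (stride > 1L) keep <- keep[(keep - 1L) %% stride == 0L]
  list(codes = codes[keep], gpos = keep, starts = starts, ids = names(seqs),
       lens = lens, seqs = seqs, k = k)
}

# Locate the global position of a hit: which reference and local coordinate.
index_locate <- function(index, gpos) {
  si <- findInterval(gpos, index$starts)
  list(seq_idx = si, local = gpos - index$starts[si] + 1L)
}

# Count character matches between two equal-length strings.
str_matches <- function(a, b) sum(utf8ToInt(a) == utf8ToInt(b))

# Map one strand of a read set against the index.  Returns a data.table of
# diagonal candidates with vote support, one row per (read, ref, start).
seed_candidates <- function(read_seqs, index, read_stride = 4L) {
  k <- index$k
  rl <- nchar(read_seqs)
  cat <- paste(read_seqs, collapse = strrep("N", k))
  codes <- kmer_codes(cat, k)
  rstarts <- cumsum(c(1L, head(rl + k, -1L)))
  qpos <- which(!is.na(codes))
  if (read_stride > 1L) {
    ri0 <- findInterval(qpos, rstarts)
    inread0 <- qpos - rstarts[ri0] + 1L
    sel <- (inread0 - 1L) %% read_stride == 0L
    qpos <- qpos[sel]
  }
  if (!length(qpos)) return(data.table(read = integer(0), ref = integer(0),
                                       start = integer(0), N = integer(0)))
  m <- match(codes[qpos], index$codes)
  hit <- !is.na(m)
  qpos <- qpos[hit]; m <- m[hit]
  if (!length(qpos)) return(data.table(read = integer(0), ref = integer(0),
                                       start = integer(0), N = integer(0)))
  ri <- findInterval(qpos, rstarts)
  inread <- qpos - rstarts[ri] + 1L
  loc <- index_locate(index, index$gpos[m])
  dt <- data.table(read = ri, ref = loc$seq_idx,
                   start = loc$local - inread + 1L)
  dt[, .N, by = c("read", "ref", "start")]
}

# Verify a candidate diagonal: ungapped comparison of the read against the
# reference window, clipped at reference ends.
verify_candidates <- function(cand, read_seqs, index, min_read_frac = 0.9) {
  n <- nrow(cand)
  ident <- numeric(n); alen <- integer(n); s_out <- integer(n)
  rl <- nchar(read_seqs)
  for (i in seq_len(n)) {
    rd <- read_seqs[cand$read[i]]
    L <- rl[cand$read[i]]
    ref <- index$seqs[cand$ref[i]]
    st <- cand$start[i]
    s <- max(1L, st); e <- min(index$lens[cand$ref[i]], st + L - 1L)
    al <- e - s + 1L
    if (al < ceiling(min_read_frac * L)) { ident[i] <- -1; next }
    rpart <- substr(rd, s - st + 1L, e - st + 1L)
    wpart <- substr(ref, s, e)
    mt <- str_matches(rpart, wpart)
    ident[i] <- mt / al; alen[i] <- al; s_out[i] <- s
  }
  cand$identity <- ident; cand$alen <- alen; cand$ref_start <- s_out
  cand[cand$identity >= 0, ]
}

# Best placement per read over both strands.  Reads whose top identity is
# tied between two references are dropped (conservative multi-mapping rule).
map_reads <- function(read_seqs, index, min_identity = 0.9,
                      min_read_frac = 0.9, read_stride = 4L) {
  read_seqs <- toupper(read_seqs)
  empty <- data.frame(read = integer(0), ref_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0))
  if (!length(read_seqs)) return(empty)
  res <- list()
  for (strand in c("+", "-")) {
    rs <- if (strand == "+") read_seqs else revcomp(read_seqs)
    cand <- seed_candidates(rs, index, read_stride)
    if (!nrow(cand)) next
    setorderv(cand, c("read", "N"), c(1L, -1L))
    cand <- cand[cand[, .I[N == N[1L]][seq_len(min(3L, sum(N == N[1L])))],
                      by = "read"]$V1]
    cand <- verify_candidates(cand, rs, index, min_read_frac)
    if (nrow(cand)) { cand$strand <- strand; res[[strand]] <- cand }
  }
  if (!length(res)) return(empty)
  all <- rbindlist(res)
  all <- all[all$identity >= min_identity, ]
  if (!nrow(all)) return(empty)
  setorderv(all, c("read", "identity"), c(1L, -1L))
  pick <- all[, {
    ok <- !(.N > 1L && identity[2L] == identity[1L] && ref[2L] != ref[1L])
    if (ok) .SD[1L] else .SD[0L]
  }, by = "read"]
  data.frame(read = pick$read, ref_id = index$ids[pick$ref],
             start = pick$ref_start,
             end = pick$ref_start + pick$alen - 1L,
             strand = pick$strand, identity = pick$identity,
             stringsAsFactors = FALSE)
}
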