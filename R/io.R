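# Readers and writers for the formats the pipeline touches.  All downstream
# modules consume the plain data.frame types returned here; coordinates in any
# emitted feature table are 0-based half-open.

TREATMENTS <- c("control", "urea", "urea_dmpp", "urea_octyne", "urea_acetylene")
NITRIFIER_GROUPS <- c("AOA", "AOB", "Nitrospira")

#' Read a nucleotide FASTA into a contig table
#'
#' Contig ids are the first whitespace-delimited token of each header and must
#' be unique.  Sequences are uppercased; GC is computed over non-N bases.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return A `data.frame` with columns `id`, `seq`, `length`, `gc`, in file
#'   order.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id in ", path, ": ", dup[1L])
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for id ", ids[which(nchar(seqs) == 0L)[1L]])
  }
  contig_table(ids, seqs)
}

#' Build a contig table from ids and sequences
#'
#' @param id Character vector of unique contig ids.
#' @param seq Nucleotide sequences (uppercased on entry).
#' @return The standard contig `data.frame` (`id`, `seq`, `length`, `gc`).
#' @export
contig_table <- function(id, seq) {
  data.frame(
    id = as.character(id), seq = toupper(as.character(seq)),
    length = nchar(seq), gc = gc_content(seq),
    stringsAsFactors = FALSE
  )
}

#' Write a contig table (or named sequences) as FASTA
#'
#' @param x A contig `data.frame` with `id` and `seq` columns, or a named
#'   character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) {
    seqs <- setNames(x$seq, x$id)
  } else {
    seqs <- x
  }
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read FASTQ reads
#'
#' Per-base qualities are parsed but ignored by all downstream computation
#' (inputs are assumed quality-filtered).
#'
#' @param path Path to a FASTQ file.
#' @return A `data.frame` with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  if (length(ss) == 0L) stop("no FASTQ records in ", path)
  data.frame(
    id = sub("\\s.*$", "", names(ss)),
    seq = toupper(as.character(ss)),
    qual = as.character(S4Vectors::mcols(ss)$qualities),
    stringsAsFactors = FALSE
  )
}

#' Write reads as FASTQ
#'
#' @param reads A `data.frame` with `id` and `seq` (and optionally `qual`)
#'   columns.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  if (is.null(qual)) qual <- strrep("I", nchar(reads$seq))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), con)
  invisible(path)
}

#' Read the sample/treatment design table
#'
#' Expects a TSV with header columns `sample_id`, `treatment`, `day`,
#' `replicate`.  Treatments must be one of `control`, `urea`, `urea_dmpp`,
#' `urea_octyne`, `urea_acetylene`; `(treatment, day, replicate)` must be
#' unique.
#'
#' @param path Path to the design TSV.
#' @return A validated `data.frame` of the design rows.
#' @export
read_design <- function(path) {
  stopifnot(file.exists(path))
  d <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                error = function(e) stop("no samples in ", path))
  if (nrow(d) == 0L) stop("no samples in ", path)
  need <- c("sample_id", "treatment", "day", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("design table missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(d$treatment), TREATMENTS)
  if (length(bad)) {
    stop("unknown treatment '", bad[1L], "'; allowed: ",
         paste(TREATMENTS, collapse = ", "))
  }
  key <- paste(d$treatment, d$day, d$replicate)
  if (anyDuplicated(key)) stop("duplicate (treatment, day, replicate) rows")
  d
}

#' The standard incubation design
#'
#' Triplicate microcosms for five treatments sampled at day 30 plus a
#' triplicate day-0 baseline (viromes and amplicon profiles exist for days 0
#' and 30 only).
#'
#' @param replicates Replicates per treatment-day (default 3).
#' @return A design `data.frame` (18 rows at the default).
#' @export
default_design <- function(replicates = 3) {
  d30 <- expand.grid(treatment = TREATMENTS, replicate = seq_len(replicates),
                     stringsAsFactors = FALSE)
  d30$day <- 30L
  d0 <- data.frame(treatment = "control", replicate = seq_len(replicates),
                   day = 0L, stringsAsFactors = FALSE)
  d <- rbind(d0, d30)
  d$sample_id <- sprintf("d%02d_%s_r%d", d$day, d$treatment, d$replicate)
  d[, c("sample_id", "treatment", "day", "replicate")]
}

#' Read an ASV relative-abundance table
#'
#' TSV with columns `sample_id`, `group`, `rel_abund`; groups are `AOA`,
#' `AOB`, `Nitrospira` or `other` and per-sample abundances must sum to at
#' most 1 (plus rounding slack).
#'
#' @param path Path to the TSV.
#' @return A validated `data.frame`.
#' @export
read_asv_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "rel_abund")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("ASV table missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(d$group), c(NITRIFIER_GROUPS, "other"))
  if (length(bad)) stop("unknown group '", bad[1L], "'")
  sums <- tapply(d$rel_abund, d$sample_id, sum)
  if (any(sums > 1 + 1e-6)) stop("per-sample relative abundances exceed 1")
  d
}

#' Write a table as TSV with fixed float precision
#'
#' Numeric columns are rendered with `digits` decimals, rounded half-up; all
#' rows must share the same columns.
#'
#' @param records A `data.frame` (or list of equal-length rows coercible to
#'   one).
#' @param path Output path.
#' @param digits Decimals used for non-integer numeric columns (default 4).
#' @export
write_table <- function(records, path, digits = 4) {
  if (!is.data.frame(records)) {
    lens <- vapply(records, length, 1L)
    if (length(unique(lens)) > 1L) stop("ragged rows: differing column counts")
    records <- tryCatch(as.data.frame(records, stringsAsFactors = FALSE),
                        error = function(e) stop("ragged rows"))
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(round_half_up(out[[j]], digits), format = "f",
                          digits = digits)
      # trim trailing zeros but keep at least one decimal
      out[[j]] <- sub("(\\.\\d*?)0+$", "\\1", out[[j]])
      out[[j]] <- sub("\\.$", ".0", out[[j]])
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Percentage in the summary-table reporting style
#'
#' @param count Numerator count.
#' @param total Denominator total (> 0).
#' @return `100 * count / total` rounded half-up to 1 decimal.
#' @examples
#' summarize_percent(200, 17817) # 1.1
#' summarize_percent(38, 39)     # 97.4
#' @export
summarize_percent <- function(count, total) {
  if (any(total <= 0)) stop("total must be > 0")
  round_half_up(100 * count / total, 1)
}

# Render a percent the way the summary tables print it: integer when the
# decimal is zero ("37%"), else one decimal ("1.1%").
format_percent <- function(p) {
  ifelse(p == floor(p), sprintf("%d%%", as.integer(p)), sprintf("%.1f%%", p))
}
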