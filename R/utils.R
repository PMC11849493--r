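#' @importFrom stats aov TukeyHSD kruskal.test pchisq pnorm p.adjust phyper
#'   lm coef confint rnorm runif rbinom setNames sd var median qt rlnorm
#'   anova as.formula complete.cases quantile
#' @importFrom utils head read.delim write.table combn data
#' @import data.table
NULL

# Round half-up at `digits` decimals (reporting convention: 97.4%, 2.8-fold).
# base::round() rounds half-to-even, which is not how the summary tables are
# rendered.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Character vector of A/C/G/T/N strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' GC content over non-N bases
#'
#' @param seq Character vector of nucleotide strings.
#' @return Numeric vector of GC fractions in \[0, 1\]; NA for sequences with
#'   no non-N bases.
#' @export
gc_content <- function(seq) {
  ss <- Biostrings::DNAStringSet(toupper(seq))
  f <- Biostrings::letterFrequency(ss, letters = c("A", "C", "G", "T"))
  tot <- rowSums(f)
  ifelse(tot == 0, NA_real_, (f[, "C"] + f[, "G"]) / tot)
}

# Derive a bounded per-stage seed from a global seed.  Keeps every derived
# seed strictly below 2^31 - 1.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + offset * 104729) %% 2147483629 + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
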