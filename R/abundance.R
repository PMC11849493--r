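# Read recruitment, strict/relaxed detection, RPKM, group-level enrichment
# statistics and the host-virus regression behind the treatment comparisons.

#' Recruit reads to contigs
#'
#' Each read is placed at its best location (both strands) and counted only
#' if its alignment identity reaches `min_identity` over at least 90% of the
#' read length; ties between contigs are dropped.  Depth is incremented over
#' the aligned span.
#'
#' @param reads Read `data.frame` (`id`, `seq`) or character vector.
#' @param contigs Contig `data.frame`.
#' @param min_identity Per-read identity floor (0.95 strict runs, 0.90
#'   relaxed runs).
#' @param sample_id Sample label carried into the profiles.
#' @return List with `profiles` (`sample_id`, `contig_id`, `mapped_reads`,
#'   `breadth`, `mean_depth`, `min_read_identity_used`), `depth` (named list
#'   of per-base depth vectors), and `assignments` (per-read placements).
#' @export
recruit_reads <- function(reads, contigs, min_identity = 0.95,
                          sample_id = "sample") {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  index <- build_kmer_index(setNames(contigs$seq, contigs$id))
  depth <- lapply(setNames(contigs$length, contigs$id), numeric)
  if (length(seqs)) {
    asg <- map_reads(seqs, index, min_identity = min_identity)
  } else {
    asg <- map_reads(character(0), index)
  }
  if (nrow(asg)) {
    for (cid in unique(asg$ref_id)) {
      sel <- asg$ref_id == cid
      L <- contigs$length[contigs$id == cid]
      d <- tabulate(asg$start[sel], nbins = L + 1L) -
        tabulate(pmin(asg$end[sel] + 1L, L + 1L), nbins = L + 1L)
      depth[[cid]] <- cumsum(d)[seq_len(L)]
    }
  }
  profiles <- data.frame(
    sample_id = sample_id, contig_id = contigs$id,
    mapped_reads = as.integer(table(factor(asg$ref_id, levels = contigs$id))),
    breadth = vapply(depth[contigs$id], function(d) mean(d >= 1), 1),
    mean_depth = vapply(depth[contigs$id], mean, 1),
    min_read_identity_used = min_identity,
    stringsAsFactors = FALSE)
  list(profiles = profiles, depth = depth, assignments = asg)
}

#' Strict or relaxed vOTU detection
#'
#' Strict detection requires breadth >= 0.85 in a profile computed at 95%
#' read identity; relaxed requires breadth >= 0.10 at 90% identity.  No
#' rounding is applied before the comparison.
#'
#' @param profile One or more rows of a recruitment profile.
#' @param mode `"strict"` or `"relaxed"`.
#' @return Logical vector.
#' @export
detect_votu <- function(profile, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  need_id <- if (mode == "strict") 0.95 else 0.90
  if (any(abs(profile$min_read_identity_used - need_id) > 1e-9)) {
    stop(mode, " detection requires profiles at ", need_id, " read identity")
  }
  thr <- if (mode == "strict") 0.85 else 0.10
  profile$breadth >= thr
}

#' Reads per kilobase per million mapped reads
#'
#' @param mapped_reads Read count per contig.
#' @param contig_length_bp Contig length (> 0).
#' @param library_size Total mapped reads in the library (> 0).
#' @return `mapped_reads / (contig_length_bp/1000) / (library_size/1e6)`.
#' @export
compute_rpkm <- function(mapped_reads, contig_length_bp, library_size) {
  if (any(contig_length_bp <= 0)) stop("zero-length contig")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  mapped_reads / (contig_length_bp / 1000) / (library_size / 1e6)
}

#' Per-sample, per-host-group virus abundance
#'
#' Sums RPKM over vOTUs by predicted host group and joins the host relative
#' abundance from the ASV table.  vOTUs with predicted group `none` are
#' excluded from all groups.
#'
#' @param profiles Recruitment profiles over samples (rows with `sample_id`,
#'   `contig_id`, `mapped_reads`); contig lengths are taken from `contigs`.
#' @param host_predictions Output of [predict_host()] (votu_id here is the
#'   contig/representative id).
#' @param asv_table ASV table (`sample_id`, `group`, `rel_abund`).
#' @param contigs Contig `data.frame` for lengths.
#' @param library_sizes Optional named per-sample library sizes; defaults to
#'   total mapped reads per sample.
#' @return `data.frame` with `sample_id`, `group`, `rpkm_sum`,
#'   `host_rel_abund`.
#' @export
group_abundance <- function(profiles, host_predictions, asv_table, contigs,
                            library_sizes = NULL) {
  miss <- setdiff(unique(profiles$sample_id), unique(asv_table$sample_id))
  if (length(miss)) stop("sample missing from ASV table: ", miss[1L])
  pred <- setNames(host_predictions$predicted_group, host_predictions$votu_id)
  profiles$group <- pred[profiles$contig_id]
  profiles$group[is.na(profiles$group)] <- "none"
  profiles$length <- contigs$length[match(profiles$contig_id, contigs$id)]
  if (is.null(library_sizes)) {
    library_sizes <- tapply(profiles$mapped_reads, profiles$sample_id, sum)
  }
  profiles$rpkm <- compute_rpkm(profiles$mapped_reads, profiles$length,
                                as.numeric(library_sizes[profiles$sample_id]))
  groups <- intersect(NITRIFIER_GROUPS, unique(asv_table$group))
  out <- expand.grid(sample_id = unique(profiles$sample_id), group = groups,
                     stringsAsFactors = FALSE)
  out$rpkm_sum <- mapply(function(s, g) {
    sum(profiles$rpkm[profiles$sample_id == s & profiles$group == g])
  }, out$sample_id, out$group)
  out$host_rel_abund <- mapply(function(s, g) {
    v <- asv_table$rel_abund[asv_table$sample_id == s & asv_table$group == g]
    if (length(v)) sum(v) else NA_real_
  }, out$sample_id, out$group)
  out[order(out$group, out$sample_id), ]
}

#' Fold change between day-0 and day-30 values
#'
#' @param day0_values,day30_values Numeric vectors of replicate values.
#' @return List with `fold` (mean ratio rounded half-up to 1 decimal),
#'   `mean_day0`, `mean_day30`, `se_day0`, `se_day30`.
#' @export
fold_change <- function(day0_values, day30_values) {
  m0 <- mean(day0_values); m30 <- mean(day30_values)
  if (m0 <= 0) stop("undefined fold change: zero (or negative) baseline")
  se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  list(fold = round_half_up(m30 / m0, 1), mean_day0 = m0, mean_day30 = m30,
       se_day0 = se(day0_values), se_day30 = se(day30_values))
}

# Dunn's rank-based post-hoc test with tie correction; two-sided p values.
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rb <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  gl <- levels(groups)
  pairs <- combn(gl, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sigma <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (rb[[a]] - rb[[b]]) / sigma
    data.frame(group_a = a, group_b = b, statistic = z,
               p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Compact letter display by insert-and-absorb over a pairwise significance
# table: groups not sharing a letter differ significantly.
letter_display <- function(group_names, pairs, alpha = 0.05) {
  sig <- pairs[pairs$p_adj < alpha, , drop = FALSE]
  letters_list <- list(group_names)  # start: everyone in one letter
  for (i in seq_len(nrow(sig))) {
    a <- sig$group_a[i]; b <- sig$group_b[i]
    for (j in seq_along(letters_list)) {
      set <- letters_list[[j]]
      if (a %in% set && b %in% set) {
        letters_list[[j]] <- setdiff(set, a)
        cand <- setdiff(set, b)
        absorbed <- any(vapply(letters_list, function(s) all(cand %in% s), TRUE))
        if (!absorbed) letters_list[[length(letters_list) + 1L]] <- cand
      }
    }
    # drop letter sets wholly contained in another
    keep <- !vapply(seq_along(letters_list), function(j) {
      any(vapply(seq_along(letters_list), function(k) {
        k != j && all(letters_list[[j]] %in% letters_list[[k]]) &&
          length(letters_list[[k]]) > length(letters_list[[j]])
      }, TRUE))
    }, TRUE)
    letters_list <- letters_list[keep]
  }
  lab <- vapply(group_names, function(g) {
    paste(letters[which(vapply(letters_list, function(s) g %in% s, TRUE))],
          collapse = "")
  }, "")
  lab
}

#' Multi-group comparison with variance-guided test choice
#'
#' A Levene test (alpha = 0.05, median-centred) selects Tukey's HSD on an
#' ANOVA fit when variances are homogeneous, otherwise Kruskal-Wallis with
#' Dunn's post-hoc test and Holm adjustment.  A compact letter display is
#' attached: groups sharing no letter differ at `alpha`.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (>= 2 groups, >= 2 replicates each).
#' @param alpha Significance level for the letters (default 0.05).
#' @return List of class `group_comparison`: `method` ("tukey" or "dunn"),
#'   `levene_p`, `pairs` (`group_a`, `group_b`, `p_adj`), `letters`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 replicates")
  lev <- car::leveneTest(values ~ groups)
  levene_p <- lev[["Pr(>F)"]][1L]
  if (levene_p >= 0.05) {
    method <- "tukey"
    fit <- aov(values ~ groups)
    tk <- TukeyHSD(fit)$groups
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairs <- data.frame(group_a = vapply(nm, `[`, "", 1L),
                        group_b = vapply(nm, `[`, "", 2L),
                        estimate = tk[, "diff"], p_adj = tk[, "p adj"],
                        stringsAsFactors = FALSE)
  } else {
    method <- "dunn"
    dn <- dunn_test(values, groups)
    pairs <- data.frame(group_a = dn$group_a, group_b = dn$group_b,
                        estimate = dn$statistic,
                        p_adj = p.adjust(dn$p, "holm"),
                        stringsAsFactors = FALSE)
  }
  rownames(pairs) <- NULL
  structure(list(method = method, levene_p = levene_p, pairs = pairs,
                 letters = letter_display(levels(groups), pairs, alpha),
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group_comparison (", x$method, "; Levene p = ",
      signif(x$levene_p, 3), ")\n", sep = "")
  print(x$pairs, row.names = FALSE)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = " "), "\n")
  invisible(x)
}

#' Ordinary least squares of virus abundance on host abundance
#'
#' @param host Host relative abundances (>= 3 paired samples).
#' @param virus Virus abundances (e.g. group RPKM sums).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `conf_int` (95% CI of the slope), `n`.
#' @export
host_virus_regression <- function(host, virus) {
  ok <- complete.cases(host, virus)
  host <- host[ok]; virus <- virus[ok]
  if (length(host) < 3L) stop("need at least 3 paired samples")
  if (var(host) == 0) stop("zero variance in host abundance")
  fit <- lm(virus ~ host)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2L, 4L],
       conf_int = unname(confint(fit)[2L, ]), n = length(host))
}

#' Per-treatment enrichment calls versus the day-0 baseline
#'
#' For one host group's virus abundances across samples, compares day-30
#' treatments and the day-0 baseline with [compare_groups()] on log-scale
#' values, and calls a treatment enriched when its adjusted p versus day 0 is
#' below `alpha`, the day-30 mean exceeds day 0, and the fold change is at
#' least `min_fold` (effect-size floor of differential-abundance practice).
#'
#' @param values Abundance values (one host group).
#' @param design Design rows matching `values` (columns `treatment`, `day`).
#' @param alpha Significance level.
#' @param min_fold Fold-change floor (default 1.5).
#' @return `data.frame` per treatment: `treatment`, `fold`, `p_adj`,
#'   `enriched`; plus the underlying comparison as attribute `comparison`.
#' @export
enrichment_calls <- function(values, design, alpha = 0.05, min_fold = 1.5) {
  stopifnot(length(values) == nrow(design))
  grp <- ifelse(design$day == 0, "day0", design$treatment)
  eps <- min(values[values > 0], na.rm = TRUE) / 2
  cmp <- compare_groups(log(values + eps), grp, alpha)
  base <- values[grp == "day0"]
  tr <- setdiff(unique(grp), "day0")
  out <- lapply(tr, function(t) {
    p <- cmp$pairs
    row <- p[(p$group_a == t & p$group_b == "day0") |
             (p$group_a == "day0" & p$group_b == t), , drop = FALSE]
    fc <- fold_change(base, values[grp == t])
    data.frame(treatment = t, fold = fc$mean_day30 / fc$mean_day0,
               p_adj = row$p_adj[1L],
               enriched = row$p_adj[1L] < alpha &&
                 fc$mean_day30 > fc$mean_day0 &&
                 fc$mean_day30 / fc$mean_day0 >= min_fold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(out, "comparison") <- cmp
  out
}
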