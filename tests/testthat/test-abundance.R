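test_that("RPKM follows its closed form and scaling laws", {
  expect_equal(compute_rpkm(100, 10000, 1e6), 10)
  expect_equal(compute_rpkm(0, 10000, 1e6), 0)
  expect_equal(compute_rpkm(100, 10000, 2e6), 5)   # doubling library halves
  expect_equal(compute_rpkm(200, 10000, 2e6),       # duplicated reads +
               compute_rpkm(100, 10000, 1e6))       # doubled library: same
  expect_error(compute_rpkm(10, 0, 1e6), "zero-length")
})

test_that("detection thresholds are inclusive and unrounded", {
  pr <- function(b, id) data.frame(breadth = b, min_read_identity_used = id)
  expect_true(detect_votu(pr(0.86, 0.95), "strict"))
  expect_true(detect_votu(pr(0.85, 0.95), "strict"))
  expect_false(detect_votu(pr(0.849999, 0.95), "strict"))
  expect_true(detect_votu(pr(0.12, 0.90), "relaxed"))
  expect_false(detect_votu(pr(0.0999, 0.90), "relaxed"))
  expect_error(detect_votu(pr(0.9, 0.90), "strict"), "0.95")
  expect_error(detect_votu(pr(0.9, 0.95), "relaxed"), "0.9")
})

test_that("read recruitment maps error-free reads to their source only", {
  set.seed(121)
  contigs <- contig_table(c("A", "B"), c(random_seq(12000), random_seq(12000)))
  starts <- seq(1, 12000 - 150, by = 40)  # ~3.7x tiling coverage of A
  reads <- substring(contigs$seq[1], starts, starts + 149)
  rr <- recruit_reads(reads, contigs, min_identity = 0.95)
  p <- rr$profiles
  expect_equal(p$mapped_reads[p$contig_id == "A"], length(starts))
  expect_equal(p$mapped_reads[p$contig_id == "B"], 0L)
  expect_gt(p$breadth[p$contig_id == "A"], 0.98)
  expect_equal(p$breadth[p$contig_id == "B"], 0)
  # mean depth matches reads * length / contig length
  expect_equal(p$mean_depth[p$contig_id == "A"],
               length(starts) * 150 / 12000, tolerance = 0.01)

  # reads at 8% divergence fail the 95% identity floor
  div <- vapply(reads[1:50], substitute_bases, "", n_sub = 12)
  rr2 <- recruit_reads(unname(div), contigs, min_identity = 0.95)
  expect_lte(sum(rr2$profiles$mapped_reads), 2)
  # ... but map at the relaxed 90% floor
  rr3 <- recruit_reads(unname(div), contigs, min_identity = 0.90)
  expect_gte(sum(rr3$profiles$mapped_reads), 45)

  # empty read set: zero profiles, not an error
  rr0 <- recruit_reads(character(0), contigs)
  expect_true(all(rr0$profiles$mapped_reads == 0))
  expect_true(all(rr0$profiles$breadth == 0))
})

test_that("detection is monotone in read depth", {
  set.seed(131)
  contig <- contig_table("A", random_seq(11000))
  starts <- sample(1:(11000 - 150), 400, replace = TRUE)
  reads <- substring(contig$seq, starts, starts + 149)
  breadths <- vapply(c(40, 100, 200, 400), function(n) {
    recruit_reads(reads[seq_len(n)], contig, 0.95)$profiles$breadth
  }, 1)
  expect_true(all(diff(breadths) >= 0))
  det <- vapply(breadths, function(b)
    detect_votu(data.frame(breadth = b, min_read_identity_used = 0.95),
                "strict"), TRUE)
  expect_true(all(diff(as.integer(det)) >= 0))
})

test_that("group abundance sums RPKM by predicted host and joins ASVs", {
  profiles <- data.frame(
    sample_id = "s1", contig_id = c("v1", "v2", "v3"),
    mapped_reads = c(100L, 50L, 20L))
  contigs <- contig_table(c("v1", "v2", "v3"),
                          c(strrep("A", 10000), strrep("A", 10000),
                            strrep("A", 10000)))
  preds <- data.frame(votu_id = c("v1", "v2", "v3"),
                      predicted_group = c("AOA", "none", "AOA"))
  asv <- data.frame(sample_id = "s1", group = c("AOA", "AOB", "Nitrospira"),
                    rel_abund = c(0.02, 0.001, 0.02))
  ga <- group_abundance(profiles, preds, asv, contigs,
                        library_sizes = c(s1 = 1e6))
  aoa <- ga[ga$group == "AOA", ]
  expect_equal(aoa$rpkm_sum, compute_rpkm(100, 10000, 1e6) +
                 compute_rpkm(20, 10000, 1e6))  # "none" excluded
  expect_equal(aoa$host_rel_abund, 0.02)
  asv_bad <- asv[0, ]
  expect_error(group_abundance(profiles, preds, asv_bad, contigs),
               "missing from ASV")
})

test_that("fold change reproduces the reported worked examples", {
  expect_equal(fold_change(1.7, 4.8)$fold, 2.8)  # AOA under DMPP
  expect_equal(fold_change(1.7, 3.6)$fold, 2.1)  # Nitrospira under 1-octyne
  expect_equal(fold_change(1.7, 4.1)$fold, 2.4)  # AOA under 1-octyne
  expect_equal(fold_change(c(2, 2), c(2, 2))$fold, 1.0)
  expect_error(fold_change(0, 5), "baseline")
})

test_that("compare_groups separates clear effects and picks the Dunn branch", {
  set.seed(141)
  vals <- c(rnorm(5, 0, 1), rnorm(5, 10, 1), rnorm(5, 0, 1))
  grp <- rep(c("a", "b", "c"), each = 5)
  cmp <- compare_groups(vals, grp)
  ab <- cmp$pairs[cmp$pairs$group_a %in% c("a", "b") &
                    cmp$pairs$group_b %in% c("a", "b"), ]
  expect_lt(ab$p_adj, 0.05)
  # a and c share a letter; b does not share with either
  expect_true(any(strsplit(cmp$letters[["a"]], "")[[1]] %in%
                    strsplit(cmp$letters[["c"]], "")[[1]]))
  expect_false(any(strsplit(cmp$letters[["b"]], "")[[1]] %in%
                     strsplit(cmp$letters[["a"]], "")[[1]]))

  # strongly heteroscedastic data routes to Kruskal-Wallis/Dunn
  vals2 <- c(rnorm(8, 0, 0.01), rnorm(8, 0.5, 5), rnorm(8, 1, 0.01))
  cmp2 <- compare_groups(vals2, rep(c("a", "b", "c"), each = 8))
  expect_equal(cmp2$method, "dunn")

  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "b")), "2 replicates")
  expect_error(compare_groups(c(1, 2), c("a", "a")), "2 groups")
})

test_that("Dunn test agrees with hand-computed z statistics", {
  # two groups, no ties: z = (mean rank diff) / sqrt(N(N+1)/12 * (1/n1+1/n2))
  vals <- c(1, 2, 3, 10, 11, 12)
  grp <- rep(c("lo", "hi"), each = 3)
  dn <- nitrivir:::dunn_test(vals, grp)
  z_hand <- (mean(c(4, 5, 6)) - mean(c(1, 2, 3))) /
    sqrt(6 * 7 / 12 * (1 / 3 + 1 / 3))
  expect_equal(abs(dn$statistic), z_hand)
  expect_equal(dn$p, 2 * pnorm(-z_hand))
})

test_that("regression recovers planted effects; permutation null is flat", {
  set.seed(151)
  x <- runif(15, 0, 10)
  y <- 2 * x + 1
  fit <- suppressWarnings(host_virus_regression(x, y))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1.0)

  # permutation: mean R^2 under the null is ~ 1/(n-1)
  n <- 10
  x <- rnorm(n); y <- rnorm(n)
  r2 <- replicate(400, host_virus_regression(x, sample(y))$r_squared)
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 0.03)

  expect_error(host_virus_regression(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(host_virus_regression(1:2, 1:2), "3 paired")
})

test_that("planted R^2 is recovered by noise calibrated in closed form", {
  set.seed(161)
  target <- 0.8
  n <- 15
  r2 <- replicate(25, {
    x <- runif(n, 1, 5)
    signal <- 2 * x
    sigma <- sd(signal) * sqrt(length(signal) / (length(signal) - 1)) *
      sqrt(1 / target - 1)
    y <- signal + rnorm(n, 0, sigma)
    host_virus_regression(x, y)$r_squared
  })
  expect_lt(abs(mean(r2) - target), 0.1)
})
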