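test_that("normalized genome similarity: self, unrelated, rearranged", {
  set.seed(171)
  a <- random_seq(8000)
  s_self <- genome_similarity(contig_table("a", a)[1, ], contig_table("a2", a)[1, ])
  expect_equal(s_self$normalized, 1.0, tolerance = 1e-6)

  # unrelated random sequences fall below the 0.05 demarcation
  for (i in 1:4) {
    b <- random_seq(8000)
    s <- genome_similarity(contig_table("a", a)[1, ], contig_table("b", b)[1, ])
    expect_lt(s$normalized, 0.05)
    expect_gte(s$normalized, 0)
  }
})

test_that("similarity is order-independent, strand-invariant and symmetric", {
  set.seed(181)
  blocks <- replicate(6, random_seq(1200))
  a <- paste(blocks, collapse = "")
  b <- paste(blocks[sample(6)], collapse = "")   # rearranged gene order
  sim <- genome_similarity(contig_table("a", a)[1, ], contig_table("b", b)[1, ])
  expect_gt(sim$normalized, 0.9)  # summed local scores ignore order

  rc <- genome_similarity(contig_table("a", a)[1, ],
                          contig_table("brc", revcomp(b))[1, ])
  expect_equal(rc$normalized, sim$normalized, tolerance = 0.05)

  ba <- genome_similarity(contig_table("b", b)[1, ], contig_table("a", a)[1, ])
  expect_equal(ba$normalized, sim$normalized, tolerance = 0.05)
})

test_that("containment stays high under min-normalization", {
  set.seed(191)
  long <- random_seq(9000)
  short <- substr(long, 2001, 5000)  # fully contained
  s <- genome_similarity(contig_table("l", long)[1, ],
                         contig_table("s", short)[1, ])
  expect_gt(s$normalized, 0.9)
  g <- genome_similarity(contig_table("l", long)[1, ],
                         contig_table("s", short)[1, ], norm = "geometric")
  expect_lt(g$normalized, s$normalized)
})

test_that("single-linkage family clustering follows linkage semantics", {
  sims <- data.frame(a_id = c("A", "B", "A"), b_id = c("B", "C", "C"),
                     normalized = c(0.6, 0.6, 0.01))
  fam <- cluster_families(sims, threshold = 0.05)
  expect_length(unique(fam$family_id), 1L)  # chain joins all three

  sims2 <- data.frame(a_id = c("A", "B", "A"), b_id = c("B", "C", "C"),
                      normalized = c(0.01, 0.02, 0.03))
  fam2 <- cluster_families(sims2, threshold = 0.05)
  expect_length(unique(fam2$family_id), 3L)  # all pairs below threshold

  # distance interpretation flips the rule
  fam3 <- cluster_families(sims, threshold = 0.4, threshold_is_distance = TRUE)
  expect_length(unique(fam3$family_id), 1L)
})

test_that("planted families are recovered exactly; counts are monotone", {
  pf <- planted_families(4, 2, shared_bp = 3000, unique_bp = 5000, seed = 201)
  sims <- genome_similarity_matrix(pf$contigs)
  within <- mapply(function(a, b) pf$truth[match(a, pf$contigs$id)] ==
                     pf$truth[match(b, pf$contigs$id)],
                   sims$a_id, sims$b_id)
  expect_true(all(sims$normalized[within] >= 0.3))
  expect_true(all(sims$normalized[!within] < 0.02))

  fam <- cluster_families(sims, 0.05, ids = pf$contigs$id)
  expect_length(unique(fam$family_id), 4L)
  for (f in unique(pf$truth)) {
    expect_length(unique(fam$family_id[pf$truth == f]), 1L)
  }
  # raising the threshold never decreases the family count
  counts <- vapply(c(0.02, 0.05, 0.2, 0.5, 0.99), function(th)
    length(unique(cluster_families(sims, th, ids = pf$contigs$id)$family_id)), 1L)
  expect_true(all(diff(counts) >= 0))

  # BIONJ on 1 - normalized keeps family members closer than non-members
  tree <- family_tree(sims, ids = pf$contigs$id)
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, pf$contigs$id)
  cd <- ape::cophenetic.phylo(tree)
  for (f in unique(pf$truth)) {
    members <- pf$contigs$id[pf$truth == f]
    others <- setdiff(pf$contigs$id, members)
    expect_lt(max(cd[members, members]), min(cd[members, others]))
  }
})

test_that("per-group family counts follow the assignment arithmetic", {
  # 13 vOTUs in 10 families for one group (the AOA-shaped example)
  assignment <- data.frame(
    votu_id = sprintf("v%02d", 1:13),
    family_id = sprintf("family_%03d", c(1:10, 1, 2, 3)))
  preds <- data.frame(votu_id = sprintf("v%02d", 1:13),
                      predicted_group = "AOA")
  tab <- count_families_per_group(assignment, preds)
  expect_equal(tab$n_votus, 13L)
  expect_equal(tab$n_families, 10L)
  expect_equal(tab$n_mixed_families, 0L)

  # a family spanning two groups is flagged mixed in both rows
  preds$predicted_group[11] <- "AOB"
  tab2 <- count_families_per_group(assignment, preds)
  expect_equal(tab2$n_mixed_families[tab2$group == "AOA"], 1L)
  expect_equal(tab2$n_mixed_families[tab2$group == "AOB"], 1L)
  expect_equal(sum(tab2$n_votus), 13L)
})
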