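test_that("ORF calling recovers planted genes and is strand-symmetric", {
  set.seed(61)
  prot <- paste0("M", random_protein_fixture(99))
  gene <- nitrivir:::encode_protein(substr(prot, 2, 100))
  # encode_protein prepends ATG: planted protein is exactly `prot`
  backbone <- random_seq(4000)
  genome <- paste0(substr(backbone, 1, 2000), "TAA", gene,
                   substr(backbone, 2001, 4000))
  orfs <- call_orfs(contig_table("c", genome), min_aa = 90)
  expect_true(prot %in% orfs$seq)

  # strand symmetry: reverse complement yields the same protein set
  orfs_rc <- call_orfs(contig_table("c", revcomp(genome)), min_aa = 90)
  expect_setequal(orfs$seq, orfs_rc$seq)

  # a stop-saturated sequence has no ORFs
  expect_equal(nrow(call_orfs(contig_table("s", strrep("TAA", 200)))), 0L)
})

test_that("protein search retains planted homologs and enforces thresholds", {
  h <- small_hosts()
  v <- small_viruses()
  dbs <- emit_reference_dbs(h, v, seed = 71)
  vid <- v$viruses$id[!v$viruses$decoy][1]
  orfs <- call_orfs(contig_table(vid, v$genomes[[vid]]))
  hits <- protein_best_hits(orfs, dbs$provirus_proteins)
  # all planted homologs (~60% identity, full length) are retained
  expect_gte(nrow(hits), v$viruses$shared_homolog_count[v$viruses$id == vid])
  expect_true(all(hits$aa_identity > 0.30))
  expect_true(all(hits$evalue < 1e-5))
  expect_true(all(hits$bitscore > 50))
  expect_true(all(hits$query_coverage > 0.70))
  expect_true(all(hits$subject_host_group ==
                    v$viruses$true_host_group[v$viruses$id == vid]))

  # thresholds are strict: a floor equal to the observed identity discards
  top <- hits[1, ]
  again <- protein_best_hits(orfs, dbs$provirus_proteins,
                             min_identity = top$aa_identity)
  expect_false(top$query_protein %in% again$query_protein)

  # coverage rule: a homolog truncated to half its length is discarded
  half <- orfs[orfs$protein_id == top$query_protein, ]
  half$seq <- paste0(substr(half$seq, 1, floor(nchar(half$seq) / 2)),
                     random_protein_fixture(ceiling(nchar(half$seq) / 2)))
  hhits <- protein_best_hits(half, dbs$provirus_proteins)
  expect_false(top$query_protein %in% hhits$query_protein)

  expect_error(protein_best_hits(orfs, NULL), "empty reference")
})

test_that("host calls require three homologs and break ties to none", {
  mk <- function(n, groups) data.frame(
    query_protein = sprintf("q%d", seq_len(n)),
    subject_host_group = groups, stringsAsFactors = FALSE)
  expect_equal(predict_host(mk(5, rep("AOA", 5)))$predicted_group, "AOA")
  expect_equal(predict_host(mk(2, rep("AOA", 2)))$predicted_group, "none")
  expect_warning(
    p <- predict_host(mk(6, rep(c("AOA", "AOB"), each = 3))),
    "ambiguous")
  expect_equal(p$predicted_group, "none")
})

test_that("planted cohort: full recall, no decoy assignments", {
  h <- small_hosts()
  v <- small_viruses()
  dbs <- emit_reference_dbs(h, v, seed = 81)
  contigs <- contig_table(names(v$genomes), unname(v$genomes))
  orfs <- call_orfs(contigs)
  hits <- protein_best_hits(orfs, dbs$provirus_proteins)
  pred <- predict_host(hits)
  truth <- v$viruses
  real <- truth[!truth$decoy, ]
  got <- pred$predicted_group[match(real$id, pred$votu_id)]
  expect_equal(got, real$true_host_group)  # recall 1 on this cohort
  decoy_pred <- pred$predicted_group[pred$votu_id %in% truth$id[truth$decoy]]
  expect_true(all(is.na(decoy_pred) | decoy_pred == "none"))
})

test_that("hallmark matching distinguishes viral from random proteins", {
  h <- small_hosts()
  v <- small_viruses()
  dbs <- emit_reference_dbs(h, v, seed = 91)
  vid <- v$viruses$id[!v$viruses$decoy][2]
  orfs <- call_orfs(contig_table(vid, v$genomes[[vid]]))
  hm <- hallmark_match(orfs, dbs$hallmark)
  expect_type(hm$hit, "logical")
  rand <- data.frame(protein_id = "r1", seq = random_protein_fixture(200))
  expect_false(hallmark_match(rand, dbs$hallmark)$hit)
})

test_that("spacer scan equals the brute-force oracle with the mismatch boundary", {
  set.seed(101)
  contig <- random_seq(5000)
  sp_exact <- substr(contig, 1001, 1032)
  sp3 <- substitute_bases(sp_exact, 3)          # 3 substitutions: no match
  sp_rc <- revcomp(substr(contig, 2001, 2032)) # reverse-strand positive
  spacers <- data.frame(spacer_id = c("s_ex", "s_3mm", "s_rc"),
                        seq = c(sp_exact, sp3, sp_rc))
  hits <- crispr_spacer_match(spacers, contig_table("c1", contig))
  ex <- hits[hits$spacer_id == "s_ex", ]
  expect_true(any(ex$position == 1000 & ex$mismatches == 0))
  expect_equal(nrow(hits[hits$spacer_id == "s_3mm" & hits$position == 1000, ]), 0L)
  expect_true(any(hits$spacer_id == "s_rc" & hits$strand == "-" &
                    hits$position == 2000))

  # full equality with the position-by-position oracle
  for (sid in spacers$spacer_id) {
    got <- hits[hits$spacer_id == sid, c("position", "strand", "mismatches")]
    got <- got[order(got$position, got$strand), ]
    want <- brute_spacer_scan(spacers$seq[spacers$spacer_id == sid], contig)
    want <- want[order(want$position, want$strand), ]
    expect_equal(got, want, ignore_attr = TRUE)
  }
  expect_error(crispr_spacer_match(data.frame(spacer_id = "x", seq = "ACGT"),
                                   contig_table("c1", contig)), "20-50")
})

test_that("gene-sharing network matches the enumeration oracle and clusters kin", {
  # hypergeometric tail by direct enumeration: N = 10, a = 4, b = 5, c = 3
  # sum_{k>=3} C(4,k) C(6,5-k) / C(10,5) = (4*15 + 1*6) / 252 = 66/252
  p_oracle <- 66 / 252
  expect_equal(phyper(2, 4, 6, 5, lower.tail = FALSE), p_oracle)

  # monotone decreasing in shared-cluster count
  ps <- phyper(0:4 - 1, 4, 6, 5, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))

  set.seed(111)
  shared <- vapply(1:8, function(i) random_protein_fixture(150), "")
  gA <- c(shared, vapply(1:2, function(i) random_protein_fixture(150), ""))
  gB <- c(shared, vapply(1:2, function(i) random_protein_fixture(150), ""))
  gC <- vapply(1:10, function(i) random_protein_fixture(150), "")
  net <- build_gene_sharing_network(list(A = gA, B = gB, C = gC))
  eAB <- net$edges[net$edges$genome_a == "A" & net$edges$genome_b == "B", ]
  expect_equal(eAB$shared_clusters, 8L)
  expect_gte(eAB$significance, 1)
  eAC <- net$edges[net$edges$genome_a == "A" & net$edges$genome_b == "C", ]
  expect_equal(eAC$shared_clusters, 0L)
  expect_equal(eAC$p_hypergeom, 1)
  comp <- setNames(net$components$component, net$components$genome)
  expect_equal(comp[["A"]], comp[["B"]])
  expect_false(comp[["A"]] == comp[["C"]])
})

test_that("same-group viruses join one network component via the references", {
  h <- small_hosts()
  v <- generate_viruses(small_hosts(), n_per_group = 2, n_decoys = 2,
                        homologs_per_virus = 8,
                        length_range = c(12000, 18000), seed = 303)
  ids <- names(v$genomes)
  # proteins >= 100 aa, as in the pipeline's network stage
  orfs <- call_orfs(contig_table(ids, unname(v$genomes)), min_aa = 100)
  sets <- lapply(setNames(ids, ids), function(id)
    orfs$seq[orfs$contig_id == id])
  refs <- split(h$provirus_proteins$seq, h$provirus_proteins$host_id)
  net <- build_gene_sharing_network(c(sets, refs))
  comp <- setNames(net$components$component, net$components$genome)
  vt <- v$viruses
  for (g in c("AOA", "AOB", "Nitrospira")) {
    kin <- vt$id[vt$true_host_group == g & !vt$decoy]
    expect_length(unique(comp[kin]), 1L)
    expect_equal(comp[[kin[1]]], comp[[paste0("host_", g, "_01")]])
  }
})
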