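test_that("host generation is deterministic and embeds the core-gene panel", {
  h1 <- generate_hosts(1, seed = 5, genome_length = c(AOA = 5e4, AOB = 5e4,
                                                      Nitrospira = 5e4))
  h2 <- generate_hosts(1, seed = 5, genome_length = c(AOA = 5e4, AOB = 5e4,
                                                      Nitrospira = 5e4))
  expect_identical(h1$genomes, h2$genomes)
  expect_identical(h1$core_genes, h2$core_genes)

  h <- small_hosts()
  expect_equal(nrow(h$hosts), 6L)
  # realized GC within 2 points of target
  expect_true(all(abs(h$hosts$gc - h$hosts$gc_target) < 0.02))
  # AOA genomes carry the panel; planted genes readable at their coordinates
  cg <- h$core_genes
  aoa1 <- h$hosts$id[h$hosts$group == "AOA"][1]
  g1 <- cg[cg$host_id == aoa1 & cg$gene_class == "amoA", ][1, ]
  planted <- substr(h$genomes[[aoa1]], g1$start0 + 1, g1$end0)
  ref <- h$panel$sequences
  expect_equal(planted,
               ref$seq[ref$gene_class == "amoA" & ref$clade == g1$clade])
  # every host has a provirus region
  expect_setequal(h$proviruses$host_id, h$hosts$id)
})

test_that("integer core-gene copies average the panel values over a cohort", {
  # copy cycles are exact at n = 20 (lcm of the amoC and MCO4 cycles)
  h <- generate_hosts(20, seed = 9, groups = "AOA",
                      genome_length = c(AOA = 6e4))
  copies <- table(h$core_genes$host_id[h$core_genes$gene_class == "amoC"])
  expect_equal(mean(copies), 2.9)
  mco4 <- table(h$core_genes$host_id[h$core_genes$gene_class == "MCO4"])
  expect_equal(mean(mco4), 1.25)
  expect_equal(nrow(h$hosts), 20L)
})

test_that("n_per_group = 0 yields an empty host set", {
  h <- generate_hosts(0, seed = 1)
  expect_equal(nrow(h$hosts), 0L)
  expect_length(h$genomes, 0L)
})

test_that("virus GC tracks host group: AOA mean 43.7, others 54.7", {
  h <- generate_hosts(1, seed = 3, genome_length = c(AOA = 5e4, AOB = 5e4,
                                                     Nitrospira = 5e4))
  v <- generate_viruses(h, n_per_group = 25, length_range = c(12000, 20000),
                        seed = 4)
  aoa <- v$viruses$gc[v$viruses$true_host_group == "AOA"]
  rest <- v$viruses$gc[v$viruses$true_host_group != "AOA"]
  expect_gt(length(aoa), 20)
  expect_lt(abs(mean(aoa) - 0.437), 0.01)
  expect_lt(abs(mean(rest) - 0.547), 0.01)
})

test_that("lysogeny flags follow the configured fraction binomially", {
  h <- small_hosts()
  v <- generate_viruses(h, n_per_group = 34, frac_lysogenic = 0.44,
                        length_range = c(12000, 16000), seed = 11)
  n <- sum(!v$viruses$decoy)
  k <- sum(v$viruses$lysogenic[!v$viruses$decoy])
  # 3 sigma binomial band around 0.44
  expect_lt(abs(k / n - 0.44), 3 * sqrt(0.44 * 0.56 / n))
})

test_that("virus generation validates homolog arguments", {
  h <- small_hosts()
  expect_error(generate_viruses(h, 1, homologs_per_virus = -1), ">= 0")
  expect_error(generate_viruses(h, 1, homologs_per_virus = 50), "<=")
})

test_that("dynamics reproduce treatment multipliers exactly at zero noise", {
  design <- default_design()
  model <- default_treatment_model(sigma_host = 0, sigma_virus = 0, seed = 2)
  dyn <- simulate_dynamics(design, model)
  asv <- dyn$asv
  d0 <- asv[asv$sample_id == "d00_control_r1", ]
  # AOA baseline 1.7% under DMPP multiplier 2.8 -> 4.76% before renormalization
  mass <- 0.017 * 2.8
  expect_equal(mass, 0.0476)
  d30 <- asv[asv$sample_id == "d30_urea_dmpp_r1", ]
  tot <- 0.0476 + 0.0007 + 0.017 + (1 - 0.017 - 0.0007 - 0.017)
  expect_equal(d30$rel_abund[d30$group == "AOA"], 0.0476 / tot)
  # acetylene: all multipliers 1 -> day-30 equals the day-0 profile
  d30a <- asv[asv$sample_id == "d30_urea_acetylene_r1", ]
  expect_equal(d30a$rel_abund, d0$rel_abund, tolerance = 1e-12)
})

test_that("zero dynamics noise gives a perfect host-virus regression", {
  design <- default_design()
  model <- default_treatment_model(sigma_host = 0.3, sigma_virus = 0, seed = 8)
  model$burst[] <- 1  # uniform burst: virus weight is exactly linear in host
  dyn <- simulate_dynamics(design, model)
  for (g in c("AOA", "AOB")) {
    w <- dyn$group_weights[dyn$group_weights$group == g, ]
    a <- dyn$asv[dyn$asv$group == g, ]
    w <- w[match(a$sample_id, w$sample_id), ]
    fit <- suppressWarnings(host_virus_regression(a$rel_abund, w$weight))
    expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)
  }
})

test_that("read simulation respects sources, errors and determinism", {
  h <- small_hosts()
  v <- small_viruses()
  design <- default_design()[1:2, ]
  model <- default_treatment_model(n_reads = 400, error_rate = 0,
                                   contamination_fraction = 0, seed = 3)
  dyn <- simulate_dynamics(design, model, v)
  reads <- simulate_virome_reads(v, dyn$virus_weights, model)
  rd <- reads[[1]]
  expect_equal(nrow(rd), 400L)
  expect_true(all(rd$source_id %in% names(v$genomes)))
  # error rate 0: every read matches its source window exactly
  for (i in sample(nrow(rd), 25)) {
    src <- v$genomes[[rd$source_id[i]]]
    win <- substr(src, rd$source_pos0[i] + 1, rd$source_pos0[i] + nchar(rd$seq[i]))
    seq <- if (rd$strand[i] == "-") revcomp(rd$seq[i]) else rd$seq[i]
    expect_identical(seq, win)
  }
  reads2 <- simulate_virome_reads(v, dyn$virus_weights, model)
  expect_identical(reads, reads2)
  # read length longer than the shortest genome is rejected
  model_bad <- default_treatment_model(n_reads = 10, seed = 3,
                                       contamination_fraction = 0)
  model_bad$read_length <- 1e6
  expect_error(simulate_virome_reads(v, dyn$virus_weights, model_bad),
               "read_length")
})

test_that("read counts follow the weight x length sampling law", {
  h <- small_hosts()
  v <- small_viruses()
  w <- data.frame(sample_id = "s1", virus_id = names(v$genomes),
                  weight = 0)
  two <- names(v$genomes)[1:2]
  w$weight[w$virus_id %in% two] <- 0.5
  model <- default_treatment_model(n_reads = 10000, error_rate = 0,
                                   contamination_fraction = 0, seed = 6)
  reads <- simulate_virome_reads(v, w, model)$s1
  lens <- nchar(v$genomes[two])
  p1 <- lens[1] / sum(lens)  # equal weights: length share decides
  n1 <- sum(reads$source_id == two[1])
  expect_lt(abs(n1 - 10000 * p1), 3 * sqrt(10000 * p1 * (1 - p1)))
})

test_that("reference databases label groups and plant recoverable spacers", {
  h <- small_hosts()
  v <- small_viruses()
  dbs <- emit_reference_dbs(h, v, n_spacers_pos = 5, n_spacers_neg = 5,
                            seed = 7)
  expect_equal(nrow(dbs$provirus_proteins), 6 * 10)  # hosts x 10 genes
  expect_true(all(dbs$hallmark$hallmark))
  expect_setequal(unique(dbs$provirus_proteins$host_group),
                  c("AOA", "AOB", "Nitrospira"))
  sp <- dbs$spacers
  expect_equal(nchar(sp$seq), rep(32L, 10))
  # planted spacers match their source genome exactly
  for (i in which(sp$planted)) {
    expect_true(grepl(sp$seq[i], v$genomes[[sp$source_id[i]]], fixed = TRUE))
  }
})
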