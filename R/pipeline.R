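# End-to-end orchestration: simulate -> cluster -> hosts -> abundance ->
# families -> amg, with one config, per-stage seeds fanned out from a single
# global seed, and a summary report in the shape of the study's headline
# tables.

#' Default pipeline configuration
#'
#' Thresholds default to the values the analysis is defined by (95%/85% vOTU
#' clustering, four-threshold homolog filter with the three-homolog rule,
#' 85%/10% detection breadths, 0.05 family demarcation, 90% core-gene
#' mapping identity).  Community sizes are kept modest so a full run
#' completes on one CPU in minutes; the synthetic model parameters are the
#' study conditions.
#'
#' @param seed Global seed; per-stage seeds are derived by fixed offsets.
#' @param outdir Output directory (NULL to keep results in memory only).
#' @return A list of class `run_config`.
#' @export
default_config <- function(seed = 7, outdir = NULL) {
  structure(list(
    seed = seed, outdir = outdir,
    hosts_per_group = 2, host_genome_length = c(AOA = 2e5, AOB = 2e5,
                                                Nitrospira = 3e5),
    viruses_per_group = 6, n_decoys = 6, homologs_per_virus = 5,
    frac_lysogenic = 0.44, frac_with_mco1 = 0.5,
    virus_length_range = c(34500, 60000),
    n_reads = 4000, read_length = 150, error_rate = 0.005,
    contamination_fraction = 0.02,
    votu_identity = 0.95, votu_coverage = 0.85, votu_min_len = 10000,
    min_homologs = 3, detection_identity = 0.95,
    family_threshold = 0.05, amg_identity = 0.90
  ), class = "run_config")
}

pipeline_stage <- function(name, expr, log, manifest = NULL) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  log(sprintf("stage %-12s %6.1fs", name, el))
  if (!is.null(manifest)) {
    manifest$rows[[name]] <- data.frame(stage = name,
                                        elapsed_s = round(el, 2),
                                        stringsAsFactors = FALSE)
  }
  res
}

#' Run the full synthetic-community pipeline
#'
#' Generates the synthetic community, clusters vOTUs, predicts hosts,
#' profiles abundances and enrichment, demarcates families and quantifies
#' core genes against the contamination null; writes stage outputs and a
#' summary report when `config$outdir` is set.
#'
#' @param config A `run_config` from [default_config()].
#' @param quiet Suppress stage logging.
#' @return A list of class `summary_report`; see its elements.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  log <- if (quiet) function(...) invisible() else function(msg) message(msg)
  manifest <- new.env(parent = emptyenv())
  manifest$rows <- list()
  seed <- config$seed

  hosts <- pipeline_stage("hosts", generate_hosts(
    n_per_group = config$hosts_per_group, seed = derive_seed(seed, 1),
    genome_length = config$host_genome_length), log, manifest)
  viruses <- pipeline_stage("viruses", generate_viruses(
    hosts, n_per_group = config$viruses_per_group,
    homologs_per_virus = config$homologs_per_virus,
    frac_lysogenic = config$frac_lysogenic,
    frac_with_mco1 = config$frac_with_mco1, n_decoys = config$n_decoys,
    length_range = config$virus_length_range,
    seed = derive_seed(seed, 2)), log, manifest)
  dbs <- pipeline_stage("refdbs", emit_reference_dbs(
    hosts, viruses, seed = derive_seed(seed, 3)), log, manifest)

  design <- default_design()
  model <- default_treatment_model(
    n_reads = config$n_reads, read_length = config$read_length,
    error_rate = config$error_rate,
    contamination_fraction = config$contamination_fraction,
    seed = derive_seed(seed, 4))
  dyn <- pipeline_stage("dynamics",
                        simulate_dynamics(design, model, viruses), log, manifest)
  reads <- pipeline_stage("reads", simulate_virome_reads(
    viruses, dyn$virus_weights, model, hosts), log, manifest)

  contigs <- contig_table(names(viruses$genomes), unname(viruses$genomes))
  votus <- pipeline_stage("votus", cluster_votus(
    contigs, config$votu_identity, config$votu_coverage,
    config$votu_min_len), log, manifest)

  rep_contigs <- contigs[match(votus$votus$representative_id, contigs$id), ]
  orfs <- pipeline_stage("orfs", call_orfs(rep_contigs), log, manifest)
  hits <- pipeline_stage("homologs",
                         protein_best_hits(orfs, dbs$provirus_proteins), log, manifest)
  predictions <- pipeline_stage("hosts_call", {
    p <- predict_host(hits, config$min_homologs)
    miss <- setdiff(votus$votus$representative_id, p$votu_id)
    if (length(miss)) {
      p <- rbind(p, data.frame(votu_id = miss, predicted_group = "none",
                               n_homologs = 0L))
    }
    p
  }, log, manifest)
  ann <- data.frame(contig_id = hits$contig_id,
                    annotation = hits$subject_gene_label,
                    stringsAsFactors = FALSE)
  votus <- annotate_lifestyle(votus, ann)
  spacer_hits <- pipeline_stage("spacers", crispr_spacer_match(
    dbs$spacers, rep_contigs), log, manifest)

  # gene-sharing network over predicted vOTUs plus the reference provirus
  # "genomes" (the reference links viruses of a group into one component)
  network <- pipeline_stage("network", {
    # all vOTUs enter as background; proteins >= 100 aa only, compensating
    # the all-frame ORF caller's overcalling relative to a gene caller
    long_orfs <- orfs[orfs$aa_length >= 100, , drop = FALSE]
    ids <- votus$votus$representative_id
    sets <- lapply(setNames(ids, ids), function(v)
      long_orfs$seq[long_orfs$contig_id == v])
    sets <- sets[vapply(sets, length, 1L) > 0]
    refs <- split(dbs$provirus_proteins$seq, dbs$provirus_proteins$host_id)
    sets <- c(sets, refs)
    if (length(sets) >= 2) build_gene_sharing_network(sets) else NULL
  }, log, manifest)
  hallmark_votus <- unique(hits$contig_id[
    hits$subject_gene_label %in% HALLMARK_LABELS])

  profiles <- pipeline_stage("recruit", {
    do.call(rbind, lapply(names(reads), function(s) {
      recruit_reads(reads[[s]], rep_contigs,
                    min_identity = config$detection_identity,
                    sample_id = s)$profiles
    }))
  }, log, manifest)
  profiles$strict_detected <- detect_votu(profiles, "strict")
  gab <- pipeline_stage("abundance", group_abundance(
    profiles, predictions, dyn$asv, rep_contigs), log, manifest)

  enr <- list(); regr <- list()
  for (g in intersect(NITRIFIER_GROUPS, unique(gab$group))) {
    sub <- gab[gab$group == g, ]
    sub <- sub[match(design$sample_id, sub$sample_id), ]
    enr[[g]] <- enrichment_calls(sub$rpkm_sum, design)
    regr[[g]] <- tryCatch(
      host_virus_regression(sub$host_rel_abund, sub$rpkm_sum),
      error = function(e) NULL)
  }

  fam_counts <- NULL; families <- NULL
  fam_list <- list()
  for (g in intersect(NITRIFIER_GROUPS, unique(predictions$predicted_group))) {
    ids <- predictions$votu_id[predictions$predicted_group == g]
    sub <- rep_contigs[rep_contigs$id %in% ids, , drop = FALSE]
    if (nrow(sub) < 1) next
    sims <- if (nrow(sub) > 1) genome_similarity_matrix(sub) else
      data.frame(a_id = character(0), b_id = character(0),
                 raw_score = numeric(0), normalized = numeric(0))
    fam_list[[g]] <- cluster_families(sims, config$family_threshold,
                                      ids = sub$id)
    fam_list[[g]]$family_id <- paste0(g, "_", fam_list[[g]]$family_id)
  }
  families <- pipeline_stage("families",
                             do.call(rbind, c(fam_list, make.row.names = FALSE)),
                             log)
  if (!is.null(families) && nrow(families)) {
    fam_counts <- count_families_per_group(families, predictions)
  }

  panel <- core_gene_panel()
  amg_profiles <- pipeline_stage("amg", {
    lapply(reads, function(rd) {
      cnt <- map_reads_to_core_genes(rd, hosts$panel$sequences,
                                     config$amg_identity)$counts
      if (cnt[["MCO1"]] > 0) normalize_profile(cnt, panel) else NULL
    })
  }, log, manifest)
  nullp <- expected_null_profile(panel)
  amg_test <- tryCatch(
    suppressWarnings(amg_enrichment_test(amg_profiles, nullp)),
    error = function(e) NULL)

  # Table-1-shaped summary
  truth <- viruses$viruses
  group_of_rep <- setNames(predictions$predicted_group, predictions$votu_id)
  vt <- votus$votus
  summary_tbl <- do.call(rbind, lapply(NITRIFIER_GROUPS, function(g) {
    reps <- vt$representative_id[group_of_rep[vt$representative_id] == g]
    n <- length(reps)
    lys <- sum(vt$is_lysogenic[vt$representative_id %in% reps])
    fams <- if (!is.null(fam_counts) && g %in% fam_counts$group)
      fam_counts$n_families[fam_counts$group == g] else 0L
    data.frame(group = g, n_votus = n, n_lysogenic = lys,
               pct_lysogenic = if (n > 0) summarize_percent(lys, n) else 0,
               n_hallmark = sum(reps %in% hallmark_votus),
               n_families = fams, stringsAsFactors = FALSE)
  }))

  report <- structure(list(
    config = config, summary = summary_tbl, votus = votus,
    predictions = predictions, hits = hits, spacer_hits = spacer_hits,
    network = network,
    profiles = profiles, group_abundance = gab, enrichment = enr,
    regression = regr, families = families, family_counts = fam_counts,
    amg_profiles = amg_profiles, amg_test = amg_test,
    null_profile = nullp, truth = truth, dynamics = dyn,
    manifest = do.call(rbind, c(unname(manifest$rows),
                                make.row.names = FALSE))
  ), class = "summary_report")

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.summary_report <- function(x, ...) {
  cat("nitrivir pipeline report (seed ", x$config$seed, ")\n", sep = "")
  cat("\nvOTU summary by predicted host group:\n")
  print(x$summary, row.names = FALSE)
  if (length(x$regression)) {
    cat("\nhost-virus regression R^2:\n")
    for (g in names(x$regression)) {
      r <- x$regression[[g]]
      if (!is.null(r)) cat(sprintf("  %-10s %.2f (p = %.3g)\n", g,
                                   r$r_squared, r$p_value))
    }
  }
  invisible(x)
}

# Write the stage outputs and a markdown report under `outdir`.
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_table(report$summary, file.path(outdir, "summary.tsv"))
  write_table(report$votus$votus, file.path(outdir, "votus.tsv"))
  write_table(report$predictions, file.path(outdir, "hosts.tsv"))
  write_table(report$group_abundance, file.path(outdir, "group_abundance.tsv"))
  if (!is.null(report$families)) {
    write_table(report$families, file.path(outdir, "families.tsv"))
  }
  if (!is.null(report$manifest)) {
    write_table(report$manifest, file.path(outdir, "manifest.tsv"))
  }
  # config serialized for provenance
  cfg <- report$config
  writeLines(vapply(names(cfg), function(nm)
    paste0(nm, ": ", paste(format(cfg[[nm]]), collapse = " ")), ""),
    file.path(outdir, "config.txt"))
  md <- c("# nitrivir pipeline report", "",
          paste("seed:", report$config$seed), "",
          "## vOTU summary", "",
          paste(utils::capture.output(print(report$summary, row.names = FALSE)),
                collapse = "\n"))
  writeLines(md, file.path(outdir, "report.md"))
  invisible(outdir)
}
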