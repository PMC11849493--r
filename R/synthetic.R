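# Synthetic nitrifier community generator.
#
# Emits host genomes (AOA / AOB / Nitrospira) with clade-specific core genes
# and embedded proviruses, free virus genomes whose GC tracks the host group,
# treatment-dependent growth dynamics, virome reads with a tunable
# host-contamination fraction, and the reference databases the host-prediction
# stage consumes.  Every stochastic stage is deterministic given its seed and
# ground-truth tables are returned alongside the sequences.

CORE_GENE_CLASSES <- c("amoA", "amoB", "amoC", "MCO1", "MCO4", "nirK")
CORE_GENE_LENGTHS <- c(651, 587, 567, 1120, 1333, 1336)
CORE_GENE_COPIES  <- c(1, 1, 2.9, 1, 1.25, 1)

# Integer copy-number cycles whose cohort means equal the panel means
# (e.g. nine genomes with 3 amoC copies and one with 2 average 2.9).
CORE_COPY_CYCLE <- list(
  amoA = 1L, amoB = 1L, amoC = c(3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 2L),
  MCO1 = 1L, MCO4 = c(1L, 1L, 1L, 2L), nirK = 1L
)

PROVIRUS_GENE_LABELS <- c(
  "terminase_large_subunit", "major_capsid_protein", "portal_protein",
  "DNA_polymerase", "integrase", "tail_fiber_protein", "lysin",
  "hypothetical_protein_1", "hypothetical_protein_2", "hypothetical_protein_3"
)
HALLMARK_LABELS <- c("terminase_large_subunit", "major_capsid_protein",
                     "portal_protein", "DNA_polymerase")

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein <- function(n_aa) paste(sample(AA20, n_aa, replace = TRUE),
                                       collapse = "")

# codon choices per amino acid (stops excluded), from the standard code
aa_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))[AA20]
}

# Reverse-translate a protein to DNA with uniformly random synonymous codons;
# ATG start and TAA stop are appended.
encode_protein <- function(protein, codons = aa_codons()) {
  aa <- strsplit(protein, "")[[1]]
  body <- vapply(codons[aa], function(cs) cs[sample.int(length(cs), 1L)], "")
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# Substitute `frac` of positions with a different residue/base.
mutate_protein <- function(protein, frac) {
  aa <- strsplit(protein, "")[[1]]
  n <- max(0L, round(frac * length(aa)))
  if (n > 0) {
    pos <- sample.int(length(aa), n)
    aa[pos] <- vapply(aa[pos], function(a) sample(setdiff(AA20, a), 1L), "")
  }
  paste(aa, collapse = "")
}

mutate_dna <- function(seq, frac) {
  b <- strsplit(seq, "")[[1]]
  n <- max(0L, round(frac * length(b)))
  if (n > 0) {
    pos <- sample.int(length(b), n)
    b[pos] <- vapply(b[pos], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
  }
  paste(b, collapse = "")
}

# Place feature sequences at random non-overlapping positions of a genome.
# A TAA is written immediately upstream of each feature so upstream genomic
# sequence cannot extend a planted reading frame.  Returns the edited genome
# and a 0-based half-open coordinate table.
embed_features <- function(genome, features, pad = 3L) {
  glen <- nchar(genome)
  taken <- matrix(numeric(0), ncol = 2)
  starts <- integer(length(features))
  for (i in seq_along(features)) {
    flen <- nchar(features[i]) + pad
    for (try in 1:200) {
      s <- sample.int(glen - flen - 1L, 1L)
      e <- s + flen - 1L
      if (!nrow(taken) || all(e < taken[, 1] | s > taken[, 2])) {
        taken <- rbind(taken, c(s, e)); starts[i] <- s; break
      }
    }
    if (starts[i] == 0L) stop("could not place features without overlap")
  }
  for (i in seq_along(features)) {
    ins <- paste0("TAA", features[i])
    substr(genome, starts[i], starts[i] + nchar(ins) - 1L) <- ins
  }
  coords <- data.frame(
    feature = names(features),
    start0 = starts + pad - 1L,             # 0-based, after the TAA guard
    end0 = starts + pad - 1L + nchar(features),
    stringsAsFactors = FALSE
  )
  list(genome = genome, coords = coords)
}

#' Default AOA core-gene panel
#'
#' Six AOA core genes with cohort-average lengths and copy numbers used by
#' the host-contamination null model: amoA, amoB, amoC (ammonia monooxygenase
#' subunits), MCO1 and MCO4 (multicopper oxidases) and nirK (nitrite
#' reductase).
#'
#' @return `data.frame` with `gene_class`, `mean_length_bp`, `mean_copies`.
#' @export
core_gene_panel <- function() {
  data.frame(gene_class = CORE_GENE_CLASSES,
             mean_length_bp = CORE_GENE_LENGTHS,
             mean_copies = CORE_GENE_COPIES,
             stringsAsFactors = FALSE)
}

#' Generate synthetic nitrifier host genomes
#'
#' AOA genomes embed the six-gene core panel at the panel lengths with
#' integer per-genome copies whose cohort mean matches the panel copy
#' numbers; every host carries one provirus region of ten protein-coding
#' genes (hallmark structural/replication genes, an integrase, and accessory
#' genes) derived from a group-level ancestor.
#'
#' @param n_per_group Hosts per group (0 allowed).
#' @param seed Integer seed; identical seeds give identical output.
#' @param groups Host groups to generate.
#' @param genome_length Named genome lengths in bp.
#' @param gc_target Named GC targets per group.
#' @param clade_divergence Per-clade core-gene divergence from the class
#'   ancestor (substitution fraction).
#' @return An object of class `synthetic_hosts`: `hosts` (table), `genomes`
#'   (named sequences), `core_genes` and `proviruses` (0-based half-open
#'   coordinates), `provirus_proteins`, and `panel` (per-clade core-gene
#'   sequences plus the panel table).
#' @export
generate_hosts <- function(n_per_group = 2, seed = 1,
                           groups = c("AOA", "AOB", "Nitrospira"),
                           genome_length = c(AOA = 2e6, AOB = 2e6,
                                             Nitrospira = 3e6),
                           gc_target = c(AOA = 0.40, AOB = 0.52,
                                         Nitrospira = 0.56),
                           clade_divergence = 0.05) {
  set.seed(seed)
  codons <- aa_codons()
  clades <- list(AOA = c("NS-zeta-2", "NS-delta-1"),
                 AOB = c("Nitrosospira", "Nitrosomonas"),
                 Nitrospira = c("lineage-I", "lineage-II"))
  # class ancestors of the core-gene panel, then per-clade versions
  ancestors <- setNames(mapply(function(len, gc) random_dna(len, gc),
                               CORE_GENE_LENGTHS, 0.45), CORE_GENE_CLASSES)
  panel_seqs <- do.call(rbind, lapply(clades$AOA, function(cl) {
    data.frame(gene_class = CORE_GENE_CLASSES, clade = cl,
               seq = vapply(ancestors, mutate_dna, "", frac = clade_divergence),
               stringsAsFactors = FALSE)
  }))
  # group-level provirus protein ancestors (10 genes per group)
  prov_ancestors <- lapply(setNames(groups, groups), function(g) {
    setNames(vapply(PROVIRUS_GENE_LABELS,
                    function(l) random_protein(sample(150:300, 1L)), ""),
             PROVIRUS_GENE_LABELS)
  })
  hosts <- list(); genomes <- character(0)
  core_genes <- list(); proviruses <- list(); prov_proteins <- list()
  for (g in groups) {
    if (n_per_group < 1) next
    for (i in seq_len(n_per_group)) {
      id <- sprintf("host_%s_%02d", g, i)
      clade <- clades[[g]][(i - 1L) %% length(clades[[g]]) + 1L]
      gc <- gc_target[[g]]
      genome <- random_dna(genome_length[[g]], gc)
      feats <- character(0); labels <- character(0)
      if (g == "AOA") {
        for (ci in seq_along(CORE_GENE_CLASSES)) {
          cls <- CORE_GENE_CLASSES[ci]
          cyc <- CORE_COPY_CYCLE[[cls]]
          ncop <- cyc[(i - 1L) %% length(cyc) + 1L]
          gseq <- panel_seqs$seq[panel_seqs$gene_class == cls &
                                 panel_seqs$clade == clade]
          feats <- c(feats, rep(gseq, ncop))
          labels <- c(labels, rep(cls, ncop))
        }
      }
      # provirus: host-specific versions of the group provirus proteins
      pp <- vapply(prov_ancestors[[g]], mutate_protein, "", frac = 0.10)
      pdna <- vapply(pp, encode_protein, "", codons = codons)
      feats <- c(feats, pdna)
      labels <- c(labels, PROVIRUS_GENE_LABELS)
      names(feats) <- labels
      emb <- embed_features(genome, feats)
      genomes[id] <- emb$genome
      kind <- c(rep("core_gene", length(feats) - length(PROVIRUS_GENE_LABELS)),
                rep("provirus_gene", length(PROVIRUS_GENE_LABELS)))
      cg <- emb$coords[kind == "core_gene", , drop = FALSE]
      if (nrow(cg)) {
        core_genes[[id]] <- data.frame(host_id = id, gene_class = cg$feature,
                                       start0 = cg$start0, end0 = cg$end0,
                                       clade = clade, stringsAsFactors = FALSE)
      }
      pv <- emb$coords[kind == "provirus_gene", , drop = FALSE]
      proviruses[[id]] <- data.frame(host_id = id,
                                     start0 = min(pv$start0), end0 = max(pv$end0),
                                     stringsAsFactors = FALSE)
      prov_proteins[[id]] <- data.frame(
        protein_id = sprintf("%s|%s", id, PROVIRUS_GENE_LABELS),
        host_id = id, host_group = g, gene_label = PROVIRUS_GENE_LABELS,
        hallmark = PROVIRUS_GENE_LABELS %in% HALLMARK_LABELS,
        seq = unname(pp), stringsAsFactors = FALSE
      )
      hosts[[id]] <- data.frame(id = id, group = g, clade = clade,
                                gc_target = gc, length = genome_length[[g]],
                                stringsAsFactors = FALSE)
    }
  }
  hosts <- if (length(hosts)) do.call(rbind, hosts) else
    data.frame(id = character(0), group = character(0), clade = character(0),
               gc_target = numeric(0), length = numeric(0))
  if (nrow(hosts)) hosts$gc <- unname(gc_content(genomes[hosts$id]))
  rownames(hosts) <- NULL
  structure(list(
    hosts = hosts, genomes = genomes,
    core_genes = if (length(core_genes)) do.call(rbind, c(core_genes, make.row.names = FALSE)) else NULL,
    proviruses = if (length(proviruses)) do.call(rbind, c(proviruses, make.row.names = FALSE)) else NULL,
    provirus_proteins = if (length(prov_proteins)) do.call(rbind, c(prov_proteins, make.row.names = FALSE)) else NULL,
    panel = list(table = core_gene_panel(), sequences = panel_seqs)
  ), class = "synthetic_hosts")
}

#' Generate synthetic virus genomes with planted host signal
#'
#' Each non-decoy virus copies `homologs_per_virus` genes from its true
#' host's provirus region at a configurable amino-acid identity; lysogenic
#' viruses additionally carry a mutated integrase; MCO1-bearing AOA viruses
#' carry a full-length copy of their host clade's MCO1 gene.  Decoys carry
#' fewer than three homologs and no true host.  Virus GC tracks the host
#' group (AOA-virus mean 0.437 versus 0.547 otherwise).
#'
#' @param hosts A `synthetic_hosts` object.
#' @param n_per_group Viruses per host group.
#' @param homologs_per_virus Number of provirus genes copied (0..9; the
#'   integrase is reserved for the lysogeny flag).
#' @param frac_lysogenic Probability a virus carries the integrase marker.
#' @param frac_with_mco1 Probability an AOA virus carries MCO1.
#' @param n_decoys Number of decoy viruses.
#' @param decoy_homologs Homologs per decoy (default 2, below the 3-homolog
#'   host-call rule).
#' @param length_range Genome length range in bp (default the observed
#'   34.5-173.3 kb range).
#' @param aa_identity Amino-acid identity of copied homologs (default 0.60).
#' @param seed Integer seed.
#' @return An object of class `synthetic_viruses`: `viruses` (ground truth),
#'   `genomes`, and `features` (planted gene coordinates, 0-based half-open).
#' @export
generate_viruses <- function(hosts, n_per_group = 20, homologs_per_virus = 5,
                             frac_lysogenic = 0.44, frac_with_mco1 = 0.05,
                             n_decoys = 0, decoy_homologs = 2,
                             length_range = c(34500, 173300),
                             aa_identity = 0.60, seed = 1) {
  stopifnot(inherits(hosts, "synthetic_hosts"))
  if (nrow(hosts$hosts) == 0) stop("hosts must be non-empty")
  if (homologs_per_virus < 0) stop("homologs_per_virus must be >= 0")
  pool <- setdiff(PROVIRUS_GENE_LABELS, "integrase")
  if (homologs_per_virus > length(pool)) {
    stop("homologs_per_virus must be <= ", length(pool))
  }
  set.seed(seed)
  codons <- aa_codons()
  groups <- unique(hosts$hosts$group)
  gc_virus <- function(g) {
    mu <- if (g == "AOA") 0.437 else 0.547
    rnorm(1, mu, 0.01)
  }
  viruses <- list(); genomes <- character(0); features <- list()
  make_virus <- function(id, g, host_id, nhom, lysogenic, with_mco1) {
    hp <- hosts$provirus_proteins[hosts$provirus_proteins$host_id == host_id, ]
    glen <- round(runif(1, length_range[1], length_range[2]))
    gc_tgt <- max(0.2, min(0.8, gc_virus(g)))
    feats <- character(0)
    if (nhom > 0) {
      lab <- sample(pool, nhom)
      prot <- hp$seq[match(lab, hp$gene_label)]
      mut <- vapply(prot, mutate_protein, "", frac = 1 - aa_identity)
      feats <- c(feats, setNames(vapply(mut, encode_protein, "", codons = codons),
                                 paste0("homolog_", lab)))
    }
    if (lysogenic) {
      integ <- mutate_protein(hp$seq[hp$gene_label == "integrase"],
                              1 - aa_identity)
      feats <- c(feats, setNames(encode_protein(integ, codons), "homolog_integrase"))
    }
    if (with_mco1) {
      clade <- hosts$hosts$clade[hosts$hosts$id == host_id]
      mseq <- hosts$panel$sequences$seq[
        hosts$panel$sequences$gene_class == "MCO1" &
        hosts$panel$sequences$clade == clade][1]
      if (!is.na(mseq)) feats <- c(feats, setNames(mseq, "MCO1"))
    }
    # compensate the backbone GC for the inserted genes so the realized
    # genome GC hits the group target
    feat_len <- sum(nchar(feats))
    feat_gc <- if (feat_len > 0) sum(gc_content(feats) * nchar(feats)) / feat_len else 0
    back_gc <- (gc_tgt * glen - feat_gc * feat_len) / (glen - feat_len)
    genome <- random_dna(glen, max(0.2, min(0.8, back_gc)))
    if (length(feats)) {
      emb <- embed_features(genome, feats)
      genome <- emb$genome
      features[[id]] <<- cbind(virus_id = id, emb$coords,
                               stringsAsFactors = FALSE)
    }
    genomes[id] <<- genome
    data.frame(id = id, true_host_group = g, true_host_id = host_id,
               decoy = FALSE, lysogenic = lysogenic, has_mco1 = with_mco1,
               shared_homolog_count = nhom + as.integer(lysogenic),
               length = glen, stringsAsFactors = FALSE)
  }
  # lifestyle and AMG flags drawn up-front so they depend only on the seed
  # and cohort size, not on the reference hosts' RNG consumption
  lys_flags <- runif(length(groups) * n_per_group) < frac_lysogenic
  mco_flags <- runif(length(groups) * n_per_group) < frac_with_mco1
  vi <- 0L
  for (g in groups) {
    ghosts <- hosts$hosts$id[hosts$hosts$group == g]
    for (i in seq_len(n_per_group)) {
      vi <- vi + 1L
      id <- sprintf("virus_%s_%03d", g, i)
      host_id <- ghosts[(i - 1L) %% length(ghosts) + 1L]
      viruses[[id]] <- make_virus(id, g, host_id, homologs_per_virus,
                                  lys_flags[vi], g == "AOA" && mco_flags[vi])
    }
  }
  for (i in seq_len(n_decoys)) {
    id <- sprintf("virus_decoy_%03d", i)
    g <- groups[(i - 1L) %% length(groups) + 1L]
    host_id <- hosts$hosts$id[hosts$hosts$group == g][1L]
    v <- make_virus(id, g, host_id, decoy_homologs, FALSE, FALSE)
    v$decoy <- TRUE; v$true_host_group <- "none"; v$true_host_id <- NA
    viruses[[id]] <- v
  }
  viruses <- do.call(rbind, c(viruses, make.row.names = FALSE))
  viruses$gc <- unname(gc_content(genomes[viruses$id]))
  structure(list(viruses = viruses, genomes = genomes,
                 features = if (length(features))
                   do.call(rbind, c(features, make.row.names = FALSE)) else NULL),
            class = "synthetic_viruses")
}

#' Default treatment model
#'
#' Host growth multipliers over the 30-day incubation follow the study
#' conditions: AOB grow most under plain urea and are suppressed by DMPP more
#' than by 1-octyne; AOA respond to DMPP and 1-octyne; Nitrospira responds to
#' 1-octyne only; acetylene blocks all ammonia oxidizers.  Virus burst
#' factors default to 1 except AOA viruses under uninhibited urea, whose
#' virome response lagged host growth.
#'
#' @param n_reads Reads simulated per virome sample.
#' @param read_length Read length (nt).
#' @param error_rate Per-base substitution error rate.
#' @param contamination_fraction Fraction of virome reads drawn from host
#'   genomes.
#' @param sigma_host,sigma_virus Log-scale replicate noise (natural-log sd)
#'   for host relative abundance and virus weights.
#' @param seed Integer seed for dynamics and read simulation.
#' @return A list of class `treatment_model`.
#' @export
default_treatment_model <- function(n_reads = 20000, read_length = 150,
                                    error_rate = 0.005,
                                    contamination_fraction = 0.02,
                                    sigma_host = 0.05, sigma_virus = 0.10,
                                    seed = 1) {
  mult <- rbind(
    AOA        = c(control = 1, urea = 1.6, urea_dmpp = 2.8,
                   urea_octyne = 2.4, urea_acetylene = 1),
    AOB        = c(control = 1, urea = 22, urea_dmpp = 1,
                   urea_octyne = 8, urea_acetylene = 1),
    Nitrospira = c(control = 1, urea = 1, urea_dmpp = 1,
                   urea_octyne = 2.1, urea_acetylene = 1)
  )
  burst <- mult; burst[] <- 1
  burst["AOA", "urea"] <- 0.65
  structure(list(
    baseline = c(AOA = 0.017, AOB = 0.0007, Nitrospira = 0.017),
    host_mult = mult, burst = burst,
    n_reads = n_reads, read_length = read_length, error_rate = error_rate,
    contamination_fraction = contamination_fraction,
    sigma_host = sigma_host, sigma_virus = sigma_virus, seed = seed
  ), class = "treatment_model")
}

#' Simulate treatment dynamics: ASV table and virus abundance weights
#'
#' Day-30 group relative abundance is the day-0 baseline times the treatment
#' multiplier (renormalized over the whole community); virus weight for a
#' group is its host abundance times the burst factor with shared lognormal
#' replicate noise, so the planted host-virus correlation is recoverable.
#'
#' @param design Design `data.frame` from [read_design()] or
#'   [default_design()]; must include day-0 rows.
#' @param model A `treatment_model`.
#' @param viruses Optional `synthetic_viruses`; when given, per-virus weights
#'   are returned (decoys act as background community).
#' @return List with `asv` (sample_id, group, rel_abund), `group_weights`
#'   (per-sample virus weight mass per host group), and `virus_weights`
#'   (per-sample per-virus normalized weights; NULL without `viruses`).
#' @export
simulate_dynamics <- function(design, model = default_treatment_model(),
                              viruses = NULL) {
  stopifnot(all(c("sample_id", "treatment", "day") %in% names(design)))
  if (!any(design$day == 0)) stop("design must include day-0 baseline samples")
  set.seed(derive_seed(model$seed, 11))
  groups <- rownames(model$host_mult)
  other_mass <- 1 - sum(model$baseline)
  asv <- list(); gw <- list()
  for (i in seq_len(nrow(design))) {
    s <- design$sample_id[i]; t <- design$treatment[i]; day <- design$day[i]
    mult <- if (day == 0) setNames(rep(1, length(groups)), groups)
            else model$host_mult[, t]
    mass <- model$baseline * mult[groups] * exp(rnorm(length(groups), 0, model$sigma_host))
    rel <- mass / (sum(mass) + other_mass)
    asv[[s]] <- data.frame(sample_id = s, group = c(groups, "other"),
                           rel_abund = c(rel, other_mass / (sum(mass) + other_mass)),
                           stringsAsFactors = FALSE)
    bt <- if (day == 0) setNames(rep(1, length(groups)), groups)
          else model$burst[, t]
    w <- rel * bt[groups] * exp(rnorm(length(groups), 0, model$sigma_virus))
    gw[[s]] <- data.frame(sample_id = s, group = groups, weight = unname(w),
                          stringsAsFactors = FALSE)
  }
  asv <- do.call(rbind, c(asv, make.row.names = FALSE))
  gw <- do.call(rbind, c(gw, make.row.names = FALSE))
  vw <- NULL
  if (!is.null(viruses)) {
    vt <- viruses$viruses
    base <- setNames(rlnorm(nrow(vt), 0, 0.5), vt$id)
    bg_mass <- other_mass  # decoy/background virus mass, constant over time
    vw <- list()
    for (s in unique(design$sample_id)) {
      gws <- gw[gw$sample_id == s, ]
      w <- numeric(nrow(vt))
      for (g in groups) {
        sel <- vt$true_host_group == g & !vt$decoy
        if (any(sel)) {
          share <- base[vt$id[sel]] / sum(base[vt$id[sel]])
          w[sel] <- gws$weight[gws$group == g] * share
        }
      }
      sel <- vt$decoy
      if (any(sel)) {
        share <- base[vt$id[sel]] / sum(base[vt$id[sel]])
        w[sel] <- bg_mass * share * exp(rnorm(sum(sel), 0, model$sigma_virus))
      }
      vw[[s]] <- data.frame(sample_id = s, virus_id = vt$id,
                            weight = w / sum(w), stringsAsFactors = FALSE)
    }
    vw <- do.call(rbind, c(vw, make.row.names = FALSE))
  }
  list(asv = asv, group_weights = gw, virus_weights = vw)
}

# Draw reads from a set of source sequences with probabilities `prob`,
# uniform positions, random strand, and substitution errors.
draw_reads <- function(seqs, prob, n, read_length, error_rate, id_prefix) {
  lens <- nchar(seqs)
  if (read_length > min(lens)) {
    stop("read_length (", read_length, ") exceeds shortest genome (",
         min(lens), ")")
  }
  src <- sample.int(length(seqs), n, replace = TRUE, prob = prob)
  pos <- floor(runif(n) * (lens[src] - read_length + 1)) + 1L
  rd <- substring(seqs[src], pos, pos + read_length - 1L)
  minus <- runif(n) < 0.5
  if (any(minus)) rd[minus] <- revcomp(rd[minus])
  nerr <- rbinom(n, read_length, error_rate)
  for (i in which(nerr > 0L)) {
    p <- sample.int(read_length, nerr[i])
    b <- strsplit(rd[i], "")[[1]]
    b[p] <- vapply(b[p], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
    rd[i] <- paste(b, collapse = "")
  }
  data.frame(id = sprintf("%s_%06d", id_prefix, seq_len(n)),
             seq = rd, source_id = names(seqs)[src], source_pos0 = pos - 1L,
             strand = ifelse(minus, "-", "+"), n_errors = nerr,
             stringsAsFactors = FALSE)
}

#' Simulate virome reads per sample
#'
#' Reads are drawn from virus genomes proportional to weight times genome
#' length, plus a host-contamination fraction drawn from host genomes
#' uniformly per base, with substitution errors at the model's per-base
#' rate.  Deterministic given the model seed.
#'
#' @param viruses A `synthetic_viruses` object.
#' @param weights Per-sample virus weights (`sample_id`, `virus_id`,
#'   `weight`), normalized per sample.
#' @param model A `treatment_model`.
#' @param hosts Optional `synthetic_hosts`, required when
#'   `contamination_fraction > 0`.
#' @return Named list per sample: `reads` (id, seq) with ground-truth source
#'   columns.
#' @export
simulate_virome_reads <- function(viruses, weights, model = default_treatment_model(),
                                  hosts = NULL) {
  stopifnot(inherits(viruses, "synthetic_viruses"))
  cf <- model$contamination_fraction
  if (cf > 0 && is.null(hosts)) stop("hosts required when contamination_fraction > 0")
  set.seed(derive_seed(model$seed, 23))
  out <- list()
  for (s in unique(weights$sample_id)) {
    ws <- weights[weights$sample_id == s, ]
    w <- setNames(ws$weight, ws$virus_id)
    vseqs <- viruses$genomes[names(w)]
    nv <- round(model$n_reads * (1 - cf))
    prob <- w * nchar(vseqs)
    reads <- draw_reads(vseqs, prob / sum(prob), nv, model$read_length,
                        model$error_rate, paste0(s, "_v"))
    if (cf > 0) {
      hseqs <- hosts$genomes
      hr <- draw_reads(hseqs, nchar(hseqs) / sum(nchar(hseqs)),
                       model$n_reads - nv, model$read_length,
                       model$error_rate, paste0(s, "_h"))
      reads <- rbind(reads, hr)
    }
    out[[s]] <- reads
  }
  out
}

#' Emit the reference databases for host prediction
#'
#' Provirus proteins labelled by host group, the hallmark
#' structural/replication subset, and a CRISPR spacer list of planted 32-nt
#' virus substrings (positives) plus random sequences (negatives).
#'
#' @param hosts A `synthetic_hosts` object.
#' @param viruses Optional `synthetic_viruses` used to plant positive
#'   spacers.
#' @param n_spacers_pos,n_spacers_neg Number of planted and random spacers.
#' @param spacer_length Spacer length in nt (default 32).
#' @param seed Integer seed.
#' @return List with `provirus_proteins`, `hallmark` (subset), and `spacers`
#'   (`spacer_id`, `seq`, `planted`, `source_id`).
#' @export
emit_reference_dbs <- function(hosts, viruses = NULL, n_spacers_pos = 10,
                               n_spacers_neg = 10, spacer_length = 32,
                               seed = 1) {
  stopifnot(inherits(hosts, "synthetic_hosts"))
  set.seed(derive_seed(seed, 37))
  pp <- hosts$provirus_proteins
  spacers <- NULL
  pos <- NULL
  if (!is.null(viruses) && n_spacers_pos > 0) {
    vids <- sample(names(viruses$genomes), n_spacers_pos, replace = TRUE)
    start <- vapply(viruses$genomes[vids],
                    function(g) sample.int(nchar(g) - spacer_length, 1L), 1L)
    pos <- data.frame(
      spacer_id = sprintf("spacer_pos_%03d", seq_len(n_spacers_pos)),
      seq = substring(viruses$genomes[vids], start, start + spacer_length - 1L),
      planted = TRUE, source_id = vids, stringsAsFactors = FALSE)
  }
  neg <- NULL
  if (n_spacers_neg > 0) {
    neg <- data.frame(
      spacer_id = sprintf("spacer_neg_%03d", seq_len(n_spacers_neg)),
      seq = vapply(seq_len(n_spacers_neg), function(i) random_dna(spacer_length), ""),
      planted = FALSE, source_id = NA_character_, stringsAsFactors = FALSE)
  }
  spacers <- rbind(pos, neg)
  rownames(spacers) <- NULL
  list(provirus_proteins = pp, hallmark = pp[pp$hallmark, , drop = FALSE],
       spacers = spacers)
}
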