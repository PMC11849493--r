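---
title: "Methods: models, thresholds and design choices in nitrivir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in nitrivir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

nitrivir implements the virome side of a differential-inhibition incubation
experiment on nitrifying soil communities. Urea-amended microcosms receive
inhibitors with different specificities — DMPP and 1-octyne suppress
ammonia-oxidizing bacteria (AOB), acetylene suppresses all ammonia oxidizers —
so that growth of ammonia-oxidizing archaea (AOA), AOB and *Nitrospira* can be
attributed to treatment, and viruses infecting each group can be identified by
the co-enrichment of their sequences in virus-size-fraction metagenomes
("viromes"). This vignette explains the models behind each stage, the
parameters that matter, and the choices made where the design was genuinely
open. Nothing here states an empirical result that the package's tests or
acceptance script do not themselves compute.

## The synthetic community is the study condition

Every stage is exercised against a generator
(`generate_hosts()`, `generate_viruses()`, `simulate_dynamics()`,
`simulate_virome_reads()`, `emit_reference_dbs()`) that emits ground truth
alongside the data. Its defaults are the study conditions, fixed once:

* **Hosts.** Three groups (AOA, AOB, *Nitrospira*), two clades per group.
  Genome lengths default to 2 Mb (AOA, AOB) and 3 Mb (*Nitrospira*) — genome size is
  not a modelled quantity, so round prokaryote-typical values are used.
  GC targets are 0.40 / 0.52 / 0.56. AOA genomes embed the six-gene core
  panel (*amoA*, *amoB*, *amoC*, MCO1, MCO4, *nirK*) at cohort-average
  lengths 651, 587, 567, 1120, 1333 and 1336 bp. Copy numbers 2.9 (*amoC*)
  and 1.25 (MCO4) are cohort averages, so they are realized as integer
  cycles (nine genomes with 3 copies and one with 2, etc.); the cycles are
  exact at cohort sizes that are multiples of 20. Every host carries one
  provirus region of ten protein-coding genes (four hallmark
  structural/replication genes, an integrase, five accessory genes) derived
  from a group-level ancestor with 10% per-host divergence.
* **Viruses.** Genome lengths are drawn uniformly from 34.5–173.3 kb, the
  range spanned by known nitrifier-infecting virus genomes. GC tracks the host group: mean 0.437 for AOA viruses
  versus 0.547 otherwise, with the backbone composition compensated for the
  GC of inserted genes so the realized genome GC hits the target. Each
  non-decoy virus carries `homologs_per_virus` (default 5) genes copied from
  its true host's provirus at a default amino-acid identity of 60%
  (substitutions only — no indels — keeping identity testable on both sides
  of the 30% filter). Lysogenic viruses (default probability 0.44)
  additionally carry a mutated integrase; the marker is the ground truth for
  the lifestyle flag. A configurable decoy set carries only 2 homologs and
  acts as the non-nitrifier background community. A planted stop codon
  upstream of every inserted gene prevents flanking sequence from extending
  the reading frame and diluting query coverage.
* **Treatment dynamics.** Day-0 baselines are 1.7% (AOA), 0.07% (AOB) and
  1.7% (*Nitrospira*) of the 16S pool. Day-30 host multipliers encode the
  differential-inhibition responses the design emulates: AOA 1.6 / 2.8 / 2.4 under urea / urea+DMPP /
  urea+1-octyne; AOB 22 / 8 under urea / urea+1-octyne; *Nitrospira* 2.1
  under urea+1-octyne; 1 elsewhere, and 1 for everything under acetylene.
  Virus weights are host abundance × a burst factor with shared lognormal
  replicate noise (`sigma_virus`, default 0.10 on the natural-log scale — a
  ~10% replicate CV, typical of virome relative abundances). Burst factors
  default to 1 except AOA viruses under uninhibited urea (0.65): the
  emulated condition includes an AOA virome response under plain urea that
  lags the 1.6-fold host growth and does not reach significance, and that
  contrast is part of what the generator reproduces. Burst sizes and absolute virus:host
  ratios are otherwise free parameters with no asserted values.
* **Reads.** Single-end 150 nt (matching 2 × 150 bp chemistry; pairing adds
  nothing the pipeline tests), substitution errors at 0.005/base, and a
  tunable `contamination_fraction` of reads drawn uniformly per base from
  host genomes (default 0.02; 1.0 gives the host-only null scenario).

What the generator deliberately does **not** emulate: assembly (contigs are
emitted, not assembled), indels and structural variation, quality-score
models, chimeras, strand bias, and real inter-genome mosaicism. Passing
tests therefore demonstrate correctness of the analysis logic under the
stated statistical structure, not robustness to assembly artefacts or real
soil community complexity.

## vOTU clustering

`pairwise_similarity()` fulfils the MIUViG-style contract: identity is
matches over aligned columns summed across merged local alignments (both
strands), coverage is the aligned fraction of the *shorter* contig. The
engine is k-mer seeded (k = 15, encoded as base-4 integers) with ungapped
diagonal verification over 500-bp windows of the shorter sequence — adequate
because the contract is defined over merged local alignments and the
divergence model is substitution-only. Windows below 30% identity are
treated as unaligned. `cluster_votus()` performs greedy centroid clustering,
longest contig first (ties broken lexicographically), joining a contig to
the first representative reaching identity ≥ 0.95 and coverage ≥ 0.85; on
transitive inputs this equals single-linkage components, which the tests
verify against an independent union–find oracle. Whether coverage is taken
over the shorter or the query contig, and whether clustering is greedy or
transitive, are convention choices on which practice varies; both are
exposed as arguments and the defaults are stated here.

Lysogeny is flagged by annotation keywords (integrase / excisionase /
repressor) on the representative's proteins rather than by an external
predictor, keeping the pipeline self-contained and testable against the
planted truth.

## Host prediction

`call_orfs()` emits maximal start-to-stop ORFs (first ATG after the previous
stop, ≥ 60 aa) on all six frames. `protein_best_hits()` is a seeded local
BLOSUM62 alignment (gap open 11, extend 1) with Karlin–Altschul statistics
(gapped λ = 0.267, K = 0.041; e-values corrected by query length × database
residues). One best hit per query is retained and must pass *all four*
thresholds — amino-acid identity > 30%, e-value < 1e−5, bit score > 50,
query coverage > 70% — as strict inequalities. `predict_host()` calls the
group with the most retained homologs when that count is ≥ 3. Two open
interpretations were fixed as: homologs count toward the host *group* (any
genome of the group), and ties between groups yield `none` with a warning.

The CRISPR scan (`crispr_spacer_match()`) is exhaustive: every spacer and
its reverse complement, at most 2 substitutions, no indels; tests hold it
equal to a position-by-position oracle. The gene-sharing network clusters
proteins into single-linkage components over pairs at ≥ 50% identity and
≥ 80% bidirectional coverage — single linkage rather than a greedy
representative scheme, because two viral copies of one gene at ~60%
identity to their full-length reference sit near ~36% mutual identity, and
only the reference can bridge them into one cluster. Genome pairs are
scored by the hypergeometric tail P(X ≥ shared clusters), corrected by the
number of genome pairs, and edges kept at −log10(corrected p) ≥ 1 — the
conventional gene-sharing default, since no cutoff is documented. Two
scale effects matter on small cohorts: an overlap of only 3 clusters in a
cluster universe of a few hundred is not always significant at that floor
(real reference databases put thousands of clusters in the universe and
make the same overlap decisive), and the all-frame ORF caller overcalls
short spurious proteins, so the pipeline's network stage admits only
proteins ≥ 100 aa.

## Abundance profiling and enrichment

`recruit_reads()` places each read at its best seeded location on either
strand and counts it when identity ≥ the floor over ≥ 90% of the read
length; equal-identity ties between contigs are dropped (conservative).
Detection is strict (breadth ≥ 0.85 at the 0.95 identity floor) or relaxed
(breadth ≥ 0.10 at 0.90); thresholds are inclusive and nothing is rounded
before comparison. RPKM is reads / (kb of contig) / (millions of mapped
reads).

`compare_groups()` selects Tukey's HSD after a median-centred Levene test at
α = 0.05, otherwise Kruskal–Wallis with a hand-implemented Dunn post-hoc
test (tie-corrected, Holm-adjusted), and emits a compact letter display.
`enrichment_calls()` compares each day-30 treatment against day 0 on
log-transformed abundances and requires three things of an enrichment:
adjusted p < 0.05, a day-30 mean above day 0, and fold change ≥ 1.5. The
effect-size floor follows standard differential-abundance practice; with
triplicate microcosms a pure significance rule would let familywise type-I
noise masquerade as enrichment of an uninhibited group. The smallest
fold change treated as a real contrast in the emulated conditions is 2.1,
so the floor does not exclude any of them.

`host_virus_regression()` is ordinary least squares of virus abundance on
host relative abundance with R², the two-sided slope p, and the 95% CI.

## Family demarcation

`genome_similarity()` sums bit scores of translated local alignments: the
six-frame translations of genome A are cut into 60-aa fragments, placed on
the six-frame translations of genome B by shared amino-acid 5-mers, and
verified with local BLOSUM62 alignment; alignments under 40 bits are treated
as noise (random 60-aa fragments against a translated genome rarely exceed
~35 bits). The self-score of a fragment is its best contiguous diagonal run
with stops scored as X — exactly what the alignment path computes — so
normalized(a, a) = 1. Both strands of both genomes contribute to cross- and
self-scores alike, so the double counting cancels in the normalization.
Normalization divides by the *smaller* self-score (default), which keeps a
genome fully contained in a larger one at high similarity — the behaviour
wanted for provirus-derived references; `norm = "geometric"` and
`threshold_is_distance` switch the conventions. Families are single-linkage
components at normalized score ≥ 0.05. The 0.05 value is treated as a
similarity floor; the alternative distance reading is available behind the
flag because the demarcation value is used in the field under both
conventions.

## AMG quantification and the contamination null

`map_reads_to_core_genes()` assigns each read to its best panel gene at
nucleotide identity ≥ 0.90 (the within-clade divergence of the panel is
< 10%). A read counts when at least *half* of it aligns inside the gene:
with uniform genomic read starts, the number of qualifying positions then
equals the gene length exactly, which makes the contamination null —
expected raw counts ∝ mean length × mean copies, hence expected relative
profile = copy-number ratio (1, 1, 2.9, 1, 1.25, 1 against MCO1) — an exact
fixed point of `normalize_profile()`. A 90%-of-read rule would shrink every
gene's effective target by ~120 bp and bias short genes by up to ~10%,
breaking the null it is meant to test.

Because profiles are normalized to MCO1, a genuine viral MCO1 excess would
appear as uniform suppression of the other five genes; `amg_enrichment_test()`
therefore centres the per-sample observed/expected ratios on their median
across genes before testing, attributing the deviation to the gene that
carries it. Reference gene, identity floor and the panel itself are
parameters.

## Numerical conventions

Reported percentages and fold changes are rounded half-up to one decimal
(matching the reporting style of the summary tables); nothing is rounded
before a threshold comparison. Coordinates in emitted tables are 0-based
half-open. All randomness flows from a single seed fanned out to per-stage
seeds by fixed offsets; identical seeds give byte-identical outputs.

## Problem sizes

The default `run_pipeline()` configuration and the test suite run
scaled-down communities chosen as the smallest sizes at which every
statistical property under test is identifiable: 2 hosts per group, 6–20
viruses per group at 11–60 kb, 1 000–4 000 reads per sample for the
end-to-end run; 30 planted species × 3 variants for the clustering oracle;
the full default cohort (60 viruses + 20 decoys at paper-scale genome
lengths) for host-prediction recovery; 100 000 reads for the host-only
contamination null; 20 seeded replicates for the treatment-contrast
recovery; 1 000 simulations for type-I control. The acceptance script
reruns all of these from scratch.

## Known limitations

* The nucleotide engine is substitution-only; indel-rich divergence would
  fragment its diagonals and underestimate identity. Real vOTU clustering
  at 95% ANI tolerates indels that this engine does not model (the
  generator does not produce them either).
* ORF calling requires ATG starts and one genetic code; alternative starts
  and recoding are out of scope.
* Karlin–Altschul constants are the standard gapped BLOSUM62 values, not
  estimated per scoring system.
* The gene-sharing network uses greedy protein clustering, not Markov
  clustering; component structure on borderline cohorts may differ from
  vConTACT-style tools.
* `compare_groups()` with triplicates has limited power in its
  rank-based branch; the Levene gate means strongly heteroscedastic inputs
  get the robust but weak test, which is the intended trade-off.
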