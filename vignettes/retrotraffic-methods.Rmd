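---
title: "Methods: retrogene discovery, dating, and gene-traffic statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrogene discovery, dating, and gene-traffic statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrotraffic)
```

`retrotraffic` implements a complete interchromosomal retrogene analysis:
discovery of retrogene/parental pairs from a focal annotated genome,
synteny-based dating of each event onto phylogenetic stages, directional
gene-traffic statistics against a random-movement expectation, and
classification of sex-biased and spermatogenesis-stage expression. This
vignette explains the model behind each step, the tunable parameters, the
numerical choices, and what the bundled simulator does and does not
emulate.

## Data model and coordinates

GFF3 files are 1-based inclusive on disk; internally every interval is
0-based half-open, and `read_annotation()` / `write_annotation()` are the
only conversion points, which removes the usual off-by-one drift. Exons of
minus-strand genes are stored in transcription order (reversed genomic
order) so that "first exon" always means the 5' exon — the orientation in
which exon-junction evidence is interpreted. Multi-isoform genes are
reduced to the longest-protein isoform, ties broken by lexicographic mRNA
id; the selection rule is a package convention, chosen because it is
deterministic and favors the most complete coding structure. Genes on
chromosomes missing from the chromosome table stay available to the
alignment screen but are flagged unplaced and excluded from chromosome
statistics, since direction classes need a chromosome identity.

## Pair discovery

Candidate paralog pairs are scored by local protein alignment
(Smith–Waterman with BLOSUM62, affine gap open 11 / extend 1, the familiar
protein-BLAST parameterization; a gap of length L costs 11 + L). The
filters, all exposed in `identification_config()`:

* `min_identity = 0.30` — identity computed over aligned columns, gaps in
  the denominator. Computing identity over aligned columns rather than
  full length is one of two defensible readings; it is the one that makes
  the 30% threshold meaningful for partially diverged pairs, and it is
  stated here explicitly because the choice matters near the cutoff.
* `min_reciprocal_coverage = 0.70` — aligned residues divided by each
  protein's *full length*, required of both genes. Using the full length
  as denominator (not the alignment envelope) reads "reciprocal coverage"
  in its strict sense and rejects truncated copies.
* `junction_flank_bp = 30` (10 aa) — a parental exon junction counts as
  supported when its residue maps inside the alignment with at least 10
  gapless aligned residue pairs on both sides and the retro copy has no
  intron at the mapped position. Junctions falling on a codon boundary are
  assigned to the preceding residue — an arbitrary but deterministic rule.
  At least one supported junction is required.
* `short_intron_bp = 50` — a putative parent whose longest intron is below
  50 bp is structurally ambiguous (it could itself be a partially
  intron-gaining copy); such pairs, and pairs with tied exon counts, are
  re-assigned by cross-species synteny conservation (the gene with the
  strictly larger conserved-neighbor score is the parent) or dropped with
  a recorded reason. Dropping rather than guessing keeps the pair list
  interpretable.
* `require_interchromosomal = TRUE` — chromosome arms sharing an
  `arm_group` (2R/2L → "2") are one chromosome, so same-arm-group pairs
  are excluded: the traffic categories are whole-chromosome.

A retrogene matched by several candidate parents keeps the
highest-identity pair (ties → longer parent protein), because each
retroduplication has a single source locus.

Before exact alignment, an optional shared k-mer prescreen
(`seed_k = 4`, `min_seed_kmers = 3`) limits which pairs are aligned, in
the same spirit as BLAST seeding; every surviving pair is still scored by
the exact alignment. The screen is a heuristic: pairs in the 30–40%
identity range with few conserved 4-mers can in principle be missed, and
`prescreen = FALSE` disables it when completeness matters more than time.

## Synteny conservation and dating

Local gene order is compared by walking outward from a locus and its
ortholog simultaneously (up to `flank_window = 10` genes per side) and
counting how far the flanks stay collinear through the ortholog map; the
two sides are summed, both relative orientations are tried (a locally
inverted block still conserves order), and gene strand is ignored — order,
not orientation, is the criterion. Support requires
`min_conserved_neighbors = 2`. The strict collinear-run rule is
deliberately conservative: a single inserted gene in the other species
truncates the run. That is harmless for the simulator's clean data and
errs toward younger, better-supported stage calls on real data.

Stages PS1 (youngest) to PS9 (oldest) label consecutive branch intervals
of the focal root path; each non-focal species carries the stage of the
branch where its lineage attaches, at the branch's recent end, so an event
on branch PSk is shared by species with stage ≤ PSk and the most distant
supporter determines the call. Presence without synteny support never
advances a call, and outgroup species are only checked for absence. For
real data the ortholog map is an input (e.g. a reciprocal-best-hit table);
computing orthology internally would bundle a second inference problem
into a dating module, so it is intentionally external. In simulated
clades, orthology is by construction (shared family names).

Grouping follows the sex-chromosome history of the clade: PS1–PS7 lineages
have differentiated sex chromosomes ("young" events), PS8–PS9 predate them
("old"), with a finer PS1–PS4 vs PS5–PS7 split of the young group.

## The traffic expectation model

Under random movement, the chance that a retroduplication goes from
chromosome *s* to chromosome *t* is proportional to

\\[ w(s \\to t) = G_s \\, D_s \\, A_t \\, F_t \\]

with `G` source gene counts, `D` source dosage weights, `A` target
insertion weights, and `F` target fixation weights. The defaults encode
the biology of an X-autosome system: full dosage compensation makes an
X-linked source gene contribute as much mRNA as an autosomal one
(`D_X = 1`); insertion opportunity scales with chromosome length
(`A_t` = length, switchable to gene count); and the X's smaller effective
population size penalizes fixation of X-landing copies (`F_X = 0.75`,
autosomes 1). Direction frequencies are normalized sums of the pair
weights, so they are invariant to uniform rescaling of any one weight
family — only ratios matter. All four families are configuration, not
constants: published expectation percentages depend on each study's
annotation counts and weight conventions, so the model is parameterized
rather than hard-coded.

Departures are reported as `excess_rate()` =
100·(observed − expected)/expected per direction (−100% means an expected
direction was never observed; a direction with zero expected share but
positive observations is undefined and reported `NA`).

## Significance testing

`permutation_chisq()` is a Monte-Carlo goodness-of-fit test: `n_perm`
multinomial samples of the observed total are drawn under the expected
frequencies, the Pearson chi-square statistic of each replicate is
compared with the observed one, and the add-one estimate
`p = (1 + #{T* ≥ T}) / (n_perm + 1)` is returned, so p can never fall
below 1/(n_perm+1) and is reproducible bit-for-bit given a seed. The
default `n_perm = 1e6` matches the scale at which such tests are usually
reported; the test suite and acceptance script use reduced replicate
numbers, with problem sizes stated below.

One property worth understanding: with a small observed total (tens of
events), the chi-square statistic takes few distinct values, so the null
distribution of p is a step function — the test is valid but
conservative, exactly like any exact-style discrete test. The package's
null-calibration check therefore simulates at a total of 400 events,
where the statistic's support is dense and uniformity of p under the null
is the meaningful property to verify; at n = 28 the same check would
measure discreteness, not miscalibration.

Contingency comparisons use the standard machinery: `odds_ratio()`
(Haldane–Anscombe +0.5 on zero cells, flagged), `woolf_ci()`
(normal-theory interval on the log odds ratio with
SE = sqrt(1/a+1/b+1/c+1/d)), and `fisher_exact()` (two-sided by summing
hypergeometric probabilities at most as large as the observed table's).
No multiple-testing correction is applied anywhere; p values are reported
raw, matching how such analyses are usually presented, and any correction
is the caller's decision.

## Expression classification

Platform handling in `normalize_expression()`: microarray values are
consumed as log2 RMA (pass-through); RNA-seq abundances get the offset
TPM + 1e-3; spermatogenesis FPKM values are transformed ln(FPKM + 1) per
sample, and stage means are averages on that log scale.

`call_sex_bias()` uses the two-tailed *equal-variance* Student's t test at
`alpha = 0.05` between male and female reproductive-organ groups — Student
rather than Welch because the equal-variance form is the stated
convention for this kind of two-group replicate comparison, and the
per-gene calls are deliberately uncorrected. A gene is `male` when
p < 0.05 with the higher testis mean, `female` in the reverse case,
`unbiased` otherwise, and `no_data` with fewer than two replicates per
group. Degenerate all-constant groups resolve to p = 1 (equal means) or
p = 0 (different means) rather than erroring. Microarray and RNA-seq
calls are kept separate and may disagree; no reconciliation rule is
invented, because the disagreement is itself informative.

`classify_stage_profile()` calls `later_stage_max` when the maximum of
meiosis I, meiosis II and postmeiotic means strictly exceeds the
premeiotic mean — the profile expected of autosomal retrogenes escaping
MSCI — and `premeiotic_max` otherwise, with exact ties going to
`premeiotic_max` (the conservative side: ties never count as escape
evidence). The classification is invariant to any monotone transform
applied to all four means.

`paired_wilcoxon()` drops zero differences, midranks ties, and computes
the exact signed-rank null distribution for n ≤ 25 by a shift-algorithm
convolution over the doubled midranks — equivalent to enumerating all 2^n
sign assignments, including tied ranks, which the textbook no-tie tables
cannot handle. Larger samples use the normal approximation with
continuity correction and the tie-corrected variance Σr²/4. Two-sided p
is the probability of a statistic at least as far from its mean as
observed; with all differences zero, p = 1. `stats::wilcox.test()` was
not used as the engine because it cannot produce exact p values in the
presence of ties or zeros; where both are exact (continuous data, n ≤
25), the two agree to numerical precision, and the test suite checks
this.

## The simulator

`sim_scenario()` fixes a study-like world: one focal species, one species
per stage PS1–PS9, two outgroups; one X-like chromosome (24 Mb) and two
autosomes (98 and 84 Mb) carrying 300 background genes (20/45/35%); nine
planted retroduplications, one per stage, cycling over the three
directions at a 90% protein identity target, plus one decoy of each class
(tandem intron-keeping duplicate, 60% truncation, 25%-identity homolog);
and expression with a 2-fold (1 log2 unit) effect for truly biased genes,
replicate noise sd 0.35 on the log2 scale, and 4 replicates per group —
an effect/noise/replication regime with closed-form t-test power ≈ 0.92,
typical of a well-powered organ-level comparison. Stage profiles encode
the MSCI motif: X-linked parents of X→A events decline after the
premeiotic stage, their autosomal retrocopies rise, and everything else
gets a gently declining baseline so that flat-profile ties cannot
masquerade as escape. A single seed fixes every draw; the generator
restores the caller's RNG state.

Planted copies are mutated at the codon level to hit their protein
identity target (plus extra synonymous changes, so DNA diverges faster
than protein — the discovery filters act on protein identity). Retrocopies
are inserted at a fixed anchor position of the target chromosome in every
species at or below the event's stage, which gives them ≥ 2 conserved
flanking neighbors there and complete absence beyond.

What the simulator does **not** emulate, and hence what passing tests do
not show about real data: no indels, codon models or selection; no
annotation errors, missing orthologs, or assembly fragmentation;
orthology is exact by construction; expression noise is Normal (log2
scale) or lognormal (TPM) with equal group variances, with none of the
heavy-tailed, batch-structured variation of real microarray/RNA-seq sets.
The pipeline's filters and statistics are exercised faithfully; its
robustness to annotation noise is bounded separately by the conservative
synteny rule.

## Problem sizes used by the checks

The test suite and acceptance script run at desk scale by choice: default
clades of 300 background genes across 12 species (about 15 s end to end),
60-gene clades for module tests, 2 000 null trials at 1 000 Monte-Carlo
replicates for the calibration check (at a simulated total of 400 events,
for the discreteness reason above), 2 000 genes for the type-I-error
check and 800–1 000 for the power check, enumeration oracles at n ≤ 10
(signed rank) and margins ≤ 30 (Fisher).

## Known limitations

* The collinear-run synteny rule under-counts conserved neighbors across
  lineage-specific insertions; with noisy annotations it biases stage
  calls young, never old.
* The k-mer prescreen can miss true pairs near the 30% identity floor;
  disable it for exhaustive screens.
* The expectation model treats insertion opportunity as a single
  per-chromosome weight; insertion hotspots and local chromatin are out
  of scope.
* Sex-bias calls assume equal group variances and at least two
  replicates; single-replicate designs return `no_data` rather than a
  guess.
* The discovery step searches one focal genome; per-species discovery
  across a clade is a matter of looping, but cross-species pair
  reconciliation is not implemented.
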