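---
title: "bacmine: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bacmine: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacmine)
```

# Scope

bacmine mines bacteriocin genes from gut metagenomes and relates their
presence to within-species strain diversity. It implements, at desk scale,
every stage of that analysis: a six-frame translated protein search with
E-value filtering, a per-sample bacteriocin gene abundance statistic,
infant-like vs adult-like enrichment testing with FDR control and prevalence
tiers, clustering of bacteriocins by normalized alignment bit score,
screening of a genome collection into per-taxon profiles, k-mer
read-to-genome classification with community profiling, a rarefied
genome-count diversity analysis fit with an analysis of covariance, and an
operon scan of contigs. A synthetic-data generator with complete ground
truth replaces the terabyte-scale public data the full-size analysis would
need, so that every stage is testable end to end.

# The statistics

## Bacteriocin gene abundance

For each sample, every read is translated in all six reading frames and
locally aligned (Smith-Waterman, BLOSUM62, gap open 11, gap extend 1)
against the bacteriocin protein database. A raw score $S$ converts to a bit
score $S' = (\lambda S - \ln K)/\ln 2$ with the ungapped Karlin-Altschul
constants $\lambda = 0.267$ nats and $K = 0.041$ applied to gapped scores as
an approximation, and a hit's E-value is $E = m \, n \, 2^{-S'}$, where $m$
is the read's summed translated length and $n$ the summed database length
(no edge-effect correction — a documented dialect difference from blast).
Hits with $E > 10^{-5}$ are discarded. The bacteriocin gene abundance of a
sample is the number of *distinct* reads with at least one surviving hit
divided by the total read count; a read hitting several proteins counts
once. Per-class (I/II/III) and per-protein columns are computed the same
way, so the overall count is at most the sum and at least the maximum of the
class counts.

Candidate (read frame, protein) pairs are found with exact 4-mer protein
seeds (`X` never seeds) followed by an ungapped X-drop extension; pairs
whose ungapped score reaches 40 are rescored with full dynamic programming.
`mode = "full"` bypasses seeding entirely and is used as the exactness
escape hatch in tests. Alignments never pair a residue with a stop symbol,
and ties are broken deterministically (lowest start coordinate, then
earliest end).

## Enrichment

Samples are grouped by age — infant 0–1, child 2–9, adolescent 10–19, adult
20–59, elderly 60–107 — and the infant group forms the infant-like
superclass; everything else is adult-like. Each bacteriocin is tested with a
one-sided Wilcoxon rank-sum test for larger abundance in infant-like
samples, exact by enumeration when both groups have at most 8 observations
and no ties, otherwise a normal approximation with tie and continuity
corrections; all-tied input returns 0.5 by the continuity convention. The
approximation is within 0.02 of the exact enumeration for tie-free groups
of 3–8 (at 2 per group the gap can reach 0.044, which is why the package
switches to enumeration there). p-values are converted to Benjamini-Hochberg
q-values (a Storey-style option exists but BH is the tested default, being
deterministic). A bacteriocin must be significant at $q < 0.01$ **and**
present (abundance $> 0$) in at least 10% of infant-like samples; survivors
are tiered by infant prevalence: high above 30%, medium in the closed
interval 20–30%, low from 10% up to 20%. The prevalence filter is applied
to the unclustered protein ids, before clustering, following the order of
the analysis stages.

## Bacteriocin clustering

The similarity of proteins $A$ and $B$ is $2S(A,B)/(S(A,A)+S(B,B))$ on
local-alignment bit scores, exactly 1.0 for identical sequences;
$S(A,B)$ is symmetrized as the larger of the two alignment orderings.
Clusters are the connected components of the graph with edges at similarity
$\ge 0.95$ — single linkage, the minimal closure of "pairs above threshold
are one bacteriocin". No linkage is canonical here, so components were
chosen as the least committal reading; cluster ids are the smallest member
id and the representative is the member with the smallest enrichment q-value
when q-values are supplied.

## Genome screening and taxon profiles

A cluster is present in a genome if any member protein hits it below the
E-value threshold (presence is boolean; co-member hits are not double
counted). The profile value for a taxon is the fraction of its genomes with
a hit, computed without weighting — each input genome counts once. Rendered
profiles drop taxa at or below 0.01 by default; the full table is always
kept. A cluster's associated species is the species with the highest
fraction (ties broken by genome count, then name) and feeds the diversity
analysis.

## Classification and community profiles

The classifier indexes every canonical k-mer (k = 31 by default,
lexicographic minimum of k-mer and reverse complement) of every genome with
an owner: the genome when unique, the species when shared only within one
species, or an ambiguous marker when shared across species. A read is
assigned to the genome with a strict plurality of genome-level votes; ties
and vote-free reads stay unassigned — genome-or-nothing, with no LCA
fallback, mirroring a custom per-genome database. Community profiles use
raw assigned-read counts; the Aitchison (centered log-ratio) transform adds
a pseudocount of 0.5 to zero cells before closure (a standard, overridable
choice), and beta diversity is the first two principal components of the
transformed matrix. Shannon diversity is $-\sum p \ln p$ over species with
$p > 0$.

## Strain diversity and the covariance model

For one bacteriocin cluster and its associated species, infant-like samples
are labelled bacteriocin-positive when the cluster's abundance after the
E-value filter is positive. Classifications are rarefied to a fixed depth by
uniform sampling without replacement (exactly the configured depth;
under-depth samples are excluded with a warning rather than scaled). Each
sample contributes $y$ = the number of distinct genomes of the species with
at least one assigned read (no minimum-read threshold), and $x$ = reads
assigned to the species per million. The model

$$ y_i = b_0 + a_0 I_i + b_1 x_i + e_i $$

is fit by ordinary least squares; $a_0$ is the diversity shift between
bacteriocin-positive and negative samples at matched abundance, tested
two-sided ($a_0 = 0$ vs $a_0 \ne 0$) even though the scientific hypothesis
is directional. Degenerate designs (single indicator level, constant or
collinear $x$) raise explicit errors. Panels whose species has fewer than
4 genomes are flagged low-resolution rather than dropped.

# The synthetic world

`synthetic_config()` defines the study conditions. The generator emulates:

- **Age structure** — samples drawn in the five age groups, ages uniform
  within each group's range.
- **Lower infant alpha diversity** — species weights are Dirichlet with
  per-species shape `alpha / n_species`; infants default to concentration 4
  against the adult-like `n_species` (12), reproducing the lower infant
  Shannon index. A single knob controls the whole pattern.
- **Strain structure** — each species has 2–4 genomes derived from a common
  backbone by 0.5% point mutations (pairwise backbone identity about 99%,
  above the 97.5% clustering floor of reference collections), and every
  genome carries a 500 bp genome-unique marker region so the classifier's
  ground truth is well defined. The marker occupies a visible fraction of a
  10 kb toy genome, so *whole-genome* identity is lower than the backbone
  identity; identity claims are about the shared backbone.
- **Planted bacteriocins** — each genome carries each bacteriocin gene
  independently with probability 0.05 (so roughly 46% of genomes carry
  something and bacteriocin-negative communities remain constructible). A
  carried gene is the cluster's base protein reverse-translated with a fixed
  preferred-codon table plus a stop codon — deterministic and guaranteed to
  give a perfect six-frame hit. One copy per carrier; copy number within a
  genome is not modelled.
- **Database variants** — within-cluster variants (identity $\ge 0.95$) use
  conservative substitutions (non-negative BLOSUM62 pairs): arbitrary
  substitutions on 40–80 residue proteins can push the normalized bit-score
  similarity below 0.95 even at 97% identity, which would contradict what
  "within-cluster variant" is supposed to mean. Lower-identity variants
  (intended as separate clusters) substitute freely.
- **Planted enrichment** — infant samples multiply carrier-genome weights by
  `infant_enrichment_factor` (default 3, matching the roughly threefold
  median abundance ratio the phenomenon shows) before renormalization. The
  realized mean abundance ratio approaches the factor when the carrier
  weight share is small; renormalization compresses it otherwise.
- **Planted diversity effect** — each sample has a latent bacteriocin-
  positive state (probability `carrier_sample_prob`). Positive samples keep
  a carrier strain in the community and add `diversity_effect` extra strains
  for carrier species over a baseline presence draw of identical size;
  negative samples swap carrier strains out at unchanged size. The expected
  difference in strains present at matched abundance therefore equals the
  planted value — provided species have enough strains that the addition is
  not truncated, which is why parameter-recovery experiments use 6–8 strains
  per species.
- **Reads** — uniform substrings of present genomes, either strand, with
  i.i.d. substitution errors (default 0.5%); read counts are exact, ids
  encode source genome, offset and strand, and constant Q30 qualities are
  written because no stage consumes qualities. Identical configurations give
  byte-identical outputs.

What the generator does **not** emulate: platform error profiles, paired
ends, GC or coverage bias, real taxon names, copy-number variation, or the
381,000-genome scale of real reference collections. Passing tests show the
machinery is correct and calibrated on communities with these simplified
properties; they do not certify performance on real gut metagenomes.

# Problem sizes and calibration experiments

The packaged experiments run on one CPU in minutes, chosen as the smallest
worlds in which each property is identifiable:

- Default end-to-end world: 12 bacteriocins × 2 variants, 12 species × 2–4
  strains of 10 kb, 30 samples × 5,000 reads of 150 bp.
- Enrichment power: factor 10, 50 infant-like + 50 adult-like samples of
  50,000 reads. The remaining knobs isolate the abundance mechanism: matched
  Dirichlet concentration (60) in both groups, all strains present, every
  sample harboring the community, and sparse carriage (0.01 over 24 genes).
  Dense carriage would hand most of the community weight to carriers and the
  renormalization would absorb the multiplier; unmatched concentrations
  shift the rank-sum null; and zero-inflating both arms merely dilutes the
  test. Those features are exercised by their own tests (alpha-diversity
  contrast, prevalence tiers, FDR null) rather than being confounded with
  power.
- FDR null: factor 1, 200 bacteriocins, 25+25 samples × 20,000 reads.
- Classifier: every marker region tiled with error-free 150 bp reads.
- Covariance model: record-level simulations (n = 30–100, 200+ replicates)
  for bias, coverage and null-uniformity; a read-level world with 6–8
  strains per species for end-to-end recovery of the planted shift.

# Numerical choices

- Gap of length $L$ costs $11 + L$; scores are integers; stop pairings are
  forced to a large negative score so local alignments reset at stops.
- Residues outside the matrix alphabet score via the wildcard `X` row (note
  BLOSUM62 as distributed includes `B`, `Z` and `J` as scored residues).
- The seeded search keeps the best hit per (read, protein) pair; unique-read
  counting makes HSP multiplicity irrelevant.
- E-values use per-query summed translated length; the filter is applied
  after exact rescoring, so no emitted hit exceeds the threshold.
- Rarefaction is deterministic per (sample, seed); BH q-values are monotone
  and capped at 1; `prevalence_tier` treats 20% and 30% as closed endpoints
  of the medium tier, ">30%" as strict, and "at least 10%" as closed.
- All randomness flows from the configuration seed; identical configurations
  reproduce identical file digests in the run manifest, and a completed run
  directory is reused rather than recomputed unless forced.

# Known limitations

- The Karlin-Altschul constants are ungapped values applied to gapped
  scores; E-values are therefore approximate (conservatively so for strong
  hits, which is all the pipeline consumes).
- The seeded search can miss weak hits lacking an exact 4-mer seed with
  ungapped score 40; planted genes are found exactly, and `mode = "full"`
  exists for exhaustive scoring.
- Abundance ratios between groups are compressed by weight renormalization
  when carriers dominate a community.
- The ANCOVA is a linear model of a count response; it is the analysis the
  pipeline is specified to perform, not the best conceivable count model
  (no Poisson/negative-binomial alternative is offered by design).
- Single-linkage clustering can chain distinct bacteriocins through
  intermediate variants; at the 0.95 threshold and desk-scale databases this
  was never observed in testing.
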