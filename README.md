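# bacmine

Bacteriocins are ribosomally synthesized antibacterial peptides and proteins
(class I: modified, <10 kDa; class II: unmodified, <10 kDa; class III:
>10 kDa) that bacteria use against close relatives. In the infant gut, where
founder communities compete for a new habitat, bacteriocin genes are more
abundant than in adults — and species exposed to a bacteriocin tend to show
*higher* within-species strain diversity, not less.

`bacmine` is an R package for the full analysis behind that observation, at
a scale a laptop can run and test:

1. **Translated search** — every metagenome read is translated in six frames
   and locally aligned (BLOSUM62, gap 11/1) against a bacteriocin protein
   database; hits are filtered at E-value `1e-5` using Karlin–Altschul
   statistics, `E = m·n·2^(−S′)` with `S′ = (λS − ln K)/ln 2`. The
   **bacteriocin gene abundance** of a sample is the number of distinct
   matching reads divided by total reads.
2. **Enrichment** — samples are grouped by age (infant 0–1 = "infant-like";
   child/adolescent/adult/elderly = "adult-like"); each bacteriocin is
   tested with a one-sided Wilcoxon rank-sum test for higher abundance in
   infant-like samples, corrected to Benjamini–Hochberg q-values, filtered
   at q < 0.01 and ≥10% infant prevalence, and tiered (high >30%, medium
   20–30%, low 10–20%).
3. **Clustering** — enriched bacteriocins are grouped at normalized
   bit-score similarity `2S(A,B)/(S(A,A)+S(B,B)) ≥ 0.95` (single linkage;
   identical sequences score exactly 1.0).
4. **Genome screen** — a strain-resolved genome collection is screened per
   cluster; the per-taxon profile is the fraction of the taxon's genomes
   with a hit, and the top species becomes the cluster's associated species.
5. **Strain diversity** — reads are classified to individual genomes with a
   canonical k-mer index (genome-or-nothing, strict plurality vote),
   rarefied to a fixed depth, and each infant-like sample contributes
   `y` = genomes of the species detected, `x` = reads per million assigned
   to it, and `I` = bacteriocin presence. The analysis of covariance

   ```
   y = b0 + a0·I + b1·x + e
   ```

   is fit by least squares; `a0 > 0` means bacteriocin-positive samples
   carry more strains at matched species abundance (two-sided test of
   `a0 = 0`).
6. **Operon scan** — contigs carrying an enriched bacteriocin are cut
   ±10 kb, ORFs (ATG-to-stop, ≥30 aa) are extracted and annotated against a
   categorized reference set; a locus reports `+`/`−` flags for bacteriocin,
   immunity and secretion genes at E < 1e-5.

A synthetic-data generator (`synthetic_config()`, `make_bacteriocin_db()`,
`make_genome_collection()`, `simulate_metagenomes()`) produces age-labelled
metagenomes with planted enrichment and diversity effects and full ground
truth, so the whole pipeline is testable without external databases.

## Worked example

A synthetic world with 8 bacteriocins (×2 database variants), 10 species of
3–5 strains, 40 age-structured samples of 10,000 reads, a 10× infant
enrichment factor and a planted diversity effect of 1 extra strain:

```r
library(bacmine)

world <- synthetic_config(
  seed = 42L,
  n_bacteriocins = 8L, variants_per_bacteriocin = 2L,
  n_species = 10L, strains_per_species = c(3L, 5L), genome_length = 12000L,
  carriage_prob = 0.04, infant_enrichment_factor = 10,
  infant_alpha_diversity = 10, adult_alpha_diversity = 10,
  diversity_effect = 1, strain_presence_prob = 0.5, carrier_sample_prob = 0.9,
  n_samples_per_group = c(infant = 20L, child = 8L, adolescent = 2L,
                          adult = 6L, elderly = 4L),
  reads_per_sample = 10000L)

res <- run_pipeline(run_config(outdir = "bacmine_run", synthetic = world))
```

Abundance by age group (infant median ~5× the other groups; one-sided
rank-sum p of infant vs each group):

```
      group  n median_abundance p_vs_infant
     infant 20           0.0222          NA
      child  8           0.0045    0.000150
 adolescent  2           0.0000    0.017179
      adult  6           0.0087    0.000451
    elderly  4           0.0000    0.002034
```

Enriched bacteriocins (q < 0.01, prevalence ≥ 10%) — both variants of each
enriched gene are found and then merged into one cluster:

```
 bacteriocin  q_value infant_prevalence tier
   bac001_v1 2.35e-03              0.90 high
   bac001_v2 2.35e-03              0.90 high
   bac002_v1 1.47e-04              0.90 high
   ...
   bac007_v2 8.55e-05              0.90 high
```

Strain-diversity fits per cluster, on its associated species (the planted
effect is +1 strain in bacteriocin-positive samples; `a0` is the estimated
shift, with its standard error and the p-value for `a0 = 0`):

```
   cluster species  n     a0 se_a0   p_a0
 bac001_v1    sp07 20  1.112 0.387 0.0105
 bac002_v1    sp03 20  0.791 0.323 0.0253
 bac003_v1    sp10 20  0.754 0.494 0.1451
 bac004_v1    sp03 20 -0.357 0.478 0.4654
 bac007_v1    sp02 20  0.346 0.486 0.4866
```

Most panels estimate a positive shift of roughly the planted size; at 20
samples per panel not every one reaches significance — the same picture the
method gives on real data, where panel power varies with species abundance.
All stage tables, a run manifest with file digests, and a plain-text report
are written under the output directory; re-running with the same
configuration reuses the completed run.

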