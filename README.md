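# insilico16S

Full-length 16S rRNA gene sequencing reads the whole ~1.5 kb gene in one
molecule, but most microbiome studies still sequence one hypervariable
sub-region (V1–V2, V1–V3, V3–V4, V4 or V5–V9) between conserved
primer-binding sites. How much taxonomic resolution does each sub-region
give up relative to the full gene — and how much does variation *inside*
the primer-binding sites themselves bias what each region can see?

`insilico16S` answers this the way it is done for long-read skin-microbiome
cohorts: sub-regions are excised *in silico* from full-length reads by
locating each degenerate primer pair, and the same community analyses are
run on every region so that differences are attributable to the region
alone. The package is aimed at microbiome researchers choosing a 16S
region (skin and other low-biomass sites especially) and at anyone who
needs a fully ground-truthed, download-free testbed for amplicon pipeline
logic.

## What the pipeline computes

- **In-silico extraction.** Each region is delimited by IUPAC-degenerate
  primers (27F `AGRGTTTGATYNTGGCTCAG`, 1492R `TASGGHTACCTTGTTASGACTT`, and
  the canonical internal pairs 338R/341F, 515F/534R, 799F/805R/806R). A
  primer matches a read window when every position is inside the code's
  expansion set, allowing up to 4 mismatches per primer (Hamming,
  substitution-only). Capture efficiency `n_extracted / n_input` must clear
  98%, and a seeded random audit verifies each extracted sequence is an
  exact substring of its parent read.
- **Features.** Exact-sequence dereplication (the ASV stand-in) and greedy
  abundance-ordered OTU clustering at 97/98/99% identity, with identity
  from global alignment (match +1, mismatch −1, gap −2, free terminal
  gaps).
- **Taxonomy.** A k-mer bootstrap voter (k = 8, 100 bootstraps): each
  bootstrap draws ⌈W/8⌉ of the variant's W k-mers, votes for the best
  shared-k-mer reference species, and per-rank confidence is the fraction
  of agreeing votes; lineages are truncated below confidence 0.8. A
  sub-region species call is **concordant** only when it equals the species
  assigned to its parent full-length variant.
- **Diversity.** Shannon index H = −Σ pᵢ log₂ pᵢ, Bray-Curtis
  dissimilarity Σ|x−y| / Σ(x+y) on relative abundances, principal
  coordinate analysis (double-centering of −D²/2) and UPGMA trees.
- **Biomarkers and site prediction.** A LEfSe-style screen
  (Kruskal-Wallis p < 0.05 plus a one-vs-rest effect size
  log₁₀|mean_g − mean_rest| ≥ 4 on per-million scale) and a seeded
  500-tree random forest evaluated with per-class precision, recall,
  F1 = 2PR/(P+R) and mean-decrease-Gini importance rankings.
- **Primer-binding-site variation.** Full-length reads are deduplicated,
  each primer's binding site is tallied across unique sequences, variants
  under 5 reads or 0.1% are excluded, and the rest are dot-masked against
  the consensus, flagged where bases escape the primer's degenerate
  coverage, and associated with the taxa that carry them.

A synthetic community generator provides the ground truth: 16S-like
templates (nine variable blocks separated by conserved blocks carrying the
real primer sites), a 7-rank taxonomy, five site-specific community
profiles whose oral analog is strongly divergent, and error-bearing reads
with per-primer-site mismatch budgets.

## Worked example

```r
library(insilico16S)

ref      <- build_reference(n_species = 60, n_genera = 20, seed = 42)
profiles <- community_profiles(ref, seed = 43)
rs       <- sample_reads(profiles$NaS, ref, n_reads = 300,
                         substitution_rate = 0.002, seed = 44)

v13 <- default_regions()$`V1-V3`
ext <- extract_read_set(rs$reads, v13)
cap <- capture_report(ext, rs$reads, seed = 45)

ok  <- ext[ext$status == "extracted", ]
vs  <- dereplicate(data.frame(read_id = ok$read_id, sample_id = "NaS01",
                              sequence = ok$sequence), min_count = 2)
asg <- classify_variants(vs, kmer_classifier(ref), seed = 46)
```

This prints (via the obvious `sprintf` calls):

```
V1-V3 capture: 300/300 reads (100.0%), audit pass 100%
24 variants; 96% annotated to species
OTUs at 97/98/99%: 10/13/17
```

Meaning: every read's V1-V3 slice was located within the 4-mismatch primer
budget and verified as an exact substring of its parent; the 300 reads
collapse to 24 repeated variants (singletons dropped), 96% of which are
confidently classified to species against the reference; and OTU counts
rise with the identity threshold, as they must.

## The analysis

`analysis/01_simulate.R` … `analysis/07_primer_variation.R` run the full
comparison on a 47-sample, five-site synthetic cohort (seed 2024; tables
under `results/`). Highlights of that run:

- capture efficiency 100% for all six regions, pooled and per sample
  (`capture_report.tsv`);
- species-concordant variant counts ordered V1-V9 (138) > V1-V3 (119) >
  V1-V2 (109) > V3-V4 (94) > V5-V9 (67) > V4 (38) — the V1-V3 region
  tracks full-length resolution most closely and V4 least
  (`concordance.tsv`);
- the oral-analog site separates sharply in every region (mean Bray-Curtis
  to skin sites ≈ 0.95 vs ≈ 0.3 within skin; `pcoa_*.tsv`,
  `upgma_*.nwk`);
- 26 of the LDA ≥ 4 biomarkers are shared by all six regions; random-forest
  site accuracy ranges 85.7–92.9% with top-30 importance overlaps of 22–25
  genera against the full-length model (`biomarkers.tsv`,
  `rf_evaluation.tsv`, `importance_overlap.tsv`);
- all four planted taxon-linked primer-site variants are recovered and
  attributed to the right genus (`primer_variants.tsv`).

Run the scripts in order from the repository root; intermediates are
cached under `scratch/`.

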