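---
title: "Comparing full-length 16S with its hypervariable sub-regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing full-length 16S with its hypervariable sub-regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insilico16S)
```

# The question and the approach

Short-read microbiome studies sequence one hypervariable region of the 16S
rRNA gene; long-read platforms read the whole gene. When both are options,
the choice should rest on how much each sub-region concedes — in species
resolution, diversity estimates, biomarker discovery and sample
classification — relative to the full gene, and on how sequence variation
inside the primer-binding sites biases what a primer pair can amplify at
all.

`insilico16S` makes that comparison controlled: sub-regions are excised
computationally from the *same* full-length reads, so every downstream
difference is attributable to the region, not to library preparation.
Because real cohorts come with unknown ground truth, the package ships a
synthetic community generator whose truth is known exactly; every stage of
the pipeline is validated against it.

# In-silico extraction

Each region is delimited by a forward and a reverse degenerate primer
(defaults: V1-V2 = 27F/338R, V1-V3 = 27F/534R, V3-V4 = 341F/805R,
V4 = 515F/806R, V5-V9 = 799F/1492R, V1-V9 = 27F/1492R; all overridable via
`region_def()`, since labs differ in their exact pairs). Matching is
substitution-only Hamming over IUPAC expansion sets — a window base
matches primer code `R` iff it is `A` or `G`, and `N` matches everything.
Indels inside a ~20 nt primer footprint are rare enough that modeling them
would complicate the coordinate arithmetic for no measurable gain.

The scan is exhaustive over every window of the read (no positional
prior — robust to length variation, and trivially cheap at these scales),
keeping the hit with the fewest mismatches under the default budget of
**4 mismatches per primer**, applied independently to the forward and
reverse primer. Ties break *leftmost* for forward primers and *rightmost*
for reverse primers so that a primer pair brackets the widest candidate
region. Reads arrive in either strand, so each read is first oriented by
whichever orientation gives the anchor primer (the region's forward
primer) fewer mismatches; an exact tie leaves the read unflipped.

The extracted sequence *excludes* the primer footprints, matching the
primer-trimmed convention of CCS pre-processing (an `include_primers`
flag restores them). Failures are statuses, not errors: `fwd_missing`,
`rev_missing`, `both_missing`, `malformed_order`. Capture efficiency is
checked against a 98% threshold — reported both pooled and per sample,
since either granularity can be the operative QC — and a seeded random
audit (default 100 draws) re-verifies that extracted sequences are exact
substrings of their parent reads.

One geometric subtlety worth knowing: with the canonical pairs, the 806R
binding site begins 2 nt downstream of the 805R site, so the V4 amplicon
overhangs the V3-V4 amplicon by 2 nt. Extraction nesting
(V1-V2 ⊂ V1-V3 ⊂ V1-V9) therefore holds exactly everywhere *except* that
V4 ⊂ V3-V4 holds only after trimming that overhang. This is a property of
the primers themselves, not of the implementation.

# Features: variants and OTUs

Exact-sequence dereplication stands in for error-model denoising: it is
deterministic, transparent, and sufficient for cross-region comparisons
that only need a consistent feature definition. An optional `min_count`
filter (default 1, i.e. keep singletons) lets analyses drop lone
error-bearing reads; the bundled analysis uses `min_count = 2` because at
a 10⁻³ substitution rate most singletons are single-error copies of an
abundant variant.

OTUs use a single greedy centroid pass in (abundance descending, sequence
ascending) order: a variant joins the qualifying centroid of highest
identity (ties to the earliest-founded centroid) or founds a new cluster.
Identity comes from global alignment with free terminal gaps
(match +1, mismatch −1, gap −2), identity = matching columns / alignment
columns excluding terminal-gap columns. Among equal-score alignments the
maximum-match (then minimum-column) alignment defines the value, which
makes identity a deterministic function of the pair — important because
the greedy pass is order-sensitive and must be reproducible. The
fast-heuristic machinery of production clusterers (k-mer sorting, early
termination) is deliberately not reproduced.

# Taxonomy and the concordance rule

The classifier is a naive k-mer bootstrap voter: with word size k = 8,
each of 100 bootstraps draws ⌈W/8⌉ of the variant's W k-mers with
replacement, scores every reference species by shared-k-mer count, and
votes for the argmax (ties to the lexicographically smallest taxon id).
Per-rank confidence is the fraction of votes agreeing with the winning
lineage at that rank — non-increasing with depth by construction — and
the lineage is truncated at the deepest rank with confidence ≥ 0.8. The
0.8 rule is applied uniformly at all ranks, species included: nothing in
the workflow justifies a separate species threshold, and uniformity keeps
the concordance comparison interpretable. Variants shorter than k are
unclassified. This is a desk-scale, reproducible stand-in for
bootstrap-confidence classifiers, not a reimplementation of any of them;
its posteriors will not match production classifiers numerically.

The deterministic tie-break has one visible consequence: a variant whose
k-mers are *exactly* equidistant between two sibling species (e.g. a V4
slice of species that differ only in V1–V3) is voted consistently to one
sibling rather than splitting 50/50, so it reaches species rank — and is
then usually counted *discordant* by the concordance rule below. Queries
that are near- but not exactly equidistant split their votes and truncate
to genus, as expected.

Species concordance scores a sub-region against the full-length standard:
a region variant is eligible when both it and its parent full-length
variant carry species-level calls, and concordant only when the two
species agree — a species call that contradicts the full-length call does
not count, even though it reaches species rank. Parents are assigned by
majority vote over the reads composing the region variant (ties to the
lexicographically smallest parent id).

# Diversity and ordination

Shannon uses log base 2 (bits) by default — common in amplicon practice —
with the base configurable. Tables are not rarefied; Bray-Curtis is
computed on relative abundances so that sequencing-depth differences do
not masquerade as community differences (raw-count mode exists via
`relative = FALSE`). PCoA double-centers −D²/2 and eigendecomposes;
negative eigenvalues (non-Euclidean D) are clamped to zero for the
proportion-explained denominator, and each axis is flipped so its
largest-magnitude coordinate is positive, which fixes the sign
indeterminacy deterministically. UPGMA is average-linkage agglomeration
with node height = merge distance / 2, so trees are ultrametric to
numerical precision; Shannon cross-group comparisons use two-sided Welch
t-tests (unequal variances are the safe default for per-site spread).

# Biomarkers and site prediction

The biomarker screen mirrors LEfSe's shape without reproducing its
internals, which are not fully specified anywhere usable: features are
scaled to parts-per-million per sample, screened by Kruskal-Wallis at raw
p < 0.05 (raw by convention for this screen), and scored one-vs-rest as
`log10(max(|mean_g − mean_rest|, 1))`, passing at score ≥ 4. The floor at
1 pins "no separation" to score 0 on the ppm scale. LEfSe's subclass
(Wilcoxon) stage is omitted — the design has no subclass structure. Under
label exchange on i.i.d. features the screen must be silent at
threshold 4 and the Kruskal-Wallis hit rate must sit at the nominal 5%;
both are asserted by simulation in the test suite.

The site-origin classifier is deliberately pluggable: the package owns
the stratified 70/30 split (per-site proportional, remainders to train),
the per-class precision/recall/F1 and overall accuracy on the percent
scale (2-decimal convention), and the mean-decrease-Gini top-30 ranking
(descending, ties lexicographic); the forest itself is an off-the-shelf
seeded 500-tree random forest. F1 arithmetic is validated against a
bundled table of published per-site precision/recall/F1 percentages from
a five-site skin cohort.

# Primer-binding-site variation

Full-length reads are oriented, exactly deduplicated, and each primer's
binding site is located with the same 4-mismatch search the extraction
uses — so sites mutated beyond the budget stay invisible, mirroring the
detection bias of primer-based methods (an unlimited-budget mode exists
for sensitivity analysis). Site sequences are tallied weighted by read
counts; variants backed by fewer than 5 reads or less than 0.1% of the
located total are excluded. The fraction denominator is the
located-and-weighted total for that primer (the "total" is ambiguous
otherwise; this choice is internally consistent). The consensus — the
most frequent site sequence — is always retained and rendered in full;
other variants are dotted at consensus-identical positions. Each variant
position is flagged when its base falls outside the primer's degenerate
expansion, and variants are attributed to taxa by grouping their backing
reads by deepest confident lineage.

# The synthetic community

Templates follow the real gene's architecture: nine variable blocks
separated by conserved blocks, five of which are concrete E. coli-like
realizations carrying the canonical primer sites at their natural
relative offsets (338R/341F share a block, 515F/534R share a block,
799F/805R/806R share a block). The default template is 1359 nt — inside
the 1.2–1.65 kb window of full-length filtering.

Defaults, chosen once as a realistic desk-scale cohort: 120 species in 40
genera (3 per genus, 8 species-distinguishing substitutions each), five
sites with 10/10/10/7/10 samples (a one-third-scale analog of a
30/31/30/20/30 cohort), 200 reads per sample, per-base substitution rate
10⁻³ (CCS-like accuracy). Half of the non-backbone species confine their
distinguishing substitutions to the V1–V3 blocks — those species pairs
are invisible to the V4 slice, which is what gives the region-resolution
ordering something to detect; the resolution-ranking checks set this
fraction to 1 to make the contrast sharp. Community structure: four skin
sites mix a shared Dirichlet core (weight 0.5) with site-specific draws,
while the oral analog puts 95% of its mass on a reserved quarter of the
genera; this guarantees (provably, not just empirically) that
oral-to-skin Bray-Curtis exceeds any skin-to-skin distance and that
top-10 genus overlap with the oral site stays under 20%. Four genera
carry a taxon-linked single-base primer-site variant — inherited by all
their species — as ground truth for the variation catalog. Substitutions
landing in a primer site obey a separate rate and a hard per-site cap, so
capture-efficiency experiments control their mismatch burden exactly;
the cap counts *injected* substitutions, on top of any taxon-linked
variant the reference itself carries.

What the generator does **not** emulate: chimeras (removed upstream by
standard tools in real pipelines), indels and length-heterogeneous 16S
copies within a taxon, realistic long-read error profiles (quality
strings are a constant 'I'), and reference databases with uneven
coverage. Passing tests therefore demonstrate the pipeline's logic and
its parameter-recovery behavior under the stated model — not performance
on real skin swabs, where database incompleteness and intragenomic copy
variation dominate species-level error.

One consequence of fixed per-species divergence is worth stating: with 8
substitutions per species, siblings sit at ~99.4% full-length identity
(merging at 97/98% OTU thresholds) but at ~96–97% identity over a short
region that concentrates their differences (splitting). Full-length OTU
counts can therefore come out *lower* than sub-region counts at fixed
thresholds — threshold-based OTU counts measure where divergence falls
relative to region length, which is exactly why the rest of the pipeline
compares regions on concordance, diversity and classification rather than
on raw OTU tallies.

# Numerical conventions and problem sizes

Coordinates are 0-based half-open internally, 1-based closed in
user-facing tables. Distance matrices must be symmetric to 1e-12 with an
exactly zero diagonal; PCoA round-trips Euclidean configurations to
1e-9 and UPGMA ultrametricity is asserted to 1e-9. All randomness flows
through explicit seeds (one root seed per run, fixed offsets per stage),
and generator output is byte-identical across runs at the same seed. The
test suite runs its heavier checks at deliberately modest sizes — a
500-read capture experiment, a 2000-read clean run for the
region-resolution ordering, 1000 random primer-scan instances and 200
random alignment pairs against independent oracles, a 500-feature null
screen — sizes at which every asserted contrast is already decisive. The
bundled analysis uses 47 samples × 200 reads; scaling these up changes
wall time, not conclusions.

# Known limitations

Beyond the generator's idealizations above: the mismatch model ignores
position-within-primer effects (a 3' mismatch is not worse than a 5'
one, unlike real PCR); the classifier's confidence calibration is tied
to this reference's divergence structure; the LDA-score surrogate is not
numerically comparable to LEfSe's published scores (only the thresholded
decisions are comparable in spirit); and greedy OTUs depend on the
abundance ordering, as all greedy clusterings do — the fixed tie-breaks
make this deterministic, not order-free.
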