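---
title: "Methods: processing non-overlapping paired 16S reads and validating them against full-length signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: processing non-overlapping paired 16S reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paired16S)
```

## The problem

Amplicon surveys of the 16S rRNA gene often target large hypervariable
regions (V3–V5 with the 357F/926R primer pair, V6–V9 with 968F/1492R) that
were designed for long-read platforms. Sequenced as 2×250 bp paired ends,
the two mates of such an amplicon do not meet in the middle: R1 covers the
first 250 bases after the forward primer, R2 covers the 250 bases before the
reverse primer (delivered reverse-complemented), and an unsequenced gap
remains between them. Standard single-read workflows either discard one mate
or analyze the mates separately, losing information.

`paired16S` keeps both mates linked through the entire analysis. The design
rests on two joined representations of a read pair, each matched to what the
downstream algorithm can tolerate:

* **Direct concatenation** (R1+R2). Dereplication, greedy OTU picking and
  read-to-OTU mapping only require that all reads be globally alignable and
  of uniform length — concatenating uniformized mates satisfies that without
  pretending the gap is sequence.
* **N-gap stitching** (R1+`N`+R2). Word (k-mer) classifiers skip any word
  containing an ambiguous base, so with a single `N` at the junction no word
  spans it: the classifier sees exactly the union of R1's and R2's words and
  the gap contributes nothing. This is what makes taxonomy assignment on
  joined reads safe.

R2 is never reverse-complemented: reads stay exactly as sequenced, and the
two orientation-sensitive steps are themselves orientation-insensitive (the
classifier is trained on both strands; the structural aligner threads each
mate in its better-scoring orientation).

## Pipeline stages and their parameters

**Quality filtering** follows the common trimming semantics: a hard Q3
cutoff at the 5' and 3' ends (`lead_q = 3`, `trail_q = 3`), a 4-base
sliding-window mean-quality cutoff of Q15 scanning from the 5' end
(truncating at the first failing window's start — the cut rule is stated
here explicitly so the tests have an unambiguous oracle), a minimum
surviving length of 3/4 of the original read length, and removal of any
read still containing a non-ACGT character. The length cutoff uses floor
rounding — the only rule consistent with all three canonical values
(112/150 bp, 187/250 bp, 225/300 bp). Reads emptied by trimming simply fail
the length rule. When R1 and R2 were sequenced at different lengths, each
mate is measured against its own original length.

**Pair uniformization.** Only ids present in both mate files survive. R1 is
kept whole; R2 is truncated to 4/5 of its original length (200 bp for
250 bp reads) because read-2 quality degrades toward the 3' end. Reads
already shorter than the cutoff are kept as they are. The 0.8 default
follows the worked example above rather than any larger round figure; it is
configurable (`pair_join_params()`).

**OTU picking** (`pick_otus()`) is abundance-sorted greedy clustering at
97% identity over dereplicated, singleton-free, length-screened clusters.
Identity is defined as matching columns over alignment columns, terminal
gap columns excluded, from a +1/−2 match/mismatch, −10/−1 gap alignment
with free terminal gaps. This definition presumes the uniform-length reads
the pipeline constructs; on such reads the optimal alignment covers the
full length. Candidate centroids are pre-screened by a shared 8-mer bound:
a single edit destroys at most 8 words, so a pair sharing fewer than
`W − 8·m_max` distinct words provably cannot reach the identity threshold
and is never aligned. The screen is exact, not heuristic, apart from the
cap of 16 alignments per candidate (word-count ranking puts the true best
hit at the top in practice).

**Chimera screening** uses a two-parent (bimera) model: a candidate is
flagged when two existing centroids, each with at least twice the
candidate's abundance, can explain it as an A-prefix + B-suffix at ≥ 99%
identity while no single centroid reaches the 97% threshold. Parents below
85% single-parent identity are not considered (a bimera whose minor parent
falls that low is near-identical to its major parent and is handled by
absorption). A pairwise word bound again filters impossible parent pairs
before any profile is computed. This is a deliberately simple bimera model;
it is not an emulation of any particular published chimera detector's
internals.

**Taxonomy** (`train_classifier()` / `classify_seq()`) is a naive Bayes
word classifier with word size 8. Word priors are
`P(w) = (n(w)+0.5)/(N+1)`; genus conditionals are
`P(w|G) = (m(w)+P(w))/(M+1)`. Presence is indexed from both strands of
every reference, which yields exact strand symmetry of the winning genus.
Distinct words are scored, not multiplicities. Confidence comes from 100
bootstrap resamples of `ceiling(W/8)` words; ranks below 0.80 confidence
are masked as `unclassified` (both values are the defaults of the widely
used implementation of this classifier). OTU representatives that are
unclassified at *all seven ranks* — the strictest reading of "fully
unclassified" — are removed as presumed contaminants.

**Structural alignment** (`align_to_template()`) threads each read into the
fixed column space of a seed alignment: the best template row is chosen by
shared 8-mer count (both query orientations considered), the query is
aligned globally-in-query / locally-in-template, matched bases are placed
into the row's columns, and query insertions relative to the template are
dropped but counted, so the information loss is visible. Global-in-query
scoring is what gives the negative-score filter its teeth: an unrelated
query must pay for every unmatched base and lands below zero, whereas
free-end-gap scoring would let it escape with a trivial non-negative
overlap. A query sharing no 8-mer with any row in either orientation is
assigned score −1 directly. Paired reads are split at their recorded
`pair_split`, threaded per mate (a structural aligner cannot bridge the
unsequenced gap), filtered pairwise — either mate negative removes the
pair — and rejoined column-wise (R1-region columns, then R2-region
columns). Exact-substring queries short-circuit the dynamic program; the
result is identical to the alignment optimum.

**Phylogeny.** Empty columns are stripped; pairwise Jukes–Cantor distances
use pairwise deletion, with saturation (p ≥ 0.74, or no shared columns)
mapped to a fixed distance of 5.0 — an arbitrary large value that keeps the
matrix finite. Trees are built by neighbor joining (via ape) with negative
branch lengths clamped to zero. NJ over JC69 was chosen because the
validation design compares trees *to each other* through Mantel
correlations of cophenetic matrices, which needs a consistent deterministic
method rather than any particular likelihood engine; `read_newick()` /
`write_newick()` provide the hook for substituting an external tree.

**β-diversity.** `unifrac_matrix()` implements classic unweighted UniFrac:
the fraction of branch length leading exclusively to leaves present in only
one of the two samples, over the branch length leading to leaves present in
either; branches leading only to globally absent leaves are excluded from
the denominator. Trees stored unrooted act as degree-3 junctions at the
root, so no artificial root edge enters the computation. An empty sample is
at distance 1 from any non-empty sample and 0 from another empty sample —
a documented convention, not a statistical claim. `mantel_test()` wraps the
standard vegan implementation (Pearson on lower triangles, one-sided
"greater", `(1+k)/(1+n)` permutation p, 999 permutations by default);
`wilcoxon_signed_rank()` computes the exact two-sided null by convolution
over tie-averaged ranks up to n = 25 and a continuity-corrected normal
approximation beyond.

## The synthetic validation framework

The generator (`simulate_reference()`) stands in for a curated full-length
reference database so the whole comparison runs from scratch:

* A pure-birth (Yule) tree with `n_taxa` leaves, scaled to unit height, is
  the ground truth.
* A random 1550-nt root sequence carries the five canonical primer sites
  (27F, 357F, 926R, 968F, 1492R; reverse primers embedded as reverse
  complements). Site coordinates are spaced so that both the V3–V5 and
  V6–V9 250+250 bp read pairs are non-overlapping, as they are on the real
  gene. Primer sites are mutation-protected, so in-silico PCR recovers an
  amplicon from 100% of taxa by construction.
* Sites evolve under per-site substitution with expected root-to-tip
  divergence `sub_rate` (default 0.15 substitutions/site at profile mean 1,
  which puts typical full-length pairwise identities in the 75–99% band —
  sister taxa straddle the 97% OTU threshold, so read length genuinely
  matters for clustering resolution). The rate profile has a conserved
  backbone (0.4) and nine hypervariable windows; V3/V4 are broad and
  moderately hot (2.4/2.0) while V5 is narrower and cooler (1.6),
  reflecting the documented variability ranking V3 > V4 > V5 of the gene.
  The contrast is kept moderate deliberately: an extreme narrow hot spot
  inside one read makes that read's distance estimates a high-variance,
  compressed transform of the true distances, which misrepresents how the
  real regions behave.
* `indel_rate` must be 0: the reference set's contract (primer sites at
  identical coordinates in every taxon; the true gapless alignment doubles
  as the seed template) is incompatible with indels, so they are rejected
  rather than half-supported.
* Taxonomy labels come from cutting the tree at depth fractions
  0.15/0.3/0.45/0.6/0.75/0.9 of root height (phylum → species); the domain
  is the constant `Bacteria_sim`. The cuts are arbitrary but deterministic.
* Communities: each sample draws `ids_per_sample` distinct reference ids
  uniformly without replacement; each id receives a clone count from the
  log-series distribution `p(n) = −x^n / (n log(1−x))` with `x = 0.9`
  (mean ≈ 3.9 clones) — the classic species-abundance model; the exact
  parameter is a declared choice, and results are insensitive within
  x ∈ (0.8, 0.99). Identical id+multiplicity sets are instantiated in all
  four library types (R1, R2, paired, full-length), which is the property
  the entire comparison rests on. For community building the mates are
  joined *untrimmed* (the synthetic reads are already uniform and perfect).

What the generator does **not** emulate: sequencing error and quality-score
structure (validation reads are perfect; the quality-filter module is
exercised by its own unit tests instead), PCR chimeras, indel variation,
intragenomic 16S copy heterogeneity, and real rRNA secondary structure.
Passing validation therefore demonstrates that the paired-read machinery
preserves more of the full-length signal than single reads *given clean
reads*; it does not measure robustness to sequencing noise.

## Validation harnesses

* `taxonomy_benchmark()` holds out a fraction (default 0.3) of the taxa of
  every genus with at least two members, trains on the rest, and classifies
  the held-out taxa's reads in four forms: full-length, R1 (250 bp), R2
  uniformized to its pipeline length (200 bp — the benchmark mirrors what
  the pipeline actually classifies), and the N-gap stitched pair. Accuracy
  is the per-rank percentage of queries whose assigned name equals the
  truth, with unclassified counting as wrong (per-query denominator).
* `compare_beta_diversity()` runs the validation pipeline per community and
  library type, computes unweighted UniFrac matrices between the samples,
  and reports each short-read matrix's Mantel r against the full-length
  matrix. By default it mirrors the contaminant-free validation procedure
  (no taxonomy screening); `classify = TRUE` enables the full pipeline's
  cleaning stage.
* `compare_phylogenies()` implements the comparable-trees procedure: OTUs
  are picked from the full-length library only, the representatives' source
  ids define equivalent read sets in all four types, each set is aligned
  and treed independently, and the trees — which share leaf ids by
  construction — are compared through Mantel correlations of their
  cophenetic matrices.
* Wilcoxon signed-rank p-values across communities require at least five
  communities; at the default desk scale (3 communities × 8 samples × 150
  ids over 400 taxa, chosen to preserve the experiment's structure while
  completing in minutes on one CPU) they are reported as NA. The original
  experiment's scale (100 × 20 × 2,500) is reached simply by raising
  `community_design()`; that run is a cluster-scale job, not part of the
  test suite.

## Numerical and tie-breaking conventions

Dereplication sorts by decreasing cluster size, then lexicographically by
sequence, then by representative id (the lexicographically smallest member
id), so all downstream results are invariant under input permutation.
Mapping ties at equal identity go to the larger-abundance centroid, then
the lower OTU index. Classifier ties go to the lexicographically first
genus. Template-row ties go to the first row. All randomness (bootstrap
resampling, Mantel permutations, the simulator) flows from explicit seeds;
`mantel_test()` restores the caller's RNG state.

## Known limitations

The template-threading aligner is a pipeline-role stand-in for a
covariance-model aligner: it preserves the split/align/rejoin logic and the
negative-score filter, but its scores are on a different scale and it drops
query insertions instead of modeling them. The chimera screen is a
simplified bimera model. The exact identity variant, tie rules and chimera
internals of the greedy clustering tools the field uses are unpublished, so
this package fixes its own documented conventions instead of claiming
emulation. Single-leaf trees are representable in newick I/O but are below
the minimum for most tree operations.
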