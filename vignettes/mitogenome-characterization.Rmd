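---
title: "Characterizing vertebrate mitogenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing vertebrate mitogenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boulenophrys)
```

This package implements the standard descriptive analysis of an annotated
vertebrate mitochondrial genome — the kind of analysis that accompanies the
release of a new mitogenome — as reusable, tested code. It was built around
the mitogenomes of two sympatric Asian horned toads of the genus
*Boulenophrys* (family Megophryidae), whose published coordinate and
composition tables ship with the package, and around a synthetic-data
generator that reproduces the statistical structure of such genomes so that
every stage can be exercised and verified without downloading sequence
data.

## The annotation model and interval accounting

A vertebrate mitogenome is a circular molecule of roughly 16–17 kb carrying
a fixed complement of 37 genes: 13 protein-coding genes (PCGs), 22 tRNAs,
2 rRNAs, and one noncoding control region (D-loop); a short light-strand
replication origin (OL) sits between tRNA-Asn and tRNA-Cys. Features are
represented as rows of a tibble with 1-based inclusive coordinates, the
GenBank convention used by every printed position in this literature. A
feature may wrap the circular origin; wrap-around is flagged explicitly and
resolved modularly, although neither study genome needs it (each D-loop
ends exactly at the last position).

Two derived quantities drive the accounting:

* `feature_length()` — `end - start + 1`, or
  `(L - start + 1) + end` for wrapping features;
* `spacer()` — `start(B) - end(A) - 1` for adjacent features: negative
  values are overlaps, positive values intergenic nucleotides (IGN).

`spacer_report()` aggregates all adjacent-pair spacers, including the pair
that closes the circle. Three conventions matter and are deliberate:

* OL and the D-loop take part in spacer accounting exactly like genes,
  because the published tables assign them intergenic values; counting the
  OL/tRNA-Cys overlap is required to reach the published 13 overlapping
  pairs in *B. sangzhiensis*.
* The two *B. tuberogranulata* totals that disagree with their own
  coordinate table in print (IGN total, and the tRNA length total in both
  species) are resolved in favor of coordinates; the package reports what
  the coordinates imply (33 bp IGN over 10 locations, 1536 bp of tRNA).
* A useful conservation law holds for genomes whose features tile the
  circle exactly once: total feature length + IGN − overlap = genome
  length. It is property-tested on both study tables and on synthetic
  genomes, and spacer totals are invariant under rotation of the circular
  origin.

## Composition and strand skew

Strand asymmetry is summarized by `AT skew = (A − T)/(A + T)` and
`GC skew = (G − C)/(G + C)`. A skew whose denominator is zero is undefined
and reported as `NA`, never coerced to zero. N bases are excluded from both
numerators and denominators; the reported region length is the full length.

`region_table()` computes one composition row per PCG plus pooled rows
(all PCGs, the three codon positions, each rRNA, pooled rRNAs, pooled
tRNAs, control region). Per-region rows are computed on the **heavy
strand** regardless of coding strand. This is the convention under which
the single light-strand PCG (ND6) shows its striking positive GC skew
while every other PCG row is negative — the published tables are only
reproducible under this choice. Codon-position rows are the exception:
they are pooled per gene on the coding strand by reading frame, and the
trailing 1–2 nt of an incomplete stop codon fall at positions 1 (and 2) of
the final, incomplete codon. Under this frame-derived split the
*B. sangzhiensis* architecture yields position lengths 3795/3793/3790.
The published table prints 3795/3795/3788 for the same genome; the first
position agrees exactly, but no straightforward frame assignment
reproduces the printed second/third split, so the package reports its own
derivation and the split is not used as an acceptance quantity.

Report emitters round percentages to 2 decimals and skews to 3 (half-up),
matching table precision; the underlying tibbles keep full precision.

## Codon usage under the vertebrate mitochondrial code

All translation uses NCBI table 2: AGA/AGG are stops, TGA is tryptophan,
ATA is methionine. Alternative initiation codons (ATA, ATT, ATC, GTG, TTG
— all attested in the study tables) are accepted with a warning-level
issue for anything else. Mitochondrial CDS frequently end in an incomplete
stop (T or TA) completed to TAA by polyadenylation; `classify_codons()`
reports these as `"T"`/`"TA"` descriptors and the report layer prints the
conventional `T(AA)` / `TA(A)` forms.

RSCU for a codon is its count times family size over the family total, so
uniform use gives 1 for every member. Terminal stop codons — complete or
incomplete — are excluded from the counts, the standard practice when the
displayed families are amino-acid families only; whether the original
analysis included them is not stated, so the choice is flagged here. The
family-sum invariant (RSCU summing to family size for every observed
family) is property-tested.

## Ka/Ks: Nei–Gojobori with Jukes–Cantor correction

The published analysis names only its tool (DnaSP); the estimator
implemented here is the tool's classic counting method, Nei–Gojobori
(1986), with Jukes–Cantor correction — the natural reading for a
descriptive mitogenome paper. Per sense codon, each position contributes
one site split into synonymous/nonsynonymous fractions over its three
single-nucleotide changes; changes to stop codons are removed from the
site mass entirely. For codon pairs differing at more than one position,
differences are averaged over all orderings of single steps with equal
weights, skipping orderings that pass through a stop codon (falling back
to all orderings in the rare case every path is blocked). Site totals for
a pair average the two sequences' counts; codons containing gaps, N, or a
stop in either sequence are removed pairwise. `p ≥ 3/4` cannot be
corrected and marks the pair saturated.

Gene-level aggregation defaults to the ratio of mean Ka to mean Ks over
all valid pairs, which remains defined when individual pairwise Ks
estimates saturate; mean-of-ratios is available behind a flag because the
published per-gene figure does not state which summary it shows. For the
same reason the published per-gene values (0.246 for ATP8 down to 0.037
for COI) are treated as method-sensitive; the hard claims carried into the
tests are the rank structure — ATP8 highest, COI lowest, all 13 ratios
below 1 — which the implementation recovers on synthetic data simulated
under that constraint pattern.

The site-counting kernel is verified against an independent brute-force
enumerator (neighbor enumeration with an external translation routine)
over all 60 sense codons, and `pairwise_kaks()` is symmetric in its
arguments by construction and by test.

## Supermatrix and tree stage

`concatenate_pcgs()` builds the concatenated PCG alignment with per-gene
partition ranges (taxa missing a gene are gap-padded and flagged), and
`write_supermatrix()` exports relaxed PHYLIP or NEXUS plus RAxML-style
partition files, per gene or per gene × codon position. Partitioned
maximum-likelihood and Bayesian inference are deliberately exported, not
re-implemented: the package writes their inputs bit-exactly and documents
the intended settings (1000 ML bootstrap replicates; 10^7 Bayesian
generations sampled every 1000 with 25% burn-in) in the export sidecar.
Re-implementing partitioned ML/BI would be out of proportion for a
characterization pipeline, and their results cannot be asserted at desk
scale anyway.

The in-package, testable tree stage is distance-based: p, JC69 or K2P
distances with pairwise deletion, Saitou–Nei neighbor joining, and a
column-resampling bootstrap (within partitions, so each gene keeps its
width) mapped onto the full-data tree as percentage support.
Implementation choices: negative NJ branch lengths are clamped to zero
with the deficit moved to the sibling edge, preserving path lengths
through the parent; saturated distance entries are an error unless
imputation (1.25 × the largest finite entry) is requested; bootstrap
resampling is driven by a single integer seed and is reproducible and
invariant to taxon order at the topology level. NJ bootstrap percentages
are not numerically comparable to ML bootstrap or Bayesian posterior
values, so tree-level claims are asserted at the topology level only:
Robinson–Foulds distance to the generating tree, and monophyly of declared
taxon sets (`check_clades()`, rooted on a declared outgroup — here
*Microhyla fissipes*).

## The synthetic-data generator

The generator exists so that every stage of the pipeline has verifiable
inputs. Its defaults emulate the study system:

* **Architecture**: the *B. sangzhiensis* feature layout (39 features,
  16,950 bp, the published strands, overlaps and spacers), so the
  generated root reproduces the published accounting totals by
  construction.
* **Composition**: the heavy-strand base proportions of that genome
  (A 27.45%, C 26.97%, G 14.81%, T 30.77%) — T-rich and C-rich, giving
  the negative AT and GC skews characteristic of these mitogenomes.
* **Tree**: a 29-taxon topology shaped like the published phylogeny (two
  subfamily clades; monophyletic genera; the two *Boulenophrys* species
  groups; *Microhyla fissipes* outgroup) with branch lengths of 0.008–0.30
  substitutions/site, spanning realistic mitogenome divergences.
* **Selection**: per-gene omegas all below 1, highest for ATP8 (0.8) and
  lowest for COI (0.05), matching the published rank pattern of
  mitochondrial PCGs; intermediate genes are spaced across 0.10–0.45.
  These values are fixed once as study conditions, not tuned.
* **kappa = 4**: a typical vertebrate mitochondrial
  transition/transversion ratio.

The root genome is drawn iid from the composition target, start and stop
codons (complete or incomplete) are written in place, and internal stop
codons are repaired by resampling — jointly across overlapping reading
frames, whose locked positions are checked for compatibility (an
architecture whose codon requirements clash is rejected as infeasible).
Evolution along each branch proposes a Poisson number of single-site
changes under an HKY-like kernel (target-frequency-weighted, transitions
up-weighted by kappa); within PCGs a synonymous proposal is always
accepted, a nonsynonymous one with probability min(1, omega) — multiplied
across overlapping genes — and proposals creating stops or touching
start/stop codons are rejected. tRNA, rRNA, OL and control-region sites
evolve neutrally. All randomness flows from the single spec seed.

The accept/reject omega scheme is a simulation convenience, not a claim of
equivalence to the counting model that estimates omega downstream;
realized divergence per branch is correspondingly below the proposal rate.
Recovery claims are therefore rank-based: recovered Ka/Ks preserves the
generator's omega ranking (Spearman rho = 1 across four omega levels at
500 codons × 8 taxa), and the generating topology is recovered exactly
(RF = 0) from the ~11.4 kb supermatrix at the default divergences. What
passing these tests shows is that the pipeline's statistics respond
correctly to known structure; what they cannot show is fidelity to the
idiosyncrasies of real data the generator omits — indels and alignment
error (sequences evolve gap-free), gene rearrangements (none are known in
this family), within-gene rate heterogeneity, and base-compositional
drift across lineages.

## Problem sizes, tolerances and degenerate inputs

The default test and acceptance workloads are sized for a laptop-class
single core: one 29-taxon genome-scale simulation, pairwise Ka/Ks over
378 taxon pairs × 13 genes via precomputed 64 × 64 codon lookup tables,
and bootstrap runs of 10–25 replicates in tests (the export sidecar
documents 1000 as the recommendation for external ML runs).

One published check deserves a note on precision. Recomputing AT/GC skews
from the published composition *percentages* (printed at 2 decimals)
reproduces the published 3-decimal skews exactly for every cell whose
value sits more than the input quantization (~0.0003) away from a
rounding boundary; 4 of 58 cells sit closer than that and can differ by
exactly one unit in the third decimal. The acceptance test asserts the
principled bound (half a printing unit plus quantization, 0.0008) rather
than pretending the rounded inputs determine the undetermined digit.

Degenerate inputs are handled explicitly rather than silently: empty or
all-N sequences are errors for composition; zero-denominator skews are
`NA`; identical sequences give Ka = Ks = 0 with an undefined ratio;
saturated pairs are excluded from gene-level means and counted;
`validate_mitogenome()` returns issues as data instead of raising.
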