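---
title: "Methods: linkage-map-guided anchoring and QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linkage-map-guided anchoring and QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(radanchor)
```

This vignette is the package's account of its science: the models behind
each stage, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where the design was genuinely open.

## Study design the package targets

The pipeline assumes a classical plant-genomics setting: a fragmented
genome assembly of a dioecious species with an XY sex system, male and
female resequencing data mapped to it, and a ddRAD-seq-genotyped F2
population from a cross between two inbred lines (P1 × P2 → F1, selfed).
Because the parents are inbred, every informative SNP has parents
homozygous for different alleles and a heterozygous F1; F2 genotypes can
then be coded 0/1/2 by parental origin, and single-marker counts are
expected to segregate 1:2:1.

## Y-linked scaffold screen

On scaffolds from the non-recombining Y region, male (XY) libraries place
roughly half their usual depth (one Y copy) while female (XX) libraries
place almost none. The screen computes `log10((m + c)/(f + c))` per
scaffold with pseudocount `c = 0.01` (in depth units) to keep zero female
depth finite, and labels a scaffold Y-linked when the ratio strictly
exceeds 0.2 *and* the scaffold exceeds 10 kb — the size condition protects
short scaffolds whose depth means are noisy. Both inequalities are strict,
matching the rule as printed in the field's usage. Depth is summarised as
mean coverage; an option normalises each library by its median depth first,
for libraries of unequal size. X-linked detection (ratio near −0.3) is out
of scope.

## The SNP filter cascade

Two site-filter tiers mirror common VCFtools practice for ddRAD data:

| parameter | stringent | less stringent |
|---|---|---|
| call-rate floor | 0.95 | 0.80 |
| site quality (phred) | 20 | 20 |
| per-call depth | 20–200 | ≥ 10 |
| minor-allele frequency | 0.025 | 0.025 |
| biallelic SNPs only, no indels | yes | yes |

Depth bounds are applied per genotype call — out-of-bounds calls are set
missing *before* the call-rate test — which is the semantics of per-genotype
depth flags in VCF tools (the alternative, a per-site mean-depth rule,
would keep bad calls at well-covered sites). MAF is computed from called
genotypes after masking; the pipeline computes it over the F2 individuals,
since parental/F1 calls are replicated at high depth and would otherwise
dominate. The less-stringent tier is thinned to a ≥ 0.8 Mb spacing floor by
a greedy left-to-right walk per scaffold (the deterministic reading of
"roughly one site per 0.8 Mb"), then merged with the full stringent set,
keys being `(scaffold, position)` and the stringent copy preferred.
Finally each marker is tested against 1:2:1 by a plain Pearson chi-square
(no continuity correction, no multiple-testing correction) at
`P > 0.001` — deliberately permissive, since the cost of keeping a mildly
distorted marker is small next to the cost of discarding real map
information. An open choice here was whether thinning should apply only to
less-stringent-exclusive sites or to the whole less-stringent set before
merging; the pipeline thins the full set and then merges, which is simpler
and makes the merge order irrelevant to the final membership.

## Recombination fractions and the genetic map

For a marker pair in an F2, the nine genotype combinations determine the
number of recombinant gametes exactly except for the double heterozygote,
which mixes zero and two recombinant gametes. The estimator is EM: with
current `r`, the double-het class contributes
`2 r² / (r² + (1−r)²)` expected recombinant gametes, and the M-step divides
total expected recombinants by twice the number of informative pairs. The
estimate is constrained to [0, 0.5]; `LOD = log10 L(r̂)/L(0.5)` under the
9-class multinomial. Missing calls are pairwise-deleted. A grid-search
likelihood oracle (tested to 1e-3 agreement) guards the implementation.

Grouping is single-linkage transitive closure over pairs with
`r ≤ 0.35` and `LOD ≥ 6`. These defaults recover the chromosome number at
the package's design scale (~100 F2, hundreds to thousands of markers);
both are exposed. Groups are named LG1, LG2, ... by descending marker
count, the conventional presentation. Ordering is heuristic — a
nearest-neighbour chain seeded at the highest-LOD pair, refined by
best-improvement 2-opt on the sum of adjacent recombination fractions —
and exact by brute force for ≤ 8 markers, which the tests exploit as an
oracle. The output orientation is canonicalised (lexicographically smaller
marker id first) so runs are comparable.

Before converting adjacent recombination fractions to distances, singleton
double recombinants are pruned: a call disagreeing with both of its
(identical) nearest non-missing neighbours implies two crossovers in a
short interval and is overwhelmingly more likely a genotyping error. At a
1% per-call error rate, skipping this step inflates every adjacent
interval by roughly twice the error rate, which at dense marker spacing
multiplies total map length severalfold; pruning restores map lengths to
near the simulated truth while leaving genuine single crossovers (steps,
not spikes) untouched. Full genotype-error-aware HMM mapping is a
non-goal. Residual inflation of order tens of percent remains and is a
documented limitation.

Distances use Kosambi by default — the common choice for plant maps, where
crossover interference is real — with Haldane selectable; the simulator
itself is interference-free, so Haldane is exact for simulated data and
Kosambi slightly compresses it, a deliberate mismatch kept because the
package's defaults describe analysis practice, not the simulator.

## Anchoring and chimera handling

Each scaffold's mapped markers are walked in bp order and clustered into
blocks: a change of linkage group, or a same-group jump of more than 20 cM
(`gap_cm`), opens a new block. A scaffold with blocks on *different*
linkage groups is chimeric; the breakpoint between adjacent conflicting
blocks is placed at the midpoint between the last marker of one and the
first marker of the next — unbiased absent any sequence-level evidence of
the join. Same-group multi-block scaffolds are flagged but not split, since
the defining evidence of a chimera is the cross-group conflict. Scaffolds
are cut at breakpoints (1-based inclusive pieces); pieces strictly longer
than 1 kb with markers become anchor segments, oriented by the sign of the
Spearman correlation between marker bp and cM (`?`, treated as `+`, when
fewer than two distinct cM values are present — the orientation of a
single-marker segment is genuinely unknowable from the map). Segments are
sorted by mean member cM within their group (ties: scaffold id, then
start — determinism over elegance) and catenated with 10 kb of N between
segments; pseudomolecules are named `chr01..chrNN` after LG1..LGn. The AGP
plan uses component type `W`, gap type `U`/contig/10 000, and is emitted
together with the FASTA so the two are mutually consistent; a round-trip
test regenerates the FASTA from AGP + scaffolds byte-identically.

## QTL mapping

Conditional genotype probabilities at a 1 cM grid (plus every marker) come
from the nearest non-missing flanking markers under the no-interference
transition matrix, with one-sided conditioning at group ends and the prior
(¼, ½, ¼) where an individual has no calls on the group. At a typed,
non-missing marker the distribution is degenerate, so the scan LOD there
equals the single-marker regression LOD — a tested identity. Scans are
Haley–Knott: phenotype regressed on expected additive (`P(BB) − P(AA)`)
and dominance (`P(AB)`) scores; `LOD = (n/2) log10(RSS0/RSS1)`. Composite
mode forward-selects up to 5 marker cofactors by BIC (additive + dominance
columns, mean-imputed) and drops any cofactor within 10 cM of the test
position from both null and full models. This is an approximation of full
composite interval mapping chosen for transparency and speed at desk
scale. The binary trait is analysed by the same linear model — the
linear-probability reading of mapping a Mendelian trait with QTL
machinery; note that a fully penetrant binary locus flanked by an
error-free co-segregating marker yields a perfect fit, and the LOD is then
reported at the guard ceiling `(n/2)·12` rather than infinity.

Genome-wide significance uses permutation of the phenotype (default 1000
permutations, 5% genome-wide level, seeded); support intervals are 1.5-LOD
drops — the standard 95% CI surrogate, since no CI method is canonical —
reported with the nearest flanking genotyped markers and, when an AGP plan
is supplied, their physical span. `PVE = 100 (1 − 10^(−2·LOD/n))` is the
single-locus conversion; joint PVE of several QTLs must come from a joint
model and is *not* the sum of single-locus values. The parental-line
comparison is an exact Wilcoxon rank-sum test: the full distribution of
the Mann–Whitney statistic is enumerated by dynamic programming over
doubled ranks (exact also under ties, where the null remains symmetric),
rather than by the normal approximation, because the group sizes at hand
(7 and 8) are far below asymptotic comfort.

## Gene confidence classes

Transcripts reduce to the best-scoring one per gene (ties: lexicographic
id). Evidence channels qualify at inclusive thresholds — UniProtKB
`E ≤ 1e-10` and identity ≥ 98%; NR `E ≤ 1e-10` and identity ≥ 95% (the NR
E-value bound is taken to match UniProt's, the natural reading of the two
searches being described in sequence); reference proteome `E ≤ 1e-50`,
90% ≤ coverage ≤ 110%, identity ≥ 98%, HSP identity ≥ 98%; Pfam
`E ≤ 1e-80`. Classification precedence is TE > HC > LC: a qualifying
UniProt hit with a transposable-element keyword is TE regardless of other
evidence (TE-related genes must not contaminate the HC set); otherwise any
qualifying channel *or* TPM > 0 gives HC (the union reading: expression
alone is evidence of a real gene); all else is LC. The TE keyword list is
configurable because no canonical list exists.

## The synthetic-data generator

The generator produces every input with known truth: chromosomes cut into
scaffolds (fragments allocated proportionally to length, each chromosome
at least one); an exact `round(chimera_fraction × n_scaffolds)` of
scaffolds join two fragments from different chromosomes; a configurable
fraction of fragments is stored reverse-complemented (default 0.5) so
orientation recovery is exercised; a Y-linked subset is flagged among
non-chimeric scaffolds above 10 kb. Depth is Poisson per 1-kb window
averaged over the scaffold — so long scaffolds have tight means, as real
per-scaffold summaries do — with Y scaffolds at half depth in the male and
a 2% cross-mapping floor in the female. Meioses are Poisson/no-interference
(Haldane): gametes are Markov chains over adjacent-marker recombination
fractions. Genotyping error flips calls uniformly to one of the other two
classes at 1% by default; 5% of F2 calls are masked, while parents and the
F1 are drawn at 4× depth without masking, reflecting pooled parental
libraries. Per-call depth is Poisson (negative binomial selectable, since
ddRAD per-site depth dispersion is rarely published). Planted QTLs sit at
their requested coordinates: their genotypes are sampled conditionally on
the nearest marker through the transition matrix, so a causal locus need
not coincide with a marker. Quantitative noise is scaled to the requested
heritability of the *realised* genetic variance; the binary locus is
dominant for the P1 allele, giving the 3:1 carrier ratio.

Default scale: 6 chromosomes of 40 Mb at 1.7 cM/Mb (≈ 68 cM each,
≈ 410 cM total), 112 scaffolds with 25% chimeras and 5% Y-linked, 101 F2,
8.5 markers/Mb (≈ 2,000 markers), mean depth 30×. The genetic-map scale,
population size, marker count, error/missingness and trait architecture
(three bolting QTLs with variance shares near 32/20/8% at joint
heritability 0.59, plus the dominant seed-shape locus) are chosen to match
the study design the package emulates; physical lengths are scaled down so
a full run with sequence-free scaffolds fits in seconds of desk time, and
the problem sizes used by the tests (on one CPU: the full design in about
a minute; the pipeline cascade itself in ~20 s) are the package's own
choice of validation scale. Residues are uniform ACGT and generated only
on request (`with_sequence`), because no downstream computation here reads
base composition.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: read-level artefacts (no FASTQ, no
restriction-site dropout or allele dropout, which in real ddRAD produce
correlated, locus-specific missingness rather than uniform masking),
repeat-driven mis-mapping, segregation distortion from selection, crossover
interference, and assembly errors other than clean two-fragment chimeras.
Recovery metrics on synthetic data are therefore upper bounds on
real-data performance.

## Numerical choices and edge cases

EM runs at most 100 iterations to 1e-8 with the estimate floored at 1e-9
(so likelihoods at planted `r = 0` stay finite); marker pairs with no
overlapping calls are flagged undefined rather than guessed. Adjacent
recombination fractions ≥ 0.5 (possible in noisy data after heuristic
ordering) are clamped just below 0.5 with a warning in `build_linkage_map`,
while the low-level `map_distances` treats them as a hard error. Ties in
2-opt are broken toward the first best move; all tie-breaks elsewhere
(segment order, group naming) are lexicographic/first-index so outputs are
deterministic. The exact rank-sum DP doubles ranks to keep tied averages
integral. All seeds derive from one user seed through fixed small offsets,
keeping every derived seed within 32-bit range.

## Known limitations

Map lengths remain modestly inflated at 1% genotyping error (no HMM error
model); the ordering heuristic guarantees optimality only locally (2-opt)
though it matches brute force on small sets; composite-mode permutation
thresholds are computed with plain Haley–Knott scans (standard practice,
but slightly conservative for CIM); multi-QTL models, epistasis and
sex-specific maps are out of scope; and AGP support covers what the
package writes (W components and U gaps), not the full format zoo.
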