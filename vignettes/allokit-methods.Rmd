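---
title: "Methods: subgenome structure and expression divergence in allo-tetraploid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgenome structure and expression divergence in allo-tetraploid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokit)
```

allokit implements the analysis stages of an allo-tetraploid subgenome
study — the cyprinid case of common carp and goldfish, whose two
chromosome sets descend from different diploid progenitors — as tested,
reusable functions.  This vignette records the models, the parameters
that matter, the numerical choices, and what the synthetic-data tests
do and do not establish about real data.

## The heptad model and subgenome assignment

A heptad is a 1:1:1:2:2 ortholog family: one gene each from zebrafish,
*P. guichenoti* and *P. tetrazona*, and two genes each from carp and
goldfish.  Under the accepted species history, the expected rooted
topology is

```
(zebrafish,(P. guichenoti,((P. tetrazona,(carpB,goldfishB)),(carpA,goldfishA))));
```

`classify_heptad_topology()` roots each gene tree on zebrafish and
searches for a clade holding exactly the *P. tetrazona* gene, one carp
gene and one goldfish gene whose sister clade holds the remaining carp
and goldfish genes.  Tetraploid copies inside the *P. tetrazona* clade
are subB (their progenitor is the *P. tetrazona*-like diploid), the
sister pair subA.  Any other shape is "complex" and excluded from
labelling — the same conservative rule a topology-based pipeline must
apply to real families, where incomplete lineage sorting, paralogy and
tree-estimation error produce non-canonical shapes.  The classifier is
checked against a clade-membership brute force over all 10,395 labelled
rooted binary shapes on seven leaves, so the structural rule itself is
exhaustively verified rather than spot-checked.

Bootstrap gating is optional (`min_support`): supports are looked up by
bipartition on the input tree, because rooting in `ape` does not keep
node labels attached to their clades.  The default ignores supports,
since family retention is decided by topology alone and supports are
reported descriptively.

Chromosomes are assigned by majority vote of their labelled genes.
Ties are resolved through the homoeologous pairing (25 pairs per
tetraploid, one A and one B member each): a tied chromosome takes the
complement of its partner, and if both members of a pair get the same
majority label the weaker margin flips, flagged `tie_broken`.  A
labelled gene hosted on the other subgenome's chromosome is a
homoeologous exchange; genes on `scaffold:*` tokens are excluded and
counted, since unanchored sequence cannot disagree with a chromosome
assignment.  HE validation compares progenitor-read coverage between
exchanged and hosted genes with a one-sided Wilcoxon rank-sum test at
alpha = 0.05; counts should be normalised per kb of gene length first,
because the compared gene sets differ in length.  Region-level HE
calling from windowed depth ratios uses `log2(depth_A/depth_B)` and
flags windows whose ratio crosses the chromosome-wide median by more
than 1 (two-fold) with inverted sign; the two-fold threshold is this
package's choice where only the comparison, not a cutoff, is standard.

## NG86 Ka/Ks and clock dating

`compute_kaks()` implements Nei–Gojobori (1986) counting.  Each codon
position contributes one site, split between synonymous and
nonsynonymous by the synonymous fraction of its non-stop
single-nucleotide changes (mutations to stops are disregarded), so
S + N = 3 × codons.  Observed differences are averaged over all
minimal mutational pathways between codon pairs, skipping pathways
through stop codons (if every pathway is blocked, all are used — a
convention needed only for pathological pairs).  Proportions are
Jukes–Cantor corrected; a saturated proportion (p >= 3/4) yields an
undefined rate rather than an arbitrary large number, and Ka/Ks is
undefined when Ks = 0.  The 64 × 64 pathway tables are computed once
and cached, which makes thousands of pairwise estimates cheap.  NG86 is
used rather than a maximum-likelihood codon model because it is fully
specified and oracle-checkable — the test suite compares S, N, Sd, Nd
against an independent brute-force neighbour/pathway enumeration on a
1,000-case random suite — and because the downstream quantity (a Ks
mode passed through a linear clock) is robust to the counting-method
choice.  A likelihood estimator (e.g. YN-style) would slot in behind
the same interface.

Ks modes come from a Gaussian KDE on a 512-point grid over
[0, max(Ks)], bandwidth by Silverman's rule; all local maxima are
reported so bimodal mixtures (two divergence events in one set of
pairs) are visible.  `ks_to_divergence_time()` applies
T = Ks/(2·rate)/1e6 Ma with a default clock of 3.51e-9
substitutions per synonymous site per year; the division by two, which
the printed times of the source system confirm (Ks mode 0.19 → 27 Ma),
reflects that both lineages accumulate substitutions.

## Synthetic heptads

`simulate_heptad_families()` evolves a random stop-free codon sequence
along the fixed species tree under a simple Markov process: per branch
of synonymous length t, each codon receives Poisson(t·s + ω·t·(3−s))
substitutions drawn among its currently allowed synonymous and
nonsynonymous single-nucleotide neighbours (ω = 0.2).  This is not a
full codon model — there is no rate heterogeneity, no codon-usage bias
— but it produces exactly the signal NG86 is built to read, which is
the point: the planted per-branch Ks are the study conditions
(A-lineage vs B-lineage 0.19, *P. tetrazona* vs the B ancestor 0.18,
carpB–goldfishB 0.10, carpA–goldfishA 0.095, with the outgroup depths
at Ks ≈ 0.26 and 0.42 for the two outgroups, consistent with the same
clock).  Alignments default to 300 codons, a typical teleost CDS
length; this matters because with ~0.75 synonymous sites per codon the
Ks granularity per pair is ~1/(0.75·n_codons), and resolving Ks modes
at the 0.01 scale requires granularity well below that (at 150 codons
the KDE locks onto discrete difference counts).  A fraction `he_rate`
of tetraploid genes is relocated to the homoeologous partner chromosome
and a fraction `topology_noise` of families is emitted with a
non-canonical tree (both carp copies as sisters inside the
*P. tetrazona* clade); both are recorded in the truth object.  HE genes
planted inside complex families are invisible to a topology-based
detector by construction, so recovery is scored over labelable genes.

## Ancestral regions, rearrangements and Dollo losses

A block longer than 1 kb whose rows from ≥4 of the seven (sub)genomes
map through the homoeolog map to one ancestral chromosome is an AR;
its orientation is the majority strand of the supporting rows, with an
exact tie going to "+" under a flag.  The homoeolog map (modern
chromosome → ancestral chromosome) is an explicit input because the
many-to-one pairing of tetraploid chromosomes onto 25 ancestral
chromosomes is knowledge the caller has, not something the block set
determines.  Translocation fractions count rows mapping to a different
ancestral chromosome than their AR; inversion fractions are computed
over non-translocated ARs only, since a translocated row's strand has
no meaningful orientation reference.  Retention/loss is counted
against an explicit locus universe and divided by subgenome size in
Mb, with a 2×2 continuity-corrected chi-square helper for
between-genome contrasts.

Dollo parsimony assumes each family originates once, at the MRCA of
the taxa carrying it; the minimal loss set is the maximal all-absent
subtrees below that origin.  The implementation is compared with an
exhaustive minimal-subset search over branch combinations on 1,000
random patterns across random trees of up to seven leaves.

## Expression divergence

All distances and correlations are computed on log2(TPM+1): raw-TPM
Euclidean distance is dominated by whichever tissue expresses highest.
The expression floor defaults to TPM ≥ 1 and is exposed everywhere,
because "expressed", "cotranscribed" and the non-F class all depend on
it.  Dominance requires a strict inequality; equal values are ties and
excluded from the chi-square against 50:50.  Conservation with the
outgroup requires r > 0.66 and p ≤ 0.05 across nine shared contexts —
at n = 9 the two-sided 5% critical value of Pearson's r is 0.666, so
the paired thresholds are mutually consistent rather than independent
knobs.  A pair is divergent when its homoeolog–homoeolog distance
reaches the 90th percentile across pairs or r < 0.66; a zero-variance
profile has no defined correlation and is classed divergent under a
flag.

Functionalization uses a fixed precedence: non-F (a copy silent in
every context), then neo-F (exactly one copy conserved and the copies
in different clusters), then sub-F (neither copy conserved but the
summed, pseudo-ancestral profile conserved — partitioned expression
that reconstitutes the ancestral pattern), then coexpressed (same
cluster), else neo-F.  The sub-F operationalisation is this package's
interpretation of partitioned conservation and is deliberately
swappable; it is the one rule here with genuine competing readings.
Clustering is agglomerative with average linkage on Euclidean
distances, cut to exactly k groups (k = 8 for expression panels,
k = 10 for splicing-count profiles), which is deterministic —
important because the functionalization classes inherit any clustering
nondeterminism.

The panel generator plants conservation (copies that track the
outgroup profile with small log-noise) and dominance (a +3 log2 shift
to the designated copy; the planted bias is the probability that subB
is the dominant one).  Expression levels are drawn high (gene-level
log2 mean 6 ± 1, tissue effects ± 1.5) so profiles sit above the floor
region: the generator emulates the *expressed* homoeolog pairs that
dominance/conservation analysis actually classifies, not silent genes,
for which correlation under the log2(TPM+1) transform is undefined.
Bias recovery is scored at the pair level (majority of contexts) via
`pair_dominance()`; per-context counts are diluted toward 0.5 by
diverged-profile noise, which is a property of the data, not of the
estimator.

## Windowed population statistics

Windows are 0-based half-open, 100 kb with a 50-kb step by default;
terminal windows at least half a window long are kept under a
`partial` flag.  Per window: pi = Σ 2p(1−p)·n/(n−1)/L over segregating
sites with the per-site observed allele count n (missing genotypes
shrink n at that site only); Watterson's theta sums 1/a_n per
segregating site at the site's own n; Tajima's D uses the 1989
variance constants; Fu & Li's D* and F* are the star variants (no
outgroup, singletons counted as minor-allele-count-one sites) with the
Simonsen et al. (1995) corrected constants — the convention DnaSP and
libsequence share.  A window with no segregating site reports zero
diversity and missing D statistics rather than zeros, since the D
numerators are undefined at S = 0.

Fst is Weir–Cockerham (1984) with the full a/b/c variance components
from diploid genotypes (observed heterozygosity enters b and c), and
windows combine sites as the weighted ratio Σa/Σ(a+b+c); negative
window estimates are truncated to zero under a flag before
Z-transformation, which standardises with the sample (n−1) standard
deviation.  Sweep calling is joint and empirical: windows in the top
5% of both the diversity ratio pi_other/pi_focal and ZFst are called
selected in the focal population, windows in the bottom 5% of both
selected in the other.  The orientation puts reduced diversity in the
domesticated (focal) population at large ratios; thresholds are always
derived from the data's own quantiles — published threshold values for
any particular dataset are those quantiles evaluated, not constants to
hard-code.  LD r² is the squared correlation of unphased genotype
dosages (composite LD); dense chromosomes are thinned to 2,000 evenly
spaced polymorphic sites before pairing, pairs are binned by distance
within chromosomes, and the half-decay distance is the first bin
midpoint at or below half the curve maximum.

The genotype simulator draws sites per window from a 1/i
site-frequency spectrum over the pooled haplotypes (for which
E[pi] = theta_w, so the site intensity is set directly by the target
diversity), with sweep windows collapsing pop1 to near-monomorphism —
fixed for the derived allele at a coin-flip of pop2's segregating
sites — plus residual diversity at the sweep target.  There is no
coalescent tree behind the draws: sites are exchangeable and unlinked.
Consequently Tajima's D centres on zero by construction of the SFS,
Fst contrasts are sharp, and the LD curve sits at the unlinked 1/n
baseline — the LD half-decay machinery is therefore tested on
constructed decaying-correlation genotypes instead.  Planted
quantities hold in expectation, and the recovery tolerances in the
tests (±0.01 on Ks modes at 2,000 families, ±0.03 on the translocation
fraction and dominance bias, 4/5 sweep windows with at most one false
call at 20 diploids per population over 100 windows) are the
sampling-error bounds of those study conditions.

## Problem sizes and limits

The test suite runs the full oracle comparisons (1,000 NG86 cases,
1,000 Dollo patterns, the 10,395-tree enumeration), 2,000-family Ks
recovery, and 10–20-Mb window scans in a few minutes on one CPU; the
analysis scripts use 400 families, 500 blocks, 2,000 pairs and a 10-Mb
chromosome, sizes chosen so the planted signals sit comfortably above
sampling noise while each script stays in seconds.

What passing these tests shows: the estimators compute their
definitions exactly (oracle equalities), and the detectors recover
planted truth under the stated conditions.  What they do not show:
robustness to tree-estimation error beyond the planted topology-noise
model, to alignment error, to expression normalisation artefacts, to
linked selection or demography in the popgen statistics, or to
reference bias in read counts — real-data effects the generators do
not emulate.  The NG86/JC estimator also saturates above Ks ≈ 1 and is
reported undefined there; the divergences this package targets
(Ks ≤ ~0.4) are well inside its working range.
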