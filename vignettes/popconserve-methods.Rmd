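---
title: "Methods: diversity, inbreeding and family structure in small conservation herds"
author: "popconserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, inbreeding and family structure in small conservation herds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popconserve)
```

## The problem

Closed conservation herds of local livestock breeds are small — a few dozen
animals, often with very few breeding males — and the central management
questions are quantitative: how much genetic diversity is left, how inbred
are individual animals, and which animals are close relatives that should
not be mated together. Genome-wide SNP panels from reduced-representation
sequencing (GBS) answer all three at once, but the panels they produce are
sparse (tens of thousands of markers over a multi-gigabase genome, roughly
20 per Mb) and carry 5–10% missing calls, which shapes several of the
numerical choices below.

popconserve implements the complete post-genotyping chain: a genotype
matrix data model with VCF and PLINK PED/MAP text I/O; SNP and sample
quality control; per-locus and population diversity statistics; runs of
homozygosity (ROH) and the genomic inbreeding coefficient F~ROH~; genomic
relationship (G), identity-by-state (IBS) distance, and PCA; neighbor-
joining dendrograms; and a kinship-threshold partition of the herd into
sire families. A pedigree-structured simulator with planted ground truth
makes every stage testable without external data.

## Quality control

`apply_qc()` first removes samples whose genotype detection rate falls
below 0.90, then evaluates four marker criteria on the remaining samples
and removes their union: call rate < 0.90, minor allele frequency < 0.01
(on called genotypes), Hardy–Weinberg exact-test p < 10^-6^, and
non-autosomal location. The per-criterion counts in the report are
*standalone* tallies — the same marker can fail several criteria — so the
rows of the report are not expected to sum to the number removed. This is
the usual presentation of a PLINK-style filter cascade, and the only
reading under which published filter tables of this kind are internally
consistent. Whether marker statistics should be computed before or after
sample removal is rarely stated in publications; popconserve computes them
after, the standard order. Read-level criteria (sequencing depth, Q20)
belong to the upstream genotype caller; `qc_config()` accepts them for
provenance but cannot enforce them on a genotype matrix.

## Diversity statistics

Per locus, with alternate-allele frequency $p$ and $q = 1 - p$ estimated
from called genotypes:

* observed heterozygosity $H_o$ = fraction of called genotypes that are
  heterozygous;
* expected heterozygosity $H_e = 1 - \sum_i p_i^2$ (the definitional gene
  diversity; Nei's $2n/(2n-1)$ correction is available as an argument but
  off by default, matching the definition used in the conservation
  literature this package serves);
* Botstein's polymorphism information content
  $PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$, maximal at 0.375
  for a biallelic marker;
* effective allele number $A_e = 1 / \sum_i p_i^2$;
* the proportion of polymorphic markers PN = fraction of loci with
  MAF ≥ 0.05. The threshold is configurable; 0.05 is the conventional
  choice, and a threshold at the QC MAF floor (0.01) would force PN = 1 on
  any QC-passed panel, so it cannot be what published PN values < 1 mean.

The Hardy–Weinberg test is the exact conditional test on heterozygote
counts (the PLINK default): given the allele counts, the p-value is the
total probability of all heterozygote-count outcomes no more probable than
the one observed. This p-value is conservative by construction — the whole
probability of the observed outcome is always included — so its null
distribution is stochastically larger than uniform at any sample size;
`hwe_exact_test(..., midp = TRUE)` provides the mid-p variant, whose null
distribution is approximately uniform and which the test suite uses to
check calibration.

### LD-based effective population size

`ne_from_ld()` forms all same-chromosome marker pairs within 1 Mb
(configurable), computes the squared genotype correlation $r^2$ over
mutually called samples, subtracts the $1/(2n)$ finite-sample term, floors
the result at 10^-3^, converts pair distance to a recombination fraction at
1 cM/Mb (capped at 0.5), and inverts Sved's drift expectation
$E[r^2] = 1/(1 + 4N_ec)$ at the mean adjusted $r^2$ and mean $c$ — the
convention of dedicated LD-Ne software. Inverting pair by pair and
averaging (`method = "per_pair"`) is also available but is dominated by the
near-zero $r^2$ of effectively unlinked pairs and can be orders of
magnitude too large; it is kept for comparison only. LD-based Ne is the
least robust statistic in the package — sensitive to marker density, the
distance window, family structure and the assumed map — and should be read
as an order of magnitude. On simulated herds whose founders are drawn from
an effectively infinite pool the estimate is accordingly large; the
simulator makes no attempt to target any particular published Ne.

## Runs of homozygosity and F~ROH~

`detect_roh()` is a PLINK-style two-stage scan, re-tuned for GBS density.
Stage 1 slides a 20-marker window along each chromosome and calls it
homozygous-compatible if it has at most 1 heterozygous and 3 missing
calls; a marker is eligible if more than 5% of the windows covering it are
compatible. Stage 2 takes maximal eligible stretches, splits them at
adjacent-marker gaps over 1 Mb, splits again (greedily, left to right)
wherever a heterozygous call would push a run past the 1-het budget, trims
runs to begin and end on called homozygous markers, and keeps runs of at
least 15 markers spanning at least 1 Mb.

The departures from PLINK's array-era defaults (50-marker window, 100-SNP
and 1000-kb minima, 5 missing per window) are deliberate:

* at ~20 markers/Mb a 1 Mb run — the shortest length of biological
  interest here — carries only ~20 markers, so a 100-SNP minimum (or a
  50-marker window) would make such runs undetectable by construction;
  hence `window_snps = 20`, `min_snps = 15`;
* at GBS missingness (~5% versus ~1% on arrays) a 2-missing allowance per
  20-marker window fails ~7.5% of windows, and a single cluster of three
  missing calls can sever a long true run; the default allowance of 3
  brings window failure to ~0.3% without materially admitting false runs.

Segment bounds are the first and last marker positions (inclusive), so
they are accurate only to the local marker spacing; detected runs shrink
by a few spacings relative to the true autozygous tract and may extend a
marker or two past it when the flanking region is homozygous by chance.

F~ROH~ for an animal is the summed length of its runs divided by the
autosome length L, both in Kb. The packaged default is the donkey autosome
complement, L = 2,302,664.694 Kb; analyses of simulated genomes use the
simulated genome length. Note that at this marker density a herd with *no*
planted autozygosity still shows F~ROH~ of roughly 0.005–0.01 from chance
homozygous stretches through low-MAF regions — a floor to keep in mind
when reading small published F~ROH~ means.

## Relatedness

`grm_vanraden()` builds the VanRaden genomic relationship matrix
$G = ZZ'/\sum_j 2p_jq_j$ with $Z$ the dosage matrix centered at $2p_j$,
allele frequencies estimated from the analyzed sample (or supplied, e.g.
founder frequencies in simulations). Missing calls contribute zero to the
numerator, and the denominator for each pair sums $2p_jq_j$ over the
mutually called loci only — the GCTA convention. The alternative (fixed
denominator with mean imputation) attenuates every off-diagonal by the
square of the call rate, which at 95% calls already biases parent–
offspring values from 0.50 to ~0.45 before any other effect. With complete
data the two definitions coincide exactly. When frequencies are estimated
from a small related sample, centering also shrinks all entries by roughly
the mean sample kinship; this is why the calibration tests in the suite
supply true founder frequencies, while threshold-based family assignment
(which tolerates the shrinkage) is tested with in-sample frequencies.

`ibs_distance()` is the PLINK allele-sharing distance
$D = 1 - (N_{IBS2} + 0.5\,N_{IBS1})/N$ over mutually called loci,
equivalently $\mathrm{mean}(|x - y|)/2$ on dosages. Unlike G it is not
centered: each animal's own homozygosity enters every one of its pairs, so
the pairwise ordering of raw IBS similarity and G agree only moderately
(Spearman ~0.7–0.8 on family-structured herds). After the standard Gower
double-centering of $D$ the two orderings agree almost perfectly
(~0.99); the test suite asserts both facts.

`pca_genotypes()` standardizes each marker to
$(x - 2p)/\sqrt{2pq}$ (the smartpca convention; `scale = "none"` for
centering only), sets missing entries to the locus mean, and
eigendecomposes the sample covariance of the standardized data.
Coordinates are eigenvectors scaled by the square roots of their
eigenvalues, and component signs are arbitrary. With `scale = "none"` and
complete data the decomposed kernel is proportional to G, so the PCA
eigenspace and the G eigenspace coincide exactly — the classical
equivalence between PCA of centered genotypes and the GRM.

## Trees and families

`nj_tree()` is Saitou–Nei neighbor joining with two determinism choices:
ties in the Q-criterion break toward the smallest index pair, and negative
branch-length estimates are clamped to zero with the deficit moved to the
sister branch so the joined pair's path length is preserved. The result is
returned as an `ape` `phylo` object (trifurcating root; rooting is
arbitrary) and serializes to Newick. On additive distance matrices NJ
provably recovers the generating topology, which the suite verifies on
random trees, alongside a cross-check against `ape::nj`.

The family partition follows conservation-breeding practice for
male-anchored herds: males are clustered by connected components of the
graph with an edge wherever pairwise G ≥ 0.1 (transitive closure — if A
relates to B and B to C, the three form one family even when A and C fall
under the threshold); each female joins the family holding her
maximum-kinship male if that kinship reaches the threshold, and otherwise
falls into an "other" class of animals with no close male relative — the
mating-safe pool. Raising the threshold can only refine the male
partition, never merge it; the suite asserts this monotonicity and
invariance of the whole partition to sample order.

## The simulator

`simulate_population()` generates the study conditions the package is
designed for, and doubles as the ground-truth engine for the test suite.
Defaults describe a herd of 4 males and 28 females genotyped at 45,000
autosomal SNPs on 30 autosomes of 76,755,490 bp each (total
2,302,664,700 bp, matching the donkey autosome length constant used by
F~ROH~), plus 1,500 X and 90 Y markers whose only purpose is to exercise
the sex-chromosome filter. Founder alternate-allele frequencies are
uniform on [0.01, 0.5] — chosen once because it reproduces the mean MAF
(~0.25), H~e~ (~0.34) and PIC (~0.27) levels typical of the GBS donkey
panels this package targets — and founder genotypes are in Hardy–Weinberg
proportions. Offspring arise by gene dropping: one recombinant gamete per
parent, crossover counts Poisson with mean equal to the chromosome map
length at 1 cM/Mb (Haldane, no interference), breakpoints uniform.

Three design choices matter for interpreting test results:

* **Families are planted, not emergent.** Males sharing a family are made
  full sibs through an unsampled founder couple; assigned females get a
  family sire and their own unsampled dam, making paternal half-sib sets.
  Expected G values are therefore known exactly (0.5, 0.25, ...), which is
  what the calibration tests use. By default 3 of the 28 females are
  assigned and 25 remain founders, mirroring the family shape of a real
  conservation herd with a large unrelated female pool.
* **Autozygosity is planted as explicit tracts**, not produced by pedigree
  loops: within each tract (lengths uniform on 1–11 Mb by default, kept
  ≥2 Mb apart, never shorter than the configured minimum) one parental
  haplotype is copied over the other. This gives exact tract bounds for
  recovery tests; the per-animal planted fraction matches `target_froh`
  (default 0.003) to within the dropped sub-minimum residual.
* **Missingness is i.i.d. per call** at rate 1 − `call_rate` (default
  0.95), optionally per sample. Real GBS missingness is locus- and
  depth-structured; nothing here models that, so QC behavior on real data
  with pathological locus dropout is not covered by passing tests.

The simulator emulates marker sparsity, irregular spacing, pedigree
structure, planted autozygosity and missingness. It does **not** emulate
coalescent ancestry (so background LD and drift-driven Ne are not
calibrated), genotyping error (no false heterozygotes inside true tracts),
linked selection, or real sex-chromosome inheritance (X/Y markers are
i.i.d. filter fodder). Conclusions from passing tests transfer to real
data only for the mechanisms actually modelled.

## Numerical and degenerate-input choices

Dosages are integers 0/1/2 with `NA` for missing; coordinates are 1-based
inclusive bp. Readers reject unsorted positions rather than silently
sorting. Multiallelic VCF records are skipped with a warning (or rejected
on request) because the dosage model is biallelic. PED text carries no
allele polarity, so the alternate allele is re-inferred as minor-by-count
(ties to the lexicographically later allele) and recorded in provenance;
round-trips are exact whenever the alternate allele is the minor one.
Monomorphic loci have MAF 0, HWE p = 1, PIC 0, A~e~ 1, and are excluded
from G and PCA (zero information, degenerate denominator). All-missing
loci and empty matrices raise errors at the operations whose definitions
require data. The exact-test implementation uses the stable ratio
recurrence from the modal heterozygote count; the test suite checks it
against full enumeration for every table up to n = 30 at 10^-10^.

## Problem sizes in the test suite

Unit tests run on fixtures of tens of samples and 10²–10³ markers.
The end-to-end validations use the sizes at which their properties are
sharp while staying lightweight: ROH recovery on 32 samples × 20,000
markers over a 1 Gb genome (20 markers/Mb, the density regime the detector
defaults target); kinship calibration and family reconstruction on 32
samples × 10,000 markers; HWE calibration on 1,000 simulated loci of
1,000 diploids; the pipeline determinism check on the full 32 × 46,590
default simulation. The whole suite completes in a few minutes on one
core.

## Known limitations

* ROH bounds are marker-resolution; F~ROH~ carries a chance-homozygosity
  floor at GBS density.
* LD-based Ne is order-of-magnitude only, and the simulator's founder pool
  is effectively infinite, so simulated Ne does not represent a closed
  herd's true drift rate.
* G-based family assignment inherits the small-sample centering shrinkage;
  with very few animals a true half-sib pair can fall below a 0.1
  threshold. Supplying external allele frequencies removes the shrinkage.
* The IBS/NJ tree is a descriptive clustering, not a phylogeny; branch
  lengths inherit all the caveats of distance-based methods on
  within-population data.
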