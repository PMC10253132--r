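---
title: "Methods: bin maps, composite interval mapping and candidate-gene integration for F2 resequencing populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bin maps and QTL scans for F2 populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Low-coverage whole-genome resequencing of a biparental F2 population gives
hundreds of thousands of segregating sites, each genotyped so shallowly
(about 4.8x here) that individual calls are unreliable — in particular,
heterozygotes are systematically under-called, because at depth $k$ a true
heterozygote shows only one allele with probability $2 \cdot 0.5^k$. The
remedy in this package follows the standard recombination-bin strategy:
filter sites to a high-quality aa $\times$ bb marker set, genotype each
individual in 15-site sliding windows, locate the recombination breakpoints
each window track implies, and merge chromosome segments that no individual
recombines in into *bin markers*. Bins are then ordered into a genetic map
(Kosambi distances), seed-colour phenotypes are scanned by composite
interval mapping (CIM) with permutation-derived genome-wide LOD thresholds,
and QTL support intervals are intersected with gene annotation, differential
expression and a weighted coexpression network to nominate candidate genes.

Every stage is driven by a meiosis-level simulator with known ground truth,
so properties such as "bin boundaries bracket true crossovers" or "peak
variance explained recovers the planted share" are testable, not assumed.

## The simulator and what it emulates

`default_map()` reproduces a 19-linkage-group *Brassica napus*-like
geometry (1618.3 cM total; the template allocation places 4148 marker
sites). Physical coordinates are collinear with genetic ones at 736 kb/cM —
a simplification: real chromosomes have recombination-suppressed
pericentromeric spans, which the package can *flag* (`collinearity()`) but
does not simulate by default.

Meiosis (`simulate_meiosis()`) draws crossovers per gamete as a Poisson
process (no interference; Haldane-consistent), with a `"kosambi"` mode using
a gamma-renewal process of shape 2.63 whose two-point recombination
fractions track the Kosambi function closely (verified by simulation at
20 cM). The default is the simpler Haldane process; all oracle checks
convert distances with the map function matching the active process.
F2 individuals are two independent F1 gametes, so genotypes segregate 1:2:1.

Variant calls (`simulate_variant_calls()`) draw Poisson read depths
(default mean 4.8), flip each read with a per-read error rate (default
0.005), call a site homozygous when all reads agree, heterozygous when both
alleles are seen, and missing at depth zero (plus an outright drop rate,
default 0.02). These error/missing defaults are nominal: the study system's
realized rates are not published, so they are configurable knobs with
round-number defaults rather than calibrated quantities.

Phenotypes (`simulate_phenotypes()`) build a standardized latent colour
value from the planted QTLs: each locus contributes $a\,x_a + d\,x_d$ with
$x_a \in \{-1,0,1\}$ and $x_d = 1$ for heterozygotes, rescaled so the
locus's theoretical 1:2:1 variance ($a^2/2 + d^2/4$) equals its target
share $h^2$; the residual is Gaussian with variance $1-\sum h^2$. The
default template (`default_qtls()`) plants the major locus at A09/81.91 cM
($h^2 = 0.2095$) and the minor locus at C03/0.31 cM ($h^2 = 0.0625$) with
partial dominance $d/a = 0.5$ toward the light-seed allele, matching the
F1's intermediate colour. Six colour traits (R, G, B, l, a, b) are affine
transforms of the latent value with noise set so pairwise correlations stay
at or above 0.9 (a and b with negative sign); the binary visual score is
$R > 67$. One caveat is worth stating plainly: a locus explaining ~21% of
variance cannot produce a strongly bimodal trait distribution — the
between-class separation is only ~0.75 residual standard deviations — so 67
is implemented as the visual-score threshold, and clear bimodality emerges
only at larger planted shares (the test suite demonstrates a density valley
at $h^2 = 0.75$).

Expression matrices (`simulate_expression()`) follow the 2-genotype x
3-stage x 3-replicate seed-coat design on the log2 scale: modules share
stage-driven latent profiles (genotype-neutral by default, so planted
differential expression is exactly the designated "flavonoid" set, which is
down-regulated by 2 log2 units in the light genotype at 25 and 35 daf, plus
one deliberately genotype-specific module). Replicate noise (0.1) and gene
noise (0.2) keep within-condition replicate correlations above 0.96. Real
RNA-seq count overdispersion, library-size variation and low-expression
censoring are *not* emulated; the stand-in DE test is a Welch t-test on
log2 values, appropriate for this generator but not a substitute for a
count model on real data — DE statistics can equally be supplied as input.

## Filtering and bin genotyping

`run_filter()` applies, in a fixed order that makes per-rule drop counts
well-defined: (1) opposite parental homozygotes with parent depth >= 2;
(2) F2 calls below depth 3 masked, sites called in fewer than half the
plants dropped; (3) minor allele frequency strictly above 0.30, computed
from the F2 calls only, $p = (2n_{aa}+n_{ab})/(2n_{called})$; (4) 1:2:1
chi-square with p >= 0.001 (asymptotic df-2 tail, no continuity
correction). "Minimum sequencing depth of each allele" is read as a
per-individual total-depth floor; a strict per-allele mode
(`per_allele_depth = TRUE`) covers the other reading.

Window genotyping uses 15-site windows stepping one site at a time (a
non-overlapping `step = 15` mode exists): a window is homozygous for a
parent when >= 11 of its informative sites carry that parent's allele,
heterozygous otherwise, unknown when more than two-thirds of its sites are
missing; the 11/15 threshold is pro-rated (`ceiling(11/15 * informative)`)
under missingness, and windows are clamped to full size at chromosome tails
so single noisy sites cannot flip a terminal call. Isolated one-window
states flanked by identical states are absorbed (toggleable smoothing).
Each genotype transition is then *refined* by a changepoint scan of the raw
site calls between the flanking windows — the boundary maximizing agreement
with the left state before it and the right state after it — which makes
breakpoint intervals exact on clean data and well-localized under noise.
One consequence of window resolution: a terminal segment shorter than ~11
sites (or an interior double-crossover segment shorter than ~5) is not
representable and is silently absorbed; the tests define truth at window
resolution accordingly. Bins are the partition of each chromosome at the
union of all individuals' refined breakpoints.

## Map construction

Pairwise recombination fractions use the full F2 codominant likelihood with
the phase-ambiguous double-heterozygote class handled by EM
(`estimate_rf()`, vectorized over all pairs in `rf_matrix()` via
indicator cross-products). Linkage groups are connected components at
LOD >= 6 and $\hat r \le 0.35$ — thresholds chosen once so that default
simulations reproduce their 19 chromosomes; they are exposed as arguments.
Within a group, markers are ordered by minimum-spanning-tree seriation (the
MST's diameter path, cheapest-insertion of off-path markers) polished by
2-opt on the sum of adjacent distances; the acceptance bar is
order-recovery quality (exhaustive-search equality up to 8 markers, perfect
rank correlation on clean simulations), not bit-compatibility with any
specific mapping program. Distances are adjacent-pair Kosambi,
$d = 25\ln\frac{1+2r}{1-2r}$, accumulated into cM positions; adjacent
$\hat r$ is capped at 0.49 to keep distances finite. A single-replicate map
length carries Monte-Carlo noise of roughly $\sqrt{100L/2n}$ cM (about
4 cM for a 60 cM group at n = 196), which is why length-recovery checks
average a few replicates.

`map_summary()` reports per-group length, marker count, mean interval
(length/(count-1)) and max interval; the whole-map mean interval is the
*unweighted mean of per-group mean intervals* — this convention, not total
length over (markers - groups), reproduces the published template's 0.400
figure, while the latter ("global") convention gives 0.39; both are
emitted.

## The CIM scan

At each grid position (default step 0.5 cM plus every marker), conditional
QTL genotype probabilities come from the flanking markers by exhaustive
enumeration of gamete configurations, assuming no interference between
flanks, with recombination fractions from the inverse Kosambi function;
missing flanks marginalize out, and at an observed marker the probabilities
collapse to the call. The scan regresses the phenotype on the expected
additive code $P(bb)-P(aa)$ and dominance code $P(ab)$ (Haley-Knott
approximation — deterministic and fast; at these effect sizes the normal
mixture EM adds little), plus background cofactors: up to 5 markers chosen
by forward stepwise regression with a partial-F entry test at p < 0.01.
The significance stop matters: forcing a fixed number of cofactors onto a
small genome parks them on markers linked to the QTL, and the 10 cM
exclusion window around the test position then carves LOD cliffs that can
displace peaks. $\mathrm{LOD} = (n/2)\log_{10}(RSS_{red}/RSS_{full})$;
with zero cofactors the scan is exactly plain interval mapping.

Genome-wide thresholds shuffle the phenotype (1000 permutations, alpha
0.05 by default; cofactors selected on the observed phenotype are reused —
the standard shortcut), recording each permutation's maximum LOD. Peaks are
local maxima above the threshold at least one exclusion window apart;
satellite shoulders whose 1-LOD support interval contains a stronger peak
on the same group are folded into it. Support intervals extend contiguously
to LOD >= peak - 1 and are projected to physical coordinates through the
markers they cover plus the bracketing pair.

Variance explained is reported from the single-QTL model against the null
(no cofactors), because the partial-given-cofactors ratio answers a
different question. The headline `r2` is the small-sample-adjusted form
$1 - \frac{RSS_1/(n-3)}{RSS_0/(n-1)}$: the raw ratio (also emitted as
`r2_raw`) carries a known $\approx p/n$ inflation — about 0.8 percentage
points at n = 196 — that would systematically overstate the variance
explained. Two biases remain inherent to *peak* estimates and are
quantified rather than hidden: the genome-wide maximum position is pulled
toward the long side of the chromosome (about -1.2 cM for a locus 11.5 cM
from a telomere at $h^2 = 0.21$), and conditioning on detection inflates a
minor QTL's apparent variance share (detection at a LOD ~4 threshold
requires a raw share of ~8%, so the conditional mean sits near 8-9% when
the planted share is 6.25%); the unconditional estimate at the planted
position is unbiased, and the acceptance machinery reports both.

The binary visual score is scanned as a numeric 0/1 trait, matching common
practice; a logistic scan is out of scope.

## Coexpression and candidate integration

The network is unsigned: adjacency $|cor|^\beta$ with soft threshold
$\beta = 8$, topological overlap
$TOM_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$,
average-linkage clustering of $1-TOM$ with a *static* cut (height 0.99) —
a deliberate simplification of dynamic tree cutting, so absolute module
counts on real data are not comparable — minimum module size 100, and
iterative merging of modules whose eigengenes correlate at or above 0.75
(merge cut height 0.25). Eigengenes are the first principal component of
the standardized module expression, signed to correlate positively with the
module's mean profile so downstream correlations are reproducible. Edges
are retained at weight strictly greater than 0.2.

Candidates satisfy all three steps: inside a peak's physical interval
(any-overlap, closed 1-based intervals); differentially expressed at the
key stages (default 25 and 35 daf — in the source system these stages were
identified by pathway enrichment, which is out of scope, so they are a
configurable input); and either in the flavonoid-related set or holding a
retained edge to a flavonoid-related DEG (optionally restricted to key
modules). "FoldChange > 1" is read as $|\log_2 FC| > 1$ — on the raw scale
the threshold would be vacuous — with a switch for tables on the raw scale.
The `delta_delta_ct()` utility implements qPCR relative quantification,
$2^{-\Delta\Delta C_t}$.

## Problem sizes and reproducibility

The replicate experiments run the scan on true marker genotypes from the
meiosis simulator — the noiseless limit of the filter + bin chain, whose
exactness is established separately — on the 19-group template thinned to
one marker per cM (1618 markers), scan step 1 cM, n = 196: 100 replicates
for the major-QTL recovery, 200 with 100-permutation thresholds for the
minor QTL, and 200 null replicates against 200-permutation thresholds for
the type-I-error check. These sizes are the package's chosen desk scale;
all estimates quote Monte-Carlo standard errors and the tests assert
recovery within three of them. Every stochastic function takes an explicit
seed, and fixture sets written by `write_fixtures()` record their seed and
all crossovers in a truth JSON.

## Known limitations

- Two-flank conditional probabilities (not a full hidden Markov model over
  all markers): with heavy missingness, information beyond the nearest
  flanks is ignored — mitigated here because bins are nearly complete.
- Adjacent-pair distances, not multipoint likelihood; marker order errors
  inflate map length.
- The simulator's collinear physical scale cannot exercise real
  structural-variation breakpoints or reference misassembly.
- Static tree cut and an unsigned network; anti-correlated expression
  blocks share modules by construction.
- The permutation threshold reuses observed-phenotype cofactors; with many
  strong QTLs this is mildly anticonservative, which the type-I-error check
  bounds empirically.
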