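# binmapqtl

Bin-map construction and QTL mapping for low-coverage resequenced F2
populations, with candidate-gene integration from expression data.

## The problem

Seed-colour genetics in *Brassica napus* (and many comparable crop traits)
is commonly dissected by resequencing a biparental F2 population at shallow
depth (~5x). Individual genotype calls at that depth are unreliable —
heterozygotes in particular are miscalled homozygous with probability
`2 * 0.5^k` at depth `k` — so mapping proceeds through *recombination bins*:
sites are filtered to a high-quality aa x bb marker set, each individual is
genotyped in 15-site sliding windows (homozygous when >= 11 sites carry one
parent's allele), window tracks are parsed into recombination breakpoints,
and chromosome segments without any recombination in the whole population
become single bin markers. Bins are ordered into a genetic map with Kosambi
distances (`d = 25 ln((1+2r)/(1-2r))` cM), traits are scanned by composite
interval mapping (Haley-Knott regression with stepwise-selected background
cofactors, excluded within 10 cM of the test position), significance is set
by a genome-wide permutation threshold (`LOD = (n/2) log10(RSS_red/RSS_full)`,
1000 shuffles, alpha 0.05), and 1-LOD support intervals are projected to
physical coordinates. Candidate genes are then the interval genes that are
differentially expressed at the key developmental stages and either belong
to a flavonoid-related set or are coexpressed (soft-threshold network,
`|cor|^8`, edges kept at weight > 0.2) with flavonoid-related DEGs.

The package implements this entire chain, together with a meiosis-level
simulator (19-group *B. napus*-like template: 1618.3 cM, major seed-colour
locus on A09 at 81.91 cM explaining 20.95% of variance, minor locus on C03
at 0.31 cM explaining 6.25%) so that every stage can be verified against
known ground truth.

## Worked example

Three chromosomes, 196 F2 plants, 4.8x calls, both template QTLs planted:

```r
library(binmapqtl)

map <- sim_map(data.frame(group = c("A09", "C03", "C07"),
                          length_cm = c(93.4, 111.3, 77.8),
                          length_bp = c(68.8e6, 81.9e6, 57.2e6),
                          n_sites = c(1100, 1300, 900)))
pop   <- simulate_f2(map, 196, seed = 11)
pheno <- simulate_phenotypes(pop, default_qtls(), sim_config(n = 196), seed = 12)
calls <- simulate_variant_calls(pop, depth = 4.8, seed = 13)

flt  <- run_filter(calls)
bins <- bin_genotype(flt$variants)
gmap <- build_map(bins)
map_summary(gmap)[, c("group", "length_cm", "n_markers", "mean_interval")]

cfg   <- cim_config(step = 1, n_perm = 200)
scan  <- cim_scan(bins$geno, gmap, pheno$R, cfg)
thr   <- permutation_threshold(bins$geno, gmap, pheno$R, cfg, seed = 14)
peaks <- call_peaks(scan, thr$threshold, map = gmap, trait = "R")
```

which prints (filter report, bins, map summary, threshold, peaks):

```
                   rule sites
1       not_polymorphic     0
2           too_missing     0
3               low_maf     0
4 distorted_segregation     3
5              retained  3297
bin_geno: 982 bins x 196 individuals on 3 chromosome(s)
  group length_cm n_markers mean_interval
1  LG01    113.72       369        0.3090
2  LG02     96.34       307        0.3148
3  LG03     89.18       306        0.2924
4 Whole    299.24       982        0.3054
genome-wide LOD threshold (alpha = 0.05): 3.36
  trait chrom    cm    lod     r2 ci_lo  ci_hi  phys_lo  phys_hi
1     R   C03  0.00  5.725  9.812  0.00  1.533        1  2269746
2     R   A09 82.54 13.039 24.051 81.52 83.053 56905551 60223476
```

Reading the output: 3297 of 3300 simulated sites survive the aa x bb
filters (three fail the 1:2:1 chi-square by chance); the population's
recombination events define 982 bins; the rebuilt linkage groups match the
simulated chromosome lengths (e.g. 96.3 cM estimated vs 93.4 cM simulated
for A09) with ~0.31 cM between adjacent bins. The scan recovers the major
locus at 82.5 cM on A09 (planted at 81.91, LOD 13.0, 24.1% variance
explained vs 20.95% planted in this realization) and the minor locus at the
top of C03 (planted at 0.31 cM), each with its 1-LOD support interval and
physical projection. `select_candidates()` then intersects such intervals
with annotation (`read_gff3()`), DE results (`de_by_stage()`, `deg_filter()`)
and a coexpression edge list (`soft_adjacency()`, `topological_overlap()`,
`detect_modules()`, `retain_edges()`).

A complete synthetic data set (VCF + phenotype TSV + GFF3 + expression TSV
+ truth JSON, all round-tripping through the package's readers) is written
by `write_fixtures(outdir)`.

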