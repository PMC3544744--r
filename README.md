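# ppmap

Genetic mapping of S-locus-independent **pollen-part mutations** (PPMs) in
species with S-RNase-based gametophytic self-incompatibility (GSI), such as
apricot and other *Prunus*. The package is written for geneticists and
breeders who need to (i) decide, from segregation ratios, whether a
self-compatible accession carries a PPM at the S-locus or at an unlinked
modifier locus, and (ii) localize that modifier locus on a linkage map using
the segregation distortion its pollen selection leaves behind.

## The genetic model

In GSI, a pollen grain is rejected when its haploid S-haplotype matches
either pistil S-allele. A *modifier* locus (here *M/m*) is a second locus
whose functional allele *M* is required, in the pollen grain itself, for
this rejection; pollen carrying the mutated allele *m* grows even on a
matching pistil. For a double heterozygote *S1S2 Mm* selfed, the four pollen
classes are `S1 M`, `S1 m`, `S2 M`, `S2 m` at ¼ each; only the *m* classes
survive the pistil, so:

* the S-genotypes segregate **2 S1S2 : 1 S1S1 : 1 S2S2** instead of 1:2:1;
* an SSR marker at recombination fraction *r* from the modifier segregates
  **(r/2, 1/2, (1−r)/2)** over (repulsion homozygote A, heterozygote H,
  coupling homozygote B) — 1:2:1 at r = ½, 1:4:3 at r = ¼, and 0:1:1 at
  r = 0. The collapse of the A class is the segregation-distortion-locus
  (SDL) signal the scan looks for.

Competing hypotheses (mutation homozygous, or in coupling with one
S-haplotype) predict different S-genotype ratios and are compared by Pearson
χ² (no continuity correction, df = k − 1). F2 individuals are classified as
*Mm* or *mm* by selfing them and testing a linked heterozygous marker's F3
counts against 1:1 (over H,B; A absent) versus 1:2:1. Recombination
fractions convert to cM by the Kosambi or Haldane map function.

## Worked example

The package bundles the published segregation tables of a self-compatible
apricot cultivar ('Katy', *S1S2 M'm'*) as plain TSV files. Testing the
pollen-selection model on the 'Harcot' × 'Katy' outcross:

```r
library(ppmap)
katy   <- parent_genotype(c("S1","S2"), modifier = c("M","m"), label = "Katy")
harcot <- parent_genotype(c("S1","S4"), label = "Harcot")
hxk    <- cross_spec(harcot, katy, "H x K")

counts <- read_s_counts(ppmap_example("katy_s_counts.tsv"))
obs    <- s_counts_for(counts, "H x K")
compare_hypotheses(obs$observed, hxk,
                   list(model_hypothesis("het_unlinked"),
                        model_hypothesis("homozygous_mutated")))
#> Hypothesis comparison for 'H x K'
#>                            hypothesis   ratio statistic df p.value excluded
#>  heterozygous mutation, unlinked to S 1:2:1:2      3.66  3 0.30100    FALSE
#>                   homozygous mutation 1:1:1:1     13.64  3 0.00344    FALSE
```

The unlinked-heterozygote model fits (χ² = 3.66, p = 0.30) while the
homozygous alternative is rejected (χ² = 13.64, p = 0.003). Scanning the
high-density chromosome-3 F2 marker table then localizes the modifier:

```r
scan <- sdl_scan(read_marker_counts(ppmap_example("katy_lg3_f2.tsv")))
localize_locus(scan)
#> Zero-loss run: PGS3_23 (18.61-18.61 Mb)
#> Locus interval (non-zero flanks): PGS3_22 - PGS3_28, 18.49-19.14 Mb
```

PGS3_23 is the only marker through which no recombinant mutation carrier
was observed (its repulsion-homozygote class is empty in 85 trees), so the
modifier is placed between its distorted neighbours PGS3_22 and PGS3_28.
`classify_f3_panel()` + `locus_interval_from_recombinants()` sharpen this
with F3 progeny tests, and `simulate_cross_population()` generates
populations under the same transmission model for power and calibration
work (see the vignette in `vignettes/`).

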