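---
title: "Mapping a pollen-part modifier locus from segregation distortion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a pollen-part modifier locus from segregation distortion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppmap)
```

## The transmission model and its assumptions

`ppmap` models S-RNase-based gametophytic self-incompatibility (GSI) with a
single modifier locus acting in pollen. The assumptions, each of which is a
real restriction:

* **Gametophytic, all-or-none pollen action.** A pollen grain is rejected
  iff its own S-haplotype matches either pistil S-allele, its pollen
  S-determinant is functional, and its modifier allele is functional.
  There is no partial rejection, no sporophytic (diploid-parent) effect,
  and the pistil side is always fully functional — appropriate for
  self-compatible accessions that are normal seed parents.
* **Diploidy and two modifier alleles.** Gametes carry one S-haplotype and
  one modifier allele; S-heteroallelic (diploid) pollen is out of scope.
* **Defective S-haplotypes.** An S-haplotype may be flagged pollen-part
  defective (e.g. a disrupted SFB gene); its pollen then escapes rejection
  regardless of the modifier. This is needed to reproduce crosses involving
  parents that carry such haplotypes.
* **Optional S–modifier linkage.** By default the modifier segregates
  independently of the S-locus (`r_sm = 0.5`); a coupling-phase
  configuration with any recombination fraction can be declared, which is
  how the "mutation linked in coupling" alternative hypothesis is built.

Under this model a self-pollinated double heterozygote *S1S2 Mm* transmits
only *m* pollen, giving the 2:1:1 S-genotype ratio and, at a marker at
recombination fraction $r$ from the modifier, genotype frequencies
$(r/2,\; 1/2,\; (1-r)/2)$ over (A, H, B). `expected_ratio()` derives the
expected ratio of any cross under any of the three mutation hypotheses by
rewriting the pollen parent and filtering its gametes — there are no
hard-coded ratios.

## Statistical procedures

**Goodness of fit.** `chisq_gof()` is the plain Pearson statistic with
$E_i = N r_i / \sum r$, df $= k-1$, upper-tail p, and no continuity
correction; this is the convention under which the bundled tables'
published values recompute exactly (to the 2 decimals they print). Expected
counts below 5 raise a classed warning but do not block, matching standard
practice for these population sizes. Statistics are kept at full precision
internally and rounded only for display.

**Distortion scan.** `marker_distortion_test()` tests 1:2:1 over (A,H,B)
for `<abxab>` intercross markers and 1:1 over the two pollen-transmitted
classes for the outcross types. Markers scored with different code pairs in
different sub-populations (composite types like `"<efxeg>/<nnxnp>"`) are
pooled by first aligning, within each pair, the majority (coupling) class
against the minority class. The alignment matters: summing by code order
instead produces a statistic that does not reproduce the published pooled
values whenever the coupling allele sits on different codes in different
sub-populations. Majority transmission is also how the coupling allele is
inferred in general — no phase annotation is required — with an explicit
ambiguity flag on ties.

**Localization from the scan.** `localize_locus()` takes the maximal run of
markers with coupling-allele loss frequency exactly zero (ties broken
toward the run holding the largest χ²) and reports both that inner span and
the interval bounded by the nearest non-zero markers. On the bundled
outcross table the zero run is PGS3_15–PGS3_28: PGS3_15 shows 24/0
transmission in the one sub-population where it segregates, so by the
counts it belongs to the run, even though a smaller marker set
(PGS3_22–PGS3_28) is sometimes quoted for these data. The implementation
follows the counts.

**F3 classification.** For an F2 from a population in which every pollen
gamete carried *m*, `classify_f2()` discriminates *Mm* from *mm* by a 1:1
test over (H,B) plus an exact binomial check that the A-class count is
compatible with its expectation $r/2$ (default $r = 0$), against a 1:2:1
test. The A-class check is the decisive design choice: a borderline 1:2:1
fit (p just above α) with a well-populated A class must still be called
*mm*, because any A individual is impossible under *Mm* with a tightly
linked marker. Both statistics are always reported; two retained or two
rejected hypotheses yield an explicit `"ambiguous"`. Families under 7
embryos are excluded from calling, mirroring the practice of discarding
under-sized F3 families.

**Recombinant-interval logic.** `locus_interval_from_recombinants()`
intersects, across classified recombinants, the chromosome regions whose
marker-implied genotype can match each recombinant's class (H regions for
*Mm*, B regions for *mm*; A regions are impossible anywhere, since every
individual received *m* through pollen). Regions extend between typed
markers under the standard at-most-one-breakpoint-per-interval reading, so
untyped markers widen, never bias, the result. Contradictory recombinants
are reported and excluded with a warning rather than silently dropped. The
bundled recombinant file completes two cells (PGS3_22 = H for K06-17 and
K06-21) that the published count table leaves blank; the completion is
taken from the published graphical map, whose breakpoint placement between
PGS3_22 and PGS3_23 — and the flanking pair it reports — admit no other
value.

## The simulator: what it emulates and what it does not

`simulate_cross_population()` is a forward gametic simulator: crossovers
between adjacent loci are independent Bernoulli events (no interference)
with fractions from the inverse Haldane transform of the map positions
(Kosambi available; at the sub-cM distances relevant here the two differ by
less than sampling noise). Pollen is passed through the pistil screen by
rejection sampling; an optional per-S-haplotype fitness multiplier lets one
explore the differential pollen-competitiveness explanation for deficits of
particular S-homozygotes, and defaults to neutral because no quantified
value exists for it. A single integer seed makes every output
bit-identical.

Defaults mirror the study conditions the bundled tables come from: 16
markers at their published Mb positions converted at 0.56 Mb/cM (the
genome-average physical-to-genetic ratio, itself recomputed by
`mb_per_cm(290, 519)`), an F2 of 87 with the modifier placed at 18.7 Mb
(inside the interval the real data delimit), outcross subsets of 60
selected carriers, and F3 family sizes uniform on 2–77 embryos, the
published range.

What the simulator does **not** model — and what passing simulation tests
therefore cannot show about real data: genotyping error and missing-data
patterns, segregation distortion from any cause other than pollen selection
(embryo lethality, gametic competition outside the declared fitness knob),
crossover interference, and marker order uncertainty. Type-I-error and
coverage results are calibration checks of the inference machinery under
its own model, not field guarantees.

## Numerical choices

* Expected-ratio probabilities are reduced to integer ratios by scanning
  denominators up to 64; all classical GSI ratios are far below this.
* Distribution invariants are enforced at `1e-12`; map-function round-trips
  are exact to `1e-9`; interval arithmetic rounds floating drift below
  `1e-9` so 3-decimal Mb endpoints behave exactly.
* Chi-square thresholds at α = 0.05 (5.99 at 2 df, 3.84 at 1 df) are
  recorded on every scan object for transparency.
* Missing calls (`-`) are excluded listwise per marker; decimal commas in
  numeric columns are normalized on read only.
* When cM and Mb orders disagree within a scaffold, physical order wins
  with a warning naming the markers (the bundled map has one such pair).
* Nei's distance uses the 1972 pooled-loci standard form; a small-sample
  variant is available behind `variant = "unbiased"` because the software
  historically used for such tables does not document its estimator. With
  single-individual profiles the correction can degenerate (zero corrected
  identity); that case returns `NA` rather than a misleading number. The
  shared-allele percentage is computed over the allele union by default,
  with the smaller-set convention behind an argument, since both
  conventions are in circulation.

## Problem sizes used by the test-suite and acceptance properties

Simulation-based checks run at the sizes a study of this design would use:
frequency convergence at $N = 10^5$ offspring; recombination-fraction
recovery over 500 replicates of $N = 85$ (the real F2 size) at
$r \in \{0, 0.05, 0.1, 0.25\}$; distortion-flag type-I error over 25 null
populations × 16 markers; localization coverage over 200 replicates of
$N = 85$; F3 classifier error rates over 500 replicates of 60-embryo
families (an upper-middle family size within the 2–77 range), where the
observed error stays within the 10% design bound for $r \le 0.05$.

## Known limitations

* The classifier's A-class rule assumes the marker–modifier recombination
  estimate supplied to it; with a badly misspecified $r$ it becomes
  anti-conservative against *Mm*.
* `localize_locus()` reasons on zero counts, so its inner span shrinks to
  single markers only as carriers accumulate; with few individuals the
  non-zero flank interval is the honest summary.
* The recombinant-interval intersection assumes correct marker order and at
  most one crossover between adjacent typed markers; dense double
  crossovers would surface as "conflicting recombinants" rather than being
  resolved.
* No multiple-testing correction is applied across markers or crosses,
  matching the practice the package reproduces; users scanning many
  chromosomes may wish to tighten α.
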