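---
title: "Estimating bacterial mutation rates and effective population size from mutation-accumulation data"
author: "mutacc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating bacterial mutation rates and effective population size from mutation-accumulation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutacc)
```

## The model

A mutation-accumulation (MA) experiment propagates many replicate lines of a
clonal organism through repeated single-colony bottlenecks. The bottlenecks
keep the within-line effective population size so small (here
`Ne = g × Nb ≈ 25`, for `g ≈ 25` generations of regrowth per transfer from a
single founding cell) that selection is effectively blind to all but the most
drastic fitness effects (`|s| > 1/Ne ≈ 0.04`), and mutations fix at close to
the spontaneous rate. After `T` generations summed across lines, the number
of fixed mutations `m` of a given class is modeled as Poisson with mean
`µ·n·T`, where `n` is the *mutational target size* — the number of genomic
positions (or repeat units) at which a mutation of that class can arise.

The maximum-likelihood rate is

```
µ̂ = m / (n·T)
```

with the exact two-sided, equal-tailed 95% interval obtained from gamma
quantiles: lower bound `qgamma(α/2, m)/(nT)` (zero when `m = 0`), upper
`qgamma(1 − α/2, m + 1)/(nT)`. This is the classical exact Poisson interval;
`poisson_rate()` implements it directly, and a unit test cross-checks the
bounds against `poisson.test()`.

```{r}
poisson_rate(428, 9080403, 85323)[c("mu", "ci_low", "ci_high")]
```

Poisson adequacy of per-line counts is checked two ways. The dispersion test
compares `(n − 1)·s²/mean` to χ²(n − 1), doubling the smaller tail so both
over- and under-dispersion (e.g. zero inflation) can reject. The
one-sample Kolmogorov–Smirnov statistic is computed against a Poisson with
the sample mean, taking the supremum over the discrete support; the
asymptotic Kolmogorov p-value is conservative for a discrete null with an
estimated rate, which we accept and document rather than correct — the test
is an adequacy screen, not an inferential endpoint.

## Target sizes from an annotated genome

Every site receives exactly one region label with the precedence
`protein_coding > rna_coding > pseudogenic > intergenic`, so labels
partition the genome even where open reading frames overlap; a substitution
inside two overlapping ORFs is one protein-coding event, never two.

Within protein-coding genes the synonymous and nonsynonymous targets are
fractional site counts from codon degeneracy under the bacterial genetic
code (translation table 11): each site's three possible single-base changes
are classified by translation in the gene's frame, and the site contributes
`(#synonymous changes)/3` to the synonymous target and the remainder to the
nonsynonymous target (nonsense changes count as nonsynonymous). The two
targets therefore sum exactly to the protein-coding site count, an invariant
asserted to 1e-6 in the tests. For sites covered by several CDS the most
constrained assignment applies: a change is synonymous only if it is
synonymous in every overlapping frame. Start codons are treated as ordinary
codons for degeneracy; this affects a negligible fraction of sites and
avoids special-casing initiator methionine. Sites containing `N` are
excluded from every target, mirroring the exclusion of positions without
adequate read coverage in resequencing data; a codon containing `N` cannot
be translated, so its other two sites leave the synonymous/nonsynonymous
pool as well. CDS whose length is not a multiple of three, or which contain
an internal stop, are skipped with a warning rather than guessed at.

The per-codon decisions are validated against an exhaustive oracle that
enumerates all nine single-base changes of every codon for 100 random genes
on both strands.

## STR scanning and the unit-based target

Microsatellites (perfect short tandem repeats) mutate mainly by
polymerase slippage that adds or removes *whole motif units*. The STR
target is therefore counted in repeat units, not base pairs: a run of `u`
units offers `u` opportunities for a single-unit event. `scan_str()` finds
all maximal perfect repeats of primitive motifs (a motif that is itself a
power of a shorter motif is reported at the shorter period only) on the
forward strand, reporting motifs by their lexicographically least rotation.
Default unit thresholds are 6 (mono), 4 (tri), 2 (penta) and 2 (16-mer
motifs; a threshold of "one repetition" for long motifs is read as one
repetition *beyond* the first, since a single occurrence is not a tandem
repeat). An optional motif whitelist restricts the scan to motif classes
actually observed to mutate, matching target definitions conditioned on
observed mutability. `str_target()` reports both the unit and the bp sum;
only the unit total enters rate estimation. The scanner is validated
against a brute-force oracle that tests every (start, period) pair on
hundreds of random strings.

An indel is classed as an STR event only if applying the edit leaves a
covering locus a perfect repeat of exactly one unit more or fewer — length
alone, or inserting a rotation of the motif out of phase, does not qualify.

## Bias tests and composition nulls

All selection/bias tests compare observed mutation counts with expectations
derived from genome composition or target sizes:

* **Region placement** (`region_chi2()`): the 2×2 table of mutated versus
  unmutated sites by region, tested with the Yates-corrected χ² (correction
  magnitude `min(0.5, |O − E|)`, so a perfectly proportional table scores
  exactly 0). The correction variant matters at these counts and is fixed by
  the package.
* **NS/S ratio** (`ns_s_test()`): same construction with the
  nonsynonymous/synonymous site targets as the null split; a nonsynonymous
  deficit would be the signature of residual purifying selection.
* **Transition fraction**: exact binomial against 1/3, the share of
  transitions among the three possible changes at any site under uniformity.
* **Toward-A/T fraction**: exact binomial against the composition null
  `gc·2/3 + (1 − gc)/3` — two of three changes at a G/C site move toward
  A/T, one of three at an A/T site. The genome-wide GC fraction is used by
  default (configurable).

Two-sided binomial p-values follow the minimum-likelihood convention of
`binom.test()`. No multiple-testing correction is applied across the
battery: the tests address distinct hypotheses and are reported
individually.

## Diversity and effective population size

Nucleotide diversity π is the mean pairwise proportion of differing sites,
with pairwise deletion of gap/ambiguous columns and no multiple-hit
correction (the raw proportion is the quantity entering the Ne formula;
at the diversity levels involved the Jukes–Cantor correction would be
sub-percent). It is typically computed at four-fold degenerate third codon
positions — extracted by `extract_fourfold_sites()` from a codon alignment
using the reference row's codon context — because those sites evolve
approximately neutrally. Under haploidy, `π = 2·Ne·µ`, so `ne_from_pi()`
returns `π/(2µ)`.

The neutral coalescent simulator (`coalescent_simulate()`) validates this
pathway end to end: Kingman genealogy, Poisson mutations at θ/2 per site
per coalescent time unit, infinite-sites placement at distinct columns. Its
expectation `E[π] = θ` is checked within Monte-Carlo error, along with a
Watterson segregating-sites check. Population-structure filtering of
natural isolates is out of scope; the module expects a pre-filtered,
unstructured sample.

## Phylogenetic regression

Across species, the drift-barrier hypothesis predicts µ to scale inversely
with Ne. Because species values are not independent, `pgls_fit()` fits
`log10 µ ~ log10 Ne` (or genome size) by generalized least squares with the
Brownian-motion covariance of a supplied tree (`C[i,j]` = shared
root-to-MRCA path length), at fixed λ = 1 — no Pagel's λ optimization,
which would be under-determined at ~20 tips. Two fit-quality numbers are
returned: the coefficient of determination in the whitened space (primary)
and the ordinary Pearson r² of the transformed variables, since both
conventions circulate in the comparative literature. The implementation is
checked against `nlme::gls` with a Brownian correlation structure, against
OLS on star trees (agreement to 1e-10), and by slope recovery without
detectable bias over 500 Brownian simulations on a 21-tip tree.

## The synthetic-data generator

`sim_config()` defaults describe the study conditions the package is built
around: GC fraction 0.69, ~90% coding, 46 lines × 1,855 generations, SNV
rate 5.52e-10 per site per generation, non-STR indel rate 1.5e-11, STR
slippage 1.23e-8 per unit, 11 ancestral variants shared by all lines, and a
motif mix of mono-, tri-, penta- and 16-mer repeats. The default genome
length (200 kb) is a deliberately scaled-down stand-in for a multi-megabase
chromosome: all rates are per site or per unit, so parameter recovery is
length-independent, and validation runs stay fast. Genes are laid out
without overlap, in frame and stop-free, on alternating strands; planted
STR loci are written into intergenic gaps with flanks adjusted so each
locus is maximal exactly as recorded.

What the generator does *not* emulate — and hence what passing tests do not
demonstrate about real data: read-level error and coverage variation
(inputs are taken as faithful calls from an upstream variant caller with
its own support filters), selection during colony growth, context-dependent
(neighbor-sensitive) mutation processes, insertion-sequence movement and
structural variation, and overlapping reading frames (the analysis handles
them; the generator does not plant them). Back mutations and multi-hit
sites are permitted but negligible at realistic rates.

## Numerical and design choices

* Coordinates are 1-based inclusive at file boundaries (GFF3 convention);
  interval arithmetic is done on plain integer vectors internally.
* Exact Poisson intervals via gamma quantiles; equal tails.
* Yates correction capped at `|O − E|` (via `chisq.test`), so exact
  proportionality gives statistic 0.
* Ties between overlapping same-period repeat candidates resolve leftmost;
  scanning is deterministic.
* Duplicate mutation calls (same line, position, alleles) collapse with a
  warning; a reference-allele mismatch against the genome is an error, not
  a warning, because it indicates a coordinate or build mix-up.
* Per-line generation counts default to a common value when only a total is
  known; the estimators use only the sum `T`.
* All simulation entry points take a single integer seed; outputs are
  byte-deterministic given the seed.

## Validation problem sizes

The shipped test suite exercises: codon-degeneracy oracles on 100+ random
genes (plus 40 during module tests); the STR scanner against brute force on
200 random strings of 60–200 bp seeded with the study's motif classes;
interval coverage over 2,000 simulated MA count datasets at the study
design (93–97% nominal band); coalescent `E[π] = θ` at θ = 0.01, L = 1e5
over 100 replicates (3-standard-error band); PGLS slope recovery over 500
Brownian replicates (mean within ±0.03 of the planted slope); and type-I
control of the dispersion and KS checks on 2,000 and 500 Poisson null
samples. These sizes keep the full suite under a minute while leaving
Monte-Carlo error well inside the asserted bands.

## Limitations

* Target sizes are computed from the reference genome with `N` masking;
  per-line coverage masks can be emulated by masking the genome, but no
  averaging rule across lines is built in.
* Spliced/joined CDS and multi-replicon bookkeeping are not supported.
* The KS adequacy p-value is asymptotic and conservative (discrete null,
  estimated rate).
* `pgls_fit()` assumes the supplied tree is correct and fully resolved;
  branch-length scaling does not affect the slope, but topology errors do.
* Imperfect (interrupted) repeats are not scanned; only perfect STRs enter
  the unit target.
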