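# mutacc

Analysis toolkit for bacterial **mutation-accumulation (MA) experiments**:
from an annotated genome and per-line mutation calls to per-category
mutation rates with exact confidence intervals, mutational-bias tests, and
effective population size.

MA experiments propagate replicate lines through repeated single-colony
bottlenecks so that selection is effectively powerless and mutations fix at
the spontaneous rate. With `m` mutations of a class observed over a
mutational target of `n` sites (or STR repeat units) and `T` generations
summed across lines, the rate is estimated by Poisson maximum likelihood,

    µ̂ = m / (n·T),   exact 95% CI from gamma quantiles,

and compared across classes whose targets come from codon degeneracy
(fractional synonymous/nonsynonymous site counting under translation
table 11), region classification (protein-coding / RNA / pseudogene /
intergenic) and exhaustive perfect-repeat scanning (STR targets in repeat
units, since slippage adds or removes whole motifs). Bias tests use
composition-derived nulls (Yates-corrected 2×2 χ², exact binomials against
1/3 transitions and the GC-dependent toward-A/T proportion). Neutral
diversity at four-fold degenerate sites gives the effective population size
via `π = 2·Ne·µ` (haploid), and a phylogenetic generalized least squares
module regresses `log10 µ` on `log10 Ne` under Brownian covariance from a
Newick tree. A synthetic-data module (genomes, MA lines, coalescent
alignments with planted truth) makes the whole pipeline testable without
external data.

## Worked example

The package ships the summary counts of a published MA study (46 lines,
85,323 total generations, GC-rich ~9.1 Mb genome) as a known-answer
fixture:

```r
library(mutacc)
wx <- reproduce_worked_example()
as.data.frame(wx$rates)[1:3, c("category", "m", "n", "mu", "ci_low", "ci_high")]
#>        category   m       n           mu       ci_low       ci_high
#> 1     snv_total 428 9080403 5.524240e-10 5.013212e-10 6.073232e-10
#> 2 nonsynonymous 249 6053873 4.820587e-10 4.240375e-10 5.458023e-10
#> 3    synonymous 109 2143616 5.959549e-10 4.893410e-10 7.188990e-10
```

The base-substitution rate is 5.52 (95% CI 5.01–6.07) × 10⁻¹⁰ per site per
generation — 0.0050 (0.0046–0.0055) mutations per genome per generation.
STR indels run at 123 (81.3–179) × 10⁻¹⁰ per repeat unit, ~800-fold above
the non-STR indel rate per target. The bias battery on the same counts:

```r
wx$biases$snv_region
#> <bias_test_result> region placement chi-square (Yates)
#>   observed: coding 361, noncoding 67
#>   statistic = 17.04, df = 1, p = 3.67e-05 (deficit in coding)
wx$ne
#> <ne_estimate> Ne = 9.956e+06
```

Mutations are depleted in coding regions relative to the 90.4% coding
fraction of the genome (χ² = 17.0), while the nonsynonymous/synonymous
ratio (2.3 observed vs 2.8 expected from target sizes, χ² = 3.2, p = 0.073)
shows no detectable selection — the coding deficit reflects region-specific
mutation/repair rates, not selection. With π = 0.011 at four-fold
degenerate sites, `π = 2·Ne·µ` gives Ne ≈ 10⁷.

End-to-end on synthetic data:

```r
sim <- generate_genome(sim_config(genome_length = 50000L, seed = 7, snv_rate = 2e-8))
ma  <- simulate_ma_lines(sim)
cat <- annotate_mutations(subtract_shared(ma$catalog)$catalog, sim$genome,
                          str_loci = sim$str_loci)
category_rates(cat, compute_targets(sim$genome, str_loci = sim$str_loci))
```

A thin CLI (`inst/scripts/mutacc`) wraps `reproduce`, `simulate` and `run`.
See the vignette (`vignettes/mutation-accumulation-analysis.Rmd`) for the
model, parameter meanings, numerical choices and limitations.

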