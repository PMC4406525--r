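# HaploRich

Truncated power-law estimation of haplotype and allele diversity.

## What problem this solves, and for whom

Stem-cell transplant registries match patients to donors by HLA
haplotype — six-locus allele combinations (A~C~B~DRBX~DRB1~DQB1) drawn
from the most polymorphic region of the human genome. Haplotype
frequencies are extremely heavy tailed: nearly half of the haplotypes
observed in a large registry appear in exactly one donor, while a few
common haplotypes cover most of the population. Registry planners (and,
more broadly, anyone estimating species richness under heavy-tailed
abundance) need two numbers that direct observation cannot give:

* **H** — how many distinct haplotypes exist in the whole population,
  observed or not;
* **coverage** — what fraction of the population carries a haplotype
  already present in the sample.

Classical richness estimators (capture–recapture, jackknife, Chao1, ACE)
assume lighter tails and severely underestimate H at realistic sampling
depths. `HaploRich` instead fits a parametric model of the whole
frequency distribution.

## The model

Category relative frequencies follow a truncated power law: the count
density (expected number of categories per unit of relative frequency)
is

    mu(x) = A x^(-alpha),   x_min <= x <= x_max,

normalized so total probability mass is one, which gives
`A = (2-alpha) / (x_max^(2-alpha) - x_min^(2-alpha))`. The total
richness is `H = integral of mu`, in closed form, and for a sample of R
draws the package evaluates closed forms for

* `U(R)` — expected number of distinct categories discovered
  (`expectedUnique`),
* `Z(R)` — probability the next draw is an unseen category
  (`probUnseen`),
* `1 - Z(R)` — population coverage (`fractionCovered`),

all via the lower incomplete gamma function analytically continued to
negative shape (`lowerGammaExt`), which the haplotype regime
(`alpha > 1`) requires. Parameters are estimated by fitting the
empirical discovery curve — unique-category counts in subsamples of
increasing size — against the closed form `U(R)` with a log-weighted
least-squares cost (`empiricalDiscoveryCurve` + `fitModel`), then
projected to any target population size (`extrapolate`,
`sampleSizeForCoverage`). A full simulator (`generatePopulation`,
`drawSample`, `convergenceBenchmark`), direct exponent estimators
(Clauset continuous/discrete, KS-selected cutoff, Ohannessian singleton
ratio), classical comparators (`captureRecapture`, `jackknife1`,
`chao1`, `ace`) and frequency-table I/O with six-locus haplotype
handling (`readFrequencyTable`, `allelesFromHaplotypes`) round out the
toolkit. See the vignette in `vignettes/` for the mathematics and the
design choices.

## Worked example

Simulate a heavy-tailed population of one million haplotype draws,
sample 10% of it, and recover the distribution:

```r
library(HaploRich)

pop <- generatePopulation(alpha = 1.5, nTotal = 1e6, seed = 7)
pop
#> SyntheticPopulation: 37251 categories (seed 7)
#>   generating model: alpha=1.5, xMin=1e-06, xMax=0.0007207

smp <- drawSample(pop, 1e5, seed = 1)
smp
#> ObservedSample: 16382 categories, 100000 draws (7020 singletons, 42.9%)

fit <- fitModel(empiricalDiscoveryCurve(smp, seed = 2), nTotal = 1e6)
fit
#> FitResult (truncated power-law discovery-curve fit)
#>   alphaHat : 1.5002
#>   xMinHat  : 1.042e-06
#>   xMaxHat  : 0.0007205
#>   hHat     : 36523.2
#>   cost     : 0.00397 over 30 curve points
#>   converged: TRUE

extrapolate(fit, 1e6)
#>       r uTarget  coverage  probUnseen     hHat
#> 1 1e+06 33352.8 0.9948848 0.005115203 36523.18

sampleSizeForCoverage(fit, 0.994)
#> [1] 915911.3
```

Reading the numbers: the sample contains 16,382 distinct haplotypes
(43% singletons — the heavy-tail signature), yet the fit recovers the
generating exponent 1.5 to four significant figures and estimates total
richness `hHat` within 2% of the true 37,251 categories. The projection
says a full-population census would realize ~33,353 of them, and that
99.5% of the population already carries a haplotype seen in some sample
of this depth. The classical comparators on the same sample
(`jackknife1(smp)` = 23,402, `chao1(smp)` = 25,624) undershoot the true
richness by 31–37%.

## Command-line use

A thin CLI over the same functions lives at
`inst/scripts/hladiversity.R`:

```sh
Rscript inst/scripts/hladiversity.R simulate --alpha 1.5 --n-total 1e6 \
    --seed 3 --out pop.tsv --sample-size 1e5 --sample-out sample.tsv
Rscript inst/scripts/hladiversity.R fit --table sample.tsv \
    --sample-size 1e5 --n-total 1e6
Rscript inst/scripts/hladiversity.R estimate --alpha 1.5 \
    --x-min 1e-6 --x-max 1e-2 --r 1000,100000
```

Subcommands: `simulate`, `fit`, `estimate`, `project`, `alpha`,
`benchmark`, `alleles`.
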