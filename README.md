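# uchap

Bayesian detection of haplotype-specific disease risk from unphased SNP
genotypes of nuclear families.

## The problem and who it is for

Genetic epidemiologists studying a candidate region with family data
(parents plus at least one affected child, possibly more siblings) want
to know which *haplotype* in the region carries risk — not just which
single SNP.  Three obstacles intervene: haplotype phase cannot be read
off unphased genotypes; which parental haplotypes were transmitted to
the affected child (versus the matched "pseudo-control" carrying the
non-transmitted pair) is itself ambiguous; and regions harbour many
haplotypes, most rare, so a per-haplotype regression is sparse and
ill-conditioned.

`uchap` folds all three uncertainties into one probabilistic design
matrix and fits a Bayesian conditional logistic regression on it.  For
family *i* with case/pseudo-control core-haplotype rows
`z1_i`, `z0_i` (each row sums to 2 — one entry per inherited haplotype,
spread as probabilities over phase explanations, transmission status,
and ancestral-core cluster membership), the likelihood is

```
L(beta) = prod_i  exp(beta' z1_i) / ( exp(beta' z1_i) + exp(beta' z0_i) )
```

with prior `beta ~ MVN(mu, sigma^2 I)`, `mu = logit(prevalence)` in every
component, and `sigma^2 ~ InverseGamma(a, b)`.  Rare haplotypes are
merged onto ancestral *core* haplotypes by an entropy-calibrated,
Hamming-distance clustering, so `beta` has one effect per core.  The fit
reports per-core relative risks against the most common haplotype and a
posterior probability of susceptibility (effect above the population
baseline); cores exceeding a 50% probability are called risk factors.

The package also contains the machinery around the model: an EM
estimator of haplotype frequencies from pedigrees, a PED-file reader and
writer, an ascertained family simulator (additive / dominant / recessive
penetrance), and a replicate-level evaluation harness (sensitivity,
specificity, accuracy, ROC/AUC).

## Worked example

```r
library(uchap)
set.seed(1)
fams <- sim_families(n = 200, mode = "additive", grr = 2.0)  # risk hap 11111211 @ 10%
fit <- uchap(fams, mcmc = mcmc_config(seed = 1))
summary(fit)
```

```
Posterior summary (reference core: 11111111 )

     core   freq   mean    sd    RR  P_RR P_susc  call
 11111111 0.4502 -4.704 0.163 1.000    NA     NA    NA
 12111111 0.3035 -4.642 0.165 1.074 0.667  0.384 FALSE
 11111211 0.1273 -4.408 0.190 1.378 0.932  0.862  TRUE
 21212121 0.0700 -4.650 0.197 1.077 0.613  0.390 FALSE
 21212122 0.0375 -4.589 0.200 1.149 0.718  0.510  TRUE

Gelman-Rubin PSRF: 1.002 1.002 1.000 1.000 1.001 
Effective sample sizes: 1470 1216 1769 1804 2166
```

Reading the table: seven haplotypes were identified by EM from the
genotypes and reduced to five cores; the generating risk haplotype
`11111211` shows a posterior relative risk of 1.38 versus the most
common haplotype (`RR`, shrunk toward the prior relative to the
generative relative risk of 2),
a 93% posterior probability that its relative risk exceeds 1 (`P_RR`),
and an 86% posterior probability that it raises risk above the 1%
population baseline (`P_susc`) — well past the 0.5 call threshold.
Convergence diagnostics (3 chains, 5000 burn-in, 10000 iterations
thinned by 10 → 3000 draws) are clean.

`run_fit()` performs the same analysis from a PED file and persists
every intermediate (EM frequencies, clustering matrix, design, draws,
summary) as text; `run_experiment()` loops simulate → fit → evaluate
over a (mode × relative-risk) grid.

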