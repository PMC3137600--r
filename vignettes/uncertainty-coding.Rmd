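---
title: "Haplotype risk from family genotypes: the uncertainty-coding model"
author: "uchap package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype risk from family genotypes: the uncertainty-coding model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uchap)
```

## The problem

Family-based association studies genotype nuclear families — parents, an
affected child, possibly further siblings — at a set of tightly linked
SNPs and ask whether any haplotype in the region raises disease risk.
Three nuisances stand between the genotypes and that question:

1. **Phase ambiguity.** Unphased genotypes are compatible with several
   haplotype configurations, especially when parental genotypes are
   partly missing.
2. **Transmission ambiguity.** The matched-pair design compares the
   affected child (carrying the two transmitted parental haplotypes)
   with a *pseudo-control* carrying the two non-transmitted ones; which
   haplotypes were transmitted is itself uncertain under phase
   ambiguity.
3. **Dimension.** A region can harbour many haplotypes, most of them
   rare, making a per-haplotype regression ill-conditioned and sparse.

`uchap` addresses all three at once.  Every family's compatible
*explanations* — quadruples of (paternal transmitted, maternal
transmitted, paternal non-transmitted, maternal non-transmitted)
haplotypes — are enumerated and weighted by the product of the four
founder-haplotype population frequencies, normalized within the family.
The case row of the design sums, over explanations, the expected count
of each haplotype among the transmitted pair; the pseudo-control row
does the same for the non-transmitted pair.  Each row totals exactly 2.
Rare haplotypes are then merged onto ancestral *core haplotypes* through
a row-stochastic clustering matrix $C$, giving the uncertainty-coded
design $Z = XC$ whose rows still total 2.

## The model

With $K$ cores and per-family difference rows
$d_i = z_{i,\text{case}} - z_{i,\text{control}}$, the conditional
logistic likelihood of the matched pairs is

$$\mathcal{L}(\beta) \;=\; \prod_{i}
  \frac{\exp(\beta^\top z_{i,\text{case}})}
       {\exp(\beta^\top z_{i,\text{case}}) + \exp(\beta^\top z_{i,\text{control}})}
  \;=\; \prod_i \bigl(1 + e^{-\beta^\top d_i}\bigr)^{-1}.$$

Because every $d_i$ sums to zero over cores, the likelihood is invariant
to adding a constant to all effects; identification of the overall level
comes from the prior

$$\beta \sim \mathrm{MVN}(\mu,\ \sigma^2 \Sigma), \qquad
  \sigma^2 \sim \mathrm{IG}(a, b),$$

with every component of $\mu$ the logit of the disease prevalence and
$\Sigma = I$ by default (independent priors; a compound-symmetry option
exists).  Sampling is adaptive Metropolis-within-Gibbs: random-walk
updates per effect component (step sizes adapted toward 44% acceptance
during burn-in) and the exact inverse-gamma Gibbs draw for $\sigma^2$.

Per core the fit reports the posterior mean and sd, the relative risk
versus the most common (reference) core, and two tail probabilities:

* `prob_rr` — the fraction of draws with $\beta_k > \beta_1$, i.e.
  $P(\mathrm{RR}_k > 1)$ against the reference core;
* `prob_susceptible` — the fraction of draws with
  $\beta_k > \operatorname{logit}(\text{prevalence})$, i.e. the
  probability that carrying the core raises risk above the population
  baseline.

Risk calls use `prob_susceptible > T` with $T = 0.5$ by default.  The
two probabilities answer different questions and behave very
differently: the likelihood pins only contrasts, so for a null core the
contrast posterior is centred near zero and `prob_rr` hovers around 0.5
regardless of how strong the true signal is elsewhere.
`prob_susceptible` additionally uses the level information supplied by
the prior: when a risk core absorbs effect mass, the remaining cores
settle slightly below the baseline, and their susceptibility
probabilities fall clearly under 0.5 as the signal grows.  That is the
behaviour a risk/non-risk classifier needs, so calls are made on the
baseline-relative probability; the reference-relative probability is
retained because it is the natural companion of the reported relative
risks.

## Tunable parameters

| argument | default | meaning |
|---|---|---|
| `theta` | 0.90 | fraction of the pool's Shannon information the cores must retain |
| `max_rare` | 0.05 | largest frequency an excluded (non-core) haplotype may have |
| `support_tol` | 1e-3 | smallest EM frequency at which a haplotype counts as identified |
| `prevalence` | 0.01 | disease prevalence; logit is the prior mean |
| `a`, `b` | 0.01, 0.01 | inverse-gamma shape/rate for $\sigma^2$ (weakly informative) |
| `chains`, `burnin`, `iter`, `thin` | 3, 5000, 10000, 10 | the standard protocol: 3000 retained draws |
| `threshold` | 0.5 | risk-call threshold on `prob_susceptible` |

The core-selection rule ranks haplotypes by decreasing frequency (rare
haplotypes are evolutionarily young; common ones ancient) and keeps the
smallest top set retaining at least `theta` of the total Shannon
information $\sum -p\log p$, provided everything excluded is rarer than
`max_rare`.  `theta = 0.90` was calibrated on two deterministic
benchmarks: the packaged 8-SNP/7-haplotype reference pool must reduce to
its five most frequent haplotypes (its top-4 information ratio is 0.846
and top-5 ratio 0.941, so any `theta` in (0.846, 0.941] works; 0.90 sits
centrally), and a 12-haplotype profile with four common and eight rare
haplotypes must also reduce to five cores.  Non-core haplotypes are
assigned to the cores at minimal Hamming distance (the mutation-count
"generation" measure) with probabilities proportional to core frequency
among those nearest cores; an equivalent iterated single-mutation
formulation exists, but both produce identical assignments on the
benchmark pools, so the direct rule is used.

## What the simulator emulates

`sim_families()` draws ascertained nuclear families: the affected index
child's haplotype pair is sampled with probability proportional to its
Hardy–Weinberg pair probability times the penetrance of its
risk-haplotype copy number; two further population draws complete the
parents; siblings arise by independent Mendelian transmission and are
affected with their own genotype's penetrance (not ascertained).  Family
size is 3 + Poisson(2) members.  Penetrances follow the conventional
genotype-relative-risk ladders — additive $f_1 = \gamma f_0$,
$f_2 = (2\gamma-1) f_0$; dominant $f_1 = f_2 = \gamma f_0$; recessive
$f_2 = \gamma f_0$ — with the baseline solved so the population
prevalence matches under Hardy–Weinberg weights.

The generator reproduces the statistical structure the method is built
for: phase ambiguity (double heterozygotes are common), ascertainment
enrichment of the transmitted pool, and a realistic frequency spectrum.
It does **not** emulate genotyping error, recombination or mutation
within the region, population stratification, or missing genotypes
(unless `missing_rate` is raised above its default 0).  Passing tests
therefore demonstrate correctness of the machinery and calibration under
clean Mendelian data, not robustness to those artefacts.

## Numerical choices

* Likelihood terms are computed as $-\log(1 + e^{-\beta^\top d})$ through
  `plogis(..., log.p = TRUE)`/`log1p`, stable on both tails.
* Haplotypes consistent with genotypes but absent from the working
  frequency table get pseudo-frequency $10^{-8}$ during enumeration so
  valid phase configurations are never annihilated; EM instead starts
  uniformly over every genotype-consistent haplotype observed.
* EM stops at $\max|\Delta p| < 10^{-6}$ (cap 500 iterations); its
  observed-data log-likelihood trace is checked non-decreasing at every
  step.  Only founders contribute haplotype counts in the M-step.
* A haplotype counts as "identified" when its EM frequency reaches
  `support_tol = 1e-3` — below the rarest reference-pool haplotype
  (0.56%) and above the one-founder-chromosome noise scale (~1/1600
  chromosomes at 200 families).
* Explanations are ordered lexicographically by the quadruple strings;
  exact frequency ties in core selection break lexicographically.
  Uninformative families ($d = 0$) are retained — each contributes a
  constant 1/2 factor — and counted.
* When a parent's direct phase expansion is infeasible (an untyped
  parent on many loci), candidate parental haplotypes are restricted to
  the frequency table's haplotypes plus those derivable from typed
  family members; orientation-ambiguous transmissions are enumerated in
  both orientations with equal prior weight.

## Worked example

The canonical two-locus family — father genotype (1/2, 1/2), mother
(−/−, 1/2) with the first locus missing, affected child (1/1, 1/1) —
has exactly two explanations, distinguished by the mother's hidden
first-locus genotype:

```{r}
fam <- hap_family("ex", father = c("12", "12"), mother = c("00", "12"),
                  children = list(c("11", "11")), affected = 1)
tab <- hap_freqs(c("11", "21", "12", "22"), c(0.42, 0.18, 0.30, 0.10))
enumerate_explanations(fam, tab)
```

With $p_1 = P(12)$ and $p_2 = P(22)$ the weights are
$p_1/(p_1+p_2) = 0.75$ and $p_2/(p_1+p_2) = 0.25$.  The case coding is
a certain 2 on haplotype 11; the pseudo-control coding spreads
$p_1/(p_1+p_2)$ onto (12) and $(p_1+2p_2)/(p_1+p_2)$ onto (22), and both
rows total 2:

```{r}
e <- enumerate_explanations(fam, tab)
case_coding(e)
pseudocontrol_coding(e)
```

## A small end-to-end fit

```{r, eval = FALSE}
set.seed(1)
fams <- sim_families(n = 200, mode = "additive", grr = 2.0)
fit <- uchap(fams, mcmc = mcmc_config(seed = 1))
summary(fit)
plot(fit)
```

On data like these the risk haplotype's core attains a posterior
susceptibility probability above 0.9 in essentially every replicate,
while null cores fall toward or below 0.5; pooled over replicates the
threshold sweep yields an AUC near 0.99 (see `run_experiment()` and
`scripts/acceptance.R`, which recompute these quantities from scratch).

## Design choices made where the design was open

* **One matched pair per family.**  The likelihood is written for one
  case/pseudo-control pair; additional affected siblings inform phasing
  only.  Multiplex families could in principle contribute several pairs,
  but the pairing rule for shared parental haplotypes is not well
  defined, so the first affected child is the designated case.
* **Risk acts on the exact generating haplotype** in the simulator, not
  on its core cluster; clustering is an analysis-side construct.
* **Susceptibility probability** is baseline-relative (see above); the
  reference-relative probability is reported alongside.
* **Scaled problem sizes.**  The replicate studies shipped in the tests
  and the acceptance script use 100 replicates of 200 families per
  setting with a single shortened chain (1000 burn-in + 2000 kept) per
  replicate — enough for stable pooled metrics while keeping a full run
  in minutes on one CPU.  The package default `mcmc_config()` keeps the
  full three-chain protocol for real analyses.

## Known limitations

* Biallelic SNPs only; allele codes are fixed 1 (common) / 2 (minor) by
  input convention, and panels are limited to 26 loci by the internal
  integer encoding.
* No recombination, mutation, or genotyping-error model in either the
  enumeration or the simulator.
* Families with both parents untyped on many loci are handled through a
  restricted candidate set (see above) and inherit its approximation.
* The entropy threshold `theta` stands in for an unpublished stopping
  rule; it is deterministic at realistic sample sizes, so the selected
  core count varies less across replicates than the original procedure
  appears to.
* Environmental covariates and gene–gene interaction terms are not
  implemented.
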