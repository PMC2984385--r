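---
title: "Fine-mapping a QTL in half-sib designs: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping a QTL in half-sib designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldlmap)
```

## The mapping problem

Livestock populations are typically organised in half-sib families: a few
sires, each mated to many unrelated dams, each dam contributing one
phenotyped progeny. With a dense SNP map and phased haplotypes, a
quantitative trait locus (QTL) segregating in such a population leaves two
signals: a *linkage* signal, carried by the co-segregation of sire
chromosome segments with phenotypes within families, and a *linkage
disequilibrium* (LD) signal, carried by the population-level association
between marker haplotypes and the causal allele, built up when the
favourable allele Q arose on one founder haplotype and eroded since by
recombination and drift.

`ldlmap` implements two scans over the marker intervals of a candidate
region, both assuming a bi-allelic QTL with a purely additive
substitution effect shared across families:

* **the haplotype-dose association scan** (`haplomax_scan()`): in each
  interval, for each observed flanking-marker haplotype $h$, fit
  $y_{ij} = s_i + \gamma\,d_{ij}(h) + e_{ij}$ where $s_i$ is a fixed sire
  effect and $d_{ij}(h) \in \{0, 1, 2\}$ counts the copies of $h$ among
  the progeny's two window haplotypes; the interval statistic is the
  largest 1-df F for $\gamma$ over haplotypes. This models LD as complete
  and constant: carrying the associated haplotype stands in for carrying
  Q.
* **the linkage + LD likelihood scan** (`ldl_scan()`): each progeny's
  phenotype is a Gaussian mixture over the sire's ordered QTL diplotype,
  the origin of the sire-transmitted allele, and the dam-transmitted
  allele,
  $$\Lambda_{ij}(x) = \sum_z \mathbb{P}(Z_i = z \mid h_i)\sum_a
  \mathbb{P}(Q^d_{ij} = a \mid h^d_{ij})\,
  \varphi\!\big(y_{ij};\, \mu_i + \alpha_{Sa},\, \sigma^2\big)\,
  w_{S}(z),$$
  where $w_S(z)$ weighs the two possible origins with exact
  flanking-marker transmission probabilities and
  $\alpha_{Qq} = \alpha_{qQ} = 0$, $\alpha_{qq} = -\alpha_{QQ}$ (additive
  model). The conditional probabilities of carrying Q given a window
  haplotype evolve over generations under a Wright–Fisher model, which is
  where the probabilistic LD modelling enters.

Both scans test interval midpoints and report the midpoint with the
largest statistic as the estimated QTL position $\hat{s}$; ties break to
the smallest interval index. The midpoint convention is the unique
symmetric choice when only the interval is identified.

## The LD model

Over a window of $m$ markers plus the tested locus, write
$\Pi_{A}(t)$ for the frequency of the haplotype carrying the alleles in a
locus set $A$ at generation $t$. Frequencies decompose into Bennett
multilocus disequilibria — the unique coefficients that decay
*geometrically*: a coefficient over locus block $S$ is multiplied each
generation by $\rho(S)$, the probability of no recombination across $S$
(`rho_no_recomb()`, a product of $(1 - c)$ over adjacent gaps with
Haldane recombination fractions $c$). Assuming the markers were at mutual
equilibrium when Q arose, the only partitions contributing to a
haplotype frequency are one distinguished block plus singletons, and all
their constant coefficients equal one; the general multi-block
coefficients needed when founder markers are themselves in LD are out of
scope and the code rejects nothing silently — they simply never arise
under the time-0 model below.

The time-0 state is the mutation model
$$\Pi_{h,Q}(0) = (1-\beta)\,\Pi_h \Pi_Q(0) + \beta\,\Pi_Q(0)\,
\delta_{h = h^*},$$
with $h^*$ the founder haplotype and $\beta$ the fraction of Q copies
that are new at time 0. The package exposes general $\beta$
(`ld_params()`), but the scans use $\beta = 1$ (no pre-existing copies),
the setting under which the simulator's complete-LD founders are
generated. The conditional probability used by the likelihood is
$$\mathbb{P}(Q \mid h, t) = \min\!\Big(1,\;
\frac{\mathbb{E}[\Pi_{Q,h}(t)]}{\mathbb{E}[\Pi_h(t)]}\Big),$$
with dams evaluated at $t + 1$ (their gametes are one generation
younger). Marker allele frequencies at time 0 are estimated from the
sampled haplotypes — drift is frequency-neutral in expectation, so the
time-$t$ sample is an unbiased (if noisy) stand-in; this is an
estimation approximation, stated here once. A window haplotype whose
expected frequency is zero (e.g. containing an allele absent from the
sample) falls back to the marginal $\Pi_Q(0)$ with a warning, keeping
the likelihood finite.

Windows are the 2 or 4 markers closest to the tested position, symmetric
and truncated at chromosome ends. Four-marker windows carry more LD
information and, in the replicated tables, locate the QTL better.

## Transmission probabilities

The probability that the allele a sire transmitted at $x$ descends from
each sire chromosome is computed exactly under no interference from the
nearest *informative* (sire-heterozygous) markers flanking $x$: given the
grand-parental origins at the left and right flank,
$p_1 \propto \Pr(\text{pattern})$ using the two sub-interval
recombination fractions. Only the two nearest informative flanks are
used; at the marker densities of interest (0.125–0.5 cM) double
crossovers between them are negligible. A sire homozygous everywhere
gives the uninformative $(1/2, 1/2)$.

## Maximisation strategy of the likelihood scan

At each midpoint the likelihood is maximised over the per-sire means,
$\alpha_{QQ}$, $\sigma^2$, the founder haplotype $h^*$ and
$\Pi_Q(0)$. Under the additive constraint the per-progeny likelihood
reduces to a three-component Gaussian mixture over the transmitted QTL
dose, so the continuous parameters are fitted by a monotone ECM
algorithm (compiled, `src/ldl_em.cpp`) from deterministic starts
($\alpha = 0, \pm 0.5\,\mathrm{sd}(y)$; the $\alpha = 0$ start
reproduces the null exactly, so the LRT is non-negative by
construction). $h^*$ is profiled over the window haplotypes observed in
the sample, and $\Pi_Q(0)$ — bounded above by the estimated frequency of
$h^*$, below by $10^{-4}$ — is profiled on a coarse grid
(`piQ0_grid`, fractions 0.08/0.25/0.5/0.85 of the bound) with the
winning point refined by a bounded golden-section search; later fits
warm-start from the previous $\hat\alpha$. EM convergence is declared at
`em_tol = 1e-6` on the log-likelihood (capped at `em_maxit`
iterations; grid prescreens use a quarter of that cap). All knobs are
arguments of `ldl_scan()`. We chose EM over bounded quasi-Newton on the
full 23-parameter vector because the mixture M-steps are closed-form and
monotone, which proved both faster and more robust. $\sigma^2$ is floored
at $10^{-6}$. The generations-since-mutation $t$ is an input, not an
estimate — known in simulations, and in practice an assumed breed age.

How $h^*$ and $\Pi_Q(0)$ should be handled is genuinely open (fixed,
profiled or integrated are all defensible); profiling is our choice, and
the null-calibration test bounds its cost: at a fixed position the null
LRT stays below the max-of-four-$\chi^2_2$ envelope.

## The simulator

`simulate_replicate()` produces study designs by gene dropping. Founders
are $N_e$ diploids whose marker alleles are i.i.d. Bernoulli(0.5) —
maximally informative markers at linkage equilibrium; the founder
frequencies are not dictated by the population model, and 0.5 is the
symmetric choice. In `complete_LD` mode the favourable allele Q is
placed on exactly one founder haplotype ($\Pi_Q(0) = 1/(2N_e)$); in
`equilibrium` mode the QTL is drawn like one more independent marker.
Each generation, $2 N_e$ gametes are formed from uniformly drawn parents
(Wright–Fisher), with Haldane crossovers and optional per-meiosis marker
mutation (the QTL never mutates after time 0). Phenotypic truncation
selection, when enabled, retains the top `selection_fraction` of
individuals by a dose-model phenotype each historical generation.

A design draws `Ns` sires without replacement; each progeny receives a
recombined paternal gamete and a maternal gamete from a dam drawn (with
replacement) among the non-sire individuals — a small evolved population
cannot supply thousands of distinct dams, and only the transmitted
maternal haplotype enters any method, so dam identity never matters.
Replicates with no QTL-heterozygous sire (including all replicates that
lost Q to drift) are discarded and redrawn inside the replicate's own
random stream; a seed therefore identifies an accepted design
deterministically. Phenotypes follow
$y_{ij} = a \cdot \#\{Q\text{ alleles}\} + e_{ij}$,
$e_{ij} \sim N(0, \sigma^2)$.

What the generator does *not* emulate: genotyping and phasing errors
(haplotypes are known exactly), multi-allelic markers, dam pedigree
structure, bottlenecks or growth, and any non-additive QTL action.
Passing tests therefore demonstrate correctness of the methods under the
idealised breeding-population model, not robustness to real-data
artefacts — with one deliberate exception, the marker-mutation switch.

## Evaluation harness

`run_replicates()` / `run_table()` orchestrate replicates (per-replicate
seeds derive from a master seed via a counter splitter, `split_seed()`),
reporting the root mean squared error
$\sqrt{\sum_r (\hat{s}_r - s)^2 / R}$ of the estimated position with a
delta-method Monte-Carlo standard error. Significance uses permutation:
phenotypes are permuted *within* sire families — preserving family means,
hence the sire nuisance structure, under the no-QTL null — and the 5%
threshold is the empirical 95% quantile of the permuted maximum
statistic (default 1000 permutations; 200 are used in the replicated
power studies). `power_estimate()` is the fraction of replicates whose
observed maximum exceeds their own threshold, and
`compare_methods_ttest()` compares two methods' paired squared position
errors. The mean absolute error is deliberately not a reported surface
(it tracks the root-MSE essentially linearly).

## Problem sizes used in the shipped tests

The replicated studies use reduced problem sizes (the original tables
were built from 500 replicates): the test-suite runs 100 replicates per
scenario for the association scan, 50 for the likelihood scan and 200
permutations per replicate; `scripts/acceptance.R` runs 150 replicates
with 1000 permutations. Agreement is judged within three Monte-Carlo
standard errors of the reduced runs, which is the honest resolution of a
study this size. Property tests run at tolerances 1e-10 to 1e-12 against
enumeration or closed-form oracles.

## Known limitations

* The likelihood approximation evaluates the likelihood at expected
  haplotype frequencies rather than integrating over their distribution;
  at small $N_e$ and large $t$ the neglected variance grows.
* Estimated marker frequencies stand in for time-0 frequencies (see
  above).
* Transmission uses the two nearest informative flanks only.
* $t$ must be supplied; mis-specifying it distorts the LD decay but, in
  our replicated runs, moves the argmax little.
* Both methods assume a single shared QTL effect; family-specific
  effects and dominance are out of scope.
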