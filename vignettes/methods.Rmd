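---
title: "Methods: simulating reciprocal recurrent genomic selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating reciprocal recurrent genomic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrgsim)
```

# Scope

`rrgsim` is a forward-in-time stochastic simulator of **reciprocal recurrent
genomic selection (RRGS)** in hybrid breeding between two heterotic pools. Its
purpose is to compare two ways of training the genomic prediction model:

* **HS (half-sib) training**: each pool's candidates are evaluated as
  testcrosses to a single inbred tester from the opposite pool, and a
  one-kernel GBLUP of testcross performance is fitted per pool.
* **FS (full-sib) training**: hybrids from a sparse factorial between the two
  pools are evaluated, and a two-kernel GBLUP separates female and male
  general combining ability (GCA), optionally with a specific combining
  ability (SCA) kernel.

The simulator tracks cumulative genetic gain of the inter-pool factorial,
GCA/SCA variance dynamics, genic (linkage-equilibrium) variances and their
ratio to the realized variances (the Bulmer effect), GBLUP accuracy for true
GCA, and modified Rogers' distances between pools.

# Genetic model

## Genomes, maps and meiosis

Individuals are fully phased diploids over biallelic markers on a genetic
map. Meiosis follows the **Haldane model**: crossover counts per chromosome
are Poisson with mean equal to the map length in Morgans, crossover positions
are uniform, and there is no interference. The recombination fraction between
two loci at distance $d$ Morgans is therefore $r = \tfrac12(1 - e^{-2d})$.
The gamete engine is implemented in C++ but uses R's RNG, so all results are
reproducible from `set.seed()`. Doubled haploids (DH) are produced by drawing
one gamete and doubling it. `maize_like_map()` (10 chromosomes, 1442 cM) and
`wheat_like_map()` (21 chromosomes, 3009 cM) provide realistic map skeletons;
`even_map()` builds toy maps.

## Synthetic founders

Because the package must run self-contained, founder pools are generated by
neutral simulation rather than read from real data: a small ancestral
population (effective size `effective_size`, default 25) is random-mated with
recombination for `burnin_generations` (default 60) to build up linkage
disequilibrium, then split into two pools that drift apart for
`divergence_generations` (default 30), after which inbred founders are drawn
and markers are filtered to those polymorphic in **both** pools. The small
ancestral size and long burn-in are deliberate: they produce the strong
marker–QTL LD typical of elite breeding germplasm, which is what gives GBLUP
a realistic starting accuracy (about 0.4–0.6 at the scales below) and the
pools a modified Rogers' distance near 0.4. These generator settings were
calibrated once, before any acceptance experiment, and are not tuned per
experiment.

## Trait architecture

A quantitative trait is controlled by `n_q` QTL sampled from a candidate
panel, with per-pool proportional quotas across chromosomes (largest-remainder
rounding). Additive effects are Gamma-distributed with random sign; a subset
of loci carries dominance (for the default "high-tau" preset, dominance
creates an SCA share $\tau \approx 15\text{–}25\%$ of the hybrid variance at
the start; the "additive" preset sets all dominance to zero). Effects are
rescaled once so the initial inter-pool factorial has unit broad-sense
genotypic variance $\sigma^2_G = 1$; the error variance is then fixed forever
at $\sigma^2_e = \sigma^2_G (1 - h^2)/h^2$ (with $h^2 = 0.4$, $\sigma^2_e =
1.5$). The prediction marker panel is disjoint from the QTL panel, so
accuracy is limited by LD, not by markers sitting on causal loci.

## Factorial decomposition and genic variances

For two sets of homozygous lines, the value of every hybrid is
$g_{ij} = \mu + \mathrm{gca}_i + \mathrm{gca}_j + \mathrm{sca}_{ij}$, the
exact two-way ANOVA decomposition of the full factorial
(`factorial_decomposition()`; verified against brute-force enumeration).
The **genic** variances are the same quantities under linkage equilibrium,
computed from allele frequencies $p$ (female pool) and $q$ (male pool):

$$\sigma^2_{gca,F} = \sum_k p_k(1-p_k)\,[a_k - (2q_k - 1) d_k]^2, \qquad
  \sigma^2_{sca} = \sum_k 4\,p_k(1-p_k)\,q_k(1-q_k)\,d_k^2,$$

and symmetrically for the male pool. The ratio of realized to genic GCA
variance isolates the LD component of the variance; directional selection
builds negative LD and pushes the ratio below 1 (Bulmer effect).

Two closed-form results are also exposed. The genetic correlation between
testcross performance with a tester of inbreeding-derived coefficient
$\varphi$ and true GCA is

$$r_g(\mathrm{TC}, \mathrm{gca}) =
  \sqrt{\frac{1-\tau}{1 + \tau(2\varphi - 1)}},$$

(`analytic_rg_tc_gca()`; 0.62 at $\tau = 0.45$, $\varphi = 1$), so the upper
bound on GBLUP accuracy for GCA under HS training is $r_{gca} = r_{TC}\cdot
r_g$ (`rgca_tc()`). The expected per-cycle loss of GCA variance from drift at
effective size $N_e$ over $g$ generations is $100\,[1 - (1 -
1/(2N_e))^g]\%$ (`expected_drift_loss()`; about 10% for $N_e = 20$, $g = 4$).

# The RRGS scheme

Each cycle $t$ consists of a training step at stage $C_{t,0}$ followed by
four rapid selection sub-cycles ($s = 1, \dots, 4$):

1. **$C_{t,0}$ (DH stage, 950 candidates per pool).** Training data are
   generated and the GBLUP model is fitted.
   * *HS*: per pool, 190 candidates are testcrossed to the opposite pool's
     tester (the tester is the best predicted DH of the opposite pool from
     the previous cycle; in cycle 1 it is the phenotypic best of a random
     100). Model: $y = \mathbf{1}\mu + u + e$, $u \sim N(0, \sigma^2_{TC}
     G)$.
   * *FS*: 380 hybrids from a sparse factorial (each parent used in two
     crosses) are phenotyped once. Model: $y = \mathbf{1}\mu + g_F + g_M
     [+ s_{FM}] + e$ with pool-specific genomic kernels; the SCA kernel is
     the elementwise product $G_F \circ G_M$ (off by default).
2. The top 40 DH per pool are selected on GBLUP, paired at random into 20
   single crosses, and a half-diallel among the 20 yields
   $\binom{20}{2} = 190$ matings $\times$ 5 progeny $= 950$ S0 candidates.
3. **$s = 1,2,3$**: the model predicts the new S0 candidates (no
   re-phenotyping), the top 20 S0 are selected, and a new half-diallel is
   made — selection on prediction alone, so accuracy erodes with
   recombination each sub-cycle.
4. **$s = 4$**: one DH is produced per selected S0, forming $C_{t+1,0}$.

Variance components are re-estimated by REML each cycle. Genomic
relationship matrices use origin-specific allele frequencies with
$(x - 2p)$ centring, so DH have diagonal values near 2.

## REML and GBLUP

Variance components are estimated by average-information REML with
step-halving and an EM fallback, guaranteeing a monotone restricted
log-likelihood; components are constrained non-negative. GBLUPs are the
exact solutions of the mixed-model equations, computed as $\hat u =
\hat\sigma^2_u G V^{-1}(y - \mathbf{1}\hat\mu_{GLS})$. When a variance
component is estimated at the zero boundary the *predictions* are computed
at a vanishing ridge ($10^{-8}\,\mathrm{var}(y)$) instead of collapsing to
exactly zero: this preserves the limiting ranking $\lim_{\sigma^2\to 0^+}
\hat u \propto G V^{-1}(y - \mathbf 1\hat\mu)$ so selection never falls back
to arbitrary index order, while the reported variance estimates are left at
the boundary. `lme4` is used in the test suite only as an independent oracle.

## Founder usage constraints

When sampling the base S0 population from the founders, each founder may
serve as the seed parent of at most `gamete_cap` matings *and* as the pollen
parent of at most `gamete_cap` matings (a per-parental-role cap). A design is
feasible when `n_matings <= n_founders * gamete_cap`; selfing is never
allowed.

# Default experiment scales

`rrgs_config()` carries the full-scale defaults. Two reduced presets are
provided as this package's own choices for fast, reproducible experiments:

* `smoke_config()` — minutes-scale end-to-end checks.
* `desk_config()` — 3 cycles, 950 candidates per pool, 6000 raw markers
  (roughly 1400–2200 survive the joint polymorphism filter), 600 QTL
  candidates, 200 QTL, $h^2 = 0.4$. A 20-replicate paired HS/FS comparison
  runs in about 2.5 minutes per preset on one CPU.

Replicates are paired: both methods start from the identical base
population, trait and seed stream, so method differences can be tested on
within-replicate differences.

```{r example, eval = FALSE}
sim <- run_rrgs(desk_config(), methods = c("HS", "FS"),
                replicates = 20, seed = 1)
aggregate_cycle_log(sim)   # means and sds per (method, t, s)
compare_methods(sim)       # paired FS - HS differences with s.e.
```

# Behaviour at desk scale, and known limitations

With the defaults above the simulator reproduces the qualitative dynamics
expected of RRGS: prediction accuracy for true GCA drops sharply (about
55–65% relative) from the training stage $C_{t,0}$ to the first unphenotyped
sub-cycle; for a high-SCA trait, FS training yields more cumulative gain
than HS training; $\tau$ declines over cycles as dominance-contrasted loci
fix; and the realized:genic GCA variance ratio is depressed during selection.

Two quantitative signatures of the full-scale system are *not* reproduced at
desk scale, and deliberately so (the generator was calibrated once and not
re-tuned toward outcomes):

* **Additive traits**: HS training is not better than FS training here. Each
  pool's HS model sees 190 testcross records while the FS model extracts
  GCA information for both pools jointly from 380 hybrid records; for an
  additive trait (no SCA noise in hybrid records) the doubled training size
  dominates at 3 cycles and desk-scale accuracy. The small HS advantage
  reported for additive traits at full scale (10 cycles, higher accuracy)
  is inside this simulator's noise at desk scale.
* **Bulmer ratio below 1 in nearly all replicates**: with 200 QTL the
  LD component of the GCA variance is noisy per replicate (sd of the
  realized:genic ratio about 0.08–0.09 around a mean of 0.92–1.00 at
  $C_{3,0}$), so the depression is visible in the mean but not in ≥90% of
  individual replicates. More QTL and more cycles sharpen it.

Both points, and every other modelling decision with room for
interpretation, are documented in the package's development notes.
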