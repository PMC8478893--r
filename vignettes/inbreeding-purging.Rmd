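---
title: "Predicting and simulating the long-term exhaustion of the inbreeding load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and simulating the long-term exhaustion of the inbreeding load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(purgeload)
```

## The scientific problem

Inbreeding depression is driven by the *inbreeding load*: partially
recessive deleterious alleles concealed in heterozygotes, expressed when
inbreeding makes them homozygous. Natural selection acting on those newly
exposed homozygotes — *genetic purging* — removes them, so the load
observed after many generations of slow inbreeding falls faster than
genetic drift alone would predict. `purgeload` implements the three
computational layers needed to analyse long-term slow-inbreeding
experiments of this kind (the motivating system is a pair of decade-long
*Drosophila melanogaster* experiments, with large base populations of
effective size about 1000–1400 and derived lines of effective size about
43–52 assayed for pupae productivity):

1. closed-form **inbreeding–purging (IP) predictions** of fitness and load
   trajectories, plus least-squares estimation of the purging coefficient;
2. the **lethal-equivalents estimator** of the load from paired
   noninbred/inbred productivity assays, with bootstrap inference;
3. an **individual-based forward simulator** with explicit
   deleterious-mutation genomes drawn from a distribution of fitness
   effects (DFE) and started at the deterministic mutation–selection
   balance.

A synthetic-data generator reproduces the paired assay design with known
truth so every estimation stage can be validated end to end.

## The IP model

Under constant effective size $N_e$, Wright's inbreeding coefficient is
$F_t = 1 - (1 - \tfrac{1}{2N_e})^t$. Purging is summarised by a single
*purging coefficient* $d$; for one locus $d = s(\tfrac12 - h)$, the part
of the homozygous effect $s$ hidden from selection in heterozygotes
(dominance $h$). The *purged inbreeding coefficient* $g$ discounts the
identity by descent whose deleterious content purging has already removed:

$$g_t = \left[\frac{1}{2N_e} + \Big(1 - \frac{1}{2N_e}\Big) g_{t-1}\right]
        (1 - 2 d F_{t-1}), \qquad g_0 = 0.$$

The initial value $g_0 = 0$ is chosen to match $F_0 = 0$; it makes
$g_1 = \tfrac{1}{2N_e} = F_1$ and collapses $g_t$ to $F_t$ exactly when
$d = 0$, which is the behaviour the theory requires. Expected mean
productivity and expected remaining load are then

$$E[P_t] = P_0\, e^{-\delta_0 g_t}, \qquad
  E[\delta_t] = \delta_0\, g_t (1 - F_t) / F_t,$$

with the *neutral* (drift-only) special case obtained at $d = 0$, i.e.
$E[P_t] = P_0 e^{-\delta_0 F_t}$ and $E[\delta_t] = \delta_0 (1 - F_t)$.
At $t = 0$ the load expression is defined by its limit
$g_t / F_t \to 1$, returning $\delta_0$. As $t \to \infty$, $g$
approaches $a(1-2d)/(1 - (1-a)(1-2d))$ with $a = 1/(2N_e)$ — the
fraction of ancestral load that escapes purging — which the test suite
verifies against long recursions.

```{r ip-example}
line <- ip_params(ne = 43, d = 0.3, delta0 = 1.402)
tr <- ip_trajectory(line, 153)
round(tail(tr, 3), 5)
predict_inbreeding_load(line, tr, model = "purging")[154]
```

The purging coefficient is estimated from an observed load series by
minimising the sum of squared deviations from the purging-model
prediction. The sum of squares can be locally flat, so the estimator
scans a dense grid over the admissible range $[0, 0.5]$ (step 0.001,
ties broken toward smaller $d$, i.e. toward the weaker-purging
interpretation) and then refines the best cell with golden-section
optimisation. A residual bootstrap supplies a percentile confidence
interval.

## Estimating the load from productivity assays

The load in lethal equivalents is estimated as
$\delta = \ln(P_O / P_I) / F$, where $P_O$ and $P_I$ are mean pupae
productivities of the noninbred and inbred schemes and $F$ averages the
inbreeding coefficients of the inbred parents and their progeny
(productivity depends on both generations: mating success and fecundity on
the parents, survival to pupation on the offspring). In the standard
full-sib design the parents carry $F = 0.25$ and the progeny $F = 0.375$,
so $\bar F = 0.3125$.

Inference resamples *pairs* with replacement, independently within each
scheme (the design pairs nothing across schemes), recomputing $\delta$
per replicate; the standard error is the bootstrap standard deviation and
the reported one-sided $p$ is the fraction of replicate loads at or below
zero. Replicates that resample to a zero scheme mean (possible only when
zero counts are present) are redrawn so the replicate count stays fixed.
Two conventions deserve note, since the choice of tail is not dictated by
the estimator itself:

* `compare_loads()` pairs two replicate series by index and reports the
  fraction of differences at or below zero, with the larger point
  estimate first — a one-sided test of equality.
* `test_against_prediction()` reports the fraction of replicates at or
  beyond a theoretical prediction on the side *opposite* the observed
  deviation.

Both conventions reproduce the magnitudes of the published significance
statements under a normal cross-check (see the test suite), but they are
conventions, and other sidedness choices would change the printed
$p$ values.

```{r delta-example}
delta_from_means(86.91, 70.30, mean_inbreeding_coefficient(0.25, 0.25))
```

## Deleterious-mutation genomes at mutation–selection balance

The simulator's genomes hold $L = 9000$ diploid positions by default.
Under the main family, homozygous effects are
$s \sim \Gamma(\beta = 0.2, \bar s)$ with draws above 1 redefined as
$s = 1$ — a lethal class that makes the effect distribution bimodal for
large $\bar s$ — and dominance is $h \mid s \sim U(0, e^{-ks})$, with $k$
solved so that the mean dominance over the truncated effect distribution
equals $\bar h$ (quadrature over the continuous part plus the point mass
at 1; the truncation is applied before dominance assignment, so lethals
receive the same $U(0, e^{-k})$ rule). A piecewise alternative fixes
$\bar s = 0.0161$, $\beta = 0.186$, and $h = 0.25$ for $s < 0.02$, else
$h = 0$ (a genomic-inference DFE without a lethal class).

Each selected locus is started at the deterministic equilibrium of the
recurrence

$$p' = \frac{[\,p^2 + p q (1 - s h)\,](1 - u)}{1 - 2 p q s h - q^2 s},$$

with one-way mutation at $u = U/L$. Rather than iterating this map — whose
contraction rate is $1 - O(s + u)$ and therefore arbitrarily slow for the
many tiny-effect loci a shape-0.2 gamma produces — the package solves its
fixed point exactly: eliminating $p = 1 - q$ reduces the equilibrium
condition to the quadratic

$$s(2h - 1)\,q^2 - s h (1 + u)\, q + u = 0,$$

whose numerically stable small root is the classical equilibrium
($q \to \sqrt{u/s}$ for $h = 0$, $q \to u/(sh)$ when $sh \gg u$). When no
interior root exists in $(0,1)$ — selection weaker than mutation
pressure — the map's only stable fixed point is fixation and $\hat q = 1$
is returned (such loci carry zero inbreeding load, since $pq = 0$). Every
returned interior frequency satisfies the recurrence to $10^{-10}$, which
the tests check by direct substitution.

The locus load is the Morton decomposition $\delta = s(1 - 2h)pq$, summed
over loci. `calibrate_mutation_rate()` adjusts $U$ (holding the $(s,h)$
draw fixed, so the reported $U$ is conditional on the genome realisation;
seed-to-seed spread is of order 2% for the default models) until the
equilibrium genome carries a target load — the mechanism by which
simulated populations are matched to the load inferred in real
populations, and the computation behind the published rates
$U \approx 0.16$ for the piecewise model and $U$ of order $0.01$–$0.02$
for the large-effect gamma models at a target of two lethal equivalents.

## The forward simulator

Populations are dioecious with a fixed one-to-one sex ratio, stored as
unphased per-locus dosages (phase is irrelevant under free recombination
and multiplicative fitness, so nothing is lost relative to haplotype
storage). Genotype fitness is multiplicative across loci with values
$1$, $1 - sh$, $1 - s$. Each generation, every one of the $N$ offspring
(exactly $N/2$ per sex) draws a mother and a father independently, with
replacement, with probability proportional to fitness within their sex —
polygamous mating, no selfing by construction. Each parent transmits one
allele per locus by a fair Mendelian draw, and each transmitted wild-type
allele mutates with probability $u$ (implemented exactly as a binomial
number of mutations placed uniformly among the transmitted wild-type
copies). A replicate in which one sex loses all fitness is reported as
extinct and excluded from the averages.

`run_experiment()` reproduces the design of the motivating experiments:
a large natural population founded once at Hardy–Weinberg proportions
from the equilibrium frequencies; per replicate, a base population
sampled from it and maintained for `t_split` generations; a line sampled
uniformly from the base at the split and both maintained synchronously
thereafter, tracking mean fitness and standing load per generation,
averaged over replicates.

Numerical conventions worth stating: sizes must be even (the strict
one-to-one sex ratio cannot hold at odd $N$; the experimental lines'
estimated $N_e = 43$ is represented as $N = 44$ in the analysis scripts);
parents are sampled within sex because the mating system is dioecious and
polygamous; loci are unlinked; the same seed reproduces a run
bit-for-bit.

## What the synthetic assay generator does and does not emulate

Synthetic pair counts are negative binomial: Poisson offspring counts
mixed with gamma-distributed heterogeneity across pairs. The default
size parameter 20 reproduces the coefficient of variation of about 0.25
implied by the published productivity means and standard errors (e.g. a
mean of 86.9 with standard error 2.12 over 108 pairs implies a standard
deviation near 22, far above Poisson). Inbreeding acts on the mean
exactly as the estimator assumes, through $e^{-\delta \bar F}$, which
makes recovery tests well-posed: passing them shows the estimation
pipeline is correct, not that real counts are negative binomial. The
generator does not model vial-level environmental trends across calendar
time (visible in the real data as parallel productivity drops in base and
lines), competitive versus noncompetitive assay environments, or
between-bottle structure.

## Problem sizes used by the tests and analysis scripts

The packaged analyses run at sizes chosen to keep every stage
interactive while leaving the conclusions unchanged:

* DFE/equilibrium computations run at the full $L = 9000$ (the solver is
  closed-form, so this is cheap), averaging over 10 genome draws where a
  share is reported.
* The drift-only simulator oracle uses a line of $N = 40$ with $L = 500$
  loci, 150 generations and 50 replicates, checked against
  $\delta_0(1 - F_t)$ at six checkpoints within three across-replicate
  standard errors.
* The model-comparison simulations use the real sizes and generations
  (base $N = 1376$, 234 generations; line $N = 44$ from generation 83)
  but a genome scaled down to $L = 600$ positions carrying the full
  initial load of two lethal equivalents. That scaling inflates the
  per-locus mutation rate by the factor $9000/600$, so these runs zero
  the mutation rate after founding and track the standing load only — at
  full scale, new-mutation input is negligible over the experimental
  timescale, and carrying the inflated input would be a scaling
  artifact, not biology. Full-scale runs ($L = 9000$, 100 replicates,
  mutation on) are available through the same interface and differ only
  in the arguments.

## Known limitations

* The IP predictions ignore non-purging selection and new mutation; they
  are long-term approximations whose accuracy degrades if new load
  builds up appreciably.
* The bootstrap sidedness conventions above are choices; the package
  documents them rather than claiming uniqueness.
* The purged-inbreeding recursion treats $d$ as a single effective
  parameter; multilocus genomes with variable effects have no single
  exact $d$, which is why the simulator exists.
* The equilibrium construction assumes linkage equilibrium and unlinked
  loci; tightly linked deleterious clusters would purge differently.
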