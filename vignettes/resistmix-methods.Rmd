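---
title: "The resistmix model: two-locus resistance genetics and deployment strategy choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The resistmix model: two-locus resistance genetics and deployment strategy choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistmix)
```

## The problem

Public-health vector control leans on a small number of insecticide
classes, and resistance in malaria vectors threatens all of them. When two
insecticides are available, programme managers must choose between
deploying them one after the other (sequential use, switching when
resistance to the current compound becomes widespread), together as a
mixture, or as an *adaptive* mixture in which the failed component is
withdrawn once resistance to it is established. `resistmix` implements a
deterministic population-genetic model to compare these policies and a
global sensitivity analysis to map which operational circumstances favour
each.

## The genetic model

Resistance to each insecticide is encoded by one biallelic locus (alleles
S and R) in a diploid, randomly mating population with discrete
non-overlapping generations. Ten two-locus genotypes are tracked per sex:
the nine combinations of {SS, RS, RR} at each locus, with the double
heterozygote split into its coupling (RR/SS chromosomes) and repulsion
(RS/SR) phases. The phases share a fitness but produce different gametes
when the loci are linked, which is what lets linkage disequilibrium (LD)
interact with recombination.

### Niches and fitness

Each generation a mosquito encounters one of nine exposure *niches*: each
insecticide absent, present at low, or present at high concentration. A
per-sex exposure vector $\alpha$ over the niches describes deployment;
differential male exposure (males do not enter houses to feed) is a
first-class feature.

Single-locus fitnesses in a niche derive from four parameters per
insecticide:

| parameter | meaning | default/range |
|---|---|---|
| effectiveness $\varphi$ | proportion of SS killed on contact | sampled 0.3–1 |
| dominance $h$ | heterozygote position between SS and RR under exposure | 0–1 |
| restoration | fraction of the insecticide-induced loss recovered by RR; selection coefficient $s = \text{restoration}\times\varphi$ | 0.2–1 |
| cost $z$ (+ its dominance) | fitness cost of resistance without insecticide | 0 unless configured |

With the insecticide present at level $c$: $w_{SS} = 1-\varphi_c$,
$w_{RS} = w_{SS} + h_c s_c$, $w_{RR} = w_{SS} + s_c$; in its absence
$w = 1$, $1 - h_\text{cost} z$, $1 - z$. Deriving $s$ from the restoration
coefficient guarantees $w_{RR} \le 1$; any calibration that still escapes
$[0,1]$ raises an error naming the offending cell rather than being
silently clamped, so mis-calibrations are loud.

Two-locus fitness in a niche is the *product* of the single-locus
fitnesses (independent killing), optionally scaled by an interaction
factor $\Lambda$ in the four dual-insecticide niches ($\Lambda<1$ synergy,
$\Lambda>1$ antagonism or cross-resistance; default 1). Marginal fitness
per sex is the exposure-weighted niche average; it is
frequency-independent and computed once per deployment phase.

### One generation

A generation is: selection on the ten genotypes (per sex), Mendelian
gamete production into the four haplotypes with recombination rate $r$
(coupling parents emit parental SS/RR haplotypes at $(1-r)/2$ each,
recombinant SR/RS at $r/2$; repulsion parents the reverse), normalisation
of each sex's gamete pool, and random union of female and male gametes.
Double heterozygotes formed from (SS, RR) gamete pairs are coupling, from
(SR, RS) pairs repulsion. Allele frequencies reported against thresholds
are sex-averaged (both sexes contribute equal gamete numbers); LD is the
Curtis metric $D = f_{RR} - f_{R_1} f_{R_2}$ on gametes, averaged over the
sexes. Mean population fitness is the female genotype-frequency-weighted
marginal fitness, a proxy for relative egg lay.

The default $r = 0.5$ treats the loci as unlinked — the headline analyses
all assume resistance mechanisms on different chromosomes — and linkage is
an explicit user option. There is no mutation: allele frequencies change
only through selection and recombination, so results condition on
resistance already being present at the starting frequencies.

## Deployment strategies

All strategies compare times measured in generations until the sex-averaged
R frequency *strictly* exceeds a threshold (default 50%, following the
conventional resistance-management criterion; equality does not trigger).

* **Solo/sequential** — one insecticide until its allele crosses at $t_1$.
  Because policy operates in one-generation timesteps, the switch triggers
  the generation *after* the crossing: the exhausted compound runs one
  further generation, then the second compound is deployed until its own
  crossing $t_2$ generations later; the sequence lasts $t_1 + 1 + t_2$.
  This is the unique convention that reproduces the published sequential
  totals of the idealised comparison grid. The full genotype state,
  including accrued LD, carries across the switch.
* **Mixture** — both compounds together; the lifetime is the generation at
  which the *second* allele crosses. The `correct_mix_deploy` parameter
  models imperfect operations: a fraction of the exposed population
  receives only one component (split equally between the two singles).
* **Adaptive mixture** — the mixture until the first allele crosses, then
  the surviving compound alone. The remaining time is computed as a solo
  run started from a fresh Hardy–Weinberg/linkage-equilibrium population
  at the allele frequencies observed at the switch. Deviations from
  equilibrium accrued under the mixture are deliberately discarded: they
  decay within a few generations of the mixture being withdrawn, and the
  approximation keeps the adaptive time derivable from the other two
  runs. (We also evaluated reading the remainder off the sequential run's
  solo trajectory; it shortens adaptive times by about half a generation
  on average and changes batch-level shares by about one percentage
  point.)

Scheduled deployments (`run_schedule()`) support interruptions — e.g.
relaxed selection between generations 4 and 12 of the classical
single-insecticide scenario — with state carried across span boundaries.

## The idealised calibration

The package ships a `curtis_idealised` fixture: effectiveness 1, dominance
1, restoration 1, no costs, equal sexes, exposure 0.9, unlinked loci.
Exposure is not printed in the historical sources; 0.9 is fixed here
because it exactly reproduces the classical one-generation updates (solo:
0.1% to 0.98%; mixture from (1%, 0.1%): rarer allele to 0.118%) and the
solo crossing times 3/4/5 from starts $10^{-2}, 10^{-3}, 10^{-4}$, and it
matches the escape-probability convention (0.1) of the 1980s two-locus
literature.

Two known discrepancies with the historical sources are documented rather
than forced:

* The idealised mixture's *higher*-frequency allele moves from 1% to
  ≈1.018% in one generation under the multiplicative nine-niche model; the
  historical table prints 1.108%. The 0.118% figure for the rarer allele
  is reproduced exactly.
* Multi-generation mixture crossings run ≈0.6 generations faster here than
  the historical multi-generation tables. Our recursion was verified
  generation-by-generation against an independent haplotype-pair
  implementation, reproduces every printed one-generation quantity, every
  sequential total, and the solo column exactly; no single threshold or
  counting convention reconciles the historical mixture column with its
  own solo column, and that source's mixture columns are internally
  inconsistent in two cells. From starts (0.01, 0.001) both alleles exceed
  50% by generation 8 under both strategies: the sequence at exactly
  $3+1+4 = 8$, the mixture at generation 7.

## Sensitivity analysis

`sample_parameter_sets()` draws each variable independently: log-uniform
starting frequencies ($10^{-4}$–$10^{-1}$, so rare alleles — where
heterozygotes dominate and dominance matters — are well covered), uniform
exposure 0.1–0.9, male exposure proportion 0–1, effectiveness 0.3–1,
dominance 0–1, restoration 0.2–1, correct mixture deployment 0.5–1; costs
are zero so their dominance is immaterial. Independent sampling (not Latin
hypercube) is used deliberately, with a required seed. Each set is run
under sequential (insecticide 1 first — the sampled parameters are
exchangeable, so this cannot bias aggregate shares), mixture, and derived
adaptive deployment, capped at 500 generations (~40 years at 12
generations per year: beyond any realistic planning horizon). Runs where
neither strategy reaches the threshold are excluded from comparisons as
operationally equivalent.

Analysis machinery:

* **PRCC** — rank-transform all columns; partial out the other inputs from
  both the input and the outcome by linear regression on ranks; correlate
  the residuals. Implemented directly and verified against an
  inverse-correlation-matrix oracle. No significance levels are computed,
  only coefficients.
* **Strategy labels** — a run favours the mixture when its mixture-type
  time strictly exceeds $(1+\text{margin})$ times the sequential time
  (margins 0 and 0.2; ties favour sequential). The *adaptive* time is the
  default comparison: empirically it is the convention under which the
  batch shares and the decision plane reproduce the published headline
  figures, and it is the operationally realistic mixture policy. The plain
  mixture comparison is available via `mixture_time = "mixture"`.
* **Decision line** — boundary runs are those with exactly equal integer
  times (margin 0) or a 19–21% relative advantage (margin 0.2); ordinary
  least squares of summed effectiveness on exposure over the boundary set
  gives a rule "prefer the mixture when summed effectiveness exceeds
  $\hat D = a + b\,\times$ exposure", scored by its true-positive and
  true-negative rates against the simulated labels.
* **Classification tree** — recursive partitioning (rpart) on the sampled
  variables plus the two starting-frequency ratios; pruned to the smallest
  size whose resubstitution error plus cross-validation standard error is
  below the cross-validation error. The unpruned tree is kept too, since
  the pruning rule tends to collapse to effectiveness-only splits.

With 10,000 sets these reproduce: ≈22% of runs censored under both
strategies, ≈51–54% of comparable runs favouring sequential use, a
margin-0 decision line of ≈$1.06 + 0.56\times$ exposure with TPR ≈0.85 and
TNR ≈0.93, a margin-0.2 line of ≈$1.40 + 0.35\times$ exposure, exposure
PRCC magnitude >0.75, and negative dominance and effectiveness
coefficients (effectiveness ≈−0.5 for sequential times). The acceptance
script (`scripts/acceptance.R`) recomputes all of these from scratch.

## What the generator does and does not emulate

The synthetic parameter sweep emulates the *decision problem* — wide,
independent operational and genetic parameter ranges — not any particular
field setting: real programmes have correlated parameters (e.g. dosing
affects effectiveness and dominance jointly), temporally varying
deployment quality, insecticide decay (the low-concentration niches are
modelled but default to the high-concentration calibration), migration,
and finite-population drift, none of which are sampled. Passing tests
therefore demonstrate internal correctness of the deterministic model and
reproducibility of the published sweep, not field predictiveness.

## Numerical choices

* Frequencies are renormalised once per generation; drift beyond $10^{-9}$
  before renormalisation is treated as a bug (and would error in the
  constructors).
* Threshold comparisons are strict (`>`), and a population already above
  threshold at the start of a phase has crossing time 0 with the switch
  lag still applied.
* Extinction (total fitness-weighted mass zero, e.g. a fully effective
  mixture with no escape and no resistance) raises an explicit error
  rather than producing NaNs.
* Batch problem sizes: the shipped tests run the full 10,000-set sweep for
  the batch-level checks and 1,000 sets for the mixture-protection
  property; the deterministic fixtures are instantaneous.

## Known limitations

Sex linkage of a locus is not implemented (autosomal loci only); no
mutation, drift, demography or epidemiological coupling; mixtures assume
symmetric mis-deployment; rotations and spatial mosaics are out of scope.
Mean population fitness is reported but not fed back into population size.
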