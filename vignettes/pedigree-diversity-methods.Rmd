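---
title: "Methods: inbreeding, kinship and diversity trends from studbook pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inbreeding, kinship and diversity trends from studbook pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedtrends)
```

## The model

`pedtrends` analyses closed studbook populations through the classical
identity-by-descent framework. The coefficient of inbreeding $F_x$ is the
probability that the two alleles carried by $x$ at a neutral locus are
identical by descent; the coefficient of kinship $f(a,b)$ is the
probability that one allele drawn at random from each of $a$ and $b$ are
identical by descent, and equals the $F$ of a prospective offspring of the
pair. Founders — animals with *both* parents unrecorded — are assumed
non-inbred and mutually unrelated; every probability the package reports
is therefore relative to the recorded pedigree base, not to an absolute
ancestral population.

Per-animal inbreeding uses the Meuwissen–Luo tabular algorithm: processing
animals parents-first, the additive contributions $L_j$ of the ancestors
of $x$ are accumulated youngest-first and
$1 + F_x = \sum_j L_j^2 D_j$, where $D_j$ is the Mendelian sampling
variance of $j$ ($1$ for founders, $0.75 - F_p/4$ with one known parent
$p$, $0.5 - (F_s + F_d)/4$ with both). Cost per animal is bounded by its
ancestor count, so complete registries of $10^5$ or more animals are
routine. Kinship queries and cohort mean kinships never form the
relationship matrix $A$: they use indirect products $Ax$ computed in two
linear sweeps from the factorisation $A = T D T'$, so the mean kinship of
a cohort of any size is two passes over the pedigree regardless of the
number of pairs it represents.

### Cohort series and sampling regimes

For each birth year $t$ the package reports the census $n_t$, the mean
observed inbreeding $F_t$, and "expected inbreeding" — the mean kinship
over distinct unordered pairs of cohort members, i.e. the mean $F$ the
cohort would produce under random mating. Although the indirect product
makes the exhaustive computation cheap, the estimator deliberately
reproduces the size-dependent sampling scheme used in registry practice,
because the scheme is part of the method being reimplemented and its
sampling dispersion is itself a reported quantity:

* $n_t \le 500$: all $\tfrac{1}{2}(n_t^2 - n_t)$ pairs;
* $500 < n_t \le 2000$: all pairs within one uniform random sample of
  500 animals (without replacement);
* $n_t > 2000$: ten independent samples of 50; the estimate is the mean
  of the ten sample means and their standard deviation is reported.

Self-pairs are always excluded — the estimate models matings, and an
animal cannot be mated to itself. Samples pool both sexes: the target is
the mean kinship of the cohort, not of feasible matings; restricting to
opposite-sex pairs would change nothing in expectation under random
mating and would halve the usable sample. Both choices are assumptions
where registry practice is not fully specified, and both are fixed and
documented rather than configurable.

A single run-level seed derives one deterministic substream seed per year
(an affine hash of seed and year, reduced modulo $2^{31}-1$), so
extending the year range never perturbs the samples drawn for other
years.

The expected series is plotted *staggered*: the kinship of the cohort
born in year $t$ is the random-mating expectation for the cohort born one
generation later, so expected values are re-indexed to $t + \mathrm{round}(L)$.
The offset rounds half-up to whole years (3.5 → 4, and an $L$ of 3.88 —
a typical cross-breed mean — gives 4); rows pushed past the end of the
observed window are retained and flagged rather than dropped.

### Rates, generation interval and effective size

The annual rate of inbreeding is obtained from the ordinary least-squares
regression of $\ln(1 - F_t)$ on $t$, unweighted across years (a
cohort-size-weighted variant exists behind an argument but is off by
default, since the reference method does not weight). The reported rate is
the *negated* slope so that rising inbreeding yields a positive rate; the
regression coefficient itself is also returned. On the log scale the
regression strictly implies the transform $\Delta F = 1 - e^{b}$; this is
available as `method = "exp"`, while the default keeps the literal
rate-equals-coefficient convention — the two differ only at second order
(for $b = -0.002$, by two parts in a thousand).

The generation interval $L$ is the mean age of parents at the birth of
progeny *which themselves go on to reproduce*; "goes on to reproduce"
means having at least one offspring anywhere in the pedigree, with no
window restriction. Ages are computed in days divided by 365.25 when full
dates exist, or as integer year differences at year resolution. Records
with impossible chronology (parent age non-positive, or above the
configurable 20-year maximum) are excluded from age statistics only —
never from relatedness, where the parentage link is still information.

The per-generation rate is $\Delta F = L \cdot \Delta F_{\mathrm{annual}}$
and the effective population size $N_e = 1/(2\Delta F)$ when
$\Delta F > 0$. Non-positive $\Delta F$ leaves $N_e$ *undetermined* — a
first-class value carrying a reason code (`undetermined_negative`,
`undetermined_zero`), never an exception, so multi-breed batch reports do
not abort on breeds whose diversity grew.

Block statistics recompute the regression inside each fixed 5-year block
(1980–1984 … 2010–2014 by default). The whole-period $L$ is reused inside
blocks: per-block intervals are descriptive and noisy, and reusing the
whole-period value isolates the block-to-block signal in the regression
slope. A block with fewer than 3 usable years is undetermined rather than
an error. Across breeds, block differences are tested with one-way ANOVA
treating breeds as replicates within blocks; breeds enter cross-breed
statistics only when mean registrations exceed 50 per year in *every*
block.

## The synthetic studbook generator

No public registry accompanies the method, so validation rests on a
simulator that emulates what the analysis assumes about real studbooks:
year-structured cohorts, a limited breeding roster per year, skewed sire
usage, migrant founders, and census trends.

Each simulated year draws a roster of `n_sires` males and `n_dams`
females from age-eligible earlier cohorts (ages drawn from a discrete
distribution, default a point mass at 4 years — at the centre of
reported breed means, which run from about 3 to 5 years). Each dam
produces a Poisson litter (`litter_mean`, default 4, a typical
companion-animal litter scale), and each offspring's sire is drawn from
the roster with geometric-decay weights $(1-s)^{\mathrm{rank}}$ over a
random ranking: `sire_skew` $s = 0$ is uniform usage and $s \to 1$ a
single dominant sire. With probability `migration_rate` a roster slot is
instead filled by a novel unrelated founder. Offspring sex is a fair
coin. All animals carry full (mid-year) birth dates, so simulated
pedigrees pass structural validation with no chronology findings, and
identical configuration plus seed reproduces byte-identical output.

Two generator-design points deserve a note:

* **The skew law.** The weights decay geometrically with ratio $1 - s$,
  chosen so the parameter reads naturally (0 = uniform, near 1 = one
  popular sire) and so a single parameter reproduces the long-tailed
  progeny-per-sire histograms seen in registry data.
* **Age mixing in the scenario presets.** With a point-mass parental age
  of exactly 4 years, birth-year cohorts split into four parallel
  lineages that never interbreed; their independent drift adds sawtooth
  noise to 5-year block estimates that has nothing to do with real
  studbooks, where breeding ages overlap. The validation presets
  therefore use ages {3, 4, 5} with equal weight (mean $L = 4$), which
  keeps the gene pool mixed. The point mass remains the default for
  idealised-population checks, where non-overlapping generations are
  exactly the assumption of Wright's formula
  $N_e = 4 N_s N_d / (N_s + N_d)$.

The generator also returns its idealised-theory expectations
($\Delta F = 1/(8 N_s) + 1/(8 N_d)$, the matching $N_e$, and the mean
parental age) as recovery targets. The test suite verifies that the full
pipeline — simulate, inbreed, regress, scale, invert — recovers Wright's
$N_e$ across a $\{10, 25, 50\}^2$ grid of breeder counts within a 25 %
relative-error band, using 20 replicates of 16 generations per cell; the
observed bias is in fact under 4 %.

`scenario_library()` freezes four presets with documented signatures: the
extreme popular-sire pedigree whose grand-progeny all have $F = 0.125$
exactly; a contraction-then-recovery history (skew easing linearly over
1980–1999 from 0.85 to 0.05, migrant use ramping quadratically from 2000
to 12 %) whose block rates decline monotonically and turn negative after
2005; and a small-census (3 sires / 8 dams) versus large-census (60 / 150)
pair sharing that history, the former showing the amplified early-block
rates expected of numerically small breeds. The migration ramp is convex
on purpose: the log-scale decline rate is proportional to the remaining
mean $F$, so a linear ramp would saturate and the late blocks would
rebound toward zero instead of continuing to fall.

### What the generator does not emulate

Simulated founders are truly unrelated, migrants carry no hidden
co-ancestry, there is no selection on traits, no litter-level sire
sharing (each offspring draws its sire independently), no seasonal
structure within years, and no sub-population (show/working/regional)
structure. Passing the recovery and signature tests therefore shows that
the estimators measure what they claim on data satisfying the method's
own assumptions; it does not address biases that incomplete migrant
pedigrees or hidden sub-structure induce in real registries, both of
which depress apparent kinship and hence $\Delta F$.

## Numerical and edge-case choices

* Missing parents are encoded as empty fields, `0` or `NA` in files;
  identifiers are compared by exact string match after whitespace
  trimming, with no case folding (registry names can be
  case-significant).
* A single known parent contributes co-ancestry through the known side
  only; such animals have $F = 0$ themselves but are *not* founders.
* Duplicate identifiers, self-parentage and ancestry cycles are hard
  load-time errors (the cycle is named); sex conflicts and chronology
  problems are soft issues reported by `validate_pedigree()`.
* Pedigree probabilities are exact binary fractions and are never rounded
  internally; writers format at 6 decimal places.
* `Ne == 1/(2 dF_gen)` holds to machine precision by construction;
  $\Delta F = 0$ maps to undetermined with its own reason code, distinct
  from negative.
* Topological order ranks animals by generation number with ties broken
  by input row order, so founders-only files keep their order and
  re-reading a written pedigree is stable.
* In usage statistics the top-$q$ % tier takes
  $\lceil q/100 \cdot n \rceil$ parents (never empty), descending by
  progeny count with ties broken by ascending identifier; the mode
  reports the smallest modal count with a multimodality flag; the sd of
  a single-parent year is reported as 0 with a flag rather than NA so
  tabulation never fails. Animals with the relevant parent unknown are
  excluded from the tier denominators.

## Problem sizes used in validation

The shipped test suite runs entirely on synthetic data built in code:
random pedigrees of up to 200 animals for the oracle comparisons (naive
recursive kinship, and gene-dropping with $2 \times 10^5$ allele drops),
single-sire cohorts of up to 2 100 animals for the sampling-regime
identities, and simulated studbooks of roughly 6 000–15 000 animals for
recovery and scenario checks. These sizes were chosen as the smallest at
which each property is sharply testable; the algorithms themselves scale
well beyond them.

## Known limitations

Kinship to an unrecorded ancestor is invisible: breeds built on few
imported lines will have $F$ and $\Delta F$ underestimated relative to
truth. $N_e$ is a whole-window summary of a possibly non-stationary
process — the block table, not the single number, carries the history.
ANOVA on block rates treats breeds as independent replicates, which
cross-breed fashions in sire use violate in spirit. Confidence intervals
on $N_e$ are deliberately not reported; the regression standard error is
available from the returned fit but a proper interval would need the
autocorrelation of $F_t$, which is out of scope.
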