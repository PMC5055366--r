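---
title: "Estimating annual fecundity of batch-spawning fishes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating annual fecundity of batch-spawning fishes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fecundr)
library(dplyr)
```

## The problem

How many eggs does an iteroparous, batch-spawning female produce in one
season? For American shad (*Alosa sapidissima*) and similar clupeids the
answer depends on how vitellogenesis is organised:

* **Group-synchronous** development: the yolked (vitellogenic) oocytes
  advance as one cohort, separated by a size gap from the previtellogenic
  reservoir. The pre-spawning standing crop of yolked oocytes *is* the
  annual fecundity, and a single gravimetric census measures it — the
  **determinate** method.
* **Asynchronous** development: new yolked oocytes keep recruiting while
  spawning is under way (de novo vitellogenesis). A standing-crop census
  then underestimates annual production, and fecundity must be assembled
  from its components — spawning-period length, spawning interval, batch
  size — the **indeterminate** method.

`fecundr` implements both estimators, the diagnostics that justify
choosing between them, and a synthetic population generator with known
ground truth so that every stage can be validated without field data.

## The determinate estimator and its three diagnostics

The gravimetric estimate expands a counted, weighed subsample of ovary
tissue to the whole ovary:

$$\mathrm{PAF} = \frac{C_S}{M_S} \, M_O,$$

with $C_S$ the advanced-cohort cell count in a subsample of mass $M_S$
and $M_O$ the ovary mass (`determinate_paf()`). When several subsamples
are available per fish their densities $C_S/M_S$ are averaged first — a
variance-reducing convention of gravimetric practice; published work
based on one subsample per fish is the special case.

The estimate is valid if three conditions hold:

1. **A size gap** separates the previtellogenic reservoir from the yolked
   cohort. `build_histogram()` and `detect_size_gap()` examine the
   whole-oocyte size-frequency distribution in the transitional band
   (default 300–500 µm, configurable). The *gap uncertainty*
   (`gap_uncertainty()`), $100\,T/(T+S)$, is the transitional share of the
   advanced cohort; it is also, exactly, the relative drop in the PAF
   estimate if transitional cells are excluded. By default transitional
   cells are **included** (`include_transitional = TRUE`): early in the
   run they recruit fully and spawn in the current season.
2. **An early decline** of the standing crop once spawning begins.
   `decline_ancova()` fits `log10(PAF) ~ log10(L_F) * group`, drops the
   interaction when it is not significant at 0.05 (the conventional
   threshold; nothing in the analysis hinges on it, and the full-model
   contrasts are still reported when the interaction is kept), and
   contrasts each spawning group — and the pooled spawning set — against
   the pooled pre-spawning baseline, without multiplicity correction.
   Base-10 logarithms are used throughout; slope and correlation are
   base-invariant, only the intercept depends on the choice.
3. **Low terminal atresia**: females ending the season should not retain
   an appreciable yolked residue. The pipeline carries presence-level
   information (macroscopic class, residual counts); it does not attempt
   to quantify atresia stages.

### Phase classification conventions

Published whole-mount size bands are approximate and overlap at
1200–1500 µm. `classify_phase()` makes the mapping total and
deterministic: half-open intervals $[0,300)$, $[300,500)$, $[500,1500)$,
$[1500,\infty)$ µm, with a recorded appearance deciding the 1200–1500 µm
overlap (translucent/transparent → maturation, opaque → secondary) and a
decisive histology stage overriding size. A boundary diameter therefore
always belongs to the upper phase (300 µm is transitional). Measured
diameters below the measurement floor (default 100 µm, where imaging
workflows stop resolving previtellogenic cells) are excluded from
histograms and reported separately, so histogram counts always conserve
the input.

## Spawning fraction, spawning interval, and a rounding convention

Each histological marker dates a female relative to a spawning day:
early nucleus migration (NM1) means spawning tomorrow (day −1); late
nucleus migration or hydration (NM2, NM3, H) or a fresh postovulatory
follicle (POF0) mean day 0; POF1 (12–24 h) day +1; POF2 day +2. We read
the POF2 window as 24–48 h — its printed "24–24 hour" range is an
evident typographical slip. Classes co-occur (a female can be NM1 and
POF2 at once), so per-date proportions are computed independently per
class and can sum past 1.

Each class proportion estimates the fraction of females spawning per
day; the spawning fraction is their mean and the spawning interval its
reciprocal:

$$\mathrm{SF} = \tfrac14\sum_k p_k, \qquad \mathrm{SI} = 1/\mathrm{SF}.$$

The canonical rounding convention, chosen because it uniquely reproduces
the published per-date table on 11 of its 12 dates, is: round SF
half-up to two decimals, then round $1/\mathrm{SF_{rounded}}$ half-up to
two decimals (`round_half_up()`; base R's round-half-even does not
reproduce the table). The implementation adds a $10^{-8}$ guard before
truncation so decimal halves that sit just under the half in binary
floating point (e.g. `1.62/4`) still round up. The remaining date
(May 12) is inconsistent with its own printed proportions under any
simple rounding — their mean is 0.225, the printed SF 0.22 — most likely
because unrounded within-sample proportions were used there; the
package computes 0.23/4.35 for that row and documents the discrepancy
rather than reproducing it.

Lower-river females sampled before spawning begins carry almost no POF
markers and yield unrealistically long apparent intervals; they are
excluded from interval pooling by site/status, exactly as a field
protocol would exclude them.

## The indeterminate estimator

$$\mathrm{PAF} = \frac{RT}{SI} \times BF$$

with residence time $RT$ (a proxy for the individual spawning period),
spawning interval $SI$, and batch fecundity $BF$ drawn independently —
no dependence structure is asserted anywhere, so none is modelled.
Component distributions (`pdf_spec` objects):

* **RT** — normal(30.0, 2.6) days truncated at zero (`fit_rt()`); at
  these parameters the truncation is numerically irrelevant
  ($\mu/\sigma \approx 11.5$) and draws span roughly 20–40 days.
* **SI** — a zero-truncated normal fitted by maximum likelihood to the
  per-date intervals (`fit_si()`). No family is named in the source
  material; the truncated normal is the simplest family consistent with
  the printed mean and spread, the truncation is mild at the fitted
  parameters ($\hat\mu/\hat\sigma \approx 3.4$), and a gamma alternative
  (and an empirical resampler) are provided. ML uses the $n$ denominator
  for the scale; on the twelve published values the fit is
  $\hat\mu = 4.824$, $\hat\sigma = 1.404$. The optimizer is Nelder–Mead
  refined by BFGS on $(\mu, \log\sigma)$; tests compare it against an
  independent multi-start optimization at $10^{-6}$.
* **BF** — lognormal (`fit_bf()`): strictly positive and right-skewed.
  With raw counts the ML fit is closed-form on the log scale; when only
  a published mean and sd exist, moment matching
  ($\sigma^2 = \log(1 + cv^2)$, $\mu = \log m - \sigma^2/2$) reproduces
  them exactly. This moment-matched constructor is first-class because
  the source study prints only summaries for its 15 gravid females.

`simulate_paf()` draws `n_draws` fish per replicate for `n_replicates`
bootstrap replicates (defaults 1000 × 1000, which reproduce a published
bootstrap sd of replicate means of a few thousand oocytes at a per-draw
CV near 0.5); the grand mean of replicate means is the estimate.
Sampling is inverse-CDF for the truncated normal, so a fixed seed gives
bit-identical results. SI draws at or below a floor (default 0.5 day)
are rejected and resampled with a logged count: the truncated-normal
left tail would otherwise admit sub-daily intervals and unbounded
spawning frequencies. The floor is the one genuinely free numerical
knob; its effect is auditable through the rejection count (well under
0.1% of draws at the fitted parameters).

`expected_paf()` evaluates the closed form
$E[RT]\,E[1/SI]\,E[BF]$ by adaptive numerical integration over the same
floored support, and the test suite requires the simulation to agree
with it within three Monte-Carlo standard errors. One consequence worth
stating plainly: with the published component summaries as inputs, this
expectation sits a little above the published simulated grand mean
(about 2–3%), and correspondingly the simulated margin over the
determinate mean computed here is larger than the published "<3%".
The package reports what the stated inputs imply; a published simulated
value is one finite-sample realisation (and its exact SI fit and raw
batch-fecundity data are not recoverable from print), so small offsets
of this order are expected. `compare_methods()` performs the
pooled-variance Student's t-test between the determinate per-fish
estimates and the bootstrap replicate means and reports the probability
itself alongside the percent difference of means.

## The synthetic generator: what it emulates, and what not

`synthetic_config()` + `generate_population()` realise a spawning run
with known truth; the defaults are the study conditions of the data the
package targets, chosen once:

* fecundity–length relation
  $\log_{10} F = -2.48 + 3.0\,\log_{10} L_F + N(0, 0.105)$ — about
  300,000 oocytes at 460 mm with CV ≈ 0.24, matching the published
  means and spread; lengths truncated-normal within 396–528 mm;
* true SI ~ truncated-normal(4.83, 1.40) days (lower bound 1 day), true
  RT ~ normal(30, 2.6); each fish spawns every SI days over RT days,
  the first batch at least two days after entry, the total production
  split evenly across scheduled batches (batch-size schedules beyond an
  even split are not modelled — only summaries of batch fecundity are
  published);
* ovary mass = 1 mg per advanced oocyte plus 10% stromal mass, somatic
  mass $1.65\times10^{-5} L_F^3$ g — gonadosomatic indices near 20, as
  observed; subsample masses uniform on 0.2–0.55 g, which yields counts
  in the published 138–532 range;
* gravimetric counts are **binomial thinnings** of the true per-phase
  cell numbers at probability $M_S/M_O$ — the physical sampling
  mechanism, hence unbiased by construction;
* histology markers follow the day arithmetic of the spawning schedule
  (NM1 the day before a batch, NM2/NM3/H or POF0 on the day, POF1/POF2
  after), so marker classes co-occur exactly as in real tables;
* in asynchronous mode, de novo recruitment runs at 1/30 of the initial
  crop per day (total recruitment ≈ the initial crop over a ~30-day
  residence — the regime in which the two methods diverge by a factor
  of about two), and the transitional band holds the steady-state
  occupancy of the recruitment pipeline (rate × 5-day transit);
* spent females retain an atretic residue of 2% of the initial crop — a
  free parameter, as no quantitative terminal-atresia rate is published.

The generator's purpose is parameter recovery, and the test suite uses
it that way: a pre-spawning census recovers true fecundity within 2%
at n = 50 (group synchrony); marker tables recover the true mean SI
within 15% at 30 females per date; the indeterminate route fed the
recovered SI/RT/BF recovers mean true fecundity within 10%; and under
asynchronous recruitment equal to the initial crop the determinate
census lands at ~0.5 of truth while the indeterminate estimate stays
within 10% — the mechanism that makes the two methods diverge between
populations with different oogenesis modes.

What the generator does **not** emulate: marker mis-staging and diel
spawning timing; oocyte shrinkage and section-plane bias of
histology-measured diameters (no correction factor is published, so
none is applied anywhere); migration dynamics along a river; egg and
larval survival; multi-year recrudescence (spent-female transitional
cells reappearing for next season are represented only as a residue,
not a dynamic cohort). Passing recovery tests therefore demonstrates
estimator correctness under the stated sampling mechanisms, not
robustness to staging error or non-representative field sampling.

## Problem sizes and runtime choices

Default test problem sizes — populations of 50–150 fish, 400 measured
oocytes per profiled fish, simulations of $10^6$ total draws, 20-seed
power loops — keep the full suite comfortably under a few minutes while
leaving Monte-Carlo standard errors an order of magnitude inside every
asserted tolerance. All are configuration arguments, not constants.

## Known limitations

* The May 12 row of the published interval table cannot be reproduced
  from its own printed proportions; the package documents rather than
  imitates it.
* The SI family is a modelling choice; the data (twelve values) cannot
  distinguish truncated-normal from gamma. Both are provided.
* ANCOVA contrasts are unadjusted for multiplicity, mirroring the
  published contrast structure; users testing many groups should adjust.
* Fish lengths enter the ANCOVA in millimetres; the unit only shifts
  the intercept.
* The package estimates potential annual fecundity; realised fecundity
  (losses to atresia within the season, skipped batches) is out of
  scope.
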