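---
title: "Model structure, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascvdcea)
```

## The decision problem

`ascvdcea` models whether adding inclisiran — a twice-yearly siRNA that
lowers LDL-C by roughly 57% on top of statins — to standard lipid-lowering
therapy is good value for Chinese patients with established atherosclerotic
cardiovascular disease (ASCVD), at the nationally negotiated price of
CNY 2,790 per dose. Because no long-term cardiovascular outcome trial of
inclisiran in a Chinese population exists, the model takes the standard
surrogate route used throughout the lipid-lowering literature: the achieved
absolute LDL-C reduction is mapped to event-rate reductions through the
Cholesterol Treatment Trialists' Collaboration (CTTC) rate ratios per
1 mmol/L.

## States and transitions

Seven states: baseline ASCVD, acute MI, acute IS, post-MI, post-IS, CV
death, non-CV death (death is split only so one-off terminal costs can
differ by cause; the published model describes six states with a single
death state). Cycles are annual. Structural rules:

* one CV event at most per cycle;
* acute-state survivors move to the matching post state the next cycle
  (the acute state lasts exactly one cycle, carrying first-year costs and
  utilities);
* the process is memoryless: recurrences from post states re-enter the
  acute state and repeat acute costs and utilities;
* recurrent-event rates carry HR 1.13 (MI from post-MI, IS from post-IS);
  CV death from the acute states carries HR 1.31 (first year after an
  event);
* death states are absorbing.

Event probabilities are `1 - exp(-r)` per channel, with the residual mass
staying put (or feeding the post state, for acute rows). With the base-case
rates the per-row event mass is well below 1; the matrix builder errors if
scaling ever pushes it past 1 rather than silently renormalising.

## Mortality: two channels, no double counting

CV death is a *disease-model* channel: the calibrated 0.70/100
patient-years rate, treatment-modifiable through RR 0.84 per mmol/L. The
life table contributes only *background* non-CV mortality — all-cause minus
CV at each integer age (no interpolation; the row for `floor(age)` is
used). Subtracting the life-table CV rate avoids counting CV death twice.
The published description does not say whether its CV-death probability
also grows with age; we evaluated an age-scaled variant (CV channel
following the life-table CV schedule, anchored at 0.70/100 py at entry) and
rejected it because it pushes the incremental QALY gain far outside the
published envelope (0.63 vs 0.41) while collapsing comparator QALYs; the
fixed-rate channel is kept, configurable inputs aside.

The Table-1 rate ratio of 0.90 per mmol/L for *all-cause* death cannot act
through the CV channel alone (it is the published tornado's top driver), so
it is implemented as a treatment-arm multiplier `0.90^ΔLDL-C` on the
background non-CV channel, toggled by `settings$apply_all_cause_effect`
(default on). This is an interpretation; switching it off removes most of
the intervention's survival benefit.

## Accrual, half-cycle correction and discounting

State occupancy is evaluated at cycle start; costs and QALYs accrued in a
cycle are discounted at the cycle *midpoint*, `(1+r)^-(k-0.5)` — the
simplest scheme consistent with a one-line "half-cycle correction applied
to both costs and QALYs" statement. One consequence worth knowing: a
1-cycle horizon shows zero incremental QALYs (both arms still occupy
baseline at cycle start), so the scenario ICER is undefined at horizon 1
and becomes very large at horizon 2. Death costs (CV 15,212; non-CV
6,044.1) are charged once, to the newly dead fraction in the cycle of
death. Drug costs (statin 3,645/year both arms; inclisiran 8,385 in year 1,
5,590 thereafter — doses × (2,790 + 5) injection fee) are charged to all
alive states: therapy is lifelong and adherence perfect by assumption. The
published methods text quotes CNY 8,370/5,580 (fee excluded); we follow its
input table's fee-inclusive 8,385/5,590, which carries the explicit
footnote and uncertainty ranges.

## Calibration arithmetic

The composite claims-cohort rate (6.40/100 py) times the Asian HR 1.04
gives 6.66/100 py. The cross-cohort transfer
`r_a = r0·HR_age^Δage·RR^ΔLDL-C` is implemented for completeness, but the
base case reads the event-specific rates (MI 3.53, IS 1.72, CV death 0.70)
directly from the input table — note they sum to 5.95, not 6.66; whether
the published analysis applied the age/LDL terms before or after
disaggregation is not stated, and the printed component rates are treated
as authoritative. `split_composite()` ships fractions back-solved from
those rows (0.5933/0.2891/0.1176) for users who want to re-disaggregate a
different composite. The per-year-of-age HR has no published value and is
therefore a required argument with no default; the base case never uses it.

## Parameter uncertainty

Ranges are 95% intervals where a CI was printed, plain ±20% bounds
otherwise. Sampling families follow the input table: lognormal for rate and
hazard ratios (location `ln(point)`, scale `(ln hi − ln lo)/3.92`), normal
for LDL-C reduction, gamma for costs and beta for utilities
(method-of-moments, sd `(hi − lo)/3.92`). Parameters flagged fixed (patient
characteristics, baseline rates) are never sampled; the composite-rate
range (5.33, 7.99) is available to the tornado, where it rescales the
component rates proportionally. PSA draws are independent — no correlation
structure was published. Invalid draws (outside a parameter's support, e.g.
a utility above 1) are redrawn up to 100 times and counted; with the
shipped ranges this essentially never triggers. The composite-MACE rate
ratio and the percentage LDL-C reduction are carried and sampled (so their
sampling distributions are testable) but do not enter the computation — the
event-specific ratios and the absolute reduction drive the model — and are
omitted from the default tornado list as flat rows.

The tornado also carries two linked rows: the per-dose inclisiran price
(2,232–2,790, moving year-1 and later annual costs together) and the
discount rate (0–5%). Rows are sorted by descending ICER spread, ties
alphabetical. The CEAC uses the strict NMB criterion
`λ·ΔQALY − Δcost > 0`, which handles dominant draws without sign
ambiguity and resolves a λ exactly equal to a draw's realized ICER as "not
cost-effective".

## The synthetic life table

The real input is an age-indexed schedule of all-cause and CV mortality
from the 2023 national health statistics yearbook, which ships with the
published analysis as a supplement we cannot redistribute. The generator
stands in for it with a Gompertz–Makeham law

`rate(age) = makeham + a·exp(b·age)`, CV share `0.25 + 0.004·(age − 40)`
capped at 0.55,

with defaults `makeham = 5e-4, a = 1.5e-5, b = 0.100` fixed once against
two stated calibration targets: remaining life expectancy at 59.5 of
~25–30 years (we sit at 24.9, the realistic end for contemporary China —
b = 0.10 reproduces yearbook-like rates of ~0.006 at 60 and ~0.12 at 90)
and base-case incremental QALYs within ±25% of the published 0.41 (we get
0.497). Under this table the comparator arm lands within 1% of the
published totals (83,922 vs 83,140 CNY) and the ICER within 7% (152,622 vs
143,045).

What a green test does *not* establish: agreement with the published
numbers that hinge on the real table's heavier old-age mortality. Two
published results are structurally out of reach of any Gompertz–Makeham
table satisfying the life-expectancy band, and their acceptance assertions
are deliberately left failing rather than loosened: the 5-year scenario
ICER (865,930 published vs 679,791 here — short-horizon increments match
almost exactly, divergence accumulates in late-life drug exposure) and the
tornado ranking (the all-cause-mortality RR ranks first in the published
diagram with roughly double the leverage it has here, where the discount
rate ranks first and the all-cause RR fifth; its leverage scales with the
size of the background mortality it multiplies). The PSA probabilities of
cost-effectiveness (97% vs published 95.1% at 2× GDP; 0% vs 0.4% at
1× GDP) and the discount-rate bracketing of the base ICER are reproduced.

## Numerical conventions

All internal arithmetic is unrounded; 2-decimal rounding happens only in
report tables. ICERs are computed from unrounded totals (the published
rounded increments 58,321.35/0.41 would give 142,247, not the printed
143,044.57 — division evidently preceded rounding there too). Occupancy
conservation is enforced at 1e-9 per cycle row. All randomness (PSA,
microsimulation test oracle) flows through explicit integer seeds.

## Known limitations

* Perfect adherence, no discontinuation, no injection-site adverse events,
  direct medical costs only — all by design of the modelled analysis.
* The all-cause-mortality channel is an interpretation (see above);
  toggling it changes the ICER materially.
* No risk stratification by baseline LDL-C or event history beyond the
  post states; no efficiency frontier over more than two strategies.
* Synthetic mortality is a stand-in: quantitative agreement with the
  published base case is approximate (within ~7% on the ICER), and users
  with access to the real yearbook schedule should load it via
  `read_life_table()`.
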