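---
title: "Dropout analysis with dropcurve: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dropout analysis with dropcurve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropcurve)
```

## Why dropout is worth modelling

In Internet-based experiments participation is voluntary throughout: a
participant can close the tab after any item. Dropout is therefore common
enough to carry signal — which items are burdensome, which experimental
condition is less attractive — and dangerous enough to bias conclusions:
when conditions differ in attrition, the participants remaining at the end
are no longer comparable groups (motivational confounding). The sound
response is to *analyze* dropout, not hide it. This vignette describes the
statistical machinery `dropcurve` uses, the conventions it fixes, and why.

## The dropout index

All analyses build on one derived quantity. For participant $i$ with $K$
selected items in presentation order, the dropout index $d_i$ is the
1-based position of the last answered item; $d_i = K$ marks a completer and
$d_i = 0$ someone who answered nothing. Crucially, only a *trailing* run of
missing values counts: a skipped item followed by later answers is
intermittent missingness (forgotten, refused, or soft-validated), not
dropout. `add_dropout_idx()` implements exactly this rule, which makes the
index immune to arbitrary mid-study skip patterns.

Missing cells are whatever the `na_policy()` says they are: empty cells,
`"NA"`, `"N/A"`, plus up to three custom codes, matched against whole
cells after whitespace trimming and *case-sensitively*. Case-folding would
risk silently destroying valid answers (a response option literally coded
`"na"`, say); users who need case-insensitive codes can list the variants
as custom codes.

## Dropout curves and the attribution rule

`compute_stats()` tabulates, per condition and pooled, the cumulative
dropout $cs(q) = \#\{i : d_i < q,\ d_i < K\}$ and percent remaining
$100\,(N - cs(q))/N$ for $q = 1 \dots K$. Two conventions interlock here:

* the sample at the **first selected item is the 100% baseline**, so the
  analysis can start anywhere in a study (e.g. dropout after an
  intermediate instruction), and
* a dropout with index $d$ is attributed to the **first unanswered
  question** — the participant still counts as present at the last item
  they answered. With $K$ items a curve therefore has at most $K - 1$
  visible steps.

Participants with $d_i = 0$ are a corner the attribution rule does not
settle by itself. We retain them in $N$ and count them as dropped from
question 1 onward (the baseline may then sit below 100%), with a logged
count: silently deleting non-starters would overstate retention.
Completers never enter $cs$; finishing the study is censoring, not an
event.

## Contingency statistics

At any question $q$, `crosstab_at()` splits each condition into dropped
vs remaining under the same attribution rule (so its column sums equal the
pooled curve at $q$), and `chisq_dropout()` applies Pearson's
$\chi^2 = \sum (O-E)^2/E$ with $(\text{conditions}-1)$ degrees of freedom.
We apply **no continuity correction at any table size**: it keeps the
$2\times2$ and $k\times2$ cases on a single formula and equal to the
squared two-proportion $z$ statistic, and the choice is stated so users can
reconcile with Yates-corrected output elsewhere. A degenerate margin
(nobody or everybody dropped) is reported as $\chi^2 = 0$ with a warning
rather than an error, since it is a legitimate observation about the data.
The default question is $q = K$: differences in *reaching the end* of the
study.

The odds-ratio matrix reports
$OR_{ij} = (\text{drop}_i\,\text{remain}_j)/(\text{remain}_i\,\text{drop}_j)$
for every condition pair; it has unit diagonal and reciprocal symmetry.
Zero cells get the Haldane–Anscombe correction — 0.5 added to all four
cells of that pair's $2\times2$ only — the standard finite estimator,
leaving other pairs untouched.

## The survival view

Dropout is a discrete-time event process on item positions: event = drop,
time = $d_i$, completers censored at $K$. `km_fit()` returns the
product-limit estimate $\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)$ per
condition with Greenwood variance and log-scale 95% intervals clipped to
$[0,1]$ (the plain log interval is simple and standard; log(−log)
intervals would also be defensible but add nothing at these sample sizes).
Ties are inherent to discrete item times and handled by the aggregate
$d_i/n_i$ step — no tie-breaking randomization. Participants with
$d_i = 0$ enter at time $0.5$ as events: they must precede every item time
without colliding with time 0, and the half-step keeps all genuine item
positions intact. Under these conventions the survival and curve views
agree exactly: with no censoring before $K$,
$\hat S(q-1) = \#\{d_i \ge q\}/N$, the proportion remaining at $q$.

`grho_test()` covers the Fleming–Harrington G-rho family: at each distinct
event time the observed minus expected events per group, weighted by
$\hat S_{\text{pooled}}(t^-)^\rho$ (the left-continuous pooled
Kaplan–Meier), accumulate into a quadratic form with the hypergeometric
covariance; the statistic is $\chi^2$ with groups − 1 df. $\rho = 0$ is
the default — the standard log-rank test, the natural first choice when no
part of the study is privileged; $\rho = 1$ (Peto–Peto-type) up-weights
early dropout and is worth reporting when early attrition is the
hypothesis. With a single common event time and two groups the statistic
collapses, up to the finite-population factor $n/(n-1)$, to the
uncorrected $2\times2$ chi-square — a useful consistency check that the
test suite exercises.

## The extreme-condition KS comparison

`find_extremes()` ranks conditions by percent remaining at a chosen
question (default: the last, i.e. end-of-study retention; ties go to the
lexicographically first label, with a warning) and `ks_dropout()` compares
the two extremes by the largest vertical gap $D$ between their
dropout-index ECDFs — which, under the attribution rule, is also the
largest gap between their dropout curves in proportion terms. The p-value
uses the asymptotic Kolmogorov distribution at
$\sqrt{n_1 n_2/(n_1+n_2)}\,D$. Item positions are heavily tied discrete
times, for which this approximation is conservative-ish but not exact;
every result therefore carries a printed discrete-time caveat rather than
pretending to an exactness the sampling situation does not support. An
exact permutation p-value would be possible but is deliberately left to
the test suite, where a seeded permutation check confirms the analytic
p-value on moderate samples.

## Figures

`plot_do_curve()`, `plot_do_kpm()` and `plot_do_ks()` are ggplot2
functions; everything is themeable downstream. Conventions worth stating:

* The colorblind-safe palette is the 8-color Okabe–Ito set, the de facto
  standard; more than eight conditions with this palette is an error, not
  a silent recycling. The pooled `"total"` curve is always black.
* Grayscale output forces line-type cycling, otherwise curves become
  indistinguishable in print.
* Dropout-curve confidence bands are normal-approximation binomial
  intervals on the remaining proportion,
  $100\,(\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/N})$, clipped to
  $[0,100]$ — the simplest defensible band for a per-question retention
  proportion, chosen over Greenwood-based bands to keep the curve view
  model-free; the KM plot carries the Greenwood-based intervals.
* `full_scale = TRUE` fixes the y axis to the full range so curves from
  different studies are visually comparable; switching it off zooms in.
* `export_figure()` writes PDF/SVG as true vector output and PNG at the
  requested dpi (pixel width = width × dpi). Rendering has no hidden
  randomness: identical inputs re-render byte-identically.

## The synthetic-study generator

`simulate_responses()` draws each participant's dropout position from a
per-condition discrete hazard $h_j$ (probability of dropping after item
$j$ given survival so far, $j = 1..K-1$), fills answered cells with
integer tokens, and blanks non-final answered cells with probability
`skip_prob` to emulate intermittent skipping. The final answered item is
never blanked, so the generated ground-truth index is exact by
construction — that is what lets tests of the trailing-missing rule be
sharp. Response *content* is deliberately meaningless: dropout analysis
only consumes the answered/missing pattern.

Fixed study shapes: `demo_like()` is a four-arm study (conditions 11, 12,
21, 22; 52 items; 180 participants per arm — a realistic mid-size online
experiment) whose hazards share an early burst over the first five items
(the classic steep initial drop of web studies) scaled by
condition-specific multipliers, so the arms differ visibly and the
extreme-condition machinery has something to find. `stress_like()` is
1000 participants × 100 items × two arms, the shape of a large online
experiment, used to show the full pipeline runs comfortably at that size
(a few seconds, figures included). Both are fixed-seed and byte-stable
across calls.

What the generator does *not* emulate: real response content and response
times, item-level heterogeneity beyond the hazard profile,
non-monotone participation (returning after closing the browser), or
technology-induced missingness correlated with conditions. Passing tests
on simulated data therefore validate the estimators and conventions, not
any substantive claim about a particular real dataset.

Calibration choices in the test suite, stated as the package's own study
conditions: the log-rank type-I error is measured over 2000 two-arm null
replicates of 50 participants per arm over 10 items at a flat hazard of
0.05 (expecting 5% ± 1.5% rejections at α = 0.05); Kaplan–Meier
consistency is checked at 2000 participants per arm against the design
survival $\prod_j (1 - h_j)$ with a 0.03 maximum-deviation bound —
roughly three binomial standard errors at these sizes.

## Numerical and degenerate-input choices

* Chi-square on a degenerate margin: statistic 0 plus warning (see above).
* G-rho with a group contributing no variance: the quadratic form falls
  back to a Moore–Penrose inverse instead of failing.
* No events at all: `km_fit()` warns and returns the flat $\hat S = 1$
  curve; `grho_test()` errors, as there is nothing to compare.
* KS needs ≥ 2 participants per compared condition; below that an ECDF
  comparison is meaningless.
* All analyses are deterministic; randomness exists only in the generator
  and flows through a single seed, restored on exit so library calls never
  disturb the caller's RNG stream.

## Known limitations

Fisher's exact test and multiple-testing correction across the $K$
questions are out of scope, as are Cox or frailty models, interval
censoring, and imputation of intermittent missingness. The KS p-value is
asymptotic under heavy ties (see the caveat above). The dropout index
cannot distinguish "closed the browser at item $d+1$" from "answered
nothing from $d+1$ on but kept paging" — with one-item-one-screen designs
the two coincide, which is why that design is the cleanest setting for
dropout analysis.
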