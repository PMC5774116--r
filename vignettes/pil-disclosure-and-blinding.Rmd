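---
title: "Placebo disclosure, blinding indices and disclosure-stratified meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placebo disclosure, blinding indices and disclosure-stratified meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pilblind)
```

## The scientific question

Informed-consent documents (participant information leaflets, PILs) are
ethically required to tell trial participants that they may receive a
placebo. In trials of procedures such as acupuncture, investigators worry
that saying so plainly undermines blinding and dampens expectation-driven
responses, so PILs range from naming the "sham" outright, through neutral
labels ("you will be in group two"), to silence. `pilblind` packages the
analysis chain needed to study that spectrum quantitatively: code the PIL
wording, measure blinding success per arm, and compare pooled treatment
effects between disclosure strata.

## Disclosure coding

Coding is a three-tier keyword engine over normalized text (lower-cased,
punctuation stripped, whole-word matching):

* any **FD token** ("sham", "placebo", "fake", "dummy") → `FD`;
* otherwise a **DD token** (a neutral/deceitful group label) *plus* an
  **escalation token** (a sham-procedure phrase such as "non-acupoint" or
  "does not penetrate") → `FD` with `escalated = TRUE` — the participant
  was given enough to infer a placebo even without the word;
* a DD token alone → `DD`; no match or empty text → `MI`.

The lexicon ships as JSON (`inst/extdata/disclosure_rules.json`) and is
replaceable: the published coding manual behind the categories is not
available in machine-readable form, so the token lists are seeded from the
category definitions and the example labels reported with them
("different", "control", "group 1 or group 2", "non-traditional", "not
typical", "test"). The engine and its invariants (deterministic,
case-insensitive, FD/DD/MI partition every input) are the tested contract;
the lexicon is configuration. Matching is whole-word after normalization —
"shambles" does not fire "sham" — and multilingual input is out of scope
(source documents are assumed translated to English first).

Category composition is summarized per *placebo group*, not per PIL (a PIL
describing two placebo groups contributes twice), with percentages rounded
half-up to one decimal. Regional composition (Asia vs non-Asia) is compared
with the Pearson chi-square on the 2×2 table, *without* continuity
correction by default — the original report does not state which variant
its software applied, so the plain Pearson form is the default and a
`yates` flag provides the corrected one.

## Bang's blinding index

For one arm with `n` respondents, of whom `n_c` guessed their own
assignment, `n_i` guessed the other one and the rest answered "don't
know",

$$\mathrm{BI} = \frac{n_c - n_i}{n} \in [-1, 1],$$

the proportion potentially unblinded *beyond chance*: 1 means everyone
guessed correctly, 0 random guessing, −1 everyone guessed the opposite arm
(in a placebo arm: everyone believed they got the real treatment —
"wishful thinking"). Don't-know answers stay in the denominator; arms with
no respondents are rejected. Since BI is a difference of two multinomial
proportions, its variance is
$[p_1(1-p_1) + p_2(1-p_2) + 2 p_1 p_2]/n$ and the CI is the symmetric Wald
interval. The interval is *not* clipped to $[-1, 1]$ by default, matching
how such intervals are usually reported near the boundary; `truncate =
TRUE` clips it.

Thresholds classify each arm: random guess for $-0.2 < \mathrm{BI} < 0.2$,
"unblinded" (meaning only *more correct guesses than chance*) for
$\mathrm{BI} \ge 0.2$, opposite guess for $\mathrm{BI} \le -0.2$; the
boundaries belong to the non-random statuses. The ordered pair of statuses
(experimental arm, control arm) maps bijectively onto the nine blinding
scenarios S1–S9; S1 (both random) and S5 (experimental unblinded, control
guessing opposite) are conventionally read as ideal blinding, S4 and S6 as
possibly problematic.

BI distributions between disclosure groups (FD vs DD/MI merged — the
published grouping, configurable) are compared with an independent t-test
when both groups pass Shapiro-Wilk normality at `alpha`, otherwise a
two-sided Mann-Whitney U. Design choices here: the t-test is the
equal-variance Student form unless `welch = TRUE` (the source analysis
says only "independent t-test", and SPSS prints both; Student is the
classical default); the Mann-Whitney is exact by enumeration when both
groups have ≤ 8 observations and otherwise uses the tie-corrected normal
approximation without continuity correction; a constant group, for which
Shapiro-Wilk is undefined, is treated as non-normal. The Shapiro-Wilk
computation itself is delegated to `stats::shapiro.test` (Royston's
algorithm, valid for 3 ≤ n ≤ 5000) — hence the n ≥ 3 precondition.

## Effect sizes

Continuous outcomes give Hedges' g: the mean difference over the
df-weighted pooled SD, shrunk by $J = 1 - 3/(4\,\mathrm{df} - 1)$, with
$\mathrm{var}(g) = \frac{n_1+n_2}{n_1 n_2} + \frac{g^2}{2(n_1+n_2)}$. The
correction is on by default because the reference software for this kind
of pooling (RevMan) computes Hedges' g for its "SMD"; `hedges = FALSE`
gives raw Cohen's d for sensitivity analysis. Dichotomous outcomes are
converted through the logistic identity $\mathrm{SMD} = \frac{\sqrt 3}{\pi}
\ln \mathrm{OR}$, $\mathrm{var} = \frac{3}{\pi^2}\mathrm{var}(\ln
\mathrm{OR})$, with 0.5 added to all four cells when any is zero (the
standard correction; the source is silent, so the common default is used).
A table whose events or non-events column is empty in *both* arms carries
no odds-ratio information and is rejected.

Sign convention: **negative SMD favors the real intervention**. For
dichotomous outcomes this requires knowing whether the event is a harm;
the explicit `event_is_harm` flag (default `TRUE`) enforces it rather than
guessing from labels.

Multi-arm trials contribute one effect per placebo group; the shared real
arm's participants are divided as evenly as possible across the
comparisons, earlier comparisons receiving the remainder — "divided
evenly" does not define the odd case, so the remainder rule is fixed here
deterministically and documented. Outcome selection per study follows a
deterministic ladder — designated primary endpoint, else the condition's
common scale among outcomes with clearly reported data, else any clearly
reported outcome; within a rule the timepoint closest to the last
treatment session, then input order — and a study with no extractable
outcome raises an error signalling exclusion.

## Random-effects pooling and subgroup comparison

Pooling is DerSimonian-Laird under the generic inverse variance method:
fixed weights $w_i = 1/v_i$, Cochran's $Q$, $\hat\tau^2 = \max(0, (Q -
\mathrm{df})/C)$ with $C = \sum w - \sum w^2 / \sum w$, random weights
$1/(v_i + \hat\tau^2)$, normal-quantile CIs and a two-sided z-test;
$I^2 = \max(0, (Q - \mathrm{df})/Q) \times 100$. No Knapp-Hartung
adjustment and no alternative $\tau^2$ estimators — the point is to mirror
the RevMan 5.x conventions the stratified analysis was built on, and
k ≈ 10–14 per stratum leaves little to estimate REML from anyway. A single
study passes through unchanged; $\hat\tau^2 = 0$ reduces exactly to the
fixed-effect pool (both property-tested against an independent
straight-line reimplementation of the formulas).

The subgroup-difference test treats each stratum's random-effects subtotal
as one observation weighted by $1/\mathrm{se}^2$ ("subtotals as studies"):
$Q_{between} = \sum_g w_g (\hat\theta_g - \bar\theta)^2$ on
(#subgroups − 1) df, with an $I^2_{between}$ defined analogously. Strata
that contribute no poolable effects (typically MI — leaflets silent on the
placebo rarely come from trials reporting usable outcome data) are dropped
with a warning rather than failing the run.

## The synthetic corpus: what it emulates, what it does not

No per-trial raw data accompany the published analysis (per-study BIs and
SMDs appear only in anonymized figures), so the package carries a
generator that emulates the *statistical structure* of the corpus and is
itself first-class, tested code.

Defaults state the world once: 70 placebo groups from 65 PILs
(40 FD / 25 DD / 5 MI; five PILs describe two groups); guess data for
17 FD + 10 DD + 1 MI groups (28 BI sets); continuous outcomes for 14 FD
and 10 DD comparisons (24 units, none from MI); per-arm sizes uniform on
16–88 so per-study SMD standard errors span ≈ 0.15–0.35; true subgroup
effects −0.12 (FD) and −0.43 (DD) with between-study SD `tau = 0.1` — a
mild heterogeneity consistent with the low-to-moderate within-stratum
inconsistency the stratified analysis reported, while the two stated
subgroup means themselves generate the large *between*-strata $I^2$.
Regional mix (P(Asia) = 0.30 under FD, 0.65 under DD/MI) reflects the
reported association between region and disclosure without reproducing
unavailable cell counts.

Guesses follow a minimal three-parameter model per category: a participant
*perceives* their true assignment with probability `p_perceive`, answers
don't-know with `p_dontknow`, and otherwise guesses "real" with the
wishful-thinking probability `w_wishful`. The model was chosen because it
is the smallest one that can realize all nine scenarios and has
closed-form expected BIs (real arm $p + r(2w-1)$, placebo arm $p +
r(1-2w)$, $r = 1-p-d$). The defaults were therefore *solved analytically*
against the published category means (0.42/−0.16 for FD, 0.41/−0.21 for
DD, shared by MI) with the don't-know rate fixed at 0.12 — a typical
don't-know fraction for end-of-trial guess questions — rather than tuned
by stochastic search; `solve_guess_params()` exposes the inversion.
Outcomes are simulated at the summary level (true placebo mean 0, SD 1;
observed means with sampling error, observed SDs as chi-square draws),
which is exactly the information a meta-analyst extracts.

Each placebo group draws from its own RNG substream derived from the
master seed, so a corpus is byte-reproducible and individual groups do not
change when category counts do.

What the generator does **not** emulate — so a green test does not
establish it: real PIL prose (snippets are templated around the lexicon,
so 100% coder agreement verifies the engine, not the lexicon's coverage of
field text); correlation between an arm's guesses and its outcome;
dropout, multiple timepoints, assessor unblinding; dichotomous outcomes or
shared multi-arm real arms (both supported by the analysis code and tested
directly, but not drawn by default); any systematic difference between
regions' true effects.

## Numerical and testing choices

* Percentages are rounded half away from zero to one decimal, matching the
  presentation convention of the summaries being reproduced.
* The exact Mann-Whitney branch enumerates all $\binom{n_1+n_2}{n_1}$
  assignments (≤ 12 870) and uses the two-sided rule $p = \min(1,
  2\min(P(U \le u), P(U \ge u)))$.
* The DerSimonian-Laird implementation is tested to 1e-10 against an
  independent loop-level reimplementation on random small meta-analyses,
  and the subgroup test's null calibration is checked by simulation
  through the full generator (rejection ≈ 5% under a shared true effect
  with the generator's heterogeneity; with `tau = 0` the test is mildly
  conservative, ≈ 3–4%, because the truncated $\hat\tau^2$ inflates
  subtotal standard errors — a known property of the estimator, not a
  defect).
* Wald CIs for BI are symmetric and can exceed $[-1,1]$ near the
  boundary; truncation is opt-in.
* Degenerate inputs fail loudly and early: empty guess tables, zero pooled
  SD, uninformative 2×2 tables, zero margins, subgroups with zero standard
  error all raise errors naming the problem.

## Known limitations

The coder is a keyword engine, not a replacement for dual-coder
qualitative content analysis; its shipped lexicon is a seed, not the full
coding manual. The blinding comparison inherits the low power of ~28 BI
sets. The published pooled statistics (−0.43 vs −0.12, subgroup χ² = 4.54,
regional χ² = 7.099) rest on per-study data that are not public, so they
serve here as calibration anchors for the synthetic world; the package can
reproduce their *structure*, not re-derive their exact values.
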