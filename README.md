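# pilblind

**pilblind** is an R toolkit for studying how the wording of *participant
information leaflets* (PILs) about a placebo control relates to blinding
success and trial outcomes in randomized placebo-controlled trials — the
setting where this question is sharpest is non-pharmacological trials
(e.g. acupuncture), where a "sham" procedure is hard to conceal and
investigators often hedge what the consent document says about it.

It is aimed at methodologists and systematic reviewers who have, per trial:
the PIL text describing the control condition, end-of-trial allocation-guess
tables, and per-arm outcome summaries — and who want to connect the three.

## What it computes

* **Disclosure coding** — rule-based classification of PIL text into
  *full disclosure* (FD: "sham", "placebo", "fake" …), *deceptive
  disclosure* (DD: neutral labels like "control group", "group two") and
  *missing information* (MI), with DD→FD escalation when a neutral label is
  accompanied by a sham-procedure description ("non-acupoint",
  "non-penetrating" …). The lexicon lives in a JSON config
  (`inst/extdata/disclosure_rules.json`); the engine, not the word list, is
  the contract.
* **Bang's blinding index** per arm,
  `BI = (n_correct − n_incorrect) / n` with "don't know" kept in the
  denominator, its multinomial-difference standard error and Wald CI, the
  threshold statuses (random guess for −0.2 < BI < 0.2, "unblinded" for
  BI ≥ 0.2, opposite guess for BI ≤ −0.2), and the 3×3 grid of nine
  blinding scenarios S1–S9. Group comparisons use a Shapiro-Wilk-gated
  independent t-test / Mann-Whitney U.
* **Effect sizes** — Hedges' g from continuous summaries
  (`var(g) = (n1+n2)/(n1 n2) + g²/(2(n1+n2))`), the logistic conversion
  `SMD = (√3/π) ln OR` from dichotomous tables (0.5 zero-cell correction),
  even splitting of shared arms in multi-arm trials, and a deterministic
  outcome-selection ladder (primary endpoint → common scale → clear data,
  closest to last treatment).
* **Meta-analysis** — DerSimonian-Laird random effects under generic
  inverse variance (`tau² = max(0, (Q − df)/C)`), with Cochran's Q /
  Higgins' I² subgroup-difference test on the subtotals, stratified by
  disclosure category. Negative SMD favors the real intervention.
* **Synthetic corpus** — a seeded generator of PIL snippets, guess tables
  and outcome summaries with known truth, calibrated analytically to
  published category summaries (mean BIs 0.42/−0.16 under FD, 0.41/−0.21
  under DD; subgroup SMDs −0.12 and −0.43), so the whole pipeline is
  testable without any external data.

## Worked example

```r
library(pilblind)

# 1. code a PIL snippet
classify_disclosure("You will be assigned to group one or group two.")$category
#> [1] "DD"

# 2. blinding index for a placebo arm: 24 guessed "real", 14 "placebo", 12 don't know
assess_blinding(guess_table("placebo", 24, 14, 12))
#> bi = -0.2, se = 0.12, CI (-0.435, 0.035), status "opposite_guess"
# a fifth of the arm guessed *the other* treatment beyond chance - wishful thinking

# 3. full pipeline on a synthetic corpus with known truth
corpus <- generate_corpus(sim_config(), seed = 42)
summarize_categories(code_corpus(corpus$pils)$category)
#>   category  n  pct
#> 1       FD 40 57.1
#> 2       DD 25 35.7
#> 3       MI  5  7.1

pooled <- pool_by_subgroup(compute_effects(corpus$outcomes))
pooled$subgroups$FD
#> <meta_result> k = 14: pooled -0.1144 [-0.2277, -0.0011], p = 0.04786
#>   Q = 15.3336 (df 13), tau2 = 0.0071, I2 = 15.2%
pooled$subgroups$DD
#> <meta_result> k = 10: pooled -0.3467 [-0.4792, -0.2142], p = 2.94e-07
#>   Q = 6.0155 (df 9), tau2 = 0.0000, I2 = 0.0%
pooled$comparison
#> <subgroup_comparison> 2 subgroups: Q = 6.8185 (df 1), p = 0.009022, I2 = 85.3%
```

The subgroup comparison says the deceptively-disclosed (DD) studies pooled
to a substantially larger advantage for the real intervention (−0.35) than
the fully disclosed ones (−0.11) — the corpus was generated with true
subgroup effects −0.43 and −0.12, so both subtotals land within their CIs.

An end-to-end run that also writes the disclosure summary, per-arm BI
table, scenario grid, BI comparison, and forest table:

```r
paths <- write_corpus(corpus, "inputs/")
cfg <- pipeline_config(pils_path = paths[["pils"]],
                       guesses_path = paths[["guesses"]],
                       outcomes_path = paths[["outcomes"]],
                       out_dir = "results/")
bundle <- run_pipeline(cfg)
```

or from the shell:

```sh
Rscript inst/cli/pilblind.R simulate --out inputs --seed 42
Rscript inst/cli/pilblind.R run-all --pils inputs/pils.jsonl \
    --guesses inputs/guesses.csv --outcomes inputs/outcomes.csv --out results
```

## Documentation

See the methods vignette (`vignettes/pil-disclosure-and-blinding.Rmd`) for
the statistical model, the synthetic-data generator's assumptions and
limitations, and the numerical design choices.
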