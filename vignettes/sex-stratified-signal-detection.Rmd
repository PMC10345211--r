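---
title: "Sex-stratified disproportionality analysis of spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-stratified disproportionality analysis of spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigiprof)
library(dplyr)
```

## The problem

Spontaneous-report databases such as FAERS collect drug–adverse-event
co-mentions without denominators: there is no count of how many patients
took a drug and had *no* event. Disproportionality analysis works around
this by asking, for each (drug, event) pair, whether the pair is reported
more often than the database background predicts under independence. For
drug classes prescribed very differently to women and men — benzodiazepines
and Z-drugs are a canonical example — running the whole analysis separately
per sex exposes signals that a pooled analysis dilutes.

`vigiprof` implements that analysis end to end: ingestion of report tables,
per-sex 2×2 contingency tables and the four standard disproportionality
statistics, conventional signal screening, aggregation of screened signals
up a MedDRA-style hierarchy, a paired sex-contrast step, and a
chemical-similarity companion used to ask whether chemically similar drugs
share safety profiles. A synthetic report generator with known ground truth
makes each stage testable without access to a licensed extract.

## Model and statistics

For one sex stratum, the 2×2 table of a (drug, event) pair counts
combinations, not cases: `a` = the drug with the event, `b` = other drugs
with the event, `c` = the drug with other events, `d` = the rest;
`n = a + b + c + d`. The comparator for `b` and `d` is the whole database
(every other drug in the table), the convention under which the standard
thresholds below were validated.

The statistics, with `aexp = (a + b)(a + c) / n` the count expected under
independence:

* information component `IC = log2((a + 0.5) / (aexp + 0.5))` — the 0.5
  continuity correction keeps IC finite at `a = 0`;
* its lower 95% credibility bound
  `IC025 = IC − 3.3 (a + 0.5)^{−1/2} − 2 (a + 0.5)^{−3/2}`, the closed-form
  approximation used in routine signal detection; it is strictly below IC
  and heavily penalises small `a`;
* `PRR = (a / (a + c)) / (b / (b + d))` and `ROR = ad / bc`. Ratios whose
  denominators vanish (`b = 0`, `a + c = 0`, `b + d = 0`, `bc = 0`) are
  carried as explicit `NA` sentinels rather than infinities, so screening
  and serialisation stay deterministic.

Pool 1 holds one record per observed pair; pool 2 is the screened subset
with `PRR > 2`, `IC025 > 0` (both strict) and `a ≥ 5`. The strictness
matters at the boundary: a pair with PRR exactly 2, IC025 exactly 0, or
four records is excluded, and the tests pin those cases.

```{r metrics}
t_sig <- list(a = 50, b = 50, c = 50, d = 850)
c(ic = compute_ic(t_sig), ic025 = compute_ic025(t_sig),
  prr = compute_prr(t_sig), ror = compute_ror(t_sig))
```

## Hierarchy aggregation

Individual preferred terms (PTs) are too granular to compare drugs, so
screened signals are summed up the hierarchy: `cIC025(drug, group)` is the
sum of the drug's positive IC025 values over PTs mapping into a high-level
group (HLG) or system organ class (SOC), and `ScIC025(group)` is the sum of
cIC025 over all drugs. Only positive IC025 values ever contribute — a
negative value means "reported less than expected", which must not cancel
genuine signal mass. Two aggregation modes are supported and named in every
output, because both occur in practice: `"pool2"` (screened records only)
and `"pool1-positive"` (every positive IC025 regardless of the screen). The
package default is `"pool2"`, the conservative reading of a screen-then-
aggregate pipeline; the alternative is one argument away.

Derived quantities: the *drug percentage* `100·cIC025/ScIC025` within a
SOC (shares sum to 100 by construction), the *report percentage*
`100 × (drug's reports in an HLG) / (drug's total reports)` computed from
raw counts rather than IC values, rankings with alphabetical tie-breaks for
reproducibility, and group decompositions per PT with an optional
combined-sex cutoff. Groups may be merged (e.g. a "neuropsychiatric" union
of the nervous-system and psychiatric SOCs) by passing several group names;
a record contributes once even if its PT sits under more than one merged
parent. PTs absent from the supplied map are excluded from aggregation but
retained in the pools, each exclusion counted.

## Sex contrast

Female and male pool-2 records are outer-joined per (drug, PT). Pairs
positive in both sexes get the dominance ratio `max/min` of the two IC025
values; at or above the 2:1 threshold they are classified female- or
male-dominant. Pairs present on one side only — or present on both but
positive on one — are `female_only`/`male_only`: a ratio of signed
logarithmic quantities is not meaningful, so one-sided pairs bypass the
ratio filter entirely. (How pairs with one negative side should be plotted
is genuinely underdetermined; treating them as one-sided is this package's
declared convention.) The classification is exhaustive, mutually exclusive
and symmetric under swapping the sex labels, which the property tests
exercise directly.

## Chemical-similarity companion

The package consumes, rather than generates, descriptor matrices and
conformer-overlay similarity reports (those upstream stages require
external, partly proprietary tools). A ROCS-style report with scores per
conformer pairing is reduced per stereoisomer pair by taking the maximum
score over all pairings and both directions, then converted to the shape
distance `D = 1 − S/S_max` (`S_max = 2` for the combo score, 1 for shape or
colour), giving a symmetric matrix in [0, 1] with zero diagonal. Descriptor
matrices are standardised and projected by PCA, with component signs fixed
so the largest-magnitude loading is positive. Hierarchical clustering uses
average linkage by default — the linkage behind the original dendrograms is
not recorded anywhere we could verify, so this is an interpretation, kept
configurable. The profile comparison draws a drug's top screened events and
the comparator's values from pool 1, so negative associations of the
comparator remain visible, and a comparator with no record at all is marked
explicitly rather than imputed.

## The synthetic generator

`generate_reports()` draws, per sex, a multinomial sample over the joint
table `p(drug)·p(pt)`, optionally multiplied cell-wise by injected factors
`lam` and renormalised. The reference conditions
(`default_sim_config()`) are 30 drugs and 150 PTs with Zipf-shaped
marginals — mimicking the heavily skewed report volumes of real
pharmacovigilance data — and 200,000 combinations per sex, the size at
which the recovery study is run; `study_injections()` places five signals
with `lam ∈ {4, 8, 16}` at mid-rank marginals, where baseline expected
pair counts are in the tens and the empirical PRR approximates `lam`.
Smaller sizes (5,000–50,000) are used where a test only needs the
mechanics, not the calibration.

What the generator does *not* emulate: case-level polypharmacy (sampling is
at the pair level, which is all the downstream statistics observe),
duplicate reports, reporting dynamics over time, and indication bias. A
passing recovery test therefore shows the statistics and screening recover
known multiplicative distortions of an independence baseline — it does not
certify behaviour under the confounding structure of real FAERS data.

## Numerical and design choices

* All metrics in double precision; log base 2 and the 0.5 continuity
  correction are fixed constants of the method.
* Undefined ratios: `NA`, never `±Inf`; screening treats `NA` as "fails".
* Ties in every ranking break alphabetically; all outputs are reproducible
  from the serialised pool TSVs alone.
* The generator scopes its RNG locally: it never disturbs the caller's
  random-number stream, and one integer seed governs a whole run.
* Unknown-sex rows are dropped (and counted) at ingestion; offspring-
  related records are handled by an externally supplied exclusion list,
  never by automated classification.
* Drug-name normalisation is exact (lowercase, trimmed, synonym lookup);
  fuzzy matching is deliberately absent for auditability.

## Worked example

```{r pipeline}
inj <- study_injections()
cfg <- default_sim_config(n_reports = 5e4, injections = inj, seed = 42)
rows <- generate_reports(cfg)
map <- toy_hierarchy_for(cfg)

strata <- split_by_sex(rows)
pool1 <- bind_rows(lapply(strata, score_all_pairs))
pool2 <- screen_signals(pool1)
semi_join(pool2, inj, by = c("drug", "pt")) |>
  select(sex, drug, pt, a, ic025, prr) |>
  arrange(drug, sex)
```

All injected pairs pass the screen and the empirical PRR tracks the
injected multiplier. Aggregation and the sex contrast continue from the
pools:

```{r agg}
screened <- screen_signals(pool1, keep_all = TRUE)
scic025_table(screened, map, level = "soc")
cls <- classify_pairs(pair_signals(pool2[pool2$sex == "female", ],
                                   pool2[pool2$sex == "male", ]))
table(cls$class)
```

## Limitations

Disproportionality is a screening statistic, not an incidence estimate: no
prescription denominators, no causality, no multiple-comparison control
(the method applies none, by design — IC025's small-count penalty is its
protection). The external benchmark — reproducing published sex-specific
IC025/PRR values for selected drug–event pairs from a curated FAERS
extract — requires the licensed extract and dictionary and therefore runs
only when those inputs are supplied locally; everything else in the test
suite is self-contained.
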