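---
title: "Disproportionality screening of spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous-report databases such as the FDA Adverse Event Reporting System
(FAERS) collect voluntary reports linking one patient to one or more drugs
and one or more adverse reactions coded as MedDRA preferred terms (PTs).
They have no denominator — nothing says how many patients took a drug
without incident — so incidence cannot be estimated. What *can* be estimated
is disproportionality: whether a target event is reported more often with a
target drug than with everything else in the database. pvsignal implements
the standard frequentist pair of disproportionality measures, the reporting
odds ratio (ROR) and the proportional reporting ratio (PRR), on top of a
reproducible cleaning pipeline, and ships a synthetic-report generator with
known ground truth so the whole pipeline can be validated end to end without
access to a regulator's database.

## The model

Every drug–event pair partitions the cleaned database into a four-fold
table: `a` reports with drug and event, `b` with the drug only, `c` with the
event only, `d` with neither, `N = a+b+c+d`. The counting unit is the unique
report: a report naming the drug twice counts once, and a multi-drug report
sits in the exposed margin of each of its drugs.

The two measures are

$$\mathrm{ROR} = \frac{a\,d}{b\,c}, \qquad
  \mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}.$$

The ROR gets a Wald 95% interval on the log scale,
$\exp(\ln \mathrm{ROR} \pm 1.96\,\sqrt{1/a+1/b+1/c+1/d})$, and the PRR is
accompanied by the Yates continuity-corrected chi-square

$$\chi^2 = \frac{(|ad-bc| - N/2)^2\,N}{(a+b)(c+d)(a+c)(b+d)},$$

clamped to zero when the correction overshoots ($|ad-bc| \le N/2$), since a
squared corrected statistic cannot be negative. A drug–event pair is called
a **signal** when it has at least 3 target reports ($a \ge 3$) and meets at
least one of:

* ROR criterion: lower 95% CI bound above 1;
* PRR criterion: $\mathrm{PRR} \ge 2$ and $\chi^2 \ge 4$.

The disjunction is deliberate — either method alone suffices — and the
$a \ge 3$ floor suppresses signals resting on one or two reports.

Because the Wald interval is symmetric in log space, the point estimate is
always the geometric mean of its bounds; `point_from_ci()` exposes this
inversion, which is also a useful consistency check on any published
ROR (95% CI) triple.

### Numerical choices

* Cell counts are coerced to double before any product: at database scale
  ($N \sim 10^5$ and beyond) `a*d` overflows 32-bit integers.
* A table with a zero cell leaves the ROR undefined under the default
  policy (`ror_defined = FALSE`, estimates `NA`) — the ratio `ad/bc` is
  taken literally. The opt-in Haldane–Anscombe policy (`zero_cell =
  "haldane"`) adds 0.5 to every cell of the affected table instead. Since
  signals need $a \ge 3$, zero-`a` tables are moot either way; the policy
  mostly matters for `b = 0` boundary tables.
* The PRR is undefined when either exposure row is empty or `c = 0`; the
  chi-square is `NA` when any margin is zero.
* 1.96 is used literally as the normal quantile.
* Displayed tables round half-up (commercial rounding) to 2 decimals for
  ratios and 1 decimal for percentages; internal computation is full
  precision. Base R's `round()` rounds half to even, so the package carries
  its own `round_half_up()`.

## Cleaning rules

Cleaning runs standardization → deduplication → exclusions, in that order,
so that duplicate keys compare standardized names (two spellings of the
same generic should collapse, not survive as distinct keys).

* **Standardization** is exact case-insensitive lookup in a user-supplied
  synonym map. Unresolved names are flagged and kept — silently dropping
  them would bias the `d` cell. Combination products (more than one active
  ingredient) keep a single combined identity; they are never split into
  components. Fuzzy matching is out of scope.
* **Deduplication** applies two rules. Reports identical on (case
  identifier, receipt date, standardized drug set) are duplicates and
  exactly one survives. Among reports of the same case with the same
  medication profile across dates, only the latest survives. We group the
  latest-retention rule by the full drug set rather than per single drug:
  per-drug grouping would discard a report that is the latest evidence for
  one of its drugs merely because another of its drugs reappears later.
  Ties keep the lexicographically greatest report identifier, which makes
  the operation deterministic and independent of input order; missing dates
  sort earliest so dated evidence is preferred. The operation is idempotent.
* **Exclusions** (non-pharmaceutical products, withdrawn drugs) remove drug
  entries; reports left drug-less are dropped and counted in the cleaning
  report, whose stage counts are monotone non-increasing.
* **Event matching** is exact on the normalized PT string — no Standardised
  MedDRA Query expansion, so "Angioedema hereditary" does not match
  "angioedema".
* **Outcome severity.** When a report carries several outcome flags and one
  final outcome is needed, the most severe is taken under the fixed order
  `DE > LT > HO > DS > CA > RI > OT` (death, life-threatening,
  hospitalization, disability, congenital anomaly, required intervention,
  other). No regulatory ordering of these flags exists; this is the
  conventional seriousness hierarchy with death worst, and it is applied
  deterministically.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `event` | `"Angioedema"` | target MedDRA PT, matched exactly |
| `min_reports` | 3 | minimum `a` for any signal |
| `top_n` | 30 | screen the most-reported drugs (by `a`) |
| `zero_cell` | `"none"` | zero-cell policy; `"haldane"` adds 0.5 |
| dialect | `"csv"` | `"tsv"` and `"faers_ascii"` (`$`-delimited) presets |

Screening ranks drugs by `a` descending (ties alphabetical) for selection,
and reports `ror_rank` — the ordering by signal strength — within the
selected set. Whether counting should use suspect drugs only cannot be
decided here: the report schema carries no role field, so all reported
drugs count; restricting to suspect drugs would need an upstream filter.

## Category rollups

`rollup_categories()` maps each standardized drug to one therapeutic
category and rebuilds the four-fold tables at category level, still
counting unique reports: two same-category drugs in one report count once,
a report spanning categories counts in each, and every category's `N` is
the dataset `N`. A packaged best-effort map
(`inst/extdata/drug_categories.csv`) assigns 30 frequently reported drugs
to 10 categories (cardiovascular drugs, anti-inflammatory analgesics,
antithrombotic agents, antibiotics, digestive system drugs,
immunosuppressors, blood sugar control drugs, antiallergic drugs,
antiasthmatics, antitumor drugs); a handful of assignments are genuinely
ambiguous (omalizumab sits between antiallergic and antiasthmatic use;
pregabalin is grouped with the analgesics by indication) and users with a
real ATC mapping should supply their own file.

## What the synthetic generator emulates — and what it does not

`generate_reports()` draws, per report: independent per-drug exposure from
catalog marginals (at least one drug enforced by redrawing empty rows);
the target event from a logistic model whose odds are the background odds
multiplied by the true odds ratio $\theta_X$ of every exposed signal drug;
demographics, country, receipt year and outcome flags i.i.d. from
categorical marginals; plus a configurable fraction of injected exact
duplicates (fresh report id, same case, date and drugs). Under this model
the population reporting odds ratio of a lone signal drug equals its
$\theta$ exactly, which is what makes parameter-recovery and coverage
experiments meaningful; with several simultaneous signal drugs the marginal
odds ratios deviate only by the non-collapsibility of the odds ratio,
negligible at the default marginals.

Default marginals are chosen to resemble a large angioedema cohort: sex
46.9/44.0/0.8% F/M/other with 8.3% missing, age bands 4.9/37.6/36.2% with
21.2% missing, reporters dominated by health professionals (72.8%), years
uniform on 2004–2023, and a 10% duplicate rate consistent with the shrink
of a raw extract after cleaning. The outcome mixture anchors
hospitalization at 30% and fills the remaining codes with plausible masses
(published per-code percentages for such cohorts are mutually inconsistent,
so the mixture is a modeling choice, not a reproduction). Ages are drawn
uniformly within bands — enough for band-level descriptives, wrong for any
finer age analysis.

The generator does **not** emulate: misspelled or free-text drug names
(standardization is exercised with hand-built fixtures instead), secular
reporting trends beyond the categorical year marginal, correlated
polypharmacy (exposures are independent), reporting biases (media
attention, stimulated reporting), country-specific demographics, or the
MedDRA hierarchy (reactions are flat PT strings). Green pipeline tests
therefore show correctness of the counting and statistics under clean,
independent exposures — they do not certify behaviour on the messier joint
distributions of real pharmacovigilance data.

## Validation design

Four kinds of checks back the statistics (sizes are the package's own
validation choices):

* **Counting** is compared against an explicit brute-force double loop over
  reports at $10^4$ synthetic reports, and category tables against
  brute-force set-union counting.
* **Formulas** are compared to independent routines: the log-ROR and its
  Wald SE against a saturated binomial GLM (Fisher scoring seeded at the
  closed form, agreement to $10^{-9}$ relative), and the chi-square against
  `stats::chisq.test(correct = TRUE)`, which applies the identical
  clamped Yates correction.
* **Null calibration**: with $\theta = 1$ and expected $a \approx 50$
  (5 000 reports, exposure 0.1, background event rate 0.1), the one-sided
  ROR criterion fires in about 2.5% of 500 simulated datasets.
* **Coverage**: with injected $\theta \in \{2, 5, 20\}$ at $10^5$ reports,
  the 95% CI covers $\theta$ in 90–99% of 200 replicates per $\theta$.

## Known limitations

Disproportionality is hypothesis-generating, not causal: no denominator, no
confounding control, no multiplicity adjustment (none is applied, matching
standard practice for these thresholds). Duplicate detection is exact-key
only — near-duplicates from manufacturer resubmissions with edited fields
survive. Exact PT matching undercounts events split across related PTs; an
SMQ-based analysis would need the MedDRA dictionary, which licensing keeps
out of scope. The `faers_ascii` dialect is a delimiter preset, not a full
parser for the raw FAERS quarterly schema.
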