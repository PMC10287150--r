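---
title: "The GR suitability index and its survey analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The GR suitability index and its survey analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grindex)
```

## The problem

Many federally listed vertebrates persist as small, fragmented populations
suffering from inbreeding depression, low genetic variation, and demographic
stochasticity. *Genetic rescue* — an increase in population fitness caused by
restored gene flow — can be engineered by *assisted migration*: deliberately
translocating individuals between isolated populations. Deciding which
species are plausible beneficiaries requires weighing the classic
small-population symptoms against the risks of outbreeding depression and
the practical barriers to moving animals.

`grindex` implements a structured triage for that decision: a nine-question
suitability score (the **GR index**) computed from coded survey answers, a
candidacy classification, and the complete tie-corrected nonparametric test
battery used to analyse how the index distributes across taxonomy,
geography, listing status, life history, management history and data
completeness. A seeded synthetic-cohort generator makes every stage testable
without any external data.

## The scoring model

Each surveyed species carries nine coded answers. Questions 1–4 capture
benefit signals and can only add to the score; questions 5–9 capture risk
signals and can only subtract:

| Question | Meaning | Codes |
|---|---|---|
| Q1 | inbreeding depression | signs = 2, concern = 1, explicitly none = 0, not mentioned = NA |
| Q2 | low genetic variation concern | yes = 1, none stated = 0, NA |
| Q3 | small population size concern | yes = 1, none stated = 0, NA |
| Q4 | population genetic survey exists | yes = 1, no = 0 (no NA state) |
| Q5 | ploidy variation between populations | yes = −1, diploid = 0 (no NA state) |
| Q6 | only option crosses adaptively differentiated populations | yes = −1, no = 0, NA |
| Q7 | only option crosses distinct ecoregions | yes = −1, no = 0 (no NA state) |
| Q8 | disease concerns for crossing | yes = −1, none = 0, NA |
| Q9 | population-specific behaviours complicate translocation | yes = −1, NA (no 0 state) |

The index is the plain integer sum with **NA treated as zero**:

$$\mathrm{GR} = \sum_{k=1}^{9} q_k \,[\,q_k\ \text{observed}\,],
\qquad \mathrm{GR} \in [-5,\, 5].$$

The bounds follow from the per-question extrema (2+1+1+1 positive, five −1
risks). Species with GR at or above a threshold (default **2**) are flagged
as candidates worth evaluating; the threshold is configurable because the
index is advisory, not prescriptive. Missing-answer burden is tracked
separately as the count of NA answers among the six NA-capable questions
(Q1, Q2, Q3, Q6, Q8, Q9), so "unknown" never masquerades as "no concern" in
any analysis, even though both contribute zero to the sum.

One subtlety: the NA-as-zero arithmetic means replacing any NA with an
explicit 0 leaves the sum unchanged — but Q9's code book defines no 0
state, so such a substituted vector is not *valid* survey data.
`compute_gr_index()` therefore validates by default and exposes
`validate = FALSE` for the raw arithmetic path; the test-suite asserts the
substitution invariance on that path and strict Table-code validation on
the default path.

## Eligibility and recodings

Records enter the analysis only if rescue-by-translocation is conceivable.
`apply_eligibility_filters()` applies record-level flags in a fixed order —
NatureServe presence, fewer than 2 populations or likely extinct, island,
marine, US range — logging each exclusion with the first rule violated.
These flags are survey inputs, not geographic computations: the original
calls were made manually, and the package does not second-guess them.

Three recodings feed the tests:

* `priority_category()`: US FWS Recovery Priority number 1–6 → High,
  7–12 → Moderate, 13–18 → Low (ordered).
* `life_history_class()`: age at maturity strictly below 4 yr → *fast*,
  4 yr or older → *slow*. The cutoff is a parameter (`cutoff_years`, years).
* `populations_ordinal()`: a populations-remaining range label becomes its
  0-based rank in an ordered catalogue. Only the two lowest labels
  ("1 to 5", "6 to 20") are fixed by convention; the default catalogue
  continues "21 to 80", "81 to 300", ">300" (NatureServe-style breaks) and
  is configurable as a data-source dialect.

## The nonparametric battery

GR indices are integers with heavy ties, so every procedure is rank-based
and tie-corrected. All p-values are two-sided.

**Mid-ranks.** Tied values share the mean of the ranks they occupy;
`midranks()` also records each tie-group size $t$, feeding the correction
term $\sum(t^3 - t)$.

**Kruskal–Wallis.** For $k$ groups with pooled rank sums $R_j$,

$$H = \frac{\dfrac{12}{N(N+1)} \sum_j R_j^2/n_j \; - \; 3(N+1)}
{1 - \sum(t^3 - t)/(N^3 - N)},$$

with $P(\chi^2_{k-1} \ge H)$. The chi-square approximation is used at all
sample sizes (no exact small-sample tables), matching the convention of the
statistics environment such surveys are analysed in. All-identical input is
a degenerate-input error (the correction denominator vanishes).

**Dunn's post-hoc.** When the parent $H$ is significant at `alpha`
(default 0.05; the gating is configurable), pairwise comparisons use the
shared pooled ranking:

$$z_{ij} = \frac{\bar R_i - \bar R_j}
{\sqrt{\left[\dfrac{N(N+1)}{12} - \dfrac{\sum(t^3-t)}{12(N-1)}\right]
\left(\dfrac{1}{n_i}+\dfrac{1}{n_j}\right)}},$$

with Bonferroni adjustment $p_{\text{adj}} = \min(1,\, m\,p)$,
$m = k(k-1)/2$. The sign convention is first minus second group, so
$z(a,b) = -z(b,a)$; with $k = 2$ untied groups, $H = z^2$ exactly (a tested
identity).

**Mann–Whitney.** $U$ counts pairs with $x_i > y_j$ (ties ½), identically
$W = R_1 - n_1(n_1+1)/2$; both names are reported because the literature
prints "W", whose value depends on group orientation ($W + W' = n_1 n_2$).
Orientation defaults to sorted label order and is configurable
(`mw_first_level`). The p-value is exact — full enumeration of the
permutation null via the standard counting recursion — when both $n \le 20$
and no ties exist; otherwise a normal approximation with tie-corrected
variance and continuity correction 0.5. The exact two-sided p doubles the
smaller tail and caps at 1.

**Kendall's τ~b~.** Both survey variables in each correlation (GR index and
an ordinal covariate) are heavily tied, so the tie-aware normalization is
used — τ~a~ would be bounded away from ±1:

$$\tau_b = \frac{C - D}{\sqrt{(n_0 - n_1)(n_0 - n_2)}},$$

with the standard tie-adjusted normal approximation for $S = C - D$.

**Fisher's exact r×c.** The p-value sums multivariate-hypergeometric
probabilities, conditional on the margins, over all tables whose
probability is at most that of the observed table (relative tolerance
10⁻⁷, applied in log space). Enumeration runs when the total count is
≤ 200 *and* a crude free-cell product bound on the number of tables is
≤ 2×10⁵ — a deliberately conservative engineering bound for a pure-R
recursion; larger problems fall back to Monte-Carlo sampling of
margin-conditioned tables (Patefield's algorithm), always recording
`n_reps` and `seed`. The Monte-Carlo estimate uses the add-one convention
$(1 + \text{hits})/(1 + n_{\text{reps}})$, which can never report exactly 0.

**Tail functions.** `chi_square_upper_tail()` and `normal_two_sided_p()`
wrap the base R distribution functions (the canonical implementations of
the regularized incomplete gamma and the complementary error function);
their contracts — closed form $e^{-x/2}$ at df = 2, the normal-quantile
identity at df = 1, symmetry and monotonicity — are tested directly.

## The pipeline

`run_full_analysis()` scores the cohort and runs, per test, on
complete cases for that test's variables (records missing a variable are
dropped *per test*, and every entry logs its effective n and dropped
count, so divergences from any externally printed statistic are
diagnosable): Kruskal–Wallis of GR by evaluator, taxonomic group, Lead
Region, populations category and translocation status; Dunn follow-ups
gated on significance; Mann–Whitney by listing status and life-history
class; Fisher r×c of translocation status × taxonomic group; Kendall τ~b~
of GR against the populations ordinal, the missing-answer count and the
priority-category ordinal; and Kruskal–Wallis of the populations ordinal by
translocation status with its own Dunn follow-up. A grouping variable with
fewer than two non-empty levels marks that test *skipped with a reason*
(e.g. an absent evaluator column), never a pipeline failure. Reports render
as lossless JSON, a CSV bundle (tabular stand-ins for the usual
distribution figures), or markdown.

## The synthetic-cohort generator

`generate_cohort()` emulates the *statistical shape* of a post-filtering
survey cohort: per-question categorical code frequencies including NA mass
(zero where the code book defines no NA state), five taxonomic groups,
eight Lead Regions, listing status, an ordered populations category with NA
mass, gamma-distributed age at maturity spanning both sides of the 4-yr
cutoff (shape 2, scale 1.75 yr: mean 3.5, ≈ 59% fast), and three evaluator
labels.

The translocation association is generative, not asserted: responses are
sampled first, the GR index computed, then translocation status drawn from
a multinomial logit whose *implemented* logit is shifted by
$\beta\,(\mathrm{GR} - E[\mathrm{GR}])$. $\beta = 0$ gives exact
independence (used for null calibration); the default $\beta = 0.5$ is a
moderate positive association, and the structure-recovery tests use
$\beta = 1.5$ as their "large" coefficient — a value fixed a priori, at
which the implemented group's mean GR shifts by roughly one index point.
Centering on the analytic $E[\mathrm{GR}]$ keeps the marginal translocation
frequencies near their baseline (defaults 0.44 / 0.20 / 0.36 for
implemented / considered / not mentioned, the magnitudes typical of
recovery documentation).

Default question tables were chosen once so that concerns about small
populations and low variation are common, risk answers are mostly missing,
and the implied candidate fraction sits near two-thirds: under the
defaults the exact convolution gives $P(\mathrm{GR} \ge 2) = 0.621$ and
$P(\mathrm{GR} = 2) = 0.335$. This is a default shape for testing, not a
claim about any real cohort.

What the generator does **not** model: phylogenetic or geographic
covariance among species, correlation between answers within a species
beyond the GR–translocation link, evaluator effects, or any relationship
between taxonomy and the response tables. A green test therefore
establishes that the pipeline's algebra, bookkeeping and calibration are
correct under a known generative model — not that any substantive field
result is reproduced.

## Numerical choices and degenerate inputs

* GR scoring is integer arithmetic throughout; no floating point.
* The Fisher observed-probability comparison uses relative tolerance 10⁻⁷
  in log space (`log1p(1e-7)`), protecting against ties in table
  probability being split by rounding.
* Monte-Carlo paths (Fisher fallback) are always explicitly seeded; the
  generator and pipeline restore the caller's RNG state, so identical
  config + seed is bit-identical and surrounding code is undisturbed.
* Degenerate inputs fail loudly and specifically: empty samples, all-tied
  rank tests, constant variables in τ~b~, out-of-range codes naming row and
  field. NA in Q4/Q5/Q7 — where the code book defines no missing state — is
  surfaced as a validation error rather than silently coerced to 0.
* Dual listings (multiple DPS rows) are assumed collapsed upstream; the
  reader rejects multi-valued listing status rather than guessing.

## Known limitations

* The Mann–Whitney exact/approximate switch (ties or n > 20) reproduces the
  convention needed for comparability with standard survey analyses; other
  environments switch at different sample sizes, so exact p-values can
  differ in the 20 < n < 50 range.
* Dunn p-values are plain two-sided normal tails with Bonferroni; no other
  multiple-testing procedures are provided.
* The Fisher enumeration bound is conservative; genuinely enumerable
  mid-size tables may take the Monte-Carlo route (with recorded seed).
* The populations catalogue above its two lowest labels is a configurable
  dialect; analyses using the ordinal ranks depend on it only through
  order, not spacing.
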