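---
title: "Methods: equianalgesic conversion, patch rounding and audit analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equianalgesic conversion, patch rounding and audit analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omeconvert)
```

## The conversion model

Equianalgesic conversion translates a dose of one opioid, given by one
route, into the dose of another opioid/route expected to provide equivalent
analgesia. Guidelines publish these equivalences as ratio tables anchored on
oral morphine. `omeconvert` encodes that anchoring directly: every supported
continuous drug/route carries a single factor $f$ (mg of 24-hour oral
morphine equivalent, OME, per unit dose), and conversion is the two-step hub
map

$$\mathrm{OME} = d_A \cdot f_A, \qquad d_B = \mathrm{OME} / f_B.$$

The hub design is a deliberate choice over a dense pairwise ratio matrix.
With one factor per drug/route, identity ($A \to A$), round-trip
($A \to B \to A$) and transitivity ($A \to C$ versus $A \to B \to C$) hold
*by construction* up to floating-point error, and the test suite asserts all
three at $10^{-9}$ relative tolerance. A pairwise matrix can silently
violate transitivity when one cell is edited; here the matrix exists only
inside the independent test oracle (`pairwise_oracle()`), which computes
$d_B = d_A f_A / f_B$ directly with no shared code, precisely so the two
routes can disagree if either is wrong.

Model assumptions worth stating: factors are symmetric (the same $f$ serves
both directions — published direction-specific dosing advice would be
encoded as explicit per-direction overrides in the formulary, which default
to absent), conversions do not apply an automatic cross-tolerance reduction
(an opioid switch is not simply arithmetic, and a tool that silently reduced
doses would misstate what it computed; the prescriber owns that decision),
and methadone is structurally excluded — its long and variable half-life
makes table-based conversion unsafe, so requests touching it return
`unsupported_drug` rather than a number.

## Units, parameters and defaults

Units are fixed by route and never travel inside numeric fields: oral and
subcutaneous doses are mg per 24 h, transdermal strengths are µg per hour.
This removes the unit-confusion error class at the type level.

Tunable values are formulary *data*, never code constants:

| parameter | default | unit | meaning |
|---|---|---|---|
| `breakthrough_divisor` | 6 | — | rescue dose = daily dose / divisor; one sixth of the 24-h dose is conventional palliative practice |
| `egfr_warning_threshold` | 30 | mL/min | below this, renally risky drugs trigger `renal_caution` |
| `practical_increments` | `oral: 2.5` (in F1) | mg | deliverable-dose grid for practical rounding |

The renal caution fires only when an eGFR was actually supplied: an absent
value produces *no* warning rather than a blanket nag, because warning on
missing data would change the documented contract ("warn in impaired renal
function") into a different one. The caution is attached to the conversion
*target* — the drug about to be prescribed — while `renal_warning()` itself
can be called for any drug. Breakthrough dosing refuses transdermal routes:
the formula needs a 24-hour dose, so patch users convert to OME first.

## Patch band selection and the border tie

Transdermal patches exist in discrete strengths, so a patch target maps the
OME into an ordered band table, each band an inclusive range
$[\mathrm{ome\_low}, \mathrm{ome\_high}]$ with adjacent bands allowed to
share a border value. The selection rules, in order:

1. OME strictly inside one band: that band.
2. OME exactly on a shared border: the **lower-strength** band. Rounding
   down is the single safety direction used everywhere in the engine
   (practical rounding floors too); rounding *up* at exactly this border is
   a historical tool defect whose signature — every border-exact
   calculation, and only those, disagreeing with the guideline table — the
   fixtures reproduce behind `patch_tie = "up"` for regression testing.
3. OME below the first band: no band, plus `below_smallest_patch` (the tool
   does not invent a sub-threshold patch).
4. OME above the last band: the largest band, plus `above_largest_patch`
   (combination patches are real practice; a warning keeps the tool honest
   without guessing a combination).
5. OME in a gap between non-contiguous bands: the band below (round down).

### Decimal safety

Whether an OME equals a band border is clinically meaningful and must not
depend on binary float representation (`0.1 * 600` is not bitwise `60`).
All *comparisons* — band membership, border equality, match-rate dose
equality — are therefore canonicalised to integer micro-milligrams,
`round(x * 1e6)`. Arithmetic itself stays in doubles, because forcing
intermediate doses onto a decimal grid would destroy the exact
inverse/round-trip property for factors like 30 (alfentanil): a micro-mg
grid cannot represent 10/30 mg. Canonical keys give exact decimal
comparisons; doubles give $10^{-16}$-level inverses; the combination
satisfies both requirements. Practical rounding computes
`floor(round(dose/increment, 9))` for the same reason, and never returns
zero for a positive dose — a dose below one increment returns the increment
itself with a `large_dose` warning, since the practical dose then *exceeds*
the exact dose.

## The audit layer

Every calculation can be captured as one append-only record (JSON-lines on
disk; fixed-order CSV export). The schema is closed: any field outside it is
rejected by name, and the only category-like field, `indication`, is
restricted to a closed list — that is how patient-identifiable free text is
kept out structurally rather than by policy. Record ids are gapless and
monotone; there is no update or delete operation.

`summarize_usage()` tallies drug-to-drug conversions by index and target
opioid (both columns sum to the conversion count — a conservation law the
suite asserts on arbitrary generated logs), counts breakthrough calculations
separately, and quarantines corrupt records by position instead of failing.

`match_rate()` reproduces an accuracy audit against a gold standard (here:
the pairwise oracle over the same formulary version; a version mismatch is a
hard error). Records with `no_guideline_equivalence` are excluded from
analysis — no reference value exists for them — and each remaining record's
final *practical* dose is compared, because rounding, not ratio arithmetic,
is where conversion tools historically diverge from guideline tables. Two
"no deliverable dose" outcomes (e.g. OME below the smallest patch on both
sides) count as a match: both computations reached the same refusal.
Percentages are rounded half-up to one decimal. With zero analyzable
records the rate is reported absent, never `0`.

## The trend test

Shifts in ordered survey categories (e.g. confidence bands, pre vs post) are
tested with the Cochran–Armitage linear trend statistic on a $2 \times k$
table with integer scores $s_i$: $T = \sum_i s_i b_i$ over the post row,
standardised by its exact conditional (hypergeometric) mean and variance
given the margins, with the two-sided p from the normal approximation
(no continuity correction). Positive $Z$ means the post row shifts toward
higher-score categories; identical rows give $Z = 0$, $p = 1$; reversing the
category order flips the sign exactly. Note `stats::prop.trend.test` uses
the $N$-denominator variance, so its chi-square equals $Z^2 \cdot N/(N-1)$
— the suite uses that identity as an extra cross-check.

The ground truth in tests is `ca_trend_permutation()`: pooled category
scores are re-drawn with both margins fixed, sampling the exact conditional
null. That null is *discrete* — at $n \approx 60$ the probability atom at
the observed deviation can be several percent — so a continuous
approximation can only be expected to land *inside* that atom. The oracle
therefore reports inclusive, exclusive and mid two-sided tails, and
agreement means the asymptotic p lies in
$[p_{\mathrm{excl}} - 3\,\mathrm{SE}_{MC},\; p_{\mathrm{incl}} + 3\,\mathrm{SE}_{MC}]$.
On random tables the mid-p tracks the normal p to about $10^{-3}$.

```{r trend}
tt <- trend_table(pre = c(10, 5, 5), post = c(5, 5, 10))
cochran_armitage_trend(tt)
ca_trend_permutation(tt, n_perm = 10000, seed = 42)[c("p.inclusive", "p.exclusive", "p.mid")]
```

## What the synthetic fixtures emulate — and what they do not

The fixture formulary `F1` (10 drug/route entries, one unsupported drug, one
patch table with four shared borders at OME 60/90/150/210) uses round,
distinct factors chosen for mental arithmetic; they deliberately differ from
any real guideline so tests can never be mistaken for clinical content.
`generate_requests()` draws seeded workloads over F1 with exact composition
(`round(frac * n)` border-exact, no-equivalence, unsupported and
breakthrough requests; doses on a 2.5 mg OME grid that excludes borders
except where tagged), using R's Mersenne-Twister so sequences are
reproducible across platforms. `build_study_log()` assembles an audit-shaped
workload — 210 conversions with 18 guideline gaps and 10 border-exact patch
hits, 76 breakthroughs, ~62% tagged "cancer pain" — and replays it through
either tie rule.

These fixtures exercise the *arithmetic surface* of a deployed tool: green
tests demonstrate that the conversion algebra, the border tie rule, the
exclusion bookkeeping and the defect signature are correct. They do not
demonstrate clinical validity of any real formulary's ratios, realistic
patient case mix or dose distributions, or inter-prescriber behaviour — all
of which live in the data a deployment supplies, not in this code.

## Problem sizes and numerical choices

The suite checks the algebra exhaustively over F1's 8 continuous pairs plus
1000-request seeded batches against the pairwise oracle; trend agreement
uses 20 seeded $2\times4$ tables (30 + 30 counts) at 20 000 resamples each,
and the single worked example at 100 000 resamples. Border epsilon checks
use $\pm 10^{-6}$ mg around every F1 border — one canonical key unit, the
smallest representable decimal step. Degenerate inputs fail loudly:
non-positive doses, negative eGFR, empty patch tables, single-category
trend tables and zero-variance tables are errors, not defaults.

## Known limitations

* Factors are scalar per drug/route: no dose-dependent equivalence curves
  (relevant to real transdermal-to-oral conversions at extremes).
* No cross-tolerance reduction, opioid-naïve starting doses, taper
  schedules, pediatric or acute-pain dosing — out of scope by design.
* A transdermal *index* converts only if the formulary supplies a factor for
  it; F1 deliberately does not, so patch-to-oral requests return
  `no_guideline_equivalence` there.
* The asymptotic trend p is a lattice approximation at small $n$; for
  reporting at $n \lesssim 30$ use the permutation p directly.
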