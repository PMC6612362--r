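# omeconvert

Equianalgesic opioid dose conversion for palliative-care decision support,
with a prescribing-audit analytics layer.

## The problem

Switching a patient from one opioid (or route) to another requires an
equianalgesic conversion through published tables of approximate
equivalence. These calculations are error-prone — conversion mistakes are a
leading class of opioid prescribing error — so clinical tools double-check
them. `omeconvert` implements the computational core of such a tool for
prescribers and for the analysts who audit its use:

* **Hub conversion.** Every dose is mapped to its 24-hour **oral morphine
  equivalent (OME)** and back: for index drug *A* with factor *f_A* (mg OME
  per unit dose) and target *B*,

  `dose_B = dose_A * f_A / f_B`,

  computed as `from_ome(to_ome(dose_A))`. Routing everything through the OME
  hub makes chained conversions exactly transitive, unlike a hand-maintained
  pairwise ratio matrix.
* **Patch band selection.** Transdermal strengths are discrete, so a patch
  target maps the OME into a band table (one strength per inclusive OME
  range). An OME landing **exactly on the border of two bands rounds down**
  to the lower strength — rounding down is the safety direction, and
  rounding up at exactly this border is a documented historical defect class
  this rule guards against (a `patch_tie = "up"` flag re-enables it for
  regression studies).
* **Safety rails.** Breakthrough (rescue) dose = daily dose / divisor
  (default 6); renal caution when eGFR < threshold (default 30 mL/min) and
  the drug is flagged; explicit `no_guideline_equivalence` /
  `unsupported_drug` statuses instead of fabricated numbers (methadone is
  never converted).
* **Audit analytics.** An append-only, patient-identifiability-proof audit
  log; per-opioid index/target usage tallies; gold-standard match rates with
  exclusion filtering; and a Cochran–Armitage trend test (with a
  permutation-null oracle) for ordered survey categories.

Conversion ratios are **data, not code**: they live in a YAML/JSON formulary
file (schema in `inst/extdata/formulary-schema.json`). The shipped formulary
`F1` is a synthetic test fixture — it is *not* clinical guidance.

## Worked example

```r
library(omeconvert)
f1 <- fixture_formulary_f1()

convert(f1, conversion_request("morphine", "oral", 60, "fentanyl", "transdermal"))
#> morphine oral 60 mg/24h -> fentanyl transdermal
#>   OME: 60 mg/24h
#>   practical dose: 12 microgram/h
#>   formulary: F1
```

60 mg/24h of oral morphine is OME 60, which sits exactly on the border of
the F1 fentanyl bands `12 µg/h ↔ OME 30–60` and `25 µg/h ↔ OME 60–90`: the
engine rounds **down** to the 12 µg/h patch. A renally impaired patient gets
a caution and a guideline gap gets a refusal, never a guess:

```r
convert(f1, conversion_request("oxycodone", "oral", 30, "morphine", "oral", egfr = 15))
#> oxycodone oral 30 mg/24h -> morphine oral
#>   OME: 60 mg/24h
#>   exact dose: 60 mg/24h
#>   practical dose: 60 mg/24h
#>   warning [renal_caution]: eGFR 15 mL/min is below 30 mL/min: consider dose adjustment of morphine in renal impairment
#>   formulary: F1

convert(f1, conversion_request("morphine", "oral", 60, "buprenorphine", "oral"))$status
#> [1] "no_guideline_equivalence"

breakthrough_dose(f1, "morphine", "oral", 60)
#> [1] 10
```

The same operations are available from a shell via the installed
`exec/omeconvert` script:

```sh
omeconvert convert --formulary formulary-f1.yaml \
    --from morphine:oral --to oxycodone:oral --dose 60 --json
omeconvert audit --log conversions.jsonl --oracle formulary-f1.yaml
```

Exit codes: 0 ok, 2 usage error, 3 no guideline equivalence, 4 unsupported
drug, 5 validation failure — so batch callers can count guideline gaps from
exit codes alone.

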