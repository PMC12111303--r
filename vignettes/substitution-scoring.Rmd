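---
title: "Scoring substitutes for medicinal products in shortage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring substitutes for medicinal products in shortage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmsub)
```

## The problem

When a medicinal product goes into shortage, the practical question is
which *marketed* product can replace it. Two products with the same active
ingredient can still differ in strength, dosage form, route and release
behaviour, and those differences matter clinically in very different
degrees: a 1 mg tablet replacing a 2 mg tablet means taking two tablets; a
prolonged-release intramuscular depot replacing an oral tablet is a
different therapy altogether. `pharmsub` encodes each product so those
differences become measurable, and turns them into a single ranked score.

## The combined code

A product is described by three internationally standardized pieces:

* the **ATC code** (7 characters, 5 levels) identifying the active
  ingredient and its therapeutic classification;
* five **EDQM Standard Terms**: basic dose form (BDF), administration
  method (AME), intended site (ISI), release characteristic (RCA) and
  transformation (TRN), each a 4-digit ID from a controlled vocabulary;
* **NDXUP**, the number of WHO Defined Daily Doses contained in one
  presentation unit — one tablet or capsule for discrete forms, one mL or
  one g for liquids and bulk solids. NDXUP makes a 2 mg tablet and a
  1 mg/mL solution comparable on the axis that matters: how much of a
  standard day's treatment one unit delivers.

Within each Standard-Term vocabulary, every term carries a *relative
position* (RP) ordering the terms by similarity: on the BDF scale, Tablet
(RP 1) sits near Lozenge (2) and Capsule (3) and far from Solution (19.5)
or Medicinal gas (47). Some positions are fractional (Cachet 3.5,
Granules 7.2); the vocabulary ships them as given and the package stores
them exactly as written — short decimal literals read into doubles, never
re-rounded — with division deferred to distance time, so no drift
accumulates. The bundled file transcribes Standard Terms version 1.2.0
(28 January 2019); `st_vocabulary(path)` loads a replacement file with the
same four columns when a newer revision is adopted, and the per-category
scale spans (BDF 46, AME 18, ISI 22, RCA 9, TRN 9) are recomputed from
whatever file is loaded. "Unknown" and "Not specified" are ordinary terms
with ordinary RPs, not special cases.

## The score

Candidates are restricted to entries with the **identical full 5-level
ATC** — the score quantifies pharmaceutical, not therapeutic,
substitution, so matching at the 4th level (different salts or congeners)
is deliberately not offered. Each candidate starts from 100 and loses
points in two classes.

**Strength (at most 10 points).** The NDXUP comparison between the lacking
product and the candidate follows an ordered rule table: equal 0, exactly
half 2, exactly double 4, strictly between half and equal 6, strictly
between equal and double 8, beyond either bound 10. The table is
intentionally asymmetric — half the strength (take two units) is judged
closer than double (split a unit) — and the engine preserves that
asymmetry, which a test asserts explicitly. Equality rules are evaluated
before interval rules with a relative tolerance of 1e-9: catalog NDXUPs
are short decimals, so true equalities must not be lost to float noise
(0.1 + 0.2 must count as 0.3), while 1 vs 1.000001 still falls into an
interval. The maximum strength deduction, 10 points, keeps dose
differences subordinate to form differences by design.

**Dosage form (at most 80 points).** For each of the five Standard-Term
categories the normalized relative distance

$$\mathrm{NRD} = \frac{|RP_{lak} - RP_{sub}|}{\max RP - \min RP} \times 100$$

is weighted by its category's weight factor — BDF 0.46, AME 0.18,
ISI 0.20, RCA 0.09, TRN 0.07, summing to 1 — and the weighted sum is
rescaled to the class maximum of 80. The unequal weights offset the
leverage of the short RCA and TRN scales (where one step is a ninth of the
whole range) and give the three most clinically visible characteristics
the lead. The result: DS lies in [10, 100], equals 100 exactly when the
full digital string matches (the definition of a pharmaceutical
equivalent), and decreases monotonically as any one Standard Term moves
away on its scale.

Weights, penalty points, tolerance and both class maxima are configurable
through `weight_factors()`, `penalty_schedule()` or a YAML file read by
`scoring_config()`; weights that do not sum to 1 are refused unless
explicitly allowed, since a silently rescaled weight set would change
every score.

**Rounding.** Scores are computed and compared at full working precision;
only display and the DS-band indicators use one-decimal rounding, half
away from zero (so 92.05 shows as 92.1). The rounding helper nudges by one
ulp before truncating so a value that is an exact half in rational
arithmetic is not dragged down by its binary representation.

## Ranking

`find_substitutes()` scores every same-ATC entry and sorts by a
deterministic total order: DS descending, then number of differing
Standard Terms ascending, then absolute NDXUP difference ascending, then
MA number. Only the first key is dictated by the method; the remaining
tie-breaks are this package's choice, made so that shuffled input yields
byte-identical output and so that, at equal score, candidates closer in
form and strength rank first. `min_ds` filters *after* ranks are assigned,
so rank numbers are stable regardless of the threshold; the conventional
"strong candidate" reading of DS > 90 is a flag for the caller, not a
hard-coded cut.

## Coding corner cases

**Fixed combinations.** Combinations have no official DDD; their NDXUP is
the sum of per-component dosage/DDD ratios. Each component's dosage and
DDD must share a dimension — mass converts across mcg/mg/g/kg
automatically, but a unit-dose DDD ("1 tab") is dimensionless and dividing
a mass by it is an error, not a number. Two published example rows mix
dimensions (a tablet-denominated DDD against an mg dosage; mg divided by g
as if raw numbers); the package refuses the first and computes the second
correctly as 0.045 rather than reproducing the raw-number 45.

**Ambiguous combination ATCs.** Where the official ATC does not identify
the components, a fictitious code keeps the first four levels of the main
therapeutic component and takes a fifth level from 99 downward to 80 —
a range official assignments essentially never reach — then, when those
twenty are exhausted, letter+digit codes A0..Z9 and digit+letter 0A..9Z
(540 codes in all). The published scheme gives the range but not the
order; scanning from 99 downward is this package's choice, and existing
assignments (whatever their origin) are always respected, never reused.
A non-numeric fifth level doubles as a marker that the code is fictitious.

**Electrolyte solutions.** These get a fictitious ATC per distinct
qualitative–quantitative composition and a formal NDXUP of 1, so identical
compositions compare as equivalents. The code is derived from an FNV-1a
hash of the case- and whitespace-normalized composition key under the
reserved base `B05X`, which makes re-imports idempotent without keeping a
registry; the cost is that injectivity is probabilistic (13,520 available
codes), a trade accepted deliberately and documented here.

**Depot injectables.** No defensible formula converts a depot's vial
content into DDDs per unit without knowing the dosing interval, so NDXUP
for such products is a catalog *input*, never computed; the helpers cover
only the unambiguous single-ingredient and fixed-combination cases.

## Indicators

`compute_indicators()` condenses a batch of queries into ten numbers: the
share of returned candidates at DS = 100, in [90, 100), in [80, 90) and
below 80 (on display-rounded DS — the upper band boundary is read as
"at least 90 and strictly below 100"); the share of candidates with the
reference's BDF; and, per reference, whether all its candidates stay
within k differing Standard Terms, k = 1..5 (cumulative by construction).
References returning no candidate are counted separately and excluded
from denominators; equivalents are included among candidates and also
counted on their own, so the indicators can be re-read over alternatives
only. Stratification by the first ATC character is a grouping option, not
separate machinery.

## The synthetic generator

`generate_catalog()` emulates the structure the engine consumes — ATC
families, a dosage ladder (default 0.5×, 1×, 2×, 3× of a base strength,
the ladder typical of oral solid ranges), a mix of four dosage-form
families (tablet, oral solution, oral drops, parenteral solution), exact
duplicate codes as equivalents, and NDXUPs kept to at most 3 decimals so
the exact-equality penalty rules engage as they do with real DDD ratios.
One seeded stream drives each call; the seed is written into the catalog
file as a comment header and restored on read. What the generator does
*not* emulate: the real ATC consumption distribution of any market,
realistic name strings, release-characteristic or transformation
diversity beyond the four families, and depot products. Passing tests on
synthetic catalogs therefore demonstrate the engine's arithmetic and
ordering guarantees, not performance on a national snapshot; the bundled
33-product risperidone fixture is the realistic anchor, and full-market
validation figures require the proprietary source data and are out of
scope here.

Problem sizes in the test suite — catalogs of tens of products, 1,000
random code pairs against the independent brute-force scorer, 500 random
penalty pairs — were chosen as comfortably exhaustive for a method whose
state space is five small vocabularies and a six-rule table.

## Known limitations

* Substitution is within-ATC only; therapeutic alternatives (different
  ingredient, same indication) are a clinical judgement the score does not
  attempt.
* One published worked-example block disagrees with the published
  vocabulary by one transformation term (a printed 55.7 that recomputes to
  54.5 with the vocabulary's RP for Dispersion, and to 55.7 only with the
  RP for Dissolution); the package follows the vocabulary as shipped and
  scores those products at 54.5.
* The electrolyte code space is finite and hash-based; two distinct
  compositions can in principle collide.
* Ranking below the first key reflects this package's documented
  tie-break order, not a published one.
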