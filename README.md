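# pharmsub

Decision support for medicine shortages: given a medicinal product that is
lacking on the market, `pharmsub` finds and ranks the marketed products that
can stand in for it — pharmaceutical *equivalents* (same active ingredient,
strength, dosage form and route) and pharmaceutical *alternatives* (same
active ingredient, differing in strength, form or route). It is aimed at
hospital and regional formulary pharmacists who must answer "what do we
dispense instead?" from a national catalog, quickly and reproducibly.

## The combined product code and the substitutability score

Every product is encoded as

```
ATC | BDF AME ISI RCA TRN | NDXUP
```

* **ATC** — the WHO Anatomical Therapeutic Chemical code (7 characters,
  5 levels) identifying the active ingredient;
* **BDF, AME, ISI, RCA, TRN** — five EDQM Standard Terms (4-digit IDs)
  describing the dosage form: basic dose form, administration method,
  intended site, release characteristic, transformation;
* **NDXUP** — the number of WHO Defined Daily Doses per presentation unit
  (per tablet/capsule, or per mL / per g for liquids and bulk solids).

Each Standard Term carries a *relative position* (RP) on its category's
similarity scale. The normalized relative distance between two terms is

```
NRD = |RP_a − RP_b| / (max RP − min RP) × 100
```

and the degree of substitutability of a candidate (`sub`) for the lacking
product (`lak`), both under the same full ATC code, is

```
DS = 100 − P_NDXUP − (Σ_k NRD_k · wf_k) / 100 × 80
```

where `P_NDXUP ∈ {0, 2, 4, 6, 8, 10}` penalizes the NDXUP ratio (0 for
equality, 2 for exactly half, 4 for exactly double, 6/8 for the open
intervals in between, 10 beyond), the sum runs over the five Standard-Term
categories with weights `wf = (0.46, 0.18, 0.20, 0.09, 0.07)`, and 80 is
the Standard-Term class maximum. DS is 100 exactly when the full digital
string matches (a pharmaceutical equivalent) and never falls below 10.
Weights, penalty points and class maxima are configurable; the defaults are
the published ones.

The package also handles the coding corner cases: NDXUP for fixed
combinations (sum of per-component dosage/DDD ratios, with unit checking),
fictitious ATC fifth levels (99..80, then letter+digit codes) for
combinations whose official ATC is ambiguous, and a deterministic fictitious
code with NDXUP = 1 for electrolyte solutions.

## Worked example

The package bundles a market snapshot of 33 risperidone products. Querying
it for the lacking 2 mg film tablet (MA number 037599230):

```r
library(pharmsub)
catalog <- read_catalog(
  system.file("extdata", "risperidone_catalog.csv", package = "pharmsub"),
  quiet = TRUE)
find_substitutes(catalog, "037599230")
```

```
Substitutes for 037599230 (RISPERIDONE SAN 60FILM TAB 2MG, ATC N05AX08):
  32 candidates (4 equivalents, 28 alternatives)
 rank ma_number                          name ndxup n_st_diff ds_display
    1 028752069    RISPERDAL 60TAB 2MG ORANGE   0.4         0        100
    2 037092222 RISPERIDONE TE 60FILM TAB 2MG   0.4         0        100
    3 040078293    RISPERIDONE AURO 60TAB 2MG   0.4         0        100
    4 040616082 RISPERIDONE MY 60FILM TAB 2MG   0.4         0        100
    5 028752057     RISPERDAL 60TAB 1MG WHITE   0.2         0         98
 classification
     equivalent
     equivalent
     equivalent
     equivalent
    alternative
  ... and 27 more rows
```

The four DS = 100 rows are the interchangeable 2 mg tablets. The 1 mg
tablets score 98 (half the DDDs per unit: two tablets replace one), the
4 mg tablets 96 (tablet splitting), the 3 mg tablets 92; oral drops and
solutions land in the 80s (same route, different basic dose form) and the
prolonged-release intramuscular suspensions below 60 (four or five
Standard Terms differ plus the maximum dose penalty). A DS above 90 is the
conventional threshold for a strong substitution candidate
(`min_ds = 90` keeps just those 19 rows).

A command-line interface wraps the same workflow
(`exec/pharmsub substitute|report|indicators|gen-synthetic|validate-catalog`),
and `compute_indicators()` summarizes batches of queries with the ten
internal-validation indicators (DS bands, same-BDF share, maximum
Standard-Term distance per reference).

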