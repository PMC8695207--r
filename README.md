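# herblike

Weighted herbicide-likeness scoring of small-molecule libraries.

Herbicide discovery increasingly mines antimalarial screening collections,
because compounds toxic to *Plasmodium* are often herbicidal. Many such hits
kill seedlings on agar plates but fail when sprayed on soil-grown plants, and
the failures are largely physico-chemical: too lipophilic, or positively
charged at physiological pH. `herblike` implements the triage tool built on
that observation — a weighted, interpretable "herbicide-likeness" score that
ranks candidate compounds by how closely their physico-chemical profile
matches commercial herbicides, for chemists and computational biologists
pre-screening libraries before glasshouse work.

## The score

Each compound is described by ten descriptors evaluated for the major species
at pH 7.4: six continuous (molar mass *M*, aromatic-atom percentage, polar
surface area, log *D*, log *S*, log *P*) and four discrete counts (rotatable
bonds, H-bond acceptors, H-bond donors, net formal charge *q*).

A reference model supplies a mean μ and standard deviation σ for every
continuous descriptor and a mode for every count, fitted from a reference
library (`fit_reference()`) or taken as the published statistics of 360
commercial herbicides (`published_reference()`).

Continuous descriptors score by the band of z = |x − μ|/σ:

| band | z ≤ 1 | z ≤ 2 | z ≤ 3 | z > 3 |
|---|---|---|---|---|
| standard | 1.5 | 1.0 | 0.5 | −1.0 |
| log *P* (weighted) | 3.0 | 2.0 | 1.0 | −1.0 |

Discrete descriptors score by the offset from the reference mode
(catch-all −1.0 beyond ±2); formal charge is weighted heavily and
asymmetrically, with q = mode + 2 (a doubly positive compound) scoring
−3.0 while the neutral/anionic side keeps positive scores. The total is the
sum over all ten descriptors; the maximum is **18 points** and the minimum
−12. Band edges are inclusive ("within one SD" keeps the better score), and
totals are accumulated in exact half-points.

## Worked example

Score one compound — a typical soil-active antimalarial profile — against the
published herbicide reference:

```r
library(herblike)
ref <- published_reference()
cmpd <- c(molar_mass = 351, aromatic_pct = 32, psa = 61.5, logd74 = 3.6,
          logs = -4.3, logp = 3.5, rotatable_bonds = 5, hba74 = 4,
          hbd74 = 1, formal_charge74 = 0)
score_compound(cmpd, ref)
#> Herbicide-likeness score: 16.5 points
#>       descriptor value      class score
#>       molar_mass 351.0 within_1sd   1.5
#>     aromatic_pct  32.0 within_1sd   1.5
#>              psa  61.5 within_1sd   1.5
#>           logd74   3.6 within_1sd   1.5
#>             logs  -4.3 within_1sd   1.5
#>             logp   3.5 within_1sd   3.0
#>  rotatable_bonds   5.0          0   1.5
#>            hba74   4.0         +2   0.5
#>            hbd74   1.0         +1   1.0
#>  formal_charge74   0.0          0   3.0
```

Every descriptor sits within one SD of the herbicide mean except the
H-bond-acceptor count (two above the mode, 0.5) and donor count (one above,
1.0), so the compound loses 1.5 points of the 18-point maximum — a strong
candidate. Ranking a whole library and shortlisting, as in the *in silico*
pre-screen of a liver-stage antimalarial collection:

```r
lib <- generate_library(herbicide_like_spec(n = 200, seed = 42))
res <- predict(ref, lib, threshold = 17)
head(res$ranked[, c("rank", "compound_id", "total")], 3)
#>   rank compound_id total
#> 1    1    SYN00050    17
#> 2    2    SYN00061    17
#> 3    3    SYN00063    17
res$shortlist$count   # compounds scoring 17 or more
#> [1] 8
```

Real tables are loaded with `read_compound_table()` (CSV/TSV, with a
`column_map` for dataset-specific headers) or computed from SMILES with
`compute_descriptors()`. Group comparisons mirror the published analysis:
`compare_descriptors()` runs the per-descriptor two-sample t-tests and
`fisher_charge_test()` the Fisher's exact test on positive versus
non-positive formal charge.

A command-line front end ships in `inst/cli/herblike`
(`herblike score|rank|refstats|compare|simulate`); every run writes its CSV
artifacts plus a `provenance.json` sidecar from which the artifact is
byte-reproducible.

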