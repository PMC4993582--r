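# onetubeSDM

Design and statistics for **one-tube site-directed mutagenesis (SDM)**: the
strategy of generating whole collections of amino-acid substitution variants
from single inverse-PCR reactions by pooling standardized mutagenic primer
pairs and/or plasmid templates, then screening a modest number of bacterial
colonies.

The package is for molecular biologists planning scanning mutagenesis
(e.g. alanine scans of PTEN-sized proteins), single-site multiple mutagenesis
(one residue, many substitutions — disease-variant collections), and the
statistics of how many colonies to sequence afterwards.

## What it computes

**Primer design (n+3+n rule).** Every mutagenic primer has fixed odd length
N = 2n+3: the mutant codon sits dead-centre, flanked by n template-matching
bases (29-mer = 13+3+13). The mutant codon is the codon of the target amino
acid with the *minimal Hamming distance* (1–3 mismatches) from the wild-type
codon; ties go to the more-used human codon. Forward and reverse primers are
fully complementary. Annotations use the QuikChange melting-temperature
convention

```
Tm = 81.5 + 0.41 (%GC) − 675/N − %mismatch ,   %mismatch = 100·mismatches/N
```

**Pool planning.** Primer pairs targeting residues d codons apart share
`max(0, N − 3d)/N` of their windows. Pairs with overlap **below 60%** (d ≥ 4
for 29-mers) can recombine into double mutants inside one tube; scanning
pools are therefore capped at 4 consecutive pairs by default.

**Coverage statistics (coupon collector).** The chance that n screened
colonies contain all c pooled mutations, assuming stochastic recovery:

```
P(c, n) = Σ_{j=0..c} (−1)^j C(c, j) ((c−j)/c)^n        (equiprobable draws)
```

plus weighted and finite-population (multivariate hypergeometric,
without-replacement) variants and a seeded 50,000-iteration Monte Carlo
simulator. `min_colonies(4, 0.90)` → **13**: screen 13 colonies to see all 4
mutations of a 4-plex pool with 90% probability.

**Screening evaluation.** Success rates (all targets recovered), recovery
frequency by mismatch class, and unions across iterative reaction rounds,
with bundled example datasets from one-tube screens of PTEN and PTPRZ-B.

## Worked example

```r
library(onetubeSDM)

cds <- coding_sequence(strrep("ATGAAACATGGC", 5), id = "toy60")  # 60-nt toy ORF
pairs <- design_ala_scan(cds, start_position = 3, length = 29)   # 10 pairs
pairs[[1]]
#> K6A  29-mer (2 mismatches)  GC 48%  Tm 71.1
#>   F: GAAACATGGCATGGCACATGGCATGAAAC
#>   R: GTTTCATGCCATGTGCCATGCCATGTTTC

pool <- plan_pools(pairs[1:6], "scanning", max_plex = 6)[[1]]
predict_double_mutants(pool)
#>   target_a target_b residue_a residue_b distance   overlap
#> 1      K6A     K10A         6        10        4 0.5862069
#> 2      K6A     H11A         6        11        5 0.4827586
#> 3      H7A     H11A         7        11        4 0.5862069

min_colonies(4, 0.90)
#> [1] 13

success_rate(load_example_screen("scanning"))
#> $percent   [1] 23      # truncated, 4/17 experiments recovered every target
#> $fraction  [1] 0.2352941
#> $successes [1] 4
#> $total     [1] 17
```

The first Ala-scan pair replaces codon 6 (AAA, Lys) by GCA (2 mismatches),
centred at primer positions 14–16; the pool analysis says only residue pairs
≥ 4 codons apart (overlap < 60%) can yield double mutants; and a 4-plex pool
needs 13 colonies for 90% coverage. The screening dataset reproduces the
observed 23% all-targets success rate of 2–8-plex scanning pools.

A command-line interface covers the same workflow
(`design ala-scan`, `design subs`, `plan pool`, `coverage`, `coverage table`,
`evaluate`); see `exec/onetubesdm` and `?run_cli`.

## Layout

* `R/` — sequence primitives, primer design, pool planning, coverage
  statistics, screening evaluation, CLI.
* `inst/extdata/` — transcribed example screening datasets (JSON).
* `vignettes/one-tube-sdm.Rmd` — methods: models, assumptions, parameter
  choices, limitations.
* `tests/testthat/` — unit, property and acceptance tests.
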