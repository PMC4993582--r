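---
title: "One-tube SDM: models, design rules, and their limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-tube SDM: models, design rules, and their limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onetubeSDM)
```

## The procedure being modelled

Whole-plasmid inverse-PCR mutagenesis amplifies a circular template with two
fully complementary oligonucleotides that both carry the desired mutation;
DpnI digestion then removes the methylated parental plasmid so that only
newly synthesized, mutant DNA transforms bacteria. The *one-tube* variant
pools several primer pairs (and/or several plasmid templates) in a single
reaction, so that one PCR and one transformation yield a whole collection of
variants, and sequencing a handful of colonies recovers them.

`onetubeSDM` covers the computational side of that workflow: primer design,
pool composition, the sampling statistics of colony screening, and the
evaluation of screening outcomes. It deliberately models no chemistry — no
PCR kinetics, no primer competition, no amplification bias (see
*Limitations*).

## Standardized primer design

All primers follow the **n+3+n rule**: odd length \(N = 2n+3\), the mutant
codon exactly central, \(n\) template-matching bases on each side, and the
reverse primer the full reverse complement of the forward one. Keeping the
length fixed across a whole scan (default **29 nt**, i.e. 13+3+13)
standardizes ordering and handling; empirically, 29-mers mutagenize as
efficiently as longer designs, while primers beyond 40 nt tend to yield
fewer colonies (the package warns above 40).

The mutant codon is chosen to encode the target amino acid with the
**minimal number of nucleotide changes** (Hamming distance 1–3 from the
wild-type codon). Where several codons tie, the package picks the one with
the higher human codon-usage weight, then the lexicographically smaller one.
The tie-break is a package design choice — the procedure itself only demands
minimality — and exists purely so that designs are deterministic and
testable; a different usage table can be supplied via `codon_table()`.

Coordinates are 1-based and the reading frame is anchored at base 1 of the
input, so the input FASTA must be the CDS itself. Protein residue *i* then
maps onto codon *i*, matching the usual mutation nomenclature (K60A, H61R).
Two degenerate-input rules are worth knowing:

* an Ala-scan start position that does not put a codon at the primer centre
  is **advanced to the next in-frame position** (with a message) rather than
  rejected — the user picks an arbitrary start, but the central triplet must
  be a codon;
* wild-type Ala codons inside an Ala scan are **skipped** (with a message),
  as the conservative reading of "replace each residue by alanine".

Melting temperatures use the QuikChange convention
\(T_m = 81.5 + 0.41\,\mathrm{\%GC} - 675/N - \mathrm{\%mismatch}\) with
\(\mathrm{\%mismatch} = 100\,m/N\). `tm_quikchange()` returns the unrounded
value; published primer tables mix nearest-integer and nearest-half-degree
presentation, so the package offers both (`report_percent()`,
`round_half_degree()`) and does not guess a single rule.

## Pools and the 60% overlap rule

Primer windows for residues \(d\) codons apart share
\(\max(0, N - 3d)\) bases, a fraction \(\max(0, N-3d)/N\). Observed
screening data show double mutants arising in scanning pools exactly when
two pairs overlap by **less than 60%** — for 29-mers, \(d \ge 4\)
(overlap 58.6%), while \(d = 3\) (69.0%) stays single. The threshold is
applied strictly (`overlap < 0.60`) and is exposed as a parameter of
`predict_double_mutants()`. A figure caption in the source study phrases the
boundary as "more than five codons", which is in mild tension with the
nucleotide-fraction rule at \(d = 4\); the package follows the 60% rule
because it is the one the observed double-mutant classes satisfy.

`plan_pools()` caps scanning pools at **4 consecutive pairs** by default:
larger pools were observed to stop yielding clean singles. Concentrations
(equimolar shares of a 0.8 µM total) are carried as metadata only.

## Coverage statistics

If a pool contains \(c\) mutations recovered stochastically, the probability
that \(n\) screened colonies contain all of them is the coupon-collector
coverage probability. Two models are implemented:

* **Multinomial (default).** Draws with replacement — the mutagenic mix has
  effectively unlimited primer copies. Equal weights give the closed form
  \(P = \sum_{j=0}^{c} (-1)^j \binom{c}{j} \left(\frac{c-j}{c}\right)^n\);
  unequal weights and an optional wild-type category (for mutagenesis
  efficiency below 100%) use inclusion–exclusion over group subsets.
* **Multivariate hypergeometric.** Draws without replacement from a finite
  population of size \(N\) with \(K_i\) copies per group — the formally
  stated sampling model. Its parameters \(N, K_i\) are never pinned down
  numerically by the source data, and the worked headline number (13
  colonies for \(c=4\) at 90%) is reproduced exactly by the \(N \to \infty\)
  multinomial limit, so that limit is the default and the finite-\(N\) model
  is an option.

Numerical choices: subset terms \(\binom{N-K_S}{n}/\binom{N}{n}\) are
evaluated as exact-ratio products \(\prod_{j=0}^{n-1}(N-K_S-j)/(N-j)\) —
no large intermediate binomials, no log-space cancellation — and the
alternating sums are clamped to \([0,1]\) against floating-point dust. The
exact hypergeometric sum refuses \(c > 20\) groups (\(2^c\) terms) and
points at the simulator, which mirrors each theory (with/without
replacement), requires a seed, and defaults to **50,000 iterations**, giving
a standard error of ~0.0013 near \(P = 0.9\) — small against the 0.031 gap
between \(P(4,12) = 0.8748\) and \(P(4,13) = 0.9057\), so the simulated
minimum-colony answer is stable across seeds.

## Screening evaluation and the bundled datasets

`screening_experiment()` records, per one-tube reaction, the colony counts of
each targeted single mutant, of double mutants, and of wild type, and
enforces the conservation invariant
\(\sum \text{singles} + \sum \text{doubles} + \text{wt} = \text{colonies}\).
Success means *every targeted mutation recovered as a single*; doubles are
tabulated separately and only credited to their constituents on request,
which does not change any bundled-dataset result. Success percentages are
floor-truncated for parity with the published summaries; exact fractions are
always returned alongside.

Three example datasets transcribe, row by row, the colony counts of a
published one-tube mutagenesis study of PTEN and PTPRZ-B: 17 scanning pools
(2–8-plex), 32 single-site pools (1–4-plex, two plasmid backbones), and 6
iterative single-site rounds. Every transcribed row passes the conservation
invariant, which is the strongest internal check available on the
transcription. They are real screening data, not simulations — but they are
*small* (2–20 colonies per experiment), so rate estimates derived from them
carry wide binomial uncertainty; a green test on these fixtures establishes
agreement with the recorded counts, not biological generality.

Two published summary figures do **not** reproduce from the transcribed
tables, and the corresponding acceptance assertions are deliberately left
failing rather than adjusted:

* the two-mismatch recovery frequency is quoted as 21/40 but recounts to
  20/40 (the one-mismatch 13/18 reproduces exactly; the three-mismatch
  figure, quoted 8/17, recounts to 10/19);
* the blanket claim that the Tm formula matches every printed value within
  0.7 °C fails for exactly two 45-mer entries printed with 42% GC
  (deviation 0.724 °C) — the printed GC values are integer-rounded, and with
  the plausible unrounded 19/45 = 42.2% GC both entries fall inside 0.7 °C.
  The primer sequences are not published, so the unrounded GC cannot be
  recovered.

## Limitations

* No thermodynamic nearest-neighbour Tm, primer-dimer or secondary-structure
  screening; the QuikChange formula is a convention, not a physical model.
* No degenerate (NNN/NNK) site-saturation designs.
* Pool chemistry (competition, bias) is out of scope; the coverage model
  assumes stochastic recovery, and the scanning datasets themselves show
  recovery is *not* always stochastic — coverage numbers are best-case
  screening budgets, not guarantees.
* Mixed-length pools are rejected rather than approximated.
* The finite-population model's \(N\) and \(K_i\) are user-supplied
  assumptions; nothing in the data identifies them.
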