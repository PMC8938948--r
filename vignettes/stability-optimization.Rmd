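---
title: "Models and design choices behind seqstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind seqstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqstab)
```

This vignette explains the mutation-rate models, the motif scanner, the
two-pass optimizer, and the synthetic fixture generators: what each assumes,
which parameters matter, and where the design was genuinely open and a
choice had to be made.

## Why hotspots, not averages

A burdensome synthetic construct is under constant negative selection:
any mutant that silences it grows faster and sweeps the culture. Empirically
most such failures trace back to a handful of hypermutable sites — tandem
repeats that slip during replication, long direct repeats that recombine,
and methylation-prone motifs that silence expression epigenetically in
mammalian and insect hosts. The useful quantity is therefore not an average
mutation rate but a ranked list of the worst sites, plus a way to remove
them without breaking the construct.

## Rate models

All rates are per generation and calibrated on *E. coli* measurements;
absolute values will differ in other organisms but the *ranking* of sites
is approximately preserved, which is what the optimizer consumes. Every
report written by the package carries this caveat.

**Baseline.** Spontaneous base-pair substitutions occur at
$\mu_{BPS} = 2.2\times10^{-10}$ per base per generation; a sequence of
length $n$ has baseline rate $n\,\mu_{BPS}$.

**SSR slippage.** A tandem run of a unit of length $L$ with $N$ copies
qualifies as slippage-prone when $N \ge 3, L \ge 2$ or $N \ge 4, L = 1$.
Slippage rates grow exponentially with copy number, so we model
$\log_{10}\mu = a\,N + b$ with separate coefficient sets for homopolymers
($L=1$: $a = 0.729$, $b = -12.915$) and multimers ($L\ge2$: $a = 0.063$,
$b = -4.749$). The two regimes differ in both qualification threshold and
empirical slope, which is why they are parameterized independently
(`rate_model()`); all four numbers can be overridden from a plain-text
config (`rate_model_from_file()`). The functional form is the package's
transcription of the published log-linear fits to *E. coli* slippage-rate
compilations; the contracts it must satisfy — strict growth in $N$ and
affinity of $\log_{10}\mu$ in $N$ at fixed $L$-class — are what the test
suite pins down.

**RMD recombination.** Two identical direct repeats of length $L \ge 16$
separated by $L_s$ nucleotides recombine at

$$\mu_{RMD} = \frac{1}{\bigl(1 + e^{(\alpha - L)/A}\bigr)\,(B + L_s)},
\qquad A = 5.8,\; B = 1465.6,\; \alpha = 29.0 .$$

The logistic term captures the minimal-efficient-processing-segment
behavior of homologous recombination — repeats much shorter than
$\alpha \approx 29$ nt recombine poorly, with $A$ setting how sharp the
transition is — and the $(B + L_s)^{-1}$ term the decay with inter-repeat
distance. The three constants are the published empirical values; the
algebraic arrangement around them is again this package's transcription,
constrained to be strictly increasing in $L$ and strictly decreasing in
$L_s$.

**RIP.** The relative-instability score divides the total predicted rate by
the baseline:
$\mathrm{RIP} = (n\mu_{BPS} + \sum\mu_{SSR} + \sum\mu_{RMD}) / (n\mu_{BPS})$.
Using the whole-sequence baseline in the denominator is the only reading
under which the no-hotspot minimum equals exactly 1, which the tests assert
on certified hotspot-free sequences.

## Detection

`find_ssr_sites()` compares the sequence against itself at every lag
$L \in 1..15$ and extracts maximal match runs; each physical repeat region
is reported once, at its leftmost phase with its smallest primitive unit
(`AAAAAA` is one $L=1, N=6$ run, never also $(AA)\times3$), counting whole
unit copies only. `find_rmd_sites()` indexes all 16-mers and merges hits at
consecutive offsets on the same diagonal into maximal repeats, emitting one
site per ordered pair of copies — each pair is an independent recombination
opportunity, so a triplicated block yields three sites. Pairs whose maximal
extents overlap are periodic regions, which belong to the SSR class and are
not reported as repeats. Reverse-complement (inverted) repeats are out of
scope: the deletion mechanism modeled here involves direct repeats only.
`N` bases match nothing, breaking both runs and repeats.

Both detectors are validated, site-for-site, against deliberately naive
enumerators (`ssr_sites_bruteforce()`, per-position unit counting;
`rmd_sites_bruteforce()`, exhaustive per-diagonal scans) on hundreds of
seeded random sequences.

## Motif scanning

Motif files are read in MEME minimal format, either the standard
`MOTIF` / `letter-probability matrix:` layout or the compact
name-line/header-line variant; a `Background letter frequencies` section is
honored and uniform 0.25 is assumed otherwise (documented default; motif
databases do not always ship a background). Probabilities become log₂-odds
scores via $(p + \varepsilon)/(q + \varepsilon)$ with pseudocount
$\varepsilon = 10^{-6}$ — published PPMs contain exact zeros, and the
pseudocount must avoid $\log 0$ without materially reordering scores
(halving or doubling it shifts every score magnitude toward or away from 0
monotonically, which the tests check).

Scanning scores every start position on both strands and keeps, per index,
only the best (motif, strand) pair with score > 0 — i.e. windows more
likely under the motif than under the background. With a uniform prior over
candidate sites, ranking by posterior reduces to ranking by PSSM score, so
only scores are reported — no methylation probabilities, and no estimate of
methylation strength. Ties prefer the forward strand, then motif order.
`N` bases contribute the background expectation (score 0). A small
synthetic methylation-motif file ships with the package
(`methylation_motifs_synthetic.meme`) as a stand-in for large published
methylation-motif databases, which users can supply as custom motif files.

## The two-pass optimizer

Running codon/GC optimization *first* and hotspot removal *second* means
removal operates on the sequence that will actually be shipped, so
objective-driven rewriting cannot re-introduce hotspots behind the
detector's back; it also means hotspots *created* by codon optimization
(poly-lysine becoming `AAAAAA...`, say) are caught and removed.

Pass 1 rewrites each ORF toward the chosen objective —
`use_best_codon` (every family's most frequent codon),
`match_codon_usage` (largest-remainder quotas per synonymous family,
keeping original codons wherever quota allows, so the edit is minimal), or
`harmonize_rca` (each codon mapped to the host codon of the same
within-family rank it held under a source table, *E. coli* by default) —
and then repairs any 50-nt GC window outside the bounds, preferring free
(non-ORF, unlocked) bases and falling back to synonymous swaps. Windows are
non-overlapping and anchored at position 0. With no organism given, only
constraints are resolved. A window that cannot be brought within bounds
(e.g. a fully locked `AAAA...` stretch) is named in an explicit
unsatisfiable report.

Pass 2 converts the top-ranked sites (default budget: 10 per class, applied
after ranking by rate or score with ties broken by position) into
constraints: for an RMD pair, every 15-nt window of the **first** copy must
contain at least one change, so no 16-mer identity can survive; for a motif
hit, the span's PSSM score must drop to ≤ 0, so re-scanning cannot report
it; for an SSR, alternating unit copies (2nd, 4th, ...) are edited first,
with fallbacks to any copy and then to any satisfying edit, stopping as
soon as re-detection of the local region is clean. Edits are synonymous
codon swaps inside ORFs (ordered by host codon frequency, keeping the
objective active in pass 2) and free substitutions outside; locked regions
are never touched, and a constraint lying entirely inside a lock is skipped
with a warning. Each candidate edit passes a safety audit — GC windows must
not leave bounds, no qualifying SSR may appear in a previously clean
region, and no 16-mer through a changed base may duplicate anywhere — so
hotspot removal does not create hotspots. Motif spans cover only a few
editable units, so their search is exhaustive over all synonymous
assignments (capped, with greedy descent as the fallback); this makes
"unsatisfiable" a proof, not a search failure. Because a later edit can
re-raise an earlier motif score, satisfied constraints are re-checked and
repaired in up to three sweeps, and anything still regressed is downgraded
to an honest `unsatisfied` entry.

Determinism: every stochastic choice (randomized restart orders) derives
from `spec$seed`; identical inputs give byte-identical outputs, and the
seed is recorded in every report. Default seed 0.

Some constraints are genuinely unsatisfiable: a weak motif hit whose
consensus is spelled by the only codons available for its amino acids
(e.g. `GATC` over an aspartate codon, where both `GAT` and `GAC` keep the
score positive) cannot be silenced without changing the protein. The result
object reports these with a reason, and `verify_result()` — an independent
audit that re-checks translation, locks, GC windows, absence of every
constraint reported satisfied, and that the change log equals the observed
Hamming distance — treats any *claimed-but-false* removal as a hard error.

## Synthetic fixtures

All tests run on generated data with exact planted truth; no downloads.

* `random_sequence()` draws i.i.d. bases at a target GC fraction.
* `hotspot_free_sequence()` resamples detected site spans until the
  sequence carries no qualifying SSR and no duplicated 16-mer, then
  certifies the result with the brute-force enumerators. Such sequences
  make the RIP minimum testable exactly.
* `plant_ssr()` / `plant_rmd()` / `plant_motif()` write a feature at exact
  coordinates and repair the flanks so the feature's maximal extent equals
  its declared extent (a coincidentally matching neighbor base would
  otherwise extend a run or repeat by one position). RMD blocks are
  rejection-sampled to be repeat- and SSR-free.
* `detection_fixture()` composes one planted SSR, one RMD
  ($L=20$, spacer 30) and one motif consensus on a hotspot-free background;
  the detection suite requires 100% recall at exact coordinates and strand
  over 100 such fixtures.
* `stability_fixture()` builds a UTR–ORF–UTR construct whose planted
  hotspots are all *removable*: a homopolymer spanning lysine codons
  (flanked by Asp/Val codons so `AAA`→`AAG` swaps always suffice), a
  duplicated seven-codon block (synonymously editable), and a motif
  consensus in the freely editable 3' UTR. The optimizer suite runs 50 of
  these end to end and requires every planted site gone, translation and
  locks intact, all GC windows in bounds, and a strict RIP decrease.

What these fixtures do **not** emulate: real codon autocorrelation,
GC skew, repeat families with near-identical (rather than identical)
copies, and real methylation motif databases. Passing tests therefore
demonstrate correctness of the detection/removal machinery under the
stated site definitions, not field performance on arbitrary genomes.

Problem sizes used by the test suite — 1-kb sequences for oracle
equivalence (200 seeds), 600-nt fixtures for detection recall (100 seeds),
~600-nt constructs for the optimizer contract (50 seeds), 10 kb for the RIP
minimum — were chosen as the smallest scales at which each property is
meaningfully exercised.

## Numerical and interface choices

* Coordinates are 0-based half-open in every in-memory object and 1-based
  inclusive in every CSV and report (stated in the headers).
* Site CSVs have a fixed schema: `seq_id, seq_num, type, start_1based,
  end_1based_inclusive, length, detail, rate_or_score, rank`.
* Ambiguity codes other than `N` are rejected at ingestion (optimizer
  semantics would be undefined); `U` is converted to `T` with a warning;
  lowercase input is upper-cased.
* Codon-usage tables for the nine supported organisms are embedded as
  within-family relative frequencies transcribed (to two decimals) from
  standard published codon-usage compilations and renormalized exactly at
  load; *M. musculus domesticus* shares the *M. musculus* table. Only the
  within-family proportions matter to any objective.
* The `match_codon_usage` distance is the amino-acid-count-weighted L1
  distance between within-family frequency vectors; `harmonize_rca`
  compares relative adaptiveness (frequency over family maximum) of the
  current codon under the host table with the original codon under the
  source table. Both are this package's concrete reading of the named
  objectives.
* Stop codons may be swapped among synonymous stops (the embedded tables
  cover the stop family).
* GenBank output marks every changed region with a labeled
  `misc_feature`; bundle folders are never overwritten (versioned suffix);
  the per-bundle zip archive is produced only when a `zip` tool is present,
  the bundle directory itself being the canonical output.
* An optional `iterate` mode repeats detection and removal (bounded
  rounds) for sequences whose budget-limited first round leaves sites
  behind; single-round behavior is the default and the audited contract.

## Known limitations

* Rates are point estimates from log-linear fits; no uncertainty is
  propagated, and cross-organism use is ranking-only by construction.
* Inverted repeats, restriction sites and RNA secondary structure are not
  modeled.
* The optimizer is a satisficer: it finds *a* constraint-satisfying,
  objective-improving sequence deterministically, not a global optimum.
* Motif hits overlapping low-degeneracy codons can be unremovable; they
  are reported, and deciding between protein changes and residual
  methylation risk is left to the user.
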