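# seqstab

Synthetic DNA constructs are a metabolic burden to their host. Variants in
which the construct has mutated into silence grow faster, so they take over
the culture — and most of those silencing mutations arise at a small number
of hypermutable sites rather than uniformly along the sequence. `seqstab`
finds those sites in batches of FASTA/GenBank files, ranks them by predicted
per-generation mutation rate, and rewrites the sequence to remove the worst
of them while preserving what must not change: amino-acid translation,
user-locked regions, and windowed GC content, all while optimizing codon
usage for a chosen host.

Three site classes are handled:

* **SSR** (simple-sequence repeats): tandem runs of a short unit (length
  *L*, copy number *N*) prone to polymerase slippage. A run qualifies when
  *N* ≥ 3 for *L* ≥ 2 (e.g. `ATATAT`) or *N* ≥ 4 for *L* = 1 (e.g. `AAAA`).
  Slippage rates follow a log-linear law, log₁₀ μ = a·N + b, with separate
  fits for homopolymers and longer units.
* **RMD** (repeat-mediated deletion): two identical direct repeats of
  length *L* ≥ 16 separated by *L*ₛ nucleotides recombine and delete the
  intervening region. The rate model is
  μ = 1 / ((1 + exp((α − L)/A)) · (B + Lₛ)) with A = 5.8, B = 1465.6,
  α = 29.0 (*E. coli* calibration).
* **Methylation / custom motifs**: position probability matrices in MEME
  minimal format are converted to log₂-odds PSSMs against the background
  frequencies and scanned over both strands; positions scoring above
  background (score > 0) are reported, best motif/strand per index.

Overall instability is summarized by the **RIP score**

    RIP = (μ_BPS·n + Σ μ_SSR + Σ μ_RMD) / (μ_BPS·n),   μ_BPS = 2.2 × 10⁻¹⁰,

the factor by which slippage and recombination hotspots raise the expected
mutation rate over the spontaneous-substitution baseline. A sequence with no
qualifying sites scores exactly 1. All rates are *E. coli*-calibrated: for
other organisms read the numbers as a ranking, not as absolute
probabilities.

The optimizer works in two passes (so that codon/GC optimization cannot
quietly re-introduce hotspots that detection has already missed): pass 1
codon-optimizes each ORF (`use_best_codon`, `match_codon_usage`, or
`harmonize_rca`) and enforces GC bounds on every 50-nt window; detection
then runs on that intermediate sequence, the top 10 sites per class are
turned into avoid-pattern constraints (every 15-mer of an RMD first copy
must change; motif spans must lose their positive score; alternating SSR
unit copies are broken), and pass 2 resolves them through synonymous codon
swaps inside ORFs and free substitutions outside, never touching locked
regions. Every result is re-audited from scratch; constraints that are
provably unsatisfiable (e.g. a motif spelled by the only codons available
for its amino acids) are reported, never silently dropped.

## Worked example

```r
library(seqstab)

fx <- stability_fixture(seed = 42)     # 603-nt construct with planted hotspots
m  <- rate_model()
ssr <- find_ssr_sites(fx$sequence, m)
rmd <- find_rmd_sites(fx$sequence, m)
rank_sites(rmd, 3)
#>   first_start second_start repeat_len spacer         rate rank
#> 1          71          359         22    266 0.0001329699    1
rip_score(nchar(fx$sequence), ssr, rmd, m)
#> [1] 1214.296
```

The 22-nt repeat pair dominates: the construct is predicted to mutate about
1214 times faster than its substitution baseline. Optimizing for *E. coli*:

```r
spec <- optimization_spec(organism = "E. coli", method = "use_best_codon",
                          gc_min = 0.25, gc_max = 0.75,
                          orf_regions = list(fx$orf_span), seed = 42)
res <- optimize_sequence(fx$sequence, spec,
                         pssms = list(ppm_to_pssm(fx$motif)))
res$site_counts
#>                  kind targeted removed skipped_locked unsatisfied
#> 1           ssr_units        6       6              0           0
#> 2 recombination_15mer        1       1              0           0
#> 3          motif_span       10       9              0           1
c(res$rip_before, res$rip_after)
#> [1] 1214.296    1.000
c(res$objective_before, res$objective_after)
#> [1] 0.3642384 0.9072848
```

131 substitutions remove every repeat hotspot (RIP drops to its minimum of
1), raise the fraction of host-preferred codons from 0.36 to 0.91, and
leave the translation, locked bytes and GC windows untouched — verified by
`verify_result()`, which re-checks all of this independently and errors on
any violation. One weak motif hit could not be silenced within its codon
context and is reported as unsatisfied.

Batch use: `run_pipeline(run_config(input_dir, output_dir, ...))` or the
`inst/cli/seqstab` script; both write per-input folders with
`sites_ssr.csv` / `sites_rmd.csv` / `sites_motif.csv` (1-based inclusive
coordinates), optimized FASTA/GenBank, a change summary, and a run
manifest.

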