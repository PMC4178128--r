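# degenlib

Design and budgeting of degenerate-codon saturation-mutagenesis libraries.

Saturation mutagenesis replaces one codon of a protein with a degenerate
codon (NNN, NNK, NNM, ... in IUPAC notation) so that a single mutagenesis
reaction yields a mixture of all — or almost all — amino acids at that
position. Because amino acids are encoded by unequal numbers of codons,
picking random clones from such a library is a coupon-collector problem with
unequal probabilities: early clones are almost always new variants, late
ones almost never are. `degenlib` answers the questions a protein engineer
asks before (and after) such an experiment:

- **What does a scheme deliver?** The variant distribution of any IUPAC
  degenerate codon: `p_i = (codons encoding i) / (expansion size)`,
  including the stop-codon burden.
- **How many clones must I screen?** The completeness probability
  `P(all targets present in L clones)` — by exact inclusion–exclusion
  `P = Σ_{S⊆T} (−1)^{|S|} (1 − Σ_{i∈S} p_i)^L` or the classical per-variant
  product `Π_i (1 − (1−p_i)^L)` — and the smallest `L` reaching a threshold
  θ (default 0.95).
- **How long until the library is complete?** The expected waiting time
  `E[T] = Σ_{∅≠S⊆T} (−1)^{|S|+1} / Σ_{i∈S} p_i`, plus a bit-reproducible
  Monte Carlo simulator of random clone picking (per-discovery-rank means
  and SDs).
- **When should I stop screening and switch to SDM?** Expected cost of the
  hybrid strategy `n·c_screen + E[missing after n]·c_SDM` and its optimal
  switch point.
- **Which oligos do I order?** QuikChange-style degenerate primer pairs and
  per-variant completion primers, with exact reverse complements across the
  full IUPAC alphabet.

## Worked example

```r
library(degenlib)

# NNM randomization: 32 codons, 18 amino acids, 2 stops
d <- amino_acid_distribution("NNM")
d$probs[c("L", "C", "*")] * 32
#> L C *
#> 3 1 2

# 95% completeness thresholds (product formula, the classical one)
min_library_size(library_design("NNN", "all20"))   #> 240
min_library_size(library_design("NNM"))            #> 163  (18 reachable aa)

# screening 21 NNM clones finds ~11.5 of the 18 reachable variants
expected_distinct("NNM", 21)                       #> 11.4527

# expected clones to collect all 18 — and its Monte Carlo check
expected_collection_time("NNM")                    #> 92.22451
s <- simulate_screening("NNM", n_iterations = 1e5, seed = 7)
tail(s$cumulative_mean, 1)                         #> 92.33152

# cost-optimal switch from screening (20/clone) to SDM (100/variant),
# targeting all 20 amino acids (Met/Trp must be built by SDM anyway)
sw <- optimal_switch_point("NNM", amino_acids(), cost_model())
sw$n_opt                                           #> 28
sw$evaluation$expected_total_cost                  #> 1247.511

# what the real 21-clone screen + 10 SDM completions cost
comp <- observed_composition(c(L = 5, P = 3, R = 3, S = 2, A = 2,
                               G = 2, H = 1, T = 1, D = 1, F = 1))
realized_cost(comp, 10)                            #> 1420

# primers around codon W373 of the (synthetic) Zm-p60.1 template
tpl <- zmp60_w373_template()
design_degenerate_primer_pair(tpl, 373, "NNM")$forward
#> "cctcctatgggaaatccaNNMatctacatgtaccctgagggc"
design_completion_primers(tpl, 373, "C")[["C"]]$reverse
#> "gccctcagggtacatgtagatGCAtggatttcccataggagg"
```

A command-line interface wraps the same operations
(`Rscript inst/cli/degenlib.R --help`): subcommands `dist`, `size`,
`simulate`, `cost`, `primers`, `report`.

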