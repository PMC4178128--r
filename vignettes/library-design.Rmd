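---
title: "Degenerate-codon library design: models, assumptions, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degenerate-codon library design: models, assumptions, numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degenlib)
```

## The model

A single codon position is randomized with a degenerate codon — a 3-letter
IUPAC string such as NNK (N = A/C/G/T, K = G/T) synthesized as an equimolar
base mixture. Every concrete codon in the expansion is therefore
equiprobable, and the probability of amino-acid variant $i$ in a random
clone is

$$p_i = \frac{\#\{\text{codons encoding } i\}}{\text{expansion size}}$$

under the standard genetic code (translation table 1 — the variant counts
quoted below, e.g. 18 amino acids and 2 stops for NNM, hold only there).
Stop codons are first-class variants (symbol `*`): a clone carrying one is
screened and wasted, which is exactly how the statistics treat it, since
all $p_i$ are fractions of the whole codon space. Clones are modeled as
i.i.d. draws from this distribution.

Everything downstream is a function of the $p_i$:

* **Completeness.** $P(\text{all targets present in } L \text{ clones})$,
  either exactly by inclusion–exclusion over target subsets,
  $P = \sum_{S \subseteq T} (-1)^{|S|}\,(1 - \sum_{i \in S} p_i)^L$, or with
  the per-variant independence product
  $\prod_{i \in T}(1 - (1-p_i)^L)$ used throughout the classical
  library-sizing literature. Presence events are negatively correlated
  (one clone carries one variant), so the product upper-bounds the exact
  value; the gap is ~0.02 at $L = 50$ and below $5\times10^{-3}$ by
  $L = 150$ for NNN/NNK/NNM.
* **Minimum library size.** The smallest $L$ with completeness $\ge \theta$
  (default $\theta = 0.95$), by doubling then binary search — completeness
  is nondecreasing in $L$, and the first $L$ at or above $\theta$ is
  returned.
* **Waiting time.** The unequal-probability coupon collector,
  $E[T] = \sum_{\emptyset \neq S \subseteq T} (-1)^{|S|+1} / \sum_{i \in S} p_i$,
  and a Monte Carlo simulator reporting per-discovery-rank incremental and
  cumulative clone counts (mean and SD).
* **Strategy cost.** Screen $n$ clones at unit cost $c_\mathrm{screen}$,
  then construct each still-missing target by site-directed mutagenesis at
  $c_\mathrm{SDM}$: expected cost
  $n\,c_\mathrm{screen} + c_\mathrm{SDM} \sum_{i \in T} (1-p_i)^n$,
  minimized over integer $n$.

## Which method defines the headline thresholds

The two formulas disagree by one clone exactly where it matters. For NNM
over its 18 reachable amino acids at $\theta = 0.95$ the product formula
gives 163 while exact inclusion–exclusion gives 164; for NNN over all 20
both give 240. The widely quoted 95% figures (240 for NNN, 163 for NNM)
are product-formula values, so `min_library_size()` defaults to
`method = "product"` and keeps `"exact"` available. When the one-clone
difference matters, the exact method is the conservative choice. (For NNK
the same conventions give 172 by the product formula and 173 exact; a
figure of 171 circulates but is not reproduced by either formula and is
not used as a reference value anywhere in the package.)

```{r thresholds}
min_library_size(library_design("NNN", "all20"))
min_library_size(library_design("NNM"))
min_library_size(library_design("NNM"), method = "exact")
```

## Parameters that matter

* `threshold` ($\theta$, dimensionless, default 0.95): the conventional
  confidence level for "library complete".
* `targets`: defaults to the scheme's *reachable* amino acids with stop
  excluded — completeness counts amino-acid variants, not codons, and a
  target that the scheme cannot encode (Met/Trp under NNM) would make
  completeness identically zero. Unreachable targets are legitimate inputs
  to the *cost* model, where they simply always incur SDM work.
* `cost_per_screened_clone` (currency/clone, default 20) and
  `cost_per_sdm_variant` (currency/variant, default 100): typical
  commercial figures — DNA isolation plus sequencing for a screened clone;
  oligo synthesis, mutagenesis kit, isolation and sequencing for an SDM
  variant. Currency is unitless; only the ratio matters for the switch
  point.
* `n_iterations` (default $10^6$, the conventional scale for these
  simulations): at $10^5$ the standard error of the NNM full-collection
  mean is already ≈ 0.2 clones; tests run at $10^5$ with 3-standard-error
  tolerances to stay fast.
* Primer flanks (`flank_up = 18`, `flank_dn = 21` bases): the lengths of a
  typical whole-plasmid mutagenesis oligo; free parameters, no
  melting-temperature optimization is attempted.

## The simulator and what a green test establishes

Draws are simulated at the variant level (amino acid or stop), not the
codon level — equivalent by construction, since only variant identity
affects discovery. The core is a small C++ loop using R's RNG stream, so
`set.seed()` (or the recorded `seed` in every artifact) makes output
bit-reproducible; per-rank moments are accumulated streaming (Welford), so
memory is independent of iteration count. The simulator emulates i.i.d.
clone picking only: real screens add transformation bias, false-negative
activity calls, colony mixing and uneven representation of the degenerate
oligo pool. A green simulation test therefore establishes agreement between
the sampler and the analytic coupon-collector model — not that a wet-lab
screen will hit its predicted clone count.

## Numerical choices

* $(1-p)^L$ is computed as $\exp(L \log(1-p))$ via `log1p` to avoid
  underflow at large $L$; subset sums exceeding 1 by float error are
  clamped.
* Exact inclusion–exclusion is evaluated meet-in-the-middle: signed subset
  sums of two target halves combined by outer product. This is exact,
  $O(2^{K/2})$ in memory, and capped at $K = 22$ targets (~33 MB, ~4M
  signed terms) with an explicit error pointing to the product method —
  single-position libraries never exceed 21 variants.
* Ties at exactly $\theta$: the first $L$ with $P \ge \theta$ is returned.
* Cost-curve ties: the smallest minimizer $n^*$ is returned (screen less
  when indifferent). The expected-cost curve's first difference is
  $c_\mathrm{screen} - c_\mathrm{SDM} \sum_i p_i (1-p_i)^n$, eventually
  positive, so exhaustive search over $[0, n_\mathrm{max}]$ (default
  $4\times$ the 95% library size) is safe and cheap.
* The hybrid cost is the risk-neutral expectation of missing variants; a
  quantile view can be built from `simulate_fixed_screen()` compositions
  when the spread matters.

## Synthetic fixtures

`generate_fixture_template()` produces deterministic random coding
sequences (ATG start, sense codons, TAA stop) for primer tests.
`zmp60_w373_template()` is a 400-codon stand-in for the maize β-glucosidase
Zm-p60.1 CDS: only codons 367–380 — the 42-nt window around the
wild-type TGG at codon 373, as fixed by the published mutagenic primer —
are authentic; the rest is synthetic filler, which is all primer design
around that codon needs. The completion-codon table
(`zmp60_codon_table()`) is the set of codon choices actually used to
finish that library; it follows no codon-usage rule and is shipped as a
named fixture rather than a default policy.

## Known limitations

* Single-position libraries only; no multi-site combinatorial designs or
  diversity indices beyond expected distinct counts.
* Standard genetic code only; no organism-specific tables or codon-usage
  weighting of the equimolar-mixture assumption.
* No model of failed SDM reactions, recloning, or screening false
  negatives; the cost model is linear in both unit costs.
* Primer design checks sequence identity only — no Tm, secondary-structure
  or mispriming analysis.
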