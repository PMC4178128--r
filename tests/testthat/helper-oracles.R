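# Independent oracles, deliberately naive: enumeration and direct sums only,
# no calls into the code paths they check.

# P(all targets present among L i.i.d. draws) by full outcome enumeration.
# p_targets: named probabilities; remaining mass is a lumped "other" category.
oracle_completeness <- function(p_targets, L) {
  stopifnot(length(p_targets) <= 3, L <= 6)
  if (L == 0) return(as.numeric(length(p_targets) == 0))
  p_other <- 1 - sum(p_targets)
  cats <- c(p_targets, if (p_other > 1e-15) c(.other = p_other))
  grid <- do.call(expand.grid, rep(list(seq_along(cats)), L))
  probs <- apply(grid, 1, function(idx) prod(cats[idx]))
  hit <- apply(grid, 1, function(idx)
    all(seq_along(p_targets) %in% idx))
  sum(probs[hit])
}

# Expected distinct targets after L draws, as a plain sum.
oracle_expected_distinct <- function(p_targets, L) {
  sum(1 - (1 - p_targets)^L)
}

# The NNM per-variant probabilities printed as fractions of 32.
nnm_printed_counts <- c(
  C = 1, D = 1, E = 1, F = 1, H = 1, K = 1, N = 1, Q = 1, Y = 1,
  A = 2, G = 2, I = 2, P = 2, T = 2, V = 2,
  L = 3, R = 3, S = 3,
  M = 0, W = 0, "*" = 2
)

# The study's printed oligos (42-mers around codon 373).
printed_fwd_nnm <- "cctcctatgggaaatccaNNMatctacatgtaccctgagggc"
printed_rev_nnm <- "gccctcagggtacatgtagatKNNtggatttcccataggagg"
printed_completion_rev <- c(
  C = "gccctcagggtacatgtagatGCAtggatttcccataggagg",
  E = "gccctcagggtacatgtagatTTCtggatttcccataggagg",
  I = "gccctcagggtacatgtagatAATtggatttcccataggagg",
  M = "gccctcagggtacatgtagatCATtggatttcccataggagg",
  N = "gccctcagggtacatgtagatGTTtggatttcccataggagg",
  Q = "gccctcagggtacatgtagatCTGtggatttcccataggagg",
  V = "gccctcagggtacatgtagatCACtggatttcccataggagg",
  Y = "gccctcagggtacatgtagatATAtggatttcccataggagg"
)

# random small variant distributions for property tests
random_small_dist <- function(n_targets, off_mass = 0) {
  w <- runif(n_targets, 0.2, 1)
  p <- (1 - off_mass) * w / sum(w)
  names(p) <- letters[seq_len(n_targets)]
  p
}
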