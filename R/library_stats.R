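# Analytic library statistics: completeness probability, minimum library
# size, expected distinct/missing variants, full-collection waiting time,
# and the monotypic-sample probability.

.EXACT_CAP <- 22L

.pow_1m <- function(s, L) {
  # (1 - s)^L with s possibly == 1 (then 0^L, with 0^0 = 1)
  s <- pmin(pmax(s, 0), 1)
  out <- exp(L * log1p(-s))
  out[s >= 1] <- if (L == 0) 1 else 0
  out
}

# Signed subset sums of p via meet-in-the-middle halves.
# Returns list(a_sum, a_sgn, b_sum, b_sgn); full subset sums are outer sums.
.subset_halves <- function(p) {
  half <- function(q) {
    s <- 0; g <- 1
    for (x in q) { s <- c(s, s + x); g <- c(g, -g) }
    list(sum = s, sgn = g)
  }
  k <- length(p)
  i <- seq_len(k %/% 2L)
  list(a = half(p[i]), b = half(p[setdiff(seq_len(k), i)]))
}

#' Library completeness probability
#'
#' Probability that a library of `L` clones, drawn i.i.d. from the codon
#' scheme's variant distribution, contains every target variant at least
#' once. Two methods are provided:
#'
#' * `"exact"`: inclusion–exclusion over target subsets,
#'   \eqn{P = \sum_{S \subseteq T} (-1)^{|S|} (1 - \sum_{i \in S} p_i)^L}.
#' * `"product"`: the per-variant independence approximation
#'   \eqn{\prod_{i \in T} (1 - (1 - p_i)^L)}, the formula of the classic
#'   library-sizing literature. It upper-bounds the exact value because
#'   presence events are negatively correlated.
#'
#' Stop codons and other off-target mass dilute the \eqn{p_i} and are
#' accounted for automatically.
#'
#' @param dist A `variant_distribution` or scheme string.
#' @param L Library size (clones), nonnegative integer.
#' @param targets Variant symbols that must all be present. Default: the
#'   scheme's reachable amino acids (stop excluded).
#' @param method `"exact"` or `"product"`.
#' @return Probability in `[0, 1]`. Any target with probability 0 forces 0.
#' @export
#' @examples
#' completeness_probability("NNM", 163)                  # product: just over 0.95
#' completeness_probability("NNM", 163, method = "exact")  # slightly below
completeness_probability <- function(dist, L,
                                     targets = reachable_variants(dist, include_stop = FALSE),
                                     method = c("exact", "product")) {
  method <- match.arg(method)
  stopifnot(length(L) == 1L, L >= 0, L == floor(L))
  p <- .target_probs(dist, targets)
  if (length(p) == 0L) return(1)
  if (any(p == 0)) return(0)
  if (method == "product") return(prod(1 - .pow_1m(p, L)))
  if (length(p) > .EXACT_CAP) {
    stop("exact inclusion-exclusion is capped at ", .EXACT_CAP,
         " targets (got ", length(p), "); use method = \"product\"",
         call. = FALSE)
  }
  h <- .subset_halves(p)
  s <- outer(h$a$sum, h$b$sum, "+")
  sgn <- outer(h$a$sgn, h$b$sgn)
  val <- sum(sgn * .pow_1m(s, L))
  min(max(val, 0), 1)
}

#' Library design
#'
#' Bundles a degenerate-codon scheme with a target variant set and a
#' completeness threshold.
#'
#' @param scheme 3-letter IUPAC string.
#' @param targets `"reachable"` (scheme's reachable amino acids, stop
#'   excluded; the default), `"all20"`, or an explicit character vector.
#' @param threshold Required completeness probability, strictly in (0, 1).
#' @return An object of class `library_design`.
#' @export
#' @examples
#' library_design("NNM")            # 18 reachable amino acids, theta = 0.95
#' library_design("NNN", "all20")
library_design <- function(scheme, targets = "reachable", threshold = 0.95) {
  stopifnot(threshold > 0, threshold < 1)
  dist <- amino_acid_distribution(scheme)
  if (identical(targets, "reachable")) {
    targets <- reachable_variants(dist, include_stop = FALSE)
  } else if (identical(targets, "all20")) {
    targets <- amino_acids()
  }
  targets <- unique(as.character(targets))
  if (length(targets) == 0L) stop("empty target set", call. = FALSE)
  structure(list(scheme = dist$scheme, dist = dist, targets = targets,
                 threshold = threshold),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf("library design: scheme %s, %d targets, threshold %.3g\n",
              x$scheme, length(x$targets), x$threshold))
  invisible(x)
}

#' Minimum library size for a completeness threshold
#'
#' Smallest `L` whose completeness probability reaches the design threshold,
#' found by doubling then binary search (completeness is nondecreasing in
#' `L`). The default method is `"product"`, the per-variant formula used for
#' the standard published 95% thresholds (240 clones for NNN over 20 amino
#' acids, 163 for NNM over its 18 reachable ones); `"exact"` gives a value
#' larger by 0 or 1 clone for these schemes.
#'
#' @param design A `library_design`, or a scheme string (then `targets` and
#'   `threshold` apply).
#' @param method `"product"` or `"exact"`.
#' @param targets,threshold Used only when `design` is a scheme string.
#' @return Integer `L*` with `P(L*) >= threshold > P(L* - 1)`.
#' @export
#' @examples
#' min_library_size(library_design("NNN", "all20"))  # 240
#' min_library_size("NNM")                           # 163
min_library_size <- function(design, method = c("product", "exact"),
                             targets = "reachable", threshold = 0.95) {
  method <- match.arg(method)
  if (!inherits(design, "library_design")) {
    design <- library_design(design, targets = targets, threshold = threshold)
  }
  p <- .target_probs(design$dist, design$targets)
  if (any(p == 0)) {
    stop("unreachable target variant(s): ",
         paste(names(p)[p == 0], collapse = ", "), call. = FALSE)
  }
  P <- function(L) completeness_probability(design$dist, L, design$targets,
                                            method = method)
  hi <- 1L
  while (P(hi) < design$threshold) hi <- hi * 2L
  lo <- hi %/% 2L  # P(lo) < threshold (or lo == 0)
  while (lo + 1L < hi) {
    mid <- (lo + hi) %/% 2L
    if (P(mid) >= design$threshold) hi <- mid else lo <- mid
  }
  hi
}

#' Expected number of distinct target variants
#'
#' \eqn{E[\mathrm{distinct}] = \sum_{i \in T} (1 - (1 - p_i)^L)} after
#' screening `L` clones.
#'
#' @inheritParams completeness_probability
#' @return Expected count (float).
#' @export
#' @examples
#' expected_distinct("NNM", 21)  # about 11.45 of the 18 reachable
expected_distinct <- function(dist, L,
                              targets = reachable_variants(dist, include_stop = FALSE)) {
  stopifnot(L >= 0)
  p <- .target_probs(dist, targets)
  sum(1 - .pow_1m(p, L))
}

#' Expected number of missing target variants
#'
#' \eqn{\sum_{i \in T} (1 - p_i)^n}; complements [expected_distinct()]
#' (their sum is `|targets|`). Unreachable targets contribute 1 each for
#' every `n` — screening can never find them.
#'
#' @param dist A `variant_distribution` or scheme string.
#' @param n Clones screened.
#' @param targets Variant symbols of interest.
#' @return Expected count (float).
#' @export
#' @examples
#' expected_missing("NNM", 21, amino_acids())  # about 8.55 (Met and Trp always missing)
expected_missing <- function(dist, n,
                             targets = reachable_variants(dist, include_stop = FALSE)) {
  stopifnot(n >= 0)
  p <- .target_probs(dist, targets)
  sum(.pow_1m(p, n))
}

#' Expected clones to collect every target variant
#'
#' The coupon-collector waiting time with unequal probabilities:
#' \eqn{E[T] = \sum_{\emptyset \ne S \subseteq T} (-1)^{|S|+1} / \sum_{i \in S} p_i}.
#' Draws landing outside the target set (stop codons, non-target amino
#' acids) consume clones; the formula accounts for this because the
#' \eqn{p_i} are fractions of the whole codon space.
#'
#' @inheritParams expected_missing
#' @return Expected number of clones (float).
#' @export
#' @examples
#' expected_collection_time(variant_distribution(c(a = 0.5, b = 0.5)))  # 3
#' expected_collection_time("NNM")  # about 92.2
expected_collection_time <- function(dist,
                                     targets = reachable_variants(dist, include_stop = FALSE)) {
  p <- .target_probs(dist, targets)
  if (length(p) == 0L) return(0)
  if (any(p == 0)) {
    stop("unreachable target variant(s): ",
         paste(names(p)[p == 0], collapse = ", "), call. = FALSE)
  }
  if (length(p) > .EXACT_CAP) {
    stop("inclusion-exclusion capped at ", .EXACT_CAP, " targets", call. = FALSE)
  }
  h <- .subset_halves(p)
  s <- outer(h$a$sum, h$b$sum, "+")
  sgn <- -outer(h$a$sgn, h$b$sgn)  # (-1)^(|S|+1)
  s[1L, 1L] <- Inf                 # exclude the empty set (1/Inf = 0)
  sum(sgn / s)
}

#' Probability that n clones are all one variant
#'
#' \eqn{p_v^n}: the chance every one of `n` clones carries the same given
#' variant. Even for the most frequent variants under NNM (p = 3/32) this
#' vanishes long before n = 21, which is why a screen returning many
#' positives must contain several distinct variants.
#'
#' @param dist A `variant_distribution` or scheme string.
#' @param variant Single variant symbol.
#' @param n Number of clones.
#' @return Probability.
#' @export
#' @examples
#' probability_monotypic("NNM", "L", 21)  # (3/32)^21, about 2.6e-22
probability_monotypic <- function(dist, variant, n) {
  stopifnot(length(variant) == 1L, n >= 0)
  p <- .target_probs(dist, variant)
  unname(p)^n
}

#' Expected per-variant counts in a screen
#'
#' @param n Clones screened.
#' @param dist A `variant_distribution` or scheme string.
#' @param targets Variants to report (default: all variants of the
#'   distribution, stop included).
#' @return Named numeric vector `n * p_i`.
#' @export
#' @examples
#' expected_counts(32, "NNM")[c("L", "C", "*")]  # 3, 1, 2
expected_counts <- function(n, dist, targets = NULL) {
  stopifnot(n >= 0)
  dist <- amino_acid_distribution(dist)
  if (is.null(targets)) targets <- names(dist$probs)
  p <- .target_probs(dist, targets)
  n * p
}

#' Write a library-size report
#'
#' Evaluates one or more designs and writes a TSV or JSON table of
#' (scheme, n_targets, threshold, method, L*, P(L*), P(L*-1)).
#'
#' @param designs A `library_design` or list of them.
#' @param path Output file, or `""` for stdout.
#' @param method Passed to [min_library_size()].
#' @param format `"tsv"` or `"json"`.
#' @return The report data.frame, invisibly.
#' @export
write_size_report <- function(designs, path = "", method = "product",
                              format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(designs, "library_design")) designs <- list(designs)
  rows <- lapply(designs, function(d) {
    L <- min_library_size(d, method = method)
    data.frame(scheme = d$scheme, n_targets = length(d$targets),
               threshold = d$threshold, method = method, L_star = L,
               P_at_L = completeness_probability(d$dist, L, d$targets, method = method),
               P_below = completeness_probability(d$dist, L - 1L, d$targets, method = method))
  })
  report <- do.call(rbind, rows)
  if (format == "tsv") {
    utils::write.table(report, if (nzchar(path)) path else stdout(),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    txt <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (nzchar(path)) writeLines(txt, path) else cat(txt, "\n")
  }
  invisible(report)
}
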