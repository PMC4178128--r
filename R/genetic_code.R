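# Genetic code, IUPAC degeneracy expansion, and sequence utilities.
# All downstream statistics and primer design are built on these.

# Complement lookup covering the full IUPAC nucleotide alphabet, both cases.
.IUPAC_CHARS <- "ACGTRYSWKMBDHVN"
.IUPAC_COMP <- "TGCAYRSWMKVHDBN"

#' The standard genetic code
#'
#' Translation table 1 as a named character vector mapping each of the 64
#' codons (uppercase DNA) to a one-letter amino-acid code or `"*"` for stop.
#' Taken from [Biostrings::GENETIC_CODE].
#'
#' @return Named character vector of length 64.
#' @export
#' @examples
#' standard_genetic_code()[["TGG"]]  # "W"
standard_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stopifnot(length(gc) == 64L, sum(gc == "*") == 3L)
  c(gc)
}

.AA20 <- sort(setdiff(unique(Biostrings::GENETIC_CODE), "*"))

#' The twenty amino acids
#'
#' One-letter codes of the 20 proteinogenic amino acids, sorted.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() .AA20

#' Translate a codon
#'
#' @param codon Character vector of 3-letter DNA codons (A/C/G/T only,
#'   case-insensitive).
#' @return Character vector of one-letter amino-acid codes, `"*"` for stop.
#' @export
#' @examples
#' translate_codon("TGG")  # "W"
#' translate_codon(c("TAA", "atg"))  # "*" "M"
translate_codon <- function(codon) {
  codon <- toupper(as.character(codon))
  bad <- nchar(codon) != 3L | grepl("[^ACGT]", codon)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "),
         " (need 3 letters from A/C/G/T)", call. = FALSE)
  }
  unname(standard_genetic_code()[codon])
}

#' Expand an IUPAC symbol to its nucleotide set
#'
#' @param symbol Single IUPAC nucleotide code.
#' @return Character vector of the A/C/G/T letters the symbol stands for.
#' @export
iupac_expand <- function(symbol) {
  symbol <- toupper(symbol)
  map <- Biostrings::IUPAC_CODE_MAP
  if (!symbol %in% names(map)) {
    stop("invalid IUPAC nucleotide code: '", symbol, "'", call. = FALSE)
  }
  strsplit(map[[symbol]], "")[[1L]]
}

#' Expand a degenerate codon
#'
#' Enumerates every concrete codon a 3-letter IUPAC scheme stands for. All
#' expanded codons are equiprobable (degenerate oligos are synthesized as
#' equimolar base mixtures), so each gets probability 1/(expansion size).
#'
#' @param scheme 3-letter IUPAC string, e.g. `"NNK"`.
#' @return A data.frame with columns `codon` (lexicographically sorted) and
#'   `probability`.
#' @export
#' @examples
#' nrow(expand_degenerate_codon("NNM"))  # 32
#' expand_degenerate_codon("ATG")        # single codon, probability 1
expand_degenerate_codon <- function(scheme) {
  scheme <- toupper(as.character(scheme))
  if (length(scheme) != 1L || nchar(scheme) != 3L) {
    stop("scheme must be a single 3-letter IUPAC string", call. = FALSE)
  }
  sets <- lapply(strsplit(scheme, "")[[1L]], iupac_expand)
  grid <- expand.grid(p3 = sets[[3L]], p2 = sets[[2L]], p1 = sets[[1L]],
                      stringsAsFactors = FALSE)
  codons <- sort(paste0(grid$p1, grid$p2, grid$p3))
  data.frame(codon = codons, probability = 1 / length(codons),
             stringsAsFactors = FALSE)
}

#' Variant distribution of a degenerate codon
#'
#' Probability of each amino-acid variant (and of a stop, symbol `"*"`) at a
#' position randomized with the given scheme: the fraction of expanded codons
#' translating to that variant. These are the per-variant probabilities
#' feeding all completeness and screening statistics.
#'
#' @param scheme 3-letter IUPAC string, or an already-built
#'   `variant_distribution` (returned unchanged).
#' @param include_zero Report unreachable amino acids with probability 0?
#' @return An object of class `variant_distribution`: a list with `probs`
#'   (named numeric, sums to 1), `counts` (codons per variant), `size`
#'   (expansion size) and `scheme`.
#' @export
#' @examples
#' d <- amino_acid_distribution("NNM")
#' d$probs[["L"]] * d$size  # 3 of the 32 codons encode Leu
#' reachable_variants(d)    # 18 amino acids plus "*"
amino_acid_distribution <- function(scheme, include_zero = FALSE) {
  if (inherits(scheme, "variant_distribution")) return(scheme)
  exp_df <- expand_degenerate_codon(scheme)
  aa <- translate_codon(exp_df$codon)
  counts <- table(factor(aa, levels = c(.AA20, "*")))
  counts <- c(counts)
  if (!include_zero) counts <- counts[counts > 0L]
  new_variant_distribution(counts / nrow(exp_df),
                           counts = counts, size = nrow(exp_df),
                           scheme = toupper(scheme))
}

#' Build a variant distribution from explicit probabilities
#'
#' For toy models and simulation studies: wraps a named probability vector in
#' the same container [amino_acid_distribution()] returns. Mass not assigned
#' to any named variant is allowed (it behaves as off-target draws, like stop
#' codons do in real schemes) but probabilities must not exceed 1.
#'
#' @param probs Named nonnegative numeric vector, `sum(probs) <= 1`.
#' @return A `variant_distribution`.
#' @export
variant_distribution <- function(probs) {
  if (is.null(names(probs)) || any(!nzchar(names(probs)))) {
    stop("probs must be a fully named vector", call. = FALSE)
  }
  if (anyDuplicated(names(probs))) stop("duplicate variant names", call. = FALSE)
  if (any(probs < 0)) stop("negative probabilities", call. = FALSE)
  if (sum(probs) > 1 + 1e-12) stop("probabilities sum to more than 1", call. = FALSE)
  new_variant_distribution(probs, counts = NULL, size = NA_integer_,
                           scheme = NA_character_)
}

new_variant_distribution <- function(probs, counts, size, scheme) {
  structure(list(probs = probs, counts = counts, size = size, scheme = scheme),
            class = "variant_distribution")
}

#' @export
print.variant_distribution <- function(x, ...) {
  hdr <- if (is.na(x$scheme)) "variant distribution" else
    sprintf("variant distribution for %s (%d codons)", x$scheme, x$size)
  cat(hdr, "\n")
  print(round(x$probs, 6))
  invisible(x)
}

#' Variants reachable under a distribution
#'
#' @param dist A `variant_distribution` (or scheme string).
#' @param include_stop Keep `"*"` in the result?
#' @return Character vector of variant symbols with probability > 0.
#' @export
reachable_variants <- function(dist, include_stop = TRUE) {
  dist <- amino_acid_distribution(dist)
  out <- names(dist$probs)[dist$probs > 0]
  if (!include_stop) out <- setdiff(out, "*")
  out
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Handles the full ambiguity alphabet (M<->K, R<->Y, B<->V, D<->H; S, W, N
#' self-complementary) and preserves case, so a mixed-case primer such as
#' `"cct...NNM...ggc"` reverse-complements to `"gcc...KNN...agg"`.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Reverse complement(s), same lengths and case pattern (reversed).
#' @export
#' @examples
#' reverse_complement("NNM")  # "KNN"
#' reverse_complement(reverse_complement("ACGTmkrw"))  # involution
reverse_complement <- function(seq) {
  seq <- as.character(seq)
  bad <- grepl(sprintf("[^%s%s]", .IUPAC_CHARS, tolower(.IUPAC_CHARS)), seq)
  if (any(bad)) {
    stop("invalid nucleotide character(s) in: ",
         paste(seq[bad], collapse = ", "), call. = FALSE)
  }
  comp <- chartr(paste0(.IUPAC_CHARS, tolower(.IUPAC_CHARS)),
                 paste0(.IUPAC_COMP, tolower(.IUPAC_COMP)),
                 seq)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# internal: probabilities for a set of target symbols, with validation
.target_probs <- function(dist, targets) {
  dist <- amino_acid_distribution(dist)
  targets <- unique(as.character(targets))
  if (length(targets) == 0L) return(numeric(0))
  known <- c(.AA20, "*")
  bad <- setdiff(targets, known)
  if (length(bad)) {
    # permit symbols present in a custom distribution even if not amino acids
    bad <- setdiff(bad, names(dist$probs))
    if (length(bad)) stop("unknown variant symbol(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  p <- dist$probs[targets]
  p[is.na(p)] <- 0
  names(p) <- targets
  p
}
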