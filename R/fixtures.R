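# Synthetic sequence fixtures, generated in code.

.SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]

#' Generate a synthetic template CDS
#'
#' Deterministic random coding sequence for tests and examples: ATG start,
#' sense codons throughout, TAA as the final codon. Same seed, same
#' sequence; the caller's RNG stream is left untouched.
#'
#' @param length_codons Total codons including start and stop, >= 3.
#' @param seed Integer seed.
#' @return A `template_cds`.
#' @export
#' @examples
#' tpl <- generate_fixture_template(125, seed = 1)
#' codon_at(tpl, 100)  # extractable with (18, 21) flanks
generate_fixture_template <- function(length_codons, seed) {
  stopifnot(length_codons >= 3L)
  body <- .with_seed(seed, function()
    sample(.SENSE_CODONS, length_codons - 2L, replace = TRUE))
  template_cds(paste0(c("ATG", body, "TAA"), collapse = ""),
               id = sprintf("synthetic_cds_%dcod_seed%d", length_codons, seed))
}

#' Synthetic Zm-p60.1 template around codon W373
#'
#' A 400-codon stand-in for the Zm-p60.1 coding sequence. Only codons
#' 367-380 are authentic — the 42-nt stretch read off the published
#' mutagenic primer region, placing the wild-type TGG at codon 373 — and the
#' remainder is a fixed synthetic CDS. Sufficient for primer design around
#' codon 373 with flanks up to (18, 21); everything outside that window is
#' synthetic filler.
#'
#' @return A `template_cds` with id `"zmp60_synthetic"`.
#' @export
#' @examples
#' codon_at(zmp60_w373_template(), 373)  # "TGG"
zmp60_w373_template <- function() {
  tpl <- generate_fixture_template(400L, seed = 373L)
  window <- toupper("cctcctatgggaaatccatggatctacatgtaccctgagggc")
  seq <- tpl$sequence
  substr(seq, 1099L, 1140L) <- window  # codons 367-380
  template_cds(seq, id = "zmp60_synthetic")
}
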