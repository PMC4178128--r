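# QuikChange-style mutagenic primer design: one degenerate primer pair to
# randomize a codon, and individual completion primers for the variants a
# screen failed to deliver.

#' Template coding sequence
#'
#' A CDS with 1-based amino-acid codon coordinates: codon `k` occupies bases
#' `3(k-1)+1 .. 3k`. The stored sequence is normalized to uppercase.
#'
#' @param sequence DNA string, length >= 3 and a multiple of 3 after the
#'   frame offset.
#' @param id Sequence identifier.
#' @param frame_offset Bases before codon 1 (default 0: in frame).
#' @return An object of class `template_cds`.
#' @export
template_cds <- function(sequence, id = "template", frame_offset = 0L) {
  sequence <- toupper(gsub("\\s", "", as.character(sequence)))
  if (grepl("[^ACGT]", sequence)) {
    stop("template contains non-ACGT characters", call. = FALSE)
  }
  if (nchar(sequence) - frame_offset < 3L) {
    stop("template shorter than one codon", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence,
                 frame_offset = as.integer(frame_offset)),
            class = "template_cds")
}

#' @export
print.template_cds <- function(x, ...) {
  cat(sprintf("template CDS '%s': %d nt (%d codons)\n", x$id,
              nchar(x$sequence), n_codons(x)))
  invisible(x)
}

#' Number of complete codons in a template
#' @param template A `template_cds`.
#' @return Integer codon count.
#' @export
n_codons <- function(template) {
  (nchar(template$sequence) - template$frame_offset) %/% 3L
}

#' Extract the codon at an amino-acid position
#' @param template A `template_cds`.
#' @param codon_pos 1-based amino-acid index.
#' @return 3-letter codon string.
#' @export
codon_at <- function(template, codon_pos) {
  .check_codon_pos(template, codon_pos)
  start <- template$frame_offset + 3L * (codon_pos - 1L) + 1L
  substr(template$sequence, start, start + 2L)
}

.check_codon_pos <- function(template, codon_pos) {
  stopifnot(length(codon_pos) == 1L, codon_pos == floor(codon_pos))
  if (codon_pos < 1L || codon_pos > n_codons(template)) {
    stop("codon position ", codon_pos, " outside template (",
         n_codons(template), " codons)", call. = FALSE)
  }
  invisible(codon_pos)
}

#' Read templates from a FASTA file
#'
#' @param path FASTA file of DNA sequences.
#' @param frame_offset Applied to every record.
#' @return A list of `template_cds`, named by record id.
#' @export
read_template_fasta <- function(path, frame_offset = 0L) {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i)
    template_cds(as.character(set[[i]]), id = names(set)[i],
                 frame_offset = frame_offset))
  stats::setNames(out, names(set))
}

# forward-strand mutagenic sequence: lowercase flanks, uppercase codon
.mutagenic_forward <- function(template, codon_pos, codon, flank_up, flank_dn) {
  .check_codon_pos(template, codon_pos)
  stopifnot(flank_up >= 0, flank_dn >= 0)
  start <- template$frame_offset + 3L * (codon_pos - 1L) + 1L
  if (start - flank_up < 1L || start + 2L + flank_dn > nchar(template$sequence)) {
    stop("flanks (", flank_up, ", ", flank_dn,
         ") exceed template bounds around codon ", codon_pos, call. = FALSE)
  }
  up <- substr(template$sequence, start - flank_up, start - 1L)
  dn <- substr(template$sequence, start + 3L, start + 2L + flank_dn)
  paste0(tolower(up), toupper(codon), tolower(dn))
}

#' Design a degenerate QuikChange primer pair
#'
#' The forward primer is the template around the chosen codon with the codon
#' replaced by the degeneracy scheme; the reverse primer is its exact
#' reverse complement (degenerate codes complement too: NNM -> KNN). Flanks
#' are written lowercase and the mutated codon uppercase, the usual way
#' mutagenic oligos are printed.
#'
#' @param template A `template_cds`.
#' @param codon_pos 1-based amino-acid position to randomize.
#' @param scheme 3-letter IUPAC degeneracy, e.g. `"NNM"`.
#' @param flank_up,flank_dn Flank lengths in bases (defaults 18 and 21,
#'   typical for whole-plasmid mutagenesis primers).
#' @return A `primer_pair`: `forward`, `reverse`, `codon_pos`, `scheme`,
#'   `wt_codon`, `flank_up`, `flank_dn`.
#' @export
#' @examples
#' tpl <- zmp60_w373_template()
#' pp <- design_degenerate_primer_pair(tpl, 373, "NNM")
#' pp$forward  # "cctcctatgggaaatccaNNMatctacatgtaccctgagggc"
design_degenerate_primer_pair <- function(template, codon_pos, scheme,
                                          flank_up = 18L, flank_dn = 21L) {
  scheme <- toupper(scheme)
  invisible(expand_degenerate_codon(scheme))  # validates IUPAC symbols
  fwd <- .mutagenic_forward(template, codon_pos, scheme, flank_up, flank_dn)
  structure(list(forward = fwd, reverse = reverse_complement(fwd),
                 codon_pos = codon_pos, scheme = scheme,
                 wt_codon = codon_at(template, codon_pos),
                 flank_up = flank_up, flank_dn = flank_dn),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("degenerate primer pair (%s at codon %d, wild type %s):\n",
              x$scheme, x$codon_pos, x$wt_codon))
  cat("  fwd 5'-", x$forward, "-3'\n  rev 5'-", x$reverse, "-3'\n", sep = "")
  invisible(x)
}

#' Design completion primers for missing variants
#'
#' One site-directed mutagenesis primer per missing variant, with the same
#' flanks as the degenerate design. The codon used for each variant comes
#' from an explicit `codon_choice` table (see [zmp60_codon_table()] for the
#' choices used in the Zm-p60.1 W373 library). Primers are returned in
#' variant-symbol order; the reverse strand is the primary output (matching
#' how completion oligos are usually ordered), the forward strand is
#' included too.
#'
#' @param template A `template_cds`.
#' @param codon_pos 1-based amino-acid position.
#' @param missing_variants Character vector of one-letter variant symbols.
#' @param codon_choice Named character vector, variant -> codon. Every
#'   missing variant needs an entry, and each codon must translate to its
#'   variant.
#' @param flank_up,flank_dn Flank lengths (defaults as in the degenerate
#'   pair).
#' @return List of `completion_primer` objects (possibly empty), each with
#'   `variant`, `codon`, `reverse`, `forward`.
#' @export
#' @examples
#' tpl <- zmp60_w373_template()
#' cp <- design_completion_primers(tpl, 373, "C")
#' cp[["C"]]$reverse  # "gccctcagggtacatgtagatGCAtggatttcccataggagg"
design_completion_primers <- function(template, codon_pos, missing_variants,
                                      codon_choice = zmp60_codon_table(),
                                      flank_up = 18L, flank_dn = 21L) {
  missing_variants <- sort(unique(as.character(missing_variants)))
  if (length(missing_variants) == 0L) return(list())
  absent <- setdiff(missing_variants, names(codon_choice))
  if (length(absent)) {
    stop("no codon chosen for variant(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  primers <- lapply(missing_variants, function(v) {
    codon <- toupper(codon_choice[[v]])
    got <- translate_codon(codon)
    if (got != v) {
      stop("codon ", codon, " translates to '", got, "', not '", v, "'",
           call. = FALSE)
    }
    fwd <- .mutagenic_forward(template, codon_pos, codon, flank_up, flank_dn)
    structure(list(variant = v, codon = codon,
                   reverse = reverse_complement(fwd), forward = fwd),
              class = "completion_primer")
  })
  stats::setNames(primers, missing_variants)
}

#' @export
print.completion_primer <- function(x, ...) {
  cat(sprintf("completion primer %s (codon %s):\n  rev 5'-%s-3'\n",
              x$variant, x$codon, x$reverse))
  invisible(x)
}

#' Completion codons used for the Zm-p60.1 W373 library
#'
#' The variant-to-codon choices used to finish that library by SDM:
#' eight variants completed after the random screen (Cys, Glu, Ile, Met,
#' Asn, Gln, Val, Tyr) plus the resynthesized Ser (TCC) and Leu (CTG)
#' codons. No codon-usage rule generates this table; it ships as a named
#' fixture.
#'
#' @return Named character vector, variant symbol -> codon.
#' @export
#' @examples
#' zmp60_codon_table()[["E"]]  # "GAA"
zmp60_codon_table <- function() {
  tab <- c(C = "TGC", E = "GAA", I = "ATT", M = "ATG", N = "AAC",
           Q = "CAG", V = "GTG", Y = "TAT", S = "TCC", L = "CTG")
  stopifnot(all(translate_codon(tab) == names(tab)))
  tab
}

#' Write primers as TSV
#'
#' Columns: name, strand, sequence, codon, variant.
#'
#' @param primers A `primer_pair`, a `completion_primer`, or a list of them.
#' @param path Output file, or `""` for stdout.
#' @return Data.frame of rows written, invisibly.
#' @export
write_primer_tsv <- function(primers, path = "") {
  rows <- .primer_rows(primers)
  utils::write.table(rows, if (nzchar(path)) path else stdout(),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' Write primers as FASTA
#'
#' @inheritParams write_primer_tsv
#' @return Data.frame of rows written, invisibly.
#' @export
write_primer_fasta <- function(primers, path = "") {
  rows <- .primer_rows(primers)
  lines <- as.vector(rbind(paste0(">", rows$name), rows$sequence))
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(rows)
}

.primer_rows <- function(primers) {
  if (inherits(primers, c("primer_pair", "completion_primer"))) {
    primers <- list(primers)
  }
  rows <- lapply(primers, function(p) {
    if (inherits(p, "primer_pair")) {
      data.frame(name = paste0("degenerate_", p$scheme, c("_fwd", "_rev")),
                 strand = c("+", "-"), sequence = c(p$forward, p$reverse),
                 codon = p$scheme, variant = NA_character_)
    } else {
      data.frame(name = paste0("completion_", p$variant, c("_rev", "_fwd")),
                 strand = c("-", "+"), sequence = c(p$reverse, p$forward),
                 codon = p$codon, variant = p$variant)
    }
  })
  do.call(rbind, rows)
}
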