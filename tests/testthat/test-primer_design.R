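test_that("template coordinates are 1-based codon indices", {
  tpl <- template_cds("ATGAAATTTGGGTAA")
  expect_identical(n_codons(tpl), 5L)
  expect_identical(codon_at(tpl, 1), "ATG")
  expect_identical(codon_at(tpl, 4), "GGG")
  expect_error(codon_at(tpl, 6), "outside template")
  expect_error(template_cds("ATGNNN"), "non-ACGT")
  expect_error(template_cds("AT"), "shorter")
  # frame offset shifts codon 1
  off <- template_cds("GGATGAAATTT", frame_offset = 2)
  expect_identical(codon_at(off, 1), "ATG")
})

test_that("the synthetic Zm-p60.1 template carries the authentic window", {
  tpl <- zmp60_w373_template()
  expect_identical(codon_at(tpl, 373), "TGG")
  expect_identical(translate_codon(codon_at(tpl, 373)), "W")
  window <- substr(tpl$sequence, 1099, 1140)
  expect_identical(tolower(window), tolower(paste0(
    "cctcctatgggaaatcca", "tgg", "atctacatgtaccctgagggc")))
  expect_identical(n_codons(tpl), 400L)
})

test_that("degenerate pair reproduces the printed NNM oligos exactly", {
  tpl <- zmp60_w373_template()
  pp <- design_degenerate_primer_pair(tpl, 373, "NNM")
  expect_identical(pp$forward, printed_fwd_nnm)
  expect_identical(pp$reverse, printed_rev_nnm)
  expect_identical(pp$wt_codon, "TGG")
  expect_identical(pp$flank_up, 18L)
  expect_identical(pp$flank_dn, 21L)
})

test_that("degenerate pair properties hold on random templates", {
  set.seed(17)
  for (rep in 1:5) {
    tpl <- generate_fixture_template(60, seed = rep)
    pos <- sample(10:50, 1)
    pp <- design_degenerate_primer_pair(tpl, pos, "NNK",
                                        flank_up = 9, flank_dn = 12)
    expect_identical(pp$reverse, reverse_complement(pp$forward))
    # scheme equal to the wild type: forward primer is the template slice
    wt <- codon_at(tpl, pos)
    same <- design_degenerate_primer_pair(tpl, pos, wt,
                                          flank_up = 9, flank_dn = 12)
    start <- 3 * (pos - 1) + 1
    expect_identical(toupper(same$forward),
                     substr(tpl$sequence, start - 9, start + 2 + 12))
  }
})

test_that("flank and position errors are caught", {
  tpl <- generate_fixture_template(20, seed = 1)
  expect_error(design_degenerate_primer_pair(tpl, 1, "NNK"), "flanks")
  expect_error(design_degenerate_primer_pair(tpl, 21, "NNK"), "outside")
  expect_error(design_degenerate_primer_pair(tpl, 10, "NXN"), "X")
})

test_that("completion primers reproduce all eight printed oligos", {
  tpl <- zmp60_w373_template()
  cp <- design_completion_primers(tpl, 373, names(printed_completion_rev))
  expect_identical(names(cp), sort(names(printed_completion_rev)))
  for (v in names(printed_completion_rev)) {
    expect_identical(cp[[v]]$reverse, printed_completion_rev[[v]],
                     info = paste("variant", v))
    expect_identical(cp[[v]]$forward, reverse_complement(cp[[v]]$reverse))
  }
})

test_that("completion primer round trip: mutated template translates to target", {
  tpl <- generate_fixture_template(50, seed = 5)
  tab <- zmp60_codon_table()
  # extend the table to all 20 variants using each amino acid's first codon
  gc <- standard_genetic_code()
  full <- vapply(amino_acids(), function(a) names(gc)[gc == a][1], "")
  full[names(tab)] <- tab
  cp <- design_completion_primers(tpl, 25, amino_acids(), codon_choice = full,
                                  flank_up = 6, flank_dn = 6)
  expect_length(cp, 20)
  for (p in cp) {
    mutated <- tpl$sequence
    substr(mutated, 3 * 24 + 1, 3 * 24 + 3) <- p$codon
    expect_identical(translate_codon(substr(mutated, 73, 75)), p$variant)
    # the reverse strand carries the reverse complement of the codon
    expect_match(p$reverse, reverse_complement(p$codon), fixed = TRUE)
  }
})

test_that("completion primer validation", {
  tpl <- zmp60_w373_template()
  expect_identical(design_completion_primers(tpl, 373, character(0)), list())
  expect_error(design_completion_primers(tpl, 373, "A"), "no codon chosen")
  expect_error(design_completion_primers(tpl, 373, "C",
                                         codon_choice = c(C = "GGG")),
               "translates to 'G', not 'C'")
})

test_that("the fixture codon table is self-consistent and matches the printed choices", {
  tab <- zmp60_codon_table()
  expect_identical(tab[["E"]], "GAA")
  expect_identical(reverse_complement(tab[["E"]]), "TTC")
  expect_identical(tab[["S"]], "TCC")
  expect_identical(tab[["L"]], "CTG")
  expect_identical(unname(translate_codon(tab)), names(tab))
})

test_that("FASTA template IO and primer writers round-trip", {
  tpl <- generate_fixture_template(40, seed = 2)
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(paste0(">", tpl$id), tpl$sequence), fa)
  back <- read_template_fasta(fa)
  expect_identical(back[[1]]$sequence, tpl$sequence)

  pp <- design_degenerate_primer_pair(tpl, 20, "NNM", flank_up = 9, flank_dn = 9)
  cp <- design_completion_primers(tpl, 20, "C", flank_up = 9, flank_dn = 9)
  tsv <- tempfile(fileext = ".tsv")
  rows <- write_primer_tsv(c(list(pp), cp), tsv)
  tab <- read.delim(tsv)
  expect_identical(nrow(tab), 4L)  # pair + completion primer, 2 strands each
  expect_setequal(tab$strand, c("+", "-"))
  fq <- tempfile(fileext = ".fasta")
  write_primer_fasta(c(list(pp), cp), fq)
  lines <- readLines(fq)
  expect_identical(sum(startsWith(lines, ">")), 4L)
  expect_identical(lines[2], pp$forward)
})
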