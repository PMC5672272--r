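test_that("gc_content counts unambiguous bases only", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGT"), 50)
  expect_equal(gc_content("ACGTNNRY"), 50) # ambiguity codes excluded
  expect_error(gc_content(""), class = "karyometry_argument_error")
  expect_error(gc_content("NNN"), class = "karyometry_argument_error")
})

test_that("gc_content is invariant under reverse complement", {
  set.seed(4)
  for (rep in 1:20) {
    seq <- random_dna(sample(10:200, 1))
    expect_equal(gc_content(seq), gc_content(revcomp(seq)))
  }
})

test_that("global alignment handles the base cases", {
  seq <- "ACGTACGT"
  aln <- global_align(seq, seq)
  expect_equal(aln$a, seq)
  expect_equal(aln$b, seq)
  expect_equal(aln$score, nchar(seq))
  expect_equal(percent_identity(aln), 100)

  # one deletion column: ACGT / AC-T scores 3 matches + one gap open
  aln2 <- global_align("ACGT", "ACT", match = 1, mismatch = -1, gap_open = -2)
  expect_equal(aln2$score, 1)
  expect_equal(nchar(aln2$a), 4)
  expect_equal(sum(strsplit(aln2$b, "")[[1]] == "-"), 1)
})

test_that("the aligner matches the exhaustive enumeration oracle", {
  set.seed(17)
  for (rep in 1:40) {
    la <- sample(1:6, 1)
    lb <- sample(1:6, 1)
    a <- random_dna(la)
    b <- random_dna(lb)
    got <- global_align(a, b)
    expect_equal(got$score, enumerate_best_score(a, b), info = paste(a, b))
    # the alignment it reports attains the score it claims
    expect_equal(score_alignment(got$a, got$b), got$score)
  }
})

test_that("the aligner matches an independent implementation up to length 12", {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  set.seed(18)
  for (rep in 1:25) {
    a <- random_dna(sample(7:12, 1))
    b <- random_dna(sample(7:12, 1))
    got <- global_align(a, b) # open -4 = first gap position; extend -1 thereafter
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = submat,
      gapOpening = 3, gapExtension = 1, scoreOnly = TRUE
    )
    expect_equal(got$score, ref, info = paste(a, b))
  }
})

test_that("variable sites and identity share the trimmed denominator", {
  aln <- list(a = "AC-GT", b = "ACTGT")
  counts <- count_variable_sites(aln)
  expect_equal(counts$variable_sites, 1)
  expect_equal(counts$aligned_columns, 5)
  expect_equal(percent_identity(aln), 80)

  # terminal gap columns are trimmed before counting
  aln2 <- list(a = "--ACGT", b = "GGACGT")
  expect_equal(count_variable_sites(aln2)$aligned_columns, 4)
  expect_equal(percent_identity(aln2), 100)

  ident <- global_align("ACACGT", "ACACGT")
  expect_equal(count_variable_sites(ident)$variable_sites, 0)

  set.seed(6)
  for (rep in 1:20) {
    aln3 <- global_align(random_dna(30), random_dna(25))
    counts3 <- count_variable_sites(aln3)
    expect_equal(
      percent_identity(aln3) + 100 * counts3$variable_sites / counts3$aligned_columns,
      100
    )
  }
})

test_that("dissection recovers the published amplicon arithmetic", {
  # minor amplicon: 40 + NTS + 58
  sim_minor <- simulate_amplicons(nts_length_a = 361, seed = 2)
  minor <- dissect_amplicon(sim_minor$sequences[["minor"]], seq_id = "minor")
  expect_equal(minor$amplicon_class, "minor")
  expect_equal(nchar(sim_minor$sequences[["minor"]]), 459)
  expect_equal(minor$segments$length, c(40L, 361L, 58L))

  # 940-bp major: 40 + 361 + 120 + 361 + 58
  major <- dissect_amplicon(sim_minor$sequences[["major"]], seq_id = "major")
  expect_equal(major$amplicon_class, "major")
  expect_equal(major$segments$length, c(40L, 361L, 120L, 361L, 58L))
  expect_equal(sum(major$segments$length), 940)

  # 948-bp major with unequal spacers: 40 + 359 + 120 + 371 + 58
  sim948 <- simulate_amplicons(nts_length_a = 359, nts_length_b = 371, seed = 3)
  major948 <- dissect_amplicon(sim948$sequences[["major"]])
  expect_equal(major948$segments$length, c(40L, 359L, 120L, 371L, 58L))
  expect_equal(sum(major948$segments$length), 948)

  # segments tile the amplicon exactly
  expect_equal(major$segments$start[-1], head(major$segments$end, -1) + 1L)
  expect_equal(major$segments$end[nrow(major$segments)], 940L)
})

test_that("dissection errors are specific", {
  expect_error(dissect_amplicon(random_dna(90)), "too short",
               class = "karyometry_validation_error")
  # internal near-match whose AGG start is mutated: annotation error
  sim <- simulate_amplicons(seed = 5)
  seq <- sim$sequences[["major"]]
  gene_start <- 40 + 361 + 1
  broken <- paste0(substr(seq, 1, gene_start - 1), "CGG",
                   substr(seq, gene_start + 3, nchar(seq)))
  expect_error(dissect_amplicon(broken), "AGG",
               class = "karyometry_annotation_error")
})

test_that("within- and cross-unit NTS comparisons report pooled counts", {
  sim <- simulate_amplicons(divergence = 0, indel_rate = 0, seed = 7)
  amp <- dissect_amplicon(sim$sequences[["major"]])
  cmp <- compare_nts(amp)
  expect_equal(cmp$variable_sites, 0)
  expect_equal(cmp$identity, 100)

  simb <- simulate_amplicons(divergence = 0.15, seed = 8)
  ampb <- dissect_amplicon(simb$sequences[["major"]])
  cross <- compare_nts_pairs(amp, ampb)
  expect_equal(cross$region, c("nts1", "nts2", "combined"))
  combined <- cross[cross$region == "combined", ]
  expect_equal(combined$aligned_columns,
               sum(cross$aligned_columns[cross$region != "combined"]))
  expect_equal(combined$identity,
               100 * (1 - combined$variable_sites / combined$aligned_columns))
})

test_that("promoter motifs are located, scored, and flagged absent", {
  gene <- gene_consensus_5s()
  hits <- find_promoter(gene)
  expect_equal(hits$element, c("a_box", "intermediate_element", "c_box"))
  expect_true(all(hits$present))
  expect_equal(hits$start, c(50L, 67L, 81L))
  expect_true(hits$start[1] < hits$start[2] && hits$start[2] < hits$start[3])

  # one mutated base: same location, lower score
  mutated <- paste0(substr(gene, 1, 49), "T", substr(gene, 51, 120))
  expect_true(substr(gene, 50, 50) != "T")
  hits2 <- find_promoter(mutated)
  expect_equal(hits2$start[1], 50L)
  expect_lt(hits2$score[1], 1)

  set.seed(9)
  scrambled <- paste(sample(strsplit(gene, "")[[1]]), collapse = "")
  hits3 <- find_promoter(scrambled, threshold = 0.9)
  expect_false(any(hits3$present[hits3$element %in% c("a_box", "c_box")]))
})

test_that("FASTA and GenBank readers round-trip sequences", {
  sim <- simulate_amplicons(seed = 10)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_amplicon_fasta(sim$sequences, fa)
  back <- read_amplicon_fasta(fa)
  expect_equal(back, sim$sequences)

  gb <- withr::local_tempfile(fileext = ".gb")
  seq <- sim$sequences[["minor"]]
  chunks <- substring(seq, seq(1, nchar(seq), 60), pmin(seq(60, nchar(seq) + 59, 60), nchar(seq)))
  writeLines(c(
    "LOCUS       SYNTH0001               459 bp    DNA     linear   PLN",
    "DEFINITION  synthetic 5S rDNA amplicon stand-in.",
    "ACCESSION   SYNTH0001",
    "ORIGIN",
    sprintf("%9d %s", seq(1, nchar(seq), 60), tolower(chunks)),
    "//"
  ), gb)
  parsed <- read_genbank_seq(gb)
  expect_equal(names(parsed), "SYNTH0001")
  expect_equal(unname(parsed), seq)
})
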