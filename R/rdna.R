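#' Default 120-bp 5S rRNA gene consensus (synthetic)
#'
#' A synthetic 120-bp stand-in for the conserved plant 5S rRNA gene used as
#' the default template by [dissect_amplicon()], [find_promoter()] and
#' [simulate_amplicons()]. It is anchored on the two published 5S PCR
#' primer sites (the forward primer footprint at gene positions 81-105 and
#' the reverse-complemented reverse-primer footprint at positions 34-58),
#' starts with `AGG`, ends with `TCC`, and uses fixed filler elsewhere. It
#' is not the sequence of any real accession.
#'
#' @return A single 120-character DNA string.
#' @export
gene_consensus_5s <- function() {
  paste0(
    "AGG",                             # gene start, positions 1-3
    "ATGCTTGGGTGTCACCACCTGAGCACGCCT",  # filler, 4-33
    "CCCATCAGAACTCCGCAGTTAAGCG",       # reverse-primer footprint (rc), 34-58
    "TGGGCGAGAGTAGTACTAGGAT",          # filler, 59-80
    "GGATGGGTGACCTCCCGGGAAGTCC",       # forward-primer footprint, 81-105
    "TCGAGAGGTACA",                    # filler, 106-117
    "TCC"                              # gene end, 118-120
  )
}

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

#' GC content of a DNA segment
#'
#' 100 x (G + C) / (A + C + G + T). IUPAC ambiguity codes and gaps are
#' excluded from both numerator and denominator.
#'
#' @param segment DNA string (or character vector of strings, vectorised).
#' @return Percent GC.
#' @examples
#' gc_content("GGCC")
#' @export
gc_content <- function(segment) {
  if (length(segment) > 1) return(vapply(segment, gc_content, 0, USE.NAMES = FALSE))
  if (!is.character(segment) || length(segment) != 1L || !nzchar(segment)) {
    stop_arg("`segment` must be a non-empty DNA string")
  }
  ch <- seq_chars(segment)
  acgt <- ch[ch %in% c("A", "C", "G", "T")]
  if (length(acgt) == 0) stop_arg("segment contains no unambiguous bases")
  100 * sum(acgt %in% c("G", "C")) / length(acgt)
}

#' Global pairwise alignment with affine gap costs
#'
#' A plain global (end-to-end) aligner under an affine gap scheme: a gap of
#' length L costs `gap_open + (L - 1) * gap_extend`. Ties are broken
#' deterministically, preferring the diagonal (substitution) move, then the
#' vertical (gap in `b`), then the horizontal (gap in `a`).
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters. Defaults
#'   (+1/-1/-4/-1) are near the classic progressive-aligner defaults.
#' @return A list of class `pairwise_alignment`: `a` and `b` (aligned
#'   strings with `-` gaps), `score`, `params`.
#' @examples
#' aln <- global_align("ACGT", "ACT")
#' aln$score
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap_open = -4, gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stop_arg("both sequences must be non-empty")
  av <- seq_chars(a)
  bv <- seq_chars(b)
  n <- length(av)
  m <- length(bv)
  neg <- -1e18

  # state matrices: M ends in a substitution column, X in a gap in b
  # (consumes a; "up"), Y in a gap in a (consumes b; "left")
  M <- matrix(neg, n + 1, m + 1)
  X <- matrix(neg, n + 1, m + 1)
  Y <- matrix(neg, n + 1, m + 1)
  # traceback: which state the maximising predecessor was in (1=M, 2=X, 3=Y)
  Mp <- matrix(0L, n + 1, m + 1)
  Xp <- matrix(0L, n + 1, m + 1)
  Yp <- matrix(0L, n + 1, m + 1)

  M[1, 1] <- 0
  if (n > 0) {
    X[2, 1] <- gap_open
    Xp[2, 1] <- 1L
    if (n > 1) for (i in 3:(n + 1)) { X[i, 1] <- X[i - 1, 1] + gap_extend; Xp[i, 1] <- 2L }
  }
  if (m > 0) {
    Y[1, 2] <- gap_open
    Yp[1, 2] <- 1L
    if (m > 1) for (j in 3:(m + 1)) { Y[1, j] <- Y[1, j - 1] + gap_extend; Yp[1, j] <- 3L }
  }

  pick3 <- function(vm, vx, vy) {
    # deterministic preference M > X > Y on ties
    if (vm >= vx && vm >= vy) c(vm, 1L) else if (vx >= vy) c(vx, 2L) else c(vy, 3L)
  }

  for (i in 2:(n + 1)) {
    ai <- av[i - 1]
    for (j in 2:(m + 1)) {
      s <- if (ai == bv[j - 1]) match else mismatch
      best <- pick3(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- best[1] + s
      Mp[i, j] <- as.integer(best[2])
      bx <- pick3(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend, Y[i - 1, j] + gap_open)
      X[i, j] <- bx[1]
      Xp[i, j] <- as.integer(bx[2])
      by <- pick3(M[i, j - 1] + gap_open, X[i, j - 1] + gap_open, Y[i, j - 1] + gap_extend)
      Y[i, j] <- by[1]
      Yp[i, j] <- as.integer(by[2])
    }
  }

  end <- pick3(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  score <- end[1]
  state <- as.integer(end[2])

  ares <- character(0)
  bres <- character(0)
  i <- n + 1
  j <- m + 1
  while (i > 1 || j > 1) {
    if (state == 1L) {
      ares <- c(av[i - 1], ares)
      bres <- c(bv[j - 1], bres)
      state <- Mp[i, j]
      i <- i - 1
      j <- j - 1
    } else if (state == 2L) {
      ares <- c(av[i - 1], ares)
      bres <- c("-", bres)
      state <- Xp[i, j]
      i <- i - 1
    } else {
      ares <- c("-", ares)
      bres <- c(bv[j - 1], bres)
      state <- Yp[i, j]
      j <- j - 1
    }
  }

  structure(
    list(
      a = paste(ares, collapse = ""), b = paste(bres, collapse = ""),
      score = score,
      params = c(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend)
    ),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<global alignment> score %g over %d columns\n", x$score, nchar(x$a)))
  cat(x$a, "\n")
  cat(x$b, "\n")
  invisible(x)
}

# drop terminal-gap columns: maximal prefix/suffix runs where either row is
# gapped (primer-anchored amplicons have no meaningful overhangs)
trim_terminal_gaps <- function(aln) {
  am <- seq_chars(aln$a)
  bm <- seq_chars(aln$b)
  gap <- am == "-" | bm == "-"
  keep <- rep(TRUE, length(gap))
  i <- 1
  while (i <= length(gap) && gap[i]) { keep[i] <- FALSE; i <- i + 1 }
  i <- length(gap)
  while (i >= 1 && gap[i]) { keep[i] <- FALSE; i <- i - 1 }
  list(a = am[keep], b = bm[keep])
}

#' Variable sites of a pairwise alignment
#'
#' Counts alignment columns where the two residues differ or exactly one
#' sequence is gapped, over the columns remaining after trimming
#' terminal-gap columns. Gapped internal columns count as variable.
#'
#' @param alignment A `pairwise_alignment` (or a list with aligned strings
#'   `a` and `b`).
#' @return A one-row tibble with `variable_sites` and `aligned_columns`.
#' @examples
#' count_variable_sites(global_align("ACGT", "ACTT"))
#' @export
count_variable_sites <- function(alignment) {
  cols <- trim_terminal_gaps(alignment)
  tibble(
    variable_sites = sum(cols$a != cols$b),
    aligned_columns = length(cols$a)
  )
}

#' Percent identity of a pairwise alignment
#'
#' 100 x matching columns / aligned columns, with the same terminal-gap
#' trimmed denominator as [count_variable_sites()], so
#' `identity + 100 * variable/columns = 100` exactly.
#'
#' @inheritParams count_variable_sites
#' @return Percent identity.
#' @export
percent_identity <- function(alignment) {
  cols <- trim_terminal_gaps(alignment)
  100 * sum(cols$a == cols$b) / length(cols$a)
}

#' Dissect a 5S rDNA amplicon into gene and spacer segments
#'
#' 5S rDNA amplicons produced by primers annealing inside the gene carry
#' 40 bp of the gene 3' portion at the amplicon 5' end and 58 bp of the
#' gene 5' portion at the 3' end. A minor amplicon spans one repeat-unit
#' junction (gene tail + NTS + gene head); a major amplicon spans a full
#' unit and carries two NTS regions separated by the whole 120-bp gene.
#' The internal gene is located by the best ungapped match to
#' `gene_consensus`; a match is accepted when its identity reaches
#' `min_similarity` and the matched segment starts `AGG` and ends `TCC`.
#'
#' @param sequence Amplicon DNA string (length > 98).
#' @param gene_consensus 120-bp gene template (default [gene_consensus_5s()]).
#' @param min_similarity Minimum identity fraction for the internal gene
#'   match (default 0.9).
#' @param seq_id Identifier carried into the result.
#' @return An object of class `repeat_amplicon`: list with `seq_id`,
#'   `sequence`, `amplicon_class` (`"minor"` or `"major"`),
#'   `gene_similarity` and `segments`, a tibble of 1-based inclusive
#'   intervals (`segment`, `start`, `end`, `length`, `sequence`) tiling
#'   the amplicon: `flank5`, `nts1`, (`gene`, `nts2` for major), `flank3`.
#' @examples
#' sim <- simulate_amplicons(seed = 1)
#' dissect_amplicon(sim$sequences[["major"]])$segments
#' @export
dissect_amplicon <- function(sequence, gene_consensus = gene_consensus_5s(),
                             min_similarity = 0.9, seq_id = "amplicon") {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L <= 98) {
    stop_validation(sprintf(
      "amplicon %s is %d bp: too short for the 40 + 58 bp gene flanks", seq_id, L
    ))
  }
  if (nchar(gene_consensus) != 120) stop_arg("`gene_consensus` must be 120 bp")
  glen <- 120L
  interior_start <- 41L
  interior_end <- L - 58L

  best_sim <- 0
  best_at <- NA_integer_
  if (interior_end - interior_start + 1L >= glen) {
    cons <- seq_chars(gene_consensus)
    ch <- seq_chars(sequence)
    for (start in interior_start:(interior_end - glen + 1L)) {
      sim <- sum(ch[start:(start + glen - 1L)] == cons) / glen
      if (sim > best_sim) {
        best_sim <- sim
        best_at <- start
      }
    }
  }

  seg <- function(name, start, end) {
    tibble(segment = name, start = start, end = end, length = end - start + 1L,
           sequence = substr(sequence, start, end))
  }

  if (!is.na(best_at) && best_sim >= min_similarity) {
    gene_seq <- substr(sequence, best_at, best_at + glen - 1L)
    if (!startsWith(gene_seq, "AGG") || !endsWith(gene_seq, "TCC")) {
      abort(sprintf(
        "internal gene match in %s violates the AGG...TCC boundary convention", seq_id
      ), class = "karyometry_annotation_error")
    }
    segments <- bind_rows(
      seg("flank5", 1L, 40L),
      seg("nts1", 41L, best_at - 1L),
      seg("gene", best_at, best_at + glen - 1L),
      seg("nts2", best_at + glen, L - 58L),
      seg("flank3", L - 57L, L)
    )
    klass <- "major"
  } else {
    segments <- bind_rows(
      seg("flank5", 1L, 40L),
      seg("nts1", 41L, L - 58L),
      seg("flank3", L - 57L, L)
    )
    klass <- "minor"
  }

  structure(
    list(seq_id = seq_id, sequence = sequence, amplicon_class = klass,
         gene_similarity = best_sim, segments = segments),
    class = "repeat_amplicon"
  )
}

#' @export
print.repeat_amplicon <- function(x, ...) {
  cat(sprintf("<5S rDNA amplicon> %s: %s, %d bp\n",
              x$seq_id, x$amplicon_class, nchar(x$sequence)))
  print(select(x$segments, -"sequence"), ...)
  invisible(x)
}

#' @rdname dissect_amplicon
#' @param x A `repeat_amplicon`.
#' @param ... Unused.
#' @export
tidy.repeat_amplicon <- function(x, ...) x$segments

amplicon_segment <- function(amp, name) {
  row <- filter(amp$segments, .data$segment == name)
  if (nrow(row) == 0) stop_arg(sprintf("amplicon %s has no `%s` segment", amp$seq_id, name))
  row$sequence
}

#' Compare two NTS regions
#'
#' Globally aligns two non-transcribed spacer sequences and reports the
#' aligned column count, variable sites, percent identity and the GC
#' content of each input. With a single major `repeat_amplicon` argument,
#' compares its 5' NTS against its 3' NTS (the within-unit comparison).
#'
#' @param a,b NTS DNA strings, or `a` a major `repeat_amplicon` and `b`
#'   missing.
#' @param ... Scoring parameters passed to [global_align()].
#' @return A one-row tibble: `aligned_columns`, `variable_sites`,
#'   `identity`, `gc_a`, `gc_b`.
#' @export
compare_nts <- function(a, b = NULL, ...) {
  if (inherits(a, "repeat_amplicon")) {
    if (a$amplicon_class != "major") stop_arg("within-unit comparison needs a major amplicon")
    b <- amplicon_segment(a, "nts2")
    a <- amplicon_segment(a, "nts1")
  }
  aln <- global_align(a, b, ...)
  counts <- count_variable_sites(aln)
  tibble(
    aligned_columns = counts$aligned_columns,
    variable_sites = counts$variable_sites,
    identity = 100 * (1 - counts$variable_sites / counts$aligned_columns),
    gc_a = gc_content(a), gc_b = gc_content(b)
  )
}

#' Cross-unit NTS comparison of two major amplicons
#'
#' Aligns the 5' NTS of one repeat unit against the 5' NTS of the other,
#' and likewise the 3' NTS regions, then concatenates the two alignments'
#' counts into a combined variable-site fraction and identity. This is the
#' between-species comparison convention: the two spacer regions are
#' homologous by position within the repeat unit, so they are compared
#' region-to-region and pooled, never cross-region.
#'
#' @param amp_a,amp_b Major `repeat_amplicon` objects (or raw sequences,
#'   dissected on the fly).
#' @param ... Scoring parameters passed to [global_align()].
#' @return A tibble with rows `nts1`, `nts2` and `combined`, columns
#'   `aligned_columns`, `variable_sites`, `identity`.
#' @export
compare_nts_pairs <- function(amp_a, amp_b, ...) {
  if (!inherits(amp_a, "repeat_amplicon")) amp_a <- dissect_amplicon(amp_a, seq_id = "a")
  if (!inherits(amp_b, "repeat_amplicon")) amp_b <- dissect_amplicon(amp_b, seq_id = "b")
  per_region <- purrr::map_dfr(c("nts1", "nts2"), function(region) {
    cmp <- compare_nts(amplicon_segment(amp_a, region), amplicon_segment(amp_b, region), ...)
    mutate(cmp, region = region, .before = 1)
  })
  combined <- tibble(
    region = "combined",
    aligned_columns = sum(per_region$aligned_columns),
    variable_sites = sum(per_region$variable_sites)
  ) |>
    mutate(identity = 100 * (1 - .data$variable_sites / .data$aligned_columns))
  bind_rows(select(per_region, "region", "aligned_columns", "variable_sites", "identity"),
            combined)
}

#' Default intragenic promoter motifs
#'
#' The RNA polymerase III type-1 internal control region of the 5S gene:
#' A-box, Intermediate Element (IE) and C-box, at their canonical offsets
#' within the 120-bp gene (A-box about +50 to +64, IE +67 to +72, C-box
#' +81 to +97). Default consensus strings are taken from the synthetic
#' [gene_consensus_5s()] template at those offsets; supply motifs derived
#' from a reference gene of interest for real annotation work.
#'
#' @return A named list of motif consensus strings with expected offsets.
#' @export
promoter_motifs <- function() {
  gene <- gene_consensus_5s()
  list(
    a_box = list(consensus = substr(gene, 50, 64), offset = 50L),
    intermediate_element = list(consensus = substr(gene, 67, 72), offset = 67L),
    c_box = list(consensus = substr(gene, 81, 97), offset = 81L)
  )
}

#' Locate intragenic promoter motifs in a 5S gene
#'
#' Slides each motif consensus over the 120-bp gene without gaps and
#' reports the best-scoring position (fraction of matching bases). Motifs
#' scoring below `threshold` are flagged absent rather than erroring.
#'
#' @param gene 120-bp gene DNA string.
#' @param motifs Motif configuration as from [promoter_motifs()].
#' @param threshold Minimum match fraction for a motif to count as present.
#' @return A tibble with one row per motif: `element`, `start`, `end`
#'   (1-based, gene-local), `score`, `present`.
#' @export
find_promoter <- function(gene, motifs = promoter_motifs(), threshold = 0.75) {
  gene <- toupper(gene)
  if (nchar(gene) != 120) stop_arg("`gene` must be the 120-bp gene sequence")
  ch <- seq_chars(gene)
  purrr::map_dfr(names(motifs), function(name) {
    cons <- seq_chars(motifs[[name]]$consensus)
    w <- length(cons)
    scores <- vapply(
      seq_len(length(ch) - w + 1L),
      function(s) sum(ch[s:(s + w - 1L)] == cons) / w,
      0
    )
    best <- which.max(scores)
    present <- scores[best] >= threshold
    tibble(
      element = name,
      start = if (present) as.integer(best) else NA_integer_,
      end = if (present) as.integer(best + w - 1L) else NA_integer_,
      score = scores[best],
      present = present
    )
  })
}

#' Read amplicon sequences from FASTA
#'
#' @param path FASTA file path.
#' @return A named character vector of DNA sequences.
#' @export
read_amplicon_fasta <- function(path) {
  if (!file.exists(path)) stop_arg(sprintf("FASTA file not found: %s", path))
  dss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(dss), names(dss))
}

#' Write amplicon sequences to FASTA
#'
#' @param sequences Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplicon_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read the sequence of a local GenBank flat file
#'
#' Minimal reader for a GenBank flat file already on disk (e.g. a
#' downloaded rDNA accession): extracts the LOCUS name and the ORIGIN
#' sequence block. No network access is performed.
#'
#' @param path Path to a GenBank flat file.
#' @return A length-one named character vector (name = LOCUS/ACCESSION).
#' @export
read_genbank_seq <- function(path) {
  if (!file.exists(path)) stop_arg(sprintf("GenBank file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  acc_line <- grep("^(ACCESSION|LOCUS)", lines, value = TRUE)
  name <- if (length(acc_line) > 0) strsplit(trimws(acc_line[1]), "\\s+")[[1]][2] else "sequence"
  origin <- grep("^ORIGIN", lines)
  if (length(origin) == 0) stop_validation("no ORIGIN block in GenBank file")
  end <- grep("^//", lines)
  end <- end[end > origin[1]][1]
  if (is.na(end)) end <- length(lines) + 1L
  block <- lines[(origin[1] + 1L):(end - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(block, collapse = "")))
  stats::setNames(seq, name)
}
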