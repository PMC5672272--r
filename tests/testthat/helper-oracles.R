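# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: indices are recomputed with explicit loops, and
# alignments are scored by enumerating every gapped alignment.

# ---- karyotype fixtures ----------------------------------------------------

# build a read_plates-compatible table from a matrix of haploid arm lengths;
# homologs are duplicated exactly
plates_from_arms <- function(short, long, plate_ids = NULL, satellite_arm = "none") {
  n_plates <- nrow(short)
  n_pairs <- ncol(short)
  plate_ids <- plate_ids %||% sprintf("P%d", seq_len(n_plates))
  rows <- list()
  for (p in seq_len(n_plates)) {
    for (h in c("a", "b")) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        plate_id = plate_ids[p],
        pair_id = seq_len(n_pairs),
        homolog = h,
        short_arm_um = short[p, ],
        long_arm_um = long[p, ],
        satellite_arm = satellite_arm
      )
    }
  }
  dplyr::bind_rows(rows)
}

random_pairs_table <- function(n_pairs = 11) {
  total <- stats::runif(n_pairs, 4, 14)
  rl_total <- 100 * total / sum(total)
  ar <- stats::runif(n_pairs, 1, 4)
  tibble::tibble(
    pair_id = seq_len(n_pairs),
    rl_total_mean = rl_total,
    rl_short_mean = rl_total / (1 + ar),
    rl_long_mean = rl_total * ar / (1 + ar),
    ar_mean = ar,
    ci_mean = 100 / (1 + ar)
  )
}

# ---- brute-force asymmetry recomputation (loops, no package calls) ---------

oracle_sample_sd <- function(x) {
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  sqrt(ss / (length(x) - 1))
}

oracle_asymmetry <- function(short, long) {
  # short, long: per-pair mean arm lengths (any units)
  n <- length(short)
  total <- short + long
  ci <- 100 * short / total
  a1_acc <- 0
  for (i in seq_len(n)) a1_acc <- a1_acc + short[i] / long[i]
  list(
    ci_mean = sum(ci) / n,
    ci_sd = oracle_sample_sd(ci),
    a1 = 1 - a1_acc / n,
    a2 = oracle_sample_sd(total) / (sum(total) / n),
    ask = 100 * sum(long) / sum(total),
    ai = (100 * oracle_sample_sd(total) / (sum(total) / n)) *
      (100 * oracle_sample_sd(ci) / (sum(ci) / n)) / 100
  )
}

# ---- exhaustive alignment oracle -------------------------------------------

# score one explicit alignment (two gapped strings) under the affine scheme:
# a gap of length L costs gap_open + (L - 1) * gap_extend
score_alignment <- function(a, b, match = 1, mismatch = -1, gap_open = -4, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  s <- 0
  in_gap_a <- FALSE
  in_gap_b <- FALSE
  for (k in seq_along(av)) {
    if (av[k] == "-") {
      s <- s + if (in_gap_a) gap_extend else gap_open
      in_gap_a <- TRUE
      in_gap_b <- FALSE
    } else if (bv[k] == "-") {
      s <- s + if (in_gap_b) gap_extend else gap_open
      in_gap_b <- TRUE
      in_gap_a <- FALSE
    } else {
      s <- s + if (av[k] == bv[k]) match else mismatch
      in_gap_a <- FALSE
      in_gap_b <- FALSE
    }
  }
  s
}

# enumerate every global alignment of a and b (no gap-gap columns) and return
# the maximum affine score; exponential, use only for short sequences
enumerate_best_score <- function(a, b, ...) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, cola, colb) {
    if (i > length(av) && j > length(bv)) {
      s <- score_alignment(paste(cola, collapse = ""), paste(colb, collapse = ""), ...)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      recurse(i + 1, j + 1, c(cola, av[i]), c(colb, bv[j]))
    }
    if (i <= length(av)) recurse(i + 1, j, c(cola, av[i]), c(colb, "-"))
    if (j <= length(bv)) recurse(i, j + 1, c(cola, "-"), c(colb, bv[j]))
  }
  recurse(1, 1, character(0), character(0))
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# ---- published reference columns -------------------------------------------

table1 <- function(species) canavalia_karyotypes(species)
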