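#' Simulate per-metaphase chromosome measurement plates
#'
#' Generates measurement tables with the statistical structure the
#' aggregation pipeline assumes, together with the ground truth used to
#' produce them, for parameter-recovery testing. Each plate draws a
#' condensation factor uniform on `[0.85, 1.15]` (so TCL varies between
#' plates as it does between real spreads); each haploid chromosome is
#' split into arms according to its true arm ratio; each arm of each
#' homolog is perturbed independently by multiplicative lognormal noise
#' with coefficient of variation `noise_cv` (keeping lengths positive, as
#' condensation variability does). Relative lengths and arm ratios are
#' invariant to the plate factor, so the generator's `true_rl`/`true_ar`
#' are the exact expectations the pipeline should recover.
#'
#' Defaults reproduce the study conditions of the measured C. gladiata
#' karyotype: 11 metacentric pairs with relative lengths 6.47-11.95% of
#' the haploid complement, arm ratios 1.09-1.65, TCL 40.46 um, five
#' plates, satellites on the short arms of pairs 6 and 7, and 2%
#' measurement noise.
#'
#' @param n_pairs Number of chromosome pairs.
#' @param true_rl Percent relative lengths, summing to 100 (default: the
#'   published C. gladiata column).
#' @param true_ar Arm ratios >= 1 (default: the published C. gladiata
#'   column).
#' @param tcl_um True haploid complement length, micrometres.
#' @param n_plates Number of metaphase plates.
#' @param noise_cv Per-arm multiplicative lognormal noise CV (fraction).
#' @param satellite_pairs Data frame with `pair_id`, `arm` for satellited
#'   pairs.
#' @param marker_spec Optional data frame with `pair_id`, `kind`, `arm`,
#'   `true_di` (percent; `NA` for centromeric sites) and
#'   `true_size_percent`; one noisy site per plate is generated per row.
#' @param seed Integer seed; identical configurations and seeds give
#'   identical output.
#' @return A list with `plates` (a [read_plates()]-compatible tibble with
#'   `condensation_rank`), `markers` (site tibble or `NULL`) and `truth`
#'   (list of the generating parameters).
#' @examples
#' sim <- simulate_plates(noise_cv = 0, seed = 1)
#' k <- aggregate_karyotype(sim$plates)
#' all.equal(sort(k$pairs$rl_total_mean), sort(sim$truth$true_rl))
#' @export
simulate_plates <- function(n_pairs = 11,
                            true_rl = NULL,
                            true_ar = NULL,
                            tcl_um = 40.46,
                            n_plates = 5,
                            noise_cv = 0.02,
                            satellite_pairs = tibble(pair_id = c(6L, 7L), arm = "short"),
                            marker_spec = NULL,
                            seed = 0) {
  defaults <- canavalia_karyotypes("gladiata")
  true_rl <- true_rl %||% defaults$rl_total_mean[seq_len(n_pairs)]
  true_ar <- true_ar %||% defaults$ar_mean[seq_len(n_pairs)]
  if (length(true_rl) != n_pairs || length(true_ar) != n_pairs) {
    stop_arg("true_rl and true_ar must have length n_pairs")
  }
  true_rl <- 100 * true_rl / sum(true_rl)
  if (any(true_ar < 1)) stop_arg("true_ar must be >= 1")
  if (noise_cv < 0) stop_arg("noise_cv must be >= 0")

  # lognormal with unit mean and the requested CV
  sdlog <- sqrt(log(1 + noise_cv^2))
  meanlog <- -sdlog^2 / 2
  noise <- function(k) if (noise_cv == 0) rep(1, k) else stats::rlnorm(k, meanlog, sdlog)

  sat_arm <- rep("none", n_pairs)
  if (!is.null(satellite_pairs) && nrow(satellite_pairs) > 0) {
    sat_arm[satellite_pairs$pair_id] <- satellite_pairs$arm
  }

  withr::local_seed(seed)
  factors <- stats::runif(n_plates, 0.85, 1.15)
  ranks <- rank(factors, ties.method = "first") # rank 1 = most condensed (shortest)

  plates <- purrr::map_dfr(seq_len(n_plates), function(p) {
    total_um <- true_rl / 100 * tcl_um * factors[p]
    short_true <- total_um / (1 + true_ar)
    long_true <- total_um - short_true
    purrr::map_dfr(c("a", "b"), function(h) {
      tibble(
        plate_id = sprintf("P%d", p),
        pair_id = seq_len(n_pairs),
        homolog = h,
        short_arm_um = short_true * noise(n_pairs),
        long_arm_um = long_true * noise(n_pairs),
        satellite_arm = sat_arm,
        condensation_rank = ranks[p]
      )
    })
  })
  # keep the long >= short convention even under noise
  flip <- plates$short_arm_um > plates$long_arm_um
  if (any(flip)) {
    s <- plates$short_arm_um[flip]
    plates$short_arm_um[flip] <- plates$long_arm_um[flip]
    plates$long_arm_um[flip] <- s
  }

  markers <- NULL
  if (!is.null(marker_spec) && nrow(marker_spec) > 0) {
    markers <- purrr::map_dfr(seq_len(n_plates), function(p) {
      tcl_p <- tcl_um * factors[p]
      purrr::map_dfr(seq_len(nrow(marker_spec)), function(r) {
        spec <- marker_spec[r, ]
        total_um <- true_rl[spec$pair_id] / 100 * tcl_p
        arm_um <- switch(spec$arm,
          short = total_um / (1 + true_ar[spec$pair_id]),
          long = total_um * true_ar[spec$pair_id] / (1 + true_ar[spec$pair_id]),
          centromere = NA_real_
        )
        tibble(
          plate_id = sprintf("P%d", p),
          pair_id = as.integer(spec$pair_id),
          kind = spec$kind,
          arm = spec$arm,
          d_um = if (spec$arm == "centromere") NA_real_ else
            min(spec$true_di / 100 * arm_um * noise(1), arm_um),
          extent_um = spec$true_size_percent / 100 * tcl_p * noise(1)
        )
      })
    })
  }

  list(
    plates = plates,
    markers = markers,
    truth = list(
      true_rl = true_rl, true_ar = true_ar, tcl_um = tcl_um,
      noise_cv = noise_cv, plate_factors = factors,
      satellite_arm = sat_arm, marker_spec = marker_spec
    )
  )
}

random_nts <- function(length, gc_percent) {
  # fix the base composition to the target GC, then shuffle positions, so the
  # generated spacer hits the configured GC content up to integer rounding
  n_gc <- round(length * gc_percent / 100)
  n_at <- length - n_gc
  pool <- c(
    rep(c("G", "C"), length.out = n_gc),
    rep(c("A", "T"), length.out = n_at)
  )
  paste(sample(pool), collapse = "")
}

mutate_seq <- function(seq, divergence, indel_rate) {
  ch <- seq_chars(seq)
  bases <- c("A", "C", "G", "T")
  mut <- stats::runif(length(ch)) < divergence
  if (any(mut)) {
    ch[mut] <- vapply(ch[mut], function(b) sample(setdiff(bases, b), 1), "")
  }
  if (indel_rate > 0) {
    out <- character(0)
    for (b in ch) {
      r <- stats::runif(1)
      if (r < indel_rate / 2) next                       # deletion
      if (r < indel_rate) out <- c(out, sample(bases, 1)) # insertion before b
      out <- c(out, b)
    }
    ch <- out
  }
  paste(ch, collapse = "")
}

adjust_length <- function(seq, target) {
  while (nchar(seq) > target) {
    pos <- sample(nchar(seq), 1)
    seq <- paste0(substr(seq, 1, pos - 1), substr(seq, pos + 1, nchar(seq)))
  }
  while (nchar(seq) < target) {
    pos <- sample(nchar(seq) + 1, 1)
    seq <- paste0(substr(seq, 1, pos - 1), sample(c("A", "C", "G", "T"), 1),
                  substr(seq, pos, nchar(seq)))
  }
  seq
}

#' Simulate 5S rDNA amplicon sequences
#'
#' Builds a major amplicon (40-bp gene tail + NTS1 + 120-bp gene + NTS2 +
#' 58-bp gene head) and a minor amplicon spanning one repeat-unit junction
#' (gene tail + NTS1 + gene head), mirroring the amplicon structure
#' produced by primers annealing inside the conserved gene. NTS1 is drawn
#' at the target GC content; NTS2 derives from NTS1 by point mutations at
#' rate `divergence` and indels at rate `indel_rate`, then adjusted to
#' `nts_length_b`. Defaults mirror the measured repeat structure: 361-bp
#' GC-rich spacers (62% GC) diverging at about 10% of sites.
#'
#' @param gene_consensus 120-bp gene template (must start `AGG`, end `TCC`).
#' @param nts_length_a,nts_length_b Spacer lengths, bp.
#' @param nts_gc Target spacer GC content, percent.
#' @param divergence Fraction of spacer sites mutated between the two copies.
#' @param indel_rate Per-site indel probability between the two copies.
#' @param seed Integer seed.
#' @return A list with `sequences` (named character: `major`, `minor`) and
#'   `truth` (generating parameters plus the true segment tibble of the
#'   major amplicon).
#' @examples
#' sim <- simulate_amplicons(seed = 1)
#' nchar(sim$sequences[["major"]])
#' @export
simulate_amplicons <- function(gene_consensus = gene_consensus_5s(),
                               nts_length_a = 361,
                               nts_length_b = 361,
                               nts_gc = 62,
                               divergence = 0.10,
                               indel_rate = 0,
                               seed = 0) {
  if (nchar(gene_consensus) != 120 || !startsWith(gene_consensus, "AGG") ||
      !endsWith(gene_consensus, "TCC")) {
    stop_arg("`gene_consensus` must be 120 bp starting AGG and ending TCC")
  }
  withr::local_seed(seed)
  nts1 <- random_nts(nts_length_a, nts_gc)
  nts2 <- adjust_length(mutate_seq(nts1, divergence, indel_rate), nts_length_b)
  tail40 <- substr(gene_consensus, 81, 120)
  head58 <- substr(gene_consensus, 1, 58)
  major <- paste0(tail40, nts1, gene_consensus, nts2, head58)
  minor <- paste0(tail40, nts1, head58)

  la <- nchar(nts1)
  lb <- nchar(nts2)
  truth_segments <- tibble(
    segment = c("flank5", "nts1", "gene", "nts2", "flank3"),
    start = c(1L, 41L, 41L + la, 161L + la, 161L + la + lb),
    length = c(40L, la, 120L, lb, 58L)
  ) |>
    mutate(end = .data$start + .data$length - 1L, .after = "start")

  list(
    sequences = c(major = major, minor = minor),
    truth = list(
      segments = truth_segments, nts1 = nts1, nts2 = nts2,
      gene = gene_consensus, divergence = divergence,
      indel_rate = indel_rate, nts_gc = nts_gc
    )
  )
}

#' Write a simulation bundle to disk
#'
#' Writes the measurement CSV, marker CSV (if any), amplicon FASTA and a
#' ground-truth JSON of a simulated dataset into a directory.
#'
#' @param dir Output directory (created if needed).
#' @param plates_sim Result of [simulate_plates()].
#' @param amplicon_sim Optional result of [simulate_amplicons()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dir, plates_sim, amplicon_sim = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(plates_sim$plates, file.path(dir, "plates.csv"))
  truth <- plates_sim$truth
  if (!is.null(plates_sim$markers)) {
    readr::write_csv(plates_sim$markers, file.path(dir, "markers.csv"))
  }
  if (!is.null(amplicon_sim)) {
    write_amplicon_fasta(amplicon_sim$sequences, file.path(dir, "amplicons.fasta"))
    truth <- c(truth, list(amplicons = amplicon_sim$truth[c("segments", "divergence", "nts_gc")]))
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
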