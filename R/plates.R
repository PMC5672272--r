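#' Read per-metaphase chromosome measurements
#'
#' Reads a CSV of per-metaphase, per-homolog chromosome arm measurements and
#' validates it into a tidy observation table. Each row is one chromosome of
#' one metaphase plate, with short- and long-arm lengths in micrometres.
#' Arm orientation is normalised on read: when a row records
#' `short_arm_um > long_arm_um` the two arms (and any satellite flag) are
#' swapped rather than rejected. Arm lengths follow the conventional
#' measurement rule for satellited chromosomes: the satellite length is part
#' of the recorded arm, stretched secondary constrictions are excluded; the
#' reader stores the satellite flags but performs no satellite arithmetic.
#'
#' @param path Path to a measurement CSV, or a data frame already in memory.
#' @param schema Optional named character vector mapping canonical column
#'   names (`plate_id`, `pair_id`, `homolog`, `short_arm_um`, `long_arm_um`,
#'   `satellite_arm`, `condensation_rank`) to the column names used in the
#'   file, e.g. `c(short_arm_um = "p_arm")`.
#'
#' @return A tibble with columns `plate_id`, `pair_id`, `homolog`,
#'   `short_arm_um`, `long_arm_um`, `satellite_arm` and (if present)
#'   `condensation_rank`, one row per measured chromosome.
#'
#' @details Validation errors identify the offending row or pair: every arm
#'   length must be finite and strictly positive, and every `pair_id` must
#'   appear exactly twice (homologs `a` and `b`) within each plate.
#'
#' @examples
#' sim <- simulate_plates(n_plates = 2, seed = 1)
#' path <- tempfile(fileext = ".csv")
#' readr::write_csv(sim$plates, path)
#' plates <- read_plates(path)
#' dplyr::count(plates, plate_id)
#' @export
read_plates <- function(path, schema = NULL) {
  if (is.data.frame(path)) {
    raw <- as_tibble(path)
  } else {
    if (!file.exists(path)) stop_arg(sprintf("measurement file not found: %s", path))
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      if (schema[[canonical]] %in% names(raw)) {
        names(raw)[names(raw) == schema[[canonical]]] <- canonical
      }
    }
  }
  required <- c("plate_id", "pair_id", "homolog", "short_arm_um", "long_arm_um")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_schema(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!"satellite_arm" %in% names(raw)) raw$satellite_arm <- "none"
  raw$satellite_arm[is.na(raw$satellite_arm)] <- "none"
  bad_sat <- !raw$satellite_arm %in% c("none", "short", "long")
  if (any(bad_sat)) {
    stop_validation(sprintf("invalid satellite_arm value in row %d", which(bad_sat)[1]))
  }

  lengths_ok <- is.finite(raw$short_arm_um) & raw$short_arm_um > 0 &
    is.finite(raw$long_arm_um) & raw$long_arm_um > 0
  if (any(!lengths_ok)) {
    stop_validation(sprintf(
      "non-positive or non-finite arm length in row %d", which(!lengths_ok)[1]
    ))
  }

  # orientation normalisation: long >= short, satellite flag follows its arm
  flip <- raw$short_arm_um > raw$long_arm_um
  if (any(flip)) {
    s <- raw$short_arm_um[flip]
    raw$short_arm_um[flip] <- raw$long_arm_um[flip]
    raw$long_arm_um[flip] <- s
    raw$satellite_arm[flip] <- c(none = "none", short = "long", long = "short")[raw$satellite_arm[flip]]
  }

  counts <- raw |>
    count(.data$plate_id, .data$pair_id, name = "n_homologs") |>
    filter(.data$n_homologs != 2L)
  if (nrow(counts) > 0) {
    stop_validation(sprintf(
      "pair %s has %d homolog%s in plate %s",
      counts$pair_id[1], counts$n_homologs[1],
      if (counts$n_homologs[1] == 1L) "" else "s", counts$plate_id[1]
    ))
  }

  keep <- intersect(
    c("plate_id", "pair_id", "homolog", "short_arm_um", "long_arm_um",
      "satellite_arm", "condensation_rank"),
    names(raw)
  )
  raw |>
    select(all_of(keep)) |>
    mutate(plate_id = as.character(.data$plate_id), pair_id = as.integer(.data$pair_id)) |>
    arrange(.data$plate_id, .data$pair_id, .data$homolog)
}

#' Per-plate haploid arm lengths and relative lengths
#'
#' Averages the two homologs of each pair within every metaphase plate to a
#' haploid arm length, then expresses each arm as a percentage of the plate's
#' haploid complement length (relative length, RL). Also returns the
#' per-plate arm ratio (AR = long/short) and centromeric index
#' (CI = 100 x short / total) of the homolog-averaged arms.
#'
#' @param plates Observation tibble from [read_plates()] (or a compatible
#'   data frame).
#' @return A tibble with one row per plate x pair: `plate_id`, `pair_id`,
#'   `short_um`, `long_um`, `total_um` (homolog-averaged, haploid),
#'   `rl_short`, `rl_long`, `rl_total` (percent of haploid complement),
#'   `ar`, `ci`. Within each plate `sum(rl_total)` is 100 up to rounding.
#' @examples
#' sim <- simulate_plates(n_plates = 1, noise_cv = 0, seed = 1)
#' rl <- relative_lengths(sim$plates)
#' sum(rl$rl_total) # 100
#' @export
relative_lengths <- function(plates) {
  plates <- read_plates(plates)
  plates |>
    group_by(.data$plate_id, .data$pair_id) |>
    summarise(
      short_um = mean(.data$short_arm_um),
      long_um = mean(.data$long_arm_um),
      .groups = "drop_last"
    ) |>
    mutate(
      total_um = .data$short_um + .data$long_um,
      rl_short = 100 * .data$short_um / sum(.data$total_um),
      rl_long = 100 * .data$long_um / sum(.data$total_um),
      rl_total = .data$rl_short + .data$rl_long,
      ar = .data$long_um / .data$short_um,
      ci = 100 * .data$short_um / .data$total_um
    ) |>
    ungroup()
}

#' Total haploid complement length (TCL)
#'
#' The karyotype length: the sum of haploid (homolog-averaged) chromosome
#' lengths of a metaphase plate, in micrometres, summarised as mean and
#' sample SD over the `k` most condensed plates. Condensation rank 1 marks
#' the most condensed plate; when no `condensation_rank` column is present
#' all plates are used with a warning.
#'
#' @param plates Observation tibble from [read_plates()].
#' @param k Number of plates to use (most condensed first). Defaults to all.
#' @return A one-row tibble with `tcl_mean`, `tcl_sd` (micrometres) and `n_plates`.
#' @examples
#' sim <- simulate_plates(n_plates = 5, seed = 1)
#' total_complement_length(sim$plates, k = 5)
#' @export
total_complement_length <- function(plates, k = NULL) {
  plates <- read_plates(plates)
  if (!is.null(k) && (!is.numeric(k) || length(k) != 1L || k <= 0)) {
    stop_arg("`k` must be a positive integer")
  }
  per_plate <- relative_lengths(plates) |>
    group_by(.data$plate_id) |>
    summarise(tcl = sum(.data$total_um), .groups = "drop")
  if ("condensation_rank" %in% names(plates)) {
    ranks <- plates |> distinct(.data$plate_id, .data$condensation_rank)
    per_plate <- per_plate |>
      left_join(ranks, by = "plate_id") |>
      arrange(.data$condensation_rank)
  } else if (!is.null(k) && k < nrow(per_plate)) {
    warn("no condensation_rank column; using all plates for TCL")
    k <- nrow(per_plate)
  }
  k <- k %||% nrow(per_plate)
  if (!is.numeric(k) || k <= 0) stop_arg("`k` must be a positive integer")
  if (k > nrow(per_plate)) stop_arg("`k` exceeds the number of plates")
  sel <- per_plate$tcl[seq_len(k)]
  tibble(tcl_mean = mean(sel), tcl_sd = sd0(sel), n_plates = as.integer(k))
}
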