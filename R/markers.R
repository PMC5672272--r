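#' Read a marker annotation table
#'
#' Reads a CSV of localized chromosomal features (5S/45S rDNA FISH sites,
#' centromeric fluorochrome bands, self-GISH blocks). Positions follow
#' cytogenetic practice: `d_um` is the micrometre distance from the
#' centromere to the middle of the site along its arm (empty for
#' centromeric sites), `extent_um` the site length along the chromosome.
#'
#' @param path CSV path or data frame. Columns: `pair_id`, `kind`
#'   (`rDNA5S`, `rDNA45S`, `CPD`, `sGISH`), `arm` (`short`, `long`,
#'   `centromere`), and either `d_um`/`extent_um` (with optional
#'   `plate_id`) or a precomputed `size_percent`.
#' @return A validated tibble of marker sites.
#' @export
read_markers <- function(path) {
  sites <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    if (!file.exists(path)) stop_arg(sprintf("marker file not found: %s", path))
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  required <- c("pair_id", "kind", "arm")
  missing <- setdiff(required, names(sites))
  if (length(missing) > 0) {
    stop_schema(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  bad_kind <- !sites$kind %in% c("rDNA5S", "rDNA45S", "CPD", "sGISH")
  if (any(bad_kind)) stop_validation(sprintf("unknown marker kind in row %d", which(bad_kind)[1]))
  bad_arm <- !sites$arm %in% c("short", "long", "centromere")
  if (any(bad_arm)) stop_validation(sprintf("unknown arm in row %d", which(bad_arm)[1]))
  if (!"size_percent" %in% names(sites) && !"extent_um" %in% names(sites)) {
    stop_schema("marker table needs either `extent_um` or `size_percent`")
  }
  mutate(sites, pair_id = as.integer(.data$pair_id))
}

#' Percent distance of a marker site from the centromere
#'
#' `di = d x 100 / a`, where `d` is the distance from the centromere to the
#' middle of the site and `a` the length of the corresponding chromosome
#' arm (satellite included, by the measurement convention). 0 marks a
#' centromere-adjacent site, 100 a terminal one.
#'
#' @param d Distance(s) centromere to site middle, micrometres, `0 <= d <= a`.
#' @param a Corresponding arm length(s), micrometres, > 0.
#' @return Numeric vector of percents in `[0, 100]`.
#' @examples
#' di_percent(1.37, 2.52)
#' @export
di_percent <- function(d, a) {
  if (any(!is.finite(a) | a <= 0)) stop_arg("arm length `a` must be > 0")
  if (any(!is.finite(d) | d < 0)) stop_arg("distance `d` must be >= 0")
  if (any(d > a)) stop_arg("`d` exceeds the arm length: site middle outside the arm")
  d * 100 / a
}

#' Marker size as a percent of the karyotype length
#'
#' @param extent Site length(s) along the chromosome, micrometres, > 0.
#' @param karyotype_length Haploid total complement length of the same
#'   plate, micrometres, > 0.
#' @return `100 * extent / karyotype_length`.
#' @examples
#' size_percent(0.4, 40)
#' @export
size_percent <- function(extent, karyotype_length) {
  if (any(!is.finite(karyotype_length) | karyotype_length <= 0)) {
    stop_arg("`karyotype_length` must be > 0")
  }
  if (any(!is.finite(extent) | extent <= 0)) stop_arg("`extent` must be > 0")
  100 * extent / karyotype_length
}

#' Summarise marker sites over a karyotype
#'
#' Aggregates marker sites into the per-pair and complement-level size
#' statistics conventionally reported next to a karyotype table: mean +/-
#' sample SD (across plates) of each site's size as a percent of the
#' karyotype length, per-pair totals, and complement totals per marker
#' kind split by arm. Centromeric sites contribute their full extent to
#' pair and complement totals; for the per-arm split only, they are divided
#' evenly between the two arms (display convention, flagged by the
#' `centromeric_split` attribute). Where `d_um` is present the per-site
#' `di_percent` is appended.
#'
#' @param sites Marker tibble from [read_markers()]. Sizes are taken from a
#'   `size_percent` column when present; otherwise computed from
#'   `extent_um` and the per-plate TCL of `plates`.
#' @param karyotype Optional `karyotype` object used to validate `pair_id`s.
#' @param plates Optional observation tibble (needed to convert `extent_um`
#'   and `d_um` to percents).
#' @return A list of class `marker_summary`: `sites` (per-site, with
#'   `size_percent` and `di`), `per_arm` (pair x kind x arm mean +/- SD),
#'   `per_pair` (pair x kind totals), `totals` (kind x arm complement
#'   totals, including a `"complement"` row per kind).
#' @examples
#' tab <- canavalia_karyotypes("gladiata")
#' sites <- dplyr::bind_rows(
#'   tibble::tibble(pair_id = tab$pair_id, kind = "sGISH", arm = "short",
#'                  size_percent = tab$sgish_short_percent),
#'   tibble::tibble(pair_id = tab$pair_id, kind = "sGISH", arm = "long",
#'                  size_percent = tab$sgish_long_percent)
#' )
#' marker_summary(sites)$totals
#' @export
marker_summary <- function(sites, karyotype = NULL, plates = NULL) {
  sites <- read_markers(sites)
  if (!is.null(karyotype)) {
    known <- karyotype$pairs$pair_id
    dangling <- setdiff(sites$pair_id, known)
    if (length(dangling) > 0) {
      stop_validation(sprintf("marker references unknown pair %d", dangling[1]))
    }
  }

  if (!"size_percent" %in% names(sites)) {
    if (is.null(plates)) stop_arg("`plates` needed to convert extent_um to size_percent")
    rl <- relative_lengths(plates)
    tcl <- rl |>
      group_by(.data$plate_id) |>
      summarise(tcl = sum(.data$total_um), .groups = "drop")
    sites <- sites |>
      left_join(tcl, by = "plate_id") |>
      mutate(size_percent = size_percent(.data$extent_um, .data$tcl)) |>
      select(-"tcl")
  }

  if ("d_um" %in% names(sites) && !is.null(plates)) {
    rl <- relative_lengths(plates) |>
      select("plate_id", "pair_id", "short_um", "long_um")
    sites <- sites |>
      left_join(rl, by = c("plate_id", "pair_id")) |>
      mutate(
        arm_um = case_when(
          .data$arm == "short" ~ .data$short_um,
          .data$arm == "long" ~ .data$long_um,
          TRUE ~ NA_real_
        ),
        di = ifelse(
          .data$arm == "centromere" | is.na(.data$d_um), NA_real_,
          di_percent(.data$d_um, .data$arm_um)
        )
      ) |>
      select(-"short_um", -"long_um", -"arm_um")
  } else if (!"di" %in% names(sites)) {
    sites$di <- NA_real_
  }

  empty_summary <- function() {
    list(
      sites = sites,
      per_arm = tibble(pair_id = integer(), kind = character(), arm = character(),
                       size_mean = double(), size_sd = double()),
      per_pair = tibble(pair_id = integer(), kind = character(),
                        size_mean = double(), size_sd = double()),
      totals = tibble(kind = character(), arm = character(), total_percent = double())
    )
  }
  if (nrow(sites) == 0) {
    return(structure(empty_summary(), class = "marker_summary"))
  }

  has_plates <- "plate_id" %in% names(sites)
  per_arm <- sites |>
    group_by(.data$pair_id, .data$kind, .data$arm) |>
    summarise(size_mean = mean(.data$size_percent), size_sd = sd0(.data$size_percent),
              .groups = "drop")

  per_pair <- if (has_plates) {
    sites |>
      group_by(.data$plate_id, .data$pair_id, .data$kind) |>
      summarise(size = sum(.data$size_percent), .groups = "drop") |>
      group_by(.data$pair_id, .data$kind) |>
      summarise(size_mean = mean(.data$size), size_sd = sd0(.data$size), .groups = "drop")
  } else {
    per_arm |>
      group_by(.data$pair_id, .data$kind) |>
      summarise(size_mean = sum(.data$size_mean), size_sd = sqrt(sum(.data$size_sd^2)),
                .groups = "drop")
  }

  # centromeric extents split evenly between arms for the per-arm columns only
  cen <- filter(per_arm, .data$arm == "centromere")
  arm_split <- filter(per_arm, .data$arm != "centromere")
  if (nrow(cen) > 0) {
    halves <- bind_rows(mutate(cen, arm = "short"), mutate(cen, arm = "long")) |>
      mutate(size_mean = .data$size_mean / 2)
    arm_split <- bind_rows(arm_split, halves)
  }

  totals <- arm_split |>
    group_by(.data$kind, .data$arm) |>
    summarise(total_percent = sum(.data$size_mean), .groups = "drop") |>
    bind_rows(
      per_pair |>
        group_by(.data$kind) |>
        summarise(total_percent = sum(.data$size_mean), .groups = "drop") |>
        mutate(arm = "complement")
    ) |>
    arrange(.data$kind, .data$arm)

  structure(
    list(sites = sites, per_arm = per_arm, per_pair = per_pair, totals = totals),
    class = "marker_summary"
  )
}

#' @export
print.marker_summary <- function(x, ...) {
  cat(sprintf("<marker summary> %d site(s)\n", nrow(x$sites)))
  cat("complement totals (% of karyotype length):\n")
  print(x$totals, ...)
  invisible(x)
}

#' @rdname marker_summary
#' @param x A `marker_summary` object.
#' @param ... Unused.
#' @export
tidy.marker_summary <- function(x, ...) x$per_pair
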