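#' Construct a karyotype object from an aggregated pair table
#'
#' Low-level constructor used both by [aggregate_karyotype()] and for typing
#' in published karyotype tables directly (per-pair relative lengths, arm
#' ratios and satellite flags). Pairs are ordered by decreasing mean total
#' relative length (ties broken by the incoming `pair_id`) and renumbered
#' 1..n; each pair is classified by [levan_type()] on its mean arm ratio and
#' the karyotype formula string is attached.
#'
#' @param pairs Data frame with one row per chromosome pair. Required
#'   columns: `rl_total_mean` and `ar_mean`. Recognised optional columns:
#'   `pair_id`, `rl_short_mean`, `rl_short_sd`, `rl_long_mean`, `rl_long_sd`,
#'   `rl_total_sd`, `ar_sd`, `ci_mean`, `ci_sd`, `satellite_arm`.
#' @param label Karyotype label (e.g. a species name).
#' @param tcl_mean,tcl_sd Total haploid complement length (micrometres),
#'   mean and sample SD, if known.
#' @return An object of class `karyotype`: a list with elements `label`,
#'   `two_n`, `pairs` (tibble), `tcl_mean`, `tcl_sd`, `formula`.
#' @examples
#' tab <- canavalia_karyotypes("gladiata")
#' k <- karyotype(tab, label = "C. gladiata", tcl_mean = 40.46, tcl_sd = 1.03)
#' k$formula
#' @export
karyotype <- function(pairs, label = "", tcl_mean = NA_real_, tcl_sd = NA_real_) {
  pairs <- as_tibble(pairs)
  for (col in c("rl_total_mean", "ar_mean")) {
    if (!col %in% names(pairs)) stop_schema(sprintf("pairs table lacks column `%s`", col))
  }
  if (!"pair_id" %in% names(pairs)) pairs$pair_id <- seq_len(nrow(pairs))
  if (!"satellite_arm" %in% names(pairs)) pairs$satellite_arm <- "none"
  if (any(pairs$ar_mean < 1)) stop_arg("ar_mean must be >= 1 (normalise arms so long >= short)")
  if (!"ci_mean" %in% names(pairs)) pairs$ci_mean <- 100 / (1 + pairs$ar_mean)

  pairs <- pairs |>
    arrange(desc(.data$rl_total_mean), .data$pair_id) |>
    mutate(
      source_pair_id = .data$pair_id,
      pair_id = dplyr::row_number(),
      type = levan_type(.data$ar_mean)
    ) |>
    relocate("pair_id")

  out <- structure(
    list(
      label = label,
      two_n = 2L * nrow(pairs),
      pairs = pairs,
      tcl_mean = tcl_mean,
      tcl_sd = tcl_sd,
      formula = NULL
    ),
    class = "karyotype"
  )
  out$formula <- karyotype_formula(out)
  out
}

#' Aggregate metaphase plates into a karyotype
#'
#' Computes per-pair means and sample SDs (n - 1 denominator) of relative
#' lengths, arm ratios and centromeric indices across metaphase plates.
#' Per-plate AR is the ratio of the homolog-averaged arms and per-plate
#' CI is 100 x short / (short + long); the reported `ar_mean` is the mean of
#' the per-plate ratios, not the ratio of the mean arms. Pairs are sorted by
#' decreasing size and renumbered; the Levan type of each pair and the
#' karyotype formula string are attached. TCL is summarised over the
#' `tcl_k` most condensed plates (see [total_complement_length()]).
#'
#' @param plates Observation tibble from [read_plates()].
#' @param label Karyotype label.
#' @param tcl_k Number of plates used for TCL (default: all).
#' @return A `karyotype` object (see [karyotype()]).
#' @examples
#' sim <- simulate_plates(seed = 1)
#' k <- aggregate_karyotype(sim$plates, label = "simulated")
#' k
#' @export
aggregate_karyotype <- function(plates, label = "", tcl_k = NULL) {
  plates <- read_plates(plates)
  pair_sets <- plates |>
    group_by(.data$plate_id) |>
    summarise(key = paste(sort(unique(.data$pair_id)), collapse = ","), .groups = "drop")
  if (length(unique(pair_sets$key)) != 1L) {
    stop_validation("plates do not share the same set of pair_ids")
  }

  per_plate <- relative_lengths(plates)
  sat <- plates |>
    group_by(.data$pair_id) |>
    summarise(
      satellite_arm = if (all(.data$satellite_arm == "none")) "none" else
        names(which.max(table(.data$satellite_arm[.data$satellite_arm != "none"]))),
      .groups = "drop"
    )

  agg <- per_plate |>
    group_by(.data$pair_id) |>
    summarise(
      rl_short_mean = mean(.data$rl_short), rl_short_sd = sd0(.data$rl_short),
      rl_long_mean = mean(.data$rl_long), rl_long_sd = sd0(.data$rl_long),
      rl_total_mean = mean(.data$rl_total), rl_total_sd = sd0(.data$rl_total),
      ar_mean = mean(.data$ar), ar_sd = sd0(.data$ar),
      ci_mean = mean(.data$ci), ci_sd = sd0(.data$ci),
      .groups = "drop"
    ) |>
    left_join(sat, by = "pair_id")

  tcl <- total_complement_length(plates, k = tcl_k)
  karyotype(agg, label = label, tcl_mean = tcl$tcl_mean, tcl_sd = tcl$tcl_sd)
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf(
    "<karyotype> %s  %s\n", if (nzchar(x$label)) x$label else "(unlabelled)", x$formula
  ))
  if (is.finite(x$tcl_mean)) {
    cat(sprintf("TCL: %.2f +/- %.2f um\n", x$tcl_mean, x$tcl_sd))
  }
  print(x$pairs, ...)
  invisible(x)
}

#' @rdname karyotype
#' @param x A `karyotype` object.
#' @param ... Unused.
#' @export
tidy.karyotype <- function(x, ...) x$pairs

#' @rdname karyotype
#' @export
glance.karyotype <- function(x, ...) {
  tibble(
    label = x$label, two_n = x$two_n, n_pairs = nrow(x$pairs),
    tcl_mean = x$tcl_mean, tcl_sd = x$tcl_sd, formula = x$formula
  )
}

#' Export a karyotype table
#'
#' Writes the aggregated per-pair table (relative lengths, arm ratios, Levan
#' types, satellite flags) to CSV or JSON, together with the formula string
#' and TCL in the JSON form.
#'
#' @param x A `karyotype` object.
#' @param path Output path.
#' @param format `"csv"` or `"json"` (default: guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_karyotype <- function(x, path, format = NULL) {
  format <- format %||% (if (grepl("\\.json$", path)) "json" else "csv")
  if (format == "csv") {
    readr::write_csv(x$pairs, path)
  } else {
    jsonlite::write_json(
      list(
        label = x$label, two_n = x$two_n, formula = x$formula,
        tcl_mean = x$tcl_mean, tcl_sd = x$tcl_sd, pairs = x$pairs
      ),
      path, auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(path)
}

#' Published karyotype table of the two cultivated Canavalia species
#'
#' The per-pair chromosome measurements (relative lengths, arm ratios, Levan
#' types, satellite flags) and marker size percentages (centromeric
#' fluorochrome bands, self-GISH signals) of Canavalia gladiata (sword bean)
#' and Canavalia ensiformis (jack bean), as published; means +/- sample SD
#' over five metaphase plates per species. Satellite pairs 6 and 7 carry
#' their secondary constrictions on the short arms.
#'
#' @param species `"gladiata"`, `"ensiformis"`, or `NULL` for both.
#' @return A tibble, one row per chromosome pair (and species).
#' @examples
#' canavalia_karyotypes("gladiata")
#' @export
canavalia_karyotypes <- function(species = NULL) {
  path <- system.file("extdata", "canavalia_karyotypes.csv", package = "karyometry")
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(species)) {
    species <- match.arg(species, c("gladiata", "ensiformis"))
    tab <- filter(tab, .data$species == !!species)
  }
  tab
}

#' @rdname canavalia_karyotypes
#' @details `canavalia_karyotype()` wraps the table of one species as a
#'   `karyotype` object with the published TCL (40.46 +/- 1.03 um for
#'   C. gladiata, 34.06 +/- 3.87 um for C. ensiformis).
#' @export
canavalia_karyotype <- function(species = c("gladiata", "ensiformis")) {
  species <- match.arg(species)
  tcl <- switch(species,
    gladiata = c(40.46, 1.03),
    ensiformis = c(34.06, 3.87)
  )
  karyotype(
    canavalia_karyotypes(species),
    label = paste("C.", species), tcl_mean = tcl[1], tcl_sd = tcl[2]
  )
}
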