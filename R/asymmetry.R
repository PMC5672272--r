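#' @name asymmetry-indices
#' @title Karyotype asymmetry indices
#'
#' @description
#' The six statistics used to summarise karyotype asymmetry of a haploid
#' complement, all computed from the aggregated per-pair table (one value
#' per pair, i.e. the haploid karyotype):
#'
#' * `ci_stats()` — mean and sample SD of the per-pair centromeric indices
#'   (CI = 100 x short / total = 100 / (1 + AR)).
#' * `a1_index()` — intrachromosomal asymmetry (Romero Zarco):
#'   A1 = 1 - mean(b/B) over pairs, with b/B the short/long mean arm
#'   lengths, i.e. 1 - mean(1/AR). 0 for a fully metacentric complement.
#' * `a2_index()` — interchromosomal asymmetry (Romero Zarco): the
#'   coefficient of variation (sample SD / mean) of chromosome lengths
#'   across the complement; scale-invariant, so relative lengths and
#'   micrometre lengths give the same value.
#' * `ask_percent()` — karyotype long-arm proportion:
#'   100 x sum(long arms) / sum(total lengths); 50 for equal-armed sets.
#' * `ai_index()` — Paszko's asymmetry index:
#'   AI = CV(chromosome length) x CV(CI) / 100, both CVs with sample SD.
#' * `stebbins_category()` — the Stebbins two-way grid: row 1/2/3 by the
#'   largest/smallest chromosome ratio (< 2, 2-4, > 4), column A-D by the
#'   proportion of chromosomes with AR > 2 (0, (0, 0.5], (0.5, 1), 1);
#'   boundary values fall in the lower row/column.
#'
#' All six are invariant to uniform rescaling of arm lengths. SDs use the
#' n - 1 denominator throughout.
#'
#' @param x A `karyotype` object, a per-pair data frame (columns `ar_mean`
#'   and/or `rl_total_mean`, `rl_long_mean` as needed), or a bare numeric
#'   vector (arm ratios for `a1_index()`, chromosome lengths for
#'   `a2_index()`).
#' @return `ci_stats()` a one-row tibble `ci_mean`, `ci_sd`; the index
#'   functions a single number; `stebbins_category()` a string.
#' @examples
#' tab <- canavalia_karyotypes("gladiata")
#' round(a1_index(tab$ar_mean), 2)
#' round(a2_index(tab$rl_total_mean), 2)
#' ask_percent(tab)
#' stebbins_category(tab)
NULL

as_pairs <- function(x) {
  if (inherits(x, "karyotype")) return(x$pairs)
  if (is.data.frame(x)) return(as_tibble(x))
  stop_arg("expected a karyotype, a per-pair data frame, or a numeric vector")
}

pair_ci <- function(pairs) {
  if ("ci_mean" %in% names(pairs)) pairs$ci_mean else 100 / (1 + pairs$ar_mean)
}

#' @rdname asymmetry-indices
#' @export
ci_stats <- function(x) {
  pairs <- as_pairs(x)
  if (nrow(pairs) == 0) stop_arg("empty pair table")
  ci <- pair_ci(pairs)
  tibble(ci_mean = mean(ci), ci_sd = sd0(ci))
}

#' @rdname asymmetry-indices
#' @export
a1_index <- function(x) {
  ar <- if (is.numeric(x)) x else as_pairs(x)$ar_mean
  if (length(ar) == 0) stop_arg("no arm ratios supplied")
  if (any(ar < 1)) stop_arg("arm ratios must be >= 1")
  1 - mean(1 / ar)
}

#' @rdname asymmetry-indices
#' @export
a2_index <- function(x) {
  len <- if (is.numeric(x)) x else as_pairs(x)$rl_total_mean
  if (length(len) < 2) stop_arg("a2_index needs at least two chromosome lengths")
  stats::sd(len) / mean(len)
}

#' @rdname asymmetry-indices
#' @export
ask_percent <- function(x) {
  pairs <- as_pairs(x)
  100 * sum(pairs$rl_long_mean) / sum(pairs$rl_total_mean)
}

#' @rdname asymmetry-indices
#' @export
ai_index <- function(x) {
  pairs <- as_pairs(x)
  if (nrow(pairs) < 2) stop_arg("ai_index needs at least two pairs")
  len <- pairs$rl_total_mean
  ci <- pair_ci(pairs)
  cv_cl <- 100 * stats::sd(len) / mean(len)
  cv_ci <- 100 * stats::sd(ci) / mean(ci)
  cv_cl * cv_ci / 100
}

#' @rdname asymmetry-indices
#' @export
stebbins_category <- function(x) {
  pairs <- as_pairs(x)
  len <- pairs$rl_total_mean
  ar <- pairs$ar_mean
  size_ratio <- max(len) / min(len)
  row <- if (size_ratio <= 2) "1" else if (size_ratio <= 4) "2" else "3"
  p <- mean(ar > 2)
  col <- if (p == 0) "A" else if (p <= 0.5) "B" else if (p < 1) "C" else "D"
  paste0(row, col)
}

#' Six-index asymmetry profile of a karyotype
#'
#' Computes all six asymmetry statistics (see [asymmetry-indices]) from an
#' aggregated karyotype and returns them as a one-row tibble, the same
#' per-species summary conventionally reported alongside a karyotype table.
#'
#' @param x A `karyotype` object or per-pair data frame with columns
#'   `rl_long_mean`, `rl_total_mean`, `ar_mean` (and optionally `ci_mean`).
#' @param digits Decimal places for the reported values (default 2,
#'   matching conventional reporting); use `NULL` for full precision.
#' @return A one-row tibble of class `asymmetry_profile` with columns
#'   `ci_mean`, `ci_sd`, `a1`, `a2`, `ask_percent`, `ai`, `stebbins`.
#' @examples
#' asymmetry_profile(canavalia_karyotype("gladiata"))
#' @export
asymmetry_profile <- function(x, digits = 2) {
  pairs <- as_pairs(x)
  ci <- ci_stats(pairs)
  out <- tibble(
    ci_mean = ci$ci_mean, ci_sd = ci$ci_sd,
    a1 = a1_index(pairs), a2 = a2_index(pairs),
    ask_percent = ask_percent(pairs), ai = ai_index(pairs),
    stebbins = stebbins_category(pairs)
  )
  if (!is.null(digits)) {
    out <- mutate(out, across(where(is.numeric), \(v) round(v, digits)))
  }
  class(out) <- c("asymmetry_profile", class(out))
  out
}

#' @export
print.asymmetry_profile <- function(x, ...) {
  cat("<asymmetry profile>\n")
  NextMethod()
  invisible(x)
}

#' Export an asymmetry profile as JSON
#'
#' @param x An `asymmetry_profile` (from [asymmetry_profile()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asymmetry <- function(x, path) {
  jsonlite::write_json(as.list(as_tibble(x)[1, ]), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
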