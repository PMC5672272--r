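#' Levan centromere-position classification
#'
#' Classifies a chromosome by its arm ratio (long arm / short arm) into the
#' Levan centromere-position categories: metacentric `m` for
#' 1.00 <= AR <= 1.70, submetacentric `sm` for 1.70 < AR <= 3.00,
#' subtelocentric `st` for 3.00 < AR <= 7.00 and acro-/telocentric `t` for
#' AR > 7.00. Boundary values belong to the lower category. The strict
#' median-point class (AR exactly 1) is folded into `m`.
#'
#' @param ar Numeric vector of arm ratios, each >= 1 (normalise arms so the
#'   long arm is the numerator before calling).
#' @return Character vector of codes among `"m"`, `"sm"`, `"st"`, `"t"`.
#' @examples
#' levan_type(c(1, 1.65, 2.4, 5, 8))
#' @export
levan_type <- function(ar) {
  if (!is.numeric(ar) || any(!is.finite(ar))) stop_arg("`ar` must be finite numeric")
  if (any(ar < 1)) stop_arg("`ar` must be >= 1; normalise arms so long >= short")
  as.character(cut(
    ar,
    breaks = c(0, 1.70, 3.00, 7.00, Inf),
    labels = c("m", "sm", "st", "t"),
    right = TRUE
  ))
}

#' Karyotype formula string
#'
#' Builds the conventional karyotype formula, counting chromosomes (two per
#' pair) by Levan type with satellited pairs suffixed `-SAT`, e.g.
#' `"2n = 22 = 18m + 4m-SAT"`. Types are ordered m, sm, st, t with the
#' plain term before the `-SAT` term within a type; zero-count terms are
#' omitted.
#'
#' @param x A `karyotype` object, or a data frame with columns `ar_mean`
#'   (or `type`) and optionally `satellite_arm`.
#' @return A single string.
#' @examples
#' karyotype_formula(canavalia_karyotype("gladiata"))
#' @export
karyotype_formula <- function(x) {
  pairs <- if (inherits(x, "karyotype")) x$pairs else as_tibble(x)
  if (!"type" %in% names(pairs)) pairs$type <- levan_type(pairs$ar_mean)
  if (!"satellite_arm" %in% names(pairs)) pairs$satellite_arm <- "none"
  counts <- pairs |>
    mutate(
      type = factor(.data$type, levels = c("m", "sm", "st", "t")),
      sat = .data$satellite_arm != "none"
    ) |>
    count(.data$type, .data$sat) |>
    arrange(.data$type, .data$sat)
  terms <- sprintf(
    "%d%s%s", 2L * counts$n, as.character(counts$type),
    ifelse(counts$sat, "-SAT", "")
  )
  sprintf("2n = %d = %s", 2L * nrow(pairs), paste(terms, collapse = " + "))
}
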