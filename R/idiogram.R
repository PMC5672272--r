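#' Idiogram rendering style
#'
#' Display parameters for [render_idiogram()]. All geometry is expressed in
#' SVG user units; `scale` converts relative-length percent to user units,
#' so bar heights stay proportional to chromosome relative lengths.
#'
#' @param bar_width Chromosome bar width.
#' @param scale User units per RL percent.
#' @param gap Horizontal gap between bars.
#' @param margin Outer margin.
#' @param centromere_gap Height of the centromere constriction gap.
#' @param satellite_fraction Fraction of a satellited arm drawn as the
#'   detached satellite block (the measured arm length includes the
#'   satellite but the secondary-constriction length is not recorded, so
#'   the split is schematic).
#' @param sc_gap Height of the secondary-constriction gap separating the
#'   satellite block.
#' @param marker_palette Named colours for the four marker kinds.
#' @param show_sd_whiskers Draw an SD whisker on top of each bar.
#' @param ordinate_ticks Axis tick positions, RL percent.
#' @return A list of class `idiogram_style`.
#' @export
idiogram_style <- function(bar_width = 18,
                           scale = 28,
                           gap = 26,
                           margin = 46,
                           centromere_gap = 4,
                           satellite_fraction = 0.12,
                           sc_gap = 3,
                           marker_palette = c(
                             rDNA5S = "#d62728", rDNA45S = "#2ca02c",
                             CPD = "#e377c2", sGISH = "#9467bd"
                           ),
                           show_sd_whiskers = TRUE,
                           ordinate_ticks = 0:8) {
  check_number(scale, "scale", positive = TRUE)
  check_number(bar_width, "bar_width", positive = TRUE)
  needed <- c("rDNA5S", "rDNA45S", "CPD", "sGISH")
  if (!all(needed %in% names(marker_palette))) {
    stop_arg("marker_palette must name colours for rDNA5S, rDNA45S, CPD, sGISH")
  }
  structure(
    list(
      bar_width = bar_width, scale = scale, gap = gap, margin = margin,
      centromere_gap = centromere_gap, satellite_fraction = satellite_fraction,
      sc_gap = sc_gap, marker_palette = marker_palette,
      show_sd_whiskers = show_sd_whiskers, ordinate_ticks = ordinate_ticks
    ),
    class = "idiogram_style"
  )
}

fmt <- function(x) sprintf("%.4f", x)

svg_rect <- function(x, y, w, h, fill, class, extra = "") {
  sprintf(
    '<rect class="%s" x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
    class, fmt(x), fmt(y), fmt(w), fmt(h), fill, extra
  )
}

#' Render a karyotype as an SVG idiogram
#'
#' Draws one vertical bar per chromosome pair, short arm up, all
#' centromere constrictions aligned on a common baseline, with a left
#' ordinate axis in relative-length percent and optional marker glyphs.
#' Output is deterministic: identical inputs give byte-identical SVG.
#'
#' @param karyotype A `karyotype` object.
#' @param sites Optional marker tibble with columns `pair_id`, `kind`,
#'   `arm` and `size_percent` (glyph height, percent of karyotype length);
#'   arm sites also need `di` (percent distance of the site middle from
#'   the centromere). A `marker_summary` may be passed; its per-arm table
#'   is used with `di` taken from the mean of the per-site values.
#' @param style An [idiogram_style()].
#' @return A single string containing an SVG 1.1 document (class
#'   `svg_document`).
#' @examples
#' svg <- render_idiogram(canavalia_karyotype("gladiata"))
#' substr(svg, 1, 60)
#' @export
render_idiogram <- function(karyotype, sites = NULL, style = idiogram_style()) {
  if (!inherits(karyotype, "karyotype")) stop_arg("`karyotype` must be a karyotype object")
  pairs <- karyotype$pairs
  n <- nrow(pairs)
  if (inherits(sites, "marker_summary")) {
    di_means <- sites$sites |>
      group_by(.data$pair_id, .data$kind, .data$arm) |>
      summarise(di = mean(.data$di), .groups = "drop")
    sites <- sites$per_arm |>
      left_join(di_means, by = c("pair_id", "kind", "arm")) |>
      rename(size_percent = "size_mean")
  }

  s <- style$scale
  baseline <- style$margin + max(pairs$rl_short_mean) * s + 10
  height <- baseline + max(pairs$rl_long_mean) * s + style$margin
  width <- style$margin + 30 + n * (style$bar_width + style$gap) + style$margin
  x0 <- style$margin + 30

  out <- character(0)
  push <- function(...) out <<- c(out, sprintf(...))

  push('<?xml version="1.0" encoding="UTF-8"?>')
  push(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
    fmt(width), fmt(height), fmt(width), fmt(height)
  )
  push('<style>text{font-family:Helvetica,Arial,sans-serif;font-size:10px;}</style>')
  if (nzchar(karyotype$label)) {
    push('<text class="label" x="%s" y="%s">%s (%s)</text>',
         fmt(x0), fmt(style$margin - 22), karyotype$label, karyotype$formula)
  }

  # ordinate axis: RL percent, 0 at the centromere baseline, increasing outward
  axis_x <- style$margin
  tick_max <- max(style$ordinate_ticks)
  push('<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1"/>',
       fmt(axis_x), fmt(baseline - tick_max * s), fmt(axis_x), fmt(baseline + tick_max * s))
  for (t in style$ordinate_ticks) {
    for (dir in if (t == 0) 0 else c(-1, 1)) {
      y <- baseline + dir * t * s
      if (y < 0 || y > height) next
      push('<line class="tick" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1"/>',
           fmt(axis_x - 4), fmt(y), fmt(axis_x), fmt(y))
      push('<text class="ticklabel" x="%s" y="%s" text-anchor="end">%s</text>',
           fmt(axis_x - 6), fmt(y + 3), format(t))
    }
  }

  half_cg <- style$centromere_gap / 2
  for (i in seq_len(n)) {
    p <- pairs[i, ]
    x <- x0 + (i - 1) * (style$bar_width + style$gap)
    short_h <- p$rl_short_mean * s
    long_h <- p$rl_long_mean * s
    sat_arm <- p$satellite_arm

    draw_arm <- function(arm_name, arm_h, upward) {
      # upward arm spans [baseline - gap/2 - h, baseline - gap/2]
      sign <- if (upward) -1 else 1
      inner <- baseline + sign * half_cg
      if (!is.na(sat_arm) && sat_arm == arm_name && style$satellite_fraction > 0) {
        body_h <- arm_h * (1 - style$satellite_fraction) - style$sc_gap
        sat_h <- arm_h * style$satellite_fraction
        y_body <- if (upward) inner - body_h else inner
        push("%s", svg_rect(x, y_body, style$bar_width, body_h, "white", "arm",
                            ' stroke="black" stroke-width="1"'))
        y_sat <- if (upward) inner - arm_h else inner + arm_h - sat_h
        push("%s", svg_rect(x, y_sat, style$bar_width, sat_h, "white", "satellite",
                            ' stroke="black" stroke-width="1"'))
      } else {
        y_arm <- if (upward) inner - arm_h else inner
        push("%s", svg_rect(x, y_arm, style$bar_width, arm_h, "white", "arm",
                            ' stroke="black" stroke-width="1"'))
      }
    }
    draw_arm("short", short_h, upward = TRUE)
    draw_arm("long", long_h, upward = FALSE)
    # centromere constriction: waist marker across the baseline
    push("%s", svg_rect(x + style$bar_width * 0.2, baseline - half_cg,
                        style$bar_width * 0.6, style$centromere_gap,
                        "black", "centromere"))
    if (style$show_sd_whiskers && "rl_total_sd" %in% names(p) && is.finite(p$rl_total_sd)) {
      tip <- baseline - half_cg - short_h
      push('<line class="whisker" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="0.8"/>',
           fmt(x + style$bar_width / 2), fmt(tip - p$rl_total_sd * s),
           fmt(x + style$bar_width / 2), fmt(tip))
    }
    push('<text class="pairlabel" x="%s" y="%s" text-anchor="middle">%d</text>',
         fmt(x + style$bar_width / 2), fmt(baseline + half_cg + long_h + 14), p$pair_id)
  }

  if (!is.null(sites) && nrow(sites) > 0) {
    sites <- as_tibble(sites)
    for (j in seq_len(nrow(sites))) {
      site <- sites[j, ]
      idx <- match(site$pair_id, pairs$pair_id)
      if (is.na(idx)) {
        stop_validation(sprintf("marker on unknown pair %d (%s)", site$pair_id, site$kind))
      }
      p <- pairs[idx, ]
      x <- x0 + (idx - 1) * (style$bar_width + style$gap)
      h <- site$size_percent * s
      colour <- style$marker_palette[[site$kind]]
      if (site$arm == "centromere") {
        y_mid <- baseline
      } else {
        arm_rl <- if (site$arm == "short") p$rl_short_mean else p$rl_long_mean
        di <- site$di
        if (is.na(di) || di < 0 || di > 100) {
          stop_validation(sprintf("marker di outside arm on pair %d (%s)", site$pair_id, site$kind))
        }
        offset <- half_cg + di / 100 * arm_rl * s
        y_mid <- baseline + (if (site$arm == "short") -offset else offset)
      }
      push("%s", svg_rect(x - 2, y_mid - h / 2, style$bar_width + 4, h, colour,
                          sprintf("marker marker-%s", site$kind), ' fill-opacity="0.75"'))
    }
    # legend, one swatch per kind present, fixed order
    kinds <- intersect(names(style$marker_palette), unique(sites$kind))
    for (m in seq_along(kinds)) {
      lx <- x0
      ly <- height - style$margin + 12 + (m - 1) * 0
      lx <- x0 + (m - 1) * 90
      push("%s", svg_rect(lx, ly - 8, 10, 10, style$marker_palette[[kinds[m]]],
                          "legend", ' fill-opacity="0.75"'))
      push('<text class="legendlabel" x="%s" y="%s">%s</text>',
           fmt(lx + 14), fmt(ly + 1), kinds[m])
    }
  }

  push("</svg>")
  structure(paste(out, collapse = "\n"), class = "svg_document")
}

#' @export
print.svg_document <- function(x, ...) {
  cat(sprintf("<svg document> %d bytes; write with write_idiogram()\n", nchar(x)))
  invisible(x)
}

#' Write an SVG document to disk
#'
#' @param svg An `svg_document` from [render_idiogram()].
#' @param path Output path (`.svg`).
#' @return `path`, invisibly.
#' @export
write_idiogram <- function(svg, path) {
  writeLines(unclass(svg), path, useBytes = TRUE)
  invisible(path)
}

#' Idiogram-style ggplot of a karyotype
#'
#' A quick ggplot2 rendering of an aggregated karyotype: one bar per pair,
#' short arm up, centromeres aligned at zero. For publication-style SVG
#' output use [render_idiogram()].
#'
#' @param object A `karyotype` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.karyotype <- function(object, ...) {
  pairs <- object$pairs
  df <- bind_rows(
    tibble(pair_id = pairs$pair_id, ymin = 0, ymax = pairs$rl_short_mean, arm = "short"),
    tibble(pair_id = pairs$pair_id, ymin = -pairs$rl_long_mean, ymax = 0, arm = "long")
  )
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(
      ggplot2::aes(
        xmin = .data$pair_id - 0.3, xmax = .data$pair_id + 0.3,
        ymin = .data$ymin, ymax = .data$ymax
      ),
      fill = "grey85", colour = "black", linewidth = 0.4
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.6) +
    ggplot2::scale_x_continuous(breaks = pairs$pair_id) +
    ggplot2::labs(
      x = "chromosome pair", y = "relative length (% of haploid complement)",
      title = object$label, subtitle = object$formula
    ) +
    ggplot2::theme_minimal()
}
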