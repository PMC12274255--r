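#' Plot specification for dropout figures
#'
#' Bundles the display options shared by the plotting functions. The
#' colorblind-safe palette is the eight-color Okabe-Ito set, so at most
#' eight conditions can be distinguished with it; the grayscale palette
#' forces line-type cycling so curves stay distinguishable in print.
#'
#' @param palette one of `"colorblind"` (Okabe-Ito, default), `"default"`
#'   (ggplot2 hues) or `"grayscale"`.
#' @param linetypes cycle line types across conditions.
#' @param stroke_width line width.
#' @param full_scale if `TRUE` (default) the y axis spans the full 0-100%
#'   range; if `FALSE` it zooms to the data.
#' @param show_confbands draw confidence bands.
#' @param width,height figure size in inches (used by [export_figure()]).
#' @param dpi raster resolution (PNG export).
#' @param conditions_shown subset of condition labels to draw (`"total"`
#'   included); `NULL` draws all.
#' @return A list of class `plot_spec`.
#' @export
plot_spec <- function(palette = c("colorblind", "default", "grayscale"),
                      linetypes = FALSE, stroke_width = 0.8,
                      full_scale = TRUE, show_confbands = FALSE,
                      width = 7, height = 5, dpi = 300,
                      conditions_shown = NULL) {
  palette <- match.arg(palette)
  stopifnot(stroke_width > 0, width > 0, height > 0, dpi > 0)
  if (palette == "grayscale") linetypes <- TRUE
  structure(
    list(palette = palette, linetypes = isTRUE(linetypes),
         stroke_width = stroke_width, full_scale = isTRUE(full_scale),
         show_confbands = isTRUE(show_confbands),
         width = width, height = height, dpi = dpi,
         conditions_shown = conditions_shown),
    class = "plot_spec"
  )
}

# Okabe-Ito colorblind-safe set (8 colors).
OKABE_ITO <- c("#000000", "#E69F00", "#56B4E9", "#009E73",
               "#F0E442", "#0072B2", "#D55E00", "#CC79A7")

#' Condition color palette
#'
#' @param palette `"colorblind"`, `"default"` or `"grayscale"`.
#' @param n number of colors needed.
#' @return A character vector of `n` colors.
#' @export
do_palette <- function(palette = c("colorblind", "default", "grayscale"),
                       n) {
  palette <- match.arg(palette)
  stopifnot(n >= 1)
  switch(palette,
    colorblind = {
      if (n > length(OKABE_ITO)) {
        stop("the colorblind-friendly palette supports at most ",
             length(OKABE_ITO), " conditions (colors); ", n, " requested",
             call. = FALSE)
      }
      OKABE_ITO[seq_len(n)]
    },
    default = grDevices::hcl(
      h = seq(15, 375, length.out = n + 1)[seq_len(n)], l = 65, c = 100
    ),
    grayscale = grDevices::gray.colors(n, start = 0, end = 0.6)
  )
}

# Map shown conditions to colors; "total" is always drawn in black.
condition_colors <- function(levels, palette) {
  has_total <- "total" %in% levels
  others <- setdiff(levels, "total")
  pal <- if (palette == "colorblind") {
    cols <- do_palette("colorblind", length(levels))
    # black is reserved for the pooled curve
    if (has_total) setdiff(OKABE_ITO, "#000000")[seq_along(others)]
    else cols
  } else {
    do_palette(palette, length(others) + has_total)[seq_along(others)]
  }
  out <- stats::setNames(pal, others)
  if (has_total) out["total"] <- "#000000"
  out[levels]
}

shown_levels <- function(all_levels, spec) {
  shown <- spec$conditions_shown
  if (is.null(shown)) return(all_levels)
  unknown <- setdiff(shown, all_levels)
  if (length(unknown)) {
    stop("unknown condition(s) in conditions_shown: ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }
  all_levels[all_levels %in% shown]
}

#' Dropout curves by condition
#'
#' Percent of participants remaining against item position, one line per
#' condition plus the pooled `"total"` curve (drawn in black). Optional
#' confidence bands are normal-approximation binomial intervals on the
#' remaining proportion, `100 * (p +/- 1.96 * sqrt(p (1 - p) / N))`,
#' clipped to [0, 100].
#'
#' @param stats a `dropout_stats` table from [compute_stats()].
#' @param spec a [plot_spec()].
#' @return A ggplot object.
#' @examples
#' stats <- compute_stats(add_dropout_idx(demo_like()))
#' plot_do_curve(stats, plot_spec(full_scale = FALSE))
#' @export
plot_do_curve <- function(stats, spec = plot_spec()) {
  stopifnot(inherits(stats, "dropout_stats"), nrow(stats) > 0)
  all_levels <- c(setdiff(sort(unique(stats$condition)), "total"),
                  intersect("total", unique(stats$condition)))
  levels <- shown_levels(all_levels, spec)
  df <- stats[stats$condition %in% levels, , drop = FALSE]
  df$condition <- factor(df$condition, levels = levels)
  cols <- condition_colors(levels, spec$palette)

  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$question, y = .data$pct_remaining, colour = .data$condition
  ))
  if (spec$show_confbands) {
    prop <- df$pct_remaining / 100
    half <- 100 * 1.96 * sqrt(prop * (1 - prop) / df$N)
    df$ci_lo <- pmax(df$pct_remaining - half, 0)
    df$ci_hi <- pmin(df$pct_remaining + half, 100)
    p <- p + ggplot2::geom_ribbon(
      data = df,
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi,
                   fill = .data$condition),
      alpha = 0.15, colour = NA
    ) + ggplot2::scale_fill_manual(values = cols, guide = "none")
  }
  if (spec$linetypes) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(linetype = .data$condition),
      linewidth = spec$stroke_width
    )
  } else {
    p <- p + ggplot2::geom_line(linewidth = spec$stroke_width)
  }
  p <- p +
    ggplot2::scale_colour_manual(values = cols, name = "Condition") +
    ggplot2::labs(x = "Item position", y = "Participants remaining (%)") +
    ggplot2::theme_minimal()
  if (spec$full_scale) {
    p <- p + ggplot2::coord_cartesian(ylim = c(0, 100))
  }
  p
}

#' Kaplan-Meier retention plot
#'
#' Step-function survival (retention) curves per condition, with optional
#' confidence ribbons and censoring ticks where completers leave the risk
#' set.
#'
#' @param km a `km_curve` table from [km_fit()], or an `indexed_table`
#'   (fitted on the fly).
#' @param spec a [plot_spec()]; `show_confbands` toggles the ribbons.
#' @return A ggplot object.
#' @export
plot_do_kpm <- function(km, spec = plot_spec()) {
  if (inherits(km, "indexed_table")) km <- km_fit(km)
  stopifnot(inherits(km, "km_curve"))
  levels <- shown_levels(sort(unique(km$condition)), spec)
  km <- km[km$condition %in% levels, , drop = FALSE]
  cols <- condition_colors(levels, spec$palette)

  # piecewise-constant paths, anchored at S(0) = 1
  steps <- do.call(rbind, lapply(levels, function(cc) {
    d <- km[km$condition == cc, , drop = FALSE]
    d <- d[order(d$time), , drop = FALSE]
    k <- nrow(d)
    data.frame(
      condition = cc,
      x = c(0, rep(d$time, each = 2), d$time[k]),
      S = c(1, 1, rep(d$S, each = 2)),
      lo = c(1, 1, rep(d$ci_lo, each = 2)),
      hi = c(1, 1, rep(d$ci_hi, each = 2)),
      stringsAsFactors = FALSE
    )[seq_len(2 * k + 1), ]
  }))
  steps$condition <- factor(steps$condition, levels = levels)
  censors <- km[km$n_censor > 0, , drop = FALSE]

  p <- ggplot2::ggplot(steps, ggplot2::aes(
    x = .data$x, y = .data$S, colour = .data$condition
  ))
  if (spec$show_confbands) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                   fill = .data$condition),
      alpha = 0.15, colour = NA
    ) + ggplot2::scale_fill_manual(values = cols, guide = "none")
  }
  if (spec$linetypes) {
    p <- p + ggplot2::geom_path(ggplot2::aes(linetype = .data$condition),
                                linewidth = spec$stroke_width)
  } else {
    p <- p + ggplot2::geom_path(linewidth = spec$stroke_width)
  }
  if (nrow(censors)) {
    p <- p + ggplot2::geom_point(
      data = censors,
      ggplot2::aes(x = .data$time, y = .data$S, colour = .data$condition),
      shape = 3, size = 2, show.legend = FALSE
    )
  }
  p <- p +
    ggplot2::scale_colour_manual(values = cols, name = "Condition") +
    ggplot2::labs(x = "Item position", y = "Retention S(t)") +
    ggplot2::theme_minimal()
  ylim <- if (spec$full_scale) c(0, 1) else NULL
  p + ggplot2::coord_cartesian(ylim = ylim)
}

#' Extreme-condition comparison plot with KS annotation
#'
#' Draws the dropout curves of the two most extreme conditions and marks
#' the question where their vertical gap is largest (the KS distance, in
#' percent).
#'
#' @param stats a `dropout_stats` table from [compute_stats()].
#' @param ks a `ks_result` from [ks_dropout()].
#' @param colors length-2 color vector for the low/high retention curves.
#' @param spec a [plot_spec()].
#' @return A ggplot object.
#' @export
plot_do_ks <- function(stats, ks, colors = c("#D55E00", "#0072B2"),
                       spec = plot_spec()) {
  stopifnot(inherits(stats, "dropout_stats"), inherits(ks, "ks_result"),
            length(colors) == 2)
  for (cc in c(ks$cond_lo, ks$cond_hi)) {
    if (!cc %in% stats$condition) {
      stop("condition ", sQuote(cc), " not present in the statistics table",
           call. = FALSE)
    }
  }
  lo <- stats[stats$condition == ks$cond_lo, , drop = FALSE]
  hi <- stats[stats$condition == ks$cond_hi, , drop = FALSE]
  df <- rbind(lo, hi)
  df$condition <- factor(df$condition, levels = c(ks$cond_lo, ks$cond_hi))

  gap <- abs(lo$pct_remaining[order(lo$question)] -
             hi$pct_remaining[order(hi$question)])
  q_gap <- which.max(gap)
  y_pair <- c(lo$pct_remaining[lo$question == q_gap],
              hi$pct_remaining[hi$question == q_gap])

  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$question, y = .data$pct_remaining, colour = .data$condition
  )) +
    ggplot2::geom_line(linewidth = spec$stroke_width) +
    ggplot2::annotate("segment", x = q_gap, xend = q_gap,
                      y = min(y_pair), yend = max(y_pair),
                      linetype = "dotted", colour = "grey30") +
    ggplot2::annotate("label", x = q_gap, y = mean(y_pair),
                      label = sprintf("D = %.2f", ks$D), size = 3) +
    ggplot2::scale_colour_manual(values = stats::setNames(
      colors, c(ks$cond_lo, ks$cond_hi)), name = "Condition") +
    ggplot2::labs(x = "Item position", y = "Participants remaining (%)",
                  subtitle = ks_copy(ks)) +
    ggplot2::theme_minimal()
  if (spec$full_scale) p <- p + ggplot2::coord_cartesian(ylim = c(0, 100))
  p
}

#' Export a figure to PDF, PNG or SVG
#'
#' PDF and SVG are vector formats and scale without rasterization; PNG is
#' rasterized at `dpi`, so its pixel width is `round(width * dpi)`.
#'
#' @param fig a ggplot object.
#' @param path output file path.
#' @param format `"pdf"`, `"png"` or `"svg"`; inferred from the file
#'   extension when omitted.
#' @param width,height figure size in inches.
#' @param dpi resolution for PNG.
#' @return `path`, invisibly.
#' @export
export_figure <- function(fig, path, format = NULL,
                          width = 7, height = 5, dpi = 300) {
  supported <- c("pdf", "png", "svg")
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% supported) {
    stop("unsupported format ", sQuote(format), "; supported formats: ",
         paste(supported, collapse = ", "), call. = FALSE)
  }
  switch(format,
    pdf = grDevices::pdf(path, width = width, height = height,
                         onefile = FALSE),
    png = grDevices::png(path, width = round(width * dpi),
                         height = round(height * dpi), res = dpi,
                         type = "cairo"),
    svg = grDevices::svg(path, width = width, height = height)
  )
  on.exit(grDevices::dev.off(), add = TRUE)
  print(fig)
  invisible(path)
}
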