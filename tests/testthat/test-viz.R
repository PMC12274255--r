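demo_stats <- function() {
  compute_stats(add_dropout_idx(demo_like()))
}

test_that("the colorblind palette supplies eight distinct colors", {
  pal <- do_palette("colorblind", 8)
  expect_length(unique(pal), 8)
  expect_error(do_palette("colorblind", 9), "at most 8")
  expect_length(unique(do_palette("default", 10)), 10)
  expect_length(unique(do_palette("grayscale", 6)), 6)
})

test_that("dropout-curve plot draws one line per shown condition plus total", {
  st <- demo_stats()
  b <- ggplot2::ggplot_build(plot_do_curve(st))
  line_layer <- b$data[[which(vapply(
    b$plot$layers, function(l) inherits(l$geom, "GeomLine"), logical(1)))]]
  expect_length(unique(line_layer$group), 5)  # 4 conditions + total

  sub <- plot_do_curve(st, plot_spec(conditions_shown = c("11", "12")))
  bs <- ggplot2::ggplot_build(sub)
  expect_length(unique(bs$data[[1]]$group), 2)  # total absent
})

test_that("full_scale toggles the 0-100 axis span", {
  st <- demo_stats()
  full <- ggplot2::ggplot_build(plot_do_curve(st, plot_spec()))
  expect_equal(full$layout$coord$limits$y, c(0, 100))
  tight <- ggplot2::ggplot_build(
    plot_do_curve(st, plot_spec(full_scale = FALSE)))
  expect_null(tight$layout$coord$limits$y)
})

test_that("confidence bands and line types appear when requested", {
  st <- demo_stats()
  with_bands <- plot_do_curve(st, plot_spec(show_confbands = TRUE,
                                            linetypes = TRUE))
  geoms <- vapply(with_bands$layers,
                  function(l) class(l$geom)[1], character(1))
  expect_true("GeomRibbon" %in% geoms)
  b <- ggplot2::ggplot_build(with_bands)
  ribbon <- b$data[[which(geoms == "GeomRibbon")]]
  expect_true(all(ribbon$ymin >= 0 & ribbon$ymax <= 100))
  # grayscale forces line-type cycling
  expect_true(plot_spec(palette = "grayscale")$linetypes)
})

test_that("KM plot is a staircase anchored at S(0) = 1, with censor ticks", {
  it <- table_from_idx(c(1, 2, 2, 3, 3), rep("A", 5), K = 3)
  p <- plot_do_kpm(km_fit(it))
  b <- ggplot2::ggplot_build(p)
  path <- b$data[[1]]
  expect_equal(path$y[1], 1)
  expect_equal(min(path$y), 0.4)
  # piecewise-constant: every y change happens at a repeated x
  steps <- which(diff(path$y) != 0)
  expect_true(all(path$x[steps] == path$x[steps + 1]))
  geoms <- vapply(p$layers, function(l) class(l$geom)[1], character(1))
  expect_true("GeomPoint" %in% geoms)  # censoring tick at K
})

test_that("KS plot annotates the maximum-gap question", {
  it <- table_from_idx(c(1, 1, 2, 3, 2, 3, 3, 3),
                       rep(c("A", "B"), each = 4), K = 3)
  st <- compute_stats(it)
  ks <- ks_dropout(it, "A", "B", q = 3)
  p <- plot_do_ks(st, ks, colors = c("#FF0000", "#0000FF"))
  b <- ggplot2::ggplot_build(p)
  geoms <- vapply(p$layers, function(l) class(l$geom)[1], character(1))
  seg <- b$data[[which(geoms == "GeomSegment")]]
  expect_equal(abs(seg$yend - seg$y), 100 * ks$D)
  line <- b$data[[which(geoms == "GeomLine")]]
  expect_setequal(unique(line$colour), c("#FF0000", "#0000FF"))
  expect_error(plot_do_ks(demo_stats(), ks), "not present")
})

test_that("figures export to pdf, png and svg; unsupported formats error", {
  p <- plot_do_curve(demo_stats())
  d <- withr::local_tempdir()
  pdf_f <- export_figure(p, file.path(d, "f.pdf"), width = 4, height = 3)
  expect_gt(file.size(pdf_f), 1000)
  expect_identical(readBin(pdf_f, "raw", 4), charToRaw("%PDF"))

  svg_f <- export_figure(p, file.path(d, "f.svg"), width = 4, height = 3)
  head <- paste(readLines(svg_f, n = 5, warn = FALSE), collapse = " ")
  expect_match(head, "<svg", fixed = TRUE)

  png_f <- export_figure(p, file.path(d, "f.png"),
                         width = 4, height = 3, dpi = 72)
  img <- png::readPNG(png_f)
  expect_identical(dim(img)[2], as.integer(round(4 * 72)))
  expect_identical(dim(img)[1], as.integer(round(3 * 72)))

  expect_error(export_figure(p, file.path(d, "f.bmp")), "supported formats")
})

test_that("figures re-render identically from identical inputs", {
  st <- demo_stats()
  d <- withr::local_tempdir()
  f1 <- export_figure(plot_do_curve(st), file.path(d, "a.svg"))
  f2 <- export_figure(plot_do_curve(st), file.path(d, "b.svg"))
  expect_identical(readLines(f1, warn = FALSE), readLines(f2, warn = FALSE))
})
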