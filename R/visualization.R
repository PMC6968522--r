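EFFECT_BANDS <- c(-0.65, -0.35, -0.15, 0.15, 0.35, 0.65)

plot_kind_names <- c(
  points = "Point", histogram = "Histogram",
  density = "Density", histogram_density = "HistogramDensity"
)
plot_order_names <- c(none = "Default", increasing = "Increasing",
                      decreasing = "Decreasing")

#' Default file name for a rendered D-score plot
#'
#' @param kind Plot kind (`"points"`, `"histogram"`, `"density"`,
#'   `"histogram_density"`).
#' @param ordering Point ordering (`"none"`, `"increasing"`, `"decreasing"`).
#' @param algorithm Algorithm id, number or spec.
#' @return A file name such as `"PointDefaultDscore3.pdf"`.
#' @export
default_plot_filename <- function(kind, ordering, algorithm) {
  paste0(plot_kind_names[[kind]], plot_order_names[[ordering]],
         "Dscore", algorithm_spec(algorithm)$number, ".pdf")
}

#' Build plot data (and optionally a rendered figure) for a scored sample
#'
#' Produces the renderer-agnostic data behind the four standard displays of a
#' D-score distribution -- individual points (optionally ordered by score),
#' histogram, kernel density, or histogram with density overlaid -- together
#' with a ggplot object and, when `file` is given, a rendered PDF (or any
#' format `ggplot2::ggsave()` infers from the extension). Every display
#' carries horizontal reference lines at the effect-size bands
#' (+/-0.15, +/-0.35, +/-0.65).
#'
#' @param results A `dscore_results` object.
#' @param kind One of `"points"` (default), `"histogram"`, `"density"`,
#'   `"histogram_density"`.
#' @param ordering For `kind = "points"`: `"none"` keeps the input
#'   participant order, `"increasing"`/`"decreasing"` sort by D-score.
#' @param bins Number of histogram bins (histogram kinds only; default 30).
#' @param file Optional output path; when `NULL` nothing is written.
#'   [default_plot_filename()] gives the conventional name.
#' @param include_excluded Logical; plot flagged participants too.
#' @return An object of class `iat_plot`: a list with `data` (columns
#'   `index`, `participant`, `dscore`), `kind`, `ordering`,
#'   `reference_lines`, `plot` (a ggplot), and -- for the relevant kinds --
#'   `histogram` (`breaks`, `counts`) and `density` (`x`, `y`).
#' @export
build_plot <- function(results,
                       kind = c("points", "histogram", "density",
                                "histogram_density"),
                       ordering = c("none", "increasing", "decreasing"),
                       bins = 30, file = NULL, include_excluded = FALSE) {
  stopifnot(inherits(results, "dscore_results"))
  kind <- match.arg(kind)
  ordering <- match.arg(ordering)
  keep <- displayed_rows(results, include_excluded)
  d <- results[[score_columns(results)[["dscore"]]]][keep]
  pid <- results$participant[keep]
  ok <- !is.na(d)
  d <- d[ok]; pid <- pid[ok]
  if (length(d) == 0) stop("no defined D-scores to plot", call. = FALSE)

  ord <- switch(ordering,
                none = seq_along(d),
                increasing = order(d, pid),
                decreasing = order(-d, pid))
  dat <- data.frame(index = seq_along(d), participant = pid[ord],
                    dscore = d[ord], stringsAsFactors = FALSE)

  out <- list(data = dat, kind = kind, ordering = ordering,
              reference_lines = EFFECT_BANDS)

  if (kind %in% c("histogram", "histogram_density")) {
    breaks <- seq(min(d), max(d), length.out = bins + 1)
    h <- graphics::hist(d, breaks = breaks, plot = FALSE)
    out$histogram <- list(breaks = h$breaks, counts = h$counts,
                          density = h$density)
  }
  if (kind %in% c("density", "histogram_density")) {
    dens <- stats::density(d)
    out$density <- list(x = dens$x, y = dens$y, bw = dens$bw)
  }

  out$plot <- render_dscore_plot(out)
  if (!is.null(file)) {
    ggplot2::ggsave(file, out$plot, width = 7, height = 5)
    out$file <- file
  }
  class(out) <- "iat_plot"
  out
}

render_dscore_plot <- function(x) {
  bands <- data.frame(y = x$reference_lines)
  if (x$kind == "points") {
    p <- ggplot2::ggplot(x$data, ggplot2::aes(x = index, y = dscore)) +
      ggplot2::geom_hline(data = bands, ggplot2::aes(yintercept = y),
                          linetype = "dashed", colour = "grey50") +
      ggplot2::geom_point(colour = "#2c7fb8") +
      ggplot2::labs(x = "Participant", y = "D-score")
  } else {
    p <- ggplot2::ggplot(x$data, ggplot2::aes(x = dscore))
    if (!is.null(x$histogram)) {
      p <- p + ggplot2::geom_histogram(
        ggplot2::aes(y = ggplot2::after_stat(density)),
        breaks = x$histogram$breaks, fill = "#a6bddb", colour = "white"
      )
    }
    if (!is.null(x$density)) {
      p <- p + ggplot2::geom_density(colour = "#2c7fb8", linewidth = 0.8)
    }
    p <- p +
      ggplot2::geom_vline(data = bands, ggplot2::aes(xintercept = y),
                          linetype = "dashed", colour = "grey50") +
      ggplot2::labs(x = "D-score", y = "Density")
  }
  p + ggplot2::theme_minimal()
}

#' @export
print.iat_plot <- function(x, ...) {
  print(x$plot, ...)
  invisible(x)
}

#' Find the participant nearest to a clicked D-score value
#'
#' Mimics the point-lookup of an interactive display: given a D-score value,
#' returns the nearest plotted participant within a tolerance, ties broken by
#' participant ID order.
#'
#' @param results A `dscore_results` object.
#' @param clicked_dscore Numeric value to match.
#' @param tolerance Maximum absolute distance (default 0.05).
#' @param include_excluded Logical; search flagged participants too.
#' @return A data frame with zero or one row (`participant`, `dscore`).
#' @export
lookup_point <- function(results, clicked_dscore, tolerance = 0.05,
                         include_excluded = FALSE) {
  stopifnot(inherits(results, "dscore_results"))
  keep <- displayed_rows(results, include_excluded)
  d <- results[[score_columns(results)[["dscore"]]]][keep]
  pid <- results$participant[keep]
  ok <- !is.na(d)
  d <- d[ok]; pid <- pid[ok]
  dist <- abs(d - clicked_dscore)
  hit <- which(dist <= tolerance)
  if (length(hit) == 0) {
    return(data.frame(participant = character(0), dscore = numeric(0)))
  }
  best <- hit[order(dist[hit], pid[hit])][1]
  data.frame(participant = pid[best], dscore = d[best],
             stringsAsFactors = FALSE)
}

#' List the participants inside a selected plot area
#'
#' Mimics the area-selection lookup: every displayed participant whose
#' D-score falls in a closed interval (and, optionally, whose plot index
#' falls in an index interval) is returned, sorted by D-score.
#'
#' @param results A `dscore_results` object.
#' @param dscore_range Numeric length-2 closed interval of D-scores.
#' @param index_range Optional numeric length-2 interval of plot indices
#'   (positions in input order).
#' @param include_excluded Logical; search flagged participants too.
#' @return A data frame (`participant`, `dscore`), sorted by `dscore`.
#' @export
lookup_area <- function(results, dscore_range, index_range = NULL,
                        include_excluded = FALSE) {
  stopifnot(inherits(results, "dscore_results"), length(dscore_range) == 2)
  keep <- displayed_rows(results, include_excluded)
  d <- results[[score_columns(results)[["dscore"]]]][keep]
  pid <- results$participant[keep]
  ok <- !is.na(d)
  d <- d[ok]; pid <- pid[ok]; idx <- seq_along(d)
  lo <- min(dscore_range); hi <- max(dscore_range)
  sel <- d >= lo & d <= hi
  if (!is.null(index_range)) {
    sel <- sel & idx >= min(index_range) & idx <= max(index_range)
  }
  out <- data.frame(participant = pid[sel], dscore = d[sel],
                    stringsAsFactors = FALSE)
  out[order(out$dscore), , drop = FALSE]
}
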