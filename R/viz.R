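#' Plot specification for heatmaps
#'
#' @param cutoff NULL (full range), `list(percentile = p)` with 0 < p <
#'   100, or `list(max_count = m)`.
#' @param colors Character vector of colors for the sequential ramp.
#' @param over_color Color for values above the cutoff.
#' @param dpi Raster resolution hint (> 0).
#' @return `plot_spec` list.
#' @export
plot_spec <- function(cutoff = list(percentile = 95), colors = NULL,
                      over_color = "#6b3226", dpi = 300) {
  if (!is.null(cutoff)) {
    stopifnot(is.list(cutoff), length(cutoff) == 1L,
              names(cutoff) %in% c("percentile", "max_count"))
    if (identical(names(cutoff), "percentile")) {
      stopifnot(cutoff$percentile > 0, cutoff$percentile < 100)
    }
  }
  stopifnot(dpi > 0)
  if (is.null(colors)) colors <- c("#ffffff", "#f5c38f", "#d7301f", "#7f0000")
  structure(list(cutoff = cutoff, colors = colors, over_color = over_color,
                 dpi = dpi), class = "plot_spec")
}

# Exact cutoff value implied by a spec: percentile over ALL upper-triangle
# entries (zeros included), linear interpolation (classic type-7 quantile).
.cutoff_value <- function(m, spec) {
  vals <- m[upper.tri(m, diag = TRUE)]
  vals <- vals[!is.na(vals)]
  if (is.null(spec$cutoff)) return(max(vals))
  if (!is.null(spec$cutoff$percentile)) {
    return(unname(stats::quantile(vals, spec$cutoff$percentile / 100,
                                  type = 7, names = FALSE)))
  }
  spec$cutoff$max_count
}

.region_bins <- function(matrix, region) {
  n <- matrix$n_bins
  if (is.null(region)) return(1:n)
  b0 <- region[1L] %/% matrix$bin_size + 1L
  b1 <- min(ceiling(region[2L] / matrix$bin_size), n)
  if (b0 > n || b1 < b0) {
    stop("region [", region[1L], ",", region[2L], ") is empty or beyond ",
         "the chromosome")
  }
  b0:b1
}

.mb_axis <- function(matrix, bins) {
  at <- pretty(range((bins - 1L) * matrix$bin_size)) / 1e6
  list(at = at * 1e6 / matrix$bin_size - (bins[1L] - 1L), lab = at)
}

#' Contact heatmap
#'
#' Pixel intensity proportional to the contact value, with an optional
#' upper cutoff (percentile of all upper-triangle entries, zeros included,
#' or an absolute count) that emphasizes local structure; values above it
#' are drawn in the spec's over-cutoff color. Axes are labeled in Mb.
#'
#' @param matrix `contact_matrix` (observed, normalized or correction).
#' @param spec `plot_spec`.
#' @param path Output pdf file.
#' @param region Optional `c(start, end)` bp window.
#' @return Invisibly, a list with the exact `cutoff` used and `path`.
#' @export
plot_heatmap <- function(matrix, spec = plot_spec(), path, region = NULL) {
  stopifnot(matrix$role %in% c("observed", "normalized", "correction"))
  bins <- .region_bins(matrix, region)
  m <- matrix$values[bins, bins, drop = FALSE]
  cutoff <- .cutoff_value(matrix$values, spec)
  ramp <- grDevices::colorRampPalette(spec$colors)(255)
  cols <- c(ramp, spec$over_color)
  top <- max(cutoff, max(m[is.finite(m)], na.rm = TRUE), 1) * 2 + 1
  breaks <- c(seq(0, max(cutoff, 1e-9), length.out = 256), top)
  grDevices::pdf(path, width = 7, height = 7)
  on.exit(grDevices::dev.off())
  nb <- length(bins)
  graphics::image(seq_len(nb), seq_len(nb), t(m[nb:1, , drop = FALSE]),
                  col = cols, breaks = breaks, axes = FALSE, xlab = "Mb",
                  ylab = "Mb", useRaster = TRUE)
  ax <- .mb_axis(matrix, bins)
  graphics::axis(1, at = ax$at, labels = ax$lab)
  graphics::axis(2, at = nb + 1 - ax$at, labels = ax$lab)
  graphics::title(sprintf("%s %s (bin %d bp, max color = %.4g)",
                          matrix$chrom, matrix$role, matrix$bin_size, cutoff))
  invisible(list(cutoff = cutoff, path = path))
}

#' Observed-over-expected heatmap
#'
#' Symmetric diverging color scale centered at log2 = 0; bins without
#' expected contacts are black and bins with expected but no observed
#' contacts are gray.
#'
#' @param oe `contact_matrix` with role "oe_log2".
#' @param spec `plot_spec` (cutoff ignored; colors may override the
#'   diverging ramp).
#' @param path Output pdf.
#' @param region Optional bp window.
#' @return Invisibly, list with symmetric color `limits` and `path`.
#' @export
plot_oe_heatmap <- function(oe, spec = plot_spec(cutoff = NULL), path,
                            region = NULL) {
  stopifnot(oe$role == "oe_log2")
  bins <- .region_bins(oe, region)
  m <- oe$values[bins, bins, drop = FALSE]
  sent <- if (!is.null(oe$sentinel)) oe$sentinel[bins, bins, drop = FALSE]
          else matrix(0L, nrow(m), ncol(m))
  hi <- max(abs(m[is.finite(m)]), 0)
  if (hi == 0) hi <- 1
  ramp <- grDevices::colorRampPalette(c("#2166ac", "#ffffff", "#b2182b"))(255)
  filled <- m
  filled[sent == 1L] <- hi + 1   # na_expected -> black
  filled[sent == 2L] <- hi + 3   # na_observed -> gray
  breaks <- c(seq(-hi, hi, length.out = 256), hi + 2, hi + 4)
  cols <- c(ramp, "#000000", "#808080")
  grDevices::pdf(path, width = 7, height = 7)
  on.exit(grDevices::dev.off())
  nb <- length(bins)
  graphics::image(seq_len(nb), seq_len(nb), t(filled[nb:1, , drop = FALSE]),
                  col = cols, breaks = breaks, axes = FALSE,
                  xlab = "Mb", ylab = "Mb", useRaster = TRUE)
  ax <- .mb_axis(oe, bins)
  graphics::axis(1, at = ax$at, labels = ax$lab)
  graphics::axis(2, at = nb + 1 - ax$at, labels = ax$lab)
  graphics::title(sprintf("%s log2(O/E), limits +/- %.3g", oe$chrom, hi))
  invisible(list(limits = c(-hi, hi), path = path))
}

#' Contact-count histogram
#'
#' Distribution of the matrix's upper-triangle entries (one count per bin
#' pair); for O/E matrices the X axis is already in log2 units.
#'
#' @param matrix `contact_matrix`.
#' @param path Output pdf.
#' @param breaks Histogram breaks (passed to [graphics::hist()]).
#' @return Invisibly, the `hist` object (counts sum to the number of
#'   upper-triangle entries with data).
#' @export
plot_histogram <- function(matrix, path, breaks = 50) {
  vals <- matrix$values[upper.tri(matrix$values, diag = TRUE)]
  vals <- vals[!is.na(vals)]
  xlab <- if (matrix$role == "oe_log2") "log2 O/E contact count"
          else "contact count"
  grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  h <- graphics::hist(vals, breaks = breaks, main = matrix$chrom,
                      xlab = xlab, ylab = "bin frequency", col = "grey70")
  invisible(h)
}

#' Observed DI bars with the decoded "true DI" state track
#'
#' Observed DI values as bars, with the +1/0/-1 decoded state step track
#' overlaid (its Y scale is nominal: states mark domain orientation, not
#' magnitude).
#'
#' @param di `di_track`.
#' @param states Optional `state_track`.
#' @param path Output pdf.
#' @param region Optional bp window.
#' @export
plot_di <- function(di, states = NULL, path, region = NULL) {
  n <- length(di$di)
  bins <- 1:n
  if (!is.null(region)) {
    bins <- max(1L, region[1L] %/% di$bin_size + 1L):
      min(n, ceiling(region[2L] / di$bin_size))
  }
  x <- (bins - 1L) * di$bin_size / 1e6
  grDevices::pdf(path, width = 9, height = 4)
  on.exit(grDevices::dev.off())
  v <- di$di[bins]
  graphics::plot(x, v, type = "h", col = ifelse(v >= 0, "#b2182b", "#2166ac"),
                 xlab = "Mb", ylab = "DI", main = di$chrom)
  if (!is.null(states)) {
    s <- states$states[bins]
    ylim <- max(abs(v), 1)
    graphics::lines(x, s * 0.5 * ylim, type = "s", lwd = 2, col = "black")
  }
  invisible(path)
}

#' Triangular heatmap with TADs along the diagonal
#'
#' The upper triangle of the matrix rotated 45 degrees, with each TAD
#' drawn as a triangle outline sitting on the diagonal; TADs outside the
#' plotted region are omitted.
#'
#' @param matrix `contact_matrix` (normalized).
#' @param tads TAD table (`start`, `end` in bp).
#' @param spec `plot_spec`.
#' @param path Output pdf.
#' @param region Optional bp window.
#' @export
plot_tads_triangle <- function(matrix, tads, spec = plot_spec(), path,
                               region = NULL) {
  bins <- .region_bins(matrix, region)
  m <- matrix$values[bins, bins, drop = FALSE]
  cutoff <- .cutoff_value(matrix$values, spec)
  ramp <- grDevices::colorRampPalette(spec$colors)(255)
  cols <- c(ramp, spec$over_color)
  brk <- c(seq(0, max(cutoff, 1e-9), length.out = 256), Inf)
  nb <- length(bins)
  grDevices::pdf(path, width = 9, height = 5)
  on.exit(grDevices::dev.off())
  graphics::plot(NULL, xlim = c(0, nb), ylim = c(0, nb / 2 + 1),
                 xlab = "bins", ylab = "", asp = 1, axes = FALSE,
                 main = sprintf("%s %s + TADs", matrix$chrom, matrix$role))
  graphics::axis(1)
  lv <- matrix(findInterval(m, brk, all.inside = TRUE), nrow(m))
  for (i in seq_len(nb)) {
    for (j in i:nb) {
      cx <- (i + j - 2) / 2
      cy <- (j - i) / 2
      graphics::polygon(cx + c(-0.5, 0, 0.5, 0), cy + c(0, 0.5, 0, -0.5),
                        col = cols[lv[i, j]], border = NA)
    }
  }
  off <- (bins[1L] - 1L) * matrix$bin_size
  for (r in seq_len(nrow(tads))) {
    b0 <- (tads$start[r] - off) / matrix$bin_size
    b1 <- (tads$end[r] - off) / matrix$bin_size
    if (b1 <= 0 || b0 >= nb) next
    apex <- (b1 - b0) / 2
    graphics::lines(c(b0, (b0 + b1) / 2, b1), c(0, apex, 0),
                    col = "#1f4e9c", lwd = 2)
  }
  invisible(path)
}
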