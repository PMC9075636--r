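# Exact 2-D Gaussian product-kernel density at the observation points,
# normal-reference bandwidths; used only to rank/color dots.
point_density_2d <- function(x, y) {
  bx <- MASS::bandwidth.nrd(x)
  by <- MASS::bandwidth.nrd(y)
  if (bx <= 0) bx <- max(stats::sd(x), 1e-8)
  if (by <= 0) by <- max(stats::sd(y), 1e-8)
  kx <- outer(x, x, function(a, b) stats::dnorm(a - b, sd = bx))
  ky <- outer(y, y, function(a, b) stats::dnorm(a - b, sd = by))
  rowMeans(kx * ky)
}

point_density_1d <- function(x) {
  h <- stats::bw.nrd0(x)
  rowMeans(outer(x, x, function(a, b) stats::dnorm(a - b, sd = h)))
}

save_plot <- function(p, path, format = c("png", "svg"), width = 6,
                      height = 5) {
  format <- match.arg(format)
  dev <- switch(format, png = function(f) grDevices::png(f, width = width,
                                                         height = height,
                                                         units = "in",
                                                         res = 150),
                svg = function(f) grDevices::svg(f, width = width,
                                                 height = height))
  dev(path)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

#' Density-colored scatter plot of predicted versus true age
#'
#' True versus predicted age with the identity line, each dot colored by the
#' local 2-D sample density (Gaussian product kernel, normal-reference
#' bandwidths), annotated with the report's R-squared and MSE.
#'
#' @param report An [evaluate()] report.
#' @param path Output image path.
#' @param format `"png"` or `"svg"`.
#' @param title Plot title.
#' @param units Age-axis unit label.
#' @return Invisibly, a list with `path` and `data` (the plotted samples
#'   with their `density` color values).
#' @export
scatter_plot <- function(report, path, format = c("png", "svg"),
                         title = "DNAm age", units = "age") {
  s <- report$samples
  if (!nrow(s)) stop("empty report")
  s$density <- point_density_2d(s$true_age, s$predicted_age)
  lab <- sprintf("R^2 = %.3f\nMSE = %.3g", report$r2, report$mse)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$true_age,
                                       y = .data$predicted_age,
                                       color = .data$density)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_color_viridis_c(name = "density") +
    ggplot2::annotate("text", x = min(s$true_age), y = max(s$predicted_age),
                      label = lab, hjust = 0, vjust = 1, size = 3.4) +
    ggplot2::labs(title = title, x = paste("chronological", units),
                  y = paste("predicted", units)) +
    ggplot2::theme_bw()
  save_plot(p, path, format)
  invisible(list(path = path, data = s, annotation = lab))
}

# Mean residual within equal-width age bins over a shared axis; the same
# binning rule as the cross-training residual aggregation.
residual_curve <- function(samples, width, lo) {
  eps <- 1e-9 * max(1, abs(width))
  b <- floor((samples$true_age - lo + eps) / width) + 1L
  agg <- stats::aggregate(samples$residual, list(bin = b), mean)
  data.frame(bin = agg$bin, bin_mid = lo + (agg$bin - 0.5) * width,
             mean_residual = agg$x,
             n = as.vector(table(b)[as.character(agg$bin)]))
}

#' Residual plot for one model
#'
#' Residual (predicted minus true) versus true age, with the zero line and
#' the binned mean-residual curve overlaid.
#'
#' @inheritParams scatter_plot
#' @param bin_width Age bin width for the mean curve; `NULL` adapts it from
#'   the report's ages via [adapt_bin_width()].
#' @return Invisibly, a list with `path`, `data`, and `curve` (the binned
#'   mean residuals).
#' @export
residual_plot <- function(report, path, format = c("png", "svg"),
                          title = "residuals", units = "age",
                          bin_width = NULL) {
  s <- report$samples
  if (!nrow(s)) stop("empty report")
  if (is.null(bin_width))
    bin_width <- adapt_bin_width(s$true_age, initial_width = 1)$width
  curve <- residual_curve(s, bin_width, min(s$true_age))
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$true_age,
                                       y = .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point(size = 1.5, alpha = 0.6) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$bin_mid,
                                    y = .data$mean_residual),
                       color = "firebrick", inherit.aes = FALSE) +
    ggplot2::labs(title = title, x = paste("chronological", units),
                  y = "residual (predicted - true)") +
    ggplot2::theme_bw()
  save_plot(p, path, format)
  invisible(list(path = path, data = s, curve = curve))
}

#' Residual comparison across models
#'
#' One binned mean-residual curve per report on a shared age axis, with the
#' zero line; the standard view for judging which clock fits the rare ages.
#'
#' @param reports Named list of [evaluate()] reports sharing an age axis.
#' @inheritParams residual_plot
#' @return Invisibly, a list with `path` and `curves` (data.frame: model,
#'   bin, bin_mid, mean_residual, n).
#' @export
residual_comparison <- function(reports, path, format = c("png", "svg"),
                                title = "residual comparison",
                                units = "age", bin_width = NULL) {
  if (!length(reports)) stop("empty report list")
  if (is.null(names(reports)))
    names(reports) <- paste0("model", seq_along(reports))
  all_ages <- unlist(lapply(reports, function(r) r$samples$true_age))
  lo <- min(all_ages)
  if (is.null(bin_width))
    bin_width <- adapt_bin_width(all_ages, initial_width = 1)$width
  curves <- do.call(rbind, lapply(names(reports), function(nm) {
    cv <- residual_curve(reports[[nm]]$samples, bin_width, lo)
    cbind(model = nm, cv)
  }))
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$bin_mid,
                                            y = .data$mean_residual,
                                            color = .data$model)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(title = title, x = paste("chronological", units),
                  y = "mean residual (predicted - true)") +
    ggplot2::theme_bw()
  save_plot(p, path, format)
  invisible(list(path = path, curves = curves))
}

# Affine age -> angle map: min(age) at angle 0, max(age) at `span` degrees
# (330 by default, leaving a gap so the two ends stay visually distinct).
age_to_angle <- function(age, age_min, age_max, span = 330) {
  if (age_max <= age_min) stop("zero age range")
  (age - age_min) / (age_max - age_min) * span
}

#' Polar clock-dial plot of predictions
#'
#' A dial whose angular scale spans the true-age range over 330 degrees
#' (leaving a gap so the extremes stay distinct). Each sample is one pointer
#' drawn at the angle of its predicted age, colored by the 1-D density of
#' the true ages; rim ticks mark the true ages, so a perfect clock has every
#' pointer meeting its tick.
#'
#' @inheritParams scatter_plot
#' @param span Angular span of the dial in degrees; default 330.
#' @return Invisibly, a list with `path` and `data` including the pointer
#'   angles (`pred_angle`, degrees) and tick angles (`true_angle`).
#' @export
clock_plot <- function(report, path, format = c("png", "svg"),
                       title = "clock plot", units = "age", span = 330) {
  s <- report$samples
  if (!nrow(s)) stop("empty report")
  amin <- min(s$true_age); amax <- max(s$true_age)
  if (amax <= amin) stop("zero age range")
  s$true_angle <- age_to_angle(s$true_age, amin, amax, span)
  s$pred_angle <- age_to_angle(s$predicted_age, amin, amax, span)
  s$density <- point_density_1d(s$true_age)
  rad <- function(deg) (90 - deg) * pi / 180  # 0 deg at 12 o'clock, clockwise
  s$px <- 0.9 * cos(rad(s$pred_angle)); s$py <- 0.9 * sin(rad(s$pred_angle))
  s$tx0 <- 0.95 * cos(rad(s$true_angle)); s$ty0 <- 0.95 * sin(rad(s$true_angle))
  s$tx1 <- 1.02 * cos(rad(s$true_angle)); s$ty1 <- 1.02 * sin(rad(s$true_angle))
  lab_age <- pretty(c(amin, amax), 8)
  lab_age <- lab_age[lab_age >= amin & lab_age <= amax]
  lab <- data.frame(age = lab_age,
                    ang = age_to_angle(lab_age, amin, amax, span))
  lab$x <- 1.14 * cos(rad(lab$ang)); lab$y <- 1.14 * sin(rad(lab$ang))
  p <- ggplot2::ggplot(s) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, y = 0, xend = .data$px,
                                       yend = .data$py,
                                       color = .data$density),
                          linewidth = 0.4, alpha = 0.8) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$tx0, y = .data$ty0,
                                       xend = .data$tx1, yend = .data$ty1),
                          color = "grey30", linewidth = 0.3) +
    ggplot2::geom_text(data = lab, ggplot2::aes(x = .data$x, y = .data$y,
                                                label = .data$age),
                       size = 3) +
    ggplot2::scale_color_viridis_c(name = "density") +
    ggplot2::coord_fixed(xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25)) +
    ggplot2::labs(title = title, subtitle = paste("dial scale:", units)) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5),
                   plot.subtitle = ggplot2::element_text(hjust = 0.5))
  save_plot(p, path, format)
  invisible(list(path = path, data = s, span = span))
}
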