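#' Z-score normalization across genotypes
#'
#' Standardises a per-genotype statistic to mean 0 and (population) sd 1,
#' the scale on which production and stability are compared across
#' genotypes.
#'
#' @param x numeric vector (one value per genotype, length \eqn{\ge 2}).
#' @return \code{(x - mean(x)) / sd_pop(x)}; all zeros with a warning
#'   when the input has no spread.
#' @export
zscore <- function(x) {
  stopifnot(length(x) >= 2)
  s <- sd_pop(x)
  if (s == 0 || !is.finite(s)) {
    warning("zero spread: z-scores undefined, returning zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Classify genotypes as productive, stable and responsive
#'
#' Applies the three decision rules of the adaptability/stability
#' analysis to a fit's posterior summaries:
#' \itemize{
#'   \item \emph{productive}: posterior-mean intercept \eqn{\beta_{i0}}
#'     z-score above 0; \emph{top tier} when more than one standard
#'     deviation above the overall mean (z > 1);
#'   \item \emph{stable}: stability statistic \eqn{\hat\sigma^2_{di}}
#'     z-score below 0 (below-average deviation variance);
#'   \item \emph{responsive}: favorable-regime slope
#'     \eqn{\beta_{i1} + \beta_{i2}} above \code{responsive_slope}
#'     (default 1, the classical unit-response criterion; the threshold
#'     is in yield units per index unit, hence scale-dependent).
#' }
#'
#' @param fit a \code{\link{fit_biseg}} result (with stability columns),
#'   or its \code{summaries} data frame.
#' @param responsive_slope threshold on the favorable-regime slope.
#' @param top_tier_z z-score threshold for top-tier production.
#' @return A \code{genotype_summary} data frame: the input summaries plus
#'   \code{z_beta0}, \code{z_sigma2_di}, \code{slope_unfav},
#'   \code{slope_fav}, \code{productive} (\code{"top"},
#'   \code{"above-mean"} or \code{"below-mean"}), \code{stable},
#'   \code{responsive}.
#' @export
classify <- function(fit, responsive_slope = 1, top_tier_z = 1) {
  s <- if (inherits(fit, "biseg_fit")) fit$summaries else fit
  need <- c("genotype", "beta0_mean", "sigma2_di_mean", "slope_fav_mean",
            "beta1_mean")
  if (!all(need %in% names(s)))
    stop("summaries must contain columns: ", paste(need, collapse = ", "))
  if (nrow(s) < 2) stop("classification needs at least 2 genotypes")
  out <- s
  out$z_beta0 <- zscore(s$beta0_mean)
  out$z_sigma2_di <- zscore(s$sigma2_di_mean)
  out$slope_unfav <- s$beta1_mean
  out$slope_fav <- s$slope_fav_mean
  out$productive <- ifelse(out$z_beta0 > top_tier_z, "top",
                           ifelse(out$z_beta0 > 0, "above-mean",
                                  "below-mean"))
  out$stable <- out$z_sigma2_di < 0
  out$responsive <- out$slope_fav > responsive_slope
  class(out) <- c("genotype_summary", "data.frame")
  out
}

## Two line segments per genotype for the adaptability chart: the
## unfavorable regime from the most negative index to the hinge at 0,
## and the favorable regime from 0 to the largest index.
slope_segments <- function(summaries, design) {
  lo <- min(design$index); hi <- max(design$index)
  ipb <- attr(design, "i_plus_bar")
  seg <- function(g, b0, b1, b2) {
    rbind(
      data.frame(genotype = g, segment = "unfavorable",
                 x0 = lo, y0 = b0 + b1 * lo, x1 = 0, y1 = b0,
                 stringsAsFactors = FALSE),
      data.frame(genotype = g, segment = "favorable",
                 x0 = 0, y0 = b0, x1 = hi,
                 y1 = b0 + b1 * hi + b2 * (hi - ipb),
                 stringsAsFactors = FALSE))
  }
  do.call(rbind, mapply(seg, summaries$genotype, summaries$beta0_mean,
                        summaries$beta1_mean, summaries$beta2_mean,
                        SIMPLIFY = FALSE))
}

#' Stability/production bar chart
#'
#' Diverging bars of z-scored posterior intercepts (production) and of
#' z-scored stability statistics annotated with each genotype's
#' \eqn{R^2}; green above/below the relevant average, following the
#' convention that below-average \eqn{\hat\sigma^2_{di}} (negative
#' z-score) is good stability.
#'
#' @param classified a \code{\link{classify}} result.
#' @param which \code{"production"} or \code{"stability"}.
#' @return A ggplot object (no device is opened).
#' @export
plot_stability <- function(classified, which = c("production",
                                                 "stability")) {
  which <- match.arg(which)
  df <- as.data.frame(classified)
  if (which == "production") {
    df$z <- df$z_beta0; df$good <- df$z > 0; lab <- "z(beta0)"
  } else {
    df$z <- df$z_sigma2_di; df$good <- df$z < 0; lab <- "z(sigma2_di)"
  }
  df$genotype <- stats::reorder(df$genotype, df$z)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = genotype, y = z,
                                        fill = good)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "forestgreen",
                                          `FALSE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = lab)
  if (which == "stability" && "r_squared_display" %in% names(df))
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f", r_squared_display)),
      hjust = -0.1, size = 2.5)
  p
}

#' Adaptability slope chart
#'
#' One polyline per genotype joining the unfavorable-regime segment
#' (slope \eqn{\beta_{i1}}) to the favorable-regime segment (slope
#' \eqn{\beta_{i1} + \beta_{i2}}) at the hinge; responsive genotypes in
#' green, non-responsive in red.
#'
#' @param classified a \code{\link{classify}} result.
#' @param design the fit's \code{\link{compute_index}} design.
#' @return A ggplot object.
#' @export
plot_slopes <- function(classified, design) {
  seg <- slope_segments(classified, design)
  seg$responsive <- classified$responsive[match(seg$genotype,
                                                classified$genotype)]
  ggplot2::ggplot(seg, ggplot2::aes(x = x0, y = y0,
                                    xend = x1, yend = y1,
                                    group = genotype,
                                    colour = responsive)) +
    ggplot2::geom_segment() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
                                            `FALSE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "environmental index", y = "yield")
}

#' Write the full analysis report bundle
#'
#' Deterministically writes, into \code{dir}: the genotype summary and
#' classification CSV, the joint ANOVA CSV, the environmental-index
#' table CSV, and the slope-chart underlying data CSV (exactly two
#' segments per genotype).  Charts are written as PNG files only when
#' \code{plots = TRUE} (chart data are always emitted as CSV so results
#' remain testable without a graphics device).
#'
#' @param fit a \code{\link{fit_biseg}} result.
#' @param anova the \code{\link{joint_anova}} table.
#' @param dir output directory (created if needed).
#' @param responsive_slope,top_tier_z passed to \code{\link{classify}}.
#' @param plots also render PNG charts.
#' @return Invisibly, the named vector of files written.
#' @export
report <- function(fit, anova, dir, responsive_slope = 1, top_tier_z = 1,
                   plots = FALSE) {
  stopifnot(inherits(fit, "biseg_fit"), inherits(anova, "anova_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cls <- classify(fit, responsive_slope, top_tier_z)
  files <- c(
    summaries = file.path(dir, "genotype_summaries.csv"),
    anova = file.path(dir, "joint_anova.csv"),
    index = file.path(dir, "environmental_index.csv"),
    slopes = file.path(dir, "slope_segments.csv"))
  write_summaries(as.data.frame(cls), files["summaries"])
  write_summaries(as.data.frame(anova), files["anova"])
  write_summaries(as.data.frame(fit$design), files["index"])
  write_summaries(slope_segments(cls, fit$design), files["slopes"])
  if (plots) {
    pf <- c(production = file.path(dir, "production.png"),
            stability = file.path(dir, "stability.png"),
            slopes_plot = file.path(dir, "slopes.png"))
    ggplot2::ggsave(pf["production"], plot_stability(cls, "production"),
                    width = 6, height = 8, dpi = 120)
    ggplot2::ggsave(pf["stability"], plot_stability(cls, "stability"),
                    width = 6, height = 8, dpi = 120)
    ggplot2::ggsave(pf["slopes_plot"], plot_slopes(cls, fit$design),
                    width = 7, height = 5, dpi = 120)
    files <- c(files, pf)
  }
  invisible(files)
}
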