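#' Kaplan-Meier curves by group
#'
#' Base-graphics step curves with censoring ticks, one color per group.
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param groups Group labels.
#' @param main Plot title.
#' @param xlab,ylab Axis labels.
#' @param col Colors recycled over groups.
#' @return Invisibly, the underlying `survfit`.
#' @export
plot_km_groups <- function(times, events, groups, main = "",
                           xlab = "Months", ylab = "Survival probability",
                           col = c("#d73027", "#4575b4", "#1a9850", "#984ea3")) {
  groups <- droplevels(as.factor(groups))
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  graphics::plot(fit, col = col[seq_len(nlevels(groups))], lwd = 2,
                 mark.time = TRUE, xlab = xlab, ylab = ylab, main = main)
  graphics::legend("topright", legend = levels(groups), lwd = 2,
                   col = col[seq_len(nlevels(groups))], bty = "n")
  invisible(fit)
}

# barycentric -> cartesian for an equilateral triangle with unit side
bary_to_xy <- function(p_cancer, p_lymphocyte, p_stromal) {
  list(x = p_lymphocyte + p_stromal / 2, y = p_stromal * sqrt(3) / 2)
}

#' Ternary plot of section compositions over the Shannon field
#'
#' Plots per-section compositions on the 3-class simplex, with the
#' theoretical Shannon diversity surface as background shading (grey-blue:
#' low entropy near the vertices; yellow: maximal entropy at the center).
#'
#' @param section_div Output of [diversity_by_section()] (or any table with
#'   `p_cancer`, `p_lymphocyte`, `p_stromal`).
#' @param resolution Background lattice resolution.
#' @param main Plot title.
#' @return Invisibly, `NULL`.
#' @export
plot_ternary <- function(section_div, resolution = 60, main = "Microenvironmental composition") {
  field <- shannon_simplex_field(resolution)
  xy <- bary_to_xy(field$p_cancer, field$p_lymphocyte, field$p_stromal)
  pal <- grDevices::hcl.colors(64, "YlGnBu", rev = TRUE)
  cols <- pal[pmax(1, ceiling(64 * field$shannon / log(3)))]
  graphics::plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.08, sqrt(3) / 2 + 0.05),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::points(xy$x, xy$y, pch = 15, cex = 120 / resolution / 2, col = cols)
  tri <- bary_to_xy(c(1, 0, 0, 1), c(0, 1, 0, 0), c(0, 0, 1, 0))
  graphics::lines(tri$x, tri$y, lwd = 1.5)
  graphics::text(c(0, 1, 0.5), c(-0.05, -0.05, sqrt(3) / 2 + 0.04),
                 labels = c("cancer", "lymphocyte", "stromal"), cex = 0.9)
  sd_dt <- as.data.table(section_div)
  pts <- bary_to_xy(sd_dt$p_cancer, sd_dt$p_lymphocyte, sd_dt$p_stromal)
  graphics::points(pts$x, pts$y, pch = 16, cex = 0.6, col = "black")
  invisible(NULL)
}
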