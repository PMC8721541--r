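# Figure output. Base graphics; every figure is reproducible from the saved
# artifacts alone.

shade_blocks <- function(scn, ylim) {
  days <- ceiling(scn$duration_h / 24)
  for (d in seq_len(days)) {
    x0 <- (d - 1) * 1440
    graphics::rect(x0, ylim[1], min(x0 + 480, scn$duration_h * 60), ylim[2],
                   col = grDevices::adjustcolor("steelblue", 0.10), border = NA)
  }
  for (tm in scn$meal_times) {
    graphics::rect(tm, ylim[1], min(tm + 240, scn$duration_h * 60), ylim[2],
                   col = grDevices::adjustcolor("orange", 0.08), border = NA)
  }
}

#' Cohort glucose ribbon plot
#'
#' Median and interquartile range of the CGM values across patients over the
#' scenario, with the 70-180 mg/dl target band, nocturnal blocks and
#' post-prandial windows shaded.
#'
#' @param trial a `loop_trial`.
#' @param main plot title.
#' @export
plot_cohort_bg <- function(trial, main = "Cohort glucose (median, IQR)") {
  ok <- !vapply(trial, inherits, TRUE, "loop_sim_error")
  sims <- trial[ok]
  stop_if(length(sims) == 0, "no successful runs to plot")
  tgrid <- sims[[1]]$cgm$t
  mat <- vapply(sims, function(s) s$cgm$value, numeric(length(tgrid)))
  med <- apply(mat, 1, stats::median)
  q1 <- apply(mat, 1, function(v) q25_75(v)[1])
  q3 <- apply(mat, 1, function(v) q25_75(v)[2])
  ylim <- range(c(q1, q3, 60, 260))
  scn <- sims[[1]]$scenario
  graphics::plot(NA, xlim = range(tgrid), ylim = ylim, xaxt = "n",
                 xlab = "time", ylab = "glucose [mg/dl]", main = main)
  shade_blocks(scn, ylim)
  graphics::rect(min(tgrid), 70, max(tgrid), 180,
                 col = grDevices::adjustcolor("seagreen", 0.12), border = NA)
  graphics::polygon(c(tgrid, rev(tgrid)), c(q1, rev(q3)),
                    col = grDevices::adjustcolor("grey40", 0.3), border = NA)
  graphics::lines(tgrid, med, lwd = 2)
  at <- seq(0, max(tgrid), by = 360)
  graphics::axis(1, at = at, labels = clock_label(at))
  invisible(data.frame(t = tgrid, median = med, q25 = q1, q75 = q3))
}

#' Mean cohort glucose with carbohydrate intake
#'
#' @param trial a `loop_trial`.
#' @export
plot_cohort_mean_bg <- function(trial) {
  ok <- !vapply(trial, inherits, TRUE, "loop_sim_error")
  sims <- trial[ok]
  stop_if(length(sims) == 0, "no successful runs to plot")
  tgrid <- sims[[1]]$cgm$t
  mat <- vapply(sims, function(s) s$cgm$value, numeric(length(tgrid)))
  mbg <- rowMeans(mat)
  scn <- sims[[1]]$scenario
  ylim <- range(c(mbg, 60, 220))
  graphics::plot(tgrid, mbg, type = "n", xaxt = "n", ylim = ylim,
                 xlab = "time", ylab = "mean glucose [mg/dl]",
                 main = "Mean glucose and CHO intake")
  shade_blocks(scn, ylim)
  graphics::rect(min(tgrid), 70, max(tgrid), 180,
                 col = grDevices::adjustcolor("seagreen", 0.12), border = NA)
  graphics::lines(tgrid, mbg, lwd = 2)
  graphics::segments(scn$meal_times, ylim[1],
                     scn$meal_times, ylim[1] + scn$meals$grams,
                     lwd = 3, col = "darkorange")
  at <- seq(0, max(tgrid), by = 360)
  graphics::axis(1, at = at, labels = clock_label(at))
  invisible(mbg)
}

#' Per-patient glucose and insulin-delivery plot
#'
#' Two stacked panels: CGM/true glucose with target band, and the insulin
#' delivery channels (scheduled basal, effective temp rate, meal boluses and
#' SMBs).
#'
#' @param x a `loop_sim`.
#' @param ... ignored.
#' @export
plot.loop_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(op))
  ylim <- range(c(x$cgm$value, 60, 260))
  graphics::plot(x$true_bg$t, x$true_bg$G, type = "n", xaxt = "n", ylim = ylim,
                 xlab = "", ylab = "glucose [mg/dl]",
                 main = sprintf("patient %s", x$id))
  shade_blocks(x$scenario, ylim)
  graphics::rect(0, 70, max(x$true_bg$t), 180,
                 col = grDevices::adjustcolor("seagreen", 0.12), border = NA)
  graphics::lines(x$true_bg$t, x$true_bg$G, col = "grey50")
  graphics::lines(x$cgm$t, x$cgm$value, lwd = 1.5)
  at <- seq(0, max(x$true_bg$t), by = 360)
  graphics::axis(1, at = at, labels = clock_label(at))

  d <- x$delivery
  ymax <- max(c(d$effective_rate, d$bolus, d$smb, 2))
  graphics::plot(d$t, d$effective_rate, type = "s", ylim = c(0, ymax),
                 xaxt = "n", xlab = "time", ylab = "insulin [U/h | U]",
                 main = "delivery")
  graphics::abline(h = d$scheduled_basal[1], lty = 2, col = "grey60")
  b <- d$bolus > 0
  s <- d$smb > 0
  if (any(b)) graphics::segments(d$t[b], 0, d$t[b], d$bolus[b],
                                 lwd = 3, col = "firebrick")
  if (any(s)) graphics::segments(d$t[s], 0, d$t[s], d$smb[s],
                                 lwd = 2, col = "dodgerblue3")
  graphics::axis(1, at = at, labels = clock_label(at))
  invisible(x)
}
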