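#' Glycemic range classification
#'
#' Consensus bands (half-open at the lower edge): level 2 hypoglycemia
#' `BG <= 54`, level 1 hypoglycemia `54 < BG <= 70`, target
#' `70 < BG <= 180`, level 1 hyperglycemia `180 < BG <= 250` and level 2
#' hyperglycemia `BG > 250` mg/dl. The tight target range `70 < BG <= 140`
#' is a subset of the target range and reported separately.
#'
#' @param bg glucose values, mg/dl (vectorized).
#' @return Factor with levels `level2_hypo`, `level1_hypo`, `target`,
#'   `level1_hyper`, `level2_hyper`.
#' @export
classify_range <- function(bg) {
  stop_if(any(bg <= 0), "BG values must be > 0")
  cut(bg, breaks = c(0, 54, 70, 180, 250, Inf),
      labels = c("level2_hypo", "level1_hypo", "target",
                 "level1_hyper", "level2_hyper"),
      right = TRUE)
}

#' Time-block membership mask
#'
#' Blocks: `"O"` overall (all samples), `"N"` nocturnal (midnight to
#' 8:00 AM each day), `"PP"` post-prandial (within 4 h after any meal; the
#' window `(meal, meal + 240]` is open on the left, closed on the right, and
#' overlapping windows are unioned).
#'
#' @param times sample times, min from scenario start (midnight day 1).
#' @param scn a [scenario()] (supplies the meal times).
#' @param block `"O"`, `"N"` or `"PP"`.
#' @return Logical mask over `times`.
#' @export
block_mask <- function(times, scn, block = c("O", "N", "PP")) {
  block <- match.arg(block)
  switch(block,
    O = rep(TRUE, length(times)),
    N = (times %% 1440) < 480,
    PP = {
      m <- rep(FALSE, length(times))
      for (tm in scn$meal_times) m <- m | (times > tm & times <= tm + 240)
      m
    })
}

#' Percent time in each glycemic range
#'
#' @param bg glucose samples in the block, mg/dl.
#' @return Named numeric vector of percentages: `Tb54`, `T54_70`, `TIR`,
#'   `T180_250`, `Ta250` (the five partition bands, summing to 100) and
#'   `TTT` (tight target range).
#' @export
time_in_ranges <- function(bg) {
  stop_if(length(bg) == 0, "no samples selected for this block")
  n <- length(bg)
  cls <- classify_range(bg)
  pct <- 100 * as.vector(table(cls)) / n
  names(pct) <- c("Tb54", "T54_70", "TIR", "T180_250", "Ta250")
  c(pct, TTT = 100 * sum(bg > 70 & bg <= 140) / n)
}

#' Low and high blood glucose risk indices
#'
#' Uses the logarithmic blood-glucose risk transform
#' \eqn{f(BG) = 1.509\,((\ln BG)^{1.084} - 5.381)}; the per-sample risks are
#' \eqn{rl = 10 f^2} for \eqn{f < 0} (else 0) and \eqn{rh = 10 f^2} for
#' \eqn{f > 0} (else 0). LBGI and HBGI are the means of `rl` and `rh` over
#' the selected samples.
#'
#' @param bg glucose samples, mg/dl (> 0).
#' @return Named numeric vector `c(LBGI, HBGI)`.
#' @export
bg_indices <- function(bg) {
  stop_if(length(bg) == 0, "no samples selected for this block")
  stop_if(any(bg <= 0), "BG values must be > 0")
  f <- 1.509 * (log(bg)^1.084 - 5.381)
  c(LBGI = mean(ifelse(f < 0, 10 * f^2, 0)),
    HBGI = mean(ifelse(f > 0, 10 * f^2, 0)))
}

#' Count hypotreatments within a block
#'
#' @param ht_times HT event times, min.
#' @param scn a [scenario()].
#' @param block block label (see [block_mask()]).
#' @return Number of HT events falling in the block.
#' @export
count_hypotreatments <- function(ht_times, scn, block = "O") {
  if (length(ht_times) == 0) return(0L)
  sum(block_mask(ht_times, scn, block))
}

#' Per-patient glycemic metrics report
#'
#' Computes the consensus metrics per time block (O, N, PP): mean glucose M,
#' SD, CV = SD/M (a fraction), the five range percentages plus tight target
#' time, the hypotreatment count, LBGI and HBGI. Metrics are computed on the
#' CGM series by default (what the controller and the evaluation observe);
#' set `use_true_bg = TRUE` to evaluate the plant glucose sampled on the
#' same 5-min grid.
#'
#' @param sim a `loop_sim` from [run_closed_loop()].
#' @param use_true_bg evaluate true plant glucose instead of CGM readings.
#' @return A `loop_metrics` data.frame with one row per block and columns
#'   `block`, `M`, `SD`, `CV`, `TIR`, `TTT`, `Ta250`, `T180_250`, `T54_70`,
#'   `Tb54`, `n_HT`, `LBGI`, `HBGI`.
#' @export
glycemic_report <- function(sim, use_true_bg = FALSE) {
  stop_if(inherits(sim, "loop_sim_error"),
          "cannot compute metrics for failed run '", sim$id, "'")
  scn <- sim$scenario
  if (use_true_bg) {
    grid <- sim$cgm$t
    series <- data.frame(t = grid,
                         value = sim$true_bg$G[match(grid, sim$true_bg$t)])
  } else {
    series <- sim$cgm
  }
  ht_times <- sim$events$t[sim$events$type == "ht"]
  rows <- lapply(c("O", "N", "PP"), function(b) {
    m <- block_mask(series$t, scn, b)
    stop_if(!any(m), "block '", b, "' selects no samples")
    bg <- series$value[m]
    rng <- time_in_ranges(bg)
    idx <- bg_indices(bg)
    data.frame(block = b, M = mean(bg), SD = stats::sd(bg),
               CV = stats::sd(bg) / mean(bg),
               TIR = rng[["TIR"]], TTT = rng[["TTT"]],
               Ta250 = rng[["Ta250"]], T180_250 = rng[["T180_250"]],
               T54_70 = rng[["T54_70"]], Tb54 = rng[["Tb54"]],
               n_HT = count_hypotreatments(ht_times, scn, b),
               LBGI = idx[["LBGI"]], HBGI = idx[["HBGI"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "id") <- sim$id
  attr(out, "age_group") <- sim$patient$age_group
  class(out) <- c("loop_metrics", "data.frame")
  out
}

#' Cohort summary of glycemic metrics
#'
#' Aggregates per-patient reports across the cohort: for every metric and
#' block the median and interquartile range (25th/75th percentiles, linear
#' interpolation) are reported, except mean glucose in the O and PP blocks,
#' which is summarised as mean (+/- SD). A per-age-group breakdown is
#' included when the reports carry age groups.
#'
#' @param reports list of [glycemic_report()] results.
#' @return A `loop_summary` data.frame with columns `group`, `metric`,
#'   `block`, `median`, `q25`, `q75`, `mean`, `sd` and `display` (formatted
#'   as the convention dictates per cell).
#' @export
summarize_cohort <- function(reports) {
  stop_if(length(reports) == 0, "no reports to summarize")
  metrics <- c("M", "SD", "CV", "TIR", "TTT", "Ta250", "T180_250",
               "T54_70", "Tb54", "n_HT", "LBGI", "HBGI")
  groups <- vapply(reports, function(r) attr(r, "age_group") %||% "unknown", "")
  tab_for <- function(keep, label) {
    rows <- list()
    for (met in metrics) {
      for (b in c("O", "N", "PP")) {
        vals <- vapply(reports[keep], function(r) r[r$block == b, met], 0)
        q <- q25_75(vals)
        mean_style <- met == "M" && b %in% c("O", "PP")
        disp <- if (mean_style) {
          sprintf("%.2f (±%.2f)", mean(vals), stats::sd(vals))
        } else {
          sprintf("%.2f [%.2f, %.2f]", stats::median(vals), q[1], q[2])
        }
        rows[[length(rows) + 1]] <- data.frame(
          group = label, metric = met, block = b,
          median = stats::median(vals), q25 = q[1], q75 = q[2],
          mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else 0,
          display = disp, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  out <- tab_for(rep(TRUE, length(reports)), "all")
  for (g in unique(groups)) {
    if (g != "unknown" && length(unique(groups)) > 1) {
      out <- rbind(out, tab_for(groups == g, g))
    }
  }
  class(out) <- c("loop_summary", "data.frame")
  out
}

#' @export
print.loop_summary <- function(x, ...) {
  if (is.null(x$group) || is.null(x$display)) {
    return(print.data.frame(x, row.names = FALSE))
  }
  for (g in unique(x$group)) {
    cat(sprintf("== %s ==\n", g))
    sub <- x[x$group == g, ]
    wide <- stats::reshape(sub[, c("metric", "block", "display")],
                           idvar = "metric", timevar = "block",
                           direction = "wide")
    names(wide) <- sub("^display\\.", "", names(wide))
    print(wide, row.names = FALSE)
  }
  invisible(x)
}

#' Metrics for a whole trial
#'
#' @param trial a `loop_trial` from [run_cohort()].
#' @param use_true_bg see [glycemic_report()].
#' @return List with `reports` (per patient) and `summary`
#'   ([summarize_cohort()] output).
#' @export
trial_metrics <- function(trial, use_true_bg = FALSE) {
  ok <- !vapply(trial, inherits, TRUE, "loop_sim_error")
  reports <- lapply(trial[ok], glycemic_report, use_true_bg = use_true_bg)
  list(reports = reports, summary = summarize_cohort(reports))
}
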