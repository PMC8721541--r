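#' Serialize a cohort to JSON (and optionally CSV)
#'
#' The JSON document carries the generator seed, package version and the full
#' parameter list of every patient, so a cohort can be reloaded byte-for-byte.
#'
#' @param cohort a [generate_cohort()] result.
#' @param path output JSON path.
#' @param csv optional path for a flat parameter table.
#' @export
write_cohort <- function(cohort, path, csv = NULL) {
  doc <- list(
    generator = "loopsim",
    version = as.character(utils::packageVersion("loopsim")),
    seed = attr(cohort, "seed"),
    n_per_group = attr(cohort, "n_per_group"),
    patients = lapply(cohort, function(p) unclass(p)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv)) {
    utils::write.csv(cohort_table(cohort), csv, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  doc <- jsonlite::read_json(path)
  cohort <- lapply(doc$patients, function(p) do.call(patient_params, p))
  names(cohort) <- vapply(cohort, `[[`, "", "id")
  attr(cohort, "seed") <- doc$seed
  attr(cohort, "n_per_group") <- doc$n_per_group
  class(cohort) <- "loop_cohort"
  cohort
}

#' Write per-patient simulation artifacts
#'
#' Writes `<id>_glucose.csv` (5-min grid: time, CGM reading and true plant
#' glucose), `<id>_delivery.csv` (the insulin/carb delivery log),
#' `<id>_events.json` (meal, bolus, SMB and HT events) and
#' `<id>_controller.jsonl` (one JSON object per controller invocation:
#' glucose status, IOB, COB, autosens ratio, deviation and the resulting
#' recommendation), all with minutes-from-start timestamps plus `HH:MM`
#' clock labels where tabular.
#'
#' @param sim a `loop_sim`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- sim$cgm$t
  glu <- data.frame(t = grid, clock = clock_label(grid),
                    cgm = sim$cgm$value,
                    true_bg = sim$true_bg$G[match(grid, sim$true_bg$t)])
  p_glu <- file.path(dir, paste0(sim$id, "_glucose.csv"))
  p_del <- file.path(dir, paste0(sim$id, "_delivery.csv"))
  p_ev <- file.path(dir, paste0(sim$id, "_events.json"))
  utils::write.csv(glu, p_glu, row.names = FALSE)
  del <- sim$delivery
  del$clock <- clock_label(del$t)
  utils::write.csv(del, p_del, row.names = FALSE)
  jsonlite::write_json(
    list(id = sim$id, seed = sim$seed,
         events = sim$events), p_ev, auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  paths <- c(p_glu, p_del, p_ev)
  # controller I/O snapshot, one JSON object per invocation
  if (!is.null(sim$controller) && nrow(sim$controller)) {
    p_ctl <- file.path(dir, paste0(sim$id, "_controller.jsonl"))
    lines <- vapply(seq_len(nrow(sim$controller)), function(i) {
      jsonlite::toJSON(as.list(sim$controller[i, ]), auto_unbox = TRUE,
                       digits = NA)
    }, "")
    writeLines(lines, p_ctl)
    paths <- c(paths, p_ctl)
  }
  invisible(paths)
}

#' Read a glucose trace written by [write_simulation()]
#'
#' @param path a `*_glucose.csv` path.
#' @param use_true_bg return the true plant glucose column instead of CGM.
#' @return data.frame `t`, `value` on the 5-min grid.
#' @export
read_trace <- function(path, use_true_bg = FALSE) {
  stop_if(!file.exists(path), "trace file not found: ", path)
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("malformed trace CSV '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  col <- if (use_true_bg) "true_bg" else "cgm"
  stop_if(!all(c("t", col) %in% names(df)),
          "trace '", path, "' lacks columns t/", col)
  stop_if(nrow(df) == 0, "trace '", path, "' is empty")
  bad <- which(!is.finite(df$t) | !is.finite(df[[col]]))
  stop_if(length(bad) > 0, "trace '", path, "' has invalid values at row ",
          bad[1])
  dt <- diff(df$t)
  stop_if(any(dt != 5), "trace '", path, "' is not on a 5-min grid")
  data.frame(t = df$t, value = df[[col]])
}

#' Write cohort summary tables
#'
#' @param summary a [summarize_cohort()] result.
#' @param csv,json output paths (either may be `NULL`).
#' @export
write_summary <- function(summary, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(as.data.frame(summary), csv,
                                      row.names = FALSE)
  if (!is.null(json)) jsonlite::write_json(as.data.frame(summary), json,
                                           auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
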