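#' Trial scenario definition
#'
#' Encodes the scripted in-silico trial protocol: a multi-day meal plan plus
#' the hypotreatment and bolus-timing rules. The default protocol covers two
#' days starting at midnight; announced meals receive a half bolus 15 min
#' before intake, and a 16 g rescue carbohydrate (hypotreatment, HT) is given
#' whenever the measured glucose falls below 65 mg/dl, with a 30-min lockout
#' between HTs.
#'
#' @param duration_h total duration, h (default 48; the clock starts at
#'   midnight of day 1).
#' @param meals data.frame with columns `day` (1-based), `time` ("HH:MM"),
#'   `grams` (CHO g) and `announced` (logical: entered into the controller
#'   and bolused).
#' @param bolus_lead_min minutes between meal bolus and CHO intake.
#' @param ht_grams rescue carbohydrate size, g.
#' @param ht_threshold CGM threshold triggering an HT, mg/dl.
#' @param ht_lockout_min minimum interval between two HTs, min.
#' @param controller_period_min controller/CGM cadence, min.
#' @return A `loop_scenario` list; `$meal_times` holds absolute meal minutes.
#' @export
scenario <- function(duration_h = 48, meals = default_meals(),
                     bolus_lead_min = 15, ht_grams = 16, ht_threshold = 65,
                     ht_lockout_min = 30, controller_period_min = 5) {
  stop_if(!is_number(duration_h) || duration_h <= 0, "duration_h must be > 0")
  stop_if(!is_number(ht_grams) || ht_grams <= 0, "ht_grams must be > 0")
  stop_if(!is_number(bolus_lead_min) || bolus_lead_min < 0,
          "bolus_lead_min must be >= 0")
  need <- c("day", "time", "grams", "announced")
  stop_if(!is.data.frame(meals) || !all(need %in% names(meals)),
          "meals must be a data.frame with columns day, time, grams, announced")
  meal_times <- (meals$day - 1) * 1440 +
    vapply(as.character(meals$time), parse_clock, 0)
  stop_if(any(meals$grams <= 0), "meal grams must be > 0")
  stop_if(any(meal_times >= duration_h * 60),
          "meal outside the scenario duration")
  o <- order(meal_times)
  s <- list(duration_h = duration_h, meals = meals[o, , drop = FALSE],
            meal_times = unname(meal_times[o]),
            bolus_lead_min = bolus_lead_min, ht_grams = ht_grams,
            ht_threshold = ht_threshold, ht_lockout_min = ht_lockout_min,
            controller_period_min = controller_period_min)
  rownames(s$meals) <- NULL
  class(s) <- "loop_scenario"
  s
}

#' @rdname scenario
#' @export
default_meals <- function() {
  one_day <- data.frame(
    time = c("07:00", "12:30", "16:00", "19:00", "22:00"),
    grams = c(45, 70, 20, 60, 15),
    announced = TRUE)
  rbind(cbind(day = 1, one_day), cbind(day = 2, one_day))[, c("day", "time", "grams", "announced")]
}

#' @rdname scenario
#' @export
default_scenario <- function() scenario()

#' @export
print.loop_scenario <- function(x, ...) {
  cat(sprintf("<loop_scenario> %g h from midnight, %d meals\n", x$duration_h,
              nrow(x$meals)))
  cat(sprintf("  HT %g g when CGM < %g mg/dl (lockout %g min); bolus lead %g min\n",
              x$ht_grams, x$ht_threshold, x$ht_lockout_min, x$bolus_lead_min))
  print(x$meals)
  invisible(x)
}

SCENARIO_KEYS <- c("duration_h", "bolus_lead_min", "ht_grams", "ht_threshold",
                   "ht_lockout_min", "controller_period_min", "meals")

#' Read / write a scenario as YAML
#'
#' The document carries the [scenario()] fields plus a `meals` list of
#' `{day, time, grams, announced}` entries; unknown keys are rejected.
#'
#' @param path file path.
#' @return `read_scenario()` returns a validated `loop_scenario`.
#' @export
read_scenario <- function(path) {
  stop_if(!file.exists(path), "scenario file not found: ", path)
  doc <- yaml::read_yaml(path)
  unknown <- setdiff(names(doc), SCENARIO_KEYS)
  stop_if(length(unknown) > 0,
          "unknown scenario keys: ", paste(unknown, collapse = ", "))
  stop_if(is.null(doc$meals), "scenario document has no 'meals' list")
  meals <- do.call(rbind, lapply(seq_along(doc$meals), function(i) {
    m <- doc$meals[[i]]
    unknown <- setdiff(names(m), c("day", "time", "grams", "announced"))
    stop_if(length(unknown) > 0, "meals[", i, "]: unknown keys: ",
            paste(unknown, collapse = ", "))
    for (f in c("day", "time", "grams")) {
      stop_if(is.null(m[[f]]), "meals[", i, "]: missing field '", f, "'")
    }
    data.frame(day = m$day, time = as.character(m$time), grams = m$grams,
               announced = isTRUE(m$announced %||% TRUE))
  }))
  args <- doc[setdiff(names(doc), "meals")]
  args$meals <- meals
  do.call(scenario, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_scenario
#' @param scn a `loop_scenario`.
#' @export
write_scenario <- function(scn, path) {
  doc <- scn[setdiff(SCENARIO_KEYS, "meals")]
  doc$meals <- lapply(seq_len(nrow(scn$meals)), function(i) {
    list(day = scn$meals$day[i], time = scn$meals$time[i],
         grams = scn$meals$grams[i], announced = scn$meals$announced[i])
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}
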