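#' Treatment history container
#'
#' Collects the dosing record the controller reasons over: discrete boluses
#' (meal boluses and SMBs) and temporary basal rates, which are discretized
#' into 5-min deviations from the scheduled basal for insulin-on-board
#' accounting.
#'
#' @param boluses data.frame with columns `t` (min) and `units` (U).
#' @param temps data.frame with columns `start` (min), `duration` (min) and
#'   `rate` (U/h).
#' @return A `loop_history` list.
#' @export
treatment_history <- function(boluses = data.frame(t = numeric(0), units = numeric(0)),
                              temps = data.frame(start = numeric(0),
                                                 duration = numeric(0),
                                                 rate = numeric(0))) {
  structure(list(boluses = boluses, temps = temps), class = "loop_history")
}

# Flatten a history into impulse events (t, units) relative to the scheduled
# basal: boluses keep their size; temps become 5-min chunks of
# (rate - basal) * chunk/60 units at the chunk start.
history_events <- function(history, basal, now) {
  t <- history$boluses$t
  u <- history$boluses$units
  tp <- history$temps
  if (nrow(tp)) {
    for (i in seq_len(nrow(tp))) {
      end <- min(tp$start[i] + tp$duration[i], now)
      if (end <= tp$start[i]) next
      starts <- seq(tp$start[i], end - 1e-9, by = 5)
      lens <- pmin(5, end - starts)
      t <- c(t, starts)
      u <- c(u, (tp$rate[i] - basal) * lens / 60)
    }
  }
  list(t = t, units = u)
}

#' Insulin on board and activity from a treatment history
#'
#' Sums the exponential-curve contributions of every bolus and every 5-min
#' temp-basal deviation from the scheduled basal. Contributions older than
#' one DIA have fully decayed.
#'
#' @param history a [treatment_history()].
#' @param profile a [therapy_profile()] (uses `DIA`, `peak`, `basal`).
#' @param now current time, min; all history timestamps must be `<= now`.
#' @return A list with `iob` (U) and `activity` (U/min).
#' @export
compute_iob <- function(history, profile, now) {
  ev <- history_events(history, profile$basal, now)
  stop_if(length(ev$t) > 0 && any(ev$t > now + 1e-9),
          "treatment history contains timestamps after 'now'")
  iob_from_events(ev$t, ev$units, profile, now)
}

# curve sums over impulse events (t, units); shared by compute_iob and the
# simulation engine's running event log
iob_from_events <- function(ev_t, ev_u, profile, now) {
  keep <- ev_t > now - profile$DIA & ev_t <= now
  if (!any(keep)) return(list(iob = 0, activity = 0))
  cv <- insulin_curve(now - ev_t[keep], profile$DIA, profile$peak)
  list(iob = sum(ev_u[keep] * cv$iob_fraction),
       activity = sum(ev_u[keep] * cv$activity_fraction))
}

activity_from_events <- function(ev_t, ev_u, profile, now, n_points = 47) {
  # events older than one DIA are fully decayed; the curve itself zeroes
  # contributions that expire mid-horizon
  keep <- ev_t > now - profile$DIA & ev_t <= now
  if (!any(keep)) return(numeric(n_points))
  tf <- now + 5 * seq_len(n_points)
  dtm <- outer(tf, ev_t[keep], "-")
  cv <- insulin_curve(as.vector(dtm), profile$DIA, profile$peak)
  mat <- matrix(cv$activity_fraction, nrow = n_points)
  as.vector(mat %*% ev_u[keep])
}

# Scheduled insulin activity (U/min) at now + 5, 10, ..., 5*n_points from the
# decay of everything already delivered. Feeds the prediction arrays.
activity_schedule <- function(history, profile, now, n_points = 47) {
  ev <- history_events(history, profile$basal, now)
  activity_from_events(ev$t, ev$units, profile, now, n_points)
}

#' Glucose status from recent CGM readings
#'
#' @param readings data.frame with columns `t` (min, 5-min grid) and `value`
#'   (mg/dl); the last row is the current reading. Only the last 9 readings
#'   (45 min) are used.
#' @return A `loop_glucose_status` list with `glucose`, `delta` (change over
#'   the last 5 min), `short_avgdelta` and `long_avgdelta` (mean per-5-min
#'   slopes against readings 2.5-17.5 and 17.5-47.5 min back).
#' @export
glucose_status <- function(readings) {
  stop_if(!is.data.frame(readings) || nrow(readings) < 2,
          "glucose status requires at least 2 CGM readings")
  readings <- utils::tail(readings[order(readings$t), ], 9)
  nR <- nrow(readings)
  now <- readings$t[nR]
  bg <- readings$value[nR]
  back <- now - readings$t[-nR]
  slope <- (bg - readings$value[-nR]) / (back / 5)
  short <- slope[back > 2.5 & back <= 17.5]
  long <- slope[back > 17.5 & back <= 47.5]
  structure(list(glucose = bg,
                 delta = bg - readings$value[nR - 1],
                 short_avgdelta = if (length(short)) mean(short) else 0,
                 long_avgdelta = if (length(long)) mean(long) else 0),
            class = "loop_glucose_status")
}

#' Unexplained glucose deviation
#'
#' The insulin-explained 5-min change is `BGI = -activity * ISF * 5`; the
#' deviation scales the unexplained remainder to a 30-min horizon:
#' `deviation = 6 * (delta - BGI)` (mg/dl per 30 min). Positive deviations
#' signal unannounced carbohydrates or insulin resistance.
#'
#' @param status a [glucose_status()].
#' @param iob result of [compute_iob()].
#' @param isf_eff effective insulin sensitivity, mg/dl per U.
#' @return Deviation, mg/dl per 30 min.
#' @export
compute_deviation <- function(status, iob, isf_eff) {
  bgi <- -iob$activity * isf_eff * 5
  (30 / 5) * (status$delta - bgi)
}

#' Carbs-on-board state
#'
#' @param carbs_entered,absorbed grams entered and already absorbed.
#' @param last_carb_time time of the latest carb entry, min (`NA` if none).
#' @return A `loop_meal` list; `COB = carbs_entered - absorbed`.
#' @export
meal_state <- function(carbs_entered = 0, absorbed = 0, last_carb_time = NA_real_) {
  stop_if(absorbed < 0 || absorbed > carbs_entered + 1e-9,
          "need 0 <= absorbed <= carbs_entered")
  structure(list(carbs_entered = carbs_entered, absorbed = absorbed,
                 last_carb_time = last_carb_time),
            class = "loop_meal")
}

#' @rdname meal_state
#' @param meal a `loop_meal`.
#' @export
cob <- function(meal) max(meal$carbs_entered - meal$absorbed, 0)

#' Register an announced carbohydrate entry
#' @param meal a [meal_state()].
#' @param grams carbohydrates, g.
#' @param t entry time, min.
#' @export
add_carbs <- function(meal, grams, t) {
  stop_if(grams < 0, "carb entry must be >= 0")
  meal_state(meal$carbs_entered + grams, meal$absorbed, t)
}

#' One 5-min carb-absorption step
#'
#' While carbs are on board, the grams absorbed in a 5-min step are
#' `max(deviation * 5/30, min_5m_carbimpact) / CSF` with carb sensitivity
#' `CSF = ISF / CR` (mg/dl per g); the minimum impact guarantees COB decays
#' even when observed deviations vanish.
#'
#' @param meal a [meal_state()].
#' @param deviation current deviation, mg/dl per 30 min.
#' @param profile a [therapy_profile()].
#' @return Updated `loop_meal`.
#' @export
update_meal <- function(meal, deviation, profile) {
  if (cob(meal) <= 0) return(meal)
  csf <- profile$ISF / profile$CR
  ci5 <- max(deviation * (5 / 30), profile$min_5m_carbimpact)
  absorbed_g <- min(ci5 / csf, cob(meal))
  meal_state(meal$carbs_entered, meal$absorbed + absorbed_g,
             meal$last_carb_time)
}

#' Autosensitivity ratio from recent deviations
#'
#' Deviations observed while no carbs were on board are averaged and scaled
#' to mg/dl per hour; the ratio `1 + D/(basal * ISF)` is clamped to
#' `[autosens_min, autosens_max]`. Ratios above 1 mean insulin resistance
#' (scale basal up, ISF down). With under one hour of usable history the
#' ratio is 1.
#'
#' @param deviations data.frame with columns `deviation` (mg/dl per 30 min)
#'   and `cob_active` (logical), one row per 5-min sample, covering up to the
#'   last 8 h.
#' @param profile a [therapy_profile()].
#' @return A list with `ratio`.
#' @export
autosens <- function(deviations, profile) {
  usable <- deviations$deviation[!deviations$cob_active]
  if (length(usable) < 12) return(list(ratio = 1))
  d_hour <- mean(usable) * 2           # per 30 min -> per hour
  ratio <- 1 + d_hour / (profile$basal * profile$ISF)
  list(ratio = clamp(ratio, profile$autosens_min, profile$autosens_max))
}

#' Glucose prediction arrays
#'
#' Builds the four oref-style 4-h forecasts on a 5-min grid (48 points, the
#' first being the current glucose): `IOBpred` propagates glucose using only
#' the decay of insulin already delivered; `ZTpred` additionally assumes a
#' zero-temp from now on; `COBpred` adds the impact of remaining carbs on
#' board absorbed at the [update_meal()] rate; `UAMpred` adds the current
#' deviation decaying linearly to zero over 60 min. All arrays are floored
#' at 39 mg/dl.
#'
#' @param status a [glucose_status()].
#' @param profile the (autosens-adjusted) [therapy_profile()].
#' @param future_activity scheduled insulin activity (U/min) at the next
#'   47 grid points, from [activity_schedule()] (length is recycled/truncated
#'   as needed).
#' @param meal a [meal_state()].
#' @param deviation current deviation, mg/dl per 30 min.
#' @return A list with the four arrays plus `eventualBG` (endpoint of the
#'   active blend: COB if carbs on board, else UAM if enabled and deviation
#'   positive, else IOB), `minPredBG` (minimum of the active blend) and
#'   `minGuardBG` (minimum over active blend and `ZTpred`).
#' @export
predict_glucose <- function(status, profile, future_activity = numeric(47),
                            meal = meal_state(), deviation = 0) {
  n <- 48
  nf <- n - 1
  act <- rep_len(future_activity, nf)
  bg0 <- status$glucose
  isf <- profile$ISF

  iob_pred <- c(bg0, bg0 - isf * 5 * cumsum(act))

  # zero-temp: future 5-min chunks of -basal/12 U at now, now+5, ...
  af5 <- insulin_curve(5 * seq_len(nf), profile$DIA, profile$peak)$activity_fraction
  zt_extra <- -(profile$basal / 12) * cumsum(af5)
  zt_pred <- c(bg0, bg0 - isf * 5 * cumsum(act + zt_extra))

  # carb impact: remaining COB absorbed at the meal-update rate
  csf <- isf / profile$CR
  ci5 <- max(deviation * (5 / 30), profile$min_5m_carbimpact)
  cob_rem <- cob(meal)
  impact <- numeric(nf)
  for (k in seq_len(nf)) {
    g <- min(ci5 / csf, cob_rem)
    impact[k] <- g * csf
    cob_rem <- cob_rem - g
    if (cob_rem <= 0) break
  }
  cob_pred <- iob_pred + c(0, cumsum(impact))

  # UAM: deviation decays linearly to 0 over 60 min (triangular area)
  uam_w <- pmax(0, 1 - (seq_len(nf) - 0.5) * 5 / 60)
  uam_pred <- iob_pred + c(0, cumsum(deviation * (5 / 30) * uam_w))

  iob_pred <- pmax(iob_pred, 39)
  zt_pred <- pmax(zt_pred, 39)
  cob_pred <- pmax(cob_pred, 39)
  uam_pred <- pmax(uam_pred, 39)

  blend <- if (cob(meal) > 0) cob_pred
           else if (profile$uam_enabled && deviation > 0) uam_pred
           else iob_pred
  list(IOBpred = iob_pred, COBpred = cob_pred, UAMpred = uam_pred,
       ZTpred = zt_pred,
       eventualBG = blend[n],
       minPredBG = min(blend),
       minGuardBG = min(c(blend, zt_pred)))
}

new_recommendation <- function(temp_rate, smb, eventualBG, reason,
                               temp_duration = 30) {
  structure(list(temp_rate = temp_rate, temp_duration = temp_duration,
                 smb = smb, eventualBG = eventualBG, reason = reason),
            class = "loop_recommendation")
}

#' @export
print.loop_recommendation <- function(x, ...) {
  cat(sprintf("<loop_recommendation> temp %.2f U/h x %d min, SMB %.2f U (eventualBG %.0f)\n  %s\n",
              x$temp_rate, as.integer(x$temp_duration), x$smb,
              x$eventualBG, x$reason))
  invisible(x)
}

#' Hybrid closed-loop dosing decision
#'
#' The oref-style decision tree: adjust the profile by the autosensitivity
#' ratio; suspend (zero-temp 30 min) when glucose or the guard prediction is
#' below the suspend threshold; low-temp toward target when the eventual
#' glucose is predicted below target; above target, dose the insulin required
#' to reach target (limited by the prediction minimum and the IOB cap),
#' either as a super micro bolus with a 30-min zero-temp or as a high temp.
#' The temp rate is always capped at `min(max_basal, 4 * basal')`.
#'
#' @param status a [glucose_status()].
#' @param iob result of [compute_iob()].
#' @param meal a [meal_state()].
#' @param autosens_ratio the [autosens()] ratio.
#' @param profile a [therapy_profile()].
#' @param future_activity scheduled activity for [predict_glucose()].
#' @param deviation current deviation, mg/dl per 30 min.
#' @return A `loop_recommendation` with `temp_rate` (U/h), `temp_duration`
#'   (min), `smb` (U), `eventualBG` and a human-readable `reason`.
#' @export
determine_basal <- function(status, iob, meal, autosens_ratio, profile,
                            future_activity = numeric(47), deviation = 0) {
  if (status$glucose < 39) {
    return(new_recommendation(profile$basal, 0, status$glucose,
                              "CGM reading invalid; neutral temp"))
  }
  ratio <- clamp(autosens_ratio, profile$autosens_min, profile$autosens_max)
  prof <- profile
  prof$ISF <- profile$ISF / ratio
  prof$basal <- profile$basal * ratio
  caps <- min(prof$max_basal, 4 * prof$basal)

  pred <- predict_glucose(status, prof, future_activity, meal, deviation)
  eBG <- pred$eventualBG

  if (status$glucose < prof$suspend_threshold ||
      pred$minGuardBG < prof$suspend_threshold) {
    return(new_recommendation(0, 0, eBG,
      sprintf("low glucose suspend (BG %.0f, minGuardBG %.0f < %g)",
              status$glucose, pred$minGuardBG, prof$suspend_threshold)))
  }

  if (eBG < prof$target) {
    insulin_req <- 2 * (eBG - prof$target) / prof$ISF
    rate <- clamp(prof$basal + 2 * insulin_req, 0, caps)
    return(new_recommendation(rate, 0, eBG,
      sprintf("eventualBG %.0f < target %g; low temp %.2f U/h",
              eBG, prof$target, rate)))
  }

  if (eBG > prof$target) {
    insulin_req <- (min(eBG, pred$minPredBG) - prof$target) / prof$ISF
    insulin_req <- min(insulin_req, prof$max_iob - iob$iob)
    if (prof$smb_enabled && insulin_req > 0) {
      smb <- quantize_insulin(min(insulin_req / 2,
                                  prof$basal * prof$maxSMBBasalMinutes / 60),
                              mode = "floor")
      # a delivered SMB is always paired with a zero-temp; if the required
      # microbolus floors to 0 U, fall through to the temp-basal branch so a
      # sub-grid insulin need is never answered by suspending basal
      if (smb > 0) {
        return(new_recommendation(0, smb, eBG,
          sprintf("eventualBG %.0f > target %g; SMB %.2f U with 30-min zero temp",
                  eBG, prof$target, smb)))
      }
    }
    rate <- clamp(prof$basal + 2 * insulin_req, 0, caps)
    return(new_recommendation(rate, 0, eBG,
      sprintf("eventualBG %.0f > target %g; temp %.2f U/h%s",
              eBG, prof$target, rate,
              if (insulin_req <= 0) " (IOB cap binding)" else "")))
  }

  new_recommendation(clamp(prof$basal, 0, caps), 0, eBG,
                     sprintf("eventualBG at target %g; neutral temp", prof$target))
}

#' Meal bolus under the half-bolus protocol
#'
#' The full bolus is `carbs / CR`; only half of it is delivered (no
#' glucose-correction term -- corrections are left to the closed loop), and
#' the result is floored to the 0.05 U pump grid.
#'
#' @param carbs announced carbohydrates, g.
#' @param profile a [therapy_profile()].
#' @return Delivered bolus, U.
#' @export
meal_bolus <- function(carbs, profile) {
  stop_if(carbs < 0, "carbs must be >= 0")
  quantize_insulin(0.5 * carbs / profile$CR, mode = "floor")
}
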