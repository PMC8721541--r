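#' CGM sensor model
#'
#' Adds first-order autoregressive measurement noise to the true plasma
#' glucose and clamps the reading to the 39-400 mg/dl sensor range:
#' \eqn{\epsilon_t = \phi \epsilon_{t-1} + e_t}, \eqn{e_t \sim N(0, \sigma^2)}.
#' Setting `sigma = 0` yields a deterministic pass-through sensor.
#'
#' @param G_true true glucose, mg/dl (> 0).
#' @param noise_state previous noise value \eqn{\epsilon_{t-1}} (0 at start).
#' @param phi AR(1) coefficient (default 0.7).
#' @param sigma innovation standard deviation, mg/dl (default 2).
#' @return A list with `value` (clamped reading, mg/dl) and `noise_state`
#'   (the new \eqn{\epsilon_t}, to be fed into the next call). Draws from the
#'   current R random stream.
#' @export
sample_cgm <- function(G_true, noise_state = 0, phi = 0.7, sigma = 2) {
  stop_if(!is_number(G_true) || G_true <= 0, "G_true must be > 0")
  eps <- phi * noise_state + if (sigma > 0) stats::rnorm(1, 0, sigma) else 0
  list(value = clamp(G_true + eps, 39, 400), noise_state = eps)
}

#' Insulin pump state
#'
#' @param scheduled_basal programmed basal rate, U/h.
#' @return A `loop_pump` list with the scheduled basal, the active temporary
#'   basal (or `NULL`) and the bolus queue.
#' @export
pump_state <- function(scheduled_basal) {
  stop_if(!is_number(scheduled_basal) || scheduled_basal < 0,
          "scheduled_basal must be >= 0")
  structure(list(scheduled_basal = scheduled_basal, temp = NULL,
                 boluses = data.frame(t = numeric(0), units = numeric(0))),
            class = "loop_pump")
}

#' Apply a controller recommendation to the pump
#'
#' The temp rate is quantized to the nearest 0.05 U/h, clamped to 0-10 U/h
#' and set for 30 min, replacing any active temp. An SMB is floored to the
#' 0.05 U grid and enqueued at `t` (an SMB of less than 0.05 U delivers
#' nothing).
#'
#' @param pump a [pump_state()].
#' @param rec a recommendation from [determine_basal()].
#' @param t current time, min.
#' @return The updated `loop_pump`.
#' @export
apply_recommendation <- function(pump, rec, t) {
  stop_if(rec$temp_rate < 0 || rec$smb < 0,
          "recommendation rates and boluses must be >= 0")
  rate <- clamp(quantize_insulin(rec$temp_rate, mode = "round"), 0, 10)
  pump$temp <- list(rate = rate, started = t, duration = 30)
  smb <- quantize_insulin(rec$smb, mode = "floor")
  if (smb > 0) {
    pump$boluses <- rbind(pump$boluses, data.frame(t = t, units = smb))
  }
  pump
}

#' Enqueue a manual bolus
#' @param pump a [pump_state()].
#' @param t delivery time, min.
#' @param units bolus size, U (floored to the 0.05 U grid).
#' @export
enqueue_bolus <- function(pump, t, units) {
  stop_if(units < 0, "bolus must be >= 0")
  units <- quantize_insulin(units, mode = "floor")
  if (units > 0) {
    pump$boluses <- rbind(pump$boluses, data.frame(t = t, units = units))
  }
  pump
}

# basal rate (U/h) the pump delivers at time t
pump_rate_at <- function(pump, t) {
  tp <- pump$temp
  if (!is.null(tp) && t >= tp$started && t < tp$started + tp$duration) {
    tp$rate
  } else {
    pump$scheduled_basal
  }
}

#' Insulin delivery at a time point
#'
#' The continuous component is the active (unexpired) temp rate, else the
#' scheduled basal, converted to U/min; any bolus queued exactly at `t` is
#' added as an impulse in U.
#'
#' @param pump a [pump_state()].
#' @param t time, min.
#' @return Delivery at `t`: `rate/60 + bolus impulse` (U/min plus impulse U).
#' @export
insulin_delivery_at <- function(pump, t) {
  stop_if(t < 0, "t must be >= 0")
  pump_rate_at(pump, t) / 60 + sum(pump$boluses$units[pump$boluses$t == t])
}
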