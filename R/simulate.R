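#' Run the closed loop for one virtual patient
#'
#' Drives the full loop on a 5-min controller grid over the scenario: sample
#' the CGM, fire a hypotreatment if the reading is below the threshold (and
#' outside the lockout), run the controller (IOB, COB, Autosens, prediction,
#' dosing decision), apply the recommendation to the pump, then integrate the
#' patient model at 1-min steps. Announced meals receive their half bolus
#' `bolus_lead_min` before intake and a controller carb entry at meal time;
#' hypotreatment carbs reach the plant but are not entered as controller
#' carbs. The run is a deterministic function of `(patient, scenario,
#' profile, seed, sensor settings)`.
#'
#' @param patient a [patient_params()].
#' @param scn a [scenario()].
#' @param prof a [therapy_profile()]; default [derive_therapy_profile()] of the
#'   patient.
#' @param seed integer seed for the sensor noise stream.
#' @param sensor_sigma,sensor_phi CGM noise parameters (see [sample_cgm()]);
#'   `sensor_sigma = 0` gives a fully deterministic run.
#' @return A `loop_sim` list: `true_bg` (per-min data.frame `t`, `G`), `cgm`
#'   (per-5-min `t`, `value`), `delivery` (per-5-min log with scheduled and
#'   effective basal, boluses, SMBs, carbs, HT flag), `events` (meals,
#'   boluses, SMBs, HTs), `controller` (per-invocation snapshot), plus the
#'   patient, profile, scenario and seed.
#' @export
run_closed_loop <- function(patient, scn = default_scenario(), prof = NULL,
                            seed = 1, sensor_sigma = 2, sensor_phi = 0.7) {
  validate_patient(patient)
  if (is.null(prof)) prof <- derive_therapy_profile(patient)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  T_end <- round(scn$duration_h * 60)
  n5 <- T_end %/% 5
  Ib <- basal_insulin(patient)
  x <- unname(init_steady_state(patient)[STATE_NAMES])

  # meal bookkeeping
  m_t <- scn$meal_times
  m_g <- scn$meals$grams
  m_ann <- scn$meals$announced
  b_t <- pmax(m_t - scn$bolus_lead_min, 0)          # bolus times (announced)
  b_u <- vapply(m_g, meal_bolus, 0, profile = prof)
  entered <- rep(FALSE, length(m_t))                # controller carb entries

  pump <- pump_state(prof$basal)
  # impulse event log for IOB accounting (boluses + basal deviations)
  ev_t <- numeric(0); ev_u <- numeric(0)

  cgm_v <- numeric(n5 + 1)
  true_g <- numeric(T_end + 1); true_g[1] <- x[1]
  dev_hist <- numeric(n5 + 1); cob_hist <- logical(n5 + 1); n_hist <- 0
  meal <- meal_state()
  eps <- 0
  last_ht <- -Inf

  # logs
  lg <- list(t = numeric(n5 + 1), scheduled = numeric(n5 + 1),
             rate = numeric(n5 + 1), bolus = numeric(n5 + 1),
             smb = numeric(n5 + 1), carbs = numeric(n5 + 1),
             ht = logical(n5 + 1))
  ctl <- list(t = numeric(0), glucose = numeric(0), delta = numeric(0),
              iob = numeric(0), cob = numeric(0), ratio = numeric(0),
              deviation = numeric(0), eventualBG = numeric(0),
              temp_rate = numeric(0), smb = numeric(0), reason = character(0))
  evl <- list(t = numeric(0), type = character(0), amount = numeric(0))
  log_event <- function(t, type, amount) {
    evl$t[length(evl$t) + 1] <<- t
    evl$type[length(evl$type) + 1] <<- type
    evl$amount[length(evl$amount) + 1] <<- amount
  }

  for (c5 in 0:n5) {
    t <- 5 * c5

    # --- CGM sample
    s <- sample_cgm(x[1], eps, sensor_phi, sensor_sigma)
    eps <- s$noise_state
    cgm_v[c5 + 1] <- s$value

    # --- hypotreatment rule (on the measured glucose)
    ht_now <- s$value < scn$ht_threshold && (t - last_ht) >= scn$ht_lockout_min
    if (ht_now) {
      last_ht <- t
      log_event(t, "ht", scn$ht_grams)
    }

    # --- controller invocation (needs >= 2 readings)
    smb_now <- 0
    if (c5 >= 1 && t < T_end) {
      idx <- max(1, c5 - 8):(c5 + 1)
      status <- glucose_status(data.frame(t = 5 * (idx - 1), value = cgm_v[idx]))
      iob_res <- iob_from_events(ev_t, ev_u, prof, t)
      deviation <- compute_deviation(status, iob_res, prof$ISF)

      due <- which(!entered & m_ann & m_t <= t)
      for (i in due) {
        meal <- add_carbs(meal, m_g[i], m_t[i])
        entered[i] <- TRUE
      }
      meal <- update_meal(meal, deviation, prof)

      n_hist <- n_hist + 1
      dev_hist[n_hist] <- deviation
      cob_hist[n_hist] <- cob(meal) > 0
      win <- max(1, n_hist - 95):n_hist
      ratio <- autosens(data.frame(deviation = dev_hist[win],
                                   cob_active = cob_hist[win]), prof)$ratio

      fut <- activity_from_events(ev_t, ev_u, prof, t, 47)
      rec <- determine_basal(status, iob_res, meal, ratio, prof, fut, deviation)
      pump <- apply_recommendation(pump, rec, t)
      smb_now <- quantize_insulin(rec$smb, mode = "floor")
      if (smb_now > 0) {
        ev_t <- c(ev_t, t); ev_u <- c(ev_u, smb_now)
        log_event(t, "smb", smb_now)
      }
      k <- length(ctl$t) + 1
      ctl$t[k] <- t; ctl$glucose[k] <- status$glucose
      ctl$delta[k] <- status$delta; ctl$iob[k] <- iob_res$iob
      ctl$cob[k] <- cob(meal); ctl$ratio[k] <- ratio
      ctl$deviation[k] <- deviation; ctl$eventualBG[k] <- rec$eventualBG
      ctl$temp_rate[k] <- rec$temp_rate; ctl$smb[k] <- rec$smb
      ctl$reason[k] <- rec$reason
    }

    # --- manual (meal) boluses due at this grid point
    bolus_now <- 0
    for (i in which(m_ann & b_t == t)) {
      pump <- enqueue_bolus(pump, t, b_u[i])
      if (b_u[i] > 0) {
        ev_t <- c(ev_t, t); ev_u <- c(ev_u, b_u[i])
        bolus_now <- bolus_now + b_u[i]
        log_event(t, "bolus", b_u[i])
      }
    }

    # --- effective basal over [t, t+5) and its IOB deviation chunk
    eff <- pump_rate_at(pump, t)
    if (t < T_end && abs(eff - prof$basal) > 1e-12) {
      ev_t <- c(ev_t, t); ev_u <- c(ev_u, (eff - prof$basal) * 5 / 60)
    }

    carbs_win <- 0
    if (t < T_end) {
      hit <- which(m_t >= t & m_t < t + 5)
      carbs_win <- sum(m_g[hit])
    }
    lg$t[c5 + 1] <- t; lg$scheduled[c5 + 1] <- prof$basal
    lg$rate[c5 + 1] <- eff; lg$bolus[c5 + 1] <- bolus_now
    lg$smb[c5 + 1] <- smb_now; lg$carbs[c5 + 1] <- carbs_win
    lg$ht[c5 + 1] <- ht_now

    # --- integrate the plant over [t, t+5) at 1-min RK4 steps
    if (t < T_end) {
      if (ht_now) x[6] <- x[6] + scn$ht_grams * 1000
      if (bolus_now > 0) x[4] <- x[4] + bolus_now
      if (smb_now > 0) x[4] <- x[4] + smb_now
      u <- eff / 60
      for (m in t:(t + 4)) {
        hit <- which(m_t >= m & m_t < m + 1)
        if (length(hit)) {
          x[6] <- x[6] + sum(m_g[hit]) * 1000
          for (i in hit) log_event(m_t[i], "meal", m_g[i])
        }
        x <- rk4_step(x, patient, 1, u, 0, Ib)
        if (any(!is.finite(x))) {
          stop("closed-loop integration diverged for patient '", patient$id,
               "' near t = ", m, " min", call. = FALSE)
        }
        true_g[m + 2] <- x[1]
      }
    }
  }

  structure(list(
    id = patient$id, patient = patient, profile = prof, scenario = scn,
    seed = as.integer(seed), sensor_sigma = sensor_sigma,
    sensor_phi = sensor_phi,
    true_bg = data.frame(t = 0:T_end, G = true_g),
    cgm = data.frame(t = 5 * (0:n5), value = cgm_v),
    delivery = data.frame(t = lg$t, scheduled_basal = lg$scheduled,
                          effective_rate = lg$rate, bolus = lg$bolus,
                          smb = lg$smb, carbs = lg$carbs, ht = lg$ht),
    events = data.frame(t = evl$t, type = evl$type, amount = evl$amount),
    controller = as.data.frame(ctl)),
    class = "loop_sim")
}

#' @export
print.loop_sim <- function(x, ...) {
  ht <- sum(x$events$type == "ht")
  cat(sprintf("<loop_sim> patient %s, %g h (seed %d)\n", x$id,
              x$scenario$duration_h, x$seed))
  cat(sprintf("  BG mean %.1f mg/dl [%.1f, %.1f]; insulin %.1f U; HTs %d\n",
              mean(x$cgm$value), min(x$cgm$value), max(x$cgm$value),
              total_insulin(x), ht))
  invisible(x)
}

# total insulin delivered over the run, U (rate integral + boluses)
total_insulin <- function(sim) {
  d <- sim$delivery
  n <- nrow(d)
  sum(d$effective_rate[-n] * 5 / 60) + sum(d$bolus) + sum(d$smb)
}

#' Run the closed loop over a cohort
#'
#' Per-patient sensor seeds are derived deterministically from the master
#' seed before any work is dispatched, so results are identical for any
#' worker count or completion order. A failing patient is reported as a
#' `loop_sim_error` element without aborting the rest of the cohort.
#'
#' @param cohort a [generate_cohort()] result (or list of patients).
#' @param scn a [scenario()].
#' @param master_seed integer master seed.
#' @param workers number of parallel workers (forked; serial fallback where
#'   forking is unavailable).
#' @param sensor_sigma,sensor_phi CGM noise settings passed to each run.
#' @param profiles optional named list of [therapy_profile()] objects per patient id.
#' @return A `loop_trial`: list of `loop_sim` named by patient id.
#' @export
run_cohort <- function(cohort, scn = default_scenario(), master_seed = 1,
                       workers = 1, sensor_sigma = 2, sensor_phi = 0.7,
                       profiles = NULL) {
  stop_if(length(cohort) < 1, "cohort is empty")
  ids <- vapply(cohort, `[[`, "", "id")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, length(cohort))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  one <- function(i) {
    tryCatch({
      pr <- if (!is.null(profiles)) profiles[[ids[i]]]
      run_closed_loop(cohort[[i]], scn, pr, seed = seeds[i],
                      sensor_sigma = sensor_sigma, sensor_phi = sensor_phi)
    }, error = function(e) {
      structure(list(id = ids[i], message = conditionMessage(e)),
                class = "loop_sim_error")
    })
  }
  workers <- max(1L, as.integer(workers))
  res <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(cohort), one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_along(cohort), one)
  }
  names(res) <- ids
  failed <- vapply(res, inherits, TRUE, "loop_sim_error")
  if (any(failed)) {
    warning(sum(failed), " patient run(s) failed: ",
            paste(ids[failed], collapse = ", "), call. = FALSE)
  }
  structure(res, master_seed = as.integer(master_seed), seeds = seeds,
            class = "loop_trial")
}

#' @export
print.loop_trial <- function(x, ...) {
  ok <- !vapply(x, inherits, TRUE, "loop_sim_error")
  cat(sprintf("<loop_trial> %d patients (%d ok), master seed %d\n",
              length(x), sum(ok), attr(x, "master_seed")))
  invisible(x)
}
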