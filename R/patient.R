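#' Virtual type 1 diabetes patient parameters
#'
#' Constructs and validates the metabolic parameter set of one virtual
#' patient. The plant is a minimal-model glucose-insulin system extended with
#' two-compartment subcutaneous insulin absorption and two-compartment gut
#' carbohydrate absorption:
#' \deqn{dS_1/dt = u - S_1/\tau_i, \quad dS_2/dt = (S_1 - S_2)/\tau_i}
#' \deqn{dI/dt = -n I + S_2 \cdot 10^6 / (\tau_i V_I BW)}
#' \deqn{dX/dt = -p_2 X + p_3 (I - I_b)}
#' \deqn{dQ_1/dt = d - Q_1/\tau_m, \quad dQ_2/dt = (Q_1 - Q_2)/\tau_m}
#' \deqn{dG/dt = -p_1 (G - G_b) - X G + f_{bio} Q_2 / (\tau_m V_G BW)}
#' with insulin infusion `u` (U/min) and carbohydrate ingestion `d` (mg/min).
#'
#' @param id character patient identifier.
#' @param age_group one of `"child"`, `"adolescent"`, `"adult"`.
#' @param BW body weight, kg.
#' @param Gb fasting glucose setpoint, mg/dl (90-160).
#' @param p1 glucose effectiveness, 1/min.
#' @param p2 insulin action decay rate, 1/min.
#' @param p3 insulin action gain, ml/uU/min^2.
#' @param n plasma insulin clearance rate, 1/min.
#' @param tau_i subcutaneous insulin absorption time constant, min.
#' @param tau_m gut carbohydrate absorption time constant, min.
#' @param f_bio carbohydrate bioavailability, fraction in (0, 1].
#' @param V_G glucose distribution volume, dl/kg.
#' @param V_I insulin distribution volume, ml/kg.
#' @param basal_ref reference basal insulin rate, U/h.
#' @return An object of class `loop_patient` (a named list).
#' @seealso [generate_cohort()], [init_steady_state()], [derive_therapy_profile()]
#' @export
patient_params <- function(id, age_group = c("adult", "adolescent", "child"),
                           BW, Gb, p1, p2, p3, n, tau_i, tau_m,
                           f_bio, V_G, V_I, basal_ref) {
  age_group <- match.arg(age_group)
  p <- list(id = as.character(id), age_group = age_group,
            BW = BW, Gb = Gb, p1 = p1, p2 = p2, p3 = p3, n = n,
            tau_i = tau_i, tau_m = tau_m, f_bio = f_bio,
            V_G = V_G, V_I = V_I, basal_ref = basal_ref)
  class(p) <- "loop_patient"
  validate_patient(p)
  p
}

validate_patient <- function(p) {
  num <- c("BW", "Gb", "p1", "p2", "p3", "n", "tau_i", "tau_m",
           "f_bio", "V_G", "V_I", "basal_ref")
  for (f in num) {
    stop_if(!is_number(p[[f]]), "patient '", p$id, "': field '", f,
            "' must be a finite number")
  }
  pos <- c("BW", "Gb", "p1", "p2", "p3", "n", "tau_i", "tau_m", "V_G", "V_I")
  for (f in pos) {
    stop_if(p[[f]] <= 0, "patient '", p$id, "': field '", f,
            "' must be strictly positive")
  }
  stop_if(p$basal_ref < 0, "patient '", p$id, "': basal_ref must be >= 0")
  stop_if(p$f_bio <= 0 || p$f_bio > 1,
          "patient '", p$id, "': f_bio must be in (0, 1]")
  stop_if(p$Gb < 90 || p$Gb > 160,
          "patient '", p$id, "': Gb must lie in [90, 160] mg/dl")
  invisible(p)
}

#' @export
print.loop_patient <- function(x, ...) {
  cat(sprintf("<loop_patient> %s (%s)\n", x$id, x$age_group))
  cat(sprintf("  BW %.1f kg, Gb %.1f mg/dl, basal_ref %.2f U/h\n",
              x$BW, x$Gb, x$basal_ref))
  cat(sprintf("  p1 %.4f, p2 %.4f, p3 %.3g, n %.3f (1/min); SI %.3g ml/uU/min\n",
              x$p1, x$p2, x$p3, x$n, x$p3 / x$p2))
  cat(sprintf("  tau_i %.0f min, tau_m %.0f min, f_bio %.2f, V_G %.2f dl/kg, V_I %.0f ml/kg\n",
              x$tau_i, x$tau_m, x$f_bio, x$V_G, x$V_I))
  invisible(x)
}

# state vector layout used throughout the integrator
STATE_NAMES <- c("G", "X", "I", "S1", "S2", "Q1", "Q2")

#' Basal plasma insulin implied by the reference basal rate
#'
#' Closed form \eqn{I_b = basal_{ref} \cdot 10^6 / (60 n V_I BW)} in uU/ml:
#' the plasma insulin concentration at which a constant subcutaneous infusion
#' of `basal_ref` U/h is exactly cleared.
#'
#' @param params a `loop_patient`.
#' @return Basal insulin concentration, uU/ml.
#' @export
basal_insulin <- function(params) {
  params$basal_ref * 1e6 / (60 * params$n * params$V_I * params$BW)
}

#' Time derivatives of the virtual patient state
#'
#' @param state named numeric vector with elements `G` (mg/dl), `X` (1/min),
#'   `I` (uU/ml), `S1`, `S2` (U), `Q1`, `Q2` (mg). See [patient_params()] for
#'   the equations.
#' @param params a `loop_patient`.
#' @param u insulin infusion rate, U/min (>= 0).
#' @param d carbohydrate ingestion rate, mg/min (>= 0).
#' @return Named numeric vector of the seven time derivatives.
#' @export
metabolic_derivatives <- function(state, params, u = 0, d = 0) {
  stop_if(any(!is.finite(state)), "non-finite patient state")
  stop_if(!is_number(u) || u < 0, "insulin infusion u must be >= 0")
  stop_if(!is_number(d) || d < 0, "carb ingestion d must be >= 0")
  stop_if(state[["G"]] <= 0, "plasma glucose must be positive")
  Ib <- basal_insulin(params)
  dot_metabolic(unname(state[STATE_NAMES]), params, u, d, Ib)
}

# fast internal derivative: x = c(G, X, I, S1, S2, Q1, Q2), no validation
dot_metabolic <- function(x, p, u, d, Ib) {
  Ra <- p$f_bio * x[7] / p$tau_m                      # mg/min
  c(G  = -p$p1 * (x[1] - p$Gb) - x[2] * x[1] + Ra / (p$V_G * p$BW),
    X  = -p$p2 * x[2] + p$p3 * (x[3] - Ib),
    I  = -p$n * x[3] + x[5] * 1e6 / (p$tau_i * p$V_I * p$BW),
    S1 = u - x[4] / p$tau_i,
    S2 = (x[4] - x[5]) / p$tau_i,
    Q1 = d - x[6] / p$tau_m,
    Q2 = (x[6] - x[7]) / p$tau_m)
}

#' Advance the patient state by one time step (fixed-step RK4)
#'
#' Inputs `u` and `d` are held constant over the step. Nonnegative
#' compartments are clamped at zero after the step and glucose is floored at
#' 1 mg/dl; boluses and rescue carbohydrates are applied as impulses on the
#' compartments at step boundaries, not through `u`/`d`.
#'
#' @inheritParams metabolic_derivatives
#' @param dt step length, min.
#' @return The advanced named state vector.
#' @export
integrate_step <- function(state, params, dt, u = 0, d = 0) {
  stop_if(!is_number(dt) || dt <= 0, "dt must be > 0")
  Ib <- basal_insulin(params)
  x <- unname(state[STATE_NAMES])
  x2 <- rk4_step(x, params, dt, u, d, Ib)
  if (any(!is.finite(x2))) {
    stop("integration produced non-finite values for patient '", params$id,
         "' near t = ", if ("t" %in% names(state)) state[["t"]] else NA,
         call. = FALSE)
  }
  out <- stats::setNames(x2, STATE_NAMES)
  if (!is.null(names(state)) && "t" %in% names(state)) {
    out <- c(t = unname(state[["t"]]) + dt, out)
  }
  out
}

rk4_step <- function(x, p, dt, u, d, Ib) {
  k1 <- dot_metabolic(x, p, u, d, Ib)
  k2 <- dot_metabolic(x + dt / 2 * k1, p, u, d, Ib)
  k3 <- dot_metabolic(x + dt / 2 * k2, p, u, d, Ib)
  k4 <- dot_metabolic(x + dt * k3, p, u, d, Ib)
  x2 <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  # physical bounds: compartments nonnegative, glucose floored
  x2[3:7] <- pmax(x2[3:7], 0)
  x2[1] <- max(x2[1], 1)
  x2
}

#' Equilibrium state of a virtual patient under basal insulin
#'
#' @param params a `loop_patient`.
#' @return Named state vector at the unique basal equilibrium: `G = Gb`,
#'   `X = 0`, `I = Ib`, `S1 = S2 = tau_i * basal_ref / 60`, `Q1 = Q2 = 0`,
#'   with `t = 0`.
#' @export
init_steady_state <- function(params) {
  validate_patient(params)
  u_b <- params$basal_ref / 60
  c(t = 0, G = params$Gb, X = 0, I = basal_insulin(params),
    S1 = params$tau_i * u_b, S2 = params$tau_i * u_b, Q1 = 0, Q2 = 0)
}

# Open-loop simulation at constant basal with optional meal impulses;
# used by the cohort plausibility filter and by tests.
# meals: data.frame(t, grams). Returns data.frame(t, G).
simulate_open_loop <- function(params, hours = 8, basal = params$basal_ref,
                               meals = NULL, dt = 1) {
  x <- init_steady_state(params)[STATE_NAMES]
  x <- unname(x)
  Ib <- basal_insulin(params)
  u <- basal / 60
  n_step <- round(hours * 60 / dt)
  G <- numeric(n_step + 1)
  G[1] <- x[1]
  tt <- seq(0, by = dt, length.out = n_step + 1)
  meal_t <- if (is.null(meals)) numeric(0) else meals$t
  for (k in seq_len(n_step)) {
    t0 <- tt[k]
    hit <- which(meal_t >= t0 & meal_t < t0 + dt)
    if (length(hit)) x[6] <- x[6] + sum(meals$grams[hit]) * 1000
    x <- rk4_step(x, params, dt, u, 0, Ib)
    G[k + 1] <- x[1]
  }
  data.frame(t = tt, G = G)
}

# Parameter sampling ranges per age group (framework defaults).
cohort_ranges <- function(age_group) {
  BW <- switch(age_group, child = c(20, 50), adolescent = c(45, 75),
               adult = c(60, 100))
  basal <- switch(age_group, child = c(0.4, 0.7), adolescent = c(0.7, 1.2),
                  adult = c(0.8, 1.4))
  list(BW = BW, Gb = c(110, 140), p1 = c(0.003, 0.010), p2 = c(0.01, 0.04),
       SI = c(2e-4, 8e-4), n = c(0.10, 0.20), tau_i = c(50, 70),
       tau_m = c(30, 60), f_bio = c(0.80, 0.95), V_G = c(1.4, 1.8),
       V_I = c(100, 140), basal_ref = basal)
}

draw_patient <- function(id, age_group) {
  r <- cohort_ranges(age_group)
  runif1 <- function(rg) stats::runif(1, rg[1], rg[2])
  p2 <- runif1(r$p2)
  # insulin sensitivity SI = p3/p2 is log-uniform; p3 follows
  SI <- exp(stats::runif(1, log(r$SI[1]), log(r$SI[2])))
  patient_params(id = id, age_group = age_group,
                 BW = runif1(r$BW), Gb = runif1(r$Gb), p1 = runif1(r$p1),
                 p2 = p2, p3 = SI * p2, n = runif1(r$n),
                 tau_i = runif1(r$tau_i), tau_m = runif1(r$tau_m),
                 f_bio = runif1(r$f_bio), V_G = runif1(r$V_G),
                 V_I = runif1(r$V_I), basal_ref = runif1(r$basal_ref))
}

# open-loop peak excursion above Gb after a meal, mg/dl; the default probe
# is weight-scaled (50 g at the 70 kg reference, ~0.7 g/kg) so that the
# plausibility band tests metabolism rather than body size
meal_excursion <- function(params, grams = 50 * params$BW / 70, hours = 8) {
  tr <- simulate_open_loop(params, hours = hours,
                           meals = data.frame(t = 0, grams = grams))
  max(tr$G) - params$Gb
}

#' Generate a reproducible virtual patient cohort
#'
#' Draws `n_per_group` patients per age group (children 2-12, adolescents
#' 13-18, adults) with parameters sampled independently and uniformly from
#' age-group ranges (insulin sensitivity log-uniformly). Candidates whose
#' open-loop peak excursion after a 50 g meal falls outside 30-200 mg/dl are
#' rejected and redrawn (at most 100 redraws each), which keeps the cohort
#' clinically plausible without hand-tuning. The probe meal is scaled with
#' body weight (50 g at a 70 kg reference, about 0.7 g/kg) because the
#' glucose rise per gram scales inversely with the distribution volume
#' `V_G * BW`; a fixed adult-sized probe would reject essentially every
#' small child on body size alone rather than on implausible metabolism.
#'
#' @param n_per_group patients per age group (default 10, i.e. a 30-patient
#'   cohort).
#' @param seed integer seed; the cohort is a deterministic function of it.
#' @return A list of `loop_patient` objects (class `loop_cohort`), ids of the
#'   form `"adult-01"`.
#' @export
generate_cohort <- function(n_per_group = 10, seed = 1) {
  stop_if(!is_number(n_per_group) || n_per_group < 1,
          "n_per_group must be >= 1")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  groups <- c("child", "adolescent", "adult")
  cohort <- list()
  for (g in groups) {
    for (i in seq_len(n_per_group)) {
      id <- sprintf("%s-%02d", g, i)
      ok <- FALSE
      for (try in seq_len(101L)) {
        cand <- draw_patient(id, g)
        exc <- meal_excursion(cand)
        if (exc >= 30 && exc <= 200) { ok <- TRUE; break }
      }
      stop_if(!ok, "could not draw a plausible '", g,
              "' patient within 100 redraws")
      cohort[[id]] <- cand
    }
  }
  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "n_per_group") <- as.integer(n_per_group)
  class(cohort) <- "loop_cohort"
  cohort
}

#' @export
print.loop_cohort <- function(x, ...) {
  tab <- table(vapply(x, `[[`, "", "age_group"))
  cat(sprintf("<loop_cohort> %d patients (seed %d): %s\n", length(x),
              attr(x, "seed"),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Cohort parameter table
#'
#' @param cohort a `loop_cohort` (or plain list of `loop_patient`).
#' @return A data.frame with one row per patient and one column per parameter.
#' @export
cohort_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(p[c("id", "age_group", "BW", "Gb", "p1", "p2", "p3", "n",
                   "tau_i", "tau_m", "f_bio", "V_G", "V_I", "basal_ref")],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Derive the therapy profile a controller sees from plant parameters
#'
#' Total daily dose is taken as `TDD = 24 * basal_ref / 0.5` (basal assumed
#' half of TDD); the 1800 rule gives ISF and the 500 rule gives the carb
#' ratio. Safety caps follow the trial protocol: maximum basal 10 U/h and
#' maximum IOB 10 U.
#'
#' @param params a `loop_patient`.
#' @param target controller glucose target, mg/dl (default 100).
#' @param smb_enabled,uam_enabled feature switches (default on).
#' @return A `loop_profile` list with fields `ISF` (mg/dl/U), `CR` (g/U),
#'   `DIA` (min), `peak` (min), `target`, `basal` (U/h), `max_basal`,
#'   `max_iob`, `smb_enabled`, `uam_enabled`, `autosens_min`, `autosens_max`,
#'   `maxSMBBasalMinutes`, `min_5m_carbimpact`, `suspend_threshold`.
#' @export
derive_therapy_profile <- function(params, target = 100,
                                   smb_enabled = TRUE, uam_enabled = TRUE) {
  stop_if(params$basal_ref <= 0, "basal_ref must be > 0 to derive a profile")
  TDD <- 24 * params$basal_ref / 0.5
  therapy_profile(ISF = 1800 / TDD, CR = 500 / TDD, DIA = 300, peak = 75,
          target = target, basal = params$basal_ref,
          smb_enabled = smb_enabled, uam_enabled = uam_enabled)
}

#' Construct a controller therapy profile
#'
#' @param ISF insulin sensitivity factor, mg/dl per U.
#' @param CR carb ratio, g per U.
#' @param DIA duration of insulin activity, min.
#' @param peak insulin activity peak time, min (must satisfy `2*peak < DIA`).
#' @param target controller glucose target, mg/dl.
#' @param basal scheduled basal rate, U/h.
#' @param max_basal maximum temporary basal rate, U/h.
#' @param max_iob maximum insulin on board the controller may accumulate, U.
#' @param smb_enabled,uam_enabled enable super micro boluses / unannounced
#'   meal detection.
#' @param autosens_min,autosens_max bounds of the autosensitivity ratio.
#' @param maxSMBBasalMinutes cap of one SMB in minutes of basal.
#' @param min_5m_carbimpact minimum assumed carb impact, mg/dl per 5 min.
#' @param suspend_threshold low-glucose suspend threshold, mg/dl.
#' @return A `loop_profile` list.
#' @export
therapy_profile <- function(ISF, CR, DIA = 300, peak = 75, target = 100, basal = 1,
                    max_basal = 10, max_iob = 10,
                    smb_enabled = TRUE, uam_enabled = TRUE,
                    autosens_min = 0.7, autosens_max = 1.2,
                    maxSMBBasalMinutes = 30, min_5m_carbimpact = 8,
                    suspend_threshold = 65) {
  p <- list(ISF = ISF, CR = CR, DIA = DIA, peak = peak, target = target,
            basal = basal, max_basal = max_basal, max_iob = max_iob,
            smb_enabled = isTRUE(smb_enabled), uam_enabled = isTRUE(uam_enabled),
            autosens_min = autosens_min, autosens_max = autosens_max,
            maxSMBBasalMinutes = maxSMBBasalMinutes,
            min_5m_carbimpact = min_5m_carbimpact,
            suspend_threshold = suspend_threshold)
  for (f in c("ISF", "CR", "DIA", "basal")) {
    stop_if(!is_number(p[[f]]) || p[[f]] <= 0, "profile field '", f,
            "' must be > 0")
  }
  stop_if(!(autosens_min > 0 && autosens_min <= 1 && autosens_max >= 1),
          "need 0 < autosens_min <= 1 <= autosens_max")
  stop_if(2 * peak >= DIA, "insulin curve requires 2*peak < DIA")
  class(p) <- "loop_profile"
  p
}

#' @export
print.loop_profile <- function(x, ...) {
  cat(sprintf("<loop_profile> ISF %.1f mg/dl/U, CR %.2f g/U, basal %.2f U/h\n",
              x$ISF, x$CR, x$basal))
  cat(sprintf("  DIA %d min (peak %d), target %g mg/dl, caps %g U/h / %g U IOB\n",
              as.integer(x$DIA), as.integer(x$peak), x$target,
              x$max_basal, x$max_iob))
  cat(sprintf("  SMB %s, UAM %s, autosens [%g, %g], suspend < %g mg/dl\n",
              if (x$smb_enabled) "on" else "off",
              if (x$uam_enabled) "on" else "off",
              x$autosens_min, x$autosens_max, x$suspend_threshold))
  invisible(x)
}
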