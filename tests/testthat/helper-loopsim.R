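# Shared fixtures, built in code. Heavy objects are cached per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# one mid-range adult with round numbers
test_patient <- function(...) {
  args <- list(id = "test-adult", age_group = "adult", BW = 75, Gb = 120,
               p1 = 0.006, p2 = 0.02, p3 = 8e-6, n = 0.15, tau_i = 60,
               tau_m = 45, f_bio = 0.9, V_G = 1.6, V_I = 120, basal_ref = 1.0)
  args[names(list(...))] <- list(...)
  do.call(patient_params, args)
}

test_profile <- function(...) {
  args <- list(ISF = 40, CR = 10, basal = 1)
  args[names(list(...))] <- list(...)
  do.call(therapy_profile, args)
}

# the standard 30-patient cohort used by the heavier suites
std_cohort <- function() fixture("cohort", function() generate_cohort(10, seed = 1))

# scenario with no meals (closed-loop quiescence runs)
no_meal_scenario <- function() {
  scenario(meals = data.frame(day = integer(0), time = character(0),
                              grams = numeric(0), announced = logical(0)))
}

# short single-day scenario for fast integration tests
short_scenario <- function(duration_h = 12,
                           meals = data.frame(day = 1, time = "07:00",
                                              grams = 40, announced = TRUE)) {
  scenario(duration_h = duration_h, meals = meals)
}

# open-loop state stepper built on the public API
step_hours <- function(state, params, hours, u = 0, d = 0, dt = 1) {
  for (i in seq_len(round(hours * 60 / dt))) {
    state <- integrate_step(state, params, dt, u, d)
  }
  state
}
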