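test_that("IOB is zero for empty or fully decayed histories", {
  pr <- test_profile()
  expect_equal(compute_iob(treatment_history(), pr, 100),
               list(iob = 0, activity = 0))
  h <- treatment_history(boluses = data.frame(t = 0, units = 1))
  expect_equal(compute_iob(h, pr, 300)$iob, 0)
  expect_error(compute_iob(h, pr, now = -10), "after")
})

test_that("IOB is additive over histories and matches the curve directly", {
  pr <- test_profile()
  h1 <- treatment_history(boluses = data.frame(t = 30, units = 1))
  h2 <- treatment_history(boluses = data.frame(t = 90, units = 2.5))
  h12 <- treatment_history(boluses = data.frame(t = c(30, 90),
                                                units = c(1, 2.5)))
  r1 <- compute_iob(h1, pr, 120)
  r2 <- compute_iob(h2, pr, 120)
  r12 <- compute_iob(h12, pr, 120)
  expect_equal(r12$iob, r1$iob + r2$iob, tolerance = 1e-12)
  expect_equal(r12$activity, r1$activity + r2$activity, tolerance = 1e-12)
  # single-bolus result equals the raw curve evaluation
  cv <- insulin_curve(90, pr$DIA, pr$peak)
  expect_equal(r1$iob, cv$iob_fraction)
  expect_equal(r1$activity, cv$activity_fraction)
})

test_that("temp basals contribute as 5-min deviation chunks", {
  pr <- test_profile(basal = 1)
  # 30 min of 3 U/h vs scheduled 1 U/h = 6 chunks of 2/12 U
  h <- treatment_history(temps = data.frame(start = 0, duration = 30, rate = 3))
  r <- compute_iob(h, pr, 60)
  chunks <- insulin_curve(60 - seq(0, 25, by = 5), pr$DIA, pr$peak)
  expect_equal(r$iob, sum((2 * 5 / 60) * chunks$iob_fraction),
               tolerance = 1e-12)
  # a zero-temp yields negative IOB relative to schedule
  hz <- treatment_history(temps = data.frame(start = 0, duration = 30, rate = 0))
  expect_lt(compute_iob(hz, pr, 60)$iob, 0)
})

test_that("glucose status reports deltas from the CGM window", {
  flat <- data.frame(t = seq(0, 40, 5), value = 120)
  st <- glucose_status(flat)
  expect_equal(st$glucose, 120)
  expect_equal(st$delta, 0)
  expect_equal(st$short_avgdelta, 0)
  expect_equal(st$long_avgdelta, 0)

  ramp <- data.frame(t = seq(0, 40, 5), value = 100 + seq(0, 40, 5))
  str <- glucose_status(ramp)
  expect_equal(str$delta, 5)
  expect_equal(str$short_avgdelta, 5)
  expect_equal(str$long_avgdelta, 5)

  expect_error(glucose_status(data.frame(t = 0, value = 100)), "at least 2")
})

test_that("deviation isolates the glucose change insulin cannot explain", {
  st <- structure(list(glucose = 120, delta = 2, short_avgdelta = 2,
                       long_avgdelta = 2), class = "loop_glucose_status")
  expect_equal(compute_deviation(st, list(iob = 0, activity = 0), 40), 12)
  # delta exactly equal to BGI -> zero deviation
  st$delta <- -2
  expect_equal(compute_deviation(st, list(iob = 1, activity = 0.01), 40), 0)
})

test_that("carb absorption follows the minimum-impact rule and floors at 0", {
  pr <- test_profile(ISF = 40, CR = 10, min_5m_carbimpact = 8)  # CSF = 4
  m <- add_carbs(meal_state(), 60, 0)
  m1 <- update_meal(m, deviation = 0, pr)
  expect_equal(m1$absorbed, 2)                 # 8 / 4 g per 5 min
  expect_equal(cob(m1), 58)
  # zero-COB state is untouched
  m0 <- meal_state()
  expect_identical(update_meal(m0, 50, pr), m0)
  # with zero deviations a 60 g entry empties within 150 min (30 steps)
  mm <- m
  steps <- 0
  while (cob(mm) > 0 && steps < 100) {
    mm <- update_meal(mm, 0, pr)
    steps <- steps + 1
  }
  expect_lte(steps, 30)
  # positive deviation absorbs faster, never below zero COB
  mf <- update_meal(add_carbs(meal_state(), 1, 0), deviation = 600, pr)
  expect_equal(cob(mf), 0)
  expect_equal(mf$absorbed, 1)
})

test_that("autosens ratio is centered, bounded and needs an hour of data", {
  pr <- test_profile(ISF = 40, basal = 1)
  mkhist <- function(dev, n = 60, cobf = FALSE) {
    data.frame(deviation = rep(dev, n), cob_active = rep(cobf, n))
  }
  expect_equal(autosens(mkhist(0), pr)$ratio, 1)
  expect_equal(autosens(mkhist(1000), pr)$ratio, 1.2)
  expect_equal(autosens(mkhist(-1000), pr)$ratio, 0.7)
  # under 12 usable samples -> neutral
  expect_equal(autosens(mkhist(1000, n = 5), pr)$ratio, 1)
  expect_equal(autosens(mkhist(1000, n = 60, cobf = TRUE), pr)$ratio, 1)
  # linear region: D = 2 mg/dl/30min -> 4 mg/dl/h over basal*ISF = 40
  expect_equal(autosens(mkhist(2), pr)$ratio, 1 + 4 / 40)
  expect_equal(autosens(mkhist(10), pr)$ratio, 1.2)  # 1.5 unclamped
})

test_that("prediction arrays are flat without insulin, carbs or deviation", {
  pr <- test_profile()
  st <- structure(list(glucose = 140, delta = 0, short_avgdelta = 0,
                       long_avgdelta = 0), class = "loop_glucose_status")
  pd <- predict_glucose(st, pr, numeric(47), meal_state(), 0)
  expect_equal(pd$IOBpred, rep(140, 48))
  expect_equal(pd$COBpred, rep(140, 48))
  expect_equal(pd$UAMpred, rep(140, 48))
  expect_equal(pd$eventualBG, 140)
  expect_equal(pd$minPredBG, 140)
  # the zero-temp array rises (insulin withdrawn is negative activity)
  expect_true(all(diff(pd$ZTpred) >= 0))
  expect_equal(pd$minGuardBG, 140)
})

test_that("IOB-only prediction lands near glucose minus iob * ISF", {
  pr <- test_profile(ISF = 40)
  # 1 U bolus 60 min ago: nearly all activity falls inside the 4-h horizon
  h <- treatment_history(boluses = data.frame(t = 0, units = 1))
  now <- 60
  iob <- compute_iob(h, pr, now)
  fut <- loopsim:::activity_schedule(h, pr, now, 47)
  st <- structure(list(glucose = 180, delta = 0, short_avgdelta = 0,
                       long_avgdelta = 0), class = "loop_glucose_status")
  pd <- predict_glucose(st, pr, fut, meal_state(), 0)
  expect_equal(pd$IOBpred[48], 180 - iob$iob * pr$ISF, tolerance = 1)
})

test_that("UAM adds the triangular deviation decay to the forecast", {
  pr <- test_profile(ISF = 40)
  st <- structure(list(glucose = 150, delta = 2, short_avgdelta = 2,
                       long_avgdelta = 2), class = "loop_glucose_status")
  pd <- predict_glucose(st, pr, numeric(47), meal_state(), deviation = 12)
  # deviation decaying linearly to 0 over 60 min integrates to dev itself
  expect_equal(pd$UAMpred[48] - pd$IOBpred[48], 12, tolerance = 1e-9)
  expect_equal(pd$eventualBG, pd$UAMpred[48])  # UAM governs: dev > 0, no COB
  # carb entry outranks UAM
  pd2 <- predict_glucose(st, pr, numeric(47), add_carbs(meal_state(), 30, 0), 12)
  expect_equal(pd2$eventualBG, pd2$COBpred[48])
})

test_that("prediction arrays never drop below the sensor floor", {
  pr <- test_profile(ISF = 100)
  h <- treatment_history(boluses = data.frame(t = 0, units = 5))
  fut <- loopsim:::activity_schedule(h, pr, 10, 47)
  st <- structure(list(glucose = 80, delta = -3, short_avgdelta = -3,
                       long_avgdelta = -2), class = "loop_glucose_status")
  pd <- predict_glucose(st, pr, fut, meal_state(), 0)
  expect_true(all(pd$IOBpred >= 39))
  expect_true(all(pd$ZTpred >= 39))
})

mk_status <- function(glucose, delta = 0) {
  structure(list(glucose = glucose, delta = delta, short_avgdelta = delta,
                 long_avgdelta = delta), class = "loop_glucose_status")
}

test_that("low glucose or a low guard prediction forces a 30-min zero temp", {
  pr <- test_profile()
  rec <- determine_basal(mk_status(60, -2), list(iob = 0, activity = 0),
                         meal_state(), 1, pr)
  expect_equal(rec$temp_rate, 0)
  expect_equal(rec$temp_duration, 30)
  expect_equal(rec$smb, 0)
  # glucose fine but minGuardBG below the suspend threshold (large IOB)
  h <- treatment_history(boluses = data.frame(t = 0, units = 3))
  fut <- loopsim:::activity_schedule(h, pr, 5, 47)
  rec2 <- determine_basal(mk_status(110), compute_iob(h, pr, 5), meal_state(),
                          1, pr, fut)
  expect_equal(rec2$temp_rate, 0)
  expect_match(rec2$reason, "suspend")
})

test_that("at-target forecasts produce a neutral temp and no SMB", {
  pr <- test_profile(target = 100)
  rec <- determine_basal(mk_status(100), list(iob = 0, activity = 0),
                         meal_state(), 1, pr)
  expect_equal(rec$temp_rate, pr$basal)
  expect_equal(rec$smb, 0)
  expect_equal(rec$eventualBG, 100)
})

test_that("the IOB cap forbids SMBs and caps the temp at the basal rate", {
  pr <- test_profile(target = 100, max_iob = 10)
  rec <- determine_basal(mk_status(260), list(iob = 10, activity = 0.02),
                         meal_state(), 1, pr)
  expect_equal(rec$smb, 0)
  expect_lte(rec$temp_rate, pr$basal)
  rec2 <- determine_basal(mk_status(260), list(iob = 12, activity = 0.02),
                          meal_state(), 1, pr)
  expect_equal(rec2$smb, 0)
  expect_lte(rec2$temp_rate, pr$basal)
})

test_that("a delivered SMB always rides on a 30-min zero temp", {
  pr <- test_profile(target = 100)
  rec <- determine_basal(mk_status(220), list(iob = 0, activity = 0),
                         meal_state(), 1, pr)
  expect_gt(rec$smb, 0)
  expect_equal(rec$temp_rate, 0)
  expect_equal(rec$temp_duration, 30)
  expect_equal(rec$smb * 20, round(rec$smb * 20), tolerance = 1e-9)
  # SMB size is capped in basal minutes
  expect_lte(rec$smb, pr$basal * pr$maxSMBBasalMinutes / 60 + 1e-9)
})

test_that("an invalid sensor reading yields a neutral temp", {
  pr <- test_profile()
  rec <- determine_basal(mk_status(20), list(iob = 0, activity = 0),
                         meal_state(), 1, pr)
  expect_equal(rec$temp_rate, pr$basal)
  expect_match(rec$reason, "invalid")
})

test_that("safety caps hold across randomized controller invocations", {
  set.seed(2024)
  n_bad_rate <- 0; n_bad_smb <- 0
  for (i in seq_len(1200)) {
    basal <- stats::runif(1, 0.3, 2)
    pr <- test_profile(ISF = stats::runif(1, 20, 90),
                       CR = stats::runif(1, 5, 25), basal = basal,
                       smb_enabled = stats::runif(1) < 0.7,
                       uam_enabled = stats::runif(1) < 0.7)
    iob <- list(iob = stats::runif(1, -2, 14),
                activity = stats::runif(1, 0, 0.05))
    st <- mk_status(stats::runif(1, 40, 380), stats::runif(1, -12, 12))
    meal <- if (stats::runif(1) < 0.4) {
      add_carbs(meal_state(), stats::runif(1, 5, 90), 0)
    } else meal_state()
    fut <- stats::runif(47, 0, 0.03)
    rec <- determine_basal(st, iob, meal, stats::runif(1, 0.5, 1.5), pr, fut,
                           deviation = stats::runif(1, -40, 160))
    if (rec$temp_rate > 10 + 1e-9) n_bad_rate <- n_bad_rate + 1
    if (rec$smb > 1e-12 && iob$iob >= 10) n_bad_smb <- n_bad_smb + 1
    expect_gte(rec$temp_rate, 0)
    expect_gte(rec$smb, 0)
    if (!pr$smb_enabled) expect_equal(rec$smb, 0)
  }
  expect_equal(n_bad_rate, 0)
  expect_equal(n_bad_smb, 0)
})

test_that("more predicted hyperglycemia never means less insulin", {
  # temp-basal path: recommended rate is nondecreasing in glucose
  pr <- test_profile(smb_enabled = FALSE, target = 100)
  rates <- vapply(seq(60, 300, by = 5), function(g) {
    determine_basal(mk_status(g), list(iob = 0, activity = 0), meal_state(),
                    1, pr)$temp_rate
  }, 0)
  expect_true(all(diff(rates) >= -1e-9))
  # SMB path: microbolus size is nondecreasing in glucose
  prs <- test_profile(smb_enabled = TRUE, target = 100)
  smbs <- vapply(seq(100, 300, by = 5), function(g) {
    determine_basal(mk_status(g), list(iob = 0, activity = 0), meal_state(),
                    1, prs)$smb
  }, 0)
  expect_true(all(diff(smbs) >= -1e-9))
})

test_that("meal boluses deliver half the calculated dose on the pump grid", {
  pr <- test_profile(CR = 10)
  expect_equal(meal_bolus(50, pr), 2.5)
  expect_equal(meal_bolus(0, pr), 0)
  expect_equal(meal_bolus(33, pr), 1.65)     # 3.3 U full, half on-grid
  expect_equal(meal_bolus(7, pr), 0.35)
  expect_error(meal_bolus(-1, pr), "carbs")
})
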