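test_that("schedules have the exact trial structure and reproduce by seed", {
  s1 <- generate_mid_schedule(seed = 101)
  s2 <- generate_mid_schedule(seed = 101)
  s3 <- generate_mid_schedule(seed = 102)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))

  expect_identical(nrow(s1), 100L)
  expect_identical(as.integer(table(s1$cue_type)), rep(20L, 5))
  for (r in 1:2) {
    expect_identical(as.integer(table(s1$cue_type[s1$run == r])), rep(10L, 5))
    on <- s1$cue_onset[s1$run == r]
    expect_true(all(diff(on) > 0))
  }
})

test_that("trial components abut with no gaps and fill the run exactly", {
  s <- generate_mid_schedule(seed = 103)
  for (r in 1:2) {
    tr <- s[s$run == r, ]
    len <- tr$cue_duration + tr$fixation_duration + tr$probe_duration +
      tr$feedback_duration
    # next cue onset = previous feedback offset
    expect_equal(tr$cue_onset[-1], (tr$cue_onset + len)[-nrow(tr)],
                 tolerance = 1e-12)
    # run length covers the last feedback offset, rounded to whole scans
    n_scans <- attr(s, "n_scans_per_run")[r]
    last_off <- tr$cue_onset[nrow(tr)] + len[nrow(tr)]
    expect_gte(n_scans * attr(s, "dt"), last_off)
    expect_lt(n_scans * attr(s, "dt") - last_off, attr(s, "dt"))
  }
})

test_that("durations stay in range and differ by outcome as configured", {
  # pool many schedules for stable frequency and mean-difference estimates
  pool <- do.call(rbind, lapply(1:400, function(i) {
    as.data.frame(generate_mid_schedule(seed = 2000 + i))
  }))
  p <- mid_params()
  expect_true(all(pool$cue_duration >= p$cue_range[1] &
                    pool$cue_duration <= p$cue_range[2]))
  expect_true(all(pool$fixation_duration >= p$fixation_range[1] &
                    pool$fixation_duration <= p$fixation_range[2]))
  expect_true(all(pool$probe_duration >= p$probe_range[1] &
                    pool$probe_duration <= p$probe_range[2]))
  expect_true(all(pool$feedback_duration >= p$feedback_range[1] &
                    pool$feedback_duration <= p$feedback_range[2]))
  rt <- pool$response_time[!is.na(pool$response_time)]
  expect_true(all(rt >= p$rt_range[1] & rt <= p$rt_range[2]))

  # outcome mix ~ 57 / 36 / 7 %
  freq <- table(pool$outcome) / nrow(pool)
  expect_lt(abs(freq[["Hit"]] - 0.57), 0.01)
  expect_lt(abs(freq[["TooSlow"]] - 0.36), 0.01)
  expect_lt(abs(freq[["TooSoon"]] - 0.07), 0.01)

  # feedback complements the probe inside its legal range
  unclipped <- pool$feedback_duration > p$feedback_range[1] &
    pool$feedback_duration < p$feedback_range[2]
  expect_equal(pool$probe_duration[unclipped] +
                 pool$feedback_duration[unclipped],
               rep(p$feedback_total, sum(unclipped)), tolerance = 1e-12)

  hit <- pool$outcome == "Hit"
  d_probe <- mean(pool$probe_duration[hit]) - mean(pool$probe_duration[!hit])
  expect_gt(d_probe, 0.020)
  expect_lt(d_probe, 0.040)
  d_fix <- mean(pool$fixation_duration[hit]) -
    mean(pool$fixation_duration[!hit])
  expect_gt(d_fix, 0.063)
  expect_lt(d_fix, 0.160)
  d_rt <- mean(pool$response_time[!hit], na.rm = TRUE) -
    mean(pool$response_time[hit], na.rm = TRUE)
  expect_gt(d_rt, 0.060)
  expect_lt(d_rt, 0.120)

  # a Too Soon trial only sometimes has a recorded RT
  ts <- pool$outcome == "TooSoon"
  expect_gt(mean(is.na(pool$response_time[ts])), 0.4)
  expect_lt(mean(is.na(pool$response_time[ts])), 0.6)
  expect_true(all(!is.na(pool$response_time[!ts])))
})

test_that("infeasible parameters are rejected", {
  expect_error(mid_params(probe_hit_shift = 2), "shifts exceed")
  expect_error(mid_params(outcome_probs = c(Hit = 0.5, TooSlow = 0.5,
                                            TooSoon = 0.5)),
               "probabilities")
  expect_error(mid_params(probe_range = c(0.5, 0.2)), "increasing")
})

test_that("staircase steps toward the target and respects the floor", {
  # all hits at a multiple-of-3 trial: duration decreases
  expect_lt(staircase_probe_duration(rep(1, 6), 0.3), 0.3)
  # at the floor it stays clipped
  expect_equal(staircase_probe_duration(rep(1, 6), 0.172), 0.172)
  # off-cycle trials leave the duration alone
  expect_equal(staircase_probe_duration(rep(1, 5), 0.3), 0.3)

  # closed loop with a latent RT responder converges near 60% accuracy
  set.seed(31)
  dur <- 0.3
  acc <- numeric(1000)
  for (i in seq_len(1000)) {
    rt <- rnorm(1, mean = 0.29, sd = 0.05)
    acc[i] <- as.numeric(rt <= dur)
    dur <- staircase_probe_duration(acc[seq_len(i)], dur)
  }
  expect_lt(abs(mean(acc[201:1000]) - 0.6), 0.05)
})

test_that("model specs produce the documented regressor and column counts", {
  s <- generate_mid_schedule(seed = 104)

  ev_cf <- schedule_to_events(s, model_spec("cuefeedback"))
  expect_length(ev_cf, 15)          # 5 cue + 10 feedback event sets
  d_cf <- mid_design(s, "cuefeedback", oversampling = 10)
  expect_length(d_cf$task_cols, 30) # each paired with its derivative

  ev_sat <- schedule_to_events(s, model_spec("saturated"))
  expect_length(ev_sat, 24)
  expect_setequal(
    names(ev_sat),
    c(paste0("Cue_", c("LargeWin", "SmallWin", "Neutral", "SmallLoss",
                       "LargeLoss")),
      paste0("Fix_", c("LargeWin", "SmallWin", "Neutral", "SmallLoss",
                       "LargeLoss")),
      paste0("Probe_", c("Win", "Loss", "Neutral")), "RT",
      as.vector(outer(paste0("FB_", c("LargeWin", "SmallWin", "Neutral",
                                      "SmallLoss", "LargeLoss")),
                      c("Hit", "Miss"), paste, sep = "_"))))
  d_sat <- mid_design(s, "saturated", oversampling = 10)
  expect_length(d_sat$task_cols, 24)

  d_sd <- mid_design(s, "saturated_derivs", oversampling = 10)
  expect_identical(ncol(d_sd$values), 49L)  # 48 task + intercept

  # RT events only for trials with a recorded response time
  expect_identical(nrow(ev_sat$RT), sum(!is.na(s$response_time)))
  # feedback split: every cue x outcome cell is non-empty by construction
  fb_n <- vapply(ev_sat[grep("^FB_", names(ev_sat))], nrow, integer(1))
  expect_true(all(fb_n >= 1))
  expect_identical(sum(fb_n), 100L)
})

test_that("the contrast library reproduces the published weight patterns", {
  s <- generate_mid_schedule(seed = 105)
  d <- mid_design(s, "saturated", oversampling = 10)
  cons <- contrast_library(d$column_names)
  expect_named(cons, c("Cue:LW-Neut", "Cue:LL-Neut", "Cue:LW-Base",
                       "FB:WHit-WMiss", "FB:LHit-LMiss", "FB:LWHit-NeutHit",
                       "FB:LWHit-Base"))
  expect_equal(sum(cons[["Cue:LW-Neut"]]), 0)
  lw_base <- cons[["FB:LWHit-Base"]]
  expect_equal(unname(lw_base[["FB_LargeWin_Hit"]]), 1)
  expect_equal(sum(lw_base != 0), 1)
  lhit <- cons[["FB:LHit-LMiss"]]
  expect_equal(sort(unname(lhit[lhit != 0])), c(-0.5, -0.5, 0.5, 0.5))
  whit <- cons[["FB:WHit-WMiss"]]
  expect_equal(unname(whit[c("FB_LargeWin_Hit", "FB_SmallWin_Hit",
                             "FB_LargeWin_Miss", "FB_SmallWin_Miss")]),
               c(0.5, 0.5, -0.5, -0.5))

  # contrasts undefined for a column set are rejected
  expect_error(contrast_library(c("foo", "bar")), "undefined")
})

test_that("emulated designs show the documented collinearity pattern", {
  # saturated: contrasts of interest acceptable; adding derivatives makes
  # many parameters excessive (the reason derivatives are dropped)
  scheds <- get_sim_schedules(6)
  cv_int <- sapply(scheds, function(s) {
    d <- mid_design(s, "saturated")
    cons <- contrast_library(d$column_names)
    vapply(cons[c("Cue:LW-Neut", "Cue:LL-Neut", "FB:WHit-WMiss",
                  "FB:LHit-LMiss")],
           function(cc) cvif(d, cc), numeric(1))
  })
  expect_lt(median(cv_int), 10)
  expect_true(all(cv_int < 15))

  n_excessive <- sapply(scheds[1:3], function(s) {
    d <- mid_design(s, "saturated_derivs")
    tv <- vapply(task_column_names(d), function(j) tvif(d, j), numeric(1))
    sum(tv > 20)
  })
  expect_true(all(n_excessive >= 15))
})

test_that("schedules export to BIDS events files and back", {
  s <- generate_mid_schedule(seed = 106)
  bids <- schedule_to_bids(s)
  expect_length(bids, 2)
  expect_identical(nrow(bids[[1]]), 200L)  # 50 trials x 4 components
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(bids[[1]], path)
  back <- read_events_tsv(path)
  expect_identical(sort(unique(sub("_.*", "", back$trial_type))),
                   c("cue", "feedback", "fixation", "probe"))
  expect_equal(sum(back$duration), sum(bids[[1]]$duration), tolerance = 1e-9)
})
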