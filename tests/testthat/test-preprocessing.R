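test_that("session filter drops training and low-accuracy sessions", {
  tr <- rbind(
    manual_trials("s1", 1.0, correct = c(rep(TRUE, 69), rep(FALSE, 31)),
                  rt = runif(100, 0.3, 1)),          # accuracy 0.69
    manual_trials("s2", 0.25, correct = rep(TRUE, 50),
                  rt = runif(50, 0.3, 1)),           # training complexity
    manual_trials("s3", 0.5, correct = c(rep(TRUE, 75), rep(FALSE, 25)),
                  rt = runif(100, 0.3, 1))           # keeper
  )
  res <- filter_sessions(tr)
  expect_equal(sort(res$sessions$session_id), c("s1", "s2", "s3"))
  expect_equal(res$sessions$kept[order(res$sessions$session_id)],
               c(FALSE, FALSE, TRUE))
  expect_true(all(res$trials$session_id == "s3"))
  s1 <- res$sessions[res$sessions$session_id == "s1", ]
  expect_equal(s1$accuracy, 0.69)
  # boundary case: exactly 70% and b = 0.5 is kept
  tr2 <- manual_trials("s4", 0.5, correct = c(rep(TRUE, 70), rep(FALSE, 30)),
                       rt = runif(100, 0.3, 1))
  expect_true(filter_sessions(tr2)$sessions$kept)
})

test_that("reaction-time normalization equalizes session means at the grand mean", {
  tr <- rbind(
    manual_trials("s1", 1, correct = rep(TRUE, 50),
                  rt = runif(50, 0.2, 0.6)),
    manual_trials("s2", 1, correct = rep(TRUE, 80),
                  rt = runif(80, 0.4, 0.8))
  )
  out <- normalize_reaction_times(tr)
  sess_means <- tapply(out$rt_normalized, out$session_id, mean)
  grand <- mean(tapply(tr$rt_raw, tr$session_id, mean))
  expect_equal(as.numeric(sess_means), rep(grand, 2), tolerance = 1e-12)
  # rank order and ratios preserved within session
  s1 <- out[out$session_id == "s1", ]
  expect_equal(order(s1$rt_normalized), order(s1$rt_raw))
  expect_equal(s1$rt_normalized[2] / s1$rt_normalized[1],
               s1$rt_raw[2] / s1$rt_raw[1], tolerance = 1e-12)
  # a single session is unchanged
  single <- normalize_reaction_times(tr[tr$session_id == "s1", ])
  expect_equal(single$rt_normalized, single$rt_raw, tolerance = 1e-12)
  # explicit two-session means 0.4 and 0.6 -> both become 0.5
  tr3 <- rbind(
    manual_trials("a", 1, correct = rep(TRUE, 4), rt = c(0.3, 0.5, 0.4, 0.4)),
    manual_trials("b", 1, correct = rep(TRUE, 2), rt = c(0.5, 0.7))
  )
  out3 <- normalize_reaction_times(tr3)
  expect_equal(as.numeric(tapply(out3$rt_normalized, out3$session_id, mean)),
               c(0.5, 0.5))
  # trial-weighted variant
  out3t <- normalize_reaction_times(tr3, grand = "trial")
  expect_equal(as.numeric(tapply(out3t$rt_normalized, out3t$session_id, mean)),
               rep(mean(tr3$rt_raw), 2))
  # identical RTs are left untouched
  tr4 <- manual_trials("c", 1, correct = rep(TRUE, 5), rt = rep(0.4, 5))
  expect_equal(normalize_reaction_times(tr4)$rt_normalized, rep(0.4, 5))
})

test_that("behavioural curves count report-present fractions per cell", {
  tr <- rbind(
    manual_trials("s1", 1, correct = c(rep(TRUE, 80), rep(FALSE, 20)),
                  rt = runif(100, 0.3, 1)),
    manual_trials("s1", 1, correct = c(rep(TRUE, 30), rep(FALSE, 10)),
                  rt = runif(40, 0.3, 1), condition = "none:2",
                  trial_type = "target_off", n_background = 2)
  )
  curves <- behavioral_curves(tr)
  on0 <- curves[curves$trial_type == "target_on" & curves$n_background == 0, ]
  expect_equal(on0$p_report_present, 0.8)
  expect_equal(on0$n, 100)
  off2 <- curves[curves$trial_type == "target_off" & curves$n_background == 2, ]
  expect_equal(off2$p_report_present, 0.25)
  empty <- curves[curves$trial_type == "target_off" & curves$n_background == 6, ]
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$p_report_present))
})

test_that("combined-mechanism data reproduce the behavioural signatures", {
  set.seed(41)
  d <- balanced_dataset(default_ground_truth(), 400)
  curves <- behavioral_curves(d)
  on <- curves[curves$trial_type == "target_on", ]
  on <- on[order(on$n_background), ]
  off <- curves[curves$trial_type == "target_off", ]
  off <- off[order(off$n_background), ]
  # report-present falls with backgrounds on target-on, rises on target-off
  expect_lt(cor(on$n_background, on$p_report_present), -0.9)
  expect_gt(cor(off$n_background, off$p_report_present), 0.9)
  # reaction times fall with backgrounds in both trial types
  expect_lt(cor(on$n_background, on$mean_rt), -0.9)
  expect_lt(cor(off$n_background, off$mean_rt), -0.9)
})

test_that("flat ground truth yields flat curves (negative control)", {
  set.seed(42)
  d <- balanced_dataset(default_ground_truth(mechanism = "flat"), 400)
  curves <- behavioral_curves(d)
  for (tt in c("target_on", "target_off")) {
    cc <- curves[curves$trial_type == tt, ]
    expect_lt(diff(range(cc$p_report_present)), 0.1)
    expect_lt(diff(range(cc$mean_rt)), 0.05)
  }
})
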