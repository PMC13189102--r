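test_that("dF/F0 normalization is exact on constant and stepped traces", {
  t <- seq(0, 10, by = 0.1)
  flat <- dff(rep(100, length(t)), t, baseline_window = c(0, 2))
  expect_true(all(flat$dff == 0))
  expect_equal(flat$f0, 100)
  stepped <- dff(ifelse(t < 5, 100, 150), t, baseline_window = c(0, 2))
  expect_equal(max(stepped$dff), 0.5)
  expect_error(dff(rep(0, length(t)), t, c(0, 2)), "non-positive")
  expect_error(dff(rep(1, 3), c(0, 1, 2), c(0, 0.5)), ">= 2 frames")
})

test_that("noiseless kernel peak matches the closed-form maximum location and height", {
  tr <- 0.5; td <- 2
  tp <- kernel_peak_time(tr, td)
  expect_equal(tp, tr * td / (td - tr) * log(td / tr))
  tt <- seq(0, 20, by = 0.001)
  k <- calcium_kernel(tt, tr, td)
  expect_equal(max(k), 1, tolerance = 1e-6)
  expect_equal(tt[which.max(k)], tp, tolerance = 0.001)

  # through the generator: amplitude A, zero noise -> extracted peak = A and
  # peak latency within one frame of the analytic kernel maximum
  cfg <- calcium_sim_config(n_rois = c(g = 3), frame_rate_hz = 50,
                            amplitude_mean = c(g = 0.8),
                            amplitude_sd = c(g = 0), noise_sd = 0,
                            onset_time_s = 10, rise_tau_s = tr,
                            decay_tau_s = td, rng_seed = 5)
  ts <- generate_calcium_traces(cfg)
  ft <- calcium_features_table(ts$traces, t0 = 10)
  expect_equal(ft$peak, rep(0.8, 3), tolerance = 1e-4)
  expect_equal(ft$latency_s, rep(tp, 3), tolerance = 1 / 50 + 1e-9)
})

test_that("onset detection finds the maximal first difference with earliest-frame ties", {
  t <- 0:9
  step <- c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1)
  expect_equal(detect_stimulus_onset(step, t), 3)
  ramp <- seq(0, 9)
  expect_equal(detect_stimulus_onset(ramp, t), 0)  # all ties -> earliest
  expect_error(detect_stimulus_onset(rep(1, 5), 0:4), "undefined")
})

test_that("triangular pulse gives the closed-form AUC and 10-90% rise time", {
  dt <- 0.01
  t <- seq(0, 30, by = dt)
  y <- numeric(length(t))
  rise <- t >= 10 & t < 15; fall <- t >= 15 & t <= 20
  y[rise] <- (t[rise] - 10) / 5
  y[fall] <- 1 - (t[fall] - 15) / 5
  ft <- extract_features(y, t, t0 = 10, window = c(0, 20))
  expect_equal(ft$auc, 5, tolerance = 0.01)
  expect_equal(ft$rise_time_s, 4, tolerance = 0.01)
  expect_equal(ft$peak, 1, tolerance = 1e-9)
  expect_equal(ft$latency_s, 5, tolerance = 0.02)
})

test_that("features ignore events outside the 0-20 s poststimulus window", {
  t <- seq(0, 60, by = 0.05)
  y <- numeric(length(t))
  y[t >= 35 & t <= 40] <- 1  # 25 s after t0 = 10
  ft <- extract_features(y, t, t0 = 10, window = c(0, 20))
  expect_equal(ft$peak, 0)
  expect_equal(ft$auc, 0)
})

test_that("flat traces report zero features and non-responder by the strict rule", {
  t <- seq(0, 30, by = 0.1)
  ft <- extract_features(rep(0, length(t)), t, t0 = 10)
  expect_equal(ft$peak, 0)
  expect_equal(ft$auc, 0)
  expect_equal(ft$latency_s, 0)
  expect_equal(ft$quality_flag, "flat")
  expect_false(ft$responder)  # 0 > 0 is false
  # peak exactly at threshold is not a responder ("exceeded" is strict)
  expect_false(classify_responder(list(peak = 0.3, baseline_mean = 0,
                                       baseline_sd = 0.1)))
  expect_true(classify_responder(list(peak = 0.300001, baseline_mean = 0,
                                      baseline_sd = 0.1)))
})

test_that("responder fractions equal per-trace brute-force evaluation on a synthetic cohort", {
  cfg <- calcium_sim_config(n_rois = c(a = 40, b = 40),
                            amplitude_mean = c(a = 0.05, b = 1),
                            amplitude_sd = c(a = 0.05, b = 0.2),
                            noise_sd = 0.02, rng_seed = 77)
  ts <- generate_calcium_traces(cfg)
  ft <- calcium_features_table(ts$traces, t0 = cfg$onset_time_s)
  # brute force: recompute every trace by hand
  brute <- vapply(split(ts$traces, ts$traces$roi_id), function(r) {
    bw <- r$t <= cfg$onset_time_s - 1
    f0 <- mean(r$f[bw])
    d <- (r$f - f0) / f0
    bm <- mean(d[bw]); bs <- sd(d[bw])
    win <- r$t >= cfg$onset_time_s & r$t <= cfg$onset_time_s + 20
    max(d[win]) > bm + 3 * bs
  }, logical(1))
  expect_equal(ft$responder, unname(brute[ft$roi_id]))
  expect_gt(mean(ft$responder[ft$group == "b"]),
            mean(ft$responder[ft$group == "a"]))
})

test_that("rank-sum comparison is exact for small untied groups", {
  res <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$p, 0.1)  # 2/20 orderings, two-sided
  same <- compare_groups(c(1, 2, 3, 1.5, 2.5, 3.5), rep(c("a", "b"), each = 3))
  expect_gt(same$p, 0.5)
  expect_error(compare_groups(1:3, rep("a", 3)), "two groups")
})

test_that("amplitude monotonicity: larger transients never decrease peak, AUC or responder", {
  t <- seq(0, 40, by = 0.05)
  k <- calcium_kernel(t - 10, 0.2, 2)
  prev <- NULL
  for (a in c(0.1, 0.5, 1, 2)) {
    ft <- extract_features(a * k, t, t0 = 10,
                           baseline_mean = 0, baseline_sd = 0.01)
    if (!is.null(prev)) {
      expect_gte(ft$peak, prev$peak)
      expect_gte(ft$auc, prev$auc)
      expect_gte(ft$responder, prev$responder)
    }
    prev <- ft
  }
})

test_that("baseline-only noisy traces have zero AUC in expectation", {
  set.seed(99)
  t <- seq(0, 40, by = 0.1)
  aucs <- replicate(200, {
    f <- 100 + rnorm(length(t), 0, 2)
    nd <- dff(f, t, baseline_window = c(0, 9))
    extract_features(nd$dff, t, t0 = 10, baseline_mean = nd$baseline_mean,
                     baseline_sd = nd$baseline_sd)$auc
  })
  expect_lt(abs(mean(aucs)), 3 * sd(aucs) / sqrt(200))
})

test_that("d7_kcl preset group mean peaks bracket the configured values", {
  cfg <- calcium_preset("d7_kcl", rng_seed = 5)
  ts <- generate_calcium_traces(cfg)
  ft <- calcium_features_table(ts$traces, t0 = cfg$onset_time_s)
  # configured group means 1.222 and 1.383 with SEM-derived SDs at n = 4;
  # extracted means must fall within 3 standard errors
  for (g in c("wildtype", "mutant")) {
    got <- mean(ft$peak[ft$group == g])
    want <- cfg$amplitude_mean[[g]]
    se <- cfg$amplitude_sd[[g]] / sqrt(cfg$n_rois[[g]])
    expect_lt(abs(got - want), 3 * se)
  }
  expect_gt(mean(ft$peak[ft$group == "mutant"]),
            mean(ft$peak[ft$group == "wildtype"]))
})

test_that("generator reproduces configuration exactly under a fixed seed", {
  cfg <- calcium_sim_config(rng_seed = 123)
  expect_identical(generate_calcium_traces(cfg)$traces,
                   generate_calcium_traces(cfg)$traces)
  # null config: amplitude 0, noise 0 -> constant at baseline
  null_cfg <- calcium_sim_config(n_rois = c(g = 2),
                                 amplitude_mean = c(g = 0),
                                 amplitude_sd = c(g = 0), noise_sd = 0)
  ts <- generate_calcium_traces(null_cfg)
  expect_true(all(ts$traces$f == null_cfg$baseline_f0))
  expect_error(calcium_sim_config(rise_tau_s = 2, decay_tau_s = 1),
               "degenerate")
})
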