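test_that("the baseline clock has a 24-h limit cycle with anchored phases", {
  lc <- control_lc()
  expect_equal(lc$period_h, 24, tolerance = 0.1 / 24)
  cyc <- lc$cycle
  # CT12 anchor: REV-ERB protein crests at CT12 by construction,
  # and ROR protein attains its minimum at the same circadian time (+/- 1.5 h)
  ct_revmax <- cyc$ct_h[which.max(cyc$p_rev)]
  ct_rormin <- cyc$ct_h[which.min(cyc$p_ror)]
  circ_dist <- function(a, b) min((a - b) %% 24, (b - a) %% 24)
  expect_lt(circ_dist(ct_revmax, 12), 0.5)
  expect_lt(circ_dist(ct_rormin, ct_revmax), 1.5)
  # the cycle closes
  gap <- vapply(clock_state_names(), function(v) {
    abs(cyc[[v]][1] - cyc[[v]][nrow(cyc)]) / max(diff(range(cyc[[v]])), 1e-12)
  }, numeric(1))
  expect_lt(max(gap), 0.01)
})

test_that("integration from non-negative states stays non-negative", {
  ps <- control_params()
  init <- c(limit_cycle_state(control_lc(), 3), immune_rest_state(ps$immune))
  init["p_endo"] <- 12
  tr <- simulate_model(ps, init, seq(0, 48, 0.1), drive = lps_drive(0, 4))
  vals <- as.matrix(tr[, c(clock_state_names(), immune_state_names())])
  expect_gt(min(vals), -1e-9)
})

test_that("perturbed initial conditions relax to the same cycle", {
  ps <- control_params()
  t_tail <- seq(30 * 24, 31 * 24, 0.1)
  run_from <- function(init) {
    tr <- simulate_model(ps, init, c(seq(0, 30 * 24 - 1, 4), t_tail))
    tr[tr$time_h >= 30 * 24, ]
  }
  a <- run_from(rep(0.5, 12))
  b <- run_from(rep(0.5, 12) * c(2, 0.5, 1.5, 0.7, 1, 2, 0.5, 1.5, 0.7, 1, 2, 0.5))
  # phase-align b to a on Bmal1 mRNA, then compare full profiles
  lags <- seq(-12, 12, by = 0.1)
  rmse <- vapply(lags, function(lag) {
    bb <- stats::approx(b$time_h + lag, b$m_bmal1, xout = a$time_h)$y
    sqrt(mean((bb - a$m_bmal1)^2, na.rm = TRUE))
  }, numeric(1))
  best_lag <- lags[which.min(rmse)]
  worst <- max(vapply(clock_state_names(), function(v) {
    bb <- stats::approx(b$time_h + best_lag, b[[v]], xout = a$time_h)$y
    ok <- !is.na(bb)
    amp <- diff(range(a[[v]]))
    sqrt(mean((bb[ok] - a[[v]][ok])^2)) / max(amp, 1e-12)
  }, numeric(1)))
  expect_lt(worst, 0.01)
})

test_that("rescaling all rates rescales the period accordingly", {
  ps <- control_params()
  rate_keys <- grep("^(v_|dm_|kp_|dp_|kf_|kb_|d_pc|d_cb)",
                    names(ps$clock), value = TRUE)
  ps2 <- ps
  ps2$clock[rate_keys] <- ps2$clock[rate_keys] * 1.15
  lc2 <- find_limit_cycle(ps2, days = 40, transient_days = 20)
  expect_equal(lc2$period_h, control_lc()$period_h / 1.15, tolerance = 0.01)
})

test_that("Bmal1 knockout damps the clock", {
  ps <- apply_knockout(control_params(), "Bmal1")
  expect_error(find_limit_cycle(ps), "damped")
})

test_that("peak counting follows the prominence and separation rules", {
  t <- seq(0, 24, by = 0.05)
  # two full cycles of a 12-h rhythm -> 2 peaks
  tr <- tibble::tibble(time_h = t, y = 1 + sin(2 * pi * t / 12))
  expect_identical(nrow(count_peaks(tr, "y")), 2L)
  # monotone decay, boundary excluded -> 0 peaks
  tr2 <- tibble::tibble(time_h = t, y = exp(-t / 4))
  expect_identical(nrow(count_peaks(tr2, "y")), 0L)
  # a 20%-prominence peak counts, a 1%-prominence ripple does not
  y3 <- exp(-((t - 6) / 2)^2) + 0.01 * exp(-((t - 15) / 0.5)^2) + 0.001 * t
  tr3 <- tibble::tibble(time_h = t, y = y3)
  expect_identical(nrow(count_peaks(tr3, "y")), 1L)
  # flat trace -> empty
  tr4 <- tibble::tibble(time_h = t, y = rep(1, length(t)))
  expect_identical(nrow(count_peaks(tr4, "y")), 0L)
})

test_that("a zero dose leaves every cytokine flat", {
  ex <- run_experiment(experiment_spec(dose = 0), control_params(),
                       lc = control_lc())
  expect_identical(nrow(ex$il10_peaks), 0L)
  rest <- immune_rest_state(control_params()$immune)
  expect_lt(max(abs(ex$trajectory$il10 - rest[["il10"]])), 1e-8)
  expect_lt(max(ex$trajectory$il6), 1e-8)
  expect_equal(ex$severity, 0, tolerance = 1e-10)
})

test_that("an 8-h phase advance with control parameters equals a shifted control run", {
  ps <- control_params()
  ps_tagged <- ps
  ps_tagged$condition <- "cjl_male"  # same parameters, advanced phase
  lc <- control_lc()
  a <- run_experiment(experiment_spec(condition = "cjl_male", dose = 3,
                                      challenge_ct = 4),
                      ps_tagged, lc = lc)
  b <- run_experiment(experiment_spec(condition = "control", dose = 3,
                                      challenge_ct = 12),
                      ps, lc = lc)
  expect_equal(a$severity, b$severity, tolerance = 1e-8)
  expect_equal(a$trajectory$il6, b$trajectory$il6, tolerance = 1e-6)
})

test_that("summary statistics are integrator-independent", {
  sp <- experiment_spec(dose = 3, challenge_ct = 12)
  ps <- control_params()
  e1 <- run_experiment(sp, ps, lc = control_lc())
  lc_tight <- find_limit_cycle(ps, dt = 0.05)
  e2_traj <- simulate_model(
    ps,
    {
      init <- c(limit_cycle_state(lc_tight, 12),
                immune_rest_state(ps$immune))
      init["p_endo"] <- init["p_endo"] + 3
      init
    },
    seq(0, 36, 0.02), drive = lps_drive(0, 1), ct_offset = 12,
    rtol = 5e-9, atol = 5e-11)
  expect_equal(max(e2_traj$il6), e1$peaks$peak[e1$peaks$variable == "il6"],
               tolerance = 1e-3)
  expect_equal(max(e2_traj$d_dam), e1$severity, tolerance = 1e-3)
})
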