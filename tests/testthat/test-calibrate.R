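test_that("the normalized residual reproduces hand and loop evaluations", {
  expect_identical(normalized_chi2(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(normalized_chi2(c(0, 0), c(0, 10)), 1)
  # independently coded naive summation on seeded random series
  set.seed(99)
  for (i in 1:5) {
    obs <- stats::runif(12, 0.1, 5)
    pred <- obs * exp(stats::rnorm(12, 0, 0.3))
    acc <- 0
    m <- -Inf
    for (y in obs) if (y > m) m <- y
    for (j in seq_along(obs)) acc <- acc + ((obs[j] - pred[j]) / m)^2
    expect_equal(normalized_chi2(pred, obs), acc, tolerance = 1e-12)
  }
  expect_error(normalized_chi2(c(0, 0), c(0, 0)), "undefined")
})

test_that("the composite cost is the sum of its six components", {
  spec <- synthetic_spec(seed = 4, sigma = 0.1, mode = "cosinor",
                         doses = c(3, 12))
  data <- generate_cytokine_series(spec)
  ps <- control_params()
  val <- total_cost(ps, data, lc = control_lc())
  comps <- attr(val, "components")
  expect_length(comps, 6)
  expect_setequal(names(comps),
                  c(t(outer(c("chi2_il6_", "chi2_tnf_", "chi2_il10_"),
                            c(3, 12), paste0))))
  expect_equal(as.numeric(val), sum(comps), tolerance = 1e-12)
  # dropping one series removes exactly its component
  data2 <- data[!(data$variable == "tnf" & data$dose == 3), ]
  val2 <- total_cost(ps, data2, lc = control_lc())
  expect_equal(as.numeric(val2), sum(comps) - comps[["chi2_tnf_3"]],
               tolerance = 1e-10)
})

test_that("noise-free model data give near-zero cost at the generating truth", {
  spec <- synthetic_spec(seed = 5, sigma = 0, mode = "model",
                         doses = c(3, 12))
  data <- generate_cytokine_series(spec)
  val <- total_cost(control_params(), data, lc = control_lc())
  expect_lt(as.numeric(val), 1e-4)
  # perturbing a production maximum by 50% strictly increases the cost
  ps2 <- control_params()
  ps2$immune["k_6"] <- ps2$immune["k_6"] * 1.5
  expect_gt(as.numeric(total_cost(ps2, data, lc = control_lc())),
            as.numeric(val) + 1e-3)
})

test_that("clock fitting recovers perturbed transcription parameters", {
  truth <- control_params()
  spec <- synthetic_spec(seed = 6, sigma = 0, mode = "model", params = truth)
  data <- generate_clock_series(spec)
  # start from the truth: cost must be essentially zero without moving
  fit0 <- fit_clock(data, init = truth, free_names = c("v_per", "v_rev"),
                    starts = 1, maxit = 40, cycle_days = 22,
                    cycle_transient = 14)
  expect_lt(fit0$cost, 1e-3)
  # perturbed start on a small free set: recover period and mRNA peak times
  set.seed(16)
  free <- c("v_per", "v_rev", "dm_rev", "v_bmal1")
  init <- truth
  init$clock[free] <- init$clock[free] * exp(stats::rnorm(4, 0, 0.2))
  fit <- fit_clock(data, init = init, free_names = free, starts = 2,
                   sigma = 0.2, maxit = 120, seed = 7,
                   cycle_days = 18, cycle_transient = 12)
  lc_true <- control_lc()
  lc_fit <- find_limit_cycle(fit$params)
  expect_lt(abs(lc_fit$period_h - lc_true$period_h), 0.1)
  circ_dist <- function(a, b) min((a - b) %% 24, (b - a) %% 24)
  for (g in c("m_per", "m_cry", "m_rev", "m_ror", "m_bmal1")) {
    pk_true <- lc_true$cycle$ct_h[which.max(lc_true$cycle[[g]])]
    pk_fit <- lc_fit$cycle$ct_h[which.max(lc_fit$cycle[[g]])]
    expect_lt(circ_dist(pk_fit, pk_true), 1)
  }
})

test_that("immune fitting recovers cytokine peaks and never touches frozen parameters", {
  truth <- control_params()
  spec <- synthetic_spec(seed = 8, sigma = 0, mode = "model", params = truth,
                         doses = c(3, 6, 12))
  data <- generate_cytokine_series(spec)
  set.seed(17)
  free <- c("immune.k_T", "immune.k_6", "immune.k_10")
  init <- truth
  flat <- par_flatten(init)
  flat[free] <- flat[free] * exp(stats::rnorm(3, 0, 0.2))
  init <- par_unflatten(flat)
  fit <- fit_immune(data, init = init, free_names = free, starts = 1,
                    sigma = 0.15, maxit = 100, seed = 9)
  # frozen blocks byte-identical
  expect_identical(fit$params$clock, init$clock)
  expect_identical(fit$params$immune[c("d_P", "s_IL10", "s_CA")],
                   init$immune[c("d_P", "s_IL10", "s_CA")])
  # recovered peak heights within 5% of the generating truth at both doses
  lc <- control_lc()
  for (d in c(3, 12)) {
    tms <- seq(0.5, 24, 0.5)
    p_true <- predict_cytokines(truth, d, tms, lc = lc)
    p_fit <- predict_cytokines(fit$params, d, tms, lc = lc)
    for (v in c("tnf", "il6", "il10")) {
      expect_lt(abs(max(p_fit[[v]]) - max(p_true[[v]])) / max(p_true[[v]]),
                0.05)
    }
    }
  # held-out 6 mg/kg validation is produced and in line with the fitted doses
  expect_false(is.null(fit$validation))
  fitted_avg <- mean(fit$components)
  expect_lt(mean(fit$validation, na.rm = TRUE), 3 * max(fitted_avg, 1e-4))
})

test_that("zero-percent CJL targets return the baseline unchanged", {
  targets <- generate_cjl_targets("male")
  targets$percent_change <- 0
  fit <- fit_cjl(targets, control_params(), sex = "male", maxit = 60,
                 cycle_days = 20, cycle_transient = 12)
  expect_equal(fit$params$clock, control_params()$clock, tolerance = 1e-8)
  expect_lt(fit$cost, 1e-10)
})
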