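test_that("generators are deterministic under a fixed seed", {
  s <- synthetic_spec(seed = 31, sigma = 0.15)
  expect_identical(generate_clock_series(s), generate_clock_series(s))
  expect_identical(generate_cytokine_series(s), generate_cytokine_series(s))
  s2 <- synthetic_spec(seed = 32, sigma = 0.15)
  expect_false(identical(generate_clock_series(s)$value,
                         generate_clock_series(s2)$value))
})

test_that("noise-free cosinor clock series are 24-h periodic with lung phase order", {
  d <- generate_clock_series(synthetic_spec(seed = 1, sigma = 0))
  for (v in unique(d$variable)) {
    ser <- d[d$variable == v, ]
    first_day <- ser$value[ser$time_h < 24]
    second_day <- ser$value[ser$time_h >= 24 & ser$time_h < 48]
    expect_equal(first_day, second_day, tolerance = 1e-12)
  }
  acro <- vapply(unique(d$variable), function(v) {
    ser <- d[d$variable == v & d$time_h < 24, ]
    (ser$time_h[which.max(ser$value)] + 18) %% 24  # series starts at CT18
  }, numeric(1))
  circ_dist <- function(a, b) min((a - b) %% 24, (b - a) %% 24)
  expect_gt(circ_dist(acro[["m_per"]], acro[["m_bmal1"]]), 9)  # antiphase
  expect_gt(circ_dist(acro[["m_rev"]], acro[["m_ror"]]), 9)
})

test_that("cytokine peak heights increase strictly with dose", {
  d <- generate_cytokine_series(synthetic_spec(seed = 2, sigma = 0))
  for (v in c("tnf", "il6", "il10")) {
    peaks <- vapply(c(3, 6, 12), function(dd) {
      max(d$value[d$variable == v & d$dose == dd])
    }, numeric(1))
    expect_true(all(diff(peaks) > 0))
  }
  # TNF earliest, IL-6 later
  t_peak <- vapply(c("tnf", "il6"), function(v) {
    ser <- d[d$variable == v & d$dose == 3, ]
    ser$time_h[which.max(ser$value)]
  }, numeric(1))
  expect_lt(t_peak[["tnf"]], t_peak[["il6"]])
})

test_that("model-mode noise-free data lie on the generating trajectory", {
  spec <- synthetic_spec(seed = 3, sigma = 0, mode = "model",
                         doses = c(3, 12))
  cyto <- generate_cytokine_series(spec)
  expect_lt(as.numeric(total_cost(control_params(), cyto,
                                  lc = control_lc())), 1e-4)
  clk <- generate_clock_series(spec)
  lc <- control_lc()
  for (v in unique(clk$variable)) {
    ser <- clk[clk$variable == v, ]
    pred <- stats::approx(lc$cycle$ct_h, lc$cycle[[v]],
                          xout = (18 + ser$time_h) %% lc$period_h,
                          rule = 2)$y
    expect_lt(normalized_chi2(pred, ser$value), 1e-3)
  }
})

test_that("a CT12 challenge emits a biphasic IL-10 course", {
  spec <- synthetic_spec(seed = 4, sigma = 0, mode = "model",
                         challenge_ct = 12)
  d <- generate_cytokine_series(spec)
  il10 <- d[d$variable == "il10" & d$dose == 12, ]
  pk <- count_peaks(il10, "value")
  expect_identical(nrow(pk), 2L)
})

test_that("noise changes scatter but not the expected structure", {
  s0 <- synthetic_spec(seed = 5, sigma = 0)
  base <- generate_clock_series(s0)$value
  reps <- vapply(seq_len(50), function(i) {
    generate_clock_series(synthetic_spec(seed = 1000 + i,
                                         sigma = 0.1))$value
  }, numeric(length(base)))
  # lognormal(sigma) has mean exp(sigma^2/2); compare on that scale
  m <- rowMeans(reps)
  se <- apply(reps, 1, stats::sd) / sqrt(ncol(reps))
  expected <- base * exp(0.1^2 / 2)
  frac_within <- mean(abs(m - expected) <= 3 * pmax(se, 1e-12))
  expect_gt(frac_within, 0.95)
})

test_that("CJL targets reproduce the sex-specific table", {
  male <- generate_cjl_targets("male")
  expect_setequal(male$gene, c("rev", "per"))
  expect_equal(male$percent_change[male$gene == "rev"], 98)
  expect_equal(male$percent_change[male$gene == "per"], 230)
  expect_false(any(c("bmal1", "cry", "clock") %in% male$gene))
  female <- generate_cjl_targets("female")
  expect_setequal(female$gene, c("rev", "bmal1", "per", "cry"))
  expect_equal(female$percent_change[female$gene == "per"], 497)
  expect_equal(female$percent_change[female$gene == "rev"], -70)
  expect_equal(female$percent_change[female$gene == "bmal1"], -43)
  expect_equal(female$percent_change[female$gene == "cry"], 69)
  expect_error(generate_cjl_targets("other"))
})

test_that("calibration CSVs round-trip", {
  d <- generate_cytokine_series(synthetic_spec(seed = 6))
  f <- tempfile(fileext = ".csv")
  write_calibration_csv(d, f)
  d2 <- read_calibration_csv(f)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(f)
})
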