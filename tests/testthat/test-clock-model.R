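test_that("zero state yields basal transcription only, no protein fluxes", {
  p <- clock_params_default()
  d <- clock_rhs(rep(0, 12), p, lps_level = 0)
  expect_equal(unname(d[6:12]), rep(0, 7))
  basal <- c(p[["v_per"]] * p[["beta_per"]],
             p[["v_cry"]] * p[["beta_cry"]],
             p[["v_rev"]] * p[["beta_rev"]],
             p[["v_ror"]] * p[["beta_ror"]],
             p[["v_bmal1"]] * p[["beta_bmal1"]])
  expect_equal(unname(d[1:5]), basal)
})

test_that("Bmal1 transcription is monotone in REV-ERB, ROR and the filter", {
  p <- clock_params_default()
  s <- stats::setNames(rep(0.5, 12), clock_state_names())
  d_base <- clock_rhs(s, p)[["m_bmal1"]]
  s_hi_rev <- s; s_hi_rev["p_rev"] <- 5
  expect_lt(clock_rhs(s_hi_rev, p)[["m_bmal1"]], d_base)
  s_hi_ror <- s; s_hi_ror["p_ror"] <- 5
  expect_gt(clock_rhs(s_hi_ror, p)[["m_bmal1"]], d_base)
  # in the limit of saturating REV-ERB, transcription falls toward its floor
  lim <- vapply(c(1, 10, 100, 1000), function(x) {
    s2 <- s; s2["p_rev"] <- x; s2["p_ror"] <- 0
    clock_rhs(s2, p)[["m_bmal1"]]
  }, numeric(1))
  expect_true(all(diff(lim) < 0))
  # endotoxin filter strictly lowers Bmal1 transcription, factor 1 at zero
  for (L in c(0.25, 1, 4)) {
    expect_lt(clock_rhs(s, p, lps_level = L)[["m_bmal1"]], d_base)
  }
  expect_identical(clock_rhs(s, p, lps_level = 0)[["m_bmal1"]], d_base)
})

test_that("endotoxin filter decays linearly to zero over its duration", {
  dr <- lps_drive(challenge_time = 10, amplitude = 1)
  expect_equal(lps_filter(10, dr), 1)
  expect_equal(lps_filter(10 + 24, dr), 0)
  expect_equal(lps_filter(10 + 12, dr), 0.5)
  expect_equal(lps_filter(9.99, dr), 0)
  expect_equal(lps_filter(60, dr), 0)
  # dose-scaled amplitude
  dr2 <- lps_drive(0, amplitude = 4)
  expect_equal(lps_filter(6, dr2), 3)
  expect_equal(lps_filter(numeric(0), dr2), numeric(0))
})

test_that("clock RHS matches the analytic Jacobian by central differences", {
  p <- clock_params_default()
  for (s in random_clock_states(20)) {
    J <- oracle_clock_jacobian(s, p, L = 0.3)
    fn <- function(x) clock_rhs(x, p, lps_level = 0.3)
    for (j in seq_len(12)) {
      fd <- central_diff(fn, s, j)
      scale <- max(abs(J[, j]), 1e-6)
      expect_lt(max(abs(fd - J[, j])) / scale, 1e-5)
    }
  }
})

test_that("knockouts zero one transcription maximum and are idempotent", {
  p <- clock_params_default()
  ko <- apply_knockout(p, "Rev-Erb")
  expect_identical(ko[["v_rev"]], 0)
  expect_identical(ko[setdiff(names(ko), "v_rev")],
                   p[setdiff(names(p), "v_rev")])
  expect_identical(p[["v_rev"]], clock_params_default()[["v_rev"]])
  expect_identical(apply_knockout(ko, "Rev-Erb"), ko)
  ps <- parameter_set()
  expect_identical(apply_knockout(ps, "Bmal1")$clock[["v_bmal1"]], 0)
  expect_error(apply_knockout(p, "Npas2"), "valid")
})

test_that("knocked-out gene products decay to zero under integration", {
  ps <- apply_knockout(parameter_set(), "Rev-Erb")
  tr <- simulate_model(ps, rep(0.5, 12), seq(0, 400, 1))
  expect_lt(tr$m_rev[nrow(tr)], 1e-6)
  expect_lt(tr$p_rev[nrow(tr)], 1e-6)
  ps2 <- apply_knockout(parameter_set(), "Cry")
  tr2 <- simulate_model(ps2, rep(0.5, 12), seq(0, 400, 1))
  expect_lt(tr2$pc[nrow(tr2)], 1e-6)
})

test_that("contract violations are signalled", {
  p <- clock_params_default()
  s <- rep(0.1, 12)
  expect_error(clock_rhs(replace(s, 3, -0.1), p), "negative")
  expect_error(clock_rhs(s, p, lps_level = -1), "negative")
})
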