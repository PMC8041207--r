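#' Clock-protein brakes on cytokine production
#'
#' The circadian clock inhibits the inflammatory response through four
#' repressive Hill factors, each of the form `1 / (1 + (x / K)^h)`: CRY and
#' ROR proteins repress TNF-alpha production, and REV-ERB protein represses
#' IL-6 and IL-10 production. Each factor equals 1 when the repressor is
#' absent and decreases strictly with the repressor level; setting a
#' threshold to `Inf` removes that link.
#'
#' @param p_cry,p_rev,p_ror Clock protein concentrations (a.u., >= 0).
#' @param coupling Named coupling parameter vector
#'   ([coupling_params_default()]).
#' @return Named numeric vector
#'   `(cry_tnf, ror_tnf, rev_il6, rev_il10)`, each in (0, 1].
#' @export
coupling_factors <- function(p_cry, p_rev, p_ror,
                             coupling = coupling_params_default()) {
  if (any(c(p_cry, p_rev, p_ror) < 0)) {
    stop("coupling_factors: negative protein level", call. = FALSE)
  }
  cp <- as.list(coupling)
  c(
    cry_tnf = hill_rep(p_cry, cp$K_cry_tnf, cp$h_cry_tnf),
    ror_tnf = hill_rep(p_ror, cp$K_ror_tnf, cp$h_ror_tnf),
    rev_il6 = hill_rep(p_rev, cp$K_rev_il6, cp$h_rev_il6),
    rev_il10 = hill_rep(p_rev, cp$K_rev_il10, cp$h_rev_il10)
  )
}

#' Right-hand side of the acute-inflammation model
#'
#' Time derivatives of the 8 inflammation variables. Endotoxin `p_endo`
#' clears first-order (`dP/dt = -d_P * P`). Phagocyte activation is driven
#' by endotoxin, TNF-alpha, IL-6 and the damage marker, and inhibited by
#' IL-10 and the slow anti-inflammatory mediator. The damage marker is
#' produced by IL-6 (Hill) and directly by endotoxin. Cytokine production
#' is Hill in activated phagocytes, modulated by the anti-inflammatory
#' inhibitions and by the clock-protein factors of [coupling_factors()]:
#' CRY and ROR on TNF-alpha, REV-ERB on IL-6 and IL-10. IL-6 production is
#' amplified by TNF-alpha; IL-10 production is amplified by IL-6, fed
#' linearly by the tissue-driven promoter `y_il10`, and topped up by the
#' constant source `s_IL10`; the slow mediator has constant source `s_CA`
#' plus phagocyte-driven production.
#'
#' @param state Named or ordered numeric vector of the 8 immune variables
#'   (see [immune_state_names()]); non-negative.
#' @param clock_proteins Numeric vector `(p_cry, p_rev, p_ror)`.
#' @param params Named immune parameter vector
#'   ([immune_params_default()]).
#' @param coupling Named coupling parameter vector.
#' @return Numeric vector of 8 time derivatives.
#' @export
immune_rhs <- function(state, clock_proteins,
                       params = immune_params_default(),
                       coupling = coupling_params_default()) {
  if (any(state < 0) || any(clock_proteins < 0)) {
    stop("immune_rhs: negative state or clock protein input", call. = FALSE)
  }
  q <- as.list(params)
  s <- stats::setNames(as.numeric(state), immune_state_names())
  f <- coupling_factors(clock_proteins[[1]], clock_proteins[[2]],
                        clock_proteins[[3]], coupling)

  g <- function(x, theta) 1 / (1 + (x / theta)^2)

  R <- (q$k_NP * s[["p_endo"]] + q$k_NT * s[["tnf"]] +
          q$k_N6 * s[["il6"]] + q$k_ND * s[["d_dam"]]) *
    g(s[["il10"]], q$theta_N10) * g(s[["c_a"]], q$theta_NCA)

  act_n <- function(x, h) hill_act(s[["n_act"]], x, h)

  prod_tnf <- q$k_T * f[["cry_tnf"]] * f[["ror_tnf"]] *
    g(s[["il10"]], q$theta_T10) * g(s[["c_a"]], q$theta_TCA) *
    act_n(q$x_T, q$h_T)
  prod_il6 <- q$k_6 * f[["rev_il6"]] *
    g(s[["il10"]], q$theta_610) * g(s[["c_a"]], q$theta_6CA) *
    (1 + q$a_6T * hill_act(s[["tnf"]], q$x_6T, q$h_6T)) *
    act_n(q$x_6, q$h_6)
  prod_il10 <- q$s_IL10 + q$k_10 * f[["rev_il10"]] *
    act_n(q$x_10, q$h_10) *
    (1 + q$a_106 * hill_act(s[["il6"]], q$x_106, q$h_106)) +
    q$k_Y10 * s[["y_il10"]]

  c(
    p_endo = -q$d_P * s[["p_endo"]],
    n_act = q$k_N * R / (q$x_N + R) - q$d_N * s[["n_act"]],
    d_dam = q$k_D * hill_act(s[["il6"]], q$x_D, q$h_D) +
      q$k_DP * s[["p_endo"]] - q$d_D * s[["d_dam"]],
    tnf = prod_tnf - q$d_T * s[["tnf"]],
    il6 = prod_il6 - q$d_6 * s[["il6"]],
    il10 = prod_il10 - q$d_10 * s[["il10"]],
    y_il10 = q$k_Y * hill_act(s[["d_dam"]], q$x_Y, q$h_Y) -
      q$d_Y * s[["y_il10"]],
    c_a = q$s_CA + q$k_CA * hill_act(s[["n_act"]], q$x_CA, q$h_CA) -
      q$d_CA * s[["c_a"]]
  )
}
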