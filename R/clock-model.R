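hill_act <- function(x, K, h) {
  xh <- x^h
  xh / (K^h + xh)
}

hill_rep <- function(x, K, h) {
  if (is.infinite(K)) return(rep(1, length(x)))
  1 / (1 + (x / K)^h)
}

#' Endotoxin drive on the circadian clock
#'
#' The sustained suppression of the clock during endotoxemia is represented
#' by a filter: at the challenge time the drive jumps to `amplitude`
#' (proportional to dose, with unit amplitude at 3 mg/kg) and then decays
#' linearly to zero over `duration` hours (24 h by default, matching the
#' duration of circadian disruption after a challenge).
#'
#' @param challenge_time Time of the endotoxin challenge (h, simulation
#'   clock).
#' @param amplitude Dimensionless drive level at the challenge.
#' @param duration Hours over which the drive decays linearly to zero.
#' @return An object of class `lps_drive`.
#' @export
lps_drive <- function(challenge_time = 0, amplitude = 1, duration = 24) {
  stopifnot(is.finite(challenge_time), amplitude >= 0, duration > 0)
  structure(list(challenge_time = challenge_time, amplitude = amplitude,
                 duration = duration),
            class = "lps_drive")
}

#' Evaluate the endotoxin filter
#'
#' Piecewise-linear drive level: zero before the challenge, `amplitude` at
#' the challenge, decaying linearly to zero over the drive's duration.
#'
#' @param t Time (h); may be a vector.
#' @param drive An [lps_drive()] object, or `NULL` for no challenge.
#' @return Non-negative drive level(s).
#' @export
lps_filter <- function(t, drive) {
  if (is.null(drive)) return(rep(0, length(t)))
  stopifnot(inherits(drive, "lps_drive"), all(is.finite(t)))
  dt <- t - drive$challenge_time
  out <- drive$amplitude * pmax(0, 1 - dt / drive$duration)
  out[dt < 0] <- 0
  out
}

#' Right-hand side of the lung circadian clock model
#'
#' Time derivatives of the 12 clock variables. Transcription of Per, Cry,
#' Rev-Erb and Ror is activated by the CLOCK-BMAL1 complex (cb) and
#' repressed by the PER-CRY complex (pc); Cry transcription carries an extra
#' REV-ERB repression. Bmal1 transcription is activated by ROR protein,
#' repressed by REV-ERB protein (competition for the RRE site, reduced to a
#' multiplicative activator x repressor product) and inhibited by the
#' endotoxin filter through the factor `1 / (1 + k_lps * lps_level)`.
#' Proteins follow linear translation/degradation, with PER and CRY also
#' exchanging with the PER-CRY complex and BMAL1 with the CLOCK-BMAL1
#' complex (CLOCK is constitutive at level `clock0`).
#'
#' @param state Named or ordered numeric vector of the 12 clock variables
#'   (see [clock_state_names()]); must be non-negative.
#' @param params Named clock parameter vector ([clock_params_default()]).
#' @param lps_level Non-negative endotoxin drive level (see [lps_filter()]).
#' @return Numeric vector of 12 time derivatives (a.u./h).
#' @export
clock_rhs <- function(state, params, lps_level = 0) {
  if (any(state < 0) || lps_level < 0) {
    stop("clock_rhs: negative state component or lps_level", call. = FALSE)
  }
  p <- as.list(params)
  s <- stats::setNames(as.numeric(state), clock_state_names())

  act_cb <- function(K, h) hill_act(s[["cb"]], K, h)
  rep_pc <- function(K, h) hill_rep(s[["pc"]], K, h)

  tx_per <- p$v_per * (p$beta_per + (1 - p$beta_per) *
                         act_cb(p$K_cb_per, p$h_cb_per)) *
    rep_pc(p$K_pc_per, p$h_pc_per)
  tx_cry <- p$v_cry * (p$beta_cry + (1 - p$beta_cry) *
                         act_cb(p$K_cb_cry, p$h_cb_cry)) *
    rep_pc(p$K_pc_cry, p$h_pc_cry) *
    hill_rep(s[["p_rev"]], p$K_revcry, p$h_revcry)
  tx_rev <- p$v_rev * (p$beta_rev + (1 - p$beta_rev) *
                         act_cb(p$K_cb_rev, p$h_cb_rev)) *
    rep_pc(p$K_pc_rev, p$h_pc_rev)
  tx_ror <- p$v_ror * (p$beta_ror + (1 - p$beta_ror) *
                         act_cb(p$K_cb_ror, p$h_cb_ror)) *
    rep_pc(p$K_pc_ror, p$h_pc_ror)
  tx_bmal1 <- p$v_bmal1 *
    (p$beta_bmal1 + (1 - p$beta_bmal1) *
       hill_act(s[["p_ror"]], p$K_ror, p$h_ror)) *
    hill_rep(s[["p_rev"]], p$K_rev, p$h_rev) /
    (1 + p$k_lps * lps_level)

  flux_pc <- p$kf_pc * s[["p_per"]] * s[["p_cry"]]
  flux_cb <- p$kf_cb * s[["p_bmal1"]] * p$clock0

  c(
    m_per = tx_per - p$dm_per * s[["m_per"]],
    m_cry = tx_cry - p$dm_cry * s[["m_cry"]],
    m_rev = tx_rev - p$dm_rev * s[["m_rev"]],
    m_ror = tx_ror - p$dm_ror * s[["m_ror"]],
    m_bmal1 = tx_bmal1 - p$dm_bmal1 * s[["m_bmal1"]],
    p_per = p$kp_per * s[["m_per"]] - p$dp_per * s[["p_per"]] -
      flux_pc + p$kb_pc * s[["pc"]],
    p_cry = p$kp_cry * s[["m_cry"]] - p$dp_cry * s[["p_cry"]] -
      flux_pc + p$kb_pc * s[["pc"]],
    p_rev = p$kp_rev * s[["m_rev"]] - p$dp_rev * s[["p_rev"]],
    p_ror = p$kp_ror * s[["m_ror"]] - p$dp_ror * s[["p_ror"]],
    p_bmal1 = p$kp_bmal1 * s[["m_bmal1"]] - p$dp_bmal1 * s[["p_bmal1"]] -
      flux_cb + p$kb_cb * s[["cb"]],
    pc = flux_pc - (p$kb_pc + p$d_pc) * s[["pc"]],
    cb = flux_cb - (p$kb_cb + p$d_cb) * s[["cb"]]
  )
}

#' Knock out a clock gene
#'
#' A knockout is encoded by setting the gene's maximal transcription rate to
#' exactly zero, leaving every other parameter untouched.
#'
#' @param params Either a named clock parameter vector or a
#'   `parameter_set`.
#' @param gene One of `"Per"`, `"Cry"`, `"Rev-Erb"`, `"Ror"`, `"Bmal1"`
#'   (case-insensitive; `"Rev"` is accepted for `"Rev-Erb"`).
#' @return Object of the same type as `params` with the knockout applied.
#' @export
apply_knockout <- function(params, gene) {
  key <- switch(tolower(gene),
                per = "v_per", cry = "v_cry",
                "rev-erb" = "v_rev", rev = "v_rev", reverb = "v_rev",
                ror = "v_ror", bmal1 = "v_bmal1",
                stop("unknown gene '", gene,
                     "'; valid: Per, Cry, Rev-Erb, Ror, Bmal1",
                     call. = FALSE))
  if (inherits(params, "parameter_set")) {
    params$clock[key] <- 0
    params
  } else {
    stopifnot(is.numeric(params), key %in% names(params))
    params[key] <- 0
    params
  }
}
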