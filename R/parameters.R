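#' Nominal clock parameters
#'
#' Named vector of kinetic parameters for the 12-variable lung circadian
#' clock model: per-gene maximal transcription rates (`v_*`, a.u./h), basal
#' transcription fractions (`beta_*`, dimensionless), CLOCK-BMAL1 activation
#' thresholds and Hill exponents (`K_cb_*`, `h_cb_*`), PER-CRY repression
#' thresholds/exponents (`K_pc_*`, `h_pc_*`), the extra REV-ERB repression of
#' Cry (`K_revcry`, `h_revcry`), ROR activation and REV-ERB repression of
#' Bmal1 (`K_ror`, `h_ror`, `K_rev`, `h_rev`), mRNA degradation rates
#' (`dm_*`, 1/h), translation rates (`kp_*`, 1/h), protein degradation rates
#' (`dp_*`, 1/h), complex association/dissociation/degradation rates
#' (`kf_pc`, `kb_pc`, `d_pc`, `kf_cb`, `kb_cb`, `d_cb`), the constitutive
#' CLOCK protein level (`clock0`, a.u.) and the endotoxin-filter inhibition
#' gain on Bmal1 transcription (`k_lps`).
#'
#' Values are the shipped nominal set, calibrated against the packaged
#' synthetic lung clock-gene dataset and time-rescaled so the free-running
#' period is 24 h.
#'
#' @return Named numeric vector.
#' @export
clock_params_default <- function() {
  c(
    v_per = 0.82185386, v_cry = 0.35373577, v_rev = 7.5368508,
    v_ror = 5.2560409, v_bmal1 = 2.8593752, beta_per = 0.02,
    beta_cry = 0.05, beta_rev = 0.01, beta_ror = 0.02,
    beta_bmal1 = 0.34947918, K_cb_per = 0.28863732, K_cb_cry = 0.31036194,
    K_cb_rev = 0.83644293, K_cb_ror = 0.15634156, h_cb_per = 6.4603781,
    h_cb_cry = 2.3624769, h_cb_rev = 6.6554396, h_cb_ror = 1,
    K_pc_per = 3.1406862, K_pc_cry = 1.3320381, K_pc_rev = 1.6452896,
    K_pc_ror = 0.92310369, h_pc_per = 8, h_pc_cry = 5.8890401,
    h_pc_rev = 4.6389878, h_pc_ror = 5.3589723, K_revcry = 14.507195,
    h_revcry = 2.556179, K_ror = 1.1794752, h_ror = 6.2609101,
    K_rev = 0.91068451, h_rev = 7.1165656, dm_per = 0.20947538,
    dm_cry = 0.088249223, dm_rev = 0.40976482, dm_ror = 2.5363133,
    dm_bmal1 = 0.69752415, kp_per = 0.35932494, kp_cry = 0.36593385,
    kp_rev = 0.72649356, kp_ror = 2.2972451, kp_bmal1 = 0.56390444,
    dp_per = 0.19470472, dp_cry = 0.037256609, dp_rev = 0.45241923,
    dp_ror = 1.0848927, dp_bmal1 = 0.21483348, kf_pc = 1.8706719,
    kb_pc = 0.11832323, d_pc = 0.57454021, kf_cb = 1.620559,
    kb_cb = 0.059161615, d_cb = 0.18958265, clock0 = 1,
    k_lps = 8
  )
}

#' Nominal immune parameters
#'
#' Named vector of parameters for the 8-variable acute-inflammation model.
#' `d_P` (endotoxin clearance, 1/h) is literature-fixed; `s_IL10` and `s_CA`
#' (baseline sources, a.u./h) are extracted directly from resting cytokine
#' levels; both are held frozen during fitting. The remaining parameters are
#' activation gains feeding phagocyte activation (`k_NP`, `k_NT`, `k_N6`,
#' `k_ND`), anti-inflammatory inhibition thresholds (`theta_*`), Hill
#' production maxima/half-saturations/exponents for each mediator, and
#' first-order decay rates (`d_*`, 1/h).
#'
#' @return Named numeric vector.
#' @export
immune_params_default <- function() {
  c(
    d_P = 3, k_NP = 5.3378018, k_NT = 0.52898068,
    k_N6 = 0.063005273, k_ND = 0.0035255017, theta_N10 = 0.23892368,
    theta_NCA = 1.895324, k_N = 1.2859377, x_N = 1.1868698,
    d_N = 0.73845763, k_D = 0.47761397, x_D = 0.4394459,
    h_D = 3, k_DP = 0.0090519491, d_D = 0.1272892,
    k_T = 27.321948, x_T = 0.54039795, h_T = 1.5,
    theta_T10 = 0.15400463, theta_TCA = 0.77280366, d_T = 1.3684361,
    k_6 = 6.9590719, x_6 = 0.90760213, h_6 = 1.5,
    theta_610 = 0.19096438, theta_6CA = 0.62939742, a_6T = 3.6235108,
    x_6T = 2.39956, h_6T = 2, d_6 = 1.2683956,
    s_IL10 = 0.025, k_10 = 0.75835524, x_10 = 0.29922467,
    h_10 = 1.5, a_106 = 2.7329564, x_106 = 1.1585186,
    h_106 = 2, k_Y10 = 0.89063851, d_10 = 0.78675319,
    k_Y = 0.22913319, x_Y = 17.844063, h_Y = 2,
    d_Y = 0.51517553, s_CA = 0.03, k_CA = 0.097936037,
    x_CA = 0.87315889, h_CA = 2, d_CA = 0.14027464
  )
}

#' Nominal clock-to-immune coupling parameters
#'
#' Repression thresholds (`K_*`) and Hill exponents (`h_*`) for the four
#' clock-protein brakes on cytokine production: CRY and ROR on TNF-alpha,
#' REV-ERB on IL-6 and on IL-10. Each factor has the form
#' `1 / (1 + (x / K)^h)`; sending a threshold to `Inf` removes that link.
#'
#' @return Named numeric vector.
#' @export
coupling_params_default <- function() {
  c(
    K_cry_tnf = 0.083509033, h_cry_tnf = 2.8761331, K_ror_tnf = 8.2140761,
    h_ror_tnf = 2.1324355, K_rev_il6 = 63.964529, h_rev_il6 = 4.5340992,
    K_rev_il10 = 6.7632287, h_rev_il10 = 1.5705977
  )
}

#' Assemble a parameter set
#'
#' Bundles clock, immune and coupling parameter vectors with a condition tag
#' into a `parameter_set` object, the unit every simulation and fitting
#' function consumes. Defaults are the shipped nominal (control) values.
#'
#' @param clock,immune,coupling Named numeric vectors; see
#'   [clock_params_default()], [immune_params_default()],
#'   [coupling_params_default()].
#' @param condition One of `"control"`, `"cjl_male"`, `"cjl_female"`.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(clock = clock_params_default(),
                          immune = immune_params_default(),
                          coupling = coupling_params_default(),
                          condition = "control") {
  condition <- match.arg(condition, c("control", "cjl_male", "cjl_female"))
  stopifnot(is.numeric(clock), is.numeric(immune), is.numeric(coupling))
  validate_param_block(clock, clock_params_default(), "clock")
  validate_param_block(immune, immune_params_default(), "immune")
  validate_param_block(coupling, coupling_params_default(), "coupling")
  structure(
    list(clock = clock, immune = immune, coupling = coupling,
         condition = condition),
    class = "parameter_set"
  )
}

validate_param_block <- function(x, template, label) {
  missing <- setdiff(names(template), names(x))
  extra <- setdiff(names(x), names(template))
  if (length(missing) || length(extra)) {
    stop(sprintf("invalid %s parameters; missing: [%s], unknown: [%s]",
                 label, paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(x)) && !all(is.infinite(x[!is.finite(x)]))) {
    stop(sprintf("non-finite %s parameter", label), call. = FALSE)
  }
  if (any(x < 0)) {
    stop(sprintf("negative %s parameter: %s", label,
                 paste(names(x)[x < 0], collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> condition:", x$condition, "\n")
  cat("  clock:   ", length(x$clock), "parameters\n")
  cat("  immune:  ", length(x$immune), "parameters\n")
  cat("  coupling:", length(x$coupling), "parameters\n")
  invisible(x)
}

#' Default parameter set for a study condition
#'
#' Returns the shipped calibrated parameter set for the requested condition.
#' The control set is the nominal calibration; the chronic-jet-lag (CJL)
#' male/female sets are the sex-specific recalibrations shipped with the
#' package (reproducible via [fit_cjl()]).
#'
#' @param condition `"control"`, `"cjl_male"` or `"cjl_female"`.
#' @return A `parameter_set`.
#' @export
default_parameters <- function(condition = "control") {
  condition <- match.arg(condition, c("control", "cjl_male", "cjl_female"))
  path <- system.file("extdata",
                      paste0("params_", condition, ".json"),
                      package = "immunoclock")
  if (nzchar(path)) {
    read_parameter_file(path)
  } else {
    stop("shipped parameter file for condition '", condition, "' not found",
         call. = FALSE)
  }
}

#' Flatten / unflatten parameter sets
#'
#' `par_flatten()` turns a `parameter_set` into a single named vector with
#' `clock.`/`immune.`/`coupling.` namespaced keys (the representation used
#' by parameter files and by the fitting routines); `par_unflatten()`
#' inverts it.
#'
#' @param ps A `parameter_set`.
#' @return `par_flatten()`: named numeric vector. `par_unflatten()`: a
#'   `parameter_set`.
#' @export
par_flatten <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  out <- c(stats::setNames(ps$clock, paste0("clock.", names(ps$clock))),
           stats::setNames(ps$immune, paste0("immune.", names(ps$immune))),
           stats::setNames(ps$coupling,
                           paste0("coupling.", names(ps$coupling))))
  out
}

#' @rdname par_flatten
#' @param x Named numeric vector with namespaced keys.
#' @param condition Condition tag for the rebuilt set.
#' @export
par_unflatten <- function(x, condition = "control") {
  pick <- function(prefix) {
    keys <- grep(paste0("^", prefix, "\\."), names(x), value = TRUE)
    stats::setNames(as.numeric(x[keys]), sub(paste0("^", prefix, "\\."), "", keys))
  }
  parameter_set(clock = pick("clock"), immune = pick("immune"),
                coupling = pick("coupling"), condition = condition)
}

#' Read / write parameter files
#'
#' Parameter files are flat key-value JSON: one entry per namespaced
#' parameter (`clock.v_per`, `immune.d_P`, `coupling.K_rev_il10`, ...) plus
#' a `"condition"` string.
#'
#' @param path File path.
#' @return `read_parameter_file()`: a `parameter_set`.
#' @export
read_parameter_file <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  condition <- raw$condition %||% "control"
  raw$condition <- NULL
  vals <- vapply(raw, function(v) as.numeric(v[[1]]), numeric(1))
  # "Inf" round-trips as string in JSON
  par_unflatten(vals, condition = condition)
}

#' @rdname read_parameter_file
#' @param ps A `parameter_set` to serialise.
#' @export
write_parameter_file <- function(ps, path) {
  flat <- as.list(par_flatten(ps))
  flat <- c(list(condition = ps$condition), flat)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clock state and immune state templates
#'
#' Canonical variable orderings. The clock block has 12 components (five
#' mRNAs, five proteins, the PER-CRY and CLOCK-BMAL1 complexes); the immune
#' block has 8 (endotoxin `p_endo`, activated phagocytes `n_act`, damage
#' marker `d_dam`, the cytokines `tnf`, `il6`, `il10`, the tissue-driven
#' IL-10 promoter `y_il10` and the slow anti-inflammatory mediator `c_a`).
#'
#' @return Character vector of state-variable names.
#' @export
clock_state_names <- function() {
  c("m_per", "m_cry", "m_rev", "m_ror", "m_bmal1",
    "p_per", "p_cry", "p_rev", "p_ror", "p_bmal1", "pc", "cb")
}

#' @rdname clock_state_names
#' @export
immune_state_names <- function() {
  c("p_endo", "n_act", "d_dam", "tnf", "il6", "il10", "y_il10", "c_a")
}

#' Infection-free rest state of the immune block
#'
#' All immune variables are zero except IL-10 and the slow anti-inflammatory
#' mediator, which rest at the baselines `s_IL10 / d_10` and `s_CA / d_CA`
#' set by their constant sources.
#'
#' @param immune Named immune parameter vector.
#' @return Named numeric vector of length 8.
#' @export
immune_rest_state <- function(immune = immune_params_default()) {
  out <- stats::setNames(numeric(8), immune_state_names())
  out["il10"] <- immune[["s_IL10"]] / immune[["d_10"]]
  out["c_a"] <- immune[["s_CA"]] / immune[["d_CA"]]
  out
}
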