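#' Specify a synthetic dataset
#'
#' Bundles the knobs of the synthetic-data generators: seed, multiplicative
#' lognormal noise level, sampling design and generation mode.
#' `"cosinor"` mode draws phenomenological curves (cosinor rhythms for
#' clock genes, gamma-shaped pulses for cytokines) with lung-typical phase
#' structure; `"model"` mode samples trajectories of a ground-truth
#' parameter set, closing the loop for parameter-recovery studies.
#'
#' @param seed Integer RNG seed, recorded in every emitted dataset.
#' @param sigma Lognormal noise sigma (0 = noise-free).
#' @param mode `"cosinor"` or `"model"`.
#' @param params Ground-truth `parameter_set` for model mode (default: the
#'   shipped control set).
#' @param clock_interval_h Clock sampling interval (h); series span 48 h.
#' @param clock_start_ct Circadian time of the first clock sample (data
#'   collection conventionally starts at CT18 after release into constant
#'   darkness).
#' @param cytokine_times_h Post-challenge sampling times (h), bracketing
#'   the early (~1 h) and late (10-12 h) cytokine features.
#' @param doses Endotoxin doses to emit (mg/kg).
#' @param challenge_ct Circadian time of the emulated challenge.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, sigma = 0.1,
                           mode = c("cosinor", "model"), params = NULL,
                           clock_interval_h = 2, clock_start_ct = 18,
                           cytokine_times_h = c(0.5, 1, 2, 4, 6, 8, 12, 24),
                           doses = c(3, 6, 12), challenge_ct = 12) {
  mode <- match.arg(mode)
  stopifnot(sigma >= 0, all(doses > 0), clock_interval_h > 0)
  structure(
    list(seed = as.integer(seed), sigma = sigma, mode = mode,
         params = params, clock_interval_h = clock_interval_h,
         clock_start_ct = clock_start_ct,
         cytokine_times_h = sort(cytokine_times_h), doses = sort(doses),
         challenge_ct = challenge_ct),
    class = "synthetic_spec"
  )
}

apply_noise <- function(x, sigma) {
  if (sigma <= 0) return(x)
  x * exp(stats::rnorm(length(x), 0, sigma))
}

# Lung-typical cosinor shapes: Bmal1 in antiphase to Per, Rev-Erb peaking
# between them, Ror in antiphase to Rev-Erb; period exactly 24 h.
cosinor_shapes <- tibble::tibble(
  variable = c("m_per", "m_cry", "m_rev", "m_ror", "m_bmal1"),
  mesor = c(1.0, 0.8, 1.4, 0.7, 0.9),
  rel_amp = c(0.75, 0.55, 0.90, 0.50, 0.85),
  acrophase_ct = c(10, 14, 6, 18, 22)
)

#' Generate synthetic lung clock-gene series
#'
#' Five mRNA series over 48 h. Cosinor mode: 24-h-periodic cosine curves
#' with lung-typical phase ordering and multiplicative lognormal noise.
#' Model mode: samples of the ground-truth parameter set's limit cycle
#' plus noise.
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble with columns `variable`, `dose` (`NA`: infection-free),
#'   `time_h`, `value`; attributes `seed`, `sigma`, `mode`.
#' @export
generate_clock_series <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  times <- seq(0, 48, by = spec$clock_interval_h)
  if (spec$mode == "cosinor") {
    out <- purrr::pmap_dfr(cosinor_shapes, function(variable, mesor, rel_amp,
                                                    acrophase_ct) {
      ct <- (spec$clock_start_ct + times) %% 24
      v <- mesor * (1 + rel_amp * cos(2 * pi * (ct - acrophase_ct) / 24))
      tibble::tibble(variable = variable, dose = NA_real_, time_h = times,
                     value = apply_noise(v, spec$sigma))
    })
  } else {
    ps <- spec$params %||% default_parameters()
    lc <- find_limit_cycle(ps)
    out <- purrr::map_dfr(cosinor_shapes$variable, function(v) {
      ct <- (spec$clock_start_ct + times) %% lc$period_h
      val <- stats::approx(lc$cycle$ct_h, lc$cycle[[v]], xout = ct,
                           rule = 2)$y
      tibble::tibble(variable = v, dose = NA_real_, time_h = times,
                     value = apply_noise(val, spec$sigma))
    })
  }
  attr(out, "seed") <- spec$seed
  attr(out, "sigma") <- spec$sigma
  attr(out, "mode") <- spec$mode
  out
}

gamma_pulse <- function(t, t_peak, shape) {
  rate <- shape / t_peak
  v <- (t / t_peak)^shape * exp(shape - rate * t)
  v[t < 0] <- 0
  v
}

#' Generate synthetic endotoxemia cytokine series
#'
#' Per dose: TNF-alpha peaking earliest, IL-6 later, IL-10 mono- or
#' biphasic (a weak early pulse plus a dominant late pulse when the
#' emulated challenge falls in the late rest phase, a single early pulse
#' otherwise). Peak heights increase strictly with dose. Cosinor mode uses
#' gamma-pulse mixtures; model mode samples simulated challenge
#' trajectories of the ground-truth parameter set.
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble with columns `variable` (`"tnf"`, `"il6"`, `"il10"`),
#'   `dose`, `time_h`, `value`; attributes as in
#'   [generate_clock_series()].
#' @export
generate_cytokine_series <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  times <- spec$cytokine_times_h
  biphasic <- spec$challenge_ct >= 7 && spec$challenge_ct <= 16
  if (spec$mode == "cosinor") {
    out <- purrr::map_dfr(spec$doses, function(d) {
      a <- (d / 3)^0.8  # strictly increasing, mildly saturating dose scale
      tnf <- 9 * a * gamma_pulse(times, 1.5, 2.5)
      il6 <- 5 * a * gamma_pulse(times, 4, 2)
      il10 <- if (biphasic) {
        0.5 * a * gamma_pulse(times, 1.5, 2) + 1.6 * a * gamma_pulse(times, 12, 4)
      } else {
        1.8 * a * gamma_pulse(times, 2.5, 2)
      }
      tibble::tibble(variable = rep(c("tnf", "il6", "il10"), each = length(times)),
                     dose = d, time_h = rep(times, 3),
                     value = apply_noise(c(tnf, il6, il10), spec$sigma))
    })
  } else {
    ps <- spec$params %||% default_parameters()
    lc <- find_limit_cycle(ps)
    out <- purrr::map_dfr(spec$doses, function(d) {
      pred <- predict_cytokines(ps, d, times, spec$challenge_ct, lc = lc)
      tibble::tibble(variable = rep(c("tnf", "il6", "il10"), each = length(times)),
                     dose = d, time_h = rep(times, 3),
                     value = apply_noise(c(pred$tnf, pred$il6, pred$il10),
                                         spec$sigma))
    })
  }
  attr(out, "seed") <- spec$seed
  attr(out, "sigma") <- spec$sigma
  attr(out, "mode") <- spec$mode
  out
}

#' Chronic-jet-lag mean-expression-change targets
#'
#' Sex-specific percent changes of 24-h mean clock-gene mRNA under chronic
#' jet lag, as measured by qPCR in mouse lung: males up-regulate Rev-Erb
#' (+98%) and Per (+230%); females down-regulate Rev-Erb (-70%) and Bmal1
#' (-43%) and up-regulate Per (+497%) and Cry (+69%). Cry up-regulation is
#' not significant in males (no male Cry target), Ror was not assayed, and
#' the male Clock decrease is not represented because CLOCK is constitutive
#' in this model.
#'
#' @param sex `"male"` or `"female"`.
#' @return Tibble with columns `gene`, `sex`, `percent_change`.
#' @export
generate_cjl_targets <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male") {
    tibble::tibble(gene = c("rev", "per"), sex = sex,
                   percent_change = c(98, 230))
  } else {
    tibble::tibble(gene = c("rev", "bmal1", "per", "cry"), sex = sex,
                   percent_change = c(-70, -43, 497, 69))
  }
}

#' Read / write calibration datasets
#'
#' CSV dialect shared by the generators and the calibration functions:
#' columns `variable`, `dose` (number, or empty for infection-free clock
#' series), `time_h`, `value`.
#'
#' @param data Tibble as produced by the generators.
#' @param path File path.
#' @return `read_calibration_csv()`: the tibble.
#' @export
write_calibration_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
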