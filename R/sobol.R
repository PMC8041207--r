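#' Variance-based (Sobol') sensitivity indices for a vector function
#'
#' Saltelli-style sampling: two independent uniform matrices A and B of
#' size `n_base` x k are drawn over `bounds`, plus the k radial matrices
#' AB_i (A with column i replaced from B). First-order indices use the
#' Saltelli (2010) estimator `mean(f_B * (f_ABi - f_A)) / V`; total-order
#' indices use the Jansen estimator `mean((f_A - f_ABi)^2) / (2 V)`.
#' Confidence intervals come from a percentile bootstrap over sample rows.
#' Rows where `fn` fails or returns non-finite output are dropped and
#' counted; more than 5 percent failures aborts.
#'
#' @param fn Function taking a numeric matrix (rows = parameter vectors,
#'   named columns) and returning a numeric matrix/data frame with one row
#'   per input row and one named column per output (or a vector for a
#'   single output).
#' @param bounds Named list of `c(lower, upper)` per parameter.
#' @param n_base Base sample size (>= 256); total evaluations are
#'   `n_base * (k + 2)`.
#' @param seed RNG seed (sampling and bootstrap).
#' @param n_boot Bootstrap replicates for the confidence intervals.
#' @param conf Confidence level.
#' @return A `sobol_result`: tibble with columns `output`, `parameter`,
#'   `first_order`, `first_lo`, `first_hi`, `total_order`, `total_lo`,
#'   `total_hi`, plus attributes `n_base`, `seed` and `n_failed`.
#' @export
sobol_indices <- function(fn, bounds, n_base = 512, seed = 1,
                          n_boot = 200, conf = 0.95) {
  stopifnot(n_base >= 256, length(bounds) >= 1)
  k <- length(bounds)
  pars <- names(bounds)
  stopifnot(!is.null(pars), all(nzchar(pars)))
  set.seed(seed)

  scale01 <- function(u) {
    out <- u
    for (j in seq_len(k)) {
      b <- bounds[[j]]
      out[, j] <- b[1] + u[, j] * (b[2] - b[1])
    }
    colnames(out) <- pars
    out
  }
  A <- scale01(matrix(stats::runif(n_base * k), n_base, k))
  B <- scale01(matrix(stats::runif(n_base * k), n_base, k))

  eval_mat <- function(X) {
    out <- tryCatch(fn(X), error = function(e) NULL)
    if (is.null(out)) return(matrix(NA_real_, nrow(X), 1))
    if (is.null(dim(out))) out <- matrix(out, ncol = 1,
                                         dimnames = list(NULL, "y"))
    as.matrix(out)
  }
  fA <- eval_mat(A)
  fB <- eval_mat(B)
  outs <- colnames(fA)
  if (is.null(outs)) outs <- paste0("y", seq_len(ncol(fA)))
  fAB <- lapply(seq_len(k), function(i) {
    ABi <- A
    ABi[, i] <- B[, i]
    eval_mat(ABi)
  })

  ok <- stats::complete.cases(fA) & stats::complete.cases(fB)
  for (i in seq_len(k)) ok <- ok & stats::complete.cases(fAB[[i]])
  n_failed <- sum(!ok)
  if (n_failed > 0.05 * n_base) {
    stop(sprintf("sobol_indices: %d of %d samples failed (> 5%%)",
                 n_failed, n_base), call. = FALSE)
  }

  estimate <- function(a, b, abi) {
    v <- stats::var(c(a, b))
    if (v <= 0) return(c(first = 0, total = 0))
    c(first = mean(b * (abi - a)) / v,
      total = mean((a - abi)^2) / (2 * v))
  }

  rows <- list()
  alpha <- (1 - conf) / 2
  for (m in seq_along(outs)) {
    a <- fA[ok, m]; b <- fB[ok, m]
    for (i in seq_len(k)) {
      abi <- fAB[[i]][ok, m]
      est <- estimate(a, b, abi)
      boot <- replicate(n_boot, {
        idx <- sample.int(length(a), replace = TRUE)
        estimate(a[idx], b[idx], abi[idx])
      })
      rows[[length(rows) + 1L]] <- tibble::tibble(
        output = outs[m], parameter = pars[i],
        first_order = est[["first"]],
        first_lo = stats::quantile(boot["first", ], alpha, names = FALSE),
        first_hi = stats::quantile(boot["first", ], 1 - alpha, names = FALSE),
        total_order = est[["total"]],
        total_lo = stats::quantile(boot["total", ], alpha, names = FALSE),
        total_hi = stats::quantile(boot["total", ], 1 - alpha, names = FALSE))
    }
  }
  res <- dplyr::bind_rows(rows)
  attr(res, "n_base") <- n_base
  attr(res, "seed") <- seed
  attr(res, "n_failed") <- n_failed
  class(res) <- c("sobol_result", class(res))
  res
}

#' Sobol' sensitivity of model summaries to parameters
#'
#' Global sensitivity screen of the coupled model: parameters in
#' `free_names` (namespaced as in [par_flatten()]) are varied uniformly
#' within `span` of their nominal values and the requested experiment
#' summaries are recomputed per sample. Outputs available: `"period"`
#' (free-running period, h), `"peak_il6"`, `"peak_tnf"`, `"peak_il10"` and
#' `"severity"` (from a challenge at `dose` mg/kg, CT `challenge_ct`).
#'
#' This is a heavy computation: `n_base * (k + 2)` model runs.
#'
#' @param params Nominal `parameter_set`.
#' @param free_names Namespaced parameter names to vary.
#' @param outputs Subset of the outputs above.
#' @param n_base Base sample size (>= 256).
#' @param seed RNG seed.
#' @param span Relative half-width of the uniform bounds (default 0.5, i.e.
#'   nominal x [0.5, 1.5]).
#' @param dose,challenge_ct Challenge used for the immune outputs.
#' @param ... Passed to [sobol_indices()].
#' @return A `sobol_result`.
#' @export
sobol_sensitivity <- function(params, free_names,
                              outputs = c("peak_il6", "severity"),
                              n_base = 256, seed = 1, span = 0.5,
                              dose = 3, challenge_ct = 12, ...) {
  stopifnot(inherits(params, "parameter_set"))
  outputs <- match.arg(outputs, c("period", "peak_il6", "peak_tnf",
                                  "peak_il10", "severity"),
                       several.ok = TRUE)
  flat0 <- par_flatten(params)
  stopifnot(all(free_names %in% names(flat0)))
  bounds <- lapply(free_names, function(nm) {
    flat0[[nm]] * c(1 - span, 1 + span)
  })
  names(bounds) <- free_names

  model_fn <- function(X) {
    out <- matrix(NA_real_, nrow(X), length(outputs),
                  dimnames = list(NULL, outputs))
    for (r in seq_len(nrow(X))) {
      flat <- flat0
      flat[colnames(X)] <- X[r, ]
      ps <- tryCatch(par_unflatten(flat, condition = params$condition),
                     error = function(e) NULL)
      if (is.null(ps)) next
      res <- tryCatch({
        lc <- find_limit_cycle(ps, days = 30, transient_days = 20,
                               n_cycles = 5, dt = 0.1)
        vals <- c(period = lc$period_h)
        if (any(outputs != "period")) {
          ex <- run_experiment(
            experiment_spec(dose = dose, challenge_ct = challenge_ct),
            ps, lc = lc, dt = 0.05)
          vals <- c(vals,
                    peak_il6 = ex$peaks$peak[ex$peaks$variable == "il6"],
                    peak_tnf = ex$peaks$peak[ex$peaks$variable == "tnf"],
                    peak_il10 = ex$peaks$peak[ex$peaks$variable == "il10"],
                    severity = ex$severity)
        }
        vals
      }, error = function(e) NULL)
      if (!is.null(res)) out[r, ] <- res[outputs]
    }
    out
  }
  sobol_indices(model_fn, bounds, n_base = n_base, seed = seed, ...)
}
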