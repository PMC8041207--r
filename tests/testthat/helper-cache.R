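# Expensive shared objects, computed at most once per test run.
.ic_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .ic_cache)) {
    assign(key, force(expr), envir = .ic_cache)
  }
  get(key, envir = .ic_cache)
}

control_params <- function() default_parameters("control")

control_lc <- function() {
  cached("control_lc", find_limit_cycle(control_params()))
}

# One CJL recalibration per sex per test run (shared by the mean-change and
# severity-ordering tests).
cjl_fit_cached <- function(sex) {
  cached(paste0("cjl_", sex),
         fit_cjl(generate_cjl_targets(sex), control_params(), sex = sex))
}

# Random non-negative states for derivative checks.
random_clock_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    stats::setNames(stats::runif(12, 0.05, 3), clock_state_names())
  })
}

random_immune_states <- function(n, seed = 43) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    stats::setNames(stats::runif(8, 0.05, 3), immune_state_names())
  })
}
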