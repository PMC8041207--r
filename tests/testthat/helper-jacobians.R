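# Independently coded analytic Jacobians of the two right-hand sides,
# used as oracles against central finite differences of the package RHS.
# Derivative building blocks (coded from the Hill forms directly, not by
# reusing package internals):
d_act <- function(x, K, h) {
  # d/dx [x^h / (K^h + x^h)]
  h * K^h * x^(h - 1) / (K^h + x^h)^2
}
d_rep <- function(x, K, h) {
  # d/dx [1 / (1 + (x/K)^h)]
  if (is.infinite(K)) return(0)
  -(h / K) * (x / K)^(h - 1) / (1 + (x / K)^h)^2
}
o_act <- function(x, K, h) x^h / (K^h + x^h)
o_rep <- function(x, K, h) if (is.infinite(K)) 1 else 1 / (1 + (x / K)^h)

oracle_clock_jacobian <- function(state, params, L = 0) {
  p <- as.list(params)
  s <- stats::setNames(as.numeric(state), clock_state_names())
  J <- matrix(0, 12, 12, dimnames = list(clock_state_names(),
                                         clock_state_names()))
  cb <- s[["cb"]]; pc <- s[["pc"]]
  prev <- s[["p_rev"]]; pror <- s[["p_ror"]]

  # mRNA rows: tx = v * (beta + (1-beta) A(cb)) * R(pc) [* Rr(prev) for cry]
  for (g in c("per", "cry", "rev", "ror")) {
    v <- p[[paste0("v_", g)]]; beta <- p[[paste0("beta_", g)]]
    Kc <- p[[paste0("K_cb_", g)]]; hc <- p[[paste0("h_cb_", g)]]
    Kp <- p[[paste0("K_pc_", g)]]; hp <- p[[paste0("h_pc_", g)]]
    Acb <- beta + (1 - beta) * o_act(cb, Kc, hc)
    Rpc <- o_rep(pc, Kp, hp)
    extra <- if (g == "cry") o_rep(prev, p$K_revcry, p$h_revcry) else 1
    row <- paste0("m_", g)
    J[row, "cb"] <- v * (1 - beta) * d_act(cb, Kc, hc) * Rpc * extra
    J[row, "pc"] <- v * Acb * d_rep(pc, Kp, hp) * extra
    if (g == "cry") {
      J[row, "p_rev"] <- v * Acb * Rpc * d_rep(prev, p$K_revcry, p$h_revcry)
    }
    J[row, row] <- -p[[paste0("dm_", g)]]
  }
  # Bmal1 row: v * (beta + (1-beta) A(pror)) * R(prev) / (1 + kL L)
  filt <- 1 / (1 + p$k_lps * L)
  Aror <- p$beta_bmal1 + (1 - p$beta_bmal1) * o_act(pror, p$K_ror, p$h_ror)
  Rrev <- o_rep(prev, p$K_rev, p$h_rev)
  J["m_bmal1", "p_ror"] <- p$v_bmal1 * (1 - p$beta_bmal1) *
    d_act(pror, p$K_ror, p$h_ror) * Rrev * filt
  J["m_bmal1", "p_rev"] <- p$v_bmal1 * Aror *
    d_rep(prev, p$K_rev, p$h_rev) * filt
  J["m_bmal1", "m_bmal1"] <- -p$dm_bmal1

  # protein rows
  J["p_per", "m_per"] <- p$kp_per
  J["p_per", "p_per"] <- -p$dp_per - p$kf_pc * s[["p_cry"]]
  J["p_per", "p_cry"] <- -p$kf_pc * s[["p_per"]]
  J["p_per", "pc"] <- p$kb_pc
  J["p_cry", "m_cry"] <- p$kp_cry
  J["p_cry", "p_per"] <- -p$kf_pc * s[["p_cry"]]
  J["p_cry", "p_cry"] <- -p$dp_cry - p$kf_pc * s[["p_per"]]
  J["p_cry", "pc"] <- p$kb_pc
  J["p_rev", "m_rev"] <- p$kp_rev
  J["p_rev", "p_rev"] <- -p$dp_rev
  J["p_ror", "m_ror"] <- p$kp_ror
  J["p_ror", "p_ror"] <- -p$dp_ror
  J["p_bmal1", "m_bmal1"] <- p$kp_bmal1
  J["p_bmal1", "p_bmal1"] <- -p$dp_bmal1 - p$kf_cb * p$clock0
  J["p_bmal1", "cb"] <- p$kb_cb
  J["pc", "p_per"] <- p$kf_pc * s[["p_cry"]]
  J["pc", "p_cry"] <- p$kf_pc * s[["p_per"]]
  J["pc", "pc"] <- -(p$kb_pc + p$d_pc)
  J["cb", "p_bmal1"] <- p$kf_cb * p$clock0
  J["cb", "cb"] <- -(p$kb_cb + p$d_cb)
  J
}

oracle_immune_jacobian <- function(state, clock_proteins, params, coupling) {
  q <- as.list(params); cp <- as.list(coupling)
  s <- stats::setNames(as.numeric(state), immune_state_names())
  J <- matrix(0, 8, 8, dimnames = list(immune_state_names(),
                                       immune_state_names()))
  P <- s[["p_endo"]]; N <- s[["n_act"]]; D <- s[["d_dam"]]
  TNF <- s[["tnf"]]; IL6 <- s[["il6"]]; IL10 <- s[["il10"]]
  Y <- s[["y_il10"]]; CA <- s[["c_a"]]
  fc <- o_rep(clock_proteins[[1]], cp$K_cry_tnf, cp$h_cry_tnf)
  fo <- o_rep(clock_proteins[[3]], cp$K_ror_tnf, cp$h_ror_tnf)
  f6 <- o_rep(clock_proteins[[2]], cp$K_rev_il6, cp$h_rev_il6)
  f10 <- o_rep(clock_proteins[[2]], cp$K_rev_il10, cp$h_rev_il10)

  g <- function(x, th) 1 / (1 + (x / th)^2)
  dg <- function(x, th) -2 * x / th^2 / (1 + (x / th)^2)^2

  # phagocyte activation
  S <- q$k_NP * P + q$k_NT * TNF + q$k_N6 * IL6 + q$k_ND * D
  g10 <- g(IL10, q$theta_N10); gca <- g(CA, q$theta_NCA)
  R <- S * g10 * gca
  dN_dR <- q$k_N * q$x_N / (q$x_N + R)^2
  J["p_endo", "p_endo"] <- -q$d_P
  J["n_act", "p_endo"] <- dN_dR * q$k_NP * g10 * gca
  J["n_act", "tnf"] <- dN_dR * q$k_NT * g10 * gca
  J["n_act", "il6"] <- dN_dR * q$k_N6 * g10 * gca
  J["n_act", "d_dam"] <- dN_dR * q$k_ND * g10 * gca
  J["n_act", "il10"] <- dN_dR * S * dg(IL10, q$theta_N10) * gca
  J["n_act", "c_a"] <- dN_dR * S * g10 * dg(CA, q$theta_NCA)
  J["n_act", "n_act"] <- -q$d_N

  J["d_dam", "il6"] <- q$k_D * d_act(IL6, q$x_D, q$h_D)
  J["d_dam", "p_endo"] <- q$k_DP
  J["d_dam", "d_dam"] <- -q$d_D

  # TNF production
  base_t <- q$k_T * fc * fo
  gt10 <- g(IL10, q$theta_T10); gtca <- g(CA, q$theta_TCA)
  At <- o_act(N, q$x_T, q$h_T)
  J["tnf", "n_act"] <- base_t * gt10 * gtca * d_act(N, q$x_T, q$h_T)
  J["tnf", "il10"] <- base_t * dg(IL10, q$theta_T10) * gtca * At
  J["tnf", "c_a"] <- base_t * gt10 * dg(CA, q$theta_TCA) * At
  J["tnf", "tnf"] <- -q$d_T

  # IL-6 production
  g610 <- g(IL10, q$theta_610); g6ca <- g(CA, q$theta_6CA)
  amp <- 1 + q$a_6T * o_act(TNF, q$x_6T, q$h_6T)
  A6 <- o_act(N, q$x_6, q$h_6)
  b6 <- q$k_6 * f6
  J["il6", "n_act"] <- b6 * g610 * g6ca * amp * d_act(N, q$x_6, q$h_6)
  J["il6", "tnf"] <- b6 * g610 * g6ca * q$a_6T * d_act(TNF, q$x_6T, q$h_6T) * A6
  J["il6", "il10"] <- b6 * dg(IL10, q$theta_610) * g6ca * amp * A6
  J["il6", "c_a"] <- b6 * g610 * dg(CA, q$theta_6CA) * amp * A6
  J["il6", "il6"] <- -q$d_6

  # IL-10 production
  A10 <- o_act(N, q$x_10, q$h_10)
  amp10 <- 1 + q$a_106 * o_act(IL6, q$x_106, q$h_106)
  J["il10", "n_act"] <- q$k_10 * f10 * d_act(N, q$x_10, q$h_10) * amp10
  J["il10", "il6"] <- q$k_10 * f10 * A10 * q$a_106 *
    d_act(IL6, q$x_106, q$h_106)
  J["il10", "y_il10"] <- q$k_Y10
  J["il10", "il10"] <- -q$d_10

  J["y_il10", "d_dam"] <- q$k_Y * d_act(D, q$x_Y, q$h_Y)
  J["y_il10", "y_il10"] <- -q$d_Y

  J["c_a", "n_act"] <- q$k_CA * d_act(N, q$x_CA, q$h_CA)
  J["c_a", "c_a"] <- -q$d_CA
  J
}

# Central finite differences of a vector function, column j.
central_diff <- function(fn, x, j, h = 1e-6) {
  xp <- x; xm <- x
  step <- h * max(abs(x[j]), 1)
  xp[j] <- xp[j] + step
  xm[j] <- xm[j] - step
  (fn(xp) - fn(xm)) / (2 * step)
}
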