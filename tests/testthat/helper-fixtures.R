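# shared fixtures: models, quick criteria, and an independent 1-D nullcline
# oracle for equilibria of the full system

default_model <- function(code = "2111", overrides = NULL) {
  build_model(default_parameters(overrides), code)
}

# decoupled configuration: hypothesis "2222" with the base-model Egr3->p18/p19
# edges switched off, so Maff/Egr3 touch nothing downstream
decoupled_model <- function(overrides = NULL) {
  build_model(default_parameters(c(g_eg18 = 0, g_eg19 = 0, overrides)), "2222")
}

quick_criteria <- function(...) {
  screen_criteria(grid_n = 12L, n_starts = 5L, ...)
}

# independent equilibrium oracle: every species except E2F is, at steady
# state, an explicit function of E2F (MF/EG closed-form; P18/P19 then CD/CE
# explicit; RB a scalar root).  Scanning the E2F residual for sign changes
# and bisecting gives all equilibria without the multi-start machinery.
nullcline_equilibria <- function(model, e2f_range = c(1e-8, 50), n_scan = 4000) {
  p <- model$params
  h <- model$hypothesis$digits
  A <- function(x, K) x / (K + x)
  I <- function(x, K) K / (K + x)
  M <- function(x, a, K) if (a == 3) 1 + p[["beta"]] * A(x, K) else
    if (a == 1) I(x, K) else 1
  pools <- static_pools(p)
  MF <- p[["ks_maff"]] / p[["kd_mf"]]
  EG <- p[["ks_egr3"]] / p[["kd_eg"]]
  state_of <- function(E2F) {
    P18 <- p[["ks_p18"]] * (p[["b18"]] + p[["a_e18"]] * A(E2F, p[["K_e18"]])) *
      (1 + p[["g_eg18"]] * A(EG, p[["K_eg18"]])) *
      M(MF, h[2], p[["K_mf_p18"]]) / p[["kd_p18"]]
    P19 <- p[["ks_p19"]] * (p[["b19"]] + p[["a_e19"]] * A(E2F, p[["K_e19"]])) *
      (1 + p[["g_eg19"]] * A(EG, p[["K_eg19"]])) / p[["kd_p19"]]
    dcd <- 1 + p[["alpha18"]] * A(P18, p[["K_i18"]]) +
      p[["alpha19"]] * A(P19, p[["K_i19"]]) +
      p[["alpha16"]] * A(p[["P16_0"]], p[["K_i16"]])
    CD <- p[["ks_cd"]] * (p[["GF"]] + p[["a_ecd"]] * A(E2F, p[["K_ecd"]])) *
      M(EG, h[4], p[["K_eg_cd"]]) / (p[["kd_cd"]] * dcd)
    dce <- 1 + p[["alpha21"]] * A(pools[["P21"]], p[["K_i21"]]) +
      p[["alpha27"]] * A(pools[["P27"]], p[["K_i27"]])
    CE <- p[["ks_ce"]] * A(E2F, p[["K_ece"]]) * M(EG, h[3], p[["K_eg_ce"]]) *
      M(MF, h[1], p[["K_mf_ce"]]) / (p[["kd_ce"]] * dce)
    flux <- p[["kp_cd"]] * CD + p[["kp_ce"]] * CE
    g_rb <- function(RB) p[["ks_rb"]] - flux * A(RB, p[["K_prb"]]) -
      p[["kd_rb"]] * RB
    RB <- uniroot(g_rb, c(0, p[["ks_rb"]] / p[["kd_rb"]] + 1),
                  tol = 1e-14)$root
    c(MF = MF, EG = EG, CD = unname(CD), CE = unname(CE), E2F = E2F,
      RB = RB, P18 = unname(P18), P19 = unname(P19))
  }
  resid <- function(E2F) {
    s <- state_of(E2F)
    p[["ks_e2f"]] * (p[["e0"]] + p[["e_auto"]] * A(E2F, p[["K_ee"]])) *
      I(s[["RB"]], p[["K_rb_e2f"]]) - p[["kd_e2f"]] * E2F
  }
  grid <- exp(seq(log(e2f_range[1]), log(e2f_range[2]), length.out = n_scan))
  vals <- vapply(grid, resid, numeric(1))
  roots <- c()
  for (i in seq_len(n_scan - 1)) {
    if (sign(vals[i]) != sign(vals[i + 1])) {
      roots <- c(roots, uniroot(resid, grid[c(i, i + 1)], tol = 1e-14)$root)
    }
  }
  lapply(roots, state_of)
}

# +1% perturbation of each coordinate, settle, and report the worst relative
# excursion from the equilibrium at the end
perturb_return <- function(model, eq_state, t_end = 5000) {
  worst <- 0
  for (j in seq_along(eq_state)) {
    x0 <- eq_state
    x0[j] <- x0[j] * 1.01 + 1e-9
    tr <- simulate(model, x0 = x0, t_end = t_end)
    xe <- tr$states[nrow(tr$states), ]
    worst <- max(worst, max(abs(xe - eq_state) / pmax(abs(eq_state), 1e-9)))
  }
  worst
}
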