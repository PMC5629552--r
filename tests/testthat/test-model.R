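test_that("edge modifiers follow the hypothesis code", {
  x <- c(MF = 2, EG = 3, CD = 0.1, CE = 0.1, E2F = 1, RB = 0.5,
         P18 = 1, P19 = 1)
  p <- default_parameters()
  syn <- function(code) {
    v <- cycleswitch:::cc_synthesis(as.numeric(p), parse_code(code)$digits, x)
    setNames(as.numeric(v), species_names())
  }
  A <- function(v, K) v / (K + v)
  I <- function(v, K) K / (K + v)
  s_none <- syn("2222")
  s_acc <- syn("2111")
  # h2 inhibitory: p18 synthesis scaled by I(MF; K_mf_p18)
  expect_equal(s_acc[["P18"]], s_none[["P18"]] * I(x[["MF"]], p[["K_mf_p18"]]))
  # h3/h4 inhibitory: CE and CD synthesis scaled by I(EG; K)
  expect_equal(s_acc[["CE"]], s_none[["CE"]] * I(x[["EG"]], p[["K_eg_ce"]]))
  expect_equal(s_acc[["CD"]], s_none[["CD"]] * I(x[["EG"]], p[["K_eg_cd"]]))
  # activatory modifier: 1 + beta * A(x; K) on Maff->Cdk2
  s_act <- syn("3222")
  expect_equal(s_act[["CE"]],
               s_none[["CE"]] * (1 + p[["beta"]] * A(x[["MF"]], p[["K_mf_ce"]])))
  # P19 synthesis never carries a hypothesis modifier
  expect_equal(s_acc[["P19"]], s_none[["P19"]])
})

test_that("none-edges leave the base model; g_eg18=g_eg19=0 decouples fully", {
  m <- decoupled_model()
  x <- c(0.5, 0.7, 0.1, 0.1, 1, 0.5, 1, 1)
  f1 <- rhs(m, x)
  x2 <- x; x2[1] <- 5; x2[2] <- 7  # change MF, EG only
  f2 <- rhs(m, x2)
  expect_equal(f1[3:8], f2[3:8])  # downstream derivatives untouched
})

test_that("half-saturation identity holds for the E2F synthesis term", {
  p <- default_parameters()
  m <- build_model(p, "2222")
  x <- c(MF = 1, EG = 1, CD = 0.1, CE = 0.1, E2F = p[["K_ee"]], RB = 0.4,
         P18 = 1, P19 = 1)
  f <- rhs(m, x)
  syn <- f[["E2F"]] + p[["kd_e2f"]] * x[["E2F"]]
  expect_equal(syn,
               p[["ks_e2f"]] * (p[["e0"]] + 0.5 * p[["e_auto"]]) *
                 p[["K_rb_e2f"]] / (p[["K_rb_e2f"]] + x[["RB"]]))
})

test_that("zero state with zero basal gains leaves only constitutive terms", {
  p <- default_parameters(c(GF = 0, e0 = 0, b18 = 0, b19 = 0))
  m <- build_model(p, "2222")
  f <- rhs(m, rep(0, 8))
  expect_equal(unname(f[c("MF", "EG", "RB")]),
               unname(p[c("ks_maff", "ks_egr3", "ks_rb")]))
  expect_equal(unname(f[c("CD", "CE", "E2F", "P18", "P19")]), rep(0, 5))
})

test_that("negative states and bad parameters are rejected with clear errors", {
  m <- default_model()
  expect_error(rhs(m, c(-0.1, rep(0.1, 7))), "non-negative")
  expect_error(rhs(m, rep(0.1, 7)), "length 8")
  expect_error(build_model(default_parameters()[-5], "2111"),
               "missing parameter.*ks_e2f")
})

test_that("analytic Jacobian matches central differences at random states", {
  set.seed(42)
  for (code in c("2111", "1233", "3322")) {
    m <- default_model(code)
    for (rep in 1:4) {
      x <- rlnorm(8, meanlog = log(0.3), sdlog = 1.2)
      J <- model_jacobian(m, x)
      Jfd <- matrix(0, 8, 8)
      hstep <- 1e-6
      for (j in 1:8) {
        xp <- x; xm <- x
        xp[j] <- xp[j] + hstep; xm[j] <- xm[j] - hstep
        Jfd[, j] <- (rhs(m, xp) - rhs(m, xm)) / (2 * hstep)
      }
      expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-4)
    }
  }
})

test_that("trajectories match the closed-form Maff kinetics", {
  p <- default_parameters(c(ks_maff = 0.02, kd_mf = 0.04))
  m <- build_model(p, "2222")
  t_end <- 5 / p[["kd_mf"]]
  tr <- simulate(m, x0 = rep(0, 8), t_end = t_end)
  mf_inf <- p[["ks_maff"]] / p[["kd_mf"]]
  expect_lt(abs(tr$states[nrow(tr$states), "MF"] - mf_inf * (1 - exp(-5))) /
              mf_inf, 0.01)
  expect_true(all(diff(tr$times) > 0))
})

test_that("default model settles and the settled state is an equilibrium", {
  m <- default_model()
  tr <- simulate(m, x0 = rep(0.01, 8), t_end = 5000)
  expect_true(tr$settled)
  eq <- find_equilibrium(m, tr$states[nrow(tr$states), ])
  expect_lte(eq$residual, 1e-8 * max(m$params[1:8]))
  # doubling the horizon leaves the settled endpoint unchanged
  tr2 <- simulate(m, x0 = rep(0.01, 8), t_end = 10000)
  xe1 <- tr$states[nrow(tr$states), ]
  xe2 <- tr2$states[nrow(tr2$states), ]
  expect_lt(max(abs(xe2 - xe1) / pmax(abs(xe1), 1e-12)), 1e-5)
})

test_that("states stay non-negative within solver tolerance", {
  set.seed(7)
  m <- default_model("1111")
  for (rep in 1:5) {
    x0 <- rlnorm(8, log(0.05), 1.5)
    tr <- simulate(m, x0 = x0, t_end = 2000)
    expect_gte(min(tr$states), -10 * 1e-9)
  }
})

test_that("trajectory TSV has the documented layout", {
  m <- default_model()
  tr <- simulate(m, x0 = rep(0.01, 8), t_end = 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_identical(names(tab), c("time", species_names()))
  expect_equal(nrow(tab), length(tr$times))
})

test_that("synthesis surrogates report the synthesis term at equilibrium", {
  m <- default_model()
  eq <- find_all_equilibria(m)[[1]]
  s <- synthesis_surrogates(m, eq$state)
  p <- m$params
  expect_equal(s[["MF"]], unname(p[["ks_maff"]]))
  expect_equal(s[["RB"]], unname(p[["ks_rb"]]))
  # linear species balance: synthesis = kd * level at steady state
  expect_equal(s[["MF"]], unname(p[["kd_mf"]] * eq$state[["MF"]]),
               tolerance = 1e-6)
  expect_equal(s[["EG"]], unname(p[["kd_eg"]] * eq$state[["EG"]]),
               tolerance = 1e-6)
  expect_error(synthesis_surrogates(m, eq$state * 2), "not an equilibrium")
})
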