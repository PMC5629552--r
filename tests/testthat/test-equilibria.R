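test_that("stability classification follows the Lyapunov eigenvalue rule", {
  expect_identical(classify_stability(c(-1, complex(real = -0.2,
                                                    imaginary = 0.5))),
                   "stable")
  expect_identical(classify_stability(c(-1, 0.01)), "unstable")
  expect_identical(classify_stability(c(-1, 0)), "marginal")
  expect_error(classify_stability(numeric(0)), "empty")
})

test_that("linear species hit their closed-form equilibria exactly", {
  p <- default_parameters(c(ks_maff = 0.031, kd_mf = 0.07,
                            ks_egr3 = 0.013, kd_eg = 0.021))
  m <- build_model(p, "2111")
  eqs <- find_all_equilibria(m)
  expect_gt(length(eqs), 0)
  for (e in eqs) {
    expect_lt(abs(e$state[["MF"]] - p[["ks_maff"]] / p[["kd_mf"]]) /
                (p[["ks_maff"]] / p[["kd_mf"]]), 1e-8)
    expect_lt(abs(e$state[["EG"]] - p[["ks_egr3"]] / p[["kd_eg"]]) /
                (p[["ks_egr3"]] / p[["kd_eg"]]), 1e-8)
  }
})

test_that("settled trajectory endpoints refine within the iteration budget", {
  m <- default_model()
  tr <- simulate(m, x0 = rep(0.02, 8), t_end = 5000)
  eq <- find_equilibrium(m, tr$states[nrow(tr$states), ], max_iter = 50L)
  expect_lte(eq$residual, 1e-8 * max(m$params[1:8]))
  expect_identical(eq$stability, "stable")
  expect_error(find_equilibrium(m, rep(1, 8), max_iter = 1L),
               "no equilibrium")
})

test_that("multi-start search matches the 1-D nullcline oracle", {
  for (ks_eg in c(1e-3, 3e-3, 0.5)) {  # monostable ON, bistable, monostable OFF
    m <- default_model("2111", c(ks_egr3 = ks_eg))
    found <- find_all_equilibria(m, n_starts = 8)
    oracle <- nullcline_equilibria(m)
    expect_equal(length(found), length(oracle))
    o_e2f <- sort(vapply(oracle, function(s) s[["E2F"]], numeric(1)))
    f_e2f <- sort(vapply(found, function(e) e$state[["E2F"]], numeric(1)))
    expect_lt(max(abs(o_e2f - f_e2f) / pmax(o_e2f, 1e-9)), 1e-6)
  }
})

test_that("dense multi-start agrees with the default in both regimes", {
  # monostable far above the bistable interval
  m_hi <- default_model("2111", c(ks_egr3 = 0.5))
  e8 <- find_all_equilibria(m_hi, n_starts = 8)
  e60 <- find_all_equilibria(m_hi, n_starts = 60, seed = 99)
  stable8 <- Filter(function(e) e$stability == "stable", e8)
  stable60 <- Filter(function(e) e$stability == "stable", e60)
  expect_length(stable8, 1L)
  expect_length(stable60, 1L)
  # inside the bistable interval: two stable states, E2F > 2-fold apart
  m_bi <- default_model("2111", c(ks_egr3 = 3e-3))
  st <- Filter(function(e) e$stability == "stable",
               find_all_equilibria(m_bi, n_starts = 8))
  expect_gte(length(st), 2L)
  e2f <- sort(vapply(st, function(e) e$state[["E2F"]], numeric(1)))
  expect_gt(e2f[length(e2f)] / e2f[1], 2)
})

test_that("decoupled hypothesis makes downstream equilibria Maff-invariant", {
  lo <- decoupled_model(c(ks_maff = 1e-3))
  hi <- decoupled_model(c(ks_maff = 0.5))
  e_lo <- find_all_equilibria(lo)
  e_hi <- find_all_equilibria(hi)
  expect_equal(length(e_lo), length(e_hi))
  down <- c("CD", "CE", "E2F", "RB", "P18", "P19")
  for (k in seq_along(e_lo)) {
    expect_equal(e_lo[[k]]$state[down], e_hi[[k]]$state[down],
                 tolerance = 1e-6)
  }
})

test_that("sweeps record branches, gaps and bistable intervals", {
  m <- default_model("2111", c(ks_maff = 1e-3))
  grid <- default_grid(12)
  sw <- sweep_parameter(m, "ks_egr3", grid, n_starts = 6)
  expect_s3_class(sw, "cc_sweep")
  expect_true(all(sw$ok))
  df <- as.data.frame(sw)
  expect_true(all(c("parameter_value", "branch_id", "stability", "E2F") %in%
                    names(df)))
  expect_error(sweep_parameter(m, "ks_egr3", rev(grid)), "increasing")
  # branch continuity on the stable upper branch away from folds
  path <- withr::local_tempfile(fileext = ".tsv")
  ipath <- withr::local_tempfile(fileext = ".tsv")
  write_sweep_tsv(sw, path, ipath)
  expect_identical(names(read.table(path, header = TRUE, sep = "\t"))[1:3],
                   c("parameter_value", "branch_id", "stability"))
  expect_identical(names(read.table(ipath, header = TRUE, sep = "\t")),
                   c("lower", "upper"))
})

test_that("sweeping a decoupled model changes only the Maff level", {
  m <- decoupled_model()
  grid <- default_grid(5)
  sw <- sweep_parameter(m, "ks_maff", grid, n_starts = 4)
  down <- c("CD", "CE", "E2F", "RB", "P18", "P19")
  ref <- sw$equilibria[[1]]
  for (i in seq_along(grid)) {
    eqs <- sw$equilibria[[i]]
    expect_equal(length(eqs), length(ref))
    for (k in seq_along(eqs)) {
      expect_equal(eqs[[k]]$state[down], ref[[k]]$state[down],
                   tolerance = 1e-6)
      expect_equal(eqs[[k]]$state[["MF"]],
                   unname(grid[i] / m$params[["kd_mf"]]), tolerance = 1e-8)
    }
  }
})

test_that("stable equilibria attract and unstable ones repel", {
  m <- default_model("2111", c(ks_egr3 = 3e-3))  # bistable point
  eqs <- find_all_equilibria(m, n_starts = 8)
  stab <- Filter(function(e) e$stability == "stable", eqs)
  unst <- Filter(function(e) e$stability == "unstable", eqs)
  expect_gte(length(stab), 2L)
  expect_gte(length(unst), 1L)
  for (e in stab) {
    expect_lt(perturb_return(m, e$state), 1e-3)
  }
  for (e in unst) {
    if (any(Re(e$eigenvalues) > 0 & abs(Im(e$eigenvalues)) < 1e-12)) {
      expect_gt(perturb_return(m, e$state), 0.05)
    }
  }
})
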