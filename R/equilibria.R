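# Steady states: Newton refinement, Lyapunov classification from Jacobian
# eigenvalues, seeded multi-start search, and one-parameter sweeps that
# assemble bifurcation branches and detect bistable intervals.

eq_tolerance <- function(model) 1e-8 * max(model$params[1:8])

#' Classify equilibrium stability from Jacobian eigenvalues
#'
#' Lyapunov linearisation rule: asymptotically stable when every eigenvalue
#' has negative real part, unstable when any real part is positive.  Real
#' parts within `eps` of zero yield `"marginal"`, an explicit label for the
#' measure-zero boundary.
#'
#' @param eigenvalues Complex (or numeric) vector of Jacobian eigenvalues.
#' @param eps Real-part tolerance (default 1e-9).
#' @return `"stable"`, `"unstable"` or `"marginal"`.
#' @examples
#' classify_stability(c(-1, complex(real = -0.2, imaginary = 0.5)))
#' @export
classify_stability <- function(eigenvalues, eps = 1e-9) {
  if (length(eigenvalues) == 0) stop("empty eigenvalue sequence")
  re <- Re(eigenvalues)
  if (all(re < -eps)) return("stable")
  if (any(re > eps)) return("unstable")
  "marginal"
}

new_equilibrium <- function(model, state, residual) {
  state <- setNames(pmax(as.numeric(state), 0), species_names())
  ev <- eigen(model_jacobian(model, state), only.values = TRUE)$values
  structure(
    list(state = state, residual = residual, eigenvalues = ev,
         stability = classify_stability(ev)),
    class = "cc_equilibrium"
  )
}

#' @export
print.cc_equilibrium <- function(x, ...) {
  cat("<cc_equilibrium> ", x$stability, " (residual ", signif(x$residual, 3),
      ")\n", sep = "")
  print(signif(x$state, 5))
  invisible(x)
}

#' Refine an equilibrium by damped Newton iteration
#'
#' Solves `f(x) = 0` from a guess (typically the settled endpoint of a
#' trajectory) with Newton steps damped by an Armijo backtracking line
#' search, states clipped to the non-negative orthant.  The converged state
#' is classified via the Jacobian eigenvalues.
#'
#' @param model A `cc_model`.
#' @param guess Non-negative initial state.
#' @param tol Residual tolerance on `max(abs(f))`; defaults to
#'   `1e-8 * max(synthesis rates)`.
#' @param max_iter Iteration cap (default 50).
#' @return A `cc_equilibrium`: `state`, `residual`, `eigenvalues`,
#'   `stability`.
#' @export
find_equilibrium <- function(model, guess, tol = NULL, max_iter = 50L) {
  stopifnot(inherits(model, "cc_model"))
  guess <- check_state(guess)
  if (is.null(tol)) tol <- eq_tolerance(model)
  res <- cc_newton(as.numeric(model$params), model$hypothesis$digits, guess,
                   tol, as.integer(max_iter))
  if (!res$converged) {
    stop("no equilibrium found from the given guess: best residual ",
         signif(res$residual, 4), " after ", res$iterations,
         " iterations (tolerance ", signif(tol, 4), ")")
  }
  new_equilibrium(model, res$state, res$residual)
}

# deterministic multi-start initial conditions spanning low/high E2F-CE
# regimes: log-spaced activity scales with high-Rb complements, lognormal
# jitter under the given seed
make_starts <- function(model, n_starts, seed) {
  p <- model$params
  mf0 <- p[["ks_maff"]] / p[["kd_mf"]]
  eg0 <- p[["ks_egr3"]] / p[["kd_eg"]]
  rb_hi <- p[["ks_rb"]] / p[["kd_rb"]]
  scales <- 10^seq(-3, 1, length.out = n_starts)
  jit <- withr_seed(seed, matrix(rlnorm(n_starts * 8L, 0, 0.05), n_starts, 8L))
  starts <- matrix(0, n_starts, 8L, dimnames = list(NULL, species_names()))
  for (i in seq_len(n_starts)) {
    s <- scales[i]
    starts[i, ] <- c(mf0, eg0, s, s, s, min(rb_hi, rb_hi * sqrt(1e-3 / s)),
                     1, 1) * jit[i, ]
  }
  starts
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Find the distinct equilibria of a model by seeded multi-start search
#'
#' Each start (log-spaced across low/high E2F and Cyc E* regimes, jittered
#' under `seed`) is integrated to settling, refined by Newton iteration, and
#' the refined states are deduplicated at relative distance `dedupe_tol`.
#' Exposes both branches of the bistable switch where they coexist.
#'
#' @param model A `cc_model`.
#' @param n_starts Number of starts (>= 2, default 8).
#' @param seed Integer seed for the start jitter.
#' @param t_settle Pre-settling horizon in minutes.
#' @param dedupe_tol Relative deduplication distance (default 1e-4).
#' @param tol Newton residual tolerance (see [find_equilibrium()]).
#' @return List of `cc_equilibrium` (possibly empty), sorted by decreasing
#'   E2F.
#' @export
find_all_equilibria <- function(model, n_starts = 8L, seed = 1L,
                                t_settle = 5000, dedupe_tol = 1e-4,
                                tol = NULL) {
  stopifnot(inherits(model, "cc_model"), n_starts >= 2)
  if (is.null(tol)) tol <- eq_tolerance(model)
  starts <- make_starts(model, n_starts, seed)
  # settling only selects the basin; relaxed tolerances suffice because the
  # Newton refinement enforces the equilibrium tolerance afterwards
  res <- cc_multistart(as.numeric(model$params), model$hypothesis$digits,
                       starts, t_settle, 1e-4, 1e-7, 100000L, tol, 50L)
  cand <- list()
  for (i in which(res$converged)) {
    cand[[length(cand) + 1L]] <- list(x = pmax(res$states[i, ], 0),
                                      residual = res$residuals[i])
  }
  # settling converges to attractors only; direct Newton from the raw starts
  # and from points between distinct attractors exposes the saddle branch
  par <- as.numeric(model$params)
  dig <- model$hypothesis$digits
  refine <- function(guess) {
    nw <- cc_newton(par, dig, pmax(guess, 0), tol, 50L)
    if (nw$converged) {
      cand[[length(cand) + 1L]] <<- list(x = pmax(as.numeric(nw$state), 0),
                                         residual = nw$residual)
    }
  }
  for (i in seq_len(nrow(starts))) refine(starts[i, ])
  uniq <- unique_states(lapply(cand, `[[`, "x"), dedupe_tol)
  if (length(uniq) >= 2) {
    for (a in seq_len(length(uniq) - 1)) {
      for (b in seq((a + 1), length(uniq))) {
        for (w in c(0.3, 0.5, 0.7)) {
          refine(w * uniq[[a]] + (1 - w) * uniq[[b]])
        }
      }
    }
  }
  eqs <- list()
  for (ca in cand) {
    dup <- FALSE
    for (e in eqs) {
      d <- sqrt(sum((ca$x - e$state)^2))
      ref <- max(sqrt(sum(ca$x^2)), sqrt(sum(e$state^2)), 1e-12)
      if (d / ref < dedupe_tol) { dup <- TRUE; break }
    }
    if (!dup) {
      eqs[[length(eqs) + 1L]] <- new_equilibrium(model, ca$x, ca$residual)
    }
  }
  if (length(eqs) > 1) {
    eqs <- eqs[order(vapply(eqs, function(e) e$state[["E2F"]], numeric(1)),
                     decreasing = TRUE)]
  }
  eqs
}

#' Sweep a parameter and assemble bifurcation branches
#'
#' For each grid value the parameter is substituted, the multi-start
#' protocol ([find_all_equilibria()]) is run, and stable/unstable equilibria
#' are recorded.  Bistable intervals are the maximal runs of grid points
#' carrying at least two stable equilibria.  Solver failures at single grid
#' points become flagged gaps rather than aborts.
#'
#' @param model A `cc_model`.
#' @param param_name Parameter to sweep; `"ks_maff"` and `"ks_egr3"` are the
#'   validated axes (the Maff/Egr3 expression levels), others are allowed.
#' @param grid Strictly increasing numeric vector of parameter values;
#'   default 60 log-spaced points over the frozen default range
#'   `[1e-3, 0.5]` moles/cell/min.
#' @param n_starts,seed Multi-start settings (see [find_all_equilibria()]).
#' @return A `cc_sweep`: `param_name`, `grid`, `equilibria` (list of lists
#'   of `cc_equilibrium`), `ok` (logical per grid point), and
#'   `bistable_intervals` (data.frame with `lower`, `upper`).
#' @examples
#' \donttest{
#' m <- build_model(default_parameters(), "2111")
#' sw <- sweep_parameter(m, "ks_egr3", default_grid(15))
#' sw$bistable_intervals
#' }
#' @export
sweep_parameter <- function(model, param_name, grid = default_grid(),
                            n_starts = 8L, seed = 1L) {
  stopifnot(inherits(model, "cc_model"))
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  eqs <- vector("list", length(grid))
  ok <- logical(length(grid))
  for (i in seq_along(grid)) {
    mi <- set_param(model, param_name, grid[i])
    eqs[[i]] <- tryCatch(
      find_all_equilibria(mi, n_starts = n_starts, seed = seed),
      error = function(e) NULL
    )
    ok[i] <- !is.null(eqs[[i]]) && length(eqs[[i]]) > 0
    if (is.null(eqs[[i]])) eqs[[i]] <- list()
  }
  n_stable <- vapply(eqs, function(e) {
    sum(vapply(e, function(q) q$stability == "stable", logical(1)))
  }, integer(1))
  structure(
    list(param_name = param_name, grid = grid, equilibria = eqs, ok = ok,
         n_stable = n_stable,
         bistable_intervals = runs_to_intervals(grid, n_stable >= 2)),
    class = "cc_sweep"
  )
}

#' Default sweep grid for the expression-level axes
#'
#' @param n Number of points (default 60).
#' @param from,to Range in moles/cell/min (defaults frozen with the default
#'   parameter set).
#' @return Log-spaced numeric vector.
#' @export
default_grid <- function(n = 60L, from = 1e-3, to = 0.5) {
  10^seq(log10(from), log10(to), length.out = n)
}

unique_states <- function(states, dedupe_tol) {
  out <- list()
  for (x in states) {
    dup <- FALSE
    for (y in out) {
      d <- sqrt(sum((x - y)^2))
      ref <- max(sqrt(sum(x^2)), sqrt(sum(y^2)), 1e-12)
      if (d / ref < dedupe_tol) { dup <- TRUE; break }
    }
    if (!dup) out[[length(out) + 1L]] <- x
  }
  out
}

runs_to_intervals <- function(grid, flag) {
  if (!any(flag)) {
    return(data.frame(lower = numeric(0), upper = numeric(0)))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  data.frame(lower = grid[starts[i]], upper = grid[ends[i]])
}

#' @export
print.cc_sweep <- function(x, ...) {
  cat("<cc_sweep> ", x$param_name, " over ", length(x$grid), " points [",
      signif(min(x$grid), 4), ", ", signif(max(x$grid), 4), "]\n", sep = "")
  nb <- nrow(x$bistable_intervals)
  if (nb) {
    for (i in seq_len(nb)) {
      cat("  bistable interval: [", signif(x$bistable_intervals$lower[i], 4),
          ", ", signif(x$bistable_intervals$upper[i], 4), "]\n", sep = "")
    }
  } else cat("  no bistable interval detected\n")
  invisible(x)
}

#' Tabulate a sweep
#'
#' @param x A `cc_sweep`.
#' @param ... Ignored.
#' @return data.frame with `parameter_value`, `branch_id`, `stability`,
#'   `residual`, then one column per species.
#' @export
as.data.frame.cc_sweep <- function(x, ...) {
  rows <- list()
  for (i in seq_along(x$grid)) {
    for (b in seq_along(x$equilibria[[i]])) {
      e <- x$equilibria[[i]][[b]]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter_value = x$grid[i], branch_id = b, stability = e$stability,
        residual = e$residual, as.list(e$state), check.names = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(parameter_value = numeric(0), branch_id = integer(0),
                      stability = character(0), residual = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Write sweep results as TSV
#'
#' Writes the per-equilibrium table to `path` and, when `interval_path` is
#' given, the bistable-interval summary alongside it.
#'
#' @param sweep A `cc_sweep`.
#' @param path Output path for the equilibrium table.
#' @param interval_path Optional output path for the interval summary.
#' @return `path`, invisibly.
#' @export
write_sweep_tsv <- function(sweep, path, interval_path = NULL) {
  stopifnot(inherits(sweep, "cc_sweep"))
  write.table(as.data.frame(sweep), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(interval_path)) {
    write.table(sweep$bistable_intervals, interval_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# stable equilibrium with the largest E2F at grid point i (NULL if none)
upper_stable <- function(sweep, i) {
  stab <- Filter(function(e) e$stability == "stable", sweep$equilibria[[i]])
  if (!length(stab)) return(NULL)
  stab[[which.max(vapply(stab, function(e) e$state[["E2F"]], numeric(1)))]]
}
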