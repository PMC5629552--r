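# Model construction and dynamic evaluation.
#
# The system couples constitutive Maff/Egr3 expression to the Rb-E2F
# restriction-point switch through first-order Hill regulation.  With
# A(x;K) = x/(K+x), I(x;K) = K/(K+x), and the pluggable edge modifier
# M(x; action, K) = 1 + beta*A(x;K) (activatory), 1 (none), I(x;K)
# (inhibitory):
#
#   dMF/dt  = ks_maff - kd_mf*MF
#   dEG/dt  = ks_egr3 - kd_eg*EG
#   dCD/dt  = ks_cd*[GF + a_ecd*A(E2F;K_ecd)]*M(EG;h4,K_eg_cd)
#             - kd_cd*CD*[1 + alpha18*A(P18;K_i18) + alpha19*A(P19;K_i19)
#                           + alpha16*A(P16_0;K_i16)]
#   dCE/dt  = ks_ce*A(E2F;K_ece)*M(EG;h3,K_eg_ce)*M(MF;h1,K_mf_ce)
#             - kd_ce*CE*[1 + alpha21*A(P21;K_i21) + alpha27*A(P27;K_i27)]
#   dE2F/dt = ks_e2f*[e0 + e_auto*A(E2F;K_ee)]*I(RB;K_rb_e2f) - kd_e2f*E2F
#   dRB/dt  = ks_rb - (kp_cd*CD + kp_ce*CE)*A(RB;K_prb) - kd_rb*RB
#   dP18/dt = ks_p18*[b18 + a_e18*A(E2F;K_e18)]*[1 + g_eg18*A(EG;K_eg18)]
#             *M(MF;h2,K_mf_p18) - kd_p18*P18
#   dP19/dt = ks_p19*[b19 + a_e19*A(E2F;K_e19)]*[1 + g_eg19*A(EG;K_eg19)]
#             - kd_p19*P19
#
# The Egr3->p18/p19 activations (g_eg18, g_eg19) are base-model edges and are
# always present, independent of the hypothesis tuple.

#' Build a cell-cycle switch model
#'
#' Combines a complete, validated parameter set with a regulatory hypothesis
#' into a model object whose right-hand side and analytic Jacobian can be
#' evaluated, simulated, and analysed for equilibria.
#'
#' @param params Parameter set (named numeric vector; see
#'   [default_parameters()]).
#' @param hypothesis A regulatory code string (e.g. `"2111"`) or a
#'   `cc_hypothesis` from [parse_code()].
#' @return A `cc_model` object.
#' @examples
#' m <- build_model(default_parameters(), "2111")
#' rhs(m, rep(0.1, 8))
#' @export
build_model <- function(params, hypothesis) {
  params <- validate_parameters(params)
  hyp <- as_hypothesis(hypothesis)
  structure(
    list(params = params, hypothesis = hyp,
         pools = cc_static_pools(as.numeric(params))),
    class = "cc_model"
  )
}

#' @export
print.cc_model <- function(x, ...) {
  cat("<cc_model> G0/G1->S switch, regulatory code ", x$hypothesis$code, "\n",
      sep = "")
  cat("  effective pools: P21 = ", signif(x$pools[["P21"]], 4),
      ", P27 = ", signif(x$pools[["P27"]], 4), " moles/cell\n", sep = "")
  invisible(x)
}

check_state <- function(state) {
  state <- as.numeric(state)
  if (length(state) != 8 || anyNA(state) || any(!is.finite(state))) {
    stop("state must be a finite numeric vector of length 8")
  }
  if (any(state < 0)) stop("state components must be non-negative")
  state
}

#' Evaluate the model right-hand side
#'
#' @param model A `cc_model`.
#' @param state Non-negative species vector in [species_names()] order
#'   (moles/cell).
#' @return Named derivative vector (moles/cell/min).
#' @export
rhs <- function(model, state) {
  stopifnot(inherits(model, "cc_model"))
  state <- check_state(state)
  v <- as.numeric(cc_rhs(as.numeric(model$params), model$hypothesis$digits, state))
  setNames(v, species_names())
}

#' Analytic Jacobian of the right-hand side
#'
#' @inheritParams rhs
#' @return 8 x 8 matrix with rows/columns named by species.
#' @export
model_jacobian <- function(model, state) {
  stopifnot(inherits(model, "cc_model"))
  state <- check_state(state)
  J <- cc_jac(as.numeric(model$params), model$hypothesis$digits, state)
  dimnames(J) <- list(species_names(), species_names())
  J
}

#' Simulate a trajectory with the stiff BDF integrator
#'
#' Integrates the model with an adaptive-order-1/2 backward-differentiation
#' scheme (Newton-corrected implicit steps with the analytic Jacobian), the
#' standard remedy for the stiffness of this system.  The trajectory is
#' flagged `settled` when the state changes by less than `settle_tol`
#' (relative) over the final 10% of the horizon.
#'
#' @param object A `cc_model`.
#' @param x0 Initial state (non-negative, length 8).
#' @param t_end Integration horizon in minutes (default 5000).
#' @param rtol,atol Relative/absolute local error tolerances.
#' @param settle_tol Relative settledness tolerance (default 1e-6).
#' @param max_steps Step budget before the solver gives up.
#' @param nsim,seed Ignored (present for the [stats::simulate()] generic).
#' @param ... Ignored.
#' @return A `cc_trajectory`: list with `times` (min), `states` (matrix, one
#'   row per accepted step, columns named by species), `settled`, and solver
#'   diagnostics (`n_accept`, `n_reject`, `final_residual`).
#' @examples
#' m <- build_model(default_parameters(), "2111")
#' tr <- simulate(m, rep(0.01, 8), t_end = 1000)
#' tr$settled
#' @export
simulate.cc_model <- function(object, nsim = 1, seed = NULL, x0, t_end = 5000,
                              rtol = 1e-6, atol = 1e-9, settle_tol = 1e-6,
                              max_steps = 100000L, ...) {
  stopifnot(t_end > 0)
  x0 <- check_state(x0)
  res <- cc_integrate(as.numeric(object$params), object$hypothesis$digits,
                      x0, t_end, rtol, atol, as.integer(max_steps))
  if (res$status == 1L) {
    stop("integration failed: step size underflow at t = ",
         signif(res$t_reached, 6), " min after ", res$n_accept,
         " accepted / ", res$n_reject, " rejected steps")
  }
  if (res$status == 2L) {
    stop("integration failed: step budget (", max_steps, ") exhausted at t = ",
         signif(res$t_reached, 6), " min")
  }
  states <- res$states
  colnames(states) <- species_names()
  x_end <- states[nrow(states), ]
  denom <- pmax(abs(x_end), 1e-12)
  settled <- max(abs(x_end - res$x90) / denom) < settle_tol
  f_end <- cc_rhs(as.numeric(object$params), object$hypothesis$digits, pmax(x_end, 0))
  structure(
    list(times = res$times, states = states, settled = settled,
         n_accept = res$n_accept, n_reject = res$n_reject,
         final_residual = max(abs(f_end))),
    class = "cc_trajectory"
  )
}

#' @export
print.cc_trajectory <- function(x, ...) {
  cat("<cc_trajectory> ", length(x$times), " points over [0, ",
      signif(max(x$times), 6), "] min; ",
      if (x$settled) "settled" else "not settled",
      " (final max|f| = ", signif(x$final_residual, 3), ")\n", sep = "")
  invisible(x)
}

#' Write a trajectory as TSV
#'
#' Columns: `time`, then the eight species.
#'
#' @param trajectory A `cc_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "cc_trajectory"))
  df <- data.frame(time = trajectory$times, trajectory$states,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthesis-rate surrogates for gene-expression activity
#'
#' Evaluates, for each dynamic species, the full synthesis (first) term of
#' its ODE at an equilibrium state.  Genetic synthesis rates are
#' proportional to transcription rates and therefore serve as surrogates for
#' gene-expression readouts; cyclin subtypes are not distinguished, so the
#' `CD`/`CE` entries cover both the cyclin and the Cdk readouts of each
#' complex.
#'
#' @param model A `cc_model`.
#' @param state An equilibrium state: `max(abs(rhs))` must be below `tol`.
#' @param tol Equilibrium residual tolerance; defaults to
#'   `1e-6 * max(synthesis rates)`.
#' @return Named numeric vector of synthesis rates (moles/cell/min).
#' @export
synthesis_surrogates <- function(model, state, tol = NULL) {
  stopifnot(inherits(model, "cc_model"))
  state <- check_state(state)
  if (is.null(tol)) tol <- 1e-6 * max(model$params[1:8])
  res <- max(abs(rhs(model, state)))
  if (res > tol) {
    stop("state is not an equilibrium: max|f| = ", signif(res, 4),
         " exceeds tolerance ", signif(tol, 4))
  }
  v <- as.numeric(cc_synthesis(as.numeric(model$params),
                               model$hypothesis$digits, state))
  setNames(v, species_names())
}

# substitute one parameter value, revalidating
set_param <- function(model, name, value) {
  p <- model$params
  if (!name %in% names(p)) stop("unknown parameter: ", name)
  p[[name]] <- value
  build_model(p, model$hypothesis)
}
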