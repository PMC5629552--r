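#' @useDynLib cycleswitch, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rlnorm runif setNames simulate
#' @importFrom utils read.table write.table modifyList
NULL

# Canonical parameter order.  Must stay in sync with the Par enum in
# src/model.cpp: the C++ routines address the vector positionally.
PARAM_NAMES <- c(
  "ks_maff", "ks_egr3", "ks_cd", "ks_ce", "ks_e2f", "ks_rb", "ks_p18", "ks_p19",
  "kd_mf", "kd_eg", "kd_cd", "kd_ce", "kd_e2f", "kd_rb", "kd_p18", "kd_p19",
  "kp_cd", "kp_ce",
  "K_ecd", "K_eg_cd", "K_i18", "K_i19", "K_i16", "K_ece", "K_eg_ce", "K_mf_ce",
  "K_i21", "K_i27", "K_ee", "K_rb_e2f", "K_prb", "K_e18", "K_eg18", "K_mf_p18",
  "K_e19", "K_eg19",
  "a_ecd", "e0", "e_auto", "b18", "a_e18", "b19", "a_e19", "g_eg18", "g_eg19",
  "alpha16", "alpha18", "alpha19", "alpha21", "alpha27", "beta",
  "GF", "P53_0", "AKT_0", "P16_0", "P21_base", "P27_base", "beta53", "K53",
  "K_akt"
)

# strictly-positive kinetic constants; the rest are non-negative gains/pools
.POSITIVE_PARAMS <- c(
  PARAM_NAMES[1:18],
  grep("^K_", PARAM_NAMES, value = TRUE), "K53", "K_akt"
)

#' Names of the dynamic species, in state-vector order
#'
#' The fixed ordering `MF, EG, CD, CE, E2F, RB, P18, P19` keeps Jacobian
#' row/column indices stable across the package.
#'
#' @return Character vector of length 8.
#' @export
species_names <- function() {
  c("MF", "EG", "CD", "CE", "E2F", "RB", "P18", "P19")
}

#' Names of all model parameters, in canonical order
#'
#' @return Character vector of length 60.
#' @export
param_names <- function() PARAM_NAMES

#' The frozen default parameter set
#'
#' A calibrated replacement for the literature-derived rate table that the
#' original study used: one named, versioned set under which the accepted
#' regulatory hypothesis (code `"2111"`) reproduces the qualitative screen
#' criteria (Maff-driven rise of Cyc D*/E2F with Cyc E* maintained,
#' Egr3-driven bistable shut-off of all three, and up-regulated p18/p19
#' under dual overexpression).  Units are moles/cell for concentrations and
#' half-saturation constants, 1/min for first-order rates, moles/cell/min
#' for synthesis rates; gain coefficients are dimensionless.
#'
#' @param overrides Named numeric vector or list of parameter values that
#'   replace the defaults (unknown names are an error).
#' @return Named numeric vector of length 60 with class `cc_params`.
#' @examples
#' p <- default_parameters()
#' p[["ks_maff"]]
#' @export
default_parameters <- function(overrides = NULL) {
  p <- c(
    # synthesis rates (moles/cell/min); ks_maff/ks_egr3 are the sweep axes
    ks_maff = 0.001, ks_egr3 = 0.001, ks_cd = 0.07, ks_ce = 0.014,
    ks_e2f = 0.45, ks_rb = 0.035, ks_p18 = 0.05, ks_p19 = 0.05,
    # degradation rates (1/min)
    kd_mf = 0.05, kd_eg = 0.05, kd_cd = 0.05, kd_ce = 0.05,
    kd_e2f = 0.05, kd_rb = 0.015, kd_p18 = 0.05, kd_p19 = 0.05,
    # Rb phosphorylation by the active cyclin complexes (1/min per moles/cell)
    kp_cd = 0.5, kp_ce = 0.5,
    # half-saturation constants (moles/cell)
    K_ecd = 1, K_eg_cd = 1, K_i18 = 0.5, K_i19 = 0.5, K_i16 = 0.5,
    K_ece = 0.05, K_eg_ce = 1, K_mf_ce = 1, K_i21 = 1, K_i27 = 1,
    K_ee = 2, K_rb_e2f = 0.05, K_prb = 0.3, K_e18 = 0.3, K_eg18 = 2,
    K_mf_p18 = 4, K_e19 = 0.3, K_eg19 = 2,
    # dimensionless gains
    a_ecd = 1, e0 = 0.02, e_auto = 1, b18 = 1, a_e18 = 0.5,
    b19 = 1, a_e19 = 0.5, g_eg18 = 8, g_eg19 = 4,
    alpha16 = 0.5, alpha18 = 15, alpha19 = 1, alpha21 = 1, alpha27 = 1,
    beta = 1,
    # quasi-static pools (moles/cell) and their couplings
    GF = 0.12, P53_0 = 0.1, AKT_0 = 1, P16_0 = 0.1,
    P21_base = 0.5, P27_base = 0.5, beta53 = 1, K53 = 0.5, K_akt = 0.5
  )
  stopifnot(identical(names(p), PARAM_NAMES))
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    bad <- setdiff(names(overrides), PARAM_NAMES)
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(overrides)] <- overrides
  }
  validate_parameters(p)
}

#' Validate a parameter set
#'
#' Checks completeness (all 60 keys, no extras), strict positivity of rates
#' and half-saturation constants, and non-negativity of gains and pools.
#'
#' @param p Named numeric vector of parameters.
#' @return The validated vector, reordered canonically, class `cc_params`.
#' @export
validate_parameters <- function(p) {
  p <- unlist(p)
  missing <- setdiff(PARAM_NAMES, names(p))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(p), PARAM_NAMES)
  if (length(extra)) {
    stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  }
  p <- p[PARAM_NAMES]
  if (anyNA(p) || any(!is.finite(p))) {
    stop("non-finite parameter(s): ",
         paste(PARAM_NAMES[!is.finite(p)], collapse = ", "))
  }
  nonpos <- PARAM_NAMES %in% .POSITIVE_PARAMS & p <= 0
  if (any(nonpos)) {
    stop("parameter(s) must be > 0: ", paste(PARAM_NAMES[nonpos], collapse = ", "))
  }
  if (any(p < 0)) {
    stop("parameter(s) must be >= 0: ", paste(PARAM_NAMES[p < 0], collapse = ", "))
  }
  structure(p, class = "cc_params")
}

#' Effective quasi-static CKI pools
#'
#' p16, p21 and p27 are carried as static pools rather than dynamic species.
#' p21 is raised by p53 (apoptosis coupling) and p27 is relieved by Akt
#' (survival coupling): `P21 = P21_base * (1 + beta53 * A(P53_0; K53))` and
#' `P27 = P27_base * I(AKT_0; K_akt)` with `A(x;K) = x/(K+x)`,
#' `I(x;K) = K/(K+x)`.
#'
#' @param p A parameter set (see [default_parameters()]).
#' @return Named numeric vector with entries `P21` and `P27` (moles/cell).
#' @export
static_pools <- function(p) {
  p <- validate_parameters(p)
  cc_static_pools(as.numeric(p))
}

#' Read a parameter file
#'
#' Flat key-value text format, one `name = value` (or tab/space separated
#' `name value`) pair per line; `#` starts a comment.  The full canonical
#' key set is required; unknown keys are rejected.
#'
#' @param path File path.
#' @return A validated `cc_params` vector.
#' @export
read_parameters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=\t ]+")
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop("malformed parameter line(s): ", paste(lines[bad], collapse = "; "))
  }
  vals <- vapply(kv, function(x) suppressWarnings(as.numeric(x[2])), numeric(1))
  if (anyNA(vals)) {
    stop("non-numeric value for: ",
         paste(vapply(kv[is.na(vals)], `[`, character(1), 1), collapse = ", "))
  }
  validate_parameters(setNames(vals, vapply(kv, `[`, character(1), 1)))
}

#' Write a parameter file
#'
#' @param p Parameter set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  p <- validate_parameters(p)
  writeLines(sprintf("%s = %.17g", names(p), as.numeric(p)), path)
  invisible(path)
}

#' @export
print.cc_params <- function(x, ...) {
  cat("<cc_params> ", length(x), " model parameters\n", sep = "")
  print(setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}
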