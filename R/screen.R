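# The 81-way regulatory hypothesis screen.  Each candidate action tuple is
# grafted onto the base cell-cycle model and judged against three
# qualitative criteria that encode the experimental reference data:
#   C1 (proliferation / G0 exit): raising Maff expression at low Egr3 must
#       lift the stable Cyc D* and E2F branches by >= fold_up_min while
#       Cyc E* is maintained (>= ce_floor_frac of baseline) throughout;
#   C2 (G0 arrest): raising Egr3 expression at low Maff must suppress
#       Cyc D*, Cyc E* and E2F to <= suppress_frac of baseline, with the
#       shut-off occurring through a bistable (fold) transition;
#   C3 (expression profile): under dual Maff/Egr3 overexpression the
#       synthesis-rate surrogates must match the configured sign profile
#       (by default p18/p19 up, Cyc D*/Cyc E*/E2F down versus baseline).

#' Screen criteria configuration
#'
#' Thresholds and sweep settings for the hypothesis screen.  Invariant:
#' `0 < suppress_frac < ce_floor_frac <= 1 < fold_up_min`.
#'
#' @param fold_up_min Minimum fold-rise of Cyc D* and E2F under the Maff
#'   sweep (default 1.5).
#' @param ce_floor_frac Minimum maintained fraction of baseline Cyc E*
#'   under the Maff sweep (default 0.5).
#' @param suppress_frac Maximum endpoint fraction of baseline for
#'   Cyc D*/Cyc E*/E2F under the Egr3 sweep (default 0.1).
#' @param require_bistable_egr3 Require a bistable interval in the Egr3
#'   sweep (default TRUE).
#' @param dual_high_profile Named character vector of required surrogate
#'   directions (`"up"`, `"down"`, `"flat"`) under dual overexpression;
#'   names among `p18, p19, cycD, cycE, E2F`.  Defaults to the directions
#'   of [generate_reference_profile()] for the `dual_high` condition.
#' @param flat_band Fold-change beyond which a surrogate ratio counts as
#'   `up` (ratio >= flat_band) or `down` (ratio <= 1/flat_band);
#'   default 1.2.
#' @param grid_n,grid_from,grid_to Sweep grid: `grid_n` log-spaced points
#'   over `[grid_from, grid_to]` moles/cell/min, shared by both axes.
#' @param maff_low,egr3_low,maff_high,egr3_high Frozen `low`/`high`
#'   expression levels (synthesis rates); defaults are the grid endpoints.
#' @param n_starts,seed Multi-start settings per grid point.
#' @param max_gap_frac Fraction of grid points allowed to lack a stable
#'   equilibrium before a hypothesis evaluation errors (default 0.2).
#' @return A `cc_criteria` list.
#' @export
screen_criteria <- function(fold_up_min = 1.5, ce_floor_frac = 0.5,
                            suppress_frac = 0.1, require_bistable_egr3 = TRUE,
                            dual_high_profile = NULL, flat_band = 1.2,
                            grid_n = 60L, grid_from = 1e-3, grid_to = 0.5,
                            maff_low = grid_from, egr3_low = grid_from,
                            maff_high = grid_to, egr3_high = grid_to,
                            n_starts = 8L, seed = 1L, max_gap_frac = 0.2) {
  if (!(0 < suppress_frac && suppress_frac < ce_floor_frac &&
        ce_floor_frac <= 1 && 1 < fold_up_min)) {
    stop("criteria must satisfy 0 < suppress_frac < ce_floor_frac <= 1 < fold_up_min")
  }
  if (is.null(dual_high_profile)) {
    prof <- generate_reference_profile("dual_high", seed = seed, sigma = 0)
    dual_high_profile <- setNames(prof$table$direction, prof$table$readout)
  }
  known <- c("p18", "p19", "cycD", "cycE", "E2F")
  dual_high_profile <- dual_high_profile[names(dual_high_profile) %in% known]
  if (!all(dual_high_profile %in% c("up", "down", "flat"))) {
    stop("profile directions must be 'up', 'down' or 'flat'")
  }
  structure(
    list(fold_up_min = fold_up_min, ce_floor_frac = ce_floor_frac,
         suppress_frac = suppress_frac,
         require_bistable_egr3 = require_bistable_egr3,
         dual_high_profile = dual_high_profile, flat_band = flat_band,
         grid_n = as.integer(grid_n), grid_from = grid_from, grid_to = grid_to,
         maff_low = maff_low, egr3_low = egr3_low,
         maff_high = maff_high, egr3_high = egr3_high,
         n_starts = as.integer(n_starts), seed = as.integer(seed),
         max_gap_frac = max_gap_frac),
    class = "cc_criteria"
  )
}

#' @export
print.cc_criteria <- function(x, ...) {
  cat("<cc_criteria> fold_up_min=", x$fold_up_min, ", ce_floor_frac=",
      x$ce_floor_frac, ", suppress_frac=", x$suppress_frac,
      ", bistable required=", x$require_bistable_egr3, "\n",
      "  grid: ", x$grid_n, " log points [", x$grid_from, ", ", x$grid_to,
      "], ", x$n_starts, " starts, seed ", x$seed, "\n",
      "  dual-high profile: ",
      paste(names(x$dual_high_profile), x$dual_high_profile, sep = ":",
            collapse = " "), "\n", sep = "")
  invisible(x)
}

criteria_grid <- function(criteria) {
  default_grid(criteria$grid_n, criteria$grid_from, criteria$grid_to)
}

# upper-branch readouts along a sweep; list(values matrix, gap fraction)
branch_values <- function(sweep) {
  vals <- matrix(NA_real_, length(sweep$grid), 3,
                 dimnames = list(NULL, c("CD", "CE", "E2F")))
  for (i in seq_along(sweep$grid)) {
    e <- upper_stable(sweep, i)
    if (!is.null(e)) vals[i, ] <- e$state[c("CD", "CE", "E2F")]
  }
  vals
}

# does any grid point carry >= 2 stable equilibria separated > 2-fold in
# E2F or CE?
has_bistable_switch <- function(sweep) {
  for (i in seq_along(sweep$grid)) {
    stab <- Filter(function(e) e$stability == "stable", sweep$equilibria[[i]])
    if (length(stab) < 2) next
    for (sp in c("E2F", "CE")) {
      v <- vapply(stab, function(e) e$state[[sp]], numeric(1))
      if (max(v) > 2 * max(min(v), 1e-300)) return(TRUE)
    }
  }
  FALSE
}

#' Evaluate one regulatory hypothesis against the screen criteria
#'
#' @param hypothesis Code string or `cc_hypothesis`.
#' @param params Parameter set.
#' @param criteria A `cc_criteria` (default [screen_criteria()]).
#' @return Named logical vector `c(C1, C2, C3)`.
#' @export
evaluate_hypothesis <- function(hypothesis, params = default_parameters(),
                                criteria = screen_criteria()) {
  hyp <- as_hypothesis(hypothesis)
  params <- validate_parameters(params)
  grid <- criteria_grid(criteria)
  ns <- criteria$n_starts
  sd <- criteria$seed

  # C1: Maff sweep at low Egr3
  m1 <- build_model(`[[<-`(params, "ks_egr3", criteria$egr3_low), hyp)
  sw1 <- sweep_parameter(m1, "ks_maff", grid, n_starts = ns, seed = sd)
  v1 <- branch_values(sw1)
  gap1 <- mean(is.na(v1[, 1]))
  if (gap1 > criteria$max_gap_frac || anyNA(v1[c(1, nrow(v1)), ])) {
    stop("hypothesis ", hyp$code, ": no stable equilibrium on ",
         round(100 * gap1), "% of the Maff sweep grid")
  }
  base1 <- v1[1, ]
  end1 <- v1[nrow(v1), ]
  C1 <- end1[["CD"]] >= criteria$fold_up_min * base1[["CD"]] &&
    end1[["E2F"]] >= criteria$fold_up_min * base1[["E2F"]] &&
    min(v1[, "CE"], na.rm = TRUE) >= criteria$ce_floor_frac * base1[["CE"]]

  # C2: Egr3 sweep at low Maff
  m2 <- build_model(`[[<-`(params, "ks_maff", criteria$maff_low), hyp)
  sw2 <- sweep_parameter(m2, "ks_egr3", grid, n_starts = ns, seed = sd)
  v2 <- branch_values(sw2)
  gap2 <- mean(is.na(v2[, 1]))
  if (gap2 > criteria$max_gap_frac || anyNA(v2[c(1, nrow(v2)), ])) {
    stop("hypothesis ", hyp$code, ": no stable equilibrium on ",
         round(100 * gap2), "% of the Egr3 sweep grid")
  }
  base2 <- v2[1, ]
  # endpoint suppression must hold for every stable equilibrium at grid max
  end_stab <- Filter(function(e) e$stability == "stable",
                     sw2$equilibria[[length(grid)]])
  end2 <- sapply(c("CD", "CE", "E2F"), function(sp) {
    max(vapply(end_stab, function(e) e$state[[sp]], numeric(1)))
  })
  C2 <- all(end2 <= criteria$suppress_frac * base2)
  if (criteria$require_bistable_egr3) {
    C2 <- C2 && has_bistable_switch(sw2)
  }

  # C3: dual-high surrogate signs, reached from the baseline state
  p_base <- params
  p_base[["ks_maff"]] <- criteria$maff_low
  p_base[["ks_egr3"]] <- criteria$egr3_low
  m_base <- build_model(p_base, hyp)
  eq_base <- find_all_equilibria(m_base, n_starts = ns, seed = sd)
  stab_base <- Filter(function(e) e$stability == "stable", eq_base)
  if (!length(stab_base)) {
    stop("hypothesis ", hyp$code, ": no stable baseline equilibrium")
  }
  base_state <- stab_base[[1]]$state  # highest-E2F stable state
  s_base <- synthesis_surrogates(m_base, base_state, tol = Inf)

  p_dual <- params
  p_dual[["ks_maff"]] <- criteria$maff_high
  p_dual[["ks_egr3"]] <- criteria$egr3_high
  m_dual <- build_model(p_dual, hyp)
  tr <- simulate(m_dual, x0 = base_state, t_end = 5000)
  eq_dual <- find_equilibrium(m_dual, tr$states[nrow(tr$states), ])
  s_dual <- synthesis_surrogates(m_dual, eq_dual$state, tol = Inf)

  map <- c(p18 = "P18", p19 = "P19", cycD = "CD", cycE = "CE", E2F = "E2F")
  C3 <- TRUE
  for (nm in names(criteria$dual_high_profile)) {
    dir <- criteria$dual_high_profile[[nm]]
    if (dir == "flat") next
    ratio <- s_dual[[map[[nm]]]] / s_base[[map[[nm]]]]
    ok <- if (dir == "up") ratio >= criteria$flat_band else
      ratio <= 1 / criteria$flat_band
    C3 <- C3 && ok
  }

  c(C1 = C1, C2 = C2, C3 = C3)
}

#' Run the exhaustive 81-hypothesis screen
#'
#' Evaluates every regulatory code (`"1111"` ... `"3333"`) against the
#' criteria; deterministic for fixed parameters, criteria and seed.
#' Per-hypothesis evaluation errors are recorded as failed rows
#' (`ok = FALSE`), not propagated.
#'
#' @param params Parameter set.
#' @param criteria A `cc_criteria`.
#' @param progress Print a progress line per hypothesis (default FALSE).
#' @return A `cc_screen` with a 81-row `table` (columns `code`, `d1`..`d4`,
#'   `C1`, `C2`, `C3`, `pass`, `ok`) and provenance hashes.
#' @export
run_screen <- function(params = default_parameters(),
                       criteria = screen_criteria(), progress = FALSE) {
  params <- validate_parameters(params)
  hyps <- enumerate_hypotheses()
  rows <- vector("list", length(hyps))
  for (i in seq_along(hyps)) {
    h <- hyps[[i]]
    cr <- tryCatch(evaluate_hypothesis(h, params, criteria),
                   error = function(e) NULL)
    ok <- !is.null(cr)
    if (!ok) cr <- c(C1 = FALSE, C2 = FALSE, C3 = FALSE)
    rows[[i]] <- data.frame(
      code = h$code, d1 = h$digits[1], d2 = h$digits[2], d3 = h$digits[3],
      d4 = h$digits[4], C1 = cr[["C1"]], C2 = cr[["C2"]], C3 = cr[["C3"]],
      pass = all(cr), ok = ok
    )
    if (progress) {
      message(sprintf("[%2d/81] %s C1=%d C2=%d C3=%d", i, h$code,
                      cr[["C1"]], cr[["C2"]], cr[["C3"]]))
    }
  }
  structure(
    list(table = do.call(rbind, rows),
         params_hash = config_hash(params),
         criteria_hash = config_hash(criteria)),
    class = "cc_screen"
  )
}

#' @export
print.cc_screen <- function(x, ...) {
  passing <- x$table$code[x$table$pass]
  cat("<cc_screen> 81 hypotheses; ", length(passing), " passing",
      if (length(passing)) paste0(": ", paste(passing, collapse = ", ")),
      "\n", sep = "")
  cat("  params ", x$params_hash, ", criteria ", x$criteria_hash, "\n",
      sep = "")
  invisible(x)
}

#' Necessary-edge set of a screen result
#'
#' The signed intersection over all passing hypotheses of their non-`none`
#' edges: edges that appear, with identical sign, in every model consistent
#' with the data — the minimum mechanistic inference.
#'
#' @param result A `cc_screen`.
#' @return data.frame with columns `edge` and `action`; zero rows (with a
#'   warning) when nothing passes.
#' @export
necessary_edges <- function(result) {
  stopifnot(inherits(result, "cc_screen"))
  tab <- result$table[result$table$pass, , drop = FALSE]
  if (!nrow(tab)) {
    warning("no passing hypothesis; necessary-edge set is empty")
    return(data.frame(edge = character(0), action = character(0)))
  }
  digits <- as.matrix(tab[, c("d1", "d2", "d3", "d4")])
  keep <- logical(4)
  for (k in 1:4) {
    keep[k] <- all(digits[, k] == digits[1, k]) && digits[1, k] != 2L
  }
  data.frame(
    edge = edge_names()[keep],
    action = c("inhibitory", "none", "activatory")[digits[1, keep]]
  )
}

#' Write the screen table as TSV
#'
#' Mirrors the exhaustive-combination table layout: four code-digit
#' columns, then 0/1 agreement columns per criterion and overall.
#'
#' @param result A `cc_screen`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(result, path) {
  stopifnot(inherits(result, "cc_screen"))
  tab <- result$table
  out <- data.frame(
    maff_cdk2 = tab$d1, maff_p18 = tab$d2, egr3_cdk2 = tab$d3,
    egr3_cdk46 = tab$d4, C1 = as.integer(tab$C1), C2 = as.integer(tab$C2),
    C3 = as.integer(tab$C3), pass = as.integer(tab$pass)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a criteria file
#'
#' Flat key-value text format; profile entries use keys
#' `profile_<readout> = up|down|flat`.
#'
#' @param path File path.
#' @return For `read_criteria`, a `cc_criteria`.
#' @export
read_criteria <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=\t ]+")
  if (any(lengths(kv) != 2)) stop("malformed criteria line(s) in ", path)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  is_prof <- startsWith(keys, "profile_")
  prof <- setNames(vals[is_prof], sub("^profile_", "", keys[is_prof]))
  args <- as.list(as.numeric(vals[!is_prof]))
  names(args) <- keys[!is_prof]
  for (nm in c("grid_n", "n_starts", "seed")) {
    if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
  }
  if ("require_bistable_egr3" %in% names(args)) {
    args$require_bistable_egr3 <- args$require_bistable_egr3 != 0
  }
  if (length(prof)) args$dual_high_profile <- prof
  do.call(screen_criteria, args)
}

#' @rdname read_criteria
#' @param criteria A `cc_criteria`.
#' @export
write_criteria <- function(criteria, path) {
  stopifnot(inherits(criteria, "cc_criteria"))
  num <- criteria[setdiff(names(criteria), "dual_high_profile")]
  num$require_bistable_egr3 <- as.integer(num$require_bistable_egr3)
  lines <- c(
    sprintf("%s = %.17g", names(num), as.numeric(unlist(num))),
    sprintf("profile_%s = %s", names(criteria$dual_high_profile),
            criteria$dual_high_profile)
  )
  writeLines(lines, path)
  invisible(path)
}

# small FNV-1a hash for provenance stamps (no external digest dependency)
config_hash <- function(x) {
  s <- paste(deparse(lapply(unclass(x), unname)), collapse = "")
  h <- 2166136261
  mul <- function(a) {
    lo <- (a %% 65536) * 16777619
    hi <- ((a %/% 65536) * 16777619) %% 65536
    (lo + hi * 65536) %% 4294967296
  }
  for (ch in utf8ToInt(s)) h <- mul(bitwXor(as.integer(h %% 2147483648), ch) +
                                      (h %/% 2147483648) * 2147483648)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
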