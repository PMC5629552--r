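# Regulatory hypotheses: the 4-tuple of candidate Maff/Egr3 actions and its
# digit code.  Digit mapping: "1" inhibitory, "2" none, "3" activatory.
# Positional order follows the hypothesis-set enumeration:
#   h1 = Maff -> Cdk2(:CyclinE), h2 = Maff -> p18,
#   h3 = Egr3 -> Cdk2(:CyclinE), h4 = Egr3 -> Cdk4/6(:CyclinD).

.ACTIONS <- c("inhibitory", "none", "activatory")  # digit = index

.EDGE_NAMES <- c(
  "Maff->Cdk2(:CycE)", "Maff->p18", "Egr3->Cdk2(:CycE)", "Egr3->Cdk4/6(:CycD)"
)

#' Names of the four candidate regulatory edges
#'
#' @return Character vector of length 4 in code-digit order.
#' @export
edge_names <- function() .EDGE_NAMES

#' Parse a 4-digit regulatory code
#'
#' Each digit encodes the action of one candidate edge: `1` inhibitory,
#' `2` none, `3` activatory.  Digit positions correspond to
#' `Maff->Cdk2(:CycE)`, `Maff->p18`, `Egr3->Cdk2(:CycE)`,
#' `Egr3->Cdk4/6(:CycD)`.
#'
#' @param code A single string matching `[123]{4}`, e.g. `"2111"`.
#' @return A `cc_hypothesis` object with fields `h1`..`h4` (action strings),
#'   `digits` (integer vector) and `code`.
#' @examples
#' parse_code("2111")
#' @export
parse_code <- function(code) {
  if (!is.character(code) || length(code) != 1 || is.na(code) ||
      !grepl("^[123]{4}$", code)) {
    stop("regulatory code must be a single string of four digits in {1,2,3}, got: ",
         deparse(code))
  }
  digits <- as.integer(strsplit(code, "")[[1]])
  structure(
    list(h1 = .ACTIONS[digits[1]], h2 = .ACTIONS[digits[2]],
         h3 = .ACTIONS[digits[3]], h4 = .ACTIONS[digits[4]],
         digits = digits, code = code),
    class = "cc_hypothesis"
  )
}

#' Encode a regulatory hypothesis back to its 4-digit code
#'
#' Round-trips with [parse_code()]: `encode_hypothesis(parse_code(x)) == x`.
#'
#' @param h A `cc_hypothesis`, or a length-4 vector of action strings
#'   (`"inhibitory"`, `"none"`, `"activatory"`).
#' @return The 4-character code string.
#' @export
encode_hypothesis <- function(h) {
  if (inherits(h, "cc_hypothesis")) return(h$code)
  acts <- as.character(unlist(h))
  if (length(acts) != 4 || !all(acts %in% .ACTIONS)) {
    stop("hypothesis must be four actions in {",
         paste(.ACTIONS, collapse = ", "), "}")
  }
  paste(match(acts, .ACTIONS), collapse = "")
}

#' Enumerate all 81 regulatory hypotheses
#'
#' All 3^4 action combinations, ordered by ascending code
#' (`"1111"` ... `"3333"`), each exactly once.
#'
#' @return List of 81 `cc_hypothesis` objects.
#' @export
enumerate_hypotheses <- function() {
  grid <- expand.grid(d4 = 1:3, d3 = 1:3, d2 = 1:3, d1 = 1:3)
  codes <- sort(apply(grid[, c("d1", "d2", "d3", "d4")], 1, paste, collapse = ""))
  lapply(codes, parse_code)
}

#' @export
print.cc_hypothesis <- function(x, ...) {
  cat("<cc_hypothesis> code ", x$code, "\n", sep = "")
  for (k in 1:4) {
    cat(sprintf("  %-22s %s\n", .EDGE_NAMES[k], x[[paste0("h", k)]]))
  }
  invisible(x)
}

as_hypothesis <- function(h) {
  if (inherits(h, "cc_hypothesis")) h else parse_code(h)
}
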