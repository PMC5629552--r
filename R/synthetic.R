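# Deterministic synthetic fixtures: promoter sequences with motifs planted
# at known upstream offsets (stand-ins for real gene records, which the
# pipeline never downloads), and qualitative reference profiles emulating
# the qRT-PCR / cell-cycle readouts that the hypothesis screen uses as its
# consistency reference.

#' Specify a synthetic promoter
#'
#' @param id Record identifier.
#' @param length Sequence length in bp.
#' @param gc GC fraction of the i.i.d. background, in (0, 1).
#' @param tss 1-based TSS position within the sequence.
#' @param plantings data.frame (or list coercible to one) with columns
#'   `pattern` (motif pattern or plain variant; optional-base patterns are
#'   planted with all optional bases present), `offset` (upstream offset of
#'   the motif base nearest the TSS, >= 1) and `strand` (`"+"`/`"-"`).
#' @param strand Strand on which the record is written out; `"-"` records
#'   are reverse-complemented in the FASTA (with the TSS coordinate
#'   transformed) and flipped back on load by [read_promoters()].
#' @param seed Integer seed; the generator is a pure function of spec+seed.
#' @return A `cc_promoter_spec`.
#' @export
synthetic_promoter_spec <- function(id, length = 2500L, gc = 0.45,
                                    tss = NULL, plantings = NULL,
                                    strand = "+", seed = 1L) {
  length <- as.integer(length)
  if (is.null(tss)) tss <- length - 100L
  tss <- as.integer(tss)
  if (gc <= 0 || gc >= 1) stop("gc fraction must be in (0, 1)")
  if (tss < 1 || tss > length) stop("TSS outside sequence")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (is.null(plantings)) {
    plantings <- data.frame(pattern = character(0), offset = integer(0),
                            strand = character(0))
  }
  plantings <- as.data.frame(plantings, stringsAsFactors = FALSE)
  if (nrow(plantings) &&
      !all(c("pattern", "offset", "strand") %in% names(plantings))) {
    stop("plantings need columns pattern, offset, strand")
  }
  spec <- structure(
    list(id = id, length = length, gc = gc, tss = tss,
         plantings = plantings, strand = strand, seed = as.integer(seed)),
    class = "cc_promoter_spec"
  )
  # feasibility: placements inside the upstream window, pairwise disjoint
  pl <- planting_layout(spec)
  if (nrow(pl) > 1) {
    o <- order(pl$start)
    pl <- pl[o, ]
    if (any(pl$start[-1] <= pl$end[-nrow(pl)])) {
      stop("plantings overlap")
    }
  }
  spec
}

# resolve each planting to (variant, start, end, strand, offset) in plus
# orientation; errors on infeasible offsets
planting_layout <- function(spec) {
  pl <- spec$plantings
  out <- list()
  for (i in seq_len(nrow(pl))) {
    variants <- expand_pattern(pl$pattern[i])
    v <- variants[which.max(nchar(variants))]  # all optional bases present
    len <- nchar(v)
    off <- as.integer(pl$offset[i])
    if (off < 1) stop("planting offset must be >= 1")
    end <- spec$tss - off        # base nearest the TSS
    start <- end - len + 1L
    if (start < 1) {
      stop("planting of ", pl$pattern[i], " at offset ", off,
           " does not fit upstream of the TSS")
    }
    strand <- pl$strand[i]
    if (!strand %in% c("+", "-")) stop("planting strand must be '+' or '-'")
    # a palindromic variant planted on the minus strand is
    # indistinguishable from a plus-strand planting; canonicalise
    if (strand == "-" && reverse_complement(v) == v) strand <- "+"
    out[[i]] <- data.frame(
      pattern = pl$pattern[i], variant = v, start = start, end = end,
      strand = strand, offset = off
    )
  }
  if (!length(out)) {
    return(data.frame(pattern = character(0), variant = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), offset = integer(0)))
  }
  do.call(rbind, out)
}

#' Generate a synthetic promoter with planted motifs
#'
#' Draws an i.i.d. background at the requested GC fraction, plants each
#' motif at its specified upstream offset (nearest-base convention), and
#' rejection-resamples the background until no unplanted occurrence of any
#' planted motif variant (either strand) remains in the upstream window.
#' Deterministic for a fixed spec and seed.
#'
#' @param spec A `cc_promoter_spec`.
#' @return List with `sequence` (plus-orientation string), `fasta_record`
#'   (named character, as written), `tss_row` (data.frame `id`,
#'   `tss_position`, `strand`), and `truth` (data.frame of expected hits:
#'   `pattern`, `variant`, `strand`, `upstream_offset`, `abs_start`).
#' @examples
#' spec <- synthetic_promoter_spec("demo", 2500, 0.45, tss = 2400,
#'   plantings = data.frame(pattern = "CGCCCCCGC", offset = 523,
#'                          strand = "+"), seed = 7)
#' pr <- generate_promoter(spec)
#' pr$truth
#' @export
generate_promoter <- function(spec) {
  stopifnot(inherits(spec, "cc_promoter_spec"))
  layout <- planting_layout(spec)
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
  patterns <- unique(layout$pattern)

  seq_chars <- NULL
  withr_seed(spec$seed, {
    for (attempt in 1:1000) {
      chars <- sample(bases, spec$length, replace = TRUE, prob = probs)
      for (i in seq_len(nrow(layout))) {
        v <- layout$variant[i]
        if (layout$strand[i] == "-") v <- reverse_complement(v)
        chars[layout$start[i]:layout$end[i]] <- strsplit(v, "")[[1]]
      }
      candidate <- paste(chars, collapse = "")
      if (promoter_is_clean(candidate, spec$tss, patterns, layout)) {
        seq_chars <- candidate
        break
      }
    }
  })
  if (is.null(seq_chars)) {
    stop("could not generate a motif-clean background in 1000 attempts")
  }

  truth <- if (nrow(layout)) {
    data.frame(pattern = layout$pattern, variant = layout$variant,
               strand = layout$strand, upstream_offset = layout$offset,
               abs_start = layout$start)
  } else {
    data.frame(pattern = character(0), variant = character(0),
               strand = character(0), upstream_offset = integer(0),
               abs_start = integer(0))
  }

  out_seq <- seq_chars
  out_tss <- spec$tss
  if (spec$strand == "-") {
    out_seq <- reverse_complement(seq_chars)
    out_tss <- spec$length - spec$tss + 1L
  }
  list(
    sequence = seq_chars,
    fasta_record = setNames(out_seq, spec$id),
    tss_row = data.frame(id = spec$id, tss_position = out_tss,
                         strand = spec$strand),
    truth = truth
  )
}

# TRUE when the upstream window contains exactly the planted occurrences
promoter_is_clean <- function(sequence, tss, patterns, layout) {
  region <- promoter_region("tmp", sequence, tss)
  for (pat in patterns) {
    hits <- scan_promoter(region, motif_pattern(pat, pat),
                          window_bp = tss - 1L, both_strands = TRUE)
    want <- layout[layout$pattern == pat, , drop = FALSE]
    if (nrow(hits) != nrow(want)) return(FALSE)
    if (nrow(want) &&
        !setequal(paste(hits$abs_start, hits$strand),
                  paste(want$start, want$strand))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Write promoter fixtures to FASTA + TSS table
#'
#' @param promoters List of [generate_promoter()] results.
#' @param fasta_path,tss_path Output paths.
#' @return Invisible list of the two paths.
#' @export
write_promoter_fixture <- function(promoters, fasta_path, tss_path) {
  recs <- unlist(lapply(promoters, `[[`, "fasta_record"))
  lines <- as.vector(rbind(paste0(">", names(recs)), unname(recs)))
  writeLines(lines, fasta_path)
  tss <- do.call(rbind, lapply(promoters, `[[`, "tss_row"))
  write.table(tss, tss_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta_path, tss = tss_path))
}

.PROFILE_READOUTS <- c("p18", "p19", "cycD", "cycE", "E2F", "G0_fraction")

.PROFILE_DIRECTIONS <- list(
  baseline = c(p18 = "flat", p19 = "flat", cycD = "flat", cycE = "flat",
               E2F = "flat", G0_fraction = "flat"),
  # Maff overexpression mobilises HSCs out of G0: Cyc D*/E2F up, G0 down,
  # p18 repressed; Cyc E* maintained
  maff_high = c(p18 = "down", p19 = "flat", cycD = "up", cycE = "flat",
                E2F = "up", G0_fraction = "down"),
  # Egr3 overexpression arrests HSCs in G0: checkpoint determinants down,
  # G0 fraction and the E2F-independent CKIs up
  egr3_high = c(p18 = "up", p19 = "up", cycD = "down", cycE = "down",
                E2F = "down", G0_fraction = "up"),
  # dual overexpression (leukemia-like): Egr3 arrest dominates, p18/p19 up
  dual_high = c(p18 = "up", p19 = "up", cycD = "down", cycE = "down",
                E2F = "down", G0_fraction = "up")
)

.FOLD_MEANS <- c(up = 2.5, down = 0.3, flat = 1.0)

#' Generate a qualitative reference profile
#'
#' Sign patterns (with lognormal fold-change noise) standing in for the
#' qRT-PCR and cell-cycle flow-cytometry readouts of the four experimental
#' conditions.  The hypothesis screen consumes only the signs, so the noise
#' exercises robustness rather than correctness.
#'
#' @param condition One of `"baseline"`, `"maff_high"`, `"egr3_high"`,
#'   `"dual_high"`.
#' @param seed Integer seed.
#' @param sigma Lognormal noise on the fold-changes (default 0.2; 0 gives
#'   the configured means exactly).
#' @return A `cc_profile`: `condition`, `table` (data.frame `readout`,
#'   `direction`, `fold`), `seed`, `sigma`.
#' @examples
#' generate_reference_profile("egr3_high", seed = 1)$table
#' @export
generate_reference_profile <- function(condition, seed = 1L, sigma = 0.2) {
  if (!condition %in% names(.PROFILE_DIRECTIONS)) {
    stop("unknown condition: ", condition, " (expected one of ",
         paste(names(.PROFILE_DIRECTIONS), collapse = ", "), ")")
  }
  dirs <- .PROFILE_DIRECTIONS[[condition]]
  noise <- withr_seed(seed, rlnorm(length(dirs), 0, sigma))
  tab <- data.frame(
    readout = names(dirs), direction = unname(dirs),
    fold = unname(.FOLD_MEANS[dirs] * noise)
  )
  structure(list(condition = condition, table = tab, seed = seed,
                 sigma = sigma),
            class = "cc_profile")
}

#' @export
print.cc_profile <- function(x, ...) {
  cat("<cc_profile> condition ", x$condition, " (seed ", x$seed,
      ", sigma ", x$sigma, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Build a self-contained screen + scan fixture directory
#'
#' Writes a parameter file, a criteria file (dual-high profile included),
#' and a promoter FASTA + TSS table with the two built-in motifs planted at
#' the upstream offsets of the validated gene geometries (MARE at 156 bp in
#' a Prdm1-like synthetic record; the Egr3 element at 523 bp in an
#' Anapc11-like synthetic record).  Regenerating with the same seed yields
#' identical bytes.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param sigma Profile fold-change noise (default 0.2).
#' @return Named list of file paths.
#' @export
make_screen_fixture <- function(dir, seed = 1L, sigma = 0.2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params_path <- file.path(dir, "params.txt")
  write_parameters(default_parameters(), params_path)

  prof <- generate_reference_profile("dual_high", seed = seed, sigma = sigma)
  crit <- screen_criteria(
    dual_high_profile = setNames(prof$table$direction, prof$table$readout),
    seed = seed
  )
  criteria_path <- file.path(dir, "criteria.txt")
  write_criteria(crit, criteria_path)

  specs <- list(
    synthetic_promoter_spec("Prdm1_synthetic", 2500, 0.45, tss = 2400,
      plantings = data.frame(pattern = "TGCTGAC(G)TCAGCA", offset = 156,
                             strand = "+"),
      seed = seed),
    synthetic_promoter_spec("Anapc11_synthetic", 2500, 0.5, tss = 2400,
      plantings = data.frame(pattern = "CGCCCCCGC", offset = 523,
                             strand = "+"),
      seed = seed + 1L),
    synthetic_promoter_spec("background_synthetic", 2500, 0.4, tss = 2400,
                            seed = seed + 2L)
  )
  proms <- lapply(specs, generate_promoter)
  fasta_path <- file.path(dir, "promoters.fasta")
  tss_path <- file.path(dir, "tss.tsv")
  write_promoter_fixture(proms, fasta_path, tss_path)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- do.call(rbind, lapply(seq_along(proms), function(i) {
    t <- proms[[i]]$truth
    if (nrow(t)) cbind(id = specs[[i]]$id, t) else NULL
  }))
  if (is.null(truth)) truth <- data.frame()
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)

  list(params = params_path, criteria = criteria_path, fasta = fasta_path,
       tss = tss_path, truth = truth_path)
}
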