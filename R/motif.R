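# Exact-match promoter motif scanning.  The two motifs of interest are the
# maf recognition element (MARE), written "TGCTGAC(G)TCAGCA" with an
# optional central G, and the Egr3-recognised cis element "CGCCCCCGC".
# Matching follows the most stringent criterion: every nucleotide must
# match exactly; N never matches.

#' Built-in motif patterns
#'
#' `MARE` is the palindromic maf recognition element bound by Maf-family
#' bZip factors; `EGR3` is the cis element through which Egr3 activates
#' transcription (found upstream of Anapc11).
#'
#' @return Named list of `cc_motif` objects.
#' @export
cc_motifs <- function() {
  list(MARE = motif_pattern("MARE", "TGCTGAC(G)TCAGCA"),
       EGR3 = motif_pattern("EGR3", "CGCCCCCGC"))
}

#' Construct a motif pattern
#'
#' Patterns are plain `A/C/G/T` strings in which a parenthesised single
#' base, e.g. the `(G)` of `TGCTGAC(G)TCAGCA`, marks an optional position;
#' a pattern with `k` optional groups expands to `2^k` plain variants.
#'
#' @param name Motif name.
#' @param pattern Pattern string.
#' @return A `cc_motif` with the deduplicated `variants` precomputed.
#' @export
motif_pattern <- function(name, pattern) {
  structure(
    list(name = name, pattern = pattern, variants = expand_pattern(pattern)),
    class = "cc_motif"
  )
}

#' @export
print.cc_motif <- function(x, ...) {
  cat("<cc_motif> ", x$name, ": ", x$pattern, " (",
      length(x$variants), " variant", if (length(x$variants) > 1) "s",
      ")\n", sep = "")
  invisible(x)
}

#' Expand an optional-base pattern into plain strings
#'
#' Generates every presence/absence combination of the parenthesised bases,
#' deduplicated, in deterministic order (absent before present, leftmost
#' group varying slowest).
#'
#' @param pattern Pattern string over `A,C,G,T` with optional `(B)` groups.
#' @return Character vector of plain variants.
#' @examples
#' expand_pattern("TGCTGAC(G)TCAGCA")
#' @export
expand_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1 || is.na(pattern)) {
    stop("pattern must be a single string")
  }
  pattern <- toupper(pattern)
  if (!grepl("^([ACGT]|\\([ACGT]\\))+$", pattern)) {
    stop("malformed motif pattern: ", pattern,
         " (expected A/C/G/T with single-base (N) optional groups)")
  }
  # tokenise into fixed runs and optional single bases
  tokens <- regmatches(pattern, gregexpr("\\([ACGT]\\)|[ACGT]+", pattern))[[1]]
  variants <- ""
  for (tok in tokens) {
    if (startsWith(tok, "(")) {
      base <- substr(tok, 2, 2)
      variants <- c(paste0(variants, ""), paste0(variants, base))
    } else {
      variants <- paste0(variants, tok)
    }
  }
  unique(variants)
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq Single string over `A,C,G,T,N` (case-insensitive).
#' @return The reverse complement, uppercased.
#' @examples
#' reverse_complement("TGCTGACGTCAGCA")  # a palindrome
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq)) {
    stop("seq must be a single string")
  }
  seq <- toupper(seq)
  if (!grepl("^[ACGTN]*$", seq)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Construct a promoter region
#'
#' @param id Sequence identifier.
#' @param sequence Nucleotide string over `A,C,G,T,N` (uppercased on input).
#' @param tss 1-based position of the first transcribed base within
#'   `sequence`.
#' @param strand Gene strand, `"+"` or `"-"` (annotation only once loaded:
#'   sequences are oriented so that upstream is leftward).
#' @return A `cc_promoter`.
#' @export
promoter_region <- function(id, sequence, tss, strand = "+") {
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGTN]*$", sequence)) {
    stop("promoter ", id, ": sequence contains invalid characters")
  }
  tss <- as.integer(tss)
  if (is.na(tss) || tss < 1 || tss > nchar(sequence)) {
    stop("promoter ", id, ": TSS position ", tss,
         " outside sequence of length ", nchar(sequence))
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(id = id, sequence = sequence, tss = tss, strand = strand),
            class = "cc_promoter")
}

#' @export
print.cc_promoter <- function(x, ...) {
  cat("<cc_promoter> ", x$id, ": ", nchar(x$sequence), " bp, TSS at ",
      x$tss, " (", x$strand, ")\n", sep = "")
  invisible(x)
}

#' Scan a promoter window for exact motif matches
#'
#' Searches the half-open window `[TSS - window_bp, TSS)` (the `window_bp`
#' bases immediately upstream of the TSS) for exact occurrences of every
#' expanded variant of the motif, and of their reverse complements when
#' `both_strands` is TRUE.  `N` never matches.  A match of a palindromic
#' variant is reported once, on the plus strand.  The upstream offset is
#' the distance from the TSS to the motif base nearest the TSS (>= 1); set
#' `offset_from = "start"` to measure to the motif's 5'-most base instead.
#'
#' @param region A `cc_promoter`.
#' @param motif A `cc_motif` (or pattern string).
#' @param window_bp Window size in bp upstream of the TSS (default 2000).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @param offset_from `"nearest"` (default) or `"start"`.
#' @return data.frame with columns `id`, `motif`, `variant`, `strand`,
#'   `upstream_offset`, `abs_start` (1-based start in the supplied
#'   sequence), sorted by increasing offset.
#' @examples
#' pr <- promoter_region("toy", strrep("A", 50), tss = 41)
#' scan_promoter(pr, motif_pattern("m", "CGCG"), window_bp = 40)
#' @export
scan_promoter <- function(region, motif, window_bp = 2000,
                          both_strands = TRUE, offset_from = c("nearest", "start")) {
  stopifnot(inherits(region, "cc_promoter"))
  if (is.character(motif)) motif <- motif_pattern(motif, motif)
  stopifnot(inherits(motif, "cc_motif"))
  offset_from <- match.arg(offset_from)
  min_len <- min(nchar(motif$variants))
  if (window_bp < min_len) stop("window_bp shorter than the motif")

  win_start <- region$tss - window_bp  # 1-based inclusive
  if (win_start < 1) {
    warning("promoter ", region$id, ": window truncated at sequence start (",
            region$tss - 1, " bp available upstream of TSS)")
    win_start <- 1
  }
  win_end <- region$tss - 1L
  if (win_end < win_start) {
    return(empty_hits())
  }
  window <- substr(region$sequence, win_start, win_end)
  subject <- Biostrings::DNAString(window)

  hits <- list()
  seen <- character(0)  # "start:variant" keys for palindromic collapse
  for (v in motif$variants) {
    strands <- list(c(v, "+"))
    if (both_strands) {
      rc <- reverse_complement(v)
      strands <- c(strands, list(c(rc, "-")))
    }
    for (sv in strands) {
      pat <- sv[1]; strand <- sv[2]
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                    fixed = TRUE)
      for (st in Biostrings::start(m)) {
        key <- paste0(st, ":", pat)
        if (key %in% seen) next  # palindrome: minus-strand duplicate
        seen <- c(seen, key)
        abs_start <- win_start + st - 1L
        last <- abs_start + nchar(pat) - 1L
        off <- if (offset_from == "nearest") region$tss - last else
          region$tss - abs_start
        hits[[length(hits) + 1L]] <- data.frame(
          id = region$id, motif = motif$name, variant = v, strand = strand,
          upstream_offset = off, abs_start = abs_start
        )
      }
    }
  }
  if (!length(hits)) return(empty_hits())
  out <- do.call(rbind, hits)
  out[order(out$upstream_offset, out$abs_start), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(id = character(0), motif = character(0), variant = character(0),
             strand = character(0), upstream_offset = integer(0),
             abs_start = integer(0))
}

#' Load promoter regions from FASTA plus a TSS table
#'
#' The TSS table is a TSV with header columns `id`, `tss_position`
#' (1-based, in the orientation of the FASTA record) and `strand`.  Records
#' annotated on the minus strand are reverse-complemented on load, with the
#' TSS coordinate transformed accordingly, so that "upstream" is uniformly
#' leftward in every returned region.
#'
#' @param fasta_path FASTA file of promoter sequences.
#' @param tss_table_path TSV with `id`, `tss_position`, `strand`.
#' @return Named list of `cc_promoter` objects, in TSS-table order.
#' @export
read_promoters <- function(fasta_path, tss_table_path) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
                   error = function(e) {
                     stop("malformed FASTA ", fasta_path, ": ",
                          conditionMessage(e))
                   })
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tab <- read.table(tss_table_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("id", "tss_position", "strand")
  if (!all(need %in% names(tab))) {
    stop("TSS table ", tss_table_path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  missing <- setdiff(tab$id, names(seqs))
  if (length(missing)) {
    stop("TSS table id(s) absent from FASTA: ", paste(missing, collapse = ", "))
  }
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    id <- tab$id[i]
    s <- toupper(as.character(seqs[[id]]))
    tss <- as.integer(tab$tss_position[i])
    strand <- tab$strand[i]
    if (identical(strand, "-")) {
      s <- reverse_complement(s)
      tss <- nchar(s) - tss + 1L
    } else if (!identical(strand, "+")) {
      stop("record ", id, ": strand must be '+' or '-', got ", strand)
    }
    out[[i]] <- promoter_region(id, s, tss, strand)
  }
  setNames(out, tab$id)
}

#' Write motif hits as TSV
#'
#' @param hits Hit data.frame from [scan_promoter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
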