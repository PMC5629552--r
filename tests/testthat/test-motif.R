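test_that("pattern expansion enumerates optional-base combinations", {
  expect_setequal(expand_pattern("TGCTGAC(G)TCAGCA"),
                  c("TGCTGACTCAGCA", "TGCTGACGTCAGCA"))
  expect_identical(expand_pattern("CGCCCCCGC"), "CGCCCCCGC")
  expect_length(expand_pattern("A(C)(G)T"), 4L)
  expect_setequal(expand_pattern("A(C)(G)T"), c("AT", "ACT", "AGT", "ACGT"))
  expect_error(expand_pattern("AC(GT)A"), "malformed")
  expect_error(expand_pattern("AC(G"), "malformed")
  expect_error(expand_pattern("ACXG"), "malformed")
})

test_that("reverse complement is correct and involutive; MARE is palindromic", {
  expect_identical(reverse_complement("AAAA"), "TTTT")
  expect_identical(reverse_complement("TGCTGACGTCAGCA"), "TGCTGACGTCAGCA")
  expect_error(reverse_complement("ACGU"), "outside")
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 30, replace = TRUE),
               collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("planted motifs are recovered at their exact upstream offsets", {
  spec <- synthetic_promoter_spec("p1", 2500, 0.5, tss = 2400,
    plantings = data.frame(pattern = "CGCCCCCGC", offset = 523,
                           strand = "+"), seed = 3)
  pr <- generate_promoter(spec)
  region <- promoter_region("p1", pr$sequence, 2400)
  hits <- scan_promoter(region, cc_motifs()$EGR3)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$upstream_offset, 523)
  expect_identical(hits$strand, "+")
  # motif-start offset convention differs by motif length - 1
  hits2 <- scan_promoter(region, cc_motifs()$EGR3, offset_from = "start")
  expect_equal(hits2$upstream_offset, 523 + nchar("CGCCCCCGC") - 1L)
  # absent motif
  expect_equal(nrow(scan_promoter(region, cc_motifs()$MARE)), 0L)
})

test_that("a single substitution anywhere removes the hit", {
  spec <- synthetic_promoter_spec("p1", 2200, 0.45, tss = 2100,
    plantings = data.frame(pattern = "CGCCCCCGC", offset = 300,
                           strand = "+"), seed = 5)
  pr <- generate_promoter(spec)
  start <- pr$truth$abs_start
  len <- nchar(pr$truth$variant)
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  for (k in seq_len(len)) {
    chars <- strsplit(pr$sequence, "")[[1]]
    chars[start + k - 1L] <- swap[[chars[start + k - 1L]]]
    mut <- promoter_region("p1", paste(chars, collapse = ""), 2100)
    expect_equal(nrow(scan_promoter(mut, cc_motifs()$EGR3)), 0L)
  }
})

test_that("minus-strand plantings and palindromes are handled", {
  # non-palindromic motif planted on the minus strand
  spec <- synthetic_promoter_spec("m1", 2200, 0.5, tss = 2100,
    plantings = data.frame(pattern = "CGCCCCCGC", offset = 400,
                           strand = "-"), seed = 8)
  pr <- generate_promoter(spec)
  region <- promoter_region("m1", pr$sequence, 2100)
  hits <- scan_promoter(region, cc_motifs()$EGR3)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$strand, "-")
  expect_equal(hits$upstream_offset, 400)
  # plus-only scan misses it
  expect_equal(nrow(scan_promoter(region, cc_motifs()$EGR3,
                                  both_strands = FALSE)), 0L)
  # palindromic MARE variant: both-strand scan reports one hit, on plus
  spec2 <- synthetic_promoter_spec("m2", 2200, 0.5, tss = 2100,
    plantings = data.frame(pattern = "TGCTGAC(G)TCAGCA", offset = 156,
                           strand = "+"), seed = 9)
  pr2 <- generate_promoter(spec2)
  region2 <- promoter_region("m2", pr2$sequence, 2100)
  hits_both <- scan_promoter(region2, cc_motifs()$MARE)
  hits_plus <- scan_promoter(region2, cc_motifs()$MARE, both_strands = FALSE)
  expect_equal(nrow(hits_both), 1L)
  expect_equal(hits_both$upstream_offset, hits_plus$upstream_offset)
  expect_identical(hits_both$strand, "+")
})

test_that("scanning is restricted to the upstream window; N never matches", {
  seqc <- paste0(strrep("A", 100), "CGCCCCCGC", strrep("A", 41),
                 "CGCCCCCGC", strrep("A", 50))
  # TSS at 151: first motif [101,109] inside a 60bp window? no; second
  # motif [151,159] is downstream of the TSS and must never be reported
  region <- promoter_region("w", seqc, tss = 151)
  hits <- scan_promoter(region, cc_motifs()$EGR3, window_bp = 60)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$abs_start, 101L)
  expect_equal(hits$upstream_offset, 151L - 109L)
  hits_narrow <- scan_promoter(region, cc_motifs()$EGR3, window_bp = 30)
  expect_equal(nrow(hits_narrow), 0L)
  expect_warning(scan_promoter(promoter_region("w2", seqc, tss = 120),
                               cc_motifs()$EGR3), "truncated")
  withN <- sub("CGCCCCCGC", "CGCCNCCGC", seqc)
  expect_equal(nrow(scan_promoter(promoter_region("w3", withN, tss = 151),
                                  cc_motifs()$EGR3, window_bp = 60)), 0L)
  expect_error(scan_promoter(region, cc_motifs()$EGR3, window_bp = 4),
               "shorter than the motif")
})

test_that("FASTA + TSS loading orients minus-strand records", {
  spec <- synthetic_promoter_spec("g1", 2200, 0.5, tss = 2100,
    plantings = data.frame(pattern = "CGCCCCCGC", offset = 250,
                           strand = "+"), seed = 12)
  pr_plus <- generate_promoter(spec)
  spec_minus <- synthetic_promoter_spec("g1", 2200, 0.5, tss = 2100,
    plantings = data.frame(pattern = "CGCCCCCGC", offset = 250,
                           strand = "+"), strand = "-", seed = 12)
  pr_minus <- generate_promoter(spec_minus)
  # same underlying promoter, written out reverse-complemented
  expect_identical(reverse_complement(pr_minus$fasta_record[[1]]),
                   pr_plus$fasta_record[[1]])
  fa <- withr::local_tempfile(fileext = ".fasta")
  ts <- withr::local_tempfile(fileext = ".tsv")
  write_promoter_fixture(list(pr_plus), fa, ts)
  regions <- read_promoters(fa, ts)
  h_plus <- scan_promoter(regions$g1, cc_motifs()$EGR3)
  write_promoter_fixture(list(pr_minus), fa, ts)
  h_minus <- scan_promoter(read_promoters(fa, ts)$g1, cc_motifs()$EGR3)
  expect_equal(h_minus$upstream_offset, h_plus$upstream_offset)
  expect_equal(h_minus$abs_start, h_plus$abs_start)
  # id mismatch errors
  tab <- read.table(ts, header = TRUE, sep = "\t")
  tab$id <- "missing_gene"
  write.table(tab, ts, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_promoters(fa, ts), "absent from FASTA")
})
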