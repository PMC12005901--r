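make_ref_with_dup <- function(seed, n = 20e3, unit_len = 100L,
                              at = 10e3) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  unit <- chars[(at + 1):(at + unit_len)]
  chars[(at + unit_len + 1):(at + 2 * unit_len)] <- unit
  list(ref = Biostrings::DNAStringSet(c(c1 = paste(chars, collapse = ""))),
       unit = paste(unit, collapse = ""), pos = at)
}

test_that("an exact tandem duplication is accepted at identity 1, offset 0", {
  x <- make_ref_with_dup(11)
  v <- verify_duplication(x$pos, x$unit, x$ref, "c1")
  expect_true(v$accepted)
  expect_equal(v$identity, 1.0)
  expect_identical(v$offset, 0L)
  # the emitted DUP spans the matched reference footprint
  expect_identical(IRanges::width(v$event), 100L)
  expect_identical(v$event$svtype, "DUP")
})

test_that("the 95% identity threshold is a hard boundary", {
  x <- make_ref_with_dup(12)
  v95 <- verify_duplication(x$pos, mutate_bases(x$unit, 5), x$ref, "c1")
  expect_equal(v95$identity, 0.95)
  expect_true(v95$accepted)
  v94 <- verify_duplication(x$pos, mutate_bases(x$unit, 6), x$ref, "c1")
  expect_equal(v94$identity, 0.94)
  expect_false(v94$accepted)
  expect_match(v94$reason, "below threshold")
})

test_that("the offset scan recovers planted offsets within the slop", {
  set.seed(13)
  ref_chr <- random_dna(20e3)
  ref <- Biostrings::DNAStringSet(c(c1 = ref_chr))
  pos <- 10e3
  for (k in -2:2) {
    s1 <- pos + 1L + k
    planted <- substr(ref_chr, s1, s1 + 99L)
    v <- verify_duplication(pos, planted, ref, "c1")
    expect_true(v$accepted)
    expect_identical(v$offset, k)
    expect_identical(v$flank, "RIGHT")
  }
  # a copy starting 3 bp away is outside the scan range: scored only at
  # in-range offsets, where random sequence identity is far below 0.95
  off3 <- substr(ref_chr, pos + 4L, pos + 103L)
  v3 <- verify_duplication(pos, off3, ref, "c1")
  expect_false(v3$accepted)
  expect_lt(v3$identity, 0.95)
})

test_that("left- and right-anchored duplications are symmetric", {
  set.seed(14)
  ref_chr <- random_dna(20e3)
  ref <- Biostrings::DNAStringSet(c(c1 = ref_chr))
  pos <- 8e3
  left_copy <- substr(ref_chr, pos - 99L, pos)     # segment ending at pos
  right_copy <- substr(ref_chr, pos + 1L, pos + 100L)
  vl <- verify_duplication(pos, left_copy, ref, "c1")
  vr <- verify_duplication(pos, right_copy, ref, "c1")
  expect_true(vl$accepted); expect_identical(vl$flank, "LEFT")
  expect_true(vr$accepted); expect_identical(vr$flank, "RIGHT")
  expect_equal(vl$identity, 1.0); expect_equal(vr$identity, 1.0)
})

test_that("reported best identity equals the exhaustive-grid oracle", {
  set.seed(15)
  ref_chr <- random_dna(50e3)
  ref <- Biostrings::DNAStringSet(c(c1 = ref_chr))
  for (i in 1:100) {
    pos <- sample(200:49e3, 1)
    L <- sample(c(50, 100, 150), 1)
    seq <- if (runif(1) < 0.5) random_dna(L) else {
      s1 <- pos + 1L + sample(-2:2, 1)
      mutate_bases(substr(ref_chr, s1, s1 + L - 1L), sample(0:8, 1))
    }
    v <- verify_duplication(pos, seq, ref, "c1")
    expect_equal(v$identity, oracle_best_identity(pos, seq, ref_chr))
  }
})

test_that("random insertions are essentially never accepted", {
  set.seed(16)
  ref <- Biostrings::DNAStringSet(c(c1 = random_dna(30e3)))
  acc <- 0L
  for (i in 1:300) {
    v <- verify_duplication(sample(500:29e3, 1), random_dna(120), ref, "c1")
    acc <- acc + v$accepted
  }
  expect_identical(acc, 0L)
})

test_that("degenerate insertions are rejected with distinct reasons", {
  ref <- Biostrings::DNAStringSet(c(c1 = random_dna(1000)))
  v <- verify_duplication(500, strrep("N", 50), ref, "c1")
  expect_false(v$accepted)
  expect_match(v$reason, "all N")
  # window longer than either flank: nothing to scan
  v2 <- verify_duplication(500, random_dna(2000), ref, "c1")
  expect_false(v2$accepted)
  expect_match(v2$reason, "no in-bounds")
  expect_error(verify_duplication(500, "ACGU", ref, "c1"), "ACGTN")
})

test_that("size filter keeps the inclusive 500 bp - 10 Mb window", {
  lens <- c(499L, 500L, 10e6, 10e6 + 1)
  ev <- cnv_events("c", rep(1, 4), lens, "DEL",
                   id = c("under", "at_min", "at_max", "over"))
  sf <- size_filter(ev)
  expect_identical(sf$kept$id, c("at_min", "at_max"))
  expect_setequal(sf$dropped$id, c("under", "over"))
  expect_match(sf$dropped$reason[sf$dropped$id == "under"], "below")
  expect_match(sf$dropped$reason[sf$dropped$id == "over"], "above")
  # idempotent; subset of input; empty in -> empty out
  again <- size_filter(sf$kept)
  expect_identical(again$kept$id, sf$kept$id)
  expect_identical(nrow(again$dropped), 0L)
  empty <- size_filter(ev[0])
  expect_length(empty$kept, 0L)
})

test_that("truth preparation converts verified insertions and windows sizes", {
  x <- make_ref_with_dup(17, unit_len = 600L)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "truth.vcf")
  ev <- cnv_events(c("c1", "c1"), c(1001, 3001), c(2000, 3300), "DEL",
                   id = c("keep", "short"), origin = "TRUTH")
  ins <- data.frame(id = c("dup_ins", "junk_ins"), chrom = "c1",
                    pos = c(x$pos, 2500L),
                    seq = c(x$unit, random_dna(700)),
                    stringsAsFactors = FALSE)
  write_sv_vcf(ev, p, insertions = ins, contig_lengths = c(c1 = 20e3))
  tp <- prepare_truth_set(p, x$ref)
  expect_setequal(tp$events$id, c("keep", "dup_ins"))
  expect_identical(tp$events$svtype[tp$events$id == "dup_ins"], "DUP")
  expect_identical(tp$size_dropped$id, "short")
  expect_identical(tp$audit$accepted, c(TRUE, FALSE))
  aud <- withr::local_tempfile(fileext = ".tsv")
  write_dup_audit(tp$audit, aud)
  expect_identical(nrow(utils::read.delim(aud)), 2L)
})
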