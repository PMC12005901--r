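test_that("reference generation is seed-deterministic and byte-stable", {
  r1 <- simulate_reference(seed = 4, n_repeats = 1)
  r2 <- simulate_reference(seed = 4, n_repeats = 1)
  expect_identical(as.character(r1$dna), as.character(r2$dna))
  expect_identical(r1$repeats, r2$repeats)
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(r1$dna, p1)
  Biostrings::writeXStringSet(r2$dna, p2)
  expect_identical(readLines(p1), readLines(p2))
  r3 <- simulate_reference(seed = 5, n_repeats = 1)
  expect_false(identical(as.character(r1$dna), as.character(r3$dna)))
})

test_that("contig count and lengths follow the request", {
  r <- simulate_reference(seed = 1,
                          contig_lengths = c(a = 50e3, b = 50e3))
  expect_identical(names(r$dna), c("a", "b"))
  expect_identical(Biostrings::width(r$dna), c(50000L, 50000L))
  expect_error(simulate_reference(seed = 1, contig_lengths = c(a = 5e3)),
               "10")
})

test_that("embedded tandem repeats verify as duplications at identity 1", {
  r <- simulate_reference(seed = 6, n_repeats = 4, repeat_unit_len = 500)
  expect_identical(nrow(r$repeats), 4L)
  for (i in seq_len(nrow(r$repeats))) {
    vr <- verify_duplication(r$repeats$ins_pos_right[i], r$repeats$unit[i],
                             r$dna, r$repeats$chrom[i])
    expect_true(vr$accepted)
    expect_equal(vr$identity, 1.0)
    vl <- verify_duplication(r$repeats$ins_pos_left[i], r$repeats$unit[i],
                             r$dna, r$repeats$chrom[i])
    expect_true(vl$accepted)
  }
  # FASTA round trip preserves the planted structure
  p <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(r$dna, p)
  back <- Biostrings::readDNAStringSet(p)
  names(back) <- sub(" .*", "", names(back))
  v <- verify_duplication(r$repeats$ins_pos_right[1], r$repeats$unit[1],
                          back, r$repeats$chrom[1])
  expect_true(v$accepted)
})

test_that("benchmark cases are seed-deterministic", {
  a <- simulate_benchmark_case(seed = 11)
  b <- simulate_benchmark_case(seed = 11)
  expect_identical(a$events, b$events)
  expect_identical(IRanges::ranges(a$genes), IRanges::ranges(b$genes))
  expect_identical(a$expected_metrics, b$expected_metrics)
  c2 <- simulate_benchmark_case(seed = 12)
  expect_false(identical(a$events, c2$events))
})

test_that("planted composition yields the planted counts", {
  case <- simulate_benchmark_case(seed = 13, detect_frac = 0.8,
                                  n_fp_direction = 4, n_fp_exon = 2,
                                  n_ignored = 3)
  n_truth <- sum(default_truth_counts()$n)
  cnt <- case$expected_counts
  expect_identical(cnt$tp_truth, as.integer(round(0.8 * n_truth)))
  expect_identical(cnt$fn, n_truth - cnt$tp_truth)
  expect_identical(cnt$tp_query, cnt$tp_truth)
  expect_identical(cnt$fp, 6L)
  expect_identical(cnt$ignored, 3L)
  em <- case$expected_metrics
  all_row <- em[em$stratum == "ALL", ]
  expect_equal(all_row$sensitivity, cnt$tp_truth / n_truth)
  expect_equal(all_row$precision, cnt$tp_query / (cnt$tp_query + cnt$fp))
})

test_that("a case with no queries has zero sensitivity, null precision", {
  case <- simulate_benchmark_case(seed = 14, detect_frac = 0,
                                  n_fp_direction = 0L, n_fp_exon = 0L,
                                  n_ignored = 0L)
  expect_length(case$queries, 0L)
  pe <- padded_exons(case$genes, case$pad)
  m <- cnv_metrics(classify_calls(case$queries, case$truth, pe))
  expect_equal(m$sensitivity[m$stratum == "ALL"], 0)
  expect_true(is.na(m$precision[m$stratum == "ALL"]))
})

test_that("infeasible specs fail loudly", {
  expect_error(simulate_benchmark_case(seed = 1, n_genes = 10L),
               "infeasible")
  expect_error(
    simulate_benchmark_case(seed = 1,
                            contig_lengths = c(ctg1 = 300e3),
                            n_genes = 40L),
    "infeasible")
})

test_that("benchmark cases round-trip through their files", {
  case <- simulate_benchmark_case(seed = 15)
  dir <- withr::local_tempdir()
  paths <- write_benchmark_case(case, dir)
  expect_true(all(file.exists(paths)))
  tr <- read_sv_vcf(paths["truth"], origin = "TRUTH")$events
  qr <- read_sv_vcf(paths["query"], origin = "QUERY")$events
  genes <- read_gene_models(paths["genes"])
  expect_identical(length(tr), length(case$truth))
  expect_identical(length(qr), length(case$queries))
  expect_identical(length(genes), length(case$genes))
  exp <- jsonlite::read_json(paths["expectations"],
                             simplifyVector = TRUE)
  expect_equal(exp$expected_counts$tp_query,
               case$expected_counts$tp_query)
  # the files alone reproduce the expected metric table
  pe <- padded_exons(genes, exp$pad)
  m <- cnv_metrics(classify_calls(qr, tr, pe))
  expect_equal(as.data.frame(m)[, names(case$expected_metrics)],
               case$expected_metrics, ignore_attr = TRUE)
})

test_that("cohort generation respects the recurrence plan", {
  coh <- simulate_artifact_cohort(seed = 3, n_samples = 4,
                                  artifact_recurrence = c(4, 2, 1))
  expect_length(coh$callsets, 4L)
  expect_identical(coh$artifacts$recurrence, c(4L, 2L, 1L))
  for (a in seq_len(nrow(coh$artifacts))) {
    members <- strsplit(coh$artifacts$samples[a], ",")[[1]]
    expect_length(members, coh$artifacts$recurrence[a])
    for (m in members) {
      ids <- coh$callsets[[m]]$id
      expect_true(any(grepl(coh$artifacts$artifact[a], ids)))
    }
  }
  expect_error(simulate_artifact_cohort(seed = 1, n_samples = 2,
                                        artifact_recurrence = c(3)),
               "artifact_recurrence")
})
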