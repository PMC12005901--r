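# one gene with 10 exons, 1 kb each, 2 kb apart, starting at 10 kb
ten_exon_gene <- function() {
  s <- 10e3 + (0:9) * 3000L
  gene_models(genomic_intervals(rep("c1", 10), s, s + 999L), rep("G", 10))
}

test_that("a call matching a truth event through a shared exon is a TP", {
  pe <- padded_exons(ten_exon_gene())
  # truth DEL over exon 3 only; query DEL spanning exons 2-3
  truth <- cnv_events("c1", 16000, 17050, "DEL", id = "t1",
                      origin = "TRUTH")
  query <- cnv_events("c1", 13500, 17200, "DEL", id = "q1",
                      origin = "QUERY")
  cls <- classify_calls(query, truth, pe)
  expect_identical(cls$queries$status, "TP")
  expect_identical(cls$queries$matched_ids[[1]], "t1")
  expect_identical(cls$truths$status, "DETECTED")
  expect_identical(cls$queries$n_exons, 2L)
  # the shared mediating exon is exon 3
  expect_true(3L %in% cls$queries$exon_idx[[1]])
})

test_that("dosage-direction mismatch over a shared exon is an FP", {
  pe <- padded_exons(ten_exon_gene())
  truth <- cnv_events("c1", 16000, 17050, "DEL", id = "t1",
                      origin = "TRUTH")
  query <- cnv_events("c1", 16000, 17050, "DUP", id = "q1",
                      origin = "QUERY")
  cls <- classify_calls(query, truth, pe)
  expect_identical(cls$queries$status, "FP")
  expect_identical(cls$truths$status, "FN")
})

test_that("calls touching no padded exon are ignored, not FP", {
  pe <- padded_exons(ten_exon_gene())
  truth <- cnv_events("c1", 16000, 17050, "DEL", origin = "TRUTH")
  query <- cnv_events("c1", c(500, 11500), c(800, 11800), "DEL",
                      id = c("intergenic", "intronic"), origin = "QUERY")
  cls <- classify_calls(query, truth, pe)
  expect_identical(cls$queries$status, c("IGNORED", "IGNORED"))
  cnt <- event_counts(cls)
  expect_identical(cnt$ignored, 2L)
  expect_identical(cnt$fp, 0L)
})

test_that("a 1 bp overlap with the splice padding suffices", {
  pe <- padded_exons(ten_exon_gene())  # exon 1 padded: 9985..11014
  truth <- cnv_events("c1", 9000, 9985, "DEL", origin = "TRUTH")
  query <- cnv_events("c1", c(9000, 9000), c(9985, 9984), "DEL",
                      id = c("touch", "miss"), origin = "QUERY")
  cls <- classify_calls(query, truth, pe)
  expect_identical(cls$queries$status, c("TP", "IGNORED"))
})

test_that("multi-exon events count once (event-level adjustment)", {
  pe <- padded_exons(ten_exon_gene())
  span_all <- cnv_events("c1", 9000, 40e3, "DEL", origin = "TRUTH")
  one_query <- cnv_events("c1", 9500, 39e3, "DEL", origin = "QUERY")
  cls <- classify_calls(one_query, span_all, pe)
  cnt <- event_counts(cls)
  expect_identical(cnt$tp_query, 1L)
  expect_identical(cnt$tp_truth, 1L)
  expect_identical(cls$queries$n_exons, 10L)
  # two queries over distinct exons of one truth: 2 query TPs, 1 truth
  two <- cnv_events("c1", c(10e3, 16e3), c(11e3, 17e3), "DEL",
                    id = c("qa", "qb"), origin = "QUERY")
  cls2 <- classify_calls(two, span_all, pe)
  cnt2 <- event_counts(cls2)
  expect_identical(cnt2$tp_query, 2L)
  expect_identical(cnt2$tp_truth, 1L)
  # zero reports
  cls0 <- classify_calls(one_query[0], span_all[0], pe)
  expect_true(all(unlist(event_counts(cls0)) == 0L))
})

test_that("metrics follow the GA4GH definitions with null denominators", {
  pe <- padded_exons(ten_exon_gene())
  truths <- cnv_events("c1", c(10e3, 13e3, 16e3, 19e3) + 100L,
                       c(10e3, 13e3, 16e3, 19e3) + 800L, "DEL",
                       id = sprintf("t%d", 1:4), origin = "TRUTH")
  queries <- cnv_events("c1", c(10e3, 13e3, 16e3) + 150L,
                        c(10e3, 13e3, 16e3) + 700L, "DEL",
                        id = sprintf("q%d", 1:3), origin = "QUERY")
  cls <- classify_calls(queries, truths, pe)
  m <- cnv_metrics(cls)
  all_row <- m[m$stratum == "ALL", ]
  expect_equal(all_row$sensitivity, 0.75)
  expect_equal(all_row$precision, 1.0)
  dup_row <- m[m$axis == "SVTYPE" & m$stratum == "DUP", ]
  expect_true(is.na(dup_row$sensitivity))
  expect_true(is.na(dup_row$precision))
  expect_identical(dup_row$tp_query + dup_row$fp, 0L)
})

test_that("truth events touching no exon leave the denominator", {
  pe <- padded_exons(ten_exon_gene())
  truths <- cnv_events("c1", c(10100, 500e3), c(10800, 501e3), "DEL",
                       id = c("exonic", "desert"), origin = "TRUTH")
  queries <- cnv_events("c1", 10150, 10700, "DEL", origin = "QUERY")
  cls <- classify_calls(queries, truths, pe)
  expect_identical(cls$truths$status, c("DETECTED", "EXCLUDED"))
  m <- cnv_metrics(cls)
  expect_equal(m$sensitivity[m$stratum == "ALL"], 1.0)
})

test_that("classification is invariant to input order", {
  set.seed(31)
  inst <- random_instance(101)
  pe <- padded_exons(exons_from_df(inst$exons), pad = 15)
  q <- gr_from_df(inst$q, "QUERY")
  t <- gr_from_df(inst$t, "TRUTH")
  cls <- classify_calls(q, t, pe)
  perm_q <- sample(length(q)); perm_t <- sample(length(t))
  cls2 <- classify_calls(q[perm_q], t[perm_t], pe)
  expect_identical(cls2$queries$status[order(perm_q)],
                   cls$queries$status)
  expect_identical(cls2$truths$status[order(perm_t)],
                   cls$truths$status)
})

test_that("a call set equal to the truth set scores 1.0 everywhere", {
  case <- simulate_benchmark_case(seed = 5, n_fp_direction = 0L,
                                  n_fp_exon = 0L, n_ignored = 0L,
                                  detect_frac = 1)
  pe <- padded_exons(case$genes, case$pad)
  mirror <- case$truth
  mirror$origin <- "QUERY"
  cls <- classify_calls(mirror, case$truth, pe)
  m <- cnv_metrics(cls)
  nonempty <- (m$tp_truth + m$fn) > 0
  expect_true(all(m$sensitivity[nonempty] == 1))
  expect_true(all(m$precision[(m$tp_query + m$fp) > 0] == 1))
})

test_that("dropping an FP weakly increases precision", {
  case <- simulate_benchmark_case(seed = 6)
  pe <- padded_exons(case$genes, case$pad)
  cls <- classify_calls(case$queries, case$truth, pe)
  base <- cnv_metrics(cls)$precision[1]
  fp_ids <- cls$queries$id[cls$queries$status == "FP"]
  keep <- case$queries[case$queries$id != fp_ids[1]]
  cls2 <- classify_calls(keep, case$truth, pe)
  expect_gte(cnv_metrics(cls2)$precision[1], base)
})

test_that("panel restriction hides off-panel exons from the evaluation", {
  genes <- c(ten_exon_gene(),
             gene_models(genomic_intervals("c1", 200e3, 201e3), "OFFP"))
  pe <- padded_exons(genes)
  truth <- cnv_events("c1", 10100, 10900, "DEL", origin = "TRUTH")
  queries <- cnv_events("c1", c(10100, 200100), c(10900, 200900), "DEL",
                        id = c("on_panel", "off_panel"), origin = "QUERY")
  full <- classify_calls(queries, truth, pe)
  expect_identical(full$queries$status, c("TP", "FP"))
  panel <- classify_calls(queries, truth, pe, panel_genes = "G")
  expect_identical(panel$queries$status, c("TP", "IGNORED"))
  # region restriction behaves the same way
  reg <- classify_calls(queries, truth, pe,
                        restrict_to = genomic_intervals("c1", 1, 100e3))
  expect_identical(reg$queries$status, c("TP", "IGNORED"))
})

test_that("insertions are refused until truth preparation has run", {
  pe <- padded_exons(ten_exon_gene())
  ins <- cnv_events("c1", 10e3, 10e3, "INS", svlen = 700L,
                    origin = "QUERY")
  truth <- cnv_events("c1", 10100, 10900, "DEL", origin = "TRUTH")
  expect_error(classify_calls(ins, truth, pe), "INS")
})
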