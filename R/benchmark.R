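#' Classify query CNV calls against a truth set via shared padded exons
#'
#' Implements the clinically oriented matching rule: a query call is a
#' true positive iff at least one padded exon it overlaps (by >= 1 bp) is
#' also overlapped by at least one truth event of the same dosage
#' direction (DEL with DEL, DUP with DUP). A query overlapping in-scope
#' exons but sharing none with a same-type truth event is a false
#' positive; a query overlapping no in-scope exon is ignored (it can
#' disrupt no protein in the evaluated space and enters no denominator).
#' On the truth side, an event overlapping at least one in-scope exon is
#' detected iff some same-type query shares one of its exons, otherwise a
#' false negative; truth events touching no in-scope exon are excluded
#' from the sensitivity denominator. No breakpoint or reciprocal-overlap
#' condition is imposed between query and truth: the padded exon is the
#' sole matching currency.
#'
#' Evaluation can be restricted to a virtual panel by gene name
#' (`panel_genes`) and/or to explicit regions (`restrict_to`); exons
#' outside the restriction are invisible to the classification.
#'
#' @param queries,truths CNV event sets (DEL/DUP only; run truth
#'   preparation first if insertions are present).
#' @param exons padded exon `GRanges` from [padded_exons()].
#' @param panel_genes optional character vector of gene names to restrict
#'   the evaluation to.
#' @param restrict_to optional `GRanges`; only exons overlapping it are
#'   in scope.
#' @return object of class `cnv_classification`: a list with
#'   \item{queries}{data.frame `id`, `svtype`, `svlen`, `n_exons`,
#'     `status` (`TP`/`FP`/`IGNORED`), `exon_idx` and `matched_ids`
#'     (list columns),}
#'   \item{truths}{data.frame `id`, `svtype`, `svlen`, `n_exons`,
#'     `status` (`DETECTED`/`FN`/`EXCLUDED`), `exon_idx`, `matched_ids`,}
#'   \item{exons}{the in-scope padded exons used.}
#' @export
classify_calls <- function(queries, truths, exons, panel_genes = NULL,
                           restrict_to = NULL) {
  validate_cnv_events(queries)
  validate_cnv_events(truths)
  if (!is.null(panel_genes))
    exons <- exons[exons$gene %in% panel_genes]
  if (!is.null(restrict_to))
    exons <- exons[overlapsAny(exons, restrict_to, minoverlap = 1L)]

  hits_of <- function(events) {
    h <- findOverlaps(events, exons, minoverlap = 1L)
    split(subjectHits(h), factor(queryHits(h), levels = seq_along(events)))
  }
  q_ex <- hits_of(queries)
  t_ex <- hits_of(truths)

  # exon x svtype keys covered by each side
  keys <- function(ex_list, svtype)
    mapply(function(e, t) if (length(e)) paste(e, t) else character(0),
           ex_list, svtype, SIMPLIFY = FALSE)
  qk <- keys(q_ex, queries$svtype)
  tk <- keys(t_ex, truths$svtype)
  truth_cover <- unique(unlist(tk, use.names = FALSE))
  query_cover <- unique(unlist(qk, use.names = FALSE))

  q_status <- vapply(seq_along(queries), function(i) {
    if (length(qk[[i]]) == 0L) "IGNORED"
    else if (any(qk[[i]] %in% truth_cover)) "TP" else "FP"
  }, character(1))
  t_status <- vapply(seq_along(truths), function(i) {
    if (length(tk[[i]]) == 0L) "EXCLUDED"
    else if (any(tk[[i]] %in% query_cover)) "DETECTED" else "FN"
  }, character(1))

  match_ids <- function(ex_list, svtype, other_ex, other_svtype, other_id,
                        status, want) {
    lapply(seq_along(ex_list), function(i) {
      if (status[i] != want) return(character(0))
      same <- which(other_svtype == svtype[i])
      hit <- vapply(same, function(j)
        any(other_ex[[j]] %in% ex_list[[i]]), logical(1))
      unique(other_id[same[hit]])
    })
  }
  q_matched <- match_ids(q_ex, queries$svtype, t_ex, truths$svtype,
                         truths$id, q_status, "TP")
  t_matched <- match_ids(t_ex, truths$svtype, q_ex, queries$svtype,
                         queries$id, t_status, "DETECTED")

  mk_report <- function(events, ex_list, status, matched) {
    data.frame(id = events$id, svtype = events$svtype,
               svlen = events$svlen,
               n_exons = lengths(ex_list), status = status,
               exon_idx = I(unname(ex_list)), matched_ids = I(matched),
               stringsAsFactors = FALSE)
  }
  structure(list(queries = mk_report(queries, q_ex, q_status, q_matched),
                 truths = mk_report(truths, t_ex, t_status, t_matched),
                 exons = exons),
            class = "cnv_classification")
}

#' Event-level benchmark counts
#'
#' Collapses a classification to event-level counts, the adjustment that
#' prevents double counting of events spanning multiple exons: every
#' query contributes exactly one TP or FP no matter how many exons it
#' overlaps, and every exon-overlapping truth event contributes exactly
#' one detected or missed unit no matter how many exons or queries are
#' involved.
#'
#' @param cls a `cnv_classification` from [classify_calls()].
#' @return named list: `tp_query`, `fp`, `ignored`, `tp_truth`, `fn`,
#'   `truth_excluded`.
#' @export
event_counts <- function(cls) {
  stopifnot(inherits(cls, "cnv_classification"))
  q <- cls$queries$status
  t <- cls$truths$status
  list(tp_query = sum(q == "TP"), fp = sum(q == "FP"),
       ignored = sum(q == "IGNORED"),
       tp_truth = sum(t == "DETECTED"), fn = sum(t == "FN"),
       truth_excluded = sum(t == "EXCLUDED"))
}

#' Default event-length strata
#'
#' The length bins used throughout: 0.5–1 kb, 1–5 kb, 1–10 kb, >= 5 kb
#' and > 10 kb. Ranged bins are lower-inclusive, upper-exclusive;
#' open-top bins follow their label (`>=` inclusive, `>` exclusive).
#' Bins may overlap — each is evaluated independently.
#'
#' @return data.frame `label`, `lo`, `hi`, `lo_open`.
#' @export
default_length_bins <- function() {
  data.frame(label = c("0.5-1kb", "1-5kb", "1-10kb", ">=5kb", ">10kb"),
             lo = c(500, 1000, 1000, 5000, 10000),
             hi = c(1000, 5000, 10000, Inf, Inf),
             lo_open = c(FALSE, FALSE, FALSE, FALSE, TRUE),
             stringsAsFactors = FALSE)
}

#' Default exons-spanned strata
#'
#' @return data.frame `label`, `lo`, `hi` (closed bounds on the number of
#'   distinct padded exons an event overlaps): 1, 2–5, >5.
#' @export
default_exon_bins <- function() {
  data.frame(label = c("1", "2-5", ">5"),
             lo = c(1, 2, 6), hi = c(1, 5, Inf), stringsAsFactors = FALSE)
}

in_length_bin <- function(len, bin) {
  lo_ok <- if (bin$lo_open) len > bin$lo else len >= bin$lo
  hi_ok <- if (is.infinite(bin$hi)) TRUE else len < bin$hi
  lo_ok & hi_ok
}

#' Stratified GA4GH-style sensitivity and precision
#'
#' Computes, overall and per stratum, the truth-side and query-side
#' counts and the derived metrics: sensitivity = tp_truth / (tp_truth +
#' fn) over truth events, precision = tp_query / (tp_query + fp) over
#' query events. Truth and query events are each stratified by their own
#' type, length and exons-spanned count. Ratios with an empty denominator
#' are reported as `NA`, never as 0. Events whose length falls in no
#' configured length bin still count in the `ALL` stratum and are listed
#' in `attr(result, "unbinned")`.
#'
#' @param cls a `cnv_classification` from [classify_calls()].
#' @param length_bins data.frame as [default_length_bins()].
#' @param exon_bins data.frame as [default_exon_bins()].
#' @return data.frame of class `cnv_metric_table` with columns `axis`
#'   (`ALL`/`SVTYPE`/`LENGTH_BIN`/`EXON_COUNT_BIN`), `stratum`,
#'   `tp_truth`, `fn`, `tp_query`, `fp`, `sensitivity`, `precision`.
#' @export
cnv_metrics <- function(cls, length_bins = default_length_bins(),
                        exon_bins = default_exon_bins()) {
  stopifnot(inherits(cls, "cnv_classification"))
  q <- cls$queries[cls$queries$status != "IGNORED", , drop = FALSE]
  t <- cls$truths[cls$truths$status != "EXCLUDED", , drop = FALSE]
  row_for <- function(axis, stratum, tsel, qsel) {
    tp_truth <- sum(t$status[tsel] == "DETECTED")
    fn <- sum(t$status[tsel] == "FN")
    tp_query <- sum(q$status[qsel] == "TP")
    fp <- sum(q$status[qsel] == "FP")
    data.frame(axis = axis, stratum = stratum, tp_truth = tp_truth,
               fn = fn, tp_query = tp_query, fp = fp,
               sensitivity = if (tp_truth + fn > 0)
                 tp_truth / (tp_truth + fn) else NA_real_,
               precision = if (tp_query + fp > 0)
                 tp_query / (tp_query + fp) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- list(row_for("ALL", "ALL", rep(TRUE, nrow(t)),
                       rep(TRUE, nrow(q))))
  for (st in c("DEL", "DUP"))
    rows[[length(rows) + 1L]] <-
      row_for("SVTYPE", st, t$svtype == st, q$svtype == st)
  for (b in seq_len(nrow(length_bins))) {
    bin <- length_bins[b, ]
    rows[[length(rows) + 1L]] <-
      row_for("LENGTH_BIN", bin$label, in_length_bin(t$svlen, bin),
              in_length_bin(q$svlen, bin))
  }
  for (b in seq_len(nrow(exon_bins))) {
    bin <- exon_bins[b, ]
    rows[[length(rows) + 1L]] <-
      row_for("EXON_COUNT_BIN", bin$label,
              t$n_exons >= bin$lo & t$n_exons <= bin$hi,
              q$n_exons >= bin$lo & q$n_exons <= bin$hi)
  }
  out <- do.call(rbind, rows)
  in_any <- function(len) {
    hit <- rep(FALSE, length(len))
    for (b in seq_len(nrow(length_bins)))
      hit <- hit | in_length_bin(len, length_bins[b, ])
    hit
  }
  attr(out, "unbinned") <- c(t$id[!in_any(t$svlen)], q$id[!in_any(q$svlen)])
  class(out) <- c("cnv_metric_table", "data.frame")
  out
}

#' Write a metric table
#'
#' @param metrics a `cnv_metric_table`.
#' @param path output path; `.json` writes JSON (empty denominators as
#'   `null`), anything else tab-separated text.
#' @export
write_metrics <- function(metrics, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(metrics), path, dataframe = "rows",
                         na = "null", auto_unbox = TRUE, digits = NA)
  } else {
    write.table(as.data.frame(metrics), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Write per-event match reports
#'
#' @param cls a `cnv_classification`.
#' @param path output TSV path.
#' @export
write_match_reports <- function(cls, path) {
  fmt <- function(df, origin) {
    data.frame(id = df$id, origin = origin, svtype = df$svtype,
               svlen = df$svlen, n_exons = df$n_exons, status = df$status,
               matched_ids = vapply(df$matched_ids, paste,
                                    character(1), collapse = ","),
               mediating_exons = vapply(df$exon_idx, function(e)
                 paste(cls$exons$gene[e], cls$exons$exon_rank[e],
                       sep = ":", collapse = ","), character(1)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(fmt(cls$queries, "QUERY"), fmt(cls$truths, "TRUTH"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
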