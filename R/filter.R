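FILTER_RULES <- c("SIZE_MIN", "SIZE_MAX", "JUNCTION_LONG", "GAP_OVERLAP",
                  "RECURRENT_ARTIFACT")

#' Configuration for the post-caller artifact filter
#'
#' Encapsulates the rules applied to high-sensitivity CNV call sets:
#' size window, junction-only long calls, assembly-gap overlap and
#' recurrent-artifact reciprocal overlap. Two artifact-matching modes are
#' available: `"reciprocal"` (default) tests reciprocal overlap >=
#' `recip_threshold` against each artifact region directly; `"two-bed"`
#' reproduces the mechanism of interval-containment against a
#' minimum-overlap and a maximum-overlap BED (the call must contain the
#' cluster's minimum interval and be contained by its maximum interval),
#' the operational approximation used when only interval containment
#' tests are available downstream.
#'
#' @param min_len,max_len size window in bases (calls strictly outside
#'   `[min_len, max_len]` are dropped); defaults 500 bp and 10 Mb.
#' @param junction_only_max_len calls supported solely by junction reads
#'   (claim `JUNCTION`) longer than this are dropped (default 1 Mb);
#'   genuine calls of that size generally carry depth support.
#' @param gap_regions `GRanges` of assembly gaps (centromeres/telomeres);
#'   any 1 bp overlap drops the call. `NULL` disables the rule.
#' @param artifact_regions an `artifact_blacklist` from
#'   [build_artifact_blacklist()], or a plain `GRanges` with an optional
#'   `svtype` column. `NULL` disables the rule.
#' @param recip_threshold reciprocal-overlap threshold (default 0.90).
#' @param artifact_mode `"reciprocal"` or `"two-bed"`.
#' @param svtype_aware match artifacts only against calls of the same
#'   dosage type (default `TRUE`); artifact regions without a `svtype`
#'   column are matched type-blind.
#' @return object of class `cnv_filter_config`.
#' @export
filter_config <- function(min_len = 500, max_len = 10e6,
                          junction_only_max_len = 1e6,
                          gap_regions = NULL, artifact_regions = NULL,
                          recip_threshold = 0.90,
                          artifact_mode = c("reciprocal", "two-bed"),
                          svtype_aware = TRUE) {
  artifact_mode <- match.arg(artifact_mode)
  stopifnot(min_len > 0, min_len < junction_only_max_len,
            junction_only_max_len < max_len,
            recip_threshold > 0, recip_threshold <= 1)
  structure(list(min_len = min_len, max_len = max_len,
                 junction_only_max_len = junction_only_max_len,
                 gap_regions = gap_regions,
                 artifact_regions = artifact_regions,
                 recip_threshold = recip_threshold,
                 artifact_mode = artifact_mode,
                 svtype_aware = svtype_aware),
            class = "cnv_filter_config")
}

artifact_svtype <- function(regions) {
  if ("svtype" %in% names(mcols(regions))) regions$svtype
  else rep(NA_character_, length(regions))
}

#' Apply the artifact-filtering rules to a call set
#'
#' Each call is evaluated against every rule independently and all failed
#' rules are reported (rule order never changes the kept set). Calls with
#' an unknown evidence claim are not subject to the junction-only rule.
#'
#' @param calls CNV event set (DEL/DUP).
#' @param config a [filter_config()].
#' @return list with `verdicts` (data.frame `id`, `svtype`, `svlen`,
#'   `kept`, `failed_rules` comma-separated, plus one logical column per
#'   rule) and `kept` (the surviving calls, input order preserved).
#' @export
apply_cnv_filters <- function(calls, config) {
  stopifnot(inherits(config, "cnv_filter_config"))
  validate_cnv_events(calls)
  n <- length(calls)
  fail <- matrix(FALSE, nrow = n, ncol = length(FILTER_RULES),
                 dimnames = list(NULL, FILTER_RULES))
  fail[, "SIZE_MIN"] <- calls$svlen < config$min_len
  fail[, "SIZE_MAX"] <- calls$svlen > config$max_len
  fail[, "JUNCTION_LONG"] <- calls$claim == "JUNCTION" &
    calls$svlen > config$junction_only_max_len
  if (!is.null(config$gap_regions))
    fail[, "GAP_OVERLAP"] <- suppressWarnings(
      overlapsAny(calls, config$gap_regions, minoverlap = 1L))
  art <- config$artifact_regions
  if (!is.null(art) && length(art)) {
    art_type <- artifact_svtype(art)
    type_ok <- function(i, j)
      !config$svtype_aware | is.na(art_type[j]) |
        art_type[j] == calls$svtype[i]
    if (config$artifact_mode == "reciprocal") {
      h <- suppressWarnings(
        findOverlaps(calls, granges(art), minoverlap = 1L))
      if (length(h)) {
        i <- queryHits(h); j <- subjectHits(h)
        ro <- reciprocal_overlap(calls[i], granges(art)[j])
        hit <- ro >= config$recip_threshold & type_ok(i, j)
        fail[, "RECURRENT_ARTIFACT"] <-
          seq_len(n) %in% unique(i[hit])
      }
    } else {
      mn <- mcols(art)
      stopifnot(all(c("min_start", "min_end", "max_start", "max_end")
                    %in% names(mn)))
      for (j in seq_along(art)) {
        cg <- as.character(seqnames(art))[j]
        cand <- as.character(seqnames(calls)) == cg &
          start(calls) <= mn$min_start[j] & end(calls) >= mn$min_end[j] &
          start(calls) >= mn$max_start[j] & end(calls) <= mn$max_end[j]
        if (config$svtype_aware && !is.na(art_type[j]))
          cand <- cand & calls$svtype == art_type[j]
        fail[, "RECURRENT_ARTIFACT"] <- fail[, "RECURRENT_ARTIFACT"] | cand
      }
    }
  }
  kept <- rowSums(fail) == 0L
  verdicts <- data.frame(id = calls$id, svtype = calls$svtype,
                         svlen = calls$svlen, kept = kept,
                         failed_rules = apply(fail, 1L, function(r)
                           paste(FILTER_RULES[r], collapse = ",")),
                         stringsAsFactors = FALSE)
  verdicts <- cbind(verdicts, as.data.frame(fail))
  list(verdicts = verdicts, kept = calls[kept])
}

uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Discover recurrent artifacts across samples
#'
#' Single-linkage clustering of same-type calls pooled across samples:
#' two calls are linked when their reciprocal overlap reaches
#' `recip_threshold`; connected clusters seen in at least
#' `min_recurrence` distinct samples become artifact regions. Each region
#' records a representative interval (median endpoints of the members),
#' the intersection of member spans (the minimum-overlap interval) and
#' the union of member spans (the maximum-overlap interval), realising
#' the two-BED containment test of [apply_cnv_filters()].
#'
#' @param callsets named list of CNV event sets, one per sample.
#' @param min_recurrence minimum number of distinct samples (default 2).
#' @param recip_threshold reciprocal-overlap linkage threshold
#'   (default 0.90).
#' @return object of class `artifact_blacklist`: a `GRanges` of
#'   representative intervals with columns `svtype`, `recurrence`,
#'   `n_members`, `member_ids` (comma-separated `sample:id`),
#'   `min_start`, `min_end`, `max_start`, `max_end`. Empty (with a
#'   warning) when `min_recurrence` exceeds the number of samples.
#' @export
build_artifact_blacklist <- function(callsets, min_recurrence = 2L,
                                     recip_threshold = 0.90) {
  stopifnot(is.list(callsets), !is.null(names(callsets)))
  if (length(callsets) < 2L)
    stop("blacklist discovery needs call sets from at least 2 samples")
  empty <- function() {
    g <- GRanges()
    mcols(g) <- DataFrame(svtype = character(0), recurrence = integer(0),
                          n_members = integer(0),
                          member_ids = character(0),
                          min_start = integer(0), min_end = integer(0),
                          max_start = integer(0), max_end = integer(0))
    g
  }
  if (min_recurrence > length(callsets)) {
    warning("min_recurrence exceeds the number of samples; ",
            "blacklist is empty")
    out <- empty()
    attr(out, "blacklist") <- TRUE
    return(out)
  }
  for (cs in callsets) validate_cnv_events(cs)
  all <- unlist(GRangesList(lapply(callsets, granges)),
                use.names = FALSE)
  sample_of <- rep(names(callsets), vapply(callsets, length, integer(1)))
  id_of <- unlist(lapply(callsets, function(x) x$id), use.names = FALSE)
  type_of <- unlist(lapply(callsets, function(x) x$svtype),
                    use.names = FALSE)
  n <- length(all)
  parent <- uf_new(n)
  for (st in unique(type_of)) {
    idx <- which(type_of == st)
    if (length(idx) < 2L) next
    sub <- all[idx]
    h <- findOverlaps(sub, sub, minoverlap = 1L)
    h <- h[queryHits(h) < subjectHits(h)]
    if (!length(h)) next
    ro <- reciprocal_overlap(sub[queryHits(h)], sub[subjectHits(h)])
    link <- which(ro >= recip_threshold)
    for (k in link) {
      a <- uf_find(parent, idx[queryHits(h)[k]])
      b <- uf_find(parent, idx[subjectHits(h)[k]])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  regions <- list()
  for (r in unique(root)) {
    members <- which(root == r)
    samples <- unique(sample_of[members])
    if (length(samples) < min_recurrence) next
    s <- start(all)[members]; e <- end(all)[members]
    rep_start <- as.integer(round(median(s)))
    rep_end <- as.integer(round(median(e)))
    min_s <- max(s); min_e <- min(e)
    if (min_s > min_e) { # degenerate chained cluster: fall back
      min_s <- rep_start; min_e <- rep_end
    }
    g <- GRanges(as.character(seqnames(all))[members[1L]],
                 IRanges(rep_start, rep_end))
    mcols(g) <- DataFrame(
      svtype = type_of[members[1L]],
      recurrence = length(samples), n_members = length(members),
      member_ids = paste(sample_of[members], id_of[members], sep = ":",
                         collapse = ","),
      min_start = min_s, min_end = min_e,
      max_start = min(s), max_end = max(e))
    regions[[length(regions) + 1L]] <- g
  }
  out <- if (length(regions))
    unlist(GRangesList(regions), use.names = FALSE) else empty()
  o <- order(as.character(seqnames(out)), start(out))
  out <- out[o]
  if (length(out)) names(out) <- sprintf("artifact%03d", seq_along(out))
  attr(out, "blacklist") <- TRUE
  out
}

#' Write and read the two-BED artifact blacklist representation
#'
#' The minimum-overlap BED holds the intersection of each cluster's
#' member spans, the maximum-overlap BED their union; BED names carry
#' `cluster|svtype` so the two files stay paired and type-aware.
#'
#' @param blacklist result of [build_artifact_blacklist()].
#' @param min_path,max_path output BED paths.
#' @export
write_blacklist_beds <- function(blacklist, min_path, max_path) {
  nm <- names(blacklist)
  if (is.null(nm)) nm <- sprintf("artifact%03d", seq_along(blacklist))
  lab <- paste(nm, blacklist$svtype, sep = "|")
  mk <- function(s, e) {
    g <- GRanges(seqnames(blacklist), IRanges(s, e))
    g$name <- lab
    g$score <- blacklist$recurrence
    g
  }
  write_bed(mk(blacklist$min_start, blacklist$min_end), min_path)
  write_bed(mk(blacklist$max_start, blacklist$max_end), max_path)
  invisible(c(min_path, max_path))
}

#' @rdname write_blacklist_beds
#' @return `read_blacklist_beds`: an `artifact_blacklist`-style `GRanges`
#'   (representative interval = midpoint-free maximum span; only the
#'   containment columns and `svtype` are recoverable from the BEDs).
#' @export
read_blacklist_beds <- function(min_path, max_path) {
  mn <- read_bed(min_path)
  mx <- read_bed(max_path)
  stopifnot(length(mn) == length(mx), all(mn$name == mx$name))
  svtype <- sub("^.*\\|", "", mn$name)
  out <- granges(mx)
  mcols(out) <- DataFrame(
    svtype = svtype,
    recurrence = as.integer(mn$score),
    n_members = NA_integer_, member_ids = NA_character_,
    min_start = start(mn), min_end = end(mn),
    max_start = start(mx), max_end = end(mx))
  names(out) <- sub("\\|.*$", "", mn$name)
  attr(out, "blacklist") <- TRUE
  out
}
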