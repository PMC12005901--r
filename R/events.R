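SVTYPES <- c("DEL", "DUP", "INS")
CLAIMS <- c("DEPTH", "JUNCTION", "BOTH", "UNKNOWN")
ORIGINS <- c("TRUTH", "QUERY")

#' Construct a set of CNV events
#'
#' A CNV event set is a `GRanges` whose ranges are the reference spans of
#' deletion/duplication events, with metadata columns:
#' \describe{
#'   \item{svtype}{dosage direction: `"DEL"`, `"DUP"` or `"INS"`
#'     (insertions are only admitted during truth-set preparation,
#'     before reclassification).}
#'   \item{svlen}{event length in bases. For DEL/DUP this equals the
#'     reference span width; for INS it is the inserted-sequence length.}
#'   \item{claim}{evidence claim of the caller: `"DEPTH"`, `"JUNCTION"`,
#'     `"BOTH"` or `"UNKNOWN"` (maps the SVCLAIM INFO annotation; `"J"`
#'     means junction-read support only).}
#'   \item{id}{record identifier.}
#'   \item{origin}{`"TRUTH"` or `"QUERY"`.}
#' }
#'
#' @param chrom,start,end reference span (1-based closed).
#' @param svtype character vector in `DEL`/`DUP`/`INS`.
#' @param id record identifiers; defaults to `evt1..evtN`.
#' @param claim evidence claim, recycled; default `"UNKNOWN"`.
#' @param origin `"TRUTH"` or `"QUERY"`, recycled.
#' @param svlen event lengths; required for INS records, otherwise
#'   derived from the span.
#' @return `GRanges` with the columns above.
#' @examples
#' cnv_events("ctg1", 1001, 2000, "DEL", origin = "TRUTH")
#' @export
cnv_events <- function(chrom, start, end, svtype,
                       id = NULL, claim = "UNKNOWN",
                       origin = "QUERY", svlen = NULL) {
  gr <- genomic_intervals(chrom, start, end)
  n <- length(gr)
  svtype <- rep_len(as.character(svtype), n)
  claim <- rep_len(as.character(claim), n)
  origin <- rep_len(as.character(origin), n)
  if (is.null(id)) id <- sprintf("evt%d", seq_len(n))
  id <- rep_len(as.character(id), n)
  if (!all(svtype %in% SVTYPES))
    stop("svtype must be one of ", paste(SVTYPES, collapse = "/"))
  if (!all(claim %in% CLAIMS))
    stop("claim must be one of ", paste(CLAIMS, collapse = "/"))
  if (!all(origin %in% ORIGINS))
    stop("origin must be TRUTH or QUERY")
  if (is.null(svlen)) {
    if (any(svtype == "INS"))
      stop("svlen (inserted-sequence length) is required for INS events")
    svlen <- width(gr)
  }
  svlen <- rep_len(as.integer(svlen), n)
  notins <- svtype != "INS"
  svlen[notins] <- width(gr)[notins]
  if (any(svlen <= 0L)) stop("event length must be positive")
  mcols(gr) <- DataFrame(svtype = svtype, svlen = svlen, claim = claim,
                         id = id, origin = origin)
  gr
}

#' Validate a CNV event set
#'
#' Checks the invariants documented in [cnv_events()]; called by every
#' consumer of event sets so malformed inputs fail loudly at the door.
#'
#' @param x candidate event set.
#' @param allow_ins whether INS records are admissible (truth preparation
#'   only).
#' @return `x`, invisibly, or an error.
#' @export
validate_cnv_events <- function(x, allow_ins = FALSE) {
  if (!is(x, "GRanges")) stop("event set must be a GRanges")
  need <- c("svtype", "svlen", "claim", "id", "origin")
  miss <- setdiff(need, names(mcols(x)))
  if (length(miss))
    stop("event set is missing columns: ", paste(miss, collapse = ", "))
  ok_types <- if (allow_ins) SVTYPES else c("DEL", "DUP")
  if (!all(x$svtype %in% ok_types))
    stop("unexpected svtype; INS events require truth preparation first")
  if (any(x$svlen <= 0L)) stop("event length must be positive")
  notins <- x$svtype != "INS"
  if (any(x$svlen[notins] != width(x)[notins]))
    stop("DEL/DUP length must equal the reference span width")
  invisible(x)
}

#' Restrict events to the evaluated size window
#'
#' Retains events whose length lies inside `[min_len, max_len]`, both
#' bounds inclusive. The default window (500 bp to 10 Mb) is the range
#' over which the benchmark is defined; events outside it are reported,
#' not silently dropped.
#'
#' @param events CNV event set ([cnv_events()]).
#' @param min_len,max_len inclusive bounds in bases.
#' @return list with `kept` (events in the window, input order preserved)
#'   and `dropped` (data.frame of `id`, `svlen`, `reason`).
#' @export
size_filter <- function(events, min_len = 500, max_len = 10e6) {
  validate_cnv_events(events, allow_ins = TRUE)
  len <- events$svlen
  keep <- len >= min_len & len <= max_len
  reason <- ifelse(len < min_len, sprintf("below %d bp", as.integer(min_len)),
                   sprintf("above %d bp", as.integer(max_len)))
  dropped <- data.frame(id = events$id[!keep], svlen = len[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  list(kept = events[keep], dropped = dropped)
}
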