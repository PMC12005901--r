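#' Construct a validated set of genomic intervals
#'
#' Thin constructor around [GenomicRanges::GRanges] that enforces the
#' package's interval invariants: positive width (empty intervals are
#' rejected) and 1-based closed coordinates. All interval containers in
#' cnvbench are plain `GRanges` objects so the full
#' GenomicRanges/IRanges toolkit applies.
#'
#' @param chrom character vector of contig names.
#' @param start,end integer vectors, 1-based closed coordinates
#'   (`start <= end`; a single base is `start == end`).
#' @param ... further metadata columns passed to the `GRanges` mcols.
#' @return a `GRanges` object.
#' @examples
#' genomic_intervals("chr1", 101, 200)
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be non-missing integers")
  if (any(start < 1L))
    stop("interval start must be >= 1 (1-based closed coordinates)")
  if (any(end < start))
    stop("empty or inverted intervals are rejected (need start <= end)")
  GRanges(chrom, IRanges(start, end), ...)
}

#' Base-pair overlap between paired intervals
#'
#' Vectorised over pairs: `a[i]` is compared with `b[i]` (shorter input
#' recycled if length 1). Intervals on different contigs overlap by 0;
#' adjacent intervals share no base and also return 0.
#'
#' @param a,b `GRanges` objects of equal length (or length 1).
#' @return integer vector of shared base counts.
#' @examples
#' a <- genomic_intervals("c", 1, 100)
#' overlap_bp(a, genomic_intervals("c", 101, 200))  # 0: adjacency
#' overlap_bp(a, genomic_intervals("c", 100, 200))  # 1
#' @export
overlap_bp <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  ov[as.character(seqnames(a)) != as.character(seqnames(b))] <- 0L
  pmax(ov, 0L)
}

#' Reciprocal overlap between paired intervals
#'
#' `min(overlap / width(a), overlap / width(b))`, the symmetric overlap
#' fraction used to match calls against recurrent artifacts. Equals 1
#' exactly when the two spans are identical and 0 when disjoint.
#'
#' @inheritParams overlap_bp
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' a <- genomic_intervals("c", 1, 100)
#' reciprocal_overlap(a, genomic_intervals("c", 51, 150))  # 0.5
#' @export
reciprocal_overlap <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  ov <- as.numeric(overlap_bp(a, b))
  pmin(ov / width(a), ov / width(b))
}

#' Overlap queries against an indexed region set
#'
#' Region sets (high-confidence regions, the assembly gap track, artifact
#' BEDs) are held as `GRanges`, which indexes intervals for overlap
#' queries. `region_hits()` returns, for each probe, the indices of
#' regions sharing at least `min_bp` bases; `overlaps_regions()` is the
#' logical convenience form. Probes on contigs absent from the region set
#' simply return no hits.
#'
#' @param probes,regions `GRanges`.
#' @param min_bp minimum shared bases to count as a hit (default 1, so
#'   touching intervals do not match).
#' @return `region_hits`: a [S4Vectors::Hits] object; `overlaps_regions`:
#'   a logical vector along `probes`.
#' @export
region_hits <- function(probes, regions, min_bp = 1L) {
  findOverlaps(probes, regions, minoverlap = as.integer(min_bp))
}

#' @rdname region_hits
#' @export
overlaps_regions <- function(probes, regions, min_bp = 1L) {
  overlapsAny(probes, regions, minoverlap = as.integer(min_bp))
}

#' Read and write BED region files
#'
#' BED input/output is delegated to rtracklayer, which performs the
#' 0-based half-open to 1-based closed conversion. A free-text `label`
#' (e.g. "high-confidence", "gap-track") is attached as metadata.
#'
#' @param path file path.
#' @param label optional free-text label stored in `metadata(x)$label`.
#' @return `read_bed`: a `GRanges`.
#' @export
read_bed <- function(path, label = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(label)) S4Vectors::metadata(gr)$label <- label
  gr
}

#' @rdname read_bed
#' @param x a `GRanges` to write.
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}
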