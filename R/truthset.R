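ungapped_identity <- function(a, b) {
  # fraction of positions where the sequences agree; N never matches
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  sum(ca == cb & ca != "N") / length(ca)
}

#' Decide whether an insertion is a tandem duplication of its flank
#'
#' Truth sets frequently represent duplications as insertions of the
#' duplicated sequence. An insertion is accepted as a duplication when its
#' sequence matches the reference segment on either side of the insertion
#' point with at least `identity_threshold` ungapped identity, allowing
#' the repeat copy to start up to `slop` bases away from the exact
#' insertion point. All `(flank, offset)` combinations are scored and the
#' best is reported; accepted insertions yield a DUP event spanning the
#' matched reference segment (the duplicated footprint, which is what
#' downstream exon matching needs).
#'
#' Identity is the fraction of aligned positions with equal bases; `N`
#' never counts as a match, and an insertion consisting only of `N` is
#' rejected outright. Windows running past a contig edge are skipped.
#'
#' @param pos 1-based position of the reference base immediately left of
#'   the insertion point (the VCF `POS` of the record).
#' @param seq inserted sequence (uppercase ACGTN).
#' @param reference `DNAStringSet`.
#' @param chrom contig of the insertion.
#' @param identity_threshold minimum identity to accept (default 0.95).
#' @param slop maximum positional offset of the repeat copy in bases
#'   (default 2); offsets `-slop..+slop` are scanned.
#' @return list with `accepted`, `identity`, `offset`, `flank`
#'   (`"LEFT"`/`"RIGHT"`/`NA`), `reason` (for rejections), and `event`
#'   (a one-row DUP [cnv_events()] when accepted, else `NULL`).
#' @examples
#' ref <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 100)))
#' # the 40 bp right of position 60 inserted back at 60: a perfect tandem dup
#' s <- as.character(Biostrings::subseq(ref[["c1"]], 61, 100))
#' verify_duplication(60, s, ref, "c1")$identity
#' @export
verify_duplication <- function(pos, seq, reference, chrom,
                               identity_threshold = 0.95, slop = 2L) {
  stopifnot(chrom %in% names(reference))
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 1L) stop("inserted sequence must be non-empty")
  if (!grepl("^[ACGTN]+$", seq))
    stop("inserted sequence must be over ACGTN")
  reject <- function(reason, identity = NA_real_)
    list(accepted = FALSE, identity = identity, offset = NA_integer_,
         flank = NA_character_, reason = reason, event = NULL)
  if (gsub("N", "", seq) == "")
    return(reject("insertion is all N"))
  contig <- reference[[chrom]]
  clen <- length(contig)
  best <- list(identity = -1, offset = NA_integer_, flank = NA_character_,
               start = NA_integer_)
  scanned <- FALSE
  for (flank in c("LEFT", "RIGHT")) {
    for (off in seq.int(-slop, slop)) {
      if (flank == "RIGHT") {
        s1 <- pos + 1L + off
      } else {
        s1 <- pos + off - L + 1L
      }
      e1 <- s1 + L - 1L
      if (s1 < 1L || e1 > clen) next
      scanned <- TRUE
      idn <- ungapped_identity(seq, as.character(subseq(contig, s1, e1)))
      if (idn > best$identity) {
        best <- list(identity = idn, offset = off, flank = flank,
                     start = s1)
      }
    }
  }
  if (!scanned)
    return(reject("no in-bounds reference window on either flank"))
  accepted <- best$identity >= identity_threshold
  event <- NULL
  if (accepted) {
    event <- cnv_events(chrom, best$start, best$start + L - 1L, "DUP",
                        origin = "TRUTH")
  }
  list(accepted = accepted, identity = best$identity, offset = best$offset,
       flank = best$flank, reason = if (accepted) NA_character_ else
         "best identity below threshold", event = event)
}

#' Reclassify a table of insertions as duplications
#'
#' Runs [verify_duplication()] over the `insertions` table produced by
#' [read_sv_vcf()] and collects accepted DUP events plus a per-record
#' audit table.
#'
#' @param insertions data.frame with `id`, `chrom`, `pos`, `seq`.
#' @param reference `DNAStringSet`.
#' @inheritParams verify_duplication
#' @return list with `events` (DUP event set, ids carried over) and
#'   `audit` (data.frame `id`, `identity`, `offset`, `flank`, `accepted`,
#'   `reason`).
#' @export
convert_insertions <- function(insertions, reference,
                               identity_threshold = 0.95, slop = 2L) {
  n <- nrow(insertions)
  audit <- data.frame(id = insertions$id, identity = NA_real_,
                      offset = NA_integer_, flank = NA_character_,
                      accepted = FALSE, reason = NA_character_,
                      stringsAsFactors = FALSE)
  evs <- vector("list", n)
  for (i in seq_len(n)) {
    v <- verify_duplication(insertions$pos[i], insertions$seq[i],
                            reference, insertions$chrom[i],
                            identity_threshold, slop)
    audit$identity[i] <- v$identity
    audit$offset[i] <- v$offset
    audit$flank[i] <- v$flank
    audit$accepted[i] <- v$accepted
    audit$reason[i] <- v$reason
    if (v$accepted) {
      e <- v$event
      e$id <- insertions$id[i]
      evs[[i]] <- e
    }
  }
  evs <- evs[!vapply(evs, is.null, logical(1))]
  events <- if (length(evs)) do.call(c, evs) else
    cnv_events(character(0), integer(0), integer(0), character(0))
  list(events = events, audit = audit)
}

#' Prepare a truth set for benchmarking
#'
#' Full truth-preparation pipeline: load the truth VCF, keep DEL/DUP
#' records, reclassify sequence-resolved insertions as duplications where
#' the flank-identity test accepts them (others are excluded), and
#' restrict everything to the evaluated size window.
#'
#' @param vcf_path truth VCF.
#' @param reference `DNAStringSet` reference genome.
#' @param identity_threshold,slop see [verify_duplication()].
#' @param min_len,max_len see [size_filter()].
#' @return list with `events` (prepared truth events), `audit`
#'   (insertion-verification table), `skipped` (unusable records),
#'   `size_dropped` (events outside the window).
#' @export
prepare_truth_set <- function(vcf_path, reference,
                              identity_threshold = 0.95, slop = 2L,
                              min_len = 500, max_len = 10e6) {
  parsed <- read_sv_vcf(vcf_path, origin = "TRUTH", reference = reference)
  conv <- convert_insertions(parsed$insertions, reference,
                             identity_threshold, slop)
  events <- c(parsed$events, conv$events)
  sf <- size_filter(events, min_len = min_len, max_len = max_len)
  list(events = sf$kept, audit = conv$audit, skipped = parsed$skipped,
       size_dropped = sf$dropped)
}

#' Write the insertion-verification audit table
#'
#' @param audit audit data.frame from [convert_insertions()].
#' @param path output TSV path.
#' @export
write_dup_audit <- function(audit, path) {
  write.table(audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
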