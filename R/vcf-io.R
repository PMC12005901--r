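#' Read a structural-variant VCF into CNV events
#'
#' Parses a VCF in the common SV dialect (symbolic `<DEL>`/`<DUP>` ALT
#' alleles or `SVTYPE` INFO, span end from `END` or `SVLEN`, optional
#' `SVCLAIM` evidence claim). Deletions and duplications become
#' [cnv_events()]; sequence-resolved insertions are returned separately so
#' truth preparation can decide whether each one is really a duplication
#' ([verify_duplication()]). Records that cannot be used (unsupported
#' SVTYPE, missing both END and SVLEN, no inserted sequence, contig absent
#' from the reference) are reported with reasons, never silently dropped.
#'
#' Only the first ALT allele of a record is considered. The event span of
#' a DEL/DUP record at `POS` with end `END` is `[POS, END]` (1-based
#' closed), i.e. length `END - POS + 1`.
#'
#' @param path VCF file path (plain text or bgzip).
#' @param origin `"TRUTH"` or `"QUERY"`, stamped on every event.
#' @param reference optional `DNAStringSet`; when given, records on
#'   contigs absent from it are rejected with a reason.
#' @return list with
#'   \item{events}{`GRanges` of DEL/DUP events,}
#'   \item{insertions}{data.frame `id`, `chrom`, `pos` (base immediately
#'     left of the insertion point), `seq` (inserted bases),}
#'   \item{skipped}{data.frame `id`, `reason`.}
#' @export
read_sv_vcf <- function(path, origin = c("QUERY", "TRUTH"),
                        reference = NULL) {
  origin <- match.arg(origin)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  ids <- names(rr)
  if (is.null(ids)) ids <- sprintf("rec%d", seq_len(n))
  inf <- info(vcf)
  chrom <- as.character(seqnames(rr))
  pos <- start(rr)
  ref <- as.character(rr$REF)
  alt1 <- vapply(rr$ALT, function(a) {
    a <- as.character(a)
    if (length(a) == 0L) NA_character_ else a[[1L]]
  }, character(1))

  first_int <- function(col) {
    if (!col %in% names(inf)) return(rep(NA_integer_, n))
    v <- inf[[col]]
    if (is.list(v) || is(v, "List"))
      vapply(v, function(e) if (length(e)) as.integer(e[[1L]]) else
        NA_integer_, integer(1))
    else as.integer(v)
  }
  first_chr <- function(col) {
    if (!col %in% names(inf)) return(rep(NA_character_, n))
    v <- inf[[col]]
    if (is.list(v) || is(v, "List"))
      vapply(v, function(e) if (length(e)) as.character(e[[1L]]) else
        NA_character_, character(1))
    else as.character(v)
  }

  svtype <- first_chr("SVTYPE")
  sym <- !is.na(alt1) & grepl("^<(DEL|DUP|INS)>$", alt1)
  svtype[is.na(svtype) & sym] <- gsub("[<>]", "", alt1[is.na(svtype) & sym])
  endi <- first_int("END")
  svlen <- first_int("SVLEN")
  claim_raw <- toupper(first_chr("SVCLAIM"))
  claim <- rep("UNKNOWN", n)
  claim[claim_raw %in% "D"] <- "DEPTH"
  claim[claim_raw %in% "J"] <- "JUNCTION"
  claim[claim_raw %in% c("DJ", "JD")] <- "BOTH"
  bad_claim <- !is.na(claim_raw) & !(claim_raw %in% c("D", "J", "DJ", "JD"))
  if (any(bad_claim))
    warning(sum(bad_claim), " record(s) with unparseable SVCLAIM treated ",
            "as UNKNOWN")

  skipped <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  skip <- function(i, why) {
    skipped[nrow(skipped) + 1L, ] <<- list(ids[i], why)
  }

  ev <- vector("list", n)
  ins <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.null(reference) && !(chrom[i] %in% names(reference))) {
      skip(i, "contig absent from reference"); next
    }
    st <- svtype[i]
    if (is.na(st)) { skip(i, "no SVTYPE and non-symbolic ALT"); next }
    if (st %in% c("DEL", "DUP")) {
      e <- endi[i]
      if (is.na(e) && !is.na(svlen[i])) e <- pos[i] + abs(svlen[i]) - 1L
      if (is.na(e)) { skip(i, "missing both END and SVLEN"); next }
      if (e < pos[i]) { skip(i, "END precedes POS"); next }
      ev[[i]] <- data.frame(chrom = chrom[i], start = pos[i], end = e,
                            svtype = st, claim = claim[i], id = ids[i],
                            stringsAsFactors = FALSE)
    } else if (st == "INS") {
      a <- alt1[i]
      seqs <- NA_character_
      if (!is.na(a) && !grepl("^<", a)) {
        # ALT carries the padding base followed by the inserted sequence
        if (nchar(a) > nchar(ref[i]) &&
            substr(a, 1L, nchar(ref[i])) == ref[i])
          seqs <- substr(a, nchar(ref[i]) + 1L, nchar(a))
        else seqs <- a
      }
      if (is.na(seqs) || !nzchar(seqs)) {
        skip(i, "insertion without sequence-resolved ALT"); next
      }
      ins[[i]] <- data.frame(id = ids[i], chrom = chrom[i], pos = pos[i],
                             seq = toupper(seqs), stringsAsFactors = FALSE)
    } else {
      skip(i, sprintf("unsupported SVTYPE %s", st))
    }
  }
  evd <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  insd <- do.call(rbind, ins[!vapply(ins, is.null, logical(1))])
  events <- if (is.null(evd) || nrow(evd) == 0L) {
    cnv_events(character(0), integer(0), integer(0), character(0))
  } else {
    cnv_events(evd$chrom, evd$start, evd$end, evd$svtype, id = evd$id,
               claim = evd$claim, origin = origin)
  }
  if (is.null(insd))
    insd <- data.frame(id = character(0), chrom = character(0),
                       pos = integer(0), seq = character(0),
                       stringsAsFactors = FALSE)
  list(events = events, insertions = insd, skipped = skipped)
}

claim_to_svclaim <- function(claim) {
  c(DEPTH = "D", JUNCTION = "J", BOTH = "DJ", UNKNOWN = NA_character_)[claim]
}

#' Write CNV events as a structural-variant VCF
#'
#' Writes DEL/DUP events as symbolic-ALT records (`<DEL>`/`<DUP>`) with
#' `SVTYPE`, `END`, `SVLEN` and, when the claim is known, `SVCLAIM` INFO
#' fields. Insertions (used by the fixture generator to emulate
#' insertion-represented truth duplications) are written sequence-resolved
#' with a padding `N` base. Output is plain-text VCF 4.2 readable by
#' [read_sv_vcf()] and standard VCF tooling.
#'
#' @param events CNV event set (DEL/DUP).
#' @param path output path.
#' @param insertions optional data.frame as returned in
#'   `read_sv_vcf()$insertions`.
#' @param contig_lengths optional named integer vector for `##contig`
#'   header lines; defaults to the event set's `seqlengths` when set.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(events, path, insertions = NULL,
                         contig_lengths = NULL) {
  validate_cnv_events(events)
  if (is.null(contig_lengths)) {
    sl <- seqlengths(events)
    if (!all(is.na(sl))) contig_lengths <- sl
  }
  contigs <- unique(c(as.character(seqnames(events)),
                      if (!is.null(insertions)) insertions$chrom,
                      names(contig_lengths)))
  hdr <- c(
    "##fileformat=VCFv4.2",
    vapply(contigs, function(cg) {
      len <- contig_lengths[cg]
      if (!is.null(len) && !is.na(len))
        sprintf("##contig=<ID=%s,length=%d>", cg, as.integer(len))
      else sprintf("##contig=<ID=%s>", cg)
    }, character(1)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"Length of the variant\">",
    "##INFO=<ID=SVCLAIM,Number=.,Type=String,Description=\"Evidence claim: D depth, J junction\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  lines <- character(0)
  if (length(events)) {
    svlen_out <- ifelse(events$svtype == "DEL", -events$svlen, events$svlen)
    claim <- claim_to_svclaim(events$claim)
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", events$svtype,
                    end(events), svlen_out)
    info <- ifelse(is.na(claim), info,
                   sprintf("%s;SVCLAIM=%s", info, claim))
    lines <- sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\t%s",
                     as.character(seqnames(events)), start(events),
                     events$id, events$svtype, info)
  }
  if (!is.null(insertions) && nrow(insertions)) {
    ilines <- sprintf("%s\t%d\t%s\tN\tN%s\t.\tPASS\tSVTYPE=INS;SVLEN=%d",
                      insertions$chrom, as.integer(insertions$pos),
                      insertions$id, insertions$seq,
                      nchar(insertions$seq))
    lines <- c(lines, ilines)
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
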