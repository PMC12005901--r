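template_structures <- function(templates) {
  stopifnot(length(templates) > 0L)
  parts <- split(seq_along(templates), templates$gene)
  parts <- parts[unique(templates$gene)]
  lapply(parts, function(idx) {
    t <- templates[idx]
    o <- order(start(t))
    t <- t[o]
    list(name = t$gene[1],
         rel_start = start(t) - start(t)[1L],
         widths = width(t),
         span = end(t)[length(t)] - start(t)[1L] + 1L,
         strand = as.character(strand(t))[1L])
  })
}

place_gene <- function(chrom, anchor, tpl, name) {
  st <- anchor + tpl$rel_start
  g <- GRanges(chrom, IRanges(st, st + tpl$widths - 1L),
               strand = tpl$strand)
  mcols(g) <- DataFrame(gene = name, exon_rank = seq_along(g),
                        synthetic = TRUE, template = tpl$name)
  g
}

#' Spike synthetic gene models into a genome
#'
#' Plants translated copies of template exon structures so that sparse
#' truth sets gain scoreable exon overlaps. Two modes:
#' \describe{
#'   \item{general}{(default, `on_top_of = NULL`) scans each contig left
#'     to right and places templates — drawn round-robin from a
#'     seed-shuffled cycle — so that every gene span lies wholly inside a
#'     high-confidence region, overlaps no real gene span, and leaves at
#'     least `min_gap` bases between consecutive synthetic genes.}
#'   \item{on-top-of}{(`on_top_of = "DUP"` or `"DEL"`) anchors one
#'     template on each truth event of that dosage type so at least one
#'     exon overlaps the event span, subject to high-confidence
#'     containment and real-gene avoidance (the inter-gene gap rule does
#'     not apply to event-anchored placements).}
#' }
#' Placement is deterministic for a given seed. When `n_target` cannot be
#' reached the function returns what was placed and records the shortfall
#' in `attr(result, "shortfall")`.
#'
#' @param templates exon `GRanges` of the template genes (coordinates are
#'   only used for their relative exon structure).
#' @param high_conf `GRanges` of high-confidence regions.
#' @param real_genes exon `GRanges` of real genes to avoid (their full
#'   spans are avoided); may be empty.
#' @param truth_events truth CNV event set, required for on-top-of mode.
#' @param min_gap minimum number of bases strictly between consecutive
#'   synthetic genes (default 100 kb).
#' @param n_target maximum number of genes to place (default unlimited).
#' @param seed RNG seed controlling the template cycle.
#' @param on_top_of `NULL` for general mode, else `"DEL"` or `"DUP"`.
#' @return exon `GRanges` of synthetic genes (`synthetic = TRUE`,
#'   `template` provenance, `mode` column `"general"`/`"on_top"`), with a
#'   `shortfall` attribute (integer, 0 when `n_target` was met).
#' @export
spike_synthetic_genes <- function(templates, high_conf,
                                  real_genes = NULL, truth_events = NULL,
                                  min_gap = 100e3, n_target = Inf,
                                  seed = 1L, on_top_of = NULL) {
  tpls <- template_structures(templates)
  cycle_names <- with_seed(seed, sample(names(tpls)))
  cyc_i <- 0L
  next_tpl <- function() {
    cyc_i <<- cyc_i + 1L
    tpls[[cycle_names[(cyc_i - 1L) %% length(cycle_names) + 1L]]]
  }
  real_spans <- if (is.null(real_genes) || length(real_genes) == 0L)
    GRanges() else gene_spans(real_genes)
  placed <- list()
  count <- 0L

  ok_real <- function(cand_start, cand_end, chrom) {
    if (length(real_spans) == 0L) return(TRUE)
    probe <- GRanges(chrom, IRanges(cand_start, cand_end))
    !suppressWarnings(overlapsAny(probe, real_spans, minoverlap = 1L))
  }
  conflict_end <- function(cand_start, cand_end, chrom) {
    probe <- GRanges(chrom, IRanges(cand_start, cand_end))
    h <- suppressWarnings(findOverlaps(probe, real_spans, minoverlap = 1L))
    max(end(real_spans)[subjectHits(h)])
  }

  if (is.null(on_top_of)) {
    hc <- sort(high_conf, ignore.strand = TRUE)
    contigs <- unique(as.character(seqnames(hc)))
    for (cg in contigs) {
      if (count >= n_target) break
      regions <- hc[seqnames(hc) == cg]
      prev_end <- NA_integer_
      for (r in seq_along(regions)) {
        if (count >= n_target) break
        lo <- start(regions)[r]
        hi <- end(regions)[r]
        cursor <- if (is.na(prev_end)) lo else
          max(lo, prev_end + min_gap + 1L)
        repeat {
          if (count >= n_target) break
          tpl <- tpls[[cycle_names[cyc_i %% length(cycle_names) + 1L]]]
          cand_end <- cursor + tpl$span - 1L
          if (cand_end > hi) break
          if (!ok_real(cursor, cand_end, cg)) {
            cursor <- conflict_end(cursor, cand_end, cg) + 1L
            next
          }
          count <- count + 1L
          cyc_i <- cyc_i + 1L
          placed[[count]] <- place_gene(cg, cursor, tpl,
                                        sprintf("SYNG%05d", count))
          placed[[count]]$mode <- "general"
          prev_end <- cand_end
          cursor <- prev_end + min_gap + 1L
        }
      }
    }
  } else {
    stopifnot(on_top_of %in% c("DEL", "DUP"), !is.null(truth_events))
    validate_cnv_events(truth_events)
    targets <- truth_events[truth_events$svtype == on_top_of]
    for (i in seq_along(targets)) {
      if (count >= n_target) break
      ev <- targets[i]
      cg <- as.character(seqnames(ev))
      tpl <- next_tpl()
      done <- FALSE
      # try anchoring each template exon at the event start, then at the
      # event end minus the exon width
      anchors <- c(start(ev) - tpl$rel_start,
                   end(ev) - tpl$rel_start - tpl$widths + 1L)
      for (anchor in anchors) {
        if (anchor < 1L) next
        cand_end <- anchor + tpl$span - 1L
        probe <- GRanges(cg, IRanges(anchor, cand_end))
        inside <- any(start(high_conf) <= anchor & end(high_conf) >=
                        cand_end &
                        as.character(seqnames(high_conf)) == cg)
        if (!inside) next
        if (!ok_real(anchor, cand_end, cg)) next
        g <- place_gene(cg, anchor, tpl, sprintf("SYNT%05d", count + 1L))
        if (!any(overlap_bp(rep(granges(ev), length(g)), granges(g)) > 0L))
          next
        count <- count + 1L
        g$mode <- "on_top"
        placed[[count]] <- g
        done <- TRUE
        break
      }
    }
  }
  out <- if (count > 0L) unlist(GRangesList(placed), use.names = FALSE)
    else {
      g <- GRanges()
      mcols(g) <- DataFrame(gene = character(0), exon_rank = integer(0),
                            synthetic = logical(0), template = character(0),
                            mode = character(0))
      g
    }
  shortfall <- if (is.finite(n_target))
    as.integer(max(0, n_target - count)) else 0L
  attr(out, "shortfall") <- shortfall
  out
}

#' Audit synthetic gene placements
#'
#' Independent post-hoc checker for the spiking constraints: every
#' synthetic gene span must lie wholly inside one high-confidence region,
#' overlap no real gene span, preserve its template's exact exon
#' structure (when templates are supplied), and — for general-mode
#' placements, per contig — leave at least `min_gap` bases before the
#' next synthetic gene. Implemented by direct arithmetic on the
#' placements, not by re-running the placer.
#'
#' @param synthetic exon `GRanges` from [spike_synthetic_genes()].
#' @param high_conf high-confidence `GRanges`.
#' @param real_genes real exon `GRanges` (or `NULL`).
#' @param min_gap gap rule in bases.
#' @param templates template exon `GRanges` to check structure against
#'   (optional).
#' @return data.frame of violations (`gene`, `rule`, `detail`); zero rows
#'   means every constraint holds.
#' @export
audit_synthetic_genes <- function(synthetic, high_conf, real_genes = NULL,
                                  min_gap = 100e3, templates = NULL) {
  bad <- data.frame(gene = character(0), rule = character(0),
                    detail = character(0), stringsAsFactors = FALSE)
  if (length(synthetic) == 0L) return(bad)
  note <- function(gene, rule, detail)
    bad[nrow(bad) + 1L, ] <<- list(gene, rule, detail)
  spans <- gene_spans(synthetic)
  mode <- synthetic$mode[match(spans$gene, synthetic$gene)]
  hc_chrom <- as.character(seqnames(high_conf))
  for (i in seq_along(spans)) {
    cg <- as.character(seqnames(spans)[i])
    s <- start(spans)[i]; e <- end(spans)[i]
    if (!any(hc_chrom == cg & start(high_conf) <= s & end(high_conf) >= e))
      note(spans$gene[i], "high_confidence",
           "gene span not contained in any high-confidence region")
  }
  if (!is.null(real_genes) && length(real_genes)) {
    rs <- gene_spans(real_genes)
    hit <- suppressWarnings(overlapsAny(spans, rs, minoverlap = 1L))
    for (i in which(hit))
      note(spans$gene[i], "real_gene_overlap",
           "gene span overlaps a real gene")
  }
  gen <- spans[mode == "general"]
  for (cg in unique(as.character(seqnames(gen)))) {
    g <- gen[seqnames(gen) == cg]
    o <- order(start(g))
    g <- g[o]
    if (length(g) < 2L) next
    gaps <- start(g)[-1L] - end(g)[-length(g)] - 1L
    for (k in which(gaps < min_gap))
      note(g$gene[k + 1L], "min_gap",
           sprintf("gap of %d bp before this gene (< %d)", gaps[k],
                   as.integer(min_gap)))
  }
  if (!is.null(templates)) {
    tpls <- template_structures(templates)
    for (gn in unique(synthetic$gene)) {
      g <- synthetic[synthetic$gene == gn]
      g <- g[order(start(g))]
      tpl <- tpls[[g$template[1L]]]
      if (is.null(tpl)) {
        note(gn, "template", "unknown template"); next
      }
      same <- length(g) == length(tpl$widths) &&
        all(width(g) == tpl$widths) &&
        all(start(g) - start(g)[1L] == tpl$rel_start)
      if (!same)
        note(gn, "template",
             "exon structure is not an exact translation of the template")
    }
  }
  bad
}
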