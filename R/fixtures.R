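#' Simulate a random reference genome
#'
#' Seed-deterministic random ACGT contigs, optionally with embedded
#' tandem-duplication sites: at each site a random unit is written twice
#' in a row, and the recorded insertion points reconstruct an insertion
#' that [verify_duplication()] must accept at identity 1 (via the right
#' flank at `ins_pos_right`, via the left flank at `ins_pos_left`).
#'
#' @param seed integer seed.
#' @param contig_lengths named integer vector (>= 10 kb each).
#' @param n_repeats tandem-duplication sites to embed per genome.
#' @param repeat_unit_len unit length of each site.
#' @return list with `dna` (`DNAStringSet`) and `repeats` (data.frame
#'   `chrom`, `start` of the first copy, `unit_len`, `unit`,
#'   `ins_pos_right`, `ins_pos_left`).
#' @export
simulate_reference <- function(seed = 1L,
                               contig_lengths = c(ctg1 = 50e3, ctg2 = 50e3),
                               n_repeats = 0L, repeat_unit_len = 1000L) {
  stopifnot(all(contig_lengths >= 10e3))
  with_seed(seed, {
    seqs <- lapply(contig_lengths, function(L)
      sample(c("A", "C", "G", "T"), L, replace = TRUE))
    names(seqs) <- names(contig_lengths)
    reps <- data.frame(chrom = character(0), start = integer(0),
                       unit_len = integer(0), unit = character(0),
                       ins_pos_right = integer(0),
                       ins_pos_left = integer(0),
                       stringsAsFactors = FALSE)
    if (n_repeats > 0L) {
      L <- as.integer(repeat_unit_len)
      slots_per <- ceiling(n_repeats / length(seqs))
      k <- 0L
      for (cg in names(seqs)) {
        clen <- length(seqs[[cg]])
        # evenly spaced slots keep sites (and their slop windows) apart
        slot_w <- clen %/% (slots_per + 1L)
        stopifnot(slot_w > 2L * L + 10L)
        for (s in seq_len(slots_per)) {
          if (k >= n_repeats) break
          k <- k + 1L
          p <- s * slot_w + sample.int(100L, 1L)
          unit <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
          seqs[[cg]][p:(p + L - 1L)] <- unit
          seqs[[cg]][(p + L):(p + 2L * L - 1L)] <- unit
          reps[nrow(reps) + 1L, ] <- list(cg, p, L,
                                          paste(unit, collapse = ""),
                                          p - 1L, p + 2L * L - 1L)
        }
      }
    }
    dna <- DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
    list(dna = dna, repeats = reps)
  })
}

#' Simulate gene models along contigs
#'
#' Left-to-right placement of genes with random exon structures and
#' random inter-gene spacing; deterministic for a seed.
#'
#' @param seed integer seed.
#' @param contig_lengths named integer vector.
#' @param n_genes number of genes to place.
#' @param exons_per_gene,exon_len,intron_len inclusive ranges
#'   (length-2 integer vectors).
#' @param gene_gap inclusive range of inter-gene gaps.
#' @return exon `GRanges` as in [gene_models()].
#' @export
simulate_gene_models <- function(seed = 1L,
                                 contig_lengths = c(ctg1 = 5e6, ctg2 = 5e6),
                                 n_genes = 50L,
                                 exons_per_gene = c(3L, 8L),
                                 exon_len = c(80L, 300L),
                                 intron_len = c(500L, 5000L),
                                 gene_gap = c(10e3, 50e3)) {
  with_seed(seed, {
    place_genes(contig_lengths, n_genes, exons_per_gene, exon_len,
                intron_len, gene_gap, margin = 0L)$genes
  })
}

rint <- function(lo, hi, n = 1L) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (hi <= lo) rep(lo, n) else lo + (sample.int(hi - lo + 1L, n,
                                                 replace = TRUE) - 1L)
}

# sequential gene placement; margin reserves a private territory around
# each gene so planted events of different genes can never interact
place_genes <- function(contig_lengths, n_genes, exons_per_gene, exon_len,
                        intron_len, gene_gap, margin) {
  rows <- list(); terr <- list()
  count <- 0L
  for (cg in names(contig_lengths)) {
    cursor <- margin + 1L
    clen <- contig_lengths[[cg]]
    while (count < n_genes) {
      nx <- rint(exons_per_gene[1], exons_per_gene[2])
      ws <- rint(exon_len[1], exon_len[2], nx)
      ins <- if (nx > 1L) rint(intron_len[1], intron_len[2], nx - 1L)
        else integer(0)
      span <- sum(ws) + sum(ins)
      if (cursor + span - 1L + margin > clen) break
      count <- count + 1L
      st <- cursor + cumsum(c(0L, head(ws, -1L) + ins))
      rows[[count]] <- data.frame(chrom = cg, start = st,
                                  end = st + ws - 1L,
                                  gene = sprintf("G%04d", count),
                                  stringsAsFactors = FALSE)
      terr[[count]] <- data.frame(chrom = cg, gene = sprintf("G%04d", count),
                                  lo = cursor - margin,
                                  hi = cursor + span - 1L + margin,
                                  stringsAsFactors = FALSE)
      cursor <- cursor + span - 1L + 2L * margin +
        rint(gene_gap[1], gene_gap[2])
    }
  }
  if (count < n_genes)
    stop(sprintf("infeasible spec: only %d of %d genes fit the contigs",
                 count, n_genes))
  ex <- do.call(rbind, rows)
  genes <- gene_models(GRanges(ex$chrom, IRanges(ex$start, ex$end),
                               strand = "+"),
                       ex$gene)
  sl <- as.integer(contig_lengths)
  names(sl) <- names(contig_lengths)
  seqlengths(genes) <- sl[seqlevels(genes)]
  list(genes = genes, territories = do.call(rbind, terr))
}

# generator-side classification: plain integer arithmetic, no interval
# machinery shared with the benchmark engine
gen_classify <- function(ev, ex, pad) {
  pex_s <- pmax(ex$start - pad, 1L)
  pex_e <- ex$end + pad
  hits <- lapply(seq_len(nrow(ev)), function(i)
    which(ex$chrom == ev$chrom[i] & pex_s <= ev$end[i] &
            pex_e >= ev$start[i]))
  ev$n_exons <- lengths(hits)
  is_t <- ev$side == "TRUTH"
  cover <- function(sel) {
    k <- unlist(lapply(which(sel), function(i)
      paste(hits[[i]], ev$svtype[i])), use.names = FALSE)
    unique(k)
  }
  tcov <- cover(is_t)
  qcov <- cover(!is_t)
  status <- character(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    k <- if (length(hits[[i]])) paste(hits[[i]], ev$svtype[i])
      else character(0)
    status[i] <- if (is_t[i]) {
      if (!length(k)) "EXCLUDED"
      else if (any(k %in% qcov)) "DETECTED" else "FN"
    } else {
      if (!length(k)) "IGNORED"
      else if (any(k %in% tcov)) "TP" else "FP"
    }
  }
  ev$status <- status
  ev
}

# generator-side stratified counting (mirrors the GA4GH definitions with
# plain sums; kept separate from cnv_metrics on purpose)
gen_expected_metrics <- function(ev, length_bins, exon_bins) {
  t <- ev[ev$side == "TRUTH" & ev$status != "EXCLUDED", ]
  q <- ev[ev$side == "QUERY" & ev$status != "IGNORED", ]
  rows <- list()
  add <- function(axis, stratum, tsel, qsel) {
    tp_t <- sum(t$status[tsel] == "DETECTED"); fn <- sum(tsel) - tp_t
    tp_q <- sum(q$status[qsel] == "TP"); fp <- sum(qsel) - tp_q
    rows[[length(rows) + 1L]] <<- data.frame(
      axis = axis, stratum = stratum, tp_truth = tp_t, fn = fn,
      tp_query = tp_q, fp = fp,
      sensitivity = if (tp_t + fn > 0) tp_t / (tp_t + fn) else NA_real_,
      precision = if (tp_q + fp > 0) tp_q / (tp_q + fp) else NA_real_,
      stringsAsFactors = FALSE)
  }
  add("ALL", "ALL", rep(TRUE, nrow(t)), rep(TRUE, nrow(q)))
  for (st in c("DEL", "DUP"))
    add("SVTYPE", st, t$svtype == st, q$svtype == st)
  memb <- function(len, b) {
    lo <- if (b$lo_open) len > b$lo else len >= b$lo
    lo & (is.infinite(b$hi) | len < b$hi)
  }
  for (k in seq_len(nrow(length_bins)))
    add("LENGTH_BIN", length_bins$label[k],
        memb(t$length, length_bins[k, ]), memb(q$length, length_bins[k, ]))
  for (k in seq_len(nrow(exon_bins)))
    add("EXON_COUNT_BIN", exon_bins$label[k],
        t$n_exons >= exon_bins$lo[k] & t$n_exons <= exon_bins$hi[k],
        q$n_exons >= exon_bins$lo[k] & q$n_exons <= exon_bins$hi[k])
  do.call(rbind, rows)
}

#' Default planted truth composition
#'
#' Counts of planted truth events per dosage type and length range,
#' spanning the sub-kilobase to multi-kilobase ranges the benchmark
#' stratifies over.
#'
#' @return data.frame `svtype`, `lo`, `hi` (event length drawn uniformly
#'   in `[lo, hi]`), `n`.
#' @export
default_truth_counts <- function() {
  data.frame(
    svtype = rep(c("DEL", "DUP"), each = 4L),
    lo = rep(c(500L, 1000L, 5000L, 12000L), 2L),
    hi = rep(c(999L, 4999L, 9999L, 40000L), 2L),
    n = c(3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE)
}

#' Simulate a complete benchmark case with known composition
#'
#' Generates gene models, a truth set and a query call set whose
#' classification is fixed by construction: a chosen fraction of truth
#' events receive a same-type query sharing their anchor exon (true
#' positives), some queries copy a truth span with the opposite dosage
#' type (direction-mismatch false positives), some overlap exons of
#' genes carrying no truth event (unmatched-exon false positives), and
#' some fall in deep intergenic space (ignored). Genes are placed in
#' private territories wide enough that events of different genes cannot
#' interact, so the planted composition is exact. Expected statuses,
#' per-event exon counts and the full stratified metric table are
#' computed at generation time by the generator's own plain-integer
#' bookkeeping, independent of the benchmark engine.
#'
#' @param seed integer seed.
#' @param contig_lengths named contig lengths.
#' @param n_genes genes to place (must accommodate truths + exon-FPs).
#' @param exons_per_gene,exon_len,intron_len gene-structure ranges.
#' @param truth_counts data.frame as [default_truth_counts()].
#' @param detect_frac fraction of truth events given a matching query.
#' @param n_fp_direction,n_fp_exon,n_ignored planted query counts.
#' @param pad splice padding used for the expected bookkeeping.
#' @param length_bins,exon_bins strata for the expected metric table.
#' @return list of class `cnv_benchmark_case`: `genes`, `truth`,
#'   `queries`, `contig_lengths`, `pad`, `events` (the generator's
#'   per-event bookkeeping: side, svtype, length, n_exons, status),
#'   `expected_metrics`, `expected_counts`.
#' @export
simulate_benchmark_case <- function(seed = 1L,
                                    contig_lengths = c(ctg1 = 5e6,
                                                       ctg2 = 5e6),
                                    n_genes = 40L,
                                    exons_per_gene = c(3L, 8L),
                                    exon_len = c(80L, 300L),
                                    intron_len = c(1000L, 4000L),
                                    truth_counts = default_truth_counts(),
                                    detect_frac = 0.75,
                                    n_fp_direction = 3L, n_fp_exon = 3L,
                                    n_ignored = 4L, pad = 15L,
                                    length_bins = default_length_bins(),
                                    exon_bins = default_exon_bins()) {
  n_truth <- sum(truth_counts$n)
  if (n_truth + n_fp_exon > n_genes)
    stop("infeasible spec: need at least ", n_truth + n_fp_exon,
         " genes for the planted events")
  max_len <- max(truth_counts$hi)
  margin <- max_len + pad + 1000L
  with_seed(seed, {
    pg <- place_genes(contig_lengths, n_genes, exons_per_gene, exon_len,
                      intron_len, gene_gap = c(10e3, 30e3),
                      margin = margin)
    genes <- pg$genes
    terr <- pg$territories
    exdf <- data.frame(chrom = as.character(seqnames(genes)),
                       start = start(genes), end = end(genes),
                       gene = genes$gene, stringsAsFactors = FALSE)
    gene_ids <- unique(exdf$gene)
    perm <- sample(gene_ids)
    truth_genes <- perm[seq_len(n_truth)]
    fp_exon_genes <- perm[n_truth + seq_len(n_fp_exon)]

    plant_on_gene <- function(gene, L) {
      ge <- exdf[exdf$gene == gene, ]
      tr <- terr[terr$gene == gene, ]
      k <- sample.int(nrow(ge), 1L)
      s_lo <- max(tr$lo, ge$start[k] - L + 1L)
      s_hi <- min(ge$end[k], tr$hi - L + 1L)
      stopifnot(s_lo <= s_hi)
      s <- rint(s_lo, s_hi)
      list(chrom = ge$chrom[1], start = s, end = s + L - 1L,
           anchor = k, terr = tr)
    }

    ev <- data.frame(side = character(0), id = character(0),
                     chrom = character(0), start = integer(0),
                     end = integer(0), svtype = character(0),
                     length = integer(0), gene = character(0),
                     planted = character(0), stringsAsFactors = FALSE)
    addev <- function(side, id, chrom, s, e, svtype, gene, planted)
      ev[nrow(ev) + 1L, ] <<- list(side, id, chrom, s, e, svtype,
                                   e - s + 1L, gene, planted)

    gi <- 0L
    truth_anchor <- list()
    for (r in seq_len(nrow(truth_counts))) {
      for (j in seq_len(truth_counts$n[r])) {
        gi <- gi + 1L
        gene <- truth_genes[gi]
        L <- rint(truth_counts$lo[r], truth_counts$hi[r])
        p <- plant_on_gene(gene, L)
        id <- sprintf("T%03d", gi)
        addev("TRUTH", id, p$chrom, p$start, p$end,
              truth_counts$svtype[r], gene, "truth")
        truth_anchor[[id]] <- p
      }
    }
    truth_ids <- ev$id[ev$side == "TRUTH"]
    n_det <- round(detect_frac * n_truth)
    detected <- sample(truth_ids, n_det)
    qn <- 0L
    for (id in detected) {
      qn <- qn + 1L
      t <- ev[ev$id == id, ]
      p <- truth_anchor[[id]]
      ge <- exdf[exdf$gene == t$gene, ][p$anchor, ]
      for (try in 1:20) {
        js <- rint(-200L, 200L); je <- rint(-200L, 200L)
        s <- max(t$start + js, p$terr$lo); e <- min(t$end + je, p$terr$hi)
        # must stay a valid interval and keep >=1 bp of the anchor exon
        if (s <= e && s <= ge$end && e >= ge$start) break
        s <- t$start; e <- t$end
      }
      addev("QUERY", sprintf("Q%03d", qn), t$chrom, s, e, t$svtype,
            t$gene, "tp")
    }
    dir_targets <- sample(truth_ids, n_fp_direction)
    for (id in dir_targets) {
      qn <- qn + 1L
      t <- ev[ev$id == id, ]
      other <- if (t$svtype == "DEL") "DUP" else "DEL"
      addev("QUERY", sprintf("Q%03d", qn), t$chrom, t$start, t$end,
            other, t$gene, "fp_direction")
    }
    for (gene in fp_exon_genes) {
      qn <- qn + 1L
      L <- rint(600L, 8000L)
      p <- plant_on_gene(gene, L)
      addev("QUERY", sprintf("Q%03d", qn), p$chrom, p$start, p$end,
            sample(c("DEL", "DUP"), 1L), gene, "fp_exon")
    }
    # ignored calls: in the dead space between territories
    free <- list()
    for (cg in names(contig_lengths)) {
      tt <- terr[terr$chrom == cg, ]
      tt <- tt[order(tt$lo), ]
      bounds <- c(1L, as.vector(rbind(tt$lo - 1L, tt$hi + 1L)),
                  contig_lengths[[cg]])
      for (k in seq(1L, length(bounds) - 1L, by = 2L)) {
        lo <- bounds[k]; hi <- bounds[k + 1L]
        if (hi - lo > 45e3)  # keep well away from padded exons
          free[[length(free) + 1L]] <- list(chrom = cg, lo = lo + 2000L,
                                            hi = hi - 2000L)
      }
    }
    stopifnot(length(free) >= 1L)
    for (j in seq_len(n_ignored)) {
      qn <- qn + 1L
      f <- free[[rint(1L, length(free))]]
      L <- rint(1000L, 20e3)
      s <- rint(f$lo, f$hi - L)
      addev("QUERY", sprintf("Q%03d", qn), f$chrom, s, s + L - 1L,
            sample(c("DEL", "DUP"), 1L), NA_character_, "ignored")
    }

    ev <- gen_classify(ev, exdf, pad)
    planted_expect <- c(truth = "", tp = "TP", fp_direction = "FP",
                        fp_exon = "FP", ignored = "IGNORED")
    qe <- ev[ev$side == "QUERY", ]
    stopifnot(all(qe$status == planted_expect[qe$planted]))
    te <- ev[ev$side == "TRUTH", ]
    stopifnot(all(te$status[te$id %in% detected] == "DETECTED"),
              all(te$status[!(te$id %in% detected)] %in%
                    c("FN", "DETECTED")))
    # a direction-mismatch FP never rescues a truth event, and every
    # truth overlaps its anchor exon, so undetected truths must be FN
    stopifnot(all(te$status[!(te$id %in% detected)] == "FN"))

    expected_metrics <- gen_expected_metrics(ev, length_bins, exon_bins)
    expected_counts <- list(
      tp_query = sum(qe$status == "TP"), fp = sum(qe$status == "FP"),
      ignored = sum(qe$status == "IGNORED"),
      tp_truth = sum(te$status == "DETECTED"),
      fn = sum(te$status == "FN"),
      truth_excluded = sum(te$status == "EXCLUDED"))

    sl <- as.integer(contig_lengths)
    names(sl) <- names(contig_lengths)
    mkev <- function(d, origin)
      cnv_events(d$chrom, d$start, d$end, d$svtype, id = d$id,
                 origin = origin)
    truth <- mkev(ev[ev$side == "TRUTH", ], "TRUTH")
    queries <- mkev(ev[ev$side == "QUERY", ], "QUERY")
    structure(list(genes = genes, truth = truth, queries = queries,
                   contig_lengths = sl, pad = pad, events = ev,
                   expected_metrics = expected_metrics,
                   expected_counts = expected_counts,
                   length_bins = length_bins, exon_bins = exon_bins),
              class = "cnv_benchmark_case")
  })
}

#' Simulate a multi-sample cohort with planted recurrent artifacts
#'
#' Each planted artifact appears (jittered by at most 1% of its length,
#' so all pairwise reciprocal overlaps stay above 0.95) in a chosen
#' number of samples; every sample additionally carries private calls.
#' Artifact sites are spaced at least 200 kb apart so clusters cannot
#' merge.
#'
#' @param seed integer seed.
#' @param n_samples number of samples.
#' @param artifact_recurrence integer vector: number of samples carrying
#'   each planted artifact.
#' @param n_private private (non-recurrent) calls per sample.
#' @param contig_lengths named contig lengths.
#' @return list with `callsets` (named list of event sets) and
#'   `artifacts` (data.frame `artifact`, `chrom`, `start`, `end`,
#'   `svtype`, `recurrence`, `samples`).
#' @export
simulate_artifact_cohort <- function(seed = 1L, n_samples = 5L,
                                     artifact_recurrence = c(5L, 4L, 3L, 1L),
                                     n_private = 3L,
                                     contig_lengths = c(ctg1 = 5e6,
                                                        ctg2 = 5e6)) {
  stopifnot(all(artifact_recurrence <= n_samples))
  with_seed(seed, {
    samples <- sprintf("S%02d", seq_len(n_samples))
    n_art <- length(artifact_recurrence)
    # one 200 kb slot per artifact and per private call, nothing adjacent
    total_slots <- n_art + n_samples * n_private
    slot <- 0L
    slot_pos <- function(k) {
      cg <- names(contig_lengths)[(k - 1L) %% length(contig_lengths) + 1L]
      idx <- (k - 1L) %/% length(contig_lengths)
      list(chrom = cg, base = 100e3 + idx * 200e3)
    }
    stopifnot(200e3 * ceiling(total_slots / length(contig_lengths)) +
                200e3 < min(contig_lengths))
    arts <- data.frame(artifact = sprintf("A%02d", seq_len(n_art)),
                       chrom = "", start = 0L, end = 0L, svtype = "",
                       recurrence = as.integer(artifact_recurrence),
                       samples = "", stringsAsFactors = FALSE)
    calls <- lapply(samples, function(s) NULL)
    names(calls) <- samples
    add_call <- function(sample, chrom, s, e, svtype, id) {
      d <- data.frame(chrom = chrom, start = s, end = e, svtype = svtype,
                      id = id, stringsAsFactors = FALSE)
      calls[[sample]] <<- rbind(calls[[sample]], d)
    }
    for (a in seq_len(n_art)) {
      slot <- slot + 1L
      sp <- slot_pos(slot)
      L <- rint(5000L, 50e3)
      s0 <- sp$base + rint(0L, 1000L)
      svtype <- sample(c("DEL", "DUP"), 1L)
      members <- sample(samples, artifact_recurrence[a])
      arts$chrom[a] <- sp$chrom; arts$start[a] <- s0
      arts$end[a] <- s0 + L - 1L; arts$svtype[a] <- svtype
      arts$samples[a] <- paste(sort(members), collapse = ",")
      j <- max(1L, L %/% 100L)
      for (m in members)
        add_call(m, sp$chrom, s0 + rint(-j, j), s0 + L - 1L + rint(-j, j),
                 svtype, sprintf("%s_%s", arts$artifact[a], m))
    }
    for (s in samples) {
      for (p in seq_len(n_private)) {
        slot <- slot + 1L
        sp <- slot_pos(slot)
        L <- rint(2000L, 20e3)
        st <- sp$base + rint(0L, 1000L)
        add_call(s, sp$chrom, st, st + L - 1L,
                 sample(c("DEL", "DUP"), 1L), sprintf("P_%s_%d", s, p))
      }
    }
    callsets <- lapply(calls, function(d)
      cnv_events(d$chrom, d$start, d$end, d$svtype, id = d$id,
                 origin = "QUERY"))
    list(callsets = callsets, artifacts = arts)
  })
}

#' Simulate a call set with known filter verdicts
#'
#' Plants calls that exercise every filtering rule at its boundary:
#' lengths just inside and outside the size window, junction-only versus
#' depth-supported calls above the junction limit, gap-track overlaps,
#' and calls at exact reciprocal overlaps of 0.92 and 0.89 with a
#' same-type artifact region. The expected verdict of every call is
#' recorded at generation time.
#'
#' @param seed integer seed.
#' @return list with `calls`, `config` (a [filter_config()]) and
#'   `expected` (data.frame `id`, `kept`, `failed_rules`).
#' @export
simulate_filter_case <- function(seed = 1L) {
  with_seed(seed, {
    gap <- genomic_intervals("ctg2", 3e6, 3.1e6)
    art <- genomic_intervals("ctg2", c(6e6, 6.5e6),
                             c(6e6 + 919L, 6.5e6 + 889L))
    art$svtype <- c("DEL", "DEL")
    # ctg1 carries the size/junction boundary calls (no gaps or
    # artifacts there); ctg2 carries the gap- and artifact-rule calls
    rows <- list(
      list("too_small", "ctg1", 1e5, 499L, "DEL", "UNKNOWN", FALSE,
           "SIZE_MIN"),
      list("at_min", "ctg1", 2e5, 500L, "DEL", "UNKNOWN", TRUE, ""),
      list("at_max", "ctg1", 5e5, 10e6, "DUP", "DEPTH", TRUE, ""),
      list("too_big", "ctg1", 11e6, 10e6 + 1L, "DUP", "DEPTH", FALSE,
           "SIZE_MAX"),
      list("junction_long", "ctg1", 22e6, 2e6, "DUP", "JUNCTION", FALSE,
           "JUNCTION_LONG"),
      list("depth_long", "ctg1", 25e6, 2e6, "DUP", "DEPTH", TRUE, ""),
      list("unknown_long", "ctg1", 28e6, 2e6, "DUP", "UNKNOWN", TRUE, ""),
      list("in_gap", "ctg2", 3.05e6, 5000L, "DEL", "UNKNOWN", FALSE,
           "GAP_OVERLAP"),
      list("near_gap", "ctg2", 3.2e6, 5000L, "DEL", "UNKNOWN", TRUE, ""),
      # artifact 1 is 920 bp; a 1000 bp call containing it has RO 0.92
      list("artifact_hit", "ctg2", 6e6 - 40L, 1000L, "DEL", "UNKNOWN",
           FALSE, "RECURRENT_ARTIFACT"),
      # artifact 2 is 890 bp; the matching 1000 bp call has RO 0.89
      list("artifact_miss", "ctg2", 6.5e6 - 55L, 1000L, "DEL", "UNKNOWN",
           TRUE, ""),
      # same span as artifact 1 but opposite dosage type
      list("artifact_wrong_type", "ctg2", 6e6 - 40L, 1000L, "DUP",
           "UNKNOWN", TRUE, ""),
      list("clean", "ctg1", 6e5, 2000L, "DEL", "DEPTH", TRUE, ""))
    d <- do.call(rbind, lapply(rows, function(r)
      data.frame(id = r[[1]], chrom = r[[2]], start = as.integer(r[[3]]),
                 len = as.integer(r[[4]]), svtype = r[[5]],
                 claim = r[[6]], kept = r[[7]], failed = r[[8]],
                 stringsAsFactors = FALSE)))
    calls <- cnv_events(d$chrom, d$start, d$start + d$len - 1L, d$svtype,
                        id = d$id, claim = d$claim)
    config <- filter_config(gap_regions = gap, artifact_regions = art,
                            artifact_mode = "reciprocal")
    list(calls = calls, config = config,
         expected = data.frame(id = d$id, kept = d$kept,
                               failed_rules = d$failed,
                               stringsAsFactors = FALSE))
  })
}

#' Write a benchmark case to disk
#'
#' Emits the fixture as standard interchange files: truth and query VCF,
#' gene models as BED12, and the generator's expectations as JSON.
#'
#' @param case a `cnv_benchmark_case`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_benchmark_case <- function(case, dir) {
  stopifnot(inherits(case, "cnv_benchmark_case"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(truth = file.path(dir, "truth.vcf"),
             query = file.path(dir, "query.vcf"),
             genes = file.path(dir, "genes.bed"),
             expectations = file.path(dir, "expectations.json"))
  write_sv_vcf(case$truth, paths["truth"],
               contig_lengths = case$contig_lengths)
  write_sv_vcf(case$queries, paths["query"],
               contig_lengths = case$contig_lengths)
  write_gene_models_bed12(case$genes, paths["genes"])
  jsonlite::write_json(
    list(pad = case$pad, expected_counts = case$expected_counts,
         expected_metrics = case$expected_metrics,
         events = case$events),
    paths["expectations"], dataframe = "rows", na = "null",
    auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
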