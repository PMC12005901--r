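# Independent oracles used across the suite. These deliberately avoid the
# package's interval machinery: everything is plain integer arithmetic on
# data.frames, so agreement with the package is a genuine cross-check.

# data.frame representation of an event set / exon set
df_events <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = IRanges::start(gr), end = IRanges::end(gr),
             svtype = gr$svtype, id = gr$id, stringsAsFactors = FALSE)
}

df_exons <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = IRanges::start(gr), end = IRanges::end(gr),
             stringsAsFactors = FALSE)
}

# brute-force classification over all (query, truth, exon) triples
oracle_classify <- function(q, t, ex) {
  hits <- function(ev)
    lapply(seq_len(nrow(ev)), function(i)
      which(ex$chrom == ev$chrom[i] & ex$start <= ev$end[i] &
              ex$end >= ev$start[i]))
  qh <- hits(q)
  th <- hits(t)
  qs <- character(nrow(q))
  for (i in seq_len(nrow(q))) {
    if (length(qh[[i]]) == 0L) { qs[i] <- "IGNORED"; next }
    tp <- FALSE
    for (j in seq_len(nrow(t))) {
      if (t$svtype[j] != q$svtype[i]) next
      for (e in th[[j]]) if (e %in% qh[[i]]) tp <- TRUE
    }
    qs[i] <- if (tp) "TP" else "FP"
  }
  ts <- character(nrow(t))
  for (j in seq_len(nrow(t))) {
    if (length(th[[j]]) == 0L) { ts[j] <- "EXCLUDED"; next }
    det <- FALSE
    for (i in seq_len(nrow(q))) {
      if (q$svtype[i] != t$svtype[j]) next
      for (e in qh[[i]]) if (e %in% th[[j]]) det <- TRUE
    }
    ts[j] <- if (det) "DETECTED" else "FN"
  }
  list(query_status = qs, truth_status = ts,
       q_n_exons = lengths(qh), t_n_exons = lengths(th))
}

# exhaustive (flank x offset) identity grid using plain substring ops
oracle_best_identity <- function(pos, seq, ref_chr, slop = 2L) {
  L <- nchar(seq)
  clen <- nchar(ref_chr)
  best <- -1
  sc <- strsplit(seq, "")[[1]]
  for (flank in c("LEFT", "RIGHT")) {
    for (off in -slop:slop) {
      s1 <- if (flank == "RIGHT") pos + 1L + off else pos + off - L + 1L
      e1 <- s1 + L - 1L
      if (s1 < 1L || e1 > clen) next
      rc <- strsplit(substr(ref_chr, s1, e1), "")[[1]]
      idn <- sum(sc == rc & sc != "N") / L
      if (idn > best) best <- idn
    }
  }
  best
}

# connected components under pairwise reciprocal overlap >= threshold,
# via exhaustive O(n^2) enumeration + igraph
oracle_clusters <- function(d, threshold) {
  n <- nrow(d)
  edges <- integer(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (d$chrom[i] != d$chrom[j] || d$svtype[i] != d$svtype[j]) next
      ov <- min(d$end[i], d$end[j]) - max(d$start[i], d$start[j]) + 1L
      if (ov <= 0L) next
      ro <- min(ov / (d$end[i] - d$start[i] + 1L),
                ov / (d$end[j] - d$start[j] + 1L))
      if (ro >= threshold) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

# random small classification instance (events + exon models)
random_instance <- function(seed) {
  set.seed(seed)
  n_ex <- sample(20:200, 1)
  n_q <- sample(5:50, 1)
  n_t <- sample(5:50, 1)
  contigs <- c("cA", "cB")
  mk_ex <- function(n) {
    s <- sample.int(90e3, n, replace = TRUE)
    data.frame(chrom = sample(contigs, n, replace = TRUE), start = s,
               end = s + sample.int(400, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  mk_ev <- function(n, prefix) {
    s <- sample.int(90e3, n, replace = TRUE)
    data.frame(chrom = sample(contigs, n, replace = TRUE), start = s,
               end = s + sample.int(8000, n, replace = TRUE),
               svtype = sample(c("DEL", "DUP"), n, replace = TRUE),
               id = sprintf("%s%03d", prefix, seq_len(n)),
               stringsAsFactors = FALSE)
  }
  list(exons = mk_ex(n_ex), q = mk_ev(n_q, "q"), t = mk_ev(n_t, "t"))
}

gr_from_df <- function(d, origin) {
  cnv_events(d$chrom, d$start, d$end, d$svtype, id = d$id, origin = origin)
}

exons_from_df <- function(d) {
  gene_models(genomic_intervals(d$chrom, d$start, d$end),
              sprintf("X%04d", seq_len(nrow(d))))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

mutate_bases <- function(x, k) {
  ch <- strsplit(x, "")[[1]]
  for (i in seq_len(k)) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  paste(ch, collapse = "")
}
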