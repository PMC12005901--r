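#' Construct a gene-model exon set
#'
#' Gene models are represented as a `GRanges` of coding exons with
#' metadata columns `gene` (transcript/gene name), `exon_rank` (ordinal in
#' ascending coordinate order), `synthetic` (planted model?) and
#' `template` (source template of a synthetic model, else `NA`). Exons of
#' one gene must be non-overlapping and sorted; overlapping exons are
#' merged with a warning.
#'
#' @param exons `GRanges` of exons (strand used as given).
#' @param gene character vector of gene names along `exons`.
#' @param synthetic logical, recycled.
#' @param template character, recycled.
#' @return exon `GRanges` sorted by gene then coordinate.
#' @export
gene_models <- function(exons, gene, synthetic = FALSE, template = NA_character_) {
  stopifnot(is(exons, "GRanges"), length(gene) == length(exons))
  if (length(exons) == 0L) {
    mcols(exons) <- DataFrame(gene = character(0), exon_rank = integer(0),
                              synthetic = logical(0),
                              template = character(0))
    return(exons)
  }
  gene <- as.character(gene)
  synthetic <- rep_len(synthetic, length(exons))
  template <- rep_len(as.character(template), length(exons))
  o <- order(gene, start(exons))
  exons <- exons[o]
  gene <- gene[o]; synthetic <- synthetic[o]; template <- template[o]
  chrom <- as.character(seqnames(exons))
  same_gene <- gene[-1L] == gene[-length(gene)]
  if (any(same_gene & chrom[-1L] != chrom[-length(chrom)]))
    stop("exons of one gene span multiple contigs")
  clash <- same_gene & start(exons)[-1L] <= end(exons)[-length(exons)]
  if (any(clash)) {
    # merge overlapping exons, gene by gene, for the affected genes only
    warning("overlapping exons merged within gene(s) ",
            paste(unique(gene[-1L][clash]), collapse = ", "))
    keep <- !(gene %in% unique(gene[-1L][clash]))
    fixed <- lapply(unique(gene[-1L][clash]), function(gn) {
      idx <- which(gene == gn)
      red <- reduce(ranges(exons[idx]))
      g2 <- GRanges(chrom[idx][1L], red, strand = strand(exons)[idx][1L])
      mcols(g2) <- DataFrame(gene = gn, synthetic = synthetic[idx][1L],
                             template = template[idx][1L])
      g2
    })
    base <- exons[keep]
    mcols(base) <- DataFrame(gene = gene[keep],
                             synthetic = synthetic[keep],
                             template = template[keep])
    res <- c(base, unlist(GRangesList(fixed), use.names = FALSE))
    res <- res[order(res$gene, start(res))]
    rl <- rle(res$gene)
  } else {
    res <- exons
    mcols(res) <- DataFrame(gene = gene, synthetic = synthetic,
                            template = template)
    rl <- rle(gene)
  }
  res$exon_rank <- unlist(lapply(rl$lengths, seq_len), use.names = FALSE)
  mcols(res) <- mcols(res)[, c("gene", "exon_rank", "synthetic", "template")]
  res
}

#' Read gene models from BED12 or GFF3
#'
#' BED12 blocks are taken as coding exons (one feature per transcript);
#' GFF3 `CDS` features are grouped into one model per transcript via
#' their `Parent` attribute. Canonical-transcript selection is up to the
#' input file. Records that violate the model invariants (no exons,
#' blocks outside the feature bounds) are rejected with a reason,
#' available in `attr(result, "rejected")`.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"bed12"` or `"gff3"`.
#' @return exon `GRanges` as in [gene_models()], with a `rejected`
#'   attribute (data.frame `gene`, `reason`).
#' @export
read_gene_models <- function(path, format = c("auto", "bed12", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed12"
  }
  rejected <- data.frame(gene = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (format == "bed12") {
    feats <- rtracklayer::import(path, format = "BED")
    if (is.null(feats$blocks))
      stop("BED input has no block structure; expected BED12")
    keep <- rep(TRUE, length(feats))
    for (i in seq_along(feats)) {
      bl <- feats$blocks[[i]]
      if (length(bl) == 0L) {
        keep[i] <- FALSE
        rejected[nrow(rejected) + 1L, ] <-
          list(feats$name[i], "transcript with zero exons")
      } else if (max(end(bl)) > width(feats)[i] || min(start(bl)) < 1L) {
        keep[i] <- FALSE
        rejected[nrow(rejected) + 1L, ] <-
          list(feats$name[i], "exon blocks outside feature bounds")
      }
    }
    feats <- feats[keep]
    if (length(feats)) {
      nblocks <- lengths(feats$blocks)
      abs_exons <- GRanges(
        rep(seqnames(feats), nblocks),
        IRanges::shift(unlist(feats$blocks, use.names = FALSE),
                       rep(start(feats) - 1L, nblocks)),
        strand = rep(strand(feats), nblocks))
      genes <- rep(feats$name, nblocks)
    } else {
      abs_exons <- GRanges(); genes <- character(0)
    }
    out <- gene_models(abs_exons, genes)
  } else {
    gff <- rtracklayer::import(path, format = "GFF3")
    cds <- gff[gff$type == "CDS"]
    if (length(cds) == 0L) stop("GFF3 input has no CDS features")
    parent <- vapply(as.list(cds$Parent), function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
    if (anyNA(parent)) {
      rejected <- rbind(rejected, data.frame(
        gene = NA_character_, reason = "CDS feature without Parent",
        stringsAsFactors = FALSE))
      cds <- cds[!is.na(parent)]
      parent <- parent[!is.na(parent)]
    }
    out <- gene_models(granges(cds), parent)
  }
  attr(out, "rejected") <- rejected
  out
}

#' Write gene models as BED12
#'
#' One feature per gene whose blocks are the exons; the feature span runs
#' from the first to the last exon.
#'
#' @param genes exon `GRanges` from [gene_models()].
#' @param path output path.
#' @export
write_gene_models_bed12 <- function(genes, path) {
  parts <- split(seq_along(genes), genes$gene)
  # preserve first-appearance order of genes
  parts <- parts[unique(genes$gene)]
  feats <- lapply(parts, function(idx) {
    g <- genes[idx]
    span <- range(ranges(g))
    out <- GRanges(seqnames(g)[1], span, strand = strand(g)[1])
    out$name <- g$gene[1]
    out$score <- 0L
    out$blocks <- IRangesList(IRanges::shift(ranges(g), 1L - start(span)))
    out
  })
  feats <- unlist(GRangesList(feats), use.names = FALSE)
  feats <- sort(feats, ignore.strand = TRUE)
  rtracklayer::export(feats, path, format = "BED")
  invisible(path)
}

#' Gene spans of an exon set
#'
#' The full span of each gene (first exon start to last exon end), used
#' for real-gene avoidance during synthetic spiking.
#'
#' @param genes exon `GRanges`.
#' @return `GRanges` with a `gene` column, one range per gene.
#' @export
gene_spans <- function(genes) {
  if (length(genes) == 0L) {
    g <- GRanges(); g$gene <- character(0); return(g)
  }
  parts <- split(seq_along(genes), genes$gene)
  parts <- parts[unique(genes$gene)]
  spans <- lapply(parts, function(idx) {
    g <- genes[idx]
    out <- GRanges(seqnames(g)[1], range(ranges(g)), strand = strand(g)[1])
    out$gene <- g$gene[1]
    out
  })
  unlist(GRangesList(spans), use.names = FALSE)
}

#' Splice-padded coding exons
#'
#' Extends every coding exon by `pad` bases of flanking intron on both
#' sides so that calls clipping a splice junction still register. Padded
#' exons of one gene may touch or overlap each other; they remain
#' distinct match units. Padding is clipped at the contig start and, when
#' `seqlengths` are known, at the contig end.
#'
#' @param genes exon `GRanges` from [gene_models()].
#' @param pad bases of intronic padding per side (default 15).
#' @return `GRanges` of padded exons carrying `gene`, `exon_rank`,
#'   `synthetic`, `template`.
#' @examples
#' g <- gene_models(genomic_intervals("c", 1001, 1100), "G1")
#' IRanges::ranges(padded_exons(g))  # 986-1115
#' @export
padded_exons <- function(genes, pad = 15L) {
  pad <- as.integer(pad)
  stopifnot(pad >= 0L)
  out <- genes
  new_start <- pmax(start(genes) - pad, 1L)
  new_end <- end(genes) + pad
  sl <- seqlengths(genes)[as.character(seqnames(genes))]
  has_len <- !is.na(sl)
  new_end[has_len] <- pmin(new_end[has_len], sl[has_len])
  ranges(out) <- IRanges(new_start, new_end)
  out
}
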