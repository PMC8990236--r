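#' Write gene models to GFF3
#'
#' Emits one `gene`, one `mRNA`, per-exon `exon` and per-coding-segment
#' `CDS` features per gene model. Internal coordinates are 1-based
#' inclusive, which is also the GFF3 convention, so no shifting occurs.
#'
#' @param genes A list of [gene_model()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  stopifnot(length(genes) > 0L, all(vapply(genes, inherits, TRUE, "gene_model")))
  rows <- lapply(genes, function(g) {
    n <- nrow(g$exons)
    lo <- pmax(g$exons[, "start"], g$cds_start)
    hi <- pmin(g$exons[, "stop"], g$cds_end)
    keep <- lo <= hi
    span <- gene_span(g)
    mrna_id <- paste0(g$gene_id, ".t1")
    # CDS phase in transcription order
    seg_len <- (hi - lo + 1)[keep]
    if (g$strand == "-") seg_len <- rev(seg_len)
    ph <- (3 - cumsum(c(0, head(seg_len, -1L))) %% 3) %% 3
    if (g$strand == "-") ph <- rev(ph)
    data.table(
      chrom = g$chrom,
      start = c(span[1L], span[1L], g$exons[, "start"], lo[keep]),
      end   = c(span[2L], span[2L], g$exons[, "stop"], hi[keep]),
      strand = g$strand,
      type = c("gene", "mRNA", rep("exon", n), rep("CDS", sum(keep))),
      phase = c(rep(NA_integer_, 2L + n), as.integer(ph)),
      ID = c(g$gene_id, mrna_id,
             paste0(mrna_id, ".exon", seq_len(n)),
             paste0(mrna_id, ".cds", seq_len(sum(keep)))),
      Parent = c(NA_character_, g$gene_id,
                 rep(mrna_id, n), rep(mrna_id, sum(keep))))
  })
  tab <- rbindlist(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand)
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$phase <- tab$phase
  S4Vectors::mcols(gr)$ID <- tab$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(tab$Parent), "", tab$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects the feature layout written by [write_gff3()] (the standard
#' gene/mRNA/exon/CDS hierarchy); one transcript per gene.
#'
#' @param path GFF3 file path.
#' @return Named list of [gene_model()] objects.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  parent <- as.character(md$Parent)
  type <- as.character(md$type)
  mrna <- which(type == "mRNA")
  out <- list()
  for (i in mrna) {
    gid <- parent[i]
    tid <- as.character(md$ID[i])
    ex <- which(type == "exon" & parent == tid)
    cds <- which(type == "CDS" & parent == tid)
    exons <- cbind(start = GenomicRanges::start(gr)[ex],
                   stop = GenomicRanges::end(gr)[ex])
    exons <- exons[order(exons[, "start"]), , drop = FALSE]
    out[[gid]] <- gene_model(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      exons = exons,
      cds_start = min(GenomicRanges::start(gr)[cds]),
      cds_end = max(GenomicRanges::end(gr)[cds]))
  }
  out
}

#' Long-read isoform exon chain
#'
#' Container for one observed or reference isoform: an exon chain on one
#' strand. Junction (intron) coordinates are derived, not stored; see
#' [intron_chain()].
#'
#' @param isoform_id Isoform identifier.
#' @param gene_id Gene the chain is assigned to (may be `NA` for
#'   unassigned long reads).
#' @param chrom,strand Location.
#' @param exons Two-column matrix of sorted, non-overlapping exon
#'   `start`,`stop` (1-based inclusive) with gaps of at least 1 bp.
#' @param source `"reference"` or `"long_read"`.
#' @param tissues Character vector of tissues the chain was observed in.
#' @return An object of class `isoform_chain`.
#' @export
isoform_chain <- function(isoform_id, gene_id, chrom, strand, exons,
                          source = c("long_read", "reference"),
                          tissues = character()) {
  source <- match.arg(source)
  exons <- as.matrix(exons)
  storage.mode(exons) <- "double"
  colnames(exons) <- c("start", "stop")
  if (any(exons[, "start"] > exons[, "stop"]))
    stop("exon start > stop in isoform ", isoform_id)
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] <= exons[-nrow(exons), "stop"] + 1))
    stop("exons must be sorted with gaps >= 1 bp in isoform ", isoform_id)
  structure(
    list(isoform_id = as.character(isoform_id),
         gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = strand, exons = exons, source = source, tissues = tissues),
    class = "isoform_chain")
}

#' @export
print.isoform_chain <- function(x, ...) {
  cat(sprintf("<isoform_chain> %s (gene %s) %s:%d-%d (%s)  %d exon(s)\n",
              x$isoform_id, x$gene_id, x$chrom,
              x$exons[1L, "start"], x$exons[nrow(x$exons), "stop"],
              x$strand, nrow(x$exons)))
  invisible(x)
}

#' Isoform chain of a gene model's annotated transcript
#'
#' @param gene A [gene_model()].
#' @return An `isoform_chain` with `source = "reference"`.
#' @export
as_isoform_chain <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  isoform_chain(paste0(gene$gene_id, ".ref"), gene$gene_id, gene$chrom,
                gene$strand, gene$exons, source = "reference")
}

#' Write isoform chains to BED12
#'
#' Conversion from the package's 1-based inclusive coordinates to BED's
#' 0-based half-open blocks is delegated to `rtracklayer`.
#'
#' @param chains List of [isoform_chain()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(chains, path) {
  stopifnot(length(chains) > 0L,
            all(vapply(chains, inherits, TRUE, "isoform_chain")))
  grl <- GenomicRanges::GRangesList(lapply(chains, function(ch) {
    GenomicRanges::GRanges(
      seqnames = ch$chrom,
      ranges = IRanges::IRanges(ch$exons[, "start"], ch$exons[, "stop"]),
      strand = ch$strand)
  }))
  names(grl) <- vapply(chains, `[[`, "", "isoform_id")
  rtracklayer::export(grl, path, format = "bed")
  invisible(path)
}

#' Read isoform chains from BED12
#'
#' @param path BED12 file path.
#' @param source Passed to [isoform_chain()]; default `"long_read"`.
#' @return List of [isoform_chain()] objects; `gene_id` is `NA` (BED12
#'   carries no gene assignment).
#' @export
read_bed12 <- function(path, source = "long_read") {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- S4Vectors::mcols(gr)$blocks
  lapply(seq_along(gr), function(i) {
    if (!is.null(blocks) && length(blocks[[i]]) > 0L) {
      rel <- blocks[[i]]
      abs_start <- GenomicRanges::start(gr)[i] + IRanges::start(rel) - 1L
      abs_stop <- GenomicRanges::start(gr)[i] + IRanges::end(rel) - 1L
    } else {
      abs_start <- GenomicRanges::start(gr)[i]
      abs_stop <- GenomicRanges::end(gr)[i]
    }
    isoform_chain(
      isoform_id = S4Vectors::mcols(gr)$name[i],
      gene_id = NA_character_,
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      exons = cbind(start = abs_start, stop = abs_stop),
      source = source)
  })
}
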