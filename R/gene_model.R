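#' Strand-aware gene model
#'
#' A `gene_model` is the coordinate frame for every downstream computation:
#' an ordered exon chain with the coding-sequence (CDS) boundaries on a
#' named chromosome and strand. Coordinates are 1-based inclusive
#' throughout the package; BED12 conversion happens only at the file
#' boundary (see [write_bed12()]).
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of exon `start`, `stop`
#'   (1-based inclusive), sorted by genomic coordinate, pairwise
#'   non-overlapping.
#' @param cds_start,cds_end Genomic coordinates of the coding span
#'   (`cds_start <= cds_end` regardless of strand). The span must lie
#'   within the transcript span.
#'
#' @return An object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `exons` (matrix), `cds_start`, `cds_end` and
#'   `five_prime_pos`, the 5'-most coding base in transcription direction
#'   (`cds_start` on `+`, `cds_end` on `-`).
#' @export
#' @examples
#' g <- gene_model("g1", "chr1", "+", rbind(c(100, 250), c(400, 600)),
#'                 cds_start = 150, cds_end = 550)
#' g$five_prime_pos
gene_model <- function(gene_id, chrom, strand, exons, cds_start, cds_end) {
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stop("`exons` must have two columns (start, stop)")
  storage.mode(exons) <- "double"
  colnames(exons) <- c("start", "stop")
  if (!strand %in% c("+", "-")) stop("`strand` must be '+' or '-'")
  if (any(exons[, "start"] > exons[, "stop"]))
    stop("exon start > stop in gene ", gene_id)
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, "start"], strictly = TRUE))
      stop("exons must be sorted by genomic coordinate in gene ", gene_id)
    if (any(exons[-1L, "start"] <= exons[-nrow(exons), "stop"]))
      stop("exons overlap in gene ", gene_id)
  }
  if (cds_start > cds_end) stop("cds_start > cds_end in gene ", gene_id)
  span <- c(exons[1L, "start"], exons[nrow(exons), "stop"])
  if (cds_start < span[1L] || cds_end > span[2L])
    stop("CDS span outside exon span in gene ", gene_id)
  structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = strand, exons = exons,
         cds_start = as.numeric(cds_start), cds_end = as.numeric(cds_end),
         five_prime_pos = if (strand == "+") as.numeric(cds_start)
                          else as.numeric(cds_end)),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d exon(s)  CDS %d-%d\n",
              x$gene_id, x$chrom, gene_span(x)[1L], gene_span(x)[2L],
              x$strand, nrow(x$exons), x$cds_start, x$cds_end))
  invisible(x)
}

#' Genomic span of a gene model
#'
#' @param gene A [gene_model()].
#' @return Numeric `c(start, stop)`, 1-based inclusive.
#' @export
gene_span <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  unname(c(gene$exons[1L, "start"], gene$exons[nrow(gene$exons), "stop"]))
}

#' Transcript 5' end (annotated TSS-side boundary) of a gene model
#'
#' The first transcribed base in transcription direction: the left edge of
#' the first exon on `+`, the right edge of the last exon on `-`.
#'
#' @param gene A [gene_model()].
#' @return Genomic position (bp).
#' @export
transcript_start <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  unname(if (gene$strand == "+") gene$exons[1L, "start"]
         else gene$exons[nrow(gene$exons), "stop"])
}

#' CDS length of a gene model in bp (exonic bases within the CDS span)
#'
#' @param gene A [gene_model()].
#' @return Length in bp.
#' @export
cds_length <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  lo <- pmax(gene$exons[, "start"], gene$cds_start)
  hi <- pmin(gene$exons[, "stop"], gene$cds_end)
  sum(pmax(hi - lo + 1, 0))
}
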