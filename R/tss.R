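#' CAGE tag-cluster peak
#'
#' A strand-aware cluster of CAGE 5'-tag positions. Boundary orientation
#' follows the reporting convention of [call_peaks()]: `stop` is the
#' boundary farther in the upstream (5'-ward, strand-aware) direction from
#' the gene's 5' coding position, `start` the other — so `stop` may be
#' numerically below `start` on either strand.
#'
#' @param chrom,strand Location.
#' @param start,stop Cluster boundaries (bp, 1-based), oriented as above.
#' @param mode_pos Position of maximum tag count; must lie between the
#'   boundaries (inclusive).
#' @param tag_count Total tags in the cluster, > 0.
#' @return An object of class `cage_peak`.
#' @export
#' @examples
#' cage_peak("chrX", "-", start = 84958298, stop = 84958477,
#'           mode_pos = 84958400, tag_count = 120)
cage_peak <- function(chrom, strand, start, stop, mode_pos = NULL,
                      tag_count = 1) {
  if (tag_count <= 0) stop("tag_count must be > 0")
  if (is.null(mode_pos)) mode_pos <- round((start + stop) / 2)
  if (mode_pos < min(start, stop) || mode_pos > max(start, stop))
    stop("mode_pos must lie between the peak boundaries")
  structure(
    list(chrom = as.character(chrom), strand = strand,
         start = as.numeric(start), stop = as.numeric(stop),
         mode_pos = as.numeric(mode_pos), tag_count = as.numeric(tag_count)),
    class = "cage_peak")
}

#' @export
print.cage_peak <- function(x, ...) {
  cat(sprintf("<cage_peak> %s:%s start=%d stop=%d mode=%d tags=%d\n",
              x$chrom, x$strand, x$start, x$stop, x$mode_pos, x$tag_count))
  invisible(x)
}

#' Call CAGE tag-cluster peaks in a gene's promoter window
#'
#' Contiguous runs of positions with at least `threshold` tags on the
#' gene's strand, within `promoter_window` bp of the annotated transcript
#' 5' end, form clusters; the cluster with the largest tag sum is the
#' gene's peak (ties broken by proximity to the gene's 5' coding
#' position). Boundaries are reported with `stop` = the boundary farther
#' upstream (5'-ward in transcription direction) of the gene's
#' `five_prime_pos`, `start` = the other; the mode is the position of the
#' maximum tag count (ties: nearest the 5' coding position).
#'
#' @param coverage data.frame/data.table with columns `chrom`, `pos`,
#'   `strand`, `tag_count` (positions with zero tags may be omitted).
#' @param gene A [gene_model()].
#' @param promoter_window Half-width of the search window around the
#'   annotated transcript 5' end (default 5000 bp).
#' @param threshold Minimum per-position tag count for cluster membership
#'   (default 1).
#' @return The gene's [cage_peak()], or `NULL` when no position passes the
#'   threshold in the window (a "no TSS" gene).
#' @export
call_peaks <- function(coverage, gene, promoter_window = 5000,
                       threshold = 1) {
  stopifnot(inherits(gene, "gene_model"))
  cov <- as.data.table(coverage)
  anchor <- transcript_start(gene)
  cov <- cov[chrom == gene$chrom & strand == gene$strand &
             abs(pos - anchor) <= promoter_window & tag_count >= threshold]
  if (nrow(cov) == 0L) return(NULL)
  setorder(cov, pos)
  cluster <- cumsum(c(1L, diff(cov$pos) > 1))
  sums <- tapply(cov$tag_count, cluster, sum)
  bounds_lo <- tapply(cov$pos, cluster, min)
  bounds_hi <- tapply(cov$pos, cluster, max)
  fp <- gene$five_prime_pos
  # nearest boundary distance to the gene 5' position, for tie-breaking
  dist <- pmin(abs(bounds_lo - fp), abs(bounds_hi - fp))
  best <- order(-sums, dist)[1L]
  in_best <- cluster == as.integer(names(sums)[best])
  cand <- cov[in_best]
  mx <- cand[tag_count == max(tag_count)]
  mode_pos <- mx$pos[order(abs(mx$pos - fp))][1L]
  lo <- bounds_lo[best]; hi <- bounds_hi[best]
  # upstream = lower coords on '+', higher on '-'
  if (gene$strand == "+") {
    start <- hi; stop <- lo
  } else {
    start <- lo; stop <- hi
  }
  cage_peak(gene$chrom, gene$strand, start = start, stop = stop,
            mode_pos = mode_pos, tag_count = sum(cand$tag_count))
}

#' 5' UTR length from a CAGE peak
#'
#' Absolute distance between the gene's 5' coding position (the 5'-most
#' coding base in transcription direction) and the peak's `stop` boundary.
#' The stop-boundary rule is the default because it reproduces published
#' reference values exactly on both strands and both peak orientations; a
#' `"center"` rule (distance to the midpoint of the boundaries) is
#' available for comparison.
#'
#' @param five_prime_pos Gene 5' coding position (bp).
#' @param peak A [cage_peak()], or `NULL` for a no-TSS gene.
#' @param rule `"stop"` (default) or `"center"`.
#' @return UTR length in bp, or `NA_real_` when `peak` is `NULL`.
#' @export
#' @examples
#' utr_length(84957236, cage_peak("chrX", "-", 84958298, 84958477))  # 1241
utr_length <- function(five_prime_pos, peak, rule = c("stop", "center")) {
  rule <- match.arg(rule)
  if (is.null(peak)) return(NA_real_)
  stopifnot(inherits(peak, "cage_peak"))
  ref <- switch(rule, stop = peak$stop, center = (peak$start + peak$stop) / 2)
  abs(ref - five_prime_pos)
}

#' Summarize TSS peaks and 5' UTR lengths across genes
#'
#' One row per gene with its 5' coding position, peak boundaries and UTR
#' length; genes without a peak are listed with `NA` coordinates and
#' excluded from the summary statistics.
#'
#' @param genes List of [gene_model()] objects.
#' @param peaks Named list of [cage_peak()] (or `NULL`) per gene, e.g.
#'   from [call_peaks()]; names must match gene ids.
#' @param rule Passed to [utr_length()].
#' @return List of class `tss_report`: `table` (data.table with columns
#'   `gene`, `five_prime_pos`, `peak_start`, `peak_stop`, `peak_mode`,
#'   `utr_length`),
#'   `no_peak` (character vector of genes without a TSS), and `stats`
#'   (list `min`, `max`, `mean` over genes with peaks, plus the
#'   corresponding `min_gene`/`max_gene`).
#' @export
summarize_tss <- function(genes, peaks, rule = "stop") {
  rows <- lapply(genes, function(g) {
    pk <- peaks[[g$gene_id]]
    data.table(
      gene = g$gene_id, five_prime_pos = g$five_prime_pos,
      peak_start = if (is.null(pk)) NA_real_ else pk$start,
      peak_stop = if (is.null(pk)) NA_real_ else pk$stop,
      peak_mode = if (is.null(pk)) NA_real_ else pk$mode_pos,
      utr_length = utr_length(g$five_prime_pos, pk, rule = rule))
  })
  tab <- rbindlist(rows)
  with_peak <- tab[!is.na(utr_length)]
  if (nrow(with_peak) == 0L) stop("no gene has a CAGE peak")
  stats <- list(
    min = min(with_peak$utr_length), max = max(with_peak$utr_length),
    mean = mean(with_peak$utr_length),
    min_gene = with_peak$gene[which.min(with_peak$utr_length)],
    max_gene = with_peak$gene[which.max(with_peak$utr_length)])
  structure(list(table = tab, no_peak = tab$gene[is.na(tab$utr_length)],
                 stats = stats),
            class = "tss_report")
}

#' @export
print.tss_report <- function(x, ...) {
  print(x$table)
  cat(sprintf("UTR length: min %g bp (%s), max %g bp (%s), mean %.1f bp\n",
              x$stats$min, x$stats$min_gene, x$stats$max, x$stats$max_gene,
              x$stats$mean))
  if (length(x$no_peak))
    cat("No CAGE peak:", paste(x$no_peak, collapse = ", "), "\n")
  invisible(x)
}
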