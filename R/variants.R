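#' Call zygosity from biallelic allele counts
#'
#' A locus is heterozygous when both alleles are observed in at least
#' `min_reads_per_allele` reads; otherwise it is homozygous for the
#' majority allele. Loci with zero total depth — or an exact tie below the
#' heterozygous threshold, where no majority exists — are reported
#' `uncallable`.
#'
#' Allele A is the reference allele by convention, so the homozygous calls
#' are `hom_ref` / `hom_alt`.
#'
#' @param count_a,count_b Non-negative read counts for the two alleles
#'   (vectorized).
#' @param min_reads_per_allele Minimum reads per allele for a heterozygous
#'   call (default 2).
#' @return Character vector in
#'   `{"het", "hom_ref", "hom_alt", "uncallable"}`.
#' @export
#' @examples
#' call_zygosity(5, 3)    # "het"
#' call_zygosity(30, 1)   # "hom_ref"
#' call_zygosity(0, 25)   # "hom_alt"
call_zygosity <- function(count_a, count_b, min_reads_per_allele = 2) {
  if (any(count_a < 0, na.rm = TRUE) || any(count_b < 0, na.rm = TRUE))
    stop("allele counts must be non-negative")
  if (min_reads_per_allele < 1) stop("min_reads_per_allele must be >= 1")
  n <- max(length(count_a), length(count_b))
  count_a <- rep_len(count_a, n)
  count_b <- rep_len(count_b, n)
  out <- rep("uncallable", n)
  het <- count_a >= min_reads_per_allele & count_b >= min_reads_per_allele
  out[het] <- "het"
  maj_a <- !het & count_a > count_b
  maj_b <- !het & count_b > count_a
  out[maj_a] <- "hom_ref"
  out[maj_b] <- "hom_alt"
  out  # !het & tie (incl. zero depth) stays "uncallable"
}

#' Tally homozygous-alternative and heterozygous loci
#'
#' Helper feeding [divergence()]: counts `hom_alt` (Ho) and `het` (He)
#' calls in a called-locus table. Reference-homozygous and uncallable loci
#' do not contribute to either count.
#'
#' @param zygosity Character vector of calls from [call_zygosity()].
#' @return List with integer `ho_count` and `he_count`.
#' @export
tally_zygosity <- function(zygosity) {
  list(ho_count = sum(zygosity == "hom_alt"),
       he_count = sum(zygosity == "het"))
}

#' Haplotype-level genome divergence and homology
#'
#' Divergence between an individual's two haplotypes and the reference
#' genome from genome-wide SNP tallies: each homozygous-alternative locus
#' differs on both haplotypes, each heterozygous locus on one, so
#' `D = (Ho + He/2) / genome_size` and homology is `100 * (1 - D)` percent.
#' Ho and He are counts of loci (not reads); computation is full precision,
#' and reports round homology to 3 decimals.
#'
#' @param ho_count Number of homozygous-alternative SNP loci (Ho).
#' @param he_count Number of heterozygous SNP loci (He).
#' @param genome_size Genome size in bp; default 2.7 Gbp (cattle).
#' @return An object of class `divergence_result`: list with `ho_count`,
#'   `he_count`, `genome_size`, `divergence` (fraction) and `homology_pct`.
#' @export
#' @examples
#' divergence(7762707, 11408849)   # homology 99.501%
divergence <- function(ho_count, he_count, genome_size = 2.7e9) {
  if (genome_size <= 0) stop("genome_size must be > 0")
  if (ho_count < 0 || he_count < 0) stop("SNP counts must be non-negative")
  d <- (ho_count + he_count / 2) / genome_size
  if (d > 1) stop("divergence > 1: SNP counts exceed genome size")
  structure(
    list(ho_count = ho_count, he_count = he_count,
         genome_size = genome_size, divergence = d,
         homology_pct = 100 * (1 - d)),
    class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf(
    "<divergence_result> Ho=%s He=%s genome=%s bp  D=%.6g  homology=%.3f%%\n",
    format(x$ho_count, big.mark = ","), format(x$he_count, big.mark = ","),
    format(x$genome_size, big.mark = ",", scientific = FALSE),
    x$divergence, x$homology_pct))
  invisible(x)
}

#' Classify the genomic context of a SNP relative to one gene model
#'
#' Strand-aware partition of positions into `five_prime_utr`, `cds`,
#' `three_prime_utr`, `intron` and `intergenic`. Exonic positions between
#' the transcript 5' boundary and the CDS start (in transcription
#' direction) are 5' UTR; exonic positions past the CDS end are 3' UTR.
#' When a CAGE peak is supplied, its stop boundary (the TSS-side edge, see
#' [call_peaks()]) replaces the annotated first-exon edge as the 5' UTR
#' outer bound; exonic positions upstream of that TSS are intergenic.
#'
#' @param chrom,pos SNP location (1-based).
#' @param gene A [gene_model()].
#' @param tss Optional [cage_peak()] for the gene; its `stop` bounds the
#'   5' UTR.
#' @return One of `"five_prime_utr"`, `"cds"`, `"three_prime_utr"`,
#'   `"intron"`, `"intergenic"`.
#' @export
classify_snp_region <- function(chrom, pos, gene, tss = NULL) {
  stopifnot(inherits(gene, "gene_model"))
  if (chrom != gene$chrom)
    stop("SNP on ", chrom, " but gene ", gene$gene_id, " on ", gene$chrom)
  span <- gene_span(gene)
  if (pos < span[1L] || pos > span[2L]) return("intergenic")
  exonic <- any(pos >= gene$exons[, "start"] & pos <= gene$exons[, "stop"])
  if (!exonic) return("intron")
  if (pos >= gene$cds_start && pos <= gene$cds_end) return("cds")
  tss_pos <- if (!is.null(tss)) tss$stop else transcript_start(gene)
  if (gene$strand == "+") {
    if (pos < gene$cds_start) {
      if (pos >= tss_pos) "five_prime_utr" else "intergenic"
    } else "three_prime_utr"
  } else {
    if (pos > gene$cds_end) {
      if (pos <= tss_pos) "five_prime_utr" else "intergenic"
    } else "three_prime_utr"
  }
}

#' Call zygosity and genomic context for a table of allele counts
#'
#' Convenience wrapper applying [call_zygosity()] and, per locus, the
#' region label of the gene model (if any) whose span contains it.
#'
#' @param counts data.frame/data.table with columns `chrom`, `pos`,
#'   `count_a`, `count_b`.
#' @param genes List of [gene_model()] objects (may be empty).
#' @param min_reads_per_allele Passed to [call_zygosity()].
#' @return data.table: input columns plus `zygosity` and `region`.
#' @export
snp_table <- function(counts, genes = list(), min_reads_per_allele = 2) {
  dt <- as.data.table(counts)
  dt[, zygosity := call_zygosity(count_a, count_b, min_reads_per_allele)]
  reg <- rep("intergenic", nrow(dt))
  for (g in genes) {
    span <- gene_span(g)
    idx <- which(dt$chrom == g$chrom & dt$pos >= span[1L] & dt$pos <= span[2L])
    for (i in idx) reg[i] <- classify_snp_region(dt$chrom[i], dt$pos[i], g)
  }
  dt[, region := reg]
  dt[]
}
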