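#' Expected allele counts under the equal-ratio (1:1) null
#'
#' At a heterozygous locus with total RNA depth `R`, the naive null expects
#' each allele in half the reads.
#'
#' @param total_depth Total reads `R` at the locus (>= 0).
#' @return Numeric pair `(R/2, R/2)`.
#' @export
#' @examples
#' expected_equal(40)  # 20 20
expected_equal <- function(total_depth) {
  if (total_depth < 0) stop("total_depth must be >= 0")
  c(total_depth / 2, total_depth / 2)
}

#' Expected allele counts under the WGS-ratio null
#'
#' To control for reference (allelic) bias, the expected RNA allele split
#' follows the allele ratio observed in the same animal's whole-genome
#' sequencing: `E_i = R * G_i / sum(G)`.
#'
#' @param total_depth Total RNA reads `R` at the locus.
#' @param wgs_counts Numeric pair `G = (G_a, G_b)` of WGS allele counts.
#' @return Numeric pair summing to `R`.
#' @export
#' @examples
#' expected_wgs(40, c(60, 40))  # 24 16
expected_wgs <- function(total_depth, wgs_counts) {
  if (total_depth < 0) stop("total_depth must be >= 0")
  if (length(wgs_counts) != 2L || any(wgs_counts < 0))
    stop("wgs_counts must be two non-negative counts")
  if (sum(wgs_counts) == 0)
    stop("sum(wgs_counts) is zero: locus untestable under the WGS-ratio null")
  total_depth * wgs_counts / sum(wgs_counts)
}

#' Pearson chi-squared test for one locus (df = 1)
#'
#' `chi2 = sum((O_i - E_i)^2 / E_i)` over the two alleles, no continuity
#' correction; the p-value is the upper tail of the chi-squared
#' distribution with 1 degree of freedom.
#'
#' @param observed Integer pair of observed allele counts `O`.
#' @param expected Numeric pair of expected counts `E`, both > 0.
#' @return List with `chi2` and `p_value`.
#' @export
#' @examples
#' ase_chisq(c(30, 10), c(20, 20))  # chi2 = 10
ase_chisq <- function(observed, expected) {
  if (length(observed) != 2L || length(expected) != 2L)
    stop("observed and expected must be pairs")
  if (any(observed < 0)) stop("observed counts must be >= 0")
  if (any(expected <= 0))
    stop("expected count of zero: locus untestable")
  chi2 <- sum((observed - expected)^2 / expected)
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Two-stage allele-specific-expression screen
#'
#' Stage 1 tests every eligible locus x tissue against the equal-ratio
#' null at `alpha_primary`; stage 2 re-tests stage-1 hits against the
#' WGS-ratio null at `alpha_confirm`, so that apparent ASE explained by
#' allelic bias already visible in the WGS data does not survive. The
#' final call requires significance under both nulls.
#'
#' Only loci heterozygous in the matching animal's WGS data (both alleles
#' in at least `min_reads_per_allele` reads) are eligible; others are
#' skipped with a logged reason, as are loci below `min_depth` RNA reads.
#'
#' @param rna_counts data.frame/data.table with columns `chrom`, `pos`,
#'   `tissue`, `count_a`, `count_b` (optionally `animal`).
#' @param wgs_counts data.frame/data.table with columns `chrom`, `pos`,
#'   `count_a`, `count_b` (optionally `animal`).
#' @param alpha_primary Stage-1 cutoff (default 1e-4).
#' @param alpha_confirm Stage-2 cutoff (default 1e-2).
#' @param min_depth Minimum RNA depth to test (default 10; set 0 to test
#'   every heterozygous locus regardless of depth).
#' @param min_reads_per_allele WGS heterozygosity threshold (default 2).
#' @return data.table, one row per locus x tissue, with observed and
#'   expected pairs, `chi2_equal`/`p_equal`/`sig_1e4`,
#'   `chi2_wgs`/`p_wgs`/`sig_1e2` (stage 2, `NA` where stage 1 did not
#'   fire), `final_call`, `eligible` and `skip_reason`.
#' @export
ase_screen <- function(rna_counts, wgs_counts,
                       alpha_primary = 1e-4, alpha_confirm = 1e-2,
                       min_depth = 10, min_reads_per_allele = 2) {
  rna <- as.data.table(rna_counts)
  wgs <- as.data.table(wgs_counts)
  keys <- intersect(c("animal", "chrom", "pos"), names(rna))
  keys <- intersect(keys, names(wgs))
  if (!all(c("chrom", "pos") %in% keys))
    stop("rna_counts and wgs_counts must share chrom and pos columns")
  wgs_k <- wgs[, c(keys, "count_a", "count_b"), with = FALSE]
  data.table::setnames(wgs_k, c("count_a", "count_b"),
                       c("wgs_count_a", "wgs_count_b"))
  res <- merge(rna, wgs_k, by = keys, all.x = TRUE)

  res[, R := count_a + count_b]
  res[, skip_reason := NA_character_]
  res[is.na(wgs_count_a), skip_reason := "locus absent from WGS table"]
  wz <- call_zygosity(ifelse(is.na(res$wgs_count_a), 0, res$wgs_count_a),
                      ifelse(is.na(res$wgs_count_b), 0, res$wgs_count_b),
                      min_reads_per_allele)
  res[is.na(skip_reason) & wz != "het",
      skip_reason := "not heterozygous in WGS"]
  res[is.na(skip_reason) & R < max(min_depth, 1),
      skip_reason := "RNA depth below min_depth"]
  res[, eligible := is.na(skip_reason)]

  res[, `:=`(exp_equal_a = NA_real_, exp_equal_b = NA_real_,
             chi2_equal = NA_real_, p_equal = NA_real_,
             sig_1e4 = NA, exp_wgs_a = NA_real_, exp_wgs_b = NA_real_,
             chi2_wgs = NA_real_, p_wgs = NA_real_, sig_1e2 = NA,
             final_call = FALSE)]

  el <- which(res$eligible)
  if (length(el)) {
    # stage 1: equal-ratio null, vectorized
    e <- res$R[el] / 2
    chi2 <- (res$count_a[el] - e)^2 / e + (res$count_b[el] - e)^2 / e
    p1 <- pchisq(chi2, df = 1, lower.tail = FALSE)
    res[el, `:=`(exp_equal_a = e, exp_equal_b = e,
                 chi2_equal = chi2, p_equal = p1,
                 sig_1e4 = p1 < alpha_primary)]
    # stage 2: WGS-ratio null on stage-1 hits
    s2 <- el[p1 < alpha_primary]
    if (length(s2)) {
      gsum <- res$wgs_count_a[s2] + res$wgs_count_b[s2]
      ea <- res$R[s2] * res$wgs_count_a[s2] / gsum
      eb <- res$R[s2] * res$wgs_count_b[s2] / gsum
      ok <- ea > 0 & eb > 0
      chi2b <- ifelse(ok,
                      (res$count_a[s2] - ea)^2 / ea +
                      (res$count_b[s2] - eb)^2 / eb, NA_real_)
      p2 <- pchisq(chi2b, df = 1, lower.tail = FALSE)
      res[s2, `:=`(exp_wgs_a = ea, exp_wgs_b = eb,
                   chi2_wgs = chi2b, p_wgs = p2,
                   sig_1e2 = p2 < alpha_confirm,
                   final_call = !is.na(p2) & p2 < alpha_confirm)]
    }
  }
  res[]
}
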