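#' Reads per million mapped reads
#'
#' `RPM = T / A * 1e6`, where `T` is reads (RNA-seq: read pairs) mapped to
#' the gene in one tissue and `A` the total mapped in that tissue for the
#' same technology. Vectorized over `mapped_reads`.
#'
#' @param mapped_reads Reads mapped to the gene, `0 <= T <= A`.
#' @param library_total Total mapped reads `A > 0` for the tissue/technology.
#' @return RPM value(s).
#' @export
#' @examples
#' rpm(500, 1e6)  # 500
rpm <- function(mapped_reads, library_total) {
  if (any(library_total <= 0)) stop("library_total must be > 0")
  if (any(mapped_reads < 0)) stop("mapped_reads must be >= 0")
  if (any(mapped_reads > library_total))
    stop("mapped_reads exceeds library_total")
  mapped_reads / library_total * 1e6
}

#' Length-correct RPM to reads per kilobase million
#'
#' Divides RPM by the coding-sequence length in kilobase pairs. The CDS
#' length of the longest annotated coding isoform is the conventional
#' choice (see [expression_matrix()]).
#'
#' @param rpm_value RPM value(s).
#' @param cds_len CDS length in bp, > 0.
#' @return Length-corrected expression.
#' @export
#' @examples
#' rpkm_correct(100, 2000)  # 50
rpkm_correct <- function(rpm_value, cds_len) {
  if (any(cds_len <= 0)) stop("cds_length must be > 0")
  rpm_value / (cds_len / 1000)
}

#' Per-gene, per-tissue, per-technology expression matrix
#'
#' Computes RPM (and RPKM when gene models are supplied) for every
#' gene x tissue x technology combination present in the library-size
#' table; genes absent from a technology's counts get `mapped_reads = 0`
#' and `detected = FALSE`. Rankings within each tissue x technology are
#' attached by decreasing RPM.
#'
#' @param gene_totals data.frame/data.table with columns `gene`, `tissue`,
#'   `technology`, `mapped_reads`, `library_total`.
#' @param genes Optional list of [gene_model()] objects; enables the
#'   `rpkm` column via [cds_length()].
#' @param rpm_floor Detection floor on RPM (default 0: `detected`
#'   means `mapped_reads > 0`).
#' @return data.table with columns `gene`, `tissue`, `technology`,
#'   `mapped_reads`, `library_total`, `rpm_value`, `rpkm`, `detected`,
#'   `rank_rpm` (1 = most expressed within tissue x technology).
#' @export
expression_matrix <- function(gene_totals, genes = NULL, rpm_floor = 0) {
  dt <- as.data.table(gene_totals)
  need <- c("gene", "tissue", "technology", "mapped_reads", "library_total")
  if (!all(need %in% names(dt)))
    stop("gene_totals must have columns: ", paste(need, collapse = ", "))
  bad <- dt[is.na(library_total) | library_total <= 0]
  if (nrow(bad))
    stop("missing library total for: ",
         paste(unique(paste0("(", bad$tissue, ", ", bad$technology, ")")),
               collapse = ", "))

  # complete the gene x tissue x technology grid with zero counts
  libs <- unique(dt[, .(tissue, technology, library_total)])
  gene_ids <- if (!is.null(genes))
    vapply(genes, `[[`, "", "gene_id") else unique(dt$gene)
  grid <- data.table::CJ(gene = gene_ids, tt = seq_len(nrow(libs)))
  grid <- cbind(grid[, .(gene)], libs[grid$tt])
  dt <- merge(grid, dt[, .(gene, tissue, technology, mapped_reads)],
              by = c("gene", "tissue", "technology"), all.x = TRUE)
  dt[is.na(mapped_reads), mapped_reads := 0]

  dt[, rpm_value := rpm(mapped_reads, library_total)]
  if (!is.null(genes)) {
    lens <- setNames(vapply(genes, cds_length, 0), gene_ids)
    dt[, rpkm := rpkm_correct(rpm_value, lens[gene])]
  } else dt[, rpkm := NA_real_]
  dt[, detected := mapped_reads > 0 & rpm_value >= rpm_floor]
  setorder(dt, tissue, technology, -rpm_value, gene)
  dt[, rank_rpm := seq_len(.N), by = .(tissue, technology)]
  dt[]
}
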