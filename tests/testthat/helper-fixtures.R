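# shared in-code fixtures; no data files beyond inst/extdata TSVs

# two-exon plus-strand gene: 5' UTR 100-149, CDS 150-550, 3' UTR 551-600
tiny_plus_gene <- function() {
  gene_model("gp", "chr1", "+", rbind(c(100, 250), c(400, 600)),
             cds_start = 150, cds_end = 550)
}

# mirror image of tiny_plus_gene about position M (strand flipped)
mirror_gene <- function(g, M) {
  ex <- cbind(start = 2 * M - g$exons[, "stop"],
              stop = 2 * M - g$exons[, "start"])
  ex <- ex[order(ex[, "start"]), , drop = FALSE]
  gene_model(g$gene_id, g$chrom, if (g$strand == "+") "-" else "+",
             ex, cds_start = 2 * M - g$cds_end,
             cds_end = 2 * M - g$cds_start)
}

# random plus-strand multi-exon gene for property tests
random_gene <- function(n_ex = 3) {
  lens <- sample(30:80, n_ex, replace = TRUE)
  gaps <- sample(20:60, n_ex - 1, replace = TRUE)
  starts <- 500 + cumsum(c(0, lens[-n_ex] + gaps))
  ex <- cbind(start = starts, stop = starts + lens - 1)
  span <- c(ex[1, 1], ex[n_ex, 2])
  cds_start <- ex[1, 1] + sample(5:(lens[1] - 5), 1)
  cds_end <- ex[n_ex, 2] - sample(5:(lens[n_ex] - 5), 1)
  gene_model("gr", "chr1", "+", ex, cds_start, cds_end)
}

# small, fast synthetic world for pipeline-level tests
fast_config <- function(seed, snp_density = 2, ...) {
  synthetic_config(seed = seed, n_genes = 8, chrom_length = 6e5,
                   snp_density = snp_density,
                   tissues = c("liver", "lung"), n_ase_loci = 5, ...)
}

# published 5' gene positions / CAGE peak boundaries for the 12 bovine
# fertility genes with a called TSS, plus the published UTR lengths
tss_reference <- function() {
  data.table::fread(system.file("extdata", "fertility_gene_tss.tsv",
                                package = "ferttx"))
}

snp_reference <- function() {
  data.table::fread(system.file("extdata", "genome_snp_counts.tsv",
                                package = "ferttx"))
}

# minimal gene model consistent with a published row: single exon around
# the 5' coding position so five_prime_pos lands exactly on it
gene_from_tss_row <- function(row) {
  fp <- row$five_prime_pos
  if (row$strand == "+")
    gene_model(row$gene, "chrN", "+", cbind(fp - 3000, fp + 3000),
               cds_start = fp, cds_end = fp + 100)
  else
    gene_model(row$gene, "chrN", "-", cbind(fp - 3000, fp + 3000),
               cds_start = fp - 100, cds_end = fp)
}
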