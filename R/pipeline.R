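#' Pipeline configuration
#'
#' Exactly one input mode: a [synthetic_config()] (the simulator feeds
#' every stage and truth scoring is added to the report) or a named list
#' of paths to real input files (`annotation`, `wgs`, `rna`, `totals`,
#' `cage`, `bed`, `junctions` — the formats written by
#' [simulate_dataset()]).
#'
#' @param out_dir Output directory.
#' @param synthetic Optional [synthetic_config()].
#' @param inputs Optional named list of input file paths.
#' @param alpha_primary,alpha_confirm,min_depth ASE screen parameters
#'   (see [ase_screen()]).
#' @param promoter_window TSS search half-window (bp).
#' @param terminal_fuzz,min_junction_reads Isoform classification
#'   parameters (see [classify_isoform()]).
#' @param genome_size Genome size for the divergence statistic; defaults
#'   to 2.7 Gbp for real inputs and to the synthetic chromosome length
#'   for simulated runs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, synthetic = NULL, inputs = NULL,
                            alpha_primary = 1e-4, alpha_confirm = 1e-2,
                            min_depth = 10, promoter_window = 5000,
                            terminal_fuzz = 50, min_junction_reads = 2,
                            genome_size = NULL) {
  if (is.null(synthetic) == is.null(inputs))
    stop("exactly one of `synthetic` or `inputs` must be given")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  if (is.null(genome_size))
    genome_size <- if (!is.null(synthetic)) synthetic$chrom_length else 2.7e9
  structure(list(out_dir = out_dir, synthetic = synthetic, inputs = inputs,
                 alpha_primary = alpha_primary, alpha_confirm = alpha_confirm,
                 min_depth = min_depth, promoter_window = promoter_window,
                 terminal_fuzz = terminal_fuzz,
                 min_junction_reads = min_junction_reads,
                 genome_size = genome_size),
            class = "pipeline_config")
}

.stage_log <- function(stage, ...) {
  message(sprintf("[ferttx] %-10s %s", stage, sprintf(...)))
}

# assign an unassigned chain to the same-strand gene with maximal span overlap
.assign_gene <- function(chain, genes) {
  ov <- vapply(genes, function(g) {
    if (g$chrom != chain$chrom || g$strand != chain$strand) return(0)
    s <- gene_span(g)
    max(0, min(s[2], chain$exons[nrow(chain$exons), "stop"]) -
          max(s[1], chain$exons[1, "start"]) + 1)
  }, 0)
  if (max(ov) <= 0) NA_character_ else names(genes)[which.max(ov)]
}

#' Run the full pipeline
#'
#' simulate (optional) -> variants -> ase -> expression -> tss ->
#' isoforms, writing one TSV per stage plus a consolidated `report.txt`
#' under the configured output directory. On synthetic input a
#' truth-scoring section (zygosity accuracy, ASE precision/recall, TSS
#' recovery, isoform classification accuracy) is appended. Every number
#' in the report is read back from a stage output table.
#'
#' @param config A [pipeline_config()].
#' @return List of class `ferttx_report` with all stage tables, the
#'   truth scores (synthetic runs) and output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$synthetic)) {
    sim <- simulate_dataset(config$synthetic, file.path(out, "sim"))
    genes <- sim$genes
    wgs <- sim$wgs_counts; rna <- sim$rna_counts
    totals <- sim$gene_totals; cage <- sim$cage_coverage
    chains <- sim$chains; junctions <- sim$junction_counts
    truth <- sim$truth
    .stage_log("simulate", "%d genes, %d WGS loci, %d isoform chains",
               length(genes), nrow(wgs), length(chains))
  } else {
    inp <- config$inputs
    genes <- read_gff3(inp$annotation)
    wgs <- fread(inp$wgs); rna <- fread(inp$rna)
    totals <- fread(inp$totals); cage <- fread(inp$cage)
    chains <- read_bed12(inp$bed)
    junctions <- if (!is.null(inp$junctions)) fread(inp$junctions) else NULL
    truth <- NULL
    .stage_log("load", "%d genes, %d WGS loci, %d isoform chains",
               length(genes), nrow(wgs), length(chains))
  }

  # variants: zygosity + region per locus, divergence per animal
  snps <- snp_table(wgs, genes)
  tal <- snps[, {
    t <- tally_zygosity(zygosity)
    d <- divergence(t$ho_count, t$he_count, genome_size = config$genome_size)
    .(ho_count = t$ho_count, he_count = t$he_count,
      divergence = d$divergence,
      homology_pct = round(d$homology_pct, 3))
  }, by = animal]
  fwrite(snps, file.path(out, "snp_table.tsv"), sep = "\t")
  fwrite(tal, file.path(out, "divergence.tsv"), sep = "\t")
  .stage_log("variants", "%d loci called, %d het",
             nrow(snps), sum(snps$zygosity == "het"))

  # ase
  ase <- ase_screen(rna, wgs, alpha_primary = config$alpha_primary,
                    alpha_confirm = config$alpha_confirm,
                    min_depth = config$min_depth)
  gene_of <- function(p) {
    for (g in genes) {
      s <- gene_span(g)
      if (p >= s[1] && p <= s[2]) return(g$gene_id)
    }
    NA_character_
  }
  ase[, gene := vapply(pos, gene_of, "")]
  ase_sum <- ase[eligible == TRUE,
                 .(tested = .N, stage1_hits = sum(sig_1e4, na.rm = TRUE),
                   final_calls = sum(final_call)), by = .(gene)]
  fwrite(ase, file.path(out, "ase_results.tsv"), sep = "\t")
  fwrite(ase_sum, file.path(out, "ase_summary.tsv"), sep = "\t")
  .stage_log("ase", "%d eligible tests, %d final calls",
             sum(ase$eligible), sum(ase$final_call))

  # expression
  expr <- expression_matrix(totals, genes)
  fwrite(expr, file.path(out, "expression_matrix.tsv"), sep = "\t")
  .stage_log("expression", "%d gene x tissue x technology records",
             nrow(expr))

  # tss
  peaks <- lapply(genes, function(g)
    call_peaks(cage, g, promoter_window = config$promoter_window))
  names(peaks) <- names(genes)
  tss_rep <- summarize_tss(genes, peaks)
  fwrite(tss_rep$table, file.path(out, "tss_report.tsv"), sep = "\t")
  .stage_log("tss", "%d genes with a peak, %d without",
             sum(!is.na(tss_rep$table$utr_length)),
             length(tss_rep$no_peak))

  # isoforms
  refs <- lapply(genes, as_isoform_chain)
  cls <- lapply(chains, function(ch) {
    gid <- if (is.na(ch$gene_id)) .assign_gene(ch, genes) else ch$gene_id
    if (is.na(gid)) return(NULL)
    cl <- classify_isoform(ch, refs[gid], junctions,
                           terminal_fuzz = config$terminal_fuzz,
                           min_junction_reads = config$min_junction_reads)
    data.table(isoform_id = cl$isoform_id, gene = gid,
               category = cl$category,
               matched_reference = cl$matched_reference,
               retained_introns = paste(cl$retained_introns,
                                        collapse = ","),
               multi_evidence = cl$multi_evidence)
  })
  cls <- rbindlist(Filter(Negate(is.null), cls))
  deps <- cls[category == "intron_retention",
              if (.N > 0) {
                objs <- lapply(seq_len(.N), function(i)
                  structure(list(category = "intron_retention",
                                 retained_introns = as.integer(strsplit(
                                   retained_introns[i], ",")[[1]])),
                            class = "isoform_classification"))
                retention_dependency(objs)
              }, by = gene]
  nested <- rbindlist(lapply(names(genes), function(a)
    rbindlist(lapply(names(genes), function(b) {
      if (a == b || genes[[a]]$chrom != genes[[b]]$chrom) return(NULL)
      sa <- gene_span(genes[[a]]); sb <- gene_span(genes[[b]])
      if (sa[1] > sb[2] || sa[2] < sb[1]) return(NULL)
      detect_nested_exons(genes[[a]], genes[[b]])
    }))), fill = TRUE)
  fwrite(cls, file.path(out, "isoform_classifications.tsv"), sep = "\t")
  fwrite(deps, file.path(out, "retention_dependencies.tsv"), sep = "\t")
  fwrite(nested, file.path(out, "nested_exons.tsv"), sep = "\t")
  .stage_log("isoforms", "%d chains classified, %d nested exon hit(s)",
             nrow(cls), nrow(nested))

  scores <- NULL
  if (!is.null(truth)) scores <- .score_truth(truth, snps, ase, tss_rep,
                                              cls, nested, genes)
  .write_report(out, tal, tss_rep, ase, cls, scores)

  structure(list(snp_table = snps, divergence = tal, ase = ase,
                 ase_summary = ase_sum, expression = expr,
                 tss = tss_rep, isoforms = cls,
                 retention_dependencies = deps, nested = nested,
                 truth_scores = scores, out_dir = out),
            class = "ferttx_report")
}

.score_truth <- function(truth, snps, ase, tss_rep, cls, nested, genes) {
  zy <- merge(snps, truth$het_loci[, c("animal", "pos", "zygosity_true")],
              by = c("animal", "pos"))
  callable <- zy$zygosity != "uncallable"
  zyg_acc <- mean(zy$zygosity[callable] == zy$zygosity_true[callable])

  planted <- unique(truth$ase[, c("pos", "tissue")])
  called <- ase[ase$final_call, c("pos", "tissue")]
  tp <- nrow(merge(planted, called, by = c("pos", "tissue")))
  ase_precision <- if (nrow(called)) tp / nrow(called) else NA_real_
  ase_recall <- if (nrow(planted)) tp / nrow(planted) else NA_real_

  # TSS recovery: the recovered peak mode must sit on the planted TSS
  tt <- merge(tss_rep$table, truth$genes[, c("gene_id", "tss_pos")],
              by.x = "gene", by.y = "gene_id")
  tss_exact <- mean(tt$peak_mode == tt$tss_pos, na.rm = TRUE)

  ic <- merge(cls, truth$isoforms, by = "isoform_id",
              suffixes = c("", "_true"))
  iso_acc <- mean(ic$category == ic$category_true)

  nested_found <- nrow(merge(nested, truth$nested,
                             by.x = c("guest_gene", "host_gene"),
                             by.y = c("guest", "host"))) > 0
  list(zygosity_accuracy = zyg_acc, ase_precision = ase_precision,
       ase_recall = ase_recall, tss_exact_fraction = tss_exact,
       isoform_accuracy = iso_acc, nested_recovered = nested_found)
}

.write_report <- function(out, tal, tss_rep, ase, cls, scores) {
  path <- file.path(out, "report.txt")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("== ferttx pipeline report ==", con)
  writeLines("-- haplotype divergence --", con)
  for (i in seq_len(nrow(tal)))
    writeLines(sprintf("%s: Ho=%d He=%d homology=%.3f%%", tal$animal[i],
                       tal$ho_count[i], tal$he_count[i],
                       tal$homology_pct[i]), con)
  writeLines("-- 5' UTR lengths --", con)
  writeLines(sprintf("min %g bp (%s), max %g bp (%s), mean %.1f bp",
                     tss_rep$stats$min, tss_rep$stats$min_gene,
                     tss_rep$stats$max, tss_rep$stats$max_gene,
                     tss_rep$stats$mean), con)
  writeLines(sprintf("-- ASE: %d eligible, %d stage-1 hits, %d final --",
                     sum(ase$eligible), sum(ase$sig_1e4, na.rm = TRUE),
                     sum(ase$final_call)), con)
  writeLines(sprintf("-- isoforms: %s --",
                     paste(sprintf("%s=%d", names(table(cls$category)),
                                   table(cls$category)), collapse = " ")),
             con)
  if (!is.null(scores)) {
    writeLines("-- truth scoring --", con)
    writeLines(sprintf("zygosity accuracy: %.4f", scores$zygosity_accuracy),
               con)
    writeLines(sprintf("ASE precision: %.4f recall: %.4f",
                       scores$ase_precision, scores$ase_recall), con)
    writeLines(sprintf("TSS exact recovery: %.4f",
                       scores$tss_exact_fraction), con)
    writeLines(sprintf("isoform accuracy: %.4f", scores$isoform_accuracy),
               con)
    writeLines(sprintf("nested exon recovered: %s",
                       scores$nested_recovered), con)
  }
  invisible(path)
}

#' @export
print.ferttx_report <- function(x, ...) {
  cat("<ferttx_report> outputs in", x$out_dir, "\n")
  cat("  divergence rows:", nrow(x$divergence),
      "| ASE final calls:", sum(x$ase$final_call),
      "| isoform chains:", nrow(x$isoforms), "\n")
  if (!is.null(x$truth_scores)) {
    s <- x$truth_scores
    cat(sprintf(
      "  truth: zygosity %.3f | ASE P %.3f R %.3f | TSS %.3f | iso %.3f | nested %s\n",
      s$zygosity_accuracy, s$ase_precision, s$ase_recall,
      s$tss_exact_fraction, s$isoform_accuracy, s$nested_recovered))
  }
  invisible(x)
}
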