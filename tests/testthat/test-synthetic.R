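test_that("synthetic_config validates fractions, seed and nesting", {
  expect_error(synthetic_config(), "seed")
  expect_error(synthetic_config(seed = 1, reference_bias = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_config(seed = 1, n_genes = 1), "nested pair")
  expect_error(synthetic_config(seed = 1,
                                nested_exon_spec = list(host_span = c(50, 500),
                                                        guest_exon = c(400, 600))),
               "within host_span")
  cfg <- synthetic_config(seed = 1, n_genes = 1, nested_exon_spec = NULL)
  expect_s3_class(cfg, "synthetic_config")
})

test_that("generate_annotation places genes per spec", {
  # zero-UTR single-exon case: CDS start equals transcript start
  cfg <- synthetic_config(seed = 2, n_genes = 1, exons_per_gene = c(1, 1),
                          tss_offsets = 0, strand_mix = 0,
                          nested_exon_spec = NULL)
  ann <- generate_annotation(cfg)
  g <- ann$genes[[1]]
  expect_equal(g$cds_start, gene_span(g)[1])

  # planted UTR is exactly realizable for both strands
  cfg <- synthetic_config(seed = 3, n_genes = 6, tss_offsets = c(81, 1919),
                          nested_exon_spec = NULL)
  ann <- generate_annotation(cfg)
  expect_equal(ann$truth$genes$utr5, rep(c(81, 1919), 3))
  for (g in ann$genes) {
    expect_true(all(diff(g$exons[, "start"]) > 0))
    expect_true(all(g$exons[, "start"] <= g$exons[, "stop"]))
  }

  # explicit nested pair: guest exon inside the host span, opposite strand
  cfg <- synthetic_config(seed = 4, n_genes = 4,
                          nested_exon_spec = list(host_span = c(5000, 9000),
                                                  guest_exon = c(6000, 6500)))
  ann <- generate_annotation(cfg)
  host <- ann$genes[[ann$truth$nested$host]]
  guest <- ann$genes[[ann$truth$nested$guest]]
  hits <- detect_nested_exons(guest, host)
  expect_gte(nrow(hits), 1)
  expect_true(any(hits$exon_start == 6000 & hits$exon_stop == 6500))
  expect_equal(hits$strand_relation[1], "opposite")

  # auto nesting: the guest's last exon lies inside the host span
  cfg <- fast_config(seed = 5)
  ann <- generate_annotation(cfg)
  nt <- ann$truth$nested
  span <- gene_span(ann$genes[[nt$host]])
  expect_true(nt$exon_start >= span[1] && nt$exon_stop <= span[2])

  # infeasible placement errors out
  expect_error(generate_annotation(
    synthetic_config(seed = 6, n_genes = 10, chrom_length = 20000,
                     nested_exon_spec = NULL)),
    "placement error")
})

test_that("simulate_dataset is byte-identical under the same seed", {
  cfg <- fast_config(seed = 9, snp_density = 0.5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("md5 of", f))
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_dataset(fast_config(seed = 10, snp_density = 0.5), d3)
  expect_false(unname(tools::md5sum(file.path(d1, "wgs_counts.tsv"))) ==
               unname(tools::md5sum(file.path(d3, "wgs_counts.tsv"))))
})

test_that("WGS counts follow the binomial sampling model", {
  # deep sampling: het allele-A fraction within 3 SE of the bias
  cfg <- synthetic_config(seed = 12, n_genes = 2, chrom_length = 1e5,
                          snp_density = 1, wgs_depth_mean = 10000,
                          nested_exon_spec = NULL)
  wgs <- generate_wgs_counts(generate_annotation(cfg), cfg)
  counts <- merge(wgs$wgs_counts, wgs$truth$het_loci[
    , c("animal", "pos", "zygosity_true")], by = c("animal", "pos"))
  het <- counts[counts$zygosity_true == "het", ]
  frac <- het$count_a / (het$count_a + het$count_b)
  se <- sqrt(0.25 / (het$count_a + het$count_b))
  expect_true(all(abs(frac - 0.5) < 3.5 * se))
  # homozygous loci have zero second-allele count with the error model off
  hom <- counts[counts$zygosity_true == "hom_alt", ]
  expect_true(all(hom$count_a == 0))

  # degenerate bias: allele B never observed at het loci
  cfg1 <- synthetic_config(seed = 13, n_genes = 2, chrom_length = 1e5,
                           snp_density = 1, reference_bias = 1,
                           nested_exon_spec = NULL)
  wgs1 <- generate_wgs_counts(generate_annotation(cfg1), cfg1)
  c1 <- merge(wgs1$wgs_counts, wgs1$truth$het_loci[
    , c("animal", "pos", "zygosity_true")], by = c("animal", "pos"))
  expect_true(all(c1[c1$zygosity_true == "het", "count_b"] == 0))
})

test_that("RNA counts realize planted allele fractions", {
  # f = 1 at planted loci: monoallelic counts up to sampling
  cfg <- synthetic_config(seed = 14, n_genes = 2, chrom_length = 1e5,
                          snp_density = 1, rna_depth_mean = 50,
                          tissues = "liver", n_ase_loci = 5,
                          ase_fraction = 1, nested_exon_spec = NULL)
  ann <- generate_annotation(cfg)
  wgs <- generate_wgs_counts(ann, cfg)
  rna <- generate_rnaseq_counts(ann, wgs$truth, cfg)
  planted <- rna$rna_counts[rna$rna_counts$pos %in% rna$truth$ase$pos, ]
  expect_true(all(planted$count_b == 0))

  # f = 0.8 at depth ~400: observed fraction within 3 SE of 0.8
  cfg8 <- synthetic_config(seed = 15, n_genes = 2, chrom_length = 1e5,
                           snp_density = 1, rna_depth_mean = 400,
                           tissues = "liver", n_ase_loci = 20,
                           ase_fraction = 0.8, nested_exon_spec = NULL)
  ann8 <- generate_annotation(cfg8)
  wgs8 <- generate_wgs_counts(ann8, cfg8)
  rna8 <- generate_rnaseq_counts(ann8, wgs8$truth, cfg8)
  pl <- rna8$rna_counts[rna8$rna_counts$pos %in% rna8$truth$ase$pos, ]
  depth <- pl$count_a + pl$count_b
  frac <- pl$count_a / depth
  expect_true(all(abs(frac - 0.8) < 3.5 * sqrt(0.8 * 0.2 / depth)))

  # an effect planted at a non-het locus is a config error
  bad <- synthetic_config(seed = 16, n_genes = 2, chrom_length = 1e5,
                          snp_density = 1, tissues = "liver",
                          nested_exon_spec = NULL,
                          ase_effects = data.frame(pos = -1, tissue = "liver",
                                                   fraction = 0.8))
  annb <- generate_annotation(bad)
  wgsb <- generate_wgs_counts(annb, bad)
  expect_error(generate_rnaseq_counts(annb, wgsb$truth, bad),
               "non-heterozygous")
})

test_that("per-gene totals conserve the configured library sizes", {
  cfg <- fast_config(seed = 18)
  ann <- generate_annotation(cfg)
  wgs <- generate_wgs_counts(ann, cfg)
  rna <- generate_rnaseq_counts(ann, wgs$truth, cfg)
  sums <- rna$gene_totals[, .(s = sum(mapped_reads)),
                          by = .(tissue, technology)]
  chk <- merge(sums, cfg$library_sizes, by = c("tissue", "technology"))
  expect_equal(chk$s, chk$library_total)
})

test_that("CAGE coverage is a unimodal cluster at the planted TSS", {
  cfg <- fast_config(seed = 20, cage_peak_width = 0,
                     cage_silent_genes = "G03")
  ann <- generate_annotation(cfg)
  cov <- generate_cage_coverage(ann, ann$truth, cfg)
  tr <- ann$truth$genes
  # width 0: a single spike per expressed gene, at the TSS
  for (gid in setdiff(tr$gene_id, "G03")) {
    g <- ann$genes[[gid]]
    rows <- cov[cov$strand == g$strand &
                abs(cov$pos - tr$tss_pos[tr$gene_id == gid]) <= 20, ]
    expect_equal(nrow(rows), 1)
    expect_equal(rows$pos, tr$tss_pos[tr$gene_id == gid])
  }
  # silent gene: no tags anywhere near its promoter
  g3 <- ann$genes[["G03"]]
  expect_equal(nrow(cov[abs(cov$pos - transcript_start(g3)) <= 5000 &
                        cov$strand == g3$strand, ]), 0)

  # planted UTR 81 bp: cluster mode exactly 81 bp 5'-ward of the CDS start
  cfg81 <- synthetic_config(seed = 22, n_genes = 2, tss_offsets = 81,
                            strand_mix = 0, nested_exon_spec = NULL,
                            cage_peak_width = 4)
  ann81 <- generate_annotation(cfg81)
  cov81 <- generate_cage_coverage(ann81, ann81$truth, cfg81)
  g <- ann81$genes[[1]]
  pk <- call_peaks(cov81, g)
  expect_equal(pk$mode_pos, g$cds_start - 81)
})

test_that("isoform generator realizes each planted category", {
  cfg <- synthetic_config(seed = 24, tissues = c("liver", "lung"))
  ann <- generate_annotation(cfg)
  iso <- generate_isoform_reads(ann, ann$truth, cfg)
  truth <- iso$truth$isoforms
  expect_gte(nrow(truth), 20)
  expect_setequal(unique(truth$category),
                  c("known", "novel_junction", "intron_retention",
                    "novel_terminal"))
  chains <- setNames(iso$chains, vapply(iso$chains, `[[`, "", "isoform_id"))

  for (i in seq_len(nrow(truth))) {
    ch <- chains[[truth$isoform_id[i]]]
    g <- ann$genes[[truth$gene[i]]]
    ref_j <- intron_chain(g$exons)
    cand_j <- intron_chain(ch)
    if (truth$category[i] == "known") {
      expect_equal(cand_j, ref_j)
      expect_equal(ch$exons, g$exons, ignore_attr = TRUE)
    } else if (truth$category[i] == "intron_retention") {
      # chain-algebra oracle: drop the retained introns from the reference
      ret <- as.integer(strsplit(truth$retained[i], ",")[[1]])
      kept <- ref_j[-ret, , drop = FALSE]
      expect_equal(unname(cand_j), unname(kept))
      expect_equal(nrow(ch$exons), nrow(g$exons) - length(ret))
    } else if (truth$category[i] == "novel_terminal") {
      expect_equal(cand_j, ref_j)   # junctions untouched
      if (g$strand == "+")
        expect_equal(ch$exons[1, "start"], g$exons[1, "start"] - 600)
      else
        expect_equal(ch$exons[nrow(ch$exons), "stop"],
                     g$exons[nrow(g$exons), "stop"] + 600)
    } else {  # novel_junction: exactly one moved splice site
      expect_false(identical(cand_j, ref_j))
      expect_equal(nrow(cand_j), nrow(ref_j))
    }
  }
  # junction counts cover every emitted junction with the configured depth
  expect_true(all(iso$junction_counts$reads == cfg$junction_read_depth))
})
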