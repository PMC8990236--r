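test_that("intron_chain derives junctions and validates input", {
  expect_equal(intron_chain(rbind(c(1, 100), c(201, 300))),
               cbind(start = 101, stop = 200))
  expect_equal(nrow(intron_chain(rbind(c(1, 100)))), 0)
  expect_equal(intron_chain(rbind(c(1, 100), c(201, 300), c(401, 500))),
               cbind(start = c(101, 301), stop = c(200, 400)))
  expect_error(intron_chain(rbind(c(201, 300), c(1, 100))), "sorted")
  expect_error(intron_chain(rbind(c(1, 100), c(50, 200))), "sorted")
})

test_that("junction_support thresholds per junction and chain", {
  j <- intron_chain(rbind(c(1, 100), c(201, 300), c(401, 500)))
  counts <- data.table::data.table(intron_start = c(101, 301),
                                   intron_stop = c(200, 400),
                                   reads = c(5, 7))
  s <- junction_support(j, counts, min_reads = 2)
  expect_true(all(s$supported))
  expect_true(s$multi_evidence)

  counts$reads <- c(5, 0)
  s <- junction_support(j, counts, min_reads = 2)
  expect_equal(s$supported, c(TRUE, FALSE))
  expect_false(s$multi_evidence)

  s <- junction_support(j, counts, min_reads = 0)
  expect_true(s$multi_evidence)   # vacuous threshold
  # junction missing from the table counts as zero reads
  s <- junction_support(j, counts[1], min_reads = 2)
  expect_equal(s$supported, c(TRUE, FALSE))
})

ref4 <- isoform_chain("ref1", "g", "chr1", "+",
                      rbind(c(1, 100), c(201, 300), c(401, 500),
                            c(601, 700)), source = "reference")
full_support <- data.table::data.table(
  intron_start = c(101, 301, 501), intron_stop = c(200, 400, 600),
  reads = 50)

test_that("classify_isoform: known, retention, terminal, junction", {
  # identical chain -> known
  cand <- isoform_chain("c1", "g", "chr1", "+", ref4$exons)
  cl <- classify_isoform(cand, list(ref4), full_support)
  expect_equal(cl$category, "known")
  expect_equal(cl$matched_reference, "ref1")

  # terminal difference exactly at the fuzz is still known
  ex <- ref4$exons; ex[1, "start"] <- ex[1, "start"] + 50
  cl <- classify_isoform(isoform_chain("c2", "g", "chr1", "+", ex),
                         list(ref4), full_support, terminal_fuzz = 50)
  expect_equal(cl$category, "known")

  # candidate splices introns {1,3} only -> retention of intron 2
  ex <- rbind(c(1, 100), c(201, 500), c(601, 700))
  cl <- classify_isoform(isoform_chain("c3", "g", "chr1", "+", ex),
                         list(ref4), full_support)
  expect_equal(cl$category, "intron_retention")
  expect_equal(cl$retained_introns, 2L)

  # all introns retained -> single exon candidate
  cl <- classify_isoform(isoform_chain("c4", "g", "chr1", "+",
                                       cbind(1, 700)),
                         list(ref4), full_support)
  expect_equal(cl$category, "intron_retention")
  expect_equal(cl$retained_introns, 1:3)

  # identical junctions, 5' end longer by 600 bp, supported -> novel_terminal
  ex <- ref4$exons + 1000; ex[1, "start"] <- ex[1, "start"] - 600
  ref_shift <- isoform_chain("ref1", "g", "chr1", "+", ref4$exons + 1000,
                             source = "reference")
  sup <- data.table::data.table(intron_start = c(1101, 1301, 1501),
                                intron_stop = c(1200, 1400, 1600),
                                reads = 50)
  cl <- classify_isoform(isoform_chain("c5", "g", "chr1", "+", ex),
                         list(ref_shift), sup)
  expect_equal(cl$category, "novel_terminal")
  expect_true(cl$multi_evidence)

  # same chain without junction support -> ambiguous_degradation
  cl <- classify_isoform(isoform_chain("c6", "g", "chr1", "+", ex),
                         list(ref_shift), sup[0])
  expect_equal(cl$category, "ambiguous_degradation")

  # a moved splice site -> novel_junction
  ex <- ref4$exons; ex[1, "stop"] <- 130
  cl <- classify_isoform(isoform_chain("c7", "g", "chr1", "+", ex),
                         list(ref4), full_support)
  expect_equal(cl$category, "novel_junction")

  # empty reference set warns and calls novel_junction
  expect_warning(
    cl <- classify_isoform(cand, list(), full_support),
    "empty reference")
  expect_equal(cl$category, "novel_junction")
})

test_that("classification is order- and translation-invariant", {
  ref_b <- isoform_chain("ref2", "g", "chr1", "+",
                         rbind(c(1, 100), c(201, 300), c(421, 500),
                               c(601, 700)), source = "reference")
  ex <- rbind(c(1, 100), c(201, 500), c(601, 700))
  cand <- isoform_chain("c", "g", "chr1", "+", ex)
  cl1 <- classify_isoform(cand, list(ref4, ref_b), full_support)
  cl2 <- classify_isoform(cand, list(ref_b, ref4), full_support)
  expect_equal(cl1$category, cl2$category)
  expect_equal(cl1$matched_reference, cl2$matched_reference)

  for (shift in c(100, 5000)) {
    ref_s <- isoform_chain("ref1", "g", "chr1", "+", ref4$exons + shift,
                           source = "reference")
    cand_s <- isoform_chain("c", "g", "chr1", "+", ex + shift)
    sup_s <- data.table::data.table(
      intron_start = full_support$intron_start + shift,
      intron_stop = full_support$intron_stop + shift, reads = 50)
    cl_s <- classify_isoform(cand_s, list(ref_s), sup_s)
    expect_equal(cl_s$category, cl1$category)
    expect_equal(cl_s$retained_introns, cl1$retained_introns)
  }
})

test_that("retention_dependency builds the implication table", {
  mk <- function(retained) structure(
    list(category = "intron_retention", retained_introns = retained),
    class = "isoform_classification")
  dep <- retention_dependency(list(mk(2L), mk(c(2L, 3L))))
  expect_true(dep[dep$intron_a == 3 & dep$intron_b == 2, implies])
  expect_false(dep[dep$intron_a == 2 & dep$intron_b == 3, implies])
  expect_true(dep[dep$intron_a == 2 & dep$intron_b == 2, implies])

  dep1 <- retention_dependency(list(mk(1L)))
  expect_equal(nrow(dep1), 1)
  expect_true(dep1$implies)

  none <- structure(list(category = "known", retained_introns = integer()),
                    class = "isoform_classification")
  expect_equal(nrow(retention_dependency(list(none))), 0)
})

test_that("detect_nested_exons requires full containment", {
  host <- gene_model("host", "chr1", "-", cbind(50, 500), 60, 490)
  guest <- gene_model("guest", "chr1", "+", rbind(c(1, 30), c(100, 200)),
                      1, 200)
  hits <- detect_nested_exons(guest, host)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$exon_start, 100)
  expect_equal(hits$strand_relation, "opposite")

  # partial overlap is not a hit
  part <- gene_model("part", "chr1", "+", rbind(c(1, 30), c(400, 600)),
                     1, 600)
  expect_equal(nrow(detect_nested_exons(part, host)), 0)

  # exon exactly equal to the host span is a hit (boundary inclusive)
  eq <- gene_model("eq", "chr1", "-", cbind(50, 500), 60, 490)
  expect_equal(nrow(detect_nested_exons(eq, host)), 1)
  expect_equal(detect_nested_exons(eq, host)$strand_relation, "same")

  # exon-level mode: containment within a host exon is required
  host2 <- gene_model("host2", "chr1", "-", rbind(c(50, 90), c(300, 500)),
                      60, 490)
  expect_equal(nrow(detect_nested_exons(guest, host2)), 1)  # span mode
  expect_equal(nrow(detect_nested_exons(guest, host2,
                                        host_exon_level = TRUE)), 0)
  expect_error(detect_nested_exons(host, host), "differ")
})
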