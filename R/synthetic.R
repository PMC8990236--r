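#' Configuration for the synthetic multi-assay dataset
#'
#' Describes the simulated world: a single chromosome carrying `n_genes`
#' non-overlapping genes (plus one optionally nested antisense pair),
#' biallelic WGS allele counts with configurable reference bias, per-tissue
#' RNA allele counts with planted allele-fraction effects, unimodal CAGE
#' tag clusters at planted TSS offsets, and long-read isoform chains
#' realizing planted structural categories. The seed is explicit and
#' mandatory; no global random state is used or left behind.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_genes Number of genes (>= 1; the nested pair, when enabled,
#'   is included in this count and needs `n_genes >= 2`).
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param strand_mix Fraction of minus-strand genes in `[0, 1]`.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param exon_length,intron_length Ranges (bp) for internal exon and
#'   intron lengths.
#' @param utr5_range Range (bp) the planted 5' UTR lengths are drawn from
#'   when `tss_offsets` is not given; the default spans the lengths
#'   observed for bovine fertility genes (81-1919 bp).
#' @param utr3_range Range (bp) of 3' UTR lengths.
#' @param tss_offsets Optional vector of planted 5' UTR lengths, one per
#'   gene (recycled; may be named by gene id).
#' @param snp_density SNPs per kbp.
#' @param het_fraction Fraction of SNP loci that are heterozygous (the
#'   rest are homozygous-alternative).
#' @param wgs_depth_mean,rna_depth_mean Mean sequencing depth per locus
#'   (Poisson) for WGS and for RNA per tissue.
#' @param reference_bias Expected reference-allele share in WGS sampling,
#'   in `[0, 1]`; 0.5 = unbiased.
#' @param error_rate Per-read probability of observing the absent allele
#'   at a homozygous locus; default 0 so genotype truth is crisp.
#' @param animals Character vector of animal names (WGS + RNA per animal).
#' @param tissues Character vector of tissue names.
#' @param n_ase_loci,ase_fraction Default planted ASE: the first
#'   `n_ase_loci` heterozygous loci get allele-A fraction `ase_fraction`
#'   in every tissue.
#' @param ase_effects Optional explicit data.frame with columns `pos`,
#'   `tissue`, `fraction` overriding the default; each `pos` must be a
#'   planted heterozygous locus.
#' @param cage_peak_width Half-width of the triangular CAGE tag kernel
#'   (bp); 0 gives a single-position spike.
#' @param cage_tags_per_gene Total CAGE tags per expressed gene.
#' @param cage_noise Mean background tags per position (Poisson) across
#'   the chromosome; default 0 (off).
#' @param cage_silent_genes Gene ids with no CAGE expression (no tags in
#'   their promoter window; they are reported as "no TSS").
#' @param planted_isoforms Optional data.frame with columns `gene`,
#'   `category`, `param` overriding the default isoform plan (see
#'   [generate_isoform_reads()]).
#' @param nested_exon_spec `NULL` to disable the nested antisense pair;
#'   `"auto"` (default) nests the last exon of gene `n_genes - 1` inside
#'   the span of gene `n_genes` on the opposite strand; or a list with
#'   `host_span = c(start, stop)`, `guest_exon = c(start, stop)`,
#'   optionally `host_strand`/`guest_strand`, for explicit placement.
#' @param junction_read_depth Short reads spanning each emitted junction.
#' @param library_sizes Optional data.frame with columns `tissue`,
#'   `technology`, `library_total`; defaults to 1e6 (rna_seq), 1e5
#'   (cage_seq) and 2e4 (iso_seq) per tissue, mirroring the depth
#'   ordering of the three assays.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_genes = 13,
                             chrom = "chr1",
                             chrom_length = 2e6,
                             strand_mix = 0.5,
                             exons_per_gene = c(4, 7),
                             exon_length = c(120, 400),
                             intron_length = c(200, 1500),
                             utr5_range = c(81, 1919),
                             utr3_range = c(100, 400),
                             tss_offsets = NULL,
                             snp_density = 5,
                             het_fraction = 0.6,
                             wgs_depth_mean = 30,
                             rna_depth_mean = 100,
                             reference_bias = 0.5,
                             error_rate = 0,
                             animals = "cow",
                             tissues = c("blood", "liver", "lung",
                                         "spleen", "uterus"),
                             n_ase_loci = 10,
                             ase_fraction = 0.8,
                             ase_effects = NULL,
                             cage_peak_width = 10,
                             cage_tags_per_gene = 200,
                             cage_noise = 0,
                             cage_silent_genes = NULL,
                             planted_isoforms = NULL,
                             nested_exon_spec = "auto",
                             junction_read_depth = 50,
                             library_sizes = NULL) {
  if (missing(seed)) stop("`seed` is mandatory in synthetic_config()")
  fracs <- c(strand_mix = strand_mix, het_fraction = het_fraction,
             reference_bias = reference_bias, error_rate = error_rate,
             ase_fraction = ase_fraction)
  bad <- fracs < 0 | fracs > 1
  if (any(bad))
    stop("fractions must lie in [0, 1]: ",
         paste(names(fracs)[bad], collapse = ", "))
  if (n_genes < 1 || chrom_length <= 0 || wgs_depth_mean <= 0 ||
      rna_depth_mean <= 0 || snp_density < 0)
    stop("counts, depths and lengths must be positive")
  if (!is.null(nested_exon_spec) && !identical(nested_exon_spec, "auto")) {
    ns <- nested_exon_spec
    if (is.null(ns$host_span) || is.null(ns$guest_exon))
      stop("explicit nested_exon_spec needs host_span and guest_exon")
    if (ns$guest_exon[1] < ns$host_span[1] ||
        ns$guest_exon[2] > ns$host_span[2])
      stop("guest_exon must lie within host_span")
  }
  if (!is.null(nested_exon_spec) && n_genes < 2)
    stop("the nested pair needs n_genes >= 2")
  if (is.null(library_sizes)) {
    library_sizes <- data.table::CJ(tissue = tissues,
                                    technology = c("rna_seq", "cage_seq",
                                                   "iso_seq"))
    library_sizes[, library_total :=
      c(rna_seq = 1e6, cage_seq = 1e5, iso_seq = 2e4)[technology]]
  } else library_sizes <- as.data.table(library_sizes)
  cfg <- list(
    seed = as.integer(seed), n_genes = n_genes, chrom = chrom,
    chrom_length = chrom_length, strand_mix = strand_mix,
    exons_per_gene = exons_per_gene, exon_length = exon_length,
    intron_length = intron_length, utr5_range = utr5_range,
    utr3_range = utr3_range, tss_offsets = tss_offsets,
    snp_density = snp_density, het_fraction = het_fraction,
    wgs_depth_mean = wgs_depth_mean, rna_depth_mean = rna_depth_mean,
    reference_bias = reference_bias, error_rate = error_rate,
    animals = animals, tissues = tissues,
    n_ase_loci = n_ase_loci, ase_fraction = ase_fraction,
    ase_effects = ase_effects,
    cage_peak_width = cage_peak_width,
    cage_tags_per_gene = cage_tags_per_gene, cage_noise = cage_noise,
    cage_silent_genes = cage_silent_genes,
    planted_isoforms = planted_isoforms,
    nested_exon_spec = nested_exon_spec,
    junction_read_depth = junction_read_depth,
    library_sizes = library_sizes)
  class(cfg) <- "synthetic_config"
  cfg
}

# one gene's exon layout; utr5/utr3 are placed at the transcription ends
.build_gene <- function(gene_id, chrom, strand, tx_start, n_ex, utr5, utr3,
                        exon_len, intron_len) {
  cp5 <- sample(60:200, 1L)  # coding piece sharing the 5'-terminal exon
  cp3 <- sample(60:200, 1L)
  if (n_ex == 1L) {
    lens <- utr5 + cp5 + cp3 + utr3
  } else {
    mids <- if (n_ex > 2L)
      sample(exon_len[1]:exon_len[2], n_ex - 2L, replace = TRUE) else integer()
    first_tx <- utr5 + cp5
    last_tx <- cp3 + utr3
    lens <- if (strand == "+") c(first_tx, mids, last_tx)
            else c(last_tx, mids, first_tx)
  }
  gaps <- if (n_ex > 1L)
    sample(intron_len[1]:intron_len[2], n_ex - 1L, replace = TRUE)
    else integer()
  starts <- tx_start + cumsum(c(0, head(lens, -1L) + gaps))
  stops <- starts + lens - 1L
  tx_end <- stops[n_ex]
  if (strand == "+") {
    cds_start <- tx_start + utr5; cds_end <- tx_end - utr3
  } else {
    cds_start <- tx_start + utr3; cds_end <- tx_end - utr5
  }
  gene_model(gene_id, chrom, strand, cbind(starts, stops),
             cds_start, cds_end)
}

#' Generate the synthetic gene annotation and truth skeleton
#'
#' Places genes left to right with 6-10 kbp gaps (so neighboring promoter
#' windows never collide), realizes each planted 5' UTR length exactly
#' within the 5'-terminal exon, and constructs the requested nested
#' antisense pair. Deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `genes` (named list of [gene_model()]) and `truth`,
#'   a `synthetic_truth` list whose `genes` table records per gene the
#'   placement, planted TSS position and 5' UTR length, and whose
#'   `nested` table records the planted nested exon.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 1L, {
    n <- config$n_genes
    ids <- sprintf("G%02d", seq_len(n))
    n_minus <- round(config$strand_mix * n)
    strands <- sample(c(rep("-", n_minus), rep("+", n - n_minus)))
    utr5 <- if (!is.null(config$tss_offsets))
      rep_len(as.numeric(config$tss_offsets), n)
      else sample(config$utr5_range[1]:config$utr5_range[2], n,
                  replace = TRUE)
    utr3 <- sample(config$utr3_range[1]:config$utr3_range[2], n,
                   replace = TRUE)
    n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], n,
                   replace = TRUE)

    nested_mode <- if (is.null(config$nested_exon_spec)) "none"
                   else if (identical(config$nested_exon_spec, "auto")) "auto"
                   else "explicit"
    genes <- vector("list", n); names(genes) <- ids
    cursor <- 3000
    nested_truth <- data.table(guest = character(), host = character(),
                               exon_start = numeric(), exon_stop = numeric(),
                               strand_relation = character())

    if (nested_mode == "explicit") {
      ns <- config$nested_exon_spec
      hs <- if (is.null(ns$host_strand)) "-" else ns$host_strand
      gs <- if (is.null(ns$guest_strand)) "+" else ns$guest_strand
      host_id <- ids[n]; guest_id <- ids[n - 1L]
      span <- ns$host_span; ge <- ns$guest_exon
      genes[[host_id]] <- gene_model(host_id, config$chrom, hs,
                                     cbind(span[1], span[2]),
                                     span[1], span[2])
      ex1 <- c(max(1, ge[1] - 120), ge[1] - 61)
      if (ex1[1] >= ex1[2])
        stop("placement error: no room for the guest's upstream exon")
      genes[[guest_id]] <- gene_model(guest_id, config$chrom, gs,
                                      rbind(ex1, ge), ex1[1], ge[2])
      strands[c(n - 1L, n)] <- c(gs, hs)
      utr5[c(n - 1L, n)] <- 0
      cursor <- max(span[2], ge[2]) + sample(6000:10000, 1L)
      nested_truth <- data.table(
        guest = guest_id, host = host_id,
        exon_start = ge[1], exon_stop = ge[2],
        strand_relation = if (gs == hs) "same" else "opposite")
    }

    regular <- if (nested_mode == "explicit") seq_len(max(0, n - 2L))
               else seq_len(n)
    auto_pair <- if (nested_mode == "auto") c(n - 1L, n) else integer()
    for (i in setdiff(regular, auto_pair)) {
      g <- .build_gene(ids[i], config$chrom, strands[i], cursor, n_ex[i],
                       utr5[i], utr3[i], config$exon_length,
                       config$intron_length)
      genes[[ids[i]]] <- g
      cursor <- gene_span(g)[2] + sample(6000:10000, 1L)
    }
    if (nested_mode == "auto") {
      # guest on '+', host on '-' overlapping only the guest's last exon
      strands[n - 1L] <- "+"; strands[n] <- "-"
      guest <- .build_gene(ids[n - 1L], config$chrom, "+", cursor,
                           n_ex[n - 1L], utr5[n - 1L], utr3[n - 1L],
                           config$exon_length, config$intron_length)
      genes[[ids[n - 1L]]] <- guest
      last_ex <- guest$exons[nrow(guest$exons), ]
      host_start <- last_ex["start"] - 150
      host <- .build_gene(ids[n], config$chrom, "-", host_start, n_ex[n],
                          utr5[n], utr3[n], config$exon_length,
                          config$intron_length)
      genes[[ids[n]]] <- host
      if (gene_span(host)[2] <= last_ex["stop"])
        stop("placement error: host span does not cover the guest exon")
      cursor <- gene_span(host)[2] + sample(6000:10000, 1L)
      nested_truth <- data.table(
        guest = ids[n - 1L], host = ids[n],
        exon_start = last_ex[["start"]], exon_stop = last_ex[["stop"]],
        strand_relation = "opposite")
    }
    if (cursor > config$chrom_length)
      stop("placement error: ", n, " genes do not fit in ",
           config$chrom_length, " bp")

    gt <- rbindlist(lapply(seq_len(n), function(i) {
      g <- genes[[ids[i]]]
      data.table(gene_id = ids[i], chrom = g$chrom, strand = g$strand,
                 tx_start = gene_span(g)[1], tx_end = gene_span(g)[2],
                 cds_start = g$cds_start, cds_end = g$cds_end,
                 five_prime_pos = g$five_prime_pos,
                 tss_pos = transcript_start(g),
                 utr5 = abs(transcript_start(g) - g$five_prime_pos))
    }))
    truth <- structure(
      list(genes = gt, nested = nested_truth,
           het_loci = NULL, ase = NULL, expression_weights = NULL,
           isoforms = NULL),
      class = "synthetic_truth")
    list(genes = genes, truth = truth)
  })
}

#' Generate WGS allele-count tables with planted genotypes
#'
#' Plants `snp_density` SNPs per kbp along the chromosome, assigns each
#' locus a true genotype per animal (heterozygous with probability
#' `het_fraction`, otherwise homozygous-alternative), and draws per-allele
#' read counts: at heterozygous loci allele A is binomial with the
#' configured reference bias; homozygous loci yield reads of one allele
#' only unless `error_rate > 0`.
#'
#' @param annotation Output of [generate_annotation()].
#' @param config A [synthetic_config()].
#' @return List with `wgs_counts` (data.table: `animal`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`, `count_a`, `count_b`, `source`) and the
#'   updated `truth` (adds the `het_loci` table with true genotypes).
#' @export
generate_wgs_counts <- function(annotation, config) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- annotation$truth
  withr::with_seed(config$seed + 2L, {
    n_snp <- max(1L, round(config$snp_density * config$chrom_length / 1000))
    pos <- sort(sample.int(config$chrom_length, n_snp))
    nts <- c("A", "C", "G", "T")
    allele_a <- sample(nts, n_snp, replace = TRUE)
    allele_b <- vapply(allele_a, function(a)
      sample(setdiff(nts, a), 1L), "")
    loci <- rbindlist(lapply(config$animals, function(an) {
      zyg <- ifelse(runif(n_snp) < config$het_fraction, "het", "hom_alt")
      data.table(animal = an, chrom = config$chrom, pos = pos,
                 allele_a = allele_a, allele_b = allele_b,
                 zygosity_true = zyg)
    }))
    depth <- rpois(nrow(loci), config$wgs_depth_mean)
    het <- loci$zygosity_true == "het"
    ca <- integer(nrow(loci))
    ca[het] <- rbinom(sum(het), depth[het], config$reference_bias)
    if (config$error_rate > 0)
      ca[!het] <- rbinom(sum(!het), depth[!het], config$error_rate)
    counts <- data.table(
      animal = loci$animal, chrom = loci$chrom, pos = loci$pos,
      allele_a = loci$allele_a, allele_b = loci$allele_b,
      count_a = ca, count_b = depth - ca, source = "wgs")
    truth$het_loci <- loci
    list(wgs_counts = counts, truth = truth)
  })
}

#' Generate per-tissue RNA allele counts and per-gene read totals
#'
#' At each true heterozygous locus and tissue, allele-A counts are
#' binomial with the planted allele fraction (ASE loci) or the WGS
#' reference bias (all others); homozygous loci yield one allele only.
#' Per-gene totals are multinomial over gamma-distributed gene weights
#' shared across technologies, so each (tissue, technology) library sums
#' exactly to its configured size.
#'
#' @param annotation Output of [generate_annotation()].
#' @param truth Truth from [generate_wgs_counts()] (needs `het_loci`).
#' @param config A [synthetic_config()].
#' @return List with `rna_counts` (data.table: `animal`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`, `tissue`, `count_a`, `count_b`, `source`),
#'   `gene_totals` (data.table: `gene`, `tissue`, `technology`,
#'   `mapped_reads`, `library_total`) and updated `truth` (adds `ase` and
#'   `expression_weights`).
#' @export
generate_rnaseq_counts <- function(annotation, truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(truth$het_loci))
    stop("truth lacks het_loci; run generate_wgs_counts() first")
  withr::with_seed(config$seed + 3L, {
    het <- truth$het_loci[truth$het_loci$zygosity_true == "het", ]
    # planted ASE map: explicit, or first n_ase_loci het loci of animal 1
    if (!is.null(config$ase_effects)) {
      ase <- as.data.table(config$ase_effects)
      if (!all(c("pos", "tissue", "fraction") %in% names(ase)))
        stop("ase_effects needs columns pos, tissue, fraction")
      if (!all(ase$pos %in% het$pos))
        stop("ASE effect planted at non-heterozygous locus")
    } else {
      p1 <- unique(het[het$animal == config$animals[1L], pos])
      take <- head(p1, config$n_ase_loci)
      ase <- data.table::CJ(pos = take, tissue = config$tissues)
      ase[, fraction := config$ase_fraction]
    }

    all_loci <- truth$het_loci
    rna <- rbindlist(lapply(config$tissues, function(ts) {
      d <- rpois(nrow(all_loci), config$rna_depth_mean)
      f <- rep(config$reference_bias, nrow(all_loci))
      eff <- ase[ase$tissue == ts, ]
      idx <- match(all_loci$pos, eff$pos)
      f[!is.na(idx)] <- eff$fraction[idx[!is.na(idx)]]
      is_het <- all_loci$zygosity_true == "het"
      ca <- integer(nrow(all_loci))
      ca[is_het] <- rbinom(sum(is_het), d[is_het], f[is_het])
      data.table(animal = all_loci$animal, chrom = all_loci$chrom,
                 pos = all_loci$pos, allele_a = all_loci$allele_a,
                 allele_b = all_loci$allele_b, tissue = ts,
                 count_a = ca, count_b = d - ca, source = "rna_seq")
    }))

    gene_ids <- truth$genes$gene_id
    w <- data.table::CJ(gene = gene_ids, tissue = config$tissues,
                        sorted = FALSE)
    w[, weight := rgamma(.N, shape = 2, rate = 2)]
    totals <- rbindlist(lapply(seq_len(nrow(config$library_sizes)),
                               function(i) {
      ts <- config$library_sizes$tissue[i]
      tech <- config$library_sizes$technology[i]
      lib <- config$library_sizes$library_total[i]
      ww <- w[w$tissue == ts, ]
      cnt <- as.vector(rmultinom(1L, lib, ww$weight))
      data.table(gene = ww$gene, tissue = ts, technology = tech,
                 mapped_reads = cnt, library_total = lib)
    }))
    truth$ase <- ase
    truth$expression_weights <- w
    list(rna_counts = rna, gene_totals = totals, truth = truth)
  })
}

#' Generate strand-split CAGE 5'-tag coverage
#'
#' Each expressed gene receives a unimodal tag cluster at its planted TSS:
#' a discretized symmetric triangular kernel of half-width
#' `cage_peak_width` whose realized counts are the rounded expected
#' counts, so the mode is exactly the planted TSS and the support is
#' finite. Background noise (Poisson per position) is off by default.
#'
#' @param annotation Output of [generate_annotation()].
#' @param truth Current truth list.
#' @param config A [synthetic_config()].
#' @return data.table with columns `chrom`, `pos`, `strand`, `tag_count`.
#' @export
generate_cage_coverage <- function(annotation, truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 4L, {
    w <- config$cage_peak_width
    kern <- (w + 1) - abs(seq(-w, w))
    rows <- lapply(annotation$genes, function(g) {
      if (g$gene_id %in% config$cage_silent_genes) return(NULL)
      center <- transcript_start(g)
      tags <- round(config$cage_tags_per_gene * kern / sum(kern))
      keep <- tags > 0
      data.table(chrom = g$chrom, pos = center + seq(-w, w)[keep],
                 strand = g$strand, tag_count = tags[keep])
    })
    cov <- rbindlist(Filter(Negate(is.null), rows))
    if (config$cage_noise > 0) {
      npos <- sample.int(config$chrom_length,
                         max(1L, round(config$chrom_length / 1000)))
      noise <- data.table(
        chrom = config$chrom, pos = npos,
        strand = sample(c("+", "-"), length(npos), replace = TRUE),
        tag_count = rpois(length(npos), config$cage_noise))
      cov <- rbind(cov, noise[noise$tag_count > 0, ])
    }
    cov <- cov[, .(tag_count = sum(tag_count)), by = .(chrom, pos, strand)]
    setorder(cov, chrom, strand, pos)
    cov[]
  })
}

# default isoform plan: a known chain per gene, plus structural variants
# cycled over genes with enough introns, plus one retention-dependency pair
.plan_isoforms <- function(annotation, config) {
  ids <- names(annotation$genes)
  n_introns <- vapply(annotation$genes, function(g) nrow(g$exons) - 1L, 0L)
  plan <- data.table(gene = ids, category = "known", param = NA_real_)
  eligible <- ids[n_introns >= 3L]
  pick <- function(k, off) eligible[(seq_len(k) - 1L + off) %%
                                    length(eligible) + 1L]
  if (length(eligible) >= 4L) {
    plan <- rbind(plan,
      data.table(gene = pick(3L, 0L), category = "novel_junction",
                 param = 30),
      data.table(gene = pick(3L, 3L), category = "intron_retention",
                 param = 2),
      data.table(gene = pick(3L, 6L), category = "novel_terminal",
                 param = 600),
      # dependency pair on one gene: retain {2} and {2,3}
      data.table(gene = rep(pick(1L, 9L), 2L),
                 category = "intron_retention", param = c(2, 23)))
  }
  plan
}

.retained_from_param <- function(param) {
  if (param == 23) c(2L, 3L) else as.integer(param)
}

# realize one planted category as an exon chain
.realize_isoform <- function(gene, category, param) {
  ex <- gene$exons
  n <- nrow(ex)
  if (category == "known") return(ex)
  if (category == "novel_junction") {
    # move the donor of the first intron by `param` bp into the intron
    if (n < 2L) stop("novel_junction needs >= 2 exons in ", gene$gene_id)
    gap <- ex[2L, "start"] - ex[1L, "stop"] - 1
    if (param >= gap) stop("junction shift exceeds intron length")
    ex[1L, "stop"] <- ex[1L, "stop"] + param
    return(ex)
  }
  if (category == "intron_retention") {
    ret <- .retained_from_param(param)
    if (any(ret >= n)) stop("retained intron index outside gene ",
                            gene$gene_id)
    drop <- sort(ret, decreasing = TRUE)
    for (j in drop) {  # fuse exons j and j+1 across retained intron j
      ex[j, "stop"] <- ex[j + 1L, "stop"]
      ex <- ex[-(j + 1L), , drop = FALSE]
    }
    return(ex)
  }
  if (category == "novel_terminal") {
    # extend the transcription 5' end beyond the terminal fuzz window
    if (gene$strand == "+") {
      ex[1L, "start"] <- ex[1L, "start"] - param
      if (ex[1L, "start"] < 1) stop("terminal extension leaves chromosome")
    } else {
      ex[n, "stop"] <- ex[n, "stop"] + param
    }
    return(ex)
  }
  stop("unknown planted category: ", category)
}

#' Generate long-read isoform chains and junction-spanning read counts
#'
#' Realizes each planted isoform category as an exon chain: `known`
#' (reference chain), `novel_junction` (first splice donor moved `param`
#' bp), `intron_retention` (reference intron(s) left unspliced; `param`
#' 2 retains intron 2, `param` 23 the dependent pair \{2,3\}), and
#' `novel_terminal` (5'-terminal exon extended `param` bp, junctions
#' untouched). Every junction of every emitted chain receives
#' `junction_read_depth` short-read support, so multi-evidence holds on
#' the noise-free fixture. The default plan plants a known chain for
#' every gene plus three of each variant category and one
#' retention-dependency pair (chains retaining \{2\} and \{2,3\}).
#'
#' @param annotation Output of [generate_annotation()].
#' @param truth Current truth list.
#' @param config A [synthetic_config()].
#' @return List with `chains` (list of [isoform_chain()]),
#'   `junction_counts` (data.table: `chrom`, `intron_start`,
#'   `intron_stop`, `strand`, `reads`) and updated `truth` (adds the
#'   `isoforms` category table).
#' @export
generate_isoform_reads <- function(annotation, truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 5L, {
    plan <- if (!is.null(config$planted_isoforms))
      as.data.table(config$planted_isoforms)
      else .plan_isoforms(annotation, config)
    plan[, isoform_id := paste0(gene, ".iso", seq_len(.N)), by = gene]
    chains <- lapply(seq_len(nrow(plan)), function(i) {
      g <- annotation$genes[[plan$gene[i]]]
      if (is.null(g)) stop("planted isoform on unknown gene ", plan$gene[i])
      ex <- .realize_isoform(g, plan$category[i], plan$param[i])
      span <- gene_span(g)
      if (plan$category[i] != "novel_terminal" &&
          (ex[1L, "start"] < span[1L] || ex[nrow(ex), "stop"] > span[2L]))
        stop("planted isoform exons outside gene span for ", plan$gene[i])
      isoform_chain(plan$isoform_id[i], g$gene_id, g$chrom, g$strand, ex,
                    source = "long_read",
                    tissues = sample(config$tissues,
                                     sample(1:min(3, length(config$tissues)),
                                            1L)))
    })
    jc <- rbindlist(lapply(chains, function(ch) {
      j <- intron_chain(ch)
      if (nrow(j) == 0L) return(NULL)
      data.table(chrom = ch$chrom, intron_start = j[, "start"],
                 intron_stop = j[, "stop"], strand = ch$strand)
    }))
    jc <- unique(jc)
    jc[, reads := config$junction_read_depth]
    plan[, retained := vapply(seq_len(.N), function(i)
      if (category[i] == "intron_retention")
        paste(.retained_from_param(param[i]), collapse = ",")
      else "", "")]
    truth$isoforms <- plan[, .(isoform_id, gene, category, retained)]
    list(chains = chains, junction_counts = jc, truth = truth)
  })
}

#' Simulate the full multi-assay dataset to disk
#'
#' Runs every generator and writes `annotation.gff3`, `wgs_counts.tsv`,
#' `rna_counts.tsv`, `gene_totals.tsv`, `cage_coverage.tsv`,
#' `isoforms.bed12`, `junction_counts.tsv` and `truth.json` under
#' `out_dir`. Identical configs (including seed) produce byte-identical
#' outputs.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with all in-memory stage outputs (`genes`,
#'   `truth`, `wgs_counts`, `rna_counts`, `gene_totals`, `cage_coverage`,
#'   `chains`, `junction_counts`) plus `paths`.
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(config)
  wgs <- generate_wgs_counts(ann, config)
  rna <- generate_rnaseq_counts(ann, wgs$truth, config)
  cov <- generate_cage_coverage(ann, rna$truth, config)
  iso <- generate_isoform_reads(ann, rna$truth, config)
  truth <- iso$truth
  truth$ase <- rna$truth$ase
  truth$expression_weights <- rna$truth$expression_weights

  paths <- file.path(out_dir, c(
    annotation = "annotation.gff3", wgs = "wgs_counts.tsv",
    rna = "rna_counts.tsv", totals = "gene_totals.tsv",
    cage = "cage_coverage.tsv", bed = "isoforms.bed12",
    junctions = "junction_counts.tsv", truth = "truth.json"))
  names(paths) <- c("annotation", "wgs", "rna", "totals", "cage", "bed",
                    "junctions", "truth")
  write_gff3(ann$genes, paths["annotation"])
  fwrite(wgs$wgs_counts, paths["wgs"], sep = "\t")
  fwrite(rna$rna_counts, paths["rna"], sep = "\t")
  fwrite(rna$gene_totals, paths["totals"], sep = "\t")
  fwrite(cov, paths["cage"], sep = "\t")
  write_bed12(iso$chains, paths["bed"])
  fwrite(iso$junction_counts, paths["junctions"], sep = "\t")
  jsonlite::write_json(lapply(unclass(truth), as.data.frame),
                       paths["truth"], digits = NA)
  invisible(list(genes = ann$genes, truth = truth,
                 wgs_counts = wgs$wgs_counts, rna_counts = rna$rna_counts,
                 gene_totals = rna$gene_totals, cage_coverage = cov,
                 chains = iso$chains, junction_counts = iso$junction_counts,
                 paths = paths))
}
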