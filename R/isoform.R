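#' Intron chain (junction list) of an exon chain
#'
#' The ordered list of introns between consecutive exons, each given
#' 1-based inclusive as `(prev_exon_stop + 1, next_exon_start - 1)`.
#' Identity of intron chains defines isoform equivalence up to
#' terminal-exon length.
#'
#' @param exons An [isoform_chain()], a [gene_model()], or a two-column
#'   matrix of sorted non-overlapping exon `start`,`stop`.
#' @return Two-column matrix (`start`, `stop`) with one row per intron;
#'   zero rows for a single-exon chain.
#' @export
#' @examples
#' intron_chain(rbind(c(1, 100), c(201, 300)))  # one intron: 101-200
intron_chain <- function(exons) {
  if (inherits(exons, "isoform_chain") || inherits(exons, "gene_model"))
    exons <- exons$exons
  exons <- as.matrix(exons)
  if (nrow(exons) > 0L) {
    if (any(exons[, 1L] > exons[, 2L])) stop("exon start > stop")
    if (nrow(exons) > 1L &&
        any(exons[-1L, 1L] <= exons[-nrow(exons), 2L] + 1))
      stop("exons must be sorted with gaps >= 1 bp")
  }
  if (nrow(exons) < 2L)
    return(matrix(numeric(), ncol = 2L,
                  dimnames = list(NULL, c("start", "stop"))))
  cbind(start = exons[-nrow(exons), 2L] + 1, stop = exons[-1L, 1L] - 1)
}

.junction_keys <- function(introns) {
  if (nrow(introns) == 0L) return(character())
  paste(introns[, 1L], introns[, 2L], sep = "-")
}

#' Per-junction short-read support
#'
#' A junction is supported when at least `min_reads` short reads span it;
#' chain-level multi-evidence requires every junction supported (vacuously
#' true for a single-exon chain).
#'
#' @param junctions Two-column matrix of introns ([intron_chain()]).
#' @param junction_counts data.frame/data.table with columns
#'   `intron_start`, `intron_stop`, `reads` (optionally `chrom`,
#'   `strand`; matching is by coordinates within one chromosome/strand
#'   context). Junctions absent from the table count as 0 reads.
#' @param min_reads Support threshold (default 2).
#' @return List with logical vector `supported` (one per junction) and
#'   flag `multi_evidence`.
#' @export
junction_support <- function(junctions, junction_counts, min_reads = 2) {
  jc <- as.data.table(junction_counts)
  if (nrow(jc) > 0 && any(jc$reads < 0)) stop("junction reads must be >= 0")
  keys <- .junction_keys(junctions)
  have <- if (nrow(jc)) setNames(jc$reads,
                                 paste(jc$intron_start, jc$intron_stop,
                                       sep = "-")) else numeric()
  counts <- ifelse(keys %in% names(have), have[keys], 0)
  supported <- counts >= min_reads
  list(supported = as.logical(supported),
       multi_evidence = all(supported))
}

#' Classify a long-read exon chain against reference isoforms
#'
#' Categories, checked in order:
#' \describe{
#'   \item{known}{some reference has an identical intron chain and both
#'     terminal ends differ by at most `terminal_fuzz` bp (a difference of
#'     exactly the fuzz is still known).}
#'   \item{intron_retention}{the candidate's intron chain is a proper
#'     subset of a reference's (identical coordinates for the introns it
#'     does splice), i.e. one or more reference introns are left
#'     unspliced; the retained reference-intron indices are reported.}
#'   \item{novel_terminal}{intron chain identical to a reference but a
#'     terminal end moved beyond the fuzz window — a UTR-only variant.
#'     Requires corroborating short-read evidence on every junction
#'     (`multi_evidence`); without it such chains cannot be distinguished
#'     from 5'-degraded RNA and are flagged `ambiguous_degradation`.}
#'   \item{novel_junction}{anything else (at least one novel splice
#'     site).}
#' }
#'
#' @param candidate An [isoform_chain()].
#' @param references List of reference [isoform_chain()] objects (same
#'   chromosome and strand). An empty list classifies every candidate
#'   `novel_junction` with a warning.
#' @param junction_counts Optional short-read junction-count table (see
#'   [junction_support()]); `NULL` disables the evidence requirement.
#' @param terminal_fuzz Terminal-end tolerance in bp (default 50).
#' @param min_junction_reads Support threshold (default 2).
#' @return List of class `isoform_classification`: `isoform_id`,
#'   `category`, `matched_reference`, `retained_introns` (integer
#'   indices into the matched reference's introns), `junction_supported`
#'   (logical per candidate junction, `NA` when no counts given) and
#'   `multi_evidence`.
#' @export
classify_isoform <- function(candidate, references, junction_counts = NULL,
                             terminal_fuzz = 50, min_junction_reads = 2) {
  stopifnot(inherits(candidate, "isoform_chain"))
  cand_j <- intron_chain(candidate)
  cand_keys <- .junction_keys(cand_j)
  cand_span <- c(candidate$exons[1L, "start"],
                 candidate$exons[nrow(candidate$exons), "stop"])

  if (!is.null(junction_counts)) {
    sup <- junction_support(cand_j, junction_counts, min_junction_reads)
    supported <- sup$supported
    multi_evidence <- sup$multi_evidence
  } else {
    supported <- rep(NA, nrow(cand_j))
    multi_evidence <- NA
  }

  result <- function(category, ref = NULL, retained = integer()) {
    structure(list(isoform_id = candidate$isoform_id, category = category,
                   matched_reference = if (is.null(ref)) NA_character_
                                       else ref$isoform_id,
                   retained_introns = retained,
                   junction_supported = supported,
                   multi_evidence = multi_evidence),
              class = "isoform_classification")
  }

  if (length(references) == 0L) {
    warning("empty reference set: candidate classified novel_junction")
    return(result("novel_junction"))
  }
  bad <- vapply(references, function(r)
    r$chrom != candidate$chrom || r$strand != candidate$strand, TRUE)
  if (any(bad))
    stop("candidate and references must share chromosome and strand")

  # deterministic, order-invariant reference preference
  ord <- order(vapply(references, `[[`, "", "isoform_id"))
  refs <- references[ord]
  ref_js <- lapply(refs, intron_chain)
  ref_keys <- lapply(ref_js, .junction_keys)
  ref_spans <- lapply(refs, function(r)
    c(r$exons[1L, "start"], r$exons[nrow(r$exons), "stop"]))

  identical_j <- vapply(ref_keys, function(k) identical(k, cand_keys), TRUE)
  term_diff <- vapply(ref_spans, function(s) max(abs(s - cand_span)), 0)

  hit <- which(identical_j & term_diff <= terminal_fuzz)
  if (length(hit)) return(result("known", refs[[hit[1L]]]))

  # retention: candidate splices a proper subset of a reference's introns
  for (i in seq_along(refs)) {
    rk <- ref_keys[[i]]
    if (length(rk) > length(cand_keys) && all(cand_keys %in% rk) &&
        term_diff[i] <= terminal_fuzz)
      return(result("intron_retention", refs[[i]],
                    retained = which(!(rk %in% cand_keys))))
  }

  hit <- which(identical_j)  # junctions match, terminal beyond fuzz
  if (length(hit)) {
    if (isFALSE(multi_evidence))
      return(result("ambiguous_degradation", refs[[hit[1L]]]))
    return(result("novel_terminal", refs[[hit[1L]]]))
  }
  result("novel_junction")
}

#' @export
print.isoform_classification <- function(x, ...) {
  cat(sprintf("<isoform_classification> %s: %s", x$isoform_id, x$category))
  if (!is.na(x$matched_reference))
    cat(" (vs ", x$matched_reference, ")", sep = "")
  if (length(x$retained_introns))
    cat("  retained introns:", paste(x$retained_introns, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Intron-retention implication table for one gene
#'
#' Across the gene's intron-retention chains, reports for every ordered
#' pair of observed retained introns `(a, b)` whether retention of `a`
#' always implies retention of `b` (e.g. chains retaining `{2}` and
#' `{2,3}` give `3 => 2` true but `2 => 3` false).
#'
#' @param classifications List of `isoform_classification` objects for
#'   one gene.
#' @return data.table with columns `intron_a`, `intron_b`, `implies`;
#'   zero rows when no chain retains an intron.
#' @export
retention_dependency <- function(classifications) {
  sets <- lapply(classifications, function(x)
    if (x$category == "intron_retention") x$retained_introns else NULL)
  sets <- Filter(Negate(is.null), sets)
  introns <- sort(unique(unlist(sets)))
  if (length(introns) == 0L)
    return(data.table(intron_a = integer(), intron_b = integer(),
                      implies = logical()))
  grid <- data.table::CJ(intron_a = introns, intron_b = introns)
  grid[, implies := vapply(seq_len(.N), function(i) {
    withA <- Filter(function(s) grid$intron_a[i] %in% s, sets)
    all(vapply(withA, function(s) grid$intron_b[i] %in% s, TRUE))
  }, TRUE)]
  grid[]
}

#' Detect guest exons nested within a host gene's span
#'
#' A hit is a guest exon lying fully inside the host gene's genomic span
#' (boundary-inclusive); partial overlaps are not hits. The host's full
#' span is used, matching the biology of an exon nested in a neighboring
#' gene's intron; set `host_exon_level = TRUE` to require containment
#' within a host exon instead.
#'
#' @param guest A [gene_model()]; its annotated exons are examined, plus
#'   the exons of any `chains` ([isoform_chain()] list) supplied.
#' @param host A [gene_model()] on the same chromosome.
#' @param chains Optional list of guest [isoform_chain()] objects.
#' @param host_exon_level Containment within host exons rather than the
#'   host span (default `FALSE`).
#' @return data.table with columns `guest_gene`, `host_gene`,
#'   `exon_start`, `exon_stop`, `strand_relation` (`"same"`/`"opposite"`);
#'   zero rows when nothing is nested.
#' @export
detect_nested_exons <- function(guest, host, chains = NULL,
                                host_exon_level = FALSE) {
  stopifnot(inherits(guest, "gene_model"), inherits(host, "gene_model"))
  if (guest$chrom != host$chrom)
    stop("guest and host must be on the same chromosome")
  if (guest$gene_id == host$gene_id) stop("guest and host must differ")
  ex <- guest$exons
  if (!is.null(chains))
    ex <- unique(do.call(rbind, c(list(ex), lapply(chains, `[[`, "exons"))))
  if (host_exon_level) {
    contained <- vapply(seq_len(nrow(ex)), function(i)
      any(ex[i, 1L] >= host$exons[, "start"] &
          ex[i, 2L] <= host$exons[, "stop"]), TRUE)
  } else {
    span <- gene_span(host)
    contained <- ex[, 1L] >= span[1L] & ex[, 2L] <= span[2L]
  }
  hits <- ex[contained, , drop = FALSE]
  data.table(
    guest_gene = rep(guest$gene_id, nrow(hits)),
    host_gene = rep(host$gene_id, nrow(hits)),
    exon_start = hits[, 1L], exon_stop = hits[, 2L],
    strand_relation = rep(
      if (guest$strand == host$strand) "same" else "opposite", nrow(hits)))
}
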