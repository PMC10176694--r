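#' CN-variable genes: genes mostly covered by CNVRs
#'
#' For each gene, the covered fraction is the base-pair size of the union
#' of all CNVR intervals intersected with the gene span, divided by the
#' span. Genes with fraction strictly greater than \code{min_frac} are
#' returned (the "completely or largely overlapped" rule).
#'
#' @param genes data.frame with columns gene_id, chrom, start, end.
#' @param cnvrs a \code{cnvr_set} or data.frame with chrom, start, end.
#' @param min_frac strict lower bound on covered fraction (default 0.5).
#' @return data.frame (gene_id, span_bp, covered_bp, fraction) for genes
#'   passing the threshold, sorted by decreasing fraction.
#' @export
cn_variable_genes <- function(genes, cnvrs, min_frac = 0.5) {
  assert_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
  if (nrow(genes) == 0L) {
    return(data.frame(gene_id = character(), span_bp = integer(),
                      covered_bp = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  gene_gr <- gr0(genes$chrom, genes$start, genes$end)
  cnvr_union <- if (nrow(cnvrs) > 0L) {
    GenomicRanges::reduce(gr0(cnvrs$chrom, cnvrs$start, cnvrs$end))
  } else GenomicRanges::GRanges()
  cov <- rep(0L, nrow(genes))
  if (length(cnvr_union) > 0L) {
    hits <- GenomicRanges::findOverlaps(gene_gr, cnvr_union)
    if (length(hits) > 0L) {
      inter <- GenomicRanges::pintersect(
        gene_gr[S4Vectors::queryHits(hits)],
        cnvr_union[S4Vectors::subjectHits(hits)])
      w <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(hits),
                  sum)
      cov[as.integer(names(w))] <- as.integer(w)
    }
  }
  span <- genes$end - genes$start
  frac <- cov / span
  out <- data.frame(gene_id = genes$gene_id, span_bp = span,
                    covered_bp = cov, fraction = frac,
                    stringsAsFactors = FALSE)
  out <- out[out$fraction > min_frac, , drop = FALSE]
  out <- out[order(-out$fraction, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# build the disjoint feature-class partition of a genome:
# CDS > exon(non-CDS) > intron > flank_upstream > flank_downstream >
# intergenic; every base belongs to exactly one class
feature_partition <- function(genome, flank_bp = 2000L) {
  chroms <- genome$chromosomes
  genome_gr <- gr0(chroms$chrom, rep(0L, nrow(chroms)), chroms$length)
  GenomeInfoDb::seqlevels(genome_gr) <- chroms$chrom
  GenomeInfoDb::seqlengths(genome_gr) <- chroms$length
  lift <- function(gr) {
    GenomeInfoDb::seqlevels(gr) <- chroms$chrom
    GenomeInfoDb::seqlengths(gr) <- chroms$length
    gr
  }
  g <- genome$genes
  empty <- GenomicRanges::GRanges(seqlengths = setNames(chroms$length,
                                                        chroms$chrom))
  gene_gr <- if (nrow(g)) lift(GenomicRanges::reduce(
    gr0(g$chrom, g$start, g$end))) else empty
  exon_gr <- if (nrow(genome$exons)) lift(GenomicRanges::reduce(
    gr0(genome$exons$chrom, genome$exons$start, genome$exons$end))) else
    empty
  cds_gr <- if (nrow(genome$cds)) lift(GenomicRanges::reduce(
    gr0(genome$cds$chrom, genome$cds$start, genome$cds$end))) else empty
  intron_gr <- GenomicRanges::setdiff(gene_gr, exon_gr)
  flank_up <- flank_down <- empty
  if (nrow(g)) {
    up_s <- ifelse(g$strand == "+", pmax(0L, g$start - flank_bp), g$end)
    up_e <- ifelse(g$strand == "+", g$start,
                   pmin(chroms$length[match(g$chrom, chroms$chrom)],
                        g$end + flank_bp))
    dn_s <- ifelse(g$strand == "+", g$end, pmax(0L, g$start - flank_bp))
    dn_e <- ifelse(g$strand == "+",
                   pmin(chroms$length[match(g$chrom, chroms$chrom)],
                        g$end + flank_bp), g$start)
    keep_u <- up_e > up_s; keep_d <- dn_e > dn_s
    flank_up <- lift(GenomicRanges::reduce(
      gr0(g$chrom[keep_u], up_s[keep_u], up_e[keep_u])))
    flank_down <- lift(GenomicRanges::reduce(
      gr0(g$chrom[keep_d], dn_s[keep_d], dn_e[keep_d])))
    flank_up <- GenomicRanges::setdiff(flank_up, gene_gr)
    # precedence: upstream flank wins where up/down flanks of
    # neighbouring genes overlap
    flank_down <- GenomicRanges::setdiff(
      GenomicRanges::setdiff(flank_down, gene_gr), flank_up)
  }
  intergenic <- GenomicRanges::setdiff(
    GenomicRanges::setdiff(GenomicRanges::setdiff(genome_gr, gene_gr),
                           flank_up), flank_down)
  list(CDS = cds_gr,
       exon = exon_gr,
       intron = intron_gr,
       gene_body = gene_gr,
       flank_upstream = flank_up,
       flank_downstream = flank_down,
       intergenic = intergenic)
}

#' Base-pair impact of CNVs on genomic feature classes
#'
#' Calls are first unioned per event type ("non-overlapping CNVs"); then,
#' for each feature class, the percentage of its bases covered by the
#' deletion union and the duplication union is reported. The classes
#' CDS/exon/gene_body overlap by construction; introns are gene bodies
#' minus exons, flanks are \code{flank_bp} windows beside genes (minus any
#' gene bodies; the upstream flank wins where flanks collide) and
#' intergenic is everything else, so exon + intron + flanks + intergenic
#' partitions the genome.
#'
#' @param genome a \code{\link{genome_model}}.
#' @param calls CNV call data.frame (accession, chrom, start, end, svtype).
#' @param flank_bp flank window size in bp (default 2000).
#' @return data.frame with one row per feature class: feature_class,
#'   total_bp, del_bp, dup_bp, del_pct, dup_pct.
#' @export
feature_impact <- function(genome, calls, flank_bp = 2000L) {
  parts <- feature_partition(genome, flank_bp)
  del_gr <- dup_gr <- GenomicRanges::GRanges()
  if (nrow(calls) > 0L) {
    del <- calls[calls$svtype == "DEL", , drop = FALSE]
    dup <- calls[calls$svtype == "DUP", , drop = FALSE]
    if (nrow(del)) del_gr <- GenomicRanges::reduce(
      gr0(del$chrom, del$start, del$end))
    if (nrow(dup)) dup_gr <- GenomicRanges::reduce(
      gr0(dup$chrom, dup$start, dup$end))
  }
  cov_bp <- function(class_gr, cnv_gr) {
    if (length(class_gr) == 0L || length(cnv_gr) == 0L) return(0)
    sum(as.numeric(GenomicRanges::width(
      GenomicRanges::intersect(class_gr, cnv_gr,
                               ignore.strand = TRUE))))
  }
  out <- do.call(rbind, lapply(names(parts), function(cl) {
    total <- sum(as.numeric(GenomicRanges::width(parts[[cl]])))
    dbp <- cov_bp(parts[[cl]], del_gr)
    pbp <- cov_bp(parts[[cl]], dup_gr)
    data.frame(feature_class = cl, total_bp = total, del_bp = dbp,
               dup_bp = pbp,
               del_pct = if (total > 0) 100 * dbp / total else NA_real_,
               dup_pct = if (total > 0) 100 * pbp / total else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Windowed feature density along the genome
#'
#' Counts features per genomic window; a feature is assigned to a window
#' when its start coordinate lies inside it. Supports non-overlapping
#' windows (\code{step_bp == window_bp}, the default) and sliding windows
#' (\code{step_bp < window_bp}). Only windows that fit entirely on the
#' chromosome are emitted (a chromosome shorter than one window yields a
#' single clipped window).
#'
#' @param features data.frame with columns chrom, start (0-based).
#' @param genome a \code{\link{genome_model}} (for chromosome sizes).
#' @param window_bp window size (default 1 Mb).
#' @param step_bp step between window starts (default = window size).
#' @return data.frame: chrom, win_start, win_end, count.
#' @export
window_density <- function(features, genome, window_bp = 1000000L,
                           step_bp = window_bp) {
  assert_columns(features, c("chrom", "start"), "features")
  stopifnot(window_bp >= 1, step_bp >= 1)
  out <- lapply(seq_len(nrow(genome$chromosomes)), function(ci) {
    ch <- genome$chromosomes$chrom[ci]
    L <- genome$chromosomes$length[ci]
    if (L < window_bp) {
      starts <- 0
    } else {
      starts <- step_bp * (0:((L - window_bp) %/% step_bp))
    }
    ends <- pmin(starts + window_bp, L)
    pos <- features$start[features$chrom == ch]
    count <- vapply(seq_along(starts), function(w) {
      sum(pos >= starts[w] & pos < ends[w])
    }, 1L)
    data.frame(chrom = ch, win_start = starts, win_end = ends,
               count = count, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two aligned window-density tracks
#'
#' @param track_a,track_b equal-length numeric vectors (or data.frames
#'   from \code{\link{window_density}}, aligned window for window).
#' @return list with \code{r} and \code{p_value} (two-sided).
#' @export
density_correlation <- function(track_a, track_b) {
  a <- if (is.data.frame(track_a)) track_a$count else track_a
  b <- if (is.data.frame(track_b)) track_b$count else track_b
  if (length(a) != length(b)) stop("tracks must have equal length")
  ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Term enrichment by one-sided Fisher's exact test with BH correction
#'
#' For each term, a 2x2 table of term membership against study membership
#' over the gene universe is tested one-sided for enrichment
#' (hypergeometric upper tail); p-values are Benjamini-Hochberg adjusted
#' and terms with adjusted p below \code{alpha} are flagged significant.
#' Terms with no genes in the universe are skipped and counted in the
#' \code{"skipped"} attribute.
#'
#' @param study_genes character vector, a subset of \code{universe}.
#' @param universe character vector of all genes considered.
#' @param term_map data.frame with columns \code{gene}, \code{term}, or a
#'   named list of gene-id vectors.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return data.frame: term, n_term, n_study, n_overlap, p_value, p_adj,
#'   significant; sorted by p-value.
#' @export
term_enrichment <- function(study_genes, universe, term_map,
                            alpha = 0.05) {
  study_genes <- unique(study_genes)
  universe <- unique(universe)
  if (!all(study_genes %in% universe)) {
    stop("study_genes must be a subset of the universe")
  }
  if (is.data.frame(term_map)) {
    assert_columns(term_map, c("gene", "term"), "term_map")
    term_map <- split(term_map$gene, term_map$term)
  }
  term_map <- lapply(term_map, unique)
  in_universe <- lapply(term_map, intersect, universe)
  skipped <- names(term_map)[lengths(in_universe) == 0L]
  keep <- lengths(in_universe) > 0L
  terms <- names(term_map)[keep]
  Nu <- length(universe); ns <- length(study_genes)
  rows <- lapply(terms, function(tm) {
    tg <- in_universe[[tm]]
    k <- length(intersect(tg, study_genes))
    K <- length(tg)
    tab <- matrix(c(k, K - k, ns - k, Nu - K - ns + k), nrow = 2L)
    p <- fisher.test(tab, alternative = "greater")$p.value
    data.frame(term = tm, n_term = K, n_study = ns, n_overlap = k,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(), n_term = integer(),
                      n_study = integer(), n_overlap = integer(),
                      p_value = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  } else {
    out$p_adj <- p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adj < alpha
    out <- out[order(out$p_value, out$term), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  out
}

#' Fraction of CNVRs overlapping a TE track
#'
#' @param cnvrs \code{cnvr_set} or data.frame with chrom, start, end.
#' @param tes data.frame with chrom, start, end (0-based half-open).
#' @return fraction of CNVRs with at least 1 bp of TE overlap.
#' @export
te_overlap_fraction <- function(cnvrs, tes) {
  if (nrow(cnvrs) == 0L) return(NA_real_)
  if (nrow(tes) == 0L) return(0)
  hits <- GenomicRanges::findOverlaps(
    gr0(cnvrs$chrom, cnvrs$start, cnvrs$end),
    gr0(tes$chrom, tes$start, tes$end))
  length(unique(S4Vectors::queryHits(hits))) / nrow(cnvrs)
}
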