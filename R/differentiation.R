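# population variance (denominator N, not N-1): the Vst formula weights
# group variances by group sizes, which is only internally consistent
# with N-denominator variances
pop_var <- function(x) mean((x - mean(x))^2)

#' Vst copy-number differentiation between two populations
#'
#' The Vst statistic compares the total copy-number variance across both
#' populations with the size-weighted average of the within-population
#' variances:
#' \deqn{V_{st} = \frac{V_{total} - (V_1 N_1 + V_2 N_2)/N_{total}}{V_{total}}}
#' It runs from 0 (no differentiation) to 1 (complete differentiation);
#' small negative values are possible when within-group variance exceeds
#' the total and are reported unclamped. Vst is undefined (NA) when the
#' pooled variance is zero.
#'
#' @param cn_cultivars,cn_wild numeric CN vectors for the two groups; both
#'   non-empty and finite.
#' @param gene_id optional id copied into the record.
#' @return one-row data.frame of class \code{vst_record}: gene_id,
#'   v_total, v_cultivars, v_wild, n_cultivars, n_wild, n_total, vst.
#' @examples
#' vst(c(2, 2), c(4, 4))$vst   # 1: complete differentiation
#' vst(c(2, 4), c(2, 4))$vst   # 0: identical distributions
#' @export
vst <- function(cn_cultivars, cn_wild, gene_id = NA_character_) {
  if (length(cn_cultivars) == 0L || length(cn_wild) == 0L) {
    stop("both groups must be non-empty")
  }
  if (!all(is.finite(cn_cultivars)) || !all(is.finite(cn_wild))) {
    stop("copy numbers must be finite")
  }
  n1 <- length(cn_cultivars); n2 <- length(cn_wild); nt <- n1 + n2
  v1 <- pop_var(cn_cultivars); v2 <- pop_var(cn_wild)
  vt <- pop_var(c(cn_cultivars, cn_wild))
  v <- if (vt > 0) (vt - (v1 * n1 + v2 * n2) / nt) / vt else NA_real_
  structure(data.frame(gene_id = gene_id, v_total = vt, v_cultivars = v1,
                       v_wild = v2, n_cultivars = n1, n_wild = n2,
                       n_total = nt, vst = v, stringsAsFactors = FALSE),
            class = c("vst_record", "data.frame"))
}

#' Per-gene Vst scan over a copy-number matrix
#'
#' Computes \code{\link{vst}} for every gene between the cultivar
#' accessions and a (possibly restricted) subset of the wild accessions.
#' Genes with undefined Vst (zero pooled variance, i.e. CN constant across
#' the panel) are reported with \code{vst = NA} and excluded from ranking
#' by \code{\link{top_percentile_genes}}.
#'
#' @param cn a \code{\link{cn_matrix}}.
#' @param wild_subset optional character vector of wild accession ids to
#'   retain (e.g. restricting the wild panel to the progenitor species);
#'   default all wild accessions.
#' @return data.frame with one \code{vst_record} row per gene.
#' @export
vst_scan <- function(cn, wild_subset = NULL) {
  stopifnot(inherits(cn, "cn_matrix"))
  cult <- cn$samples[cn$populations == "cultivar"]
  wild <- cn$samples[cn$populations == "wild"]
  if (!is.null(wild_subset)) {
    wild <- intersect(wild, wild_subset)
  }
  if (length(cult) == 0L || length(wild) == 0L) {
    stop("both populations must be non-empty after subsetting")
  }
  out <- do.call(rbind, lapply(seq_along(cn$genes), function(i) {
    vst(cn$cn[i, cult], cn$cn[i, wild], gene_id = cn$genes[i])
  }))
  rownames(out) <- NULL
  out
}

#' Genes in the top percentile of the Vst distribution
#'
#' The cutoff is the empirical \code{1 - pct} quantile (type 7, linear
#' interpolation) of the defined Vst values; genes with
#' \code{vst >= cutoff} are returned, so ties at the cutoff are included.
#'
#' @param records data.frame of \code{vst_record} rows.
#' @param pct upper tail fraction (default 0.01 for "top 1\%").
#' @return character vector of gene ids, with the cutoff attached as the
#'   \code{"cutoff"} attribute.
#' @export
top_percentile_genes <- function(records, pct = 0.01) {
  defined <- records[!is.na(records$vst), , drop = FALSE]
  if (nrow(defined) == 0L) stop("no defined Vst values")
  cutoff <- quantile(defined$vst, 1 - pct, type = 7, names = FALSE)
  genes <- defined$gene_id[defined$vst >= cutoff]
  attr(genes, "cutoff") <- cutoff
  genes
}

#' Compare per-group copy numbers with a Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon rank-sum test with continuity correction on a
#' gene's CN values split by population, with group means reported.
#' When every value is identical the test is degenerate: p = 1 is
#' returned with \code{degenerate = TRUE}.
#'
#' @param cn_group1,cn_group2 numeric CN vectors (each of size >= 1).
#' @return list with \code{mean1}, \code{mean2}, \code{p_value},
#'   \code{degenerate}.
#' @export
group_cn_test <- function(cn_group1, cn_group2) {
  stopifnot(length(cn_group1) >= 1L, length(cn_group2) >= 1L)
  m1 <- mean(cn_group1); m2 <- mean(cn_group2)
  pooled <- c(cn_group1, cn_group2)
  if (length(unique(pooled)) == 1L) {
    return(list(mean1 = m1, mean2 = m2, p_value = 1, degenerate = TRUE))
  }
  wt <- suppressWarnings(wilcox.test(cn_group1, cn_group2,
                                     alternative = "two.sided",
                                     correct = TRUE, exact = FALSE))
  list(mean1 = m1, mean2 = m2, p_value = wt$p.value, degenerate = FALSE)
}

#' Manhattan-style plot of a Vst scan
#'
#' @param records \code{vst_record} data.frame from \code{\link{vst_scan}}.
#' @param genome optional \code{\link{genome_model}} to order genes by
#'   position; otherwise input order is used.
#' @param pct percentile cutoff drawn as a dashed line.
#' @export
plot_vst <- function(records, genome = NULL, pct = 0.01) {
  v <- records$vst
  x <- seq_along(v)
  col <- "grey40"
  if (!is.null(genome)) {
    idx <- match(records$gene_id, genome$genes$gene_id)
    o <- order(genome$genes$chrom[idx], genome$genes$start[idx])
    v <- v[o]
    col <- c("grey40", "steelblue")[
      1L + (as.integer(factor(genome$genes$chrom[idx][o])) %% 2L)]
  }
  plot(x, v, pch = 20, col = col, xlab = "gene index (genome order)",
       ylab = expression(V[st]), main = "Copy-number differentiation")
  ok <- !is.na(records$vst)
  if (any(ok)) {
    abline(h = quantile(records$vst[ok], 1 - pct, type = 7),
           lty = 2, col = "red")
  }
  invisible(NULL)
}
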