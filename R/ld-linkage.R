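#' Squared Pearson correlation of genotype dosages
#'
#' LD between two markers measured as r-squared of their dosage vectors,
#' with pairwise-complete handling of missing genotypes. Undefined (NA)
#' when fewer than two complete pairs remain or either vector is constant.
#'
#' @param dosage_a,dosage_b numeric vectors of equal length.
#' @return r-squared in [0, 1], or NA when undefined.
#' @export
r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b)) {
    stop("dosage vectors must have equal length")
  }
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (length(a) < 2L) return(NA_real_)
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' Classify a CNVR's linkage disequilibrium with its flanking SNPs
#'
#' Selects up to \code{k_per_side} nearest SNPs upstream and downstream of
#' the CNVR (same chromosome, MAF >= \code{maf_floor}; SNPs inside the
#' CNVR span are excluded). All pairwise SNP-SNP r-squared values among the
#' selected SNPs and all CNVR-SNP r-squared values are pooled and ranked by
#' decreasing r-squared (average ranks on ties). With \code{m} the median
#' rank of the SNP-SNP values, \code{N} counts the CNVR-SNP values ranking
#' strictly better (smaller rank) than \code{m}. The CNVR is classified
#' Low if \code{N <= n/3}, Mid if \code{n/3 < N <= 2n/3} and High
#' otherwise, where \code{n} is the number of SNPs used — reproducing the
#' 0-200 / 200-400 / 400-600 boundaries when 600 SNPs are available.
#'
#' The count of CNVR-SNP r-squared values exceeding the median SNP-SNP
#' r-squared value is also recorded (\code{N_value}); the two counts agree
#' whenever the pooled values are tie-free.
#'
#' @param cnvr_dosage recoded CNVR dosage vector over the panel (loss
#'   carriers 1, gain carriers 2, neutral 0), sample-aligned with
#'   \code{snps}.
#' @param snps a \code{\link{genotype_matrix}} of SNPs, position-sorted.
#' @param cnvr_chrom,cnvr_start,cnvr_end CNVR locus (0-based half-open).
#' @param cnvr_id id copied into the result.
#' @param k_per_side SNPs selected on each side (default 300).
#' @param maf_floor SNP MAF floor (default 0.05).
#' @param max_pairs optional cap on the number of SNP-SNP pairs, randomly
#'   subsampled with \code{pair_seed}, for speed.
#' @param pair_seed seed for pair subsampling (only used with
#'   \code{max_pairs}).
#' @return one-row data.frame of class \code{ld_result}: cnvr_id,
#'   n_snps_used, n_pairs, N, N_value, median_snp_snp_r2, category,
#'   unclassifiable.
#' @export
classify_cnvr_ld <- function(cnvr_dosage, snps, cnvr_chrom, cnvr_start,
                             cnvr_end, cnvr_id = NA_character_,
                             k_per_side = 300L, maf_floor = 0.05,
                             max_pairs = NULL, pair_seed = 1L) {
  stopifnot(inherits(snps, "genotype_matrix"),
            length(cnvr_dosage) == length(snps$samples))
  m <- snps$markers
  eligible <- which(m$chrom == cnvr_chrom & snps$maf >= maf_floor)
  pos <- m$pos[eligible]
  up <- eligible[pos < cnvr_start]
  down <- eligible[pos >= cnvr_end]
  # nearest-by-distance on each side
  if (length(up) > k_per_side) up <- tail(up, k_per_side)
  if (length(down) > k_per_side) down <- head(down, k_per_side)
  sel <- c(up, down)

  unclass_result <- function() {
    structure(data.frame(cnvr_id = cnvr_id, n_snps_used = length(sel),
                         n_pairs = 0L, N = NA_integer_,
                         N_value = NA_integer_,
                         median_snp_snp_r2 = NA_real_,
                         category = NA_character_, unclassifiable = TRUE,
                         stringsAsFactors = FALSE),
              class = c("ld_result", "data.frame"))
  }
  if (length(sel) == 0L) return(unclass_result())

  dos <- snps$dosage[sel, , drop = FALSE]
  # marker x marker r^2 in one shot; pairwise-complete missing handling
  cc <- suppressWarnings(cor(t(dos), use = "pairwise.complete.obs"))^2
  pair_idx <- which(upper.tri(cc), arr.ind = TRUE)
  ss <- cc[pair_idx]
  if (!is.null(max_pairs) && length(ss) > max_pairs) {
    keep <- with_seed(pair_seed, sample.int(length(ss), max_pairs))
    ss <- ss[keep]
  }
  ss <- ss[!is.na(ss)]
  cs <- apply(dos, 1L, function(row) r2(cnvr_dosage, row))
  cs <- cs[!is.na(cs)]
  if (length(ss) == 0L || length(cs) == 0L) return(unclass_result())

  pooled <- c(cs, ss)
  rk <- rank(-pooled, ties.method = "average")
  rk_cs <- rk[seq_along(cs)]
  rk_ss <- rk[-seq_along(cs)]
  med_rank <- median(rk_ss)
  N <- sum(rk_cs < med_rank)
  med_val <- median(ss)
  N_value <- sum(cs > med_val)

  n <- length(sel)
  category <- if (N <= n / 3) "Low" else if (N <= 2 * n / 3) "Mid"
    else "High"
  structure(data.frame(cnvr_id = cnvr_id, n_snps_used = n,
                       n_pairs = length(ss), N = N, N_value = N_value,
                       median_snp_snp_r2 = med_val, category = category,
                       unclassifiable = FALSE, stringsAsFactors = FALSE),
            class = c("ld_result", "data.frame"))
}

#' Classify LD for every CNVR in a set
#'
#' Convenience wrapper running \code{\link{classify_cnvr_ld}} over a
#' \code{cnvr_set}, deriving the recoded CNVR dosages with
#' \code{\link{cnvr_genotypes}}.
#'
#' @param cnvrs a \code{cnvr_set}.
#' @param snps a \code{\link{genotype_matrix}} of SNPs; its sample panel
#'   is used for the CNVR recoding.
#' @inheritParams classify_cnvr_ld
#' @return data.frame, one \code{ld_result} row per CNVR.
#' @export
ld_scan <- function(cnvrs, snps, k_per_side = 300L, maf_floor = 0.05,
                    max_pairs = NULL, pair_seed = 1L) {
  stopifnot(inherits(cnvrs, "cnvr_set"))
  g <- cnvr_genotypes(cnvrs, snps$samples)
  out <- lapply(seq_len(nrow(cnvrs)), function(i) {
    classify_cnvr_ld(g$dosage[i, ], snps, cnvrs$chrom[i], cnvrs$start[i],
                     cnvrs$end[i], cnvr_id = cnvrs$id[i],
                     k_per_side = k_per_side, maf_floor = maf_floor,
                     max_pairs = max_pairs, pair_seed = pair_seed)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise LD classification results
#'
#' Category proportions overall and by CNVR event type, plus a per-category
#' summary of CNVR minor allele frequencies.
#'
#' @param results data.frame of \code{ld_result} rows (see
#'   \code{\link{ld_scan}}).
#' @param cnvrs the matching \code{cnvr_set} (for event type and MAF).
#' @return list with \code{proportions}, \code{by_event_type} and
#'   \code{maf_by_category}.
#' @export
ld_summary <- function(results, cnvrs = NULL) {
  lev <- c("Low", "Mid", "High")
  if (nrow(results) == 0L) {
    return(list(proportions = setNames(numeric(3), lev),
                by_event_type = NULL, maf_by_category = NULL))
  }
  cl <- results[!results$unclassifiable, , drop = FALSE]
  prop <- prop.table(table(factor(cl$category, levels = lev)))
  by_type <- maf_summary <- NULL
  if (!is.null(cnvrs)) {
    idx <- match(cl$cnvr_id, cnvrs$id)
    by_type <- prop.table(
      table(event_type = cnvrs$event_type[idx],
            category = factor(cl$category, levels = lev)),
      margin = 1L)
    if (!anyNA(cnvrs$maf)) {
      maf_summary <- do.call(rbind, lapply(lev, function(L) {
        v <- cnvrs$maf[idx][cl$category == L]
        data.frame(category = L, n = length(v),
                   maf_mean = if (length(v)) mean(v) else NA_real_,
                   maf_median = if (length(v)) median(v) else NA_real_)
      }))
    }
  }
  list(proportions = prop, by_event_type = by_type,
       maf_by_category = maf_summary)
}
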