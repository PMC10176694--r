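#' Construct a genotype matrix
#'
#' Marker x sample allele-dosage container used for both SNP genotypes and
#' recoded CNVR genotypes. Dosages are integers in {0, 1, 2} with \code{NA}
#' as the missing sentinel; positions are 0-based bp and strictly increasing
#' within a chromosome.
#'
#' @param markers data.frame with columns \code{id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}.
#' @param samples ordered character vector of sample ids.
#' @param dosage integer matrix, \code{nrow(markers)} x
#'   \code{length(samples)}.
#' @param strict_pos require strictly increasing positions within each
#'   chromosome (the SNP contract). Recoded CNVR matrices may carry tied
#'   start positions and set this to \code{FALSE} (non-decreasing only).
#' @return An object of class \code{genotype_matrix} with a \code{maf}
#'   element computed from the non-missing dosages.
#' @export
genotype_matrix <- function(markers, samples, dosage, strict_pos = TRUE) {
  assert_columns(markers, c("id", "chrom", "pos", "ref", "alt"), "markers")
  dosage <- as.matrix(dosage)
  stopifnot(nrow(dosage) == nrow(markers), ncol(dosage) == length(samples))
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0) || any(bad > 2))) {
    stop("dosages must be in {0, 1, 2} or NA")
  }
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    bad <- if (strict_pos) any(diff(p) <= 0) else any(diff(p) < 0)
    if (length(p) > 1L && bad) {
      stop("marker positions must be ",
           if (strict_pos) "strictly increasing" else "sorted",
           " within chromosome ", ch)
    }
  }
  dimnames(dosage) <- list(markers$id, samples)
  structure(list(markers = markers, samples = samples, dosage = dosage,
                 maf = dosage_maf(dosage)),
            class = "genotype_matrix")
}

# per-marker minor allele frequency from non-missing dosages
dosage_maf <- function(dosage) {
  f <- rowMeans(dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$markers), "marker(s) x",
      length(x$samples), "sample(s);",
      sum(is.na(x$dosage)), "missing dosage(s)\n")
  invisible(x)
}

#' Simulate LD-structured SNP genotypes by a founder-mosaic model
#'
#' Each of the \code{2 * n_samples} haplotypes is a mosaic of
#' \code{n_founders} founder haplotypes with recombination breakpoints
#' arriving as a Poisson process of rate \code{1 / block_length} along each
#' chromosome. Founder alleles are drawn independently per site, so markers
#' within a block are in strong LD and markers many blocks apart are near
#' linkage equilibrium. Only SNPs with minor allele frequency >=
#' \code{maf_floor} are emitted; candidate sites are redrawn a bounded
#' number of times to reach \code{n_snps}.
#'
#' @param genome a \code{\link{genome_model}}.
#' @param n_samples number of diploid samples.
#' @param n_snps number of SNPs to emit (after the MAF filter).
#' @param n_founders number of founder haplotypes (>= 2).
#' @param block_length mean recombination block length in bp.
#' @param maf_floor minimum minor allele frequency of emitted SNPs.
#' @param seed integer seed.
#' @param max_redraws candidate-expansion rounds before giving up.
#' @param sample_ids optional character vector of sample names (length
#'   \code{n_samples}), e.g. the accession panel of a CNV simulation, so
#'   SNPs and CNVR genotypes share one panel.
#' @return A \code{\link{genotype_matrix}}.
#' @export
simulate_snp_genotypes <- function(genome, n_samples, n_snps,
                                   n_founders = 20L, block_length = 50000L,
                                   maf_floor = 0.05, seed = 1L,
                                   max_redraws = 6L, sample_ids = NULL) {
  stopifnot(inherits(genome, "genome_model"), n_samples >= 1, n_snps >= 1,
            block_length >= 1, maf_floor >= 0, maf_floor <= 0.5)
  if (n_founders < 2) stop("n_founders must be >= 2")
  chroms <- genome$chromosomes
  with_seed(seed, {
    # per-haplotype recombination maps, fixed once
    n_hap <- 2L * n_samples
    hap_maps <- lapply(seq_len(nrow(chroms)), function(ci) {
      L <- chroms$length[ci]
      lapply(seq_len(n_hap), function(h) {
        nb <- rpois(1, L / block_length)
        bp <- sort(runif(nb, 0, L))
        founders <- sample.int(n_founders, nb + 1L, replace = TRUE)
        list(bp = bp, founders = founders)
      })
    })

    draw_candidates <- function(m) {
      # sites spread over chromosomes proportional to length
      ci <- sample.int(nrow(chroms), m, replace = TRUE,
                       prob = chroms$length / sum(chroms$length))
      pos <- floor(runif(m, 0, chroms$length[ci]))
      keep <- !duplicated(paste(ci, pos))
      ci <- ci[keep]; pos <- pos[keep]
      founder_allele <- matrix(runif(n_founders * length(pos)) < 0.5,
                               nrow = n_founders)
      dosage <- matrix(0L, nrow = length(pos), ncol = n_samples)
      for (k in seq_along(pos)) {
        alle <- integer(n_hap)
        maps <- hap_maps[[ci[k]]]
        for (h in seq_len(n_hap)) {
          seg <- findInterval(pos[k], maps[[h]]$bp) + 1L
          alle[h] <- as.integer(founder_allele[maps[[h]]$founders[seg], k])
        }
        dosage[k, ] <- alle[seq(1L, n_hap, by = 2L)] +
          alle[seq(2L, n_hap, by = 2L)]
      }
      list(chrom = chroms$chrom[ci], pos = as.integer(pos), dosage = dosage)
    }

    acc_chrom <- character(); acc_pos <- integer(); acc_dos <- NULL
    m <- ceiling(1.5 * n_snps)
    for (round in seq_len(max_redraws)) {
      cand <- draw_candidates(m)
      maf <- dosage_maf(cand$dosage)
      pass <- which(maf >= maf_floor)
      acc_chrom <- c(acc_chrom, cand$chrom[pass])
      acc_pos <- c(acc_pos, cand$pos[pass])
      acc_dos <- rbind(acc_dos, cand$dosage[pass, , drop = FALSE])
      # drop duplicated sites across rounds
      keep <- !duplicated(paste(acc_chrom, acc_pos))
      acc_chrom <- acc_chrom[keep]; acc_pos <- acc_pos[keep]
      acc_dos <- acc_dos[keep, , drop = FALSE]
      if (length(acc_pos) >= n_snps) break
      m <- 2L * m
    }
    if (length(acc_pos) < n_snps) {
      stop("could not reach ", n_snps, " SNPs with MAF >= ", maf_floor,
           " after ", max_redraws, " redraw rounds")
    }
    # random subsample (not head-of-sort, which would bias chromosomes)
    take <- sample.int(length(acc_pos), n_snps)
    acc_chrom <- acc_chrom[take]
    acc_pos <- acc_pos[take]
    acc_dos <- acc_dos[take, , drop = FALSE]
    o2 <- order(acc_chrom, acc_pos)
    markers <- data.frame(
      id = sprintf("snp%05d", seq_len(n_snps)),
      chrom = acc_chrom[o2], pos = acc_pos[o2],
      ref = "A", alt = "T", stringsAsFactors = FALSE
    )
    samples <- sample_ids %||% sprintf("S%03d", seq_len(n_samples))
    stopifnot(length(samples) == n_samples)
    genotype_matrix(markers, samples = samples,
                    dosage = acc_dos[o2, , drop = FALSE])
  })
}
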