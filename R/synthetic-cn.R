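#' Construct a copy-number matrix
#'
#' Gene x accession real-valued copy-number estimates (diploid baseline 2)
#' with a population label per accession, the input of the Vst scan.
#'
#' @param cn numeric matrix, genes in rows, accessions in columns;
#'   no negative values.
#' @param genes character vector of gene ids (row names).
#' @param samples character vector of accession ids (column names).
#' @param populations named character vector (or data.frame with columns
#'   \code{accession}, \code{population}) labelling every accession as
#'   \code{"cultivar"} or \code{"wild"}.
#' @export
cn_matrix <- function(cn, genes, samples, populations) {
  cn <- as.matrix(cn)
  stopifnot(nrow(cn) == length(genes), ncol(cn) == length(samples))
  if (any(cn < 0, na.rm = TRUE)) stop("negative copy numbers not allowed")
  if (is.data.frame(populations)) {
    populations <- setNames(populations$population, populations$accession)
  }
  if (!all(samples %in% names(populations))) {
    stop("every accession must have a population label")
  }
  populations <- populations[samples]
  if (!all(populations %in% c("cultivar", "wild"))) {
    stop("population labels must be 'cultivar' or 'wild'")
  }
  dimnames(cn) <- list(genes, samples)
  structure(list(cn = cn, genes = genes, samples = samples,
                 populations = populations),
            class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat("cn_matrix:", length(x$genes), "gene(s) x", length(x$samples),
      "accession(s) (", sum(x$populations == "cultivar"), "cultivar /",
      sum(x$populations == "wild"), "wild )\n")
  invisible(x)
}

#' Simulate per-gene copy-number estimates
#'
#' Emulates read-depth-based CN estimation: every gene/accession starts at
#' the diploid baseline 2.0; genes overlapping a planted deletion locus lose
#' one copy in that locus's carriers, genes overlapping a planted
#' duplication gain one; Gaussian noise is added and values are clipped at
#' zero.
#'
#' @param genome a \code{\link{genome_model}}.
#' @param truth a \code{cnv_truth} from
#'   \code{\link{simulate_population_cnvs}}.
#' @param noise_sd standard deviation of additive Gaussian noise, in copy
#'   number units.
#' @param seed integer seed.
#' @return A \code{\link{cn_matrix}} over all genes in the genome and all
#'   accessions in the truth.
#' @export
simulate_cn_matrix <- function(genome, truth, noise_sd = 0.2, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), inherits(truth, "cnv_truth"),
            noise_sd >= 0)
  genes <- genome$genes
  samples <- truth$populations$accession
  with_seed(seed, {
    cn <- matrix(2.0, nrow = nrow(genes), ncol = length(samples),
                 dimnames = list(genes$gene_id, samples))
    if (nrow(genes) > 0L && nrow(truth$loci) > 0L) {
      hits <- GenomicRanges::findOverlaps(
        gr0(genes$chrom, genes$start, genes$end),
        gr0(truth$loci$chrom, truth$loci$start, truth$loci$end))
      for (h in seq_along(hits)) {
        gi <- S4Vectors::queryHits(hits)[h]
        li <- S4Vectors::subjectHits(hits)[h]
        carriers <- truth$carriers$accession[
          truth$carriers$locus_id == truth$loci$locus_id[li]]
        delta <- if (truth$loci$svtype[li] == "DEL") -1 else +1
        cn[gi, samples %in% carriers] <- cn[gi, samples %in% carriers] + delta
      }
    }
    if (noise_sd > 0) {
      cn <- cn + matrix(rnorm(length(cn), 0, noise_sd), nrow = nrow(cn))
    }
    cn[cn < 0] <- 0
    cn_matrix(cn, genes$gene_id, samples,
              setNames(truth$populations$population, samples))
  })
}
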