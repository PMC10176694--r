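# VCF input goes through VariantAnnotation; output is emitted directly,
# because the CNVR records carry the bespoke loss/gain recoding
# (0/1 loss carrier, 1/1 gain carrier, 0/0 neutral) in a single
# record per CNVR, with SVTYPE=CNV and the class in INFO/CNVCLASS.

#' Write CNVRs as a VCF 4.2 file with the loss/gain genotype recoding
#'
#' One record per CNVR: \code{POS = start + 1} (half-open to 1-based),
#' \code{REF = N}, \code{ALT = <CNV>}, \code{INFO} carries
#' \code{SVTYPE=CNV}, \code{END} and \code{CNVCLASS} (loss/gain/both).
#' Per-sample genotypes follow the recoding: a loss carrier is \code{0/1},
#' a gain carrier \code{1/1}, a non-carrier \code{0/0}. In a "both"-class
#' record, loss carriers are 0/1 and gain carriers 1/1 in the same record;
#' an accession carrying both events in one CNVR is emitted as 1/1
#' (gain wins; pinned convention).
#'
#' @param cnvrs a \code{cnvr_set} (see \code{\link{merge_to_cnvrs}}).
#' @param samples ordered character vector of all sample ids; every carrier
#'   must appear in it.
#' @param path output .vcf file.
#' @param chromosomes optional data.frame (chrom, length) for contig
#'   header lines.
#' @export
write_cnvr_vcf <- function(cnvrs, samples, path, chromosomes = NULL) {
  stopifnot(inherits(cnvrs, "cnvr_set"))
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  carriers <- attr(cnvrs, "carriers")
  all_carr <- unique(unlist(lapply(carriers, names)))
  if (!all(all_carr %in% samples)) {
    stop("carrier accession(s) absent from samples: ",
         paste(setdiff(all_carr, samples), collapse = ", "))
  }
  if (is.null(chromosomes)) {
    chromosomes <- data.frame(chrom = unique(cnvrs$chrom),
                              length = NA_integer_)
    contig <- paste0("##contig=<ID=", chromosomes$chrom, ">")
  } else {
    contig <- paste0("##contig=<ID=", chromosomes$chrom, ",length=",
                     chromosomes$length, ">")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    contig,
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
    "##INFO=<ID=CNVCLASS,Number=1,Type=String,Description=\"CNVR class: loss, gain or both\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Recoded CNVR genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rows <- vapply(seq_len(nrow(cnvrs)), function(i) {
    carr <- carriers[[i]]
    gt <- rep("0/0", length(samples))
    names(gt) <- samples
    if (length(carr)) {
      gt[names(carr)[carr == "loss"]] <- "0/1"
      gt[names(carr)[carr %in% c("gain", "both")]] <- "1/1"
    }
    paste(c(cnvrs$chrom[i], cnvrs$start[i] + 1L, cnvrs$id[i], "N", "<CNV>",
            ".", "PASS",
            paste0("SVTYPE=CNV;END=", cnvrs$end[i],
                   ";CNVCLASS=", cnvrs$event_type[i]),
            "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a CNVR VCF written by \code{\link{write_cnvr_vcf}}
#'
#' @param path .vcf file.
#' @return a \code{cnvr_set} with carriers reconstructed from the
#'   genotype recoding (0/1 = loss carrier, 1/1 = gain carrier).
#' @export
read_cnvr_vcf <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  info <- VariantAnnotation::info(v)
  gt <- VariantAnnotation::geno(v)$GT
  samples <- colnames(gt)
  n <- length(rr)
  cls <- as.character(info$CNVCLASS)
  carriers <- lapply(seq_len(n), function(i) {
    g <- gt[i, ]
    loss <- samples[g == "0/1"]
    gain <- samples[g == "1/1"]
    ev <- c(setNames(rep("loss", length(loss)), loss),
            setNames(rep("gain", length(gain)), gain))
    ev[order(names(ev))]
  })
  out <- data.frame(
    id = names(rr) %||% sprintf("cnvr%05d", seq_len(n)),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    start = GenomicRanges::start(rr) - 1L,
    end = as.integer(info$END),
    event_type = cls,
    n_carriers = vapply(carriers, length, 1L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  new_cnvr_set(out, carriers, members = NULL)
}

#' Read a SNP VCF into a genotype matrix
#'
#' Biallelic SNP records only: multi-allelic records are rejected with a
#' message reporting their count. Dosage is the count of alt alleles
#' parsed from GT (\code{0/0} = 0, \code{0/1} or \code{1/0} = 1,
#' \code{1/1} = 2, \code{./.} = NA). The file must be position-sorted
#' within each chromosome; unsorted input is an error because downstream
#' nearest-SNP queries require sorted positions.
#'
#' @param path .vcf file.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_snp_vcf <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(v)
  multi <- S4Vectors::elementNROWS(alt) != 1L
  if (any(multi)) {
    message("rejected ", sum(multi), " multi-allelic record(s)")
    v <- v[!multi]
    alt <- alt[!multi]
  }
  rr <- SummarizedExperiment::rowRanges(v)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr) - 1L  # to 0-based
  for (ch in unique(chrom)) {
    if (is.unsorted(pos[chrom == ch], strictly = TRUE)) {
      stop("VCF is not position-sorted on chromosome ", ch,
           "; sorted input is required for nearest-SNP queries")
    }
  }
  gt <- VariantAnnotation::geno(v)$GT
  dosage <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage[clean %in% c("0/0")] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean %in% c("1/1")] <- 2L
  markers <- data.frame(
    id = rownames(gt) %||% sprintf("snp%05d", seq_len(nrow(gt))),
    chrom = chrom, pos = pos,
    ref = as.character(VariantAnnotation::ref(v)),
    alt = vapply(seq_along(alt), function(i) as.character(alt[[i]][1L]), ""),
    stringsAsFactors = FALSE
  )
  genotype_matrix(markers, colnames(gt), dosage)
}

#' Write a genotype matrix as a sorted biallelic SNP VCF
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param path output .vcf file.
#' @param chromosomes optional data.frame (chrom, length) for contig lines.
#' @export
write_genotype_vcf <- function(g, path, chromosomes = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  m <- g$markers
  o <- order(m$chrom, m$pos)
  m <- m[o, , drop = FALSE]
  dos <- g$dosage[o, , drop = FALSE]
  contig <- if (is.null(chromosomes)) {
    paste0("##contig=<ID=", unique(m$chrom), ">")
  } else {
    paste0("##contig=<ID=", chromosomes$chrom, ",length=",
           chromosomes$length, ">")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    contig,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    gt <- ifelse(is.na(dos[i, ]), "./.", gt_code[dos[i, ] + 1L])
    paste(c(m$chrom[i], m$pos[i] + 1L, m$id[i], m$ref[i], m$alt[i],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}
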