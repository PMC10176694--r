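#' Write a genome model's annotation as GFF3
#'
#' Emits the standard gene/mRNA/exon/CDS hierarchy (one mRNA per gene),
#' 1-based inclusive as GFF3 requires.
#'
#' @param genome a \code{\link{genome_model}}.
#' @param path output .gff3 file.
#' @export
write_genome_gff <- function(genome, path) {
  g <- genome$genes
  parts <- function(df, type, suffix) {
    if (nrow(df) == 0L) return(NULL)
    gr <- gr0(df$chrom, df$start, df$end)
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- paste0(df$gene_id, suffix, seq_len(nrow(df)))
    S4Vectors::mcols(gr)$Parent <- paste0(df$gene_id, ".m1")
    gr
  }
  grs <- list()
  if (nrow(g) > 0L) {
    gene_gr <- gr0(g$chrom, g$start, g$end)
    GenomicRanges::strand(gene_gr) <- g$strand
    S4Vectors::mcols(gene_gr)$type <- "gene"
    S4Vectors::mcols(gene_gr)$ID <- g$gene_id
    S4Vectors::mcols(gene_gr)$Parent <- NA_character_
    mrna_gr <- gene_gr
    S4Vectors::mcols(mrna_gr)$type <- "mRNA"
    S4Vectors::mcols(mrna_gr)$ID <- paste0(g$gene_id, ".m1")
    S4Vectors::mcols(mrna_gr)$Parent <- g$gene_id
    grs <- list(gene_gr, mrna_gr,
                parts(genome$exons, "exon", ".e"),
                parts(genome$cds, "CDS", ".c"))
  }
  grs <- grs[!vapply(grs, is.null, TRUE)]
  all_gr <- if (length(grs)) suppressWarnings(do.call(c, grs)) else
    GenomicRanges::GRanges()
  GenomeInfoDb::seqlevels(all_gr) <- genome$chromosomes$chrom
  GenomeInfoDb::seqlengths(all_gr) <- genome$chromosomes$length
  suppressWarnings(rtracklayer::export(all_gr, path, format = "gff3"))
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Assembles gene spans with their exon and CDS children (via mRNA
#' Parent links); coordinates are converted from GFF3's 1-based inclusive
#' to the internal 0-based half-open convention.
#'
#' @param path a GFF3 file.
#' @return list with data.frames \code{genes} (gene_id, chrom, start, end,
#'   strand), \code{exons} and \code{cds} (gene_id, chrom, start, end).
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  d <- df0(gr)
  d$type <- as.character(m$type)
  d$ID <- as.character(m$ID)
  parent <- m$Parent
  d$parent <- vapply(seq_along(gr), function(i) {
    p <- parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, "")
  d$strand <- as.character(GenomicRanges::strand(gr))

  genes <- d[d$type == "gene", , drop = FALSE]
  mrna <- d[d$type == "mRNA", , drop = FALSE]
  mrna_gene <- setNames(mrna$parent, mrna$ID)
  child <- function(type) {
    x <- d[d$type == type, , drop = FALSE]
    if (nrow(x) == 0L) {
      return(data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE))
    }
    gene_id <- ifelse(x$parent %in% names(mrna_gene),
                      mrna_gene[x$parent], x$parent)
    out <- data.frame(gene_id = unname(gene_id), chrom = x$chrom,
                      start = x$start, end = x$end,
                      stringsAsFactors = FALSE)
    out[order(out$gene_id, out$start), , drop = FALSE]
  }
  genes_df <- data.frame(gene_id = genes$ID, chrom = genes$chrom,
                         start = genes$start, end = genes$end,
                         strand = ifelse(genes$strand == "*", "+",
                                         genes$strand),
                         stringsAsFactors = FALSE)
  genes_df <- genes_df[order(genes_df$chrom, genes_df$start), , drop = FALSE]
  rownames(genes_df) <- NULL
  ex <- child("exon"); rownames(ex) <- NULL
  cd <- child("CDS"); rownames(cd) <- NULL
  list(genes = genes_df, exons = ex, cds = cd)
}

#' Read / write BED interval tracks
#'
#' BED is 0-based half-open, which matches the internal convention, so
#' coordinates pass through unchanged. Reading and writing go through
#' \pkg{rtracklayer}.
#'
#' @param path BED file.
#' @return \code{read_bed}: data.frame with columns chrom, start, end.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- df0(gr)
  rownames(out) <- NULL
  out
}

#' @param intervals data.frame with columns chrom, start, end
#'   (0-based half-open).
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  assert_columns(intervals, c("chrom", "start", "end"), "intervals")
  gr <- gr0(intervals$chrom, intervals$start, intervals$end)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read / write chromosome sizes as a two-column TSV
#' @param path TSV file (chrom, length; no header).
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "integer"))
  df
}

#' @param chromosomes data.frame with columns chrom, length.
#' @rdname read_chrom_sizes
#' @export
write_chrom_sizes <- function(chromosomes, path) {
  write.table(chromosomes[, c("chrom", "length")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a synthetic truth set as documented TSVs
#'
#' Two files: a locus table (locus_id, chrom, start, end, svtype,
#' freq_pop1, freq_pop2, differentiated) and a carrier table (locus_id,
#' accession, population). Coordinates are 0-based half-open. This lets
#' evaluation run from files alone.
#'
#' @param truth a \code{cnv_truth}.
#' @param locus_path,carrier_path output TSV paths.
#' @export
write_truth <- function(truth, locus_path, carrier_path) {
  stopifnot(inherits(truth, "cnv_truth"))
  write.table(truth$loci, locus_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  pop <- setNames(truth$populations$population, truth$populations$accession)
  carriers <- truth$carriers
  carriers$population <- unname(pop[carriers$accession])
  # carry the full panel so population labels survive even for non-carriers
  write.table(carriers, carrier_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  attr_path <- paste0(carrier_path, ".panel")
  write.table(truth$populations, attr_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(locus_path, carrier_path))
}

#' @rdname write_truth
#' @export
read_truth <- function(locus_path, carrier_path) {
  loci <- read.table(locus_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  carriers <- read.table(carrier_path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  panel_path <- paste0(carrier_path, ".panel")
  populations <- if (file.exists(panel_path)) {
    read.table(panel_path, sep = "\t", header = TRUE,
               stringsAsFactors = FALSE)
  } else {
    unique(carriers[, c("accession", "population")])
  }
  cnv_truth(loci = loci,
            carriers = carriers[, c("locus_id", "accession")],
            populations = populations,
            differentiated_genes = character(),
            seed = NA_integer_)
}
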