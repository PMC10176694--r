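#' Construct a genome model
#'
#' A genome model bundles chromosome sizes, a gene annotation (gene spans
#' with exon and CDS children) and an optional transposable-element (TE)
#' track. It stands in for a reference genome plus its GFF3 annotation.
#' All coordinates are 0-based half-open.
#'
#' @param chromosomes data.frame with columns \code{chrom}, \code{length}.
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}; may have zero rows.
#' @param exons data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}; exons of one gene must be non-overlapping
#'   and within the gene span.
#' @param cds like \code{exons}; defaults to the exon table.
#' @param tes data.frame with columns \code{chrom}, \code{start}, \code{end}.
#' @return An object of class \code{genome_model}.
#' @export
genome_model <- function(chromosomes, genes = NULL, exons = NULL,
                         cds = NULL, tes = NULL) {
  assert_columns(chromosomes, c("chrom", "length"), "chromosomes")
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (anyDuplicated(chromosomes$chrom)) stop("duplicate chromosome names")

  empty_genes <- data.frame(gene_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), stringsAsFactors = FALSE)
  empty_parts <- data.frame(gene_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            stringsAsFactors = FALSE)
  empty_tes <- data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  genes <- genes %||% empty_genes
  exons <- exons %||% empty_parts
  cds <- cds %||% exons
  tes <- tes %||% empty_tes
  assert_columns(genes, c("gene_id", "chrom", "start", "end", "strand"),
                 "genes")
  assert_columns(exons, c("gene_id", "chrom", "start", "end"), "exons")
  assert_columns(tes, c("chrom", "start", "end"), "tes")

  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  chrom_len <- setNames(chromosomes$length, chromosomes$chrom)
  check_bounds <- function(df, what) {
    if (nrow(df) == 0L) return(invisible())
    bad <- !(df$chrom %in% names(chrom_len))
    if (any(bad)) stop(what, ": unknown chromosome ", df$chrom[bad][1L])
    out <- df$start < 0 | df$end > chrom_len[df$chrom] | df$end <= df$start
    if (any(out)) stop(what, ": interval outside chromosome bounds or empty")
    invisible()
  }
  check_bounds(genes, "genes")
  check_bounds(exons, "exons")
  check_bounds(cds, "cds")
  check_bounds(tes, "tes")

  # exons within parent span, non-overlapping per gene
  if (nrow(exons) > 0L) {
    span <- genes[match(exons$gene_id, genes$gene_id), ]
    if (anyNA(span$gene_id)) stop("exon refers to unknown gene id")
    if (any(exons$start < span$start | exons$end > span$end)) {
      stop("exon extends beyond its gene span")
    }
    by_gene <- split(exons[, c("start", "end")], exons$gene_id)
    for (ex in by_gene) {
      o <- order(ex$start)
      if (any(ex$start[o][-1] < ex$end[o][-nrow(ex)])) {
        stop("overlapping exons within one gene")
      }
    }
  }

  structure(list(chromosomes = chromosomes, genes = genes, exons = exons,
                 cds = cds, tes = tes),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosome(s),",
      format(sum(as.numeric(x$chromosomes$length)), big.mark = ","), "bp;",
      nrow(x$genes), "gene(s);", nrow(x$tes), "TE(s)\n")
  invisible(x)
}

genome_size <- function(genome) sum(as.numeric(genome$chromosomes$length))

# place n non-overlapping intervals of given lengths uniformly in [0, L)
# via stick-breaking on the slack; errors if they cannot fit
place_nonoverlapping <- function(lengths, chrom_len, min_gap = 0L) {
  n <- length(lengths)
  if (n == 0L) return(integer())
  slack <- chrom_len - sum(lengths) - min_gap * (n - 1L)
  if (slack < 0) {
    stop("infeasible packing: requested ", sum(lengths),
         " bp of features (plus gaps) in a ", chrom_len, " bp chromosome")
  }
  offsets <- sort(floor(runif(n, 0, slack + 1)))
  starts <- offsets + cumsum(c(0L, lengths[-n] + min_gap))
  as.integer(starts)
}

#' Simulate a genome model
#'
#' Generates chromosomes of equal length, places \code{n_genes}
#' non-overlapping genes uniformly at random (each with 1-5 exons, which
#' double as CDS), and lays down a TE track at a requested base-pair
#' density. Deterministic given \code{seed}.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param n_genes total number of genes across the genome.
#' @param te_density target fraction of the genome covered by TE intervals
#'   (approximate; TEs are placed independently and may overlap anything).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param gene_length_range gene span range in bp, drawn uniformly.
#' @return A \code{\link{genome_model}}.
#' @examples
#' g <- simulate_genome(2, 5e5, 50, 0.1, seed = 1)
#' @export
simulate_genome <- function(n_chrom, chrom_length, n_genes, te_density = 0,
                            seed, gene_length_range = c(1000L, 5000L)) {
  stopifnot(n_chrom >= 1, chrom_length >= 1, n_genes >= 0,
            te_density >= 0, te_density < 1)
  mean_gene <- mean(gene_length_range)
  if (n_genes > 0 && chrom_length < 10 * mean_gene) {
    stop("chrom_length must be at least 10x the mean gene length")
  }
  with_seed(seed, {
    chroms <- data.frame(
      chrom = sprintf("chr%02d", seq_len(n_chrom)),
      length = as.integer(chrom_length),
      stringsAsFactors = FALSE
    )
    genes <- exons <- NULL
    if (n_genes > 0) {
      gene_chrom <- sort(sample.int(n_chrom, n_genes, replace = TRUE))
      gene_len <- as.integer(floor(runif(
        n_genes, gene_length_range[1], gene_length_range[2] + 1)))
      if (sum(as.numeric(gene_len)) > 0.95 * n_chrom * chrom_length) {
        stop("infeasible packing: requested gene span exceeds genome capacity")
      }
      starts <- integer(n_genes)
      for (ci in seq_len(n_chrom)) {
        idx <- which(gene_chrom == ci)
        if (length(idx) == 0L) next
        starts[idx] <- place_nonoverlapping(gene_len[idx], chrom_length,
                                            min_gap = 1L)
      }
      genes <- data.frame(
        gene_id = sprintf("G%04d", seq_len(n_genes)),
        chrom = chroms$chrom[gene_chrom],
        start = starts,
        end = starts + gene_len,
        strand = sample(c("+", "-"), n_genes, replace = TRUE),
        stringsAsFactors = FALSE
      )
      exons <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
        n_ex <- sample.int(5L, 1L)
        # 2*n_ex distinct breakpoints inside the span delimit exons/introns
        bp <- sort(sample.int(gene_len[i] - 1L, 2L * n_ex - 2L)) # interior
        edges <- c(0L, bp, gene_len[i])
        ex_s <- edges[seq(1L, by = 2L, length.out = n_ex)]
        ex_e <- edges[seq(2L, by = 2L, length.out = n_ex)]
        keep <- ex_e > ex_s
        data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                   start = genes$start[i] + ex_s[keep],
                   end = genes$start[i] + ex_e[keep],
                   stringsAsFactors = FALSE)
      }))
    }
    tes <- NULL
    if (te_density > 0) {
      mean_te <- 1500
      n_te <- max(1L, round(te_density * n_chrom * chrom_length / mean_te))
      te_chrom <- sample.int(n_chrom, n_te, replace = TRUE)
      te_len <- pmin(as.integer(round(exp(runif(n_te, log(100),
                                                log(5000))))),
                     as.integer(chrom_length))
      te_start <- as.integer(floor(runif(n_te, 0, chrom_length - te_len + 1)))
      tes <- data.frame(chrom = chroms$chrom[te_chrom], start = te_start,
                        end = te_start + te_len, stringsAsFactors = FALSE)
      tes <- tes[order(tes$chrom, tes$start, tes$end), ]
      rownames(tes) <- NULL
    }
    genome_model(chroms, genes = genes, exons = exons, tes = tes)
  })
}
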