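#' Simulate two-population CNV call sets with known truth
#'
#' Plants \code{n_loci} non-overlapping CNV loci on a genome and assigns
#' carriers in two populations ("cultivar" and "wild") by independent
#' Bernoulli draws at per-population locus frequencies. Each carrier's call
#' is the locus interval with truncated Gaussian breakpoint jitter: jitter is
#' resampled (then zeroed) so the call keeps length >= \code{min_len} and
#' >= 90\% reciprocal overlap with the planted locus, which guarantees that
#' planted loci survive 90\% reciprocal-overlap merging. Deletions outnumber
#' duplications \code{del_dup_ratio}:1 by default, mirroring the strong
#' deletion excess seen in resequencing panels.
#'
#' @param genome a \code{\link{genome_model}}.
#' @param n_pop1,n_pop2 number of accessions in the cultivar and wild
#'   populations. Defaults mirror a 289-cultivar / 57-wild panel.
#' @param n_loci number of planted CNV loci.
#' @param freq_pop1,freq_pop2 either a length-2 range from which each
#'   locus's carrier frequency in that population is drawn uniformly, or a
#'   vector of length \code{n_loci} of exact per-locus frequencies.
#' @param del_dup_ratio expected ratio of DEL to DUP planted loci.
#' @param jitter_sd standard deviation (bp) of Gaussian breakpoint jitter.
#' @param min_len,max_len planted locus length range (log-uniform draw).
#' @param diff_threshold loci with per-population frequency difference
#'   >= this value are recorded as differentiated in the truth, and genes
#'   they overlap become the truth's differentiated gene set.
#' @param seed integer seed.
#' @return list with elements \code{calls} (data.frame: accession, chrom,
#'   start, end, svtype) and \code{truth} (class \code{cnv_truth}).
#' @export
simulate_population_cnvs <- function(genome, n_pop1 = 289L, n_pop2 = 57L,
                                     n_loci = 100L,
                                     freq_pop1 = c(0.05, 0.95),
                                     freq_pop2 = c(0.05, 0.95),
                                     del_dup_ratio = 10,
                                     jitter_sd = 10,
                                     min_len = 100L, max_len = 50000L,
                                     diff_threshold = 0.6,
                                     seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), n_pop1 >= 0, n_pop2 >= 0,
            n_loci >= 0, jitter_sd >= 0, del_dup_ratio > 0)
  if (min_len < 50L) stop("min_len must be >= 50 (CNV definition)")
  if (max_len < min_len) stop("max_len must be >= min_len")
  check_freq <- function(f, n, what) {
    # length-2 vectors are always read as a range; length-n as exact values
    if (!length(f) %in% c(2L, n)) {
      stop(what, ": must be a length-2 range or one frequency per locus")
    }
    if (any(f < 0 | f > 1)) stop(what, ": frequencies must lie in [0,1]")
    invisible(f)
  }
  check_freq(freq_pop1, n_loci, "freq_pop1")
  check_freq(freq_pop2, n_loci, "freq_pop2")

  samples1 <- sprintf("C%03d", seq_len(n_pop1))
  samples2 <- sprintf("W%03d", seq_len(n_pop2))
  populations <- data.frame(
    accession = c(samples1, samples2),
    population = rep(c("cultivar", "wild"), c(n_pop1, n_pop2)),
    stringsAsFactors = FALSE
  )

  with_seed(seed, {
    if (n_loci == 0L) {
      truth <- cnv_truth(
        loci = data.frame(locus_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          svtype = character(), freq_pop1 = numeric(),
                          freq_pop2 = numeric(), differentiated = logical(),
                          stringsAsFactors = FALSE),
        carriers = data.frame(locus_id = character(),
                              accession = character(),
                              stringsAsFactors = FALSE),
        populations = populations,
        differentiated_genes = character(),
        seed = seed
      )
      calls <- data.frame(accession = character(), chrom = character(),
                          start = integer(), end = integer(),
                          svtype = character(), stringsAsFactors = FALSE)
      return(list(calls = calls, truth = truth))
    }

    # loci: log-uniform lengths, non-overlapping placement with a guard gap
    # wide enough that jittered calls at distinct loci can never merge
    len <- as.integer(round(exp(runif(n_loci, log(min_len), log(max_len)))))
    len <- as.integer(pmin(pmax(len, min_len), max_len))
    n_chrom <- nrow(genome$chromosomes)
    locus_chrom <- sort(sample.int(n_chrom, n_loci, replace = TRUE))
    gap <- as.integer(max(1, ceiling(0.2 * max_len), ceiling(8 * jitter_sd)))
    start <- integer(n_loci)
    for (ci in seq_len(n_chrom)) {
      idx <- which(locus_chrom == ci)
      if (length(idx) == 0L) next
      start[idx] <- place_nonoverlapping(
        len[idx], genome$chromosomes$length[ci], min_gap = gap)
    }
    svtype <- ifelse(
      runif(n_loci) < del_dup_ratio / (del_dup_ratio + 1), "DEL", "DUP")
    f1 <- if (length(freq_pop1) == 2L) runif(n_loci, freq_pop1[1],
                                             freq_pop1[2]) else freq_pop1
    f2 <- if (length(freq_pop2) == 2L) runif(n_loci, freq_pop2[1],
                                             freq_pop2[2]) else freq_pop2
    loci <- data.frame(
      locus_id = sprintf("L%04d", seq_len(n_loci)),
      chrom = genome$chromosomes$chrom[locus_chrom],
      start = start, end = start + len, svtype = svtype,
      freq_pop1 = f1, freq_pop2 = f2,
      differentiated = abs(f1 - f2) >= diff_threshold,
      stringsAsFactors = FALSE
    )

    calls_list <- vector("list", n_loci)
    carriers_list <- vector("list", n_loci)
    for (i in seq_len(n_loci)) {
      hit1 <- samples1[runif(n_pop1) < f1[i]]
      hit2 <- samples2[runif(n_pop2) < f2[i]]
      acc <- c(hit1, hit2)
      if (length(acc) == 0L) next
      s <- loci$start[i]; e <- loci$end[i]
      js <- je <- integer(length(acc))
      if (jitter_sd > 0) {
        for (j in seq_along(acc)) {
          ok <- FALSE
          for (try in 1:20) {
            ds <- as.integer(round(rnorm(1, 0, jitter_sd)))
            de <- as.integer(round(rnorm(1, 0, jitter_sd)))
            ns <- s + ds; ne <- e + de
            if (ns < 0 || ne <= ns || ne - ns < min_len) next
            ov <- interval_overlap(ns, ne, s, e)
            if (ov >= 0.9 * (ne - ns) && ov >= 0.9 * (e - s)) {
              js[j] <- ds; je[j] <- de; ok <- TRUE; break
            }
          }
          if (!ok) { js[j] <- 0L; je[j] <- 0L }
        }
      }
      calls_list[[i]] <- data.frame(
        accession = acc, chrom = loci$chrom[i],
        start = s + js, end = e + je, svtype = loci$svtype[i],
        stringsAsFactors = FALSE
      )
      carriers_list[[i]] <- data.frame(locus_id = loci$locus_id[i],
                                       accession = acc,
                                       stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, c(calls_list, list(
      data.frame(accession = character(), chrom = character(),
                 start = integer(), end = integer(), svtype = character(),
                 stringsAsFactors = FALSE))))
    rownames(calls) <- NULL
    carriers <- do.call(rbind, c(carriers_list, list(
      data.frame(locus_id = character(), accession = character(),
                 stringsAsFactors = FALSE))))
    rownames(carriers) <- NULL

    diff_genes <- character()
    if (nrow(genome$genes) > 0L && any(loci$differentiated)) {
      dl <- loci[loci$differentiated, ]
      hits <- GenomicRanges::findOverlaps(
        gr0(genome$genes$chrom, genome$genes$start, genome$genes$end),
        gr0(dl$chrom, dl$start, dl$end))
      diff_genes <- unique(
        genome$genes$gene_id[S4Vectors::queryHits(hits)])
    }

    truth <- cnv_truth(loci = loci, carriers = carriers,
                       populations = populations,
                       differentiated_genes = diff_genes, seed = seed)
    list(calls = calls, truth = truth)
  })
}

cnv_truth <- function(loci, carriers, populations, differentiated_genes,
                      seed) {
  stopifnot(all(loci$freq_pop1 >= 0 & loci$freq_pop1 <= 1),
            all(loci$freq_pop2 >= 0 & loci$freq_pop2 <= 1))
  structure(list(loci = loci, carriers = carriers,
                 populations = populations,
                 differentiated_genes = differentiated_genes,
                 seed = as.integer(seed)),
            class = "cnv_truth")
}

#' @export
print.cnv_truth <- function(x, ...) {
  cat("cnv_truth:", nrow(x$loci), "planted locus/loci,",
      nrow(x$carriers), "carrier assignment(s),",
      nrow(x$populations), "accessions (",
      sum(x$populations$population == "cultivar"), "cultivar /",
      sum(x$populations$population == "wild"), "wild ),",
      length(x$differentiated_genes), "differentiated gene(s)\n")
  invisible(x)
}
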