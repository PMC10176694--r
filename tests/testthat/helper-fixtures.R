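# small programmatic fixtures shared across test files

make_calls <- function(accession, chrom, start, end, svtype) {
  data.frame(accession = accession, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             svtype = svtype, stringsAsFactors = FALSE)
}

# n identical calls over one interval, one accession each
stack_calls <- function(n, chrom, start, end, svtype = "DEL",
                        prefix = "A") {
  make_calls(sprintf("%s%02d", prefix, seq_len(n)), chrom,
             rep(start, n), rep(end, n), rep(svtype, n))
}

tiny_genome <- function() {
  genome_model(
    chromosomes = data.frame(chrom = "chr1", length = 10000L),
    genes = data.frame(gene_id = "g1", chrom = "chr1", start = 4000L,
                       end = 6000L, strand = "+",
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = "g1", chrom = "chr1", start = 4000L,
                       end = 5000L, stringsAsFactors = FALSE)
  )
}

# independent greedy-merge re-implementation used as oracle: same rule,
# written over explicit per-cluster member vectors instead of a running
# single-pass state machine
oracle_greedy_merge <- function(calls, reciprocal = 0.9) {
  o <- order(calls$chrom, calls$start, calls$end, calls$accession)
  calls <- calls[o, , drop = FALSE]
  clusters <- list()
  for (i in seq_len(nrow(calls))) {
    s <- calls$start[i]; e <- calls$end[i]; ch <- calls$chrom[i]
    placed <- FALSE
    if (length(clusters) > 0L) {
      cl <- clusters[[length(clusters)]]
      if (cl$chrom == ch) {
        cs <- min(cl$start); ce <- max(cl$end)
        ov <- max(0, min(e, ce) - max(s, cs))
        if (ov >= reciprocal * (e - s) && ov >= reciprocal * (ce - cs)) {
          cl$start <- c(cl$start, s); cl$end <- c(cl$end, e)
          cl$acc <- c(cl$acc, calls$accession[i])
          cl$type <- c(cl$type, calls$svtype[i])
          clusters[[length(clusters)]] <- cl
          placed <- TRUE
        }
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(
        chrom = ch, start = s, end = e, acc = calls$accession[i],
        type = calls$svtype[i])
    }
  }
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(chrom = cl$chrom, start = min(cl$start), end = max(cl$end),
               n_carriers = length(unique(cl$acc)),
               stringsAsFactors = FALSE)
  }))
}

# random call set on one chromosome for oracle-equivalence sweeps
random_calls <- function(n, chrom_len = 100000L, max_len = 5000L) {
  start <- sample.int(chrom_len - max_len, n, replace = TRUE)
  len <- sample(50:max_len, n, replace = TRUE)
  make_calls(sprintf("A%02d", sample.int(max(5L, n %/% 2L), n,
                                         replace = TRUE)),
             "chr1", start, start + len,
             sample(c("DEL", "DUP"), n, replace = TRUE, prob = c(.9, .1)))
}

# exhaustive oracle: enumerate all candidate pairs, apply the same
# greedy acceptance over an explicitly sorted pair list
oracle_match <- function(truth, calls, reciprocal = 0.5,
                         type_strict = TRUE) {
  cand <- expand.grid(t = seq_len(nrow(truth)), c = seq_len(nrow(calls)))
  keep <- logical(nrow(cand)); frac <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    tr <- truth[cand$t[i], ]; cl <- calls[cand$c[i], ]
    if (tr$chrom != cl$chrom) next
    if (type_strict && tr$svtype != cl$svtype) next
    ov <- max(0, min(tr$end, cl$end) - max(tr$start, cl$start))
    f <- min(ov / (tr$end - tr$start), ov / (cl$end - cl$start))
    if (f >= reciprocal) { keep[i] <- TRUE; frac[i] <- f }
  }
  cand <- cand[keep, , drop = FALSE]; frac <- frac[keep]
  o <- order(-frac, cand$t, cand$c)
  cand <- cand[o, , drop = FALSE]
  used_t <- logical(nrow(truth)); used_c <- logical(nrow(calls))
  tp <- 0L
  for (i in seq_len(nrow(cand))) {
    if (!used_t[cand$t[i]] && !used_c[cand$c[i]]) {
      used_t[cand$t[i]] <- TRUE; used_c[cand$c[i]] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fn = sum(!used_t), fp = sum(!used_c))
}
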