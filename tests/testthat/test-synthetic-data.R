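test_that("simulate_genome handles empty, deterministic and infeasible cases", {
  # empty gene list
  g0 <- simulate_genome(1, 1e6, 0, 0, seed = 1)
  expect_equal(nrow(g0$genes), 0L)
  expect_equal(g0$chromosomes$length, 1000000L)

  # determinism and non-overlap
  g1 <- simulate_genome(2, 5e6, 200, 0.3, seed = 7)
  g2 <- simulate_genome(2, 5e6, 200, 0.3, seed = 7)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$genes), 200L)
  for (ch in unique(g1$genes$chrom)) {
    gg <- g1$genes[g1$genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  # all features within bounds (constructor validates, but assert anyway)
  expect_true(all(g1$genes$end <= 5e6))
  expect_true(all(g1$exons$start >= 0))

  # infeasible packing: 50 genes of ~5 kb cannot fit 100 kb
  expect_error(
    simulate_genome(1, 1e5, 50, 0, seed = 1,
                    gene_length_range = c(4500L, 5500L)),
    "infeasible|packing"
  )
})

test_that("simulate_genome exon structure is valid", {
  g <- simulate_genome(1, 2e6, 100, 0, seed = 11)
  sp <- split(g$exons, g$exons$gene_id)
  expect_true(all(vapply(sp, function(ex) {
    gene <- g$genes[g$genes$gene_id == ex$gene_id[1], ]
    o <- order(ex$start)
    within <- all(ex$start >= gene$start & ex$end <= gene$end)
    nonov <- all(ex$start[o][-1] >= ex$end[o][-nrow(ex)])
    within && nonov && nrow(ex) >= 1 && nrow(ex) <= 5
  }, TRUE)))
})

test_that("simulate_population_cnvs trivial cases and determinism", {
  g <- simulate_genome(1, 1e6, 0, 0, seed = 1)

  # no loci -> empty calls, empty truth
  s0 <- simulate_population_cnvs(g, 5, 5, n_loci = 0, seed = 1)
  expect_equal(nrow(s0$calls), 0L)
  expect_equal(nrow(s0$truth$loci), 0L)

  # full penetrance, zero jitter: exactly 10 identical calls
  s1 <- simulate_population_cnvs(g, 5, 5, n_loci = 1,
                                 freq_pop1 = 1.0, freq_pop2 = 1.0,
                                 jitter_sd = 0, min_len = 500,
                                 max_len = 500, seed = 2)
  expect_equal(nrow(s1$calls), 10L)
  expect_equal(length(unique(s1$calls$start)), 1L)
  expect_equal(length(unique(s1$calls$end)), 1L)
  expect_equal(s1$calls$end - s1$calls$start, rep(500L, 10L))

  # bit-identical rerun
  s1b <- simulate_population_cnvs(g, 5, 5, n_loci = 1,
                                  freq_pop1 = 1.0, freq_pop2 = 1.0,
                                  jitter_sd = 0, min_len = 500,
                                  max_len = 500, seed = 2)
  expect_identical(s1, s1b)

  # invalid inputs
  expect_error(simulate_population_cnvs(g, 5, 5, n_loci = 1,
                                        freq_pop1 = 1.2, seed = 1),
               "\\[0,1\\]")
  expect_error(simulate_population_cnvs(g, 5, 5, n_loci = 1,
                                        min_len = 500, max_len = 100,
                                        seed = 1),
               "max_len")
  expect_error(simulate_population_cnvs(g, 5, 5, n_loci = 1,
                                        min_len = 10, seed = 1),
               ">= 50")
})

test_that("carrier counts follow the planted per-population frequencies", {
  g <- simulate_genome(1, 5e6, 0, 0, seed = 1)
  # one DEL locus at pop1 freq 0.9, pop2 freq 0.1, 100 accessions each;
  # carrier counts must fall within central 99% binomial bounds
  lo1 <- qbinom(0.005, 100, 0.9); hi1 <- qbinom(0.995, 100, 0.9)
  lo2 <- qbinom(0.005, 100, 0.1); hi2 <- qbinom(0.995, 100, 0.1)
  s <- simulate_population_cnvs(g, 100, 100, n_loci = 1,
                                freq_pop1 = 0.9, freq_pop2 = 0.1,
                                del_dup_ratio = 1e9, jitter_sd = 0,
                                seed = 42)
  acc <- s$truth$carriers$accession
  n1 <- sum(grepl("^C", acc)); n2 <- sum(grepl("^W", acc))
  expect_gte(n1, lo1); expect_lte(n1, hi1)
  expect_gte(n2, lo2); expect_lte(n2, hi2)
})

test_that("jittered calls keep >= 90% reciprocal overlap with their locus", {
  g <- simulate_genome(1, 5e6, 0, 0, seed = 1)
  s <- simulate_population_cnvs(g, 30, 30, n_loci = 10,
                                freq_pop1 = c(0.5, 1), freq_pop2 = c(0.5, 1),
                                jitter_sd = 50, min_len = 200,
                                max_len = 2000, seed = 9)
  # map each call back to its locus via the carrier table order
  loci <- s$truth$loci
  for (i in seq_len(nrow(s$calls))) {
    call <- s$calls[i, ]
    lr <- loci[loci$chrom == call$chrom &
                 abs(loci$start - call$start) ==
                 min(abs(loci$start - call$start)), ][1, ]
    ov <- max(0, min(call$end, lr$end) - max(call$start, lr$start))
    expect_gte(ov, 0.9 * (call$end - call$start))
    expect_gte(ov, 0.9 * (lr$end - lr$start))
    expect_gte(call$end - call$start, 200)
  }
})

test_that("snp simulator: MAF floor, determinism, perfect-LD limit", {
  g <- simulate_genome(1, 2e5, 0, 0, seed = 1)
  snp <- simulate_snp_genotypes(g, 40, 100, n_founders = 6,
                                block_length = 1e4, maf_floor = 0.05,
                                seed = 3)
  expect_equal(nrow(snp$markers), 100L)
  expect_true(min(snp$maf) >= 0.05)
  expect_true(all(diff(snp$markers$pos) > 0))
  snp2 <- simulate_snp_genotypes(g, 40, 100, n_founders = 6,
                                 block_length = 1e4, maf_floor = 0.05,
                                 seed = 3)
  expect_identical(snp, snp2)

  # two founders, block length >> chromosome: only two haplotype classes,
  # so every SNP pair is in complete LD (r^2 = 1)
  perf <- simulate_snp_genotypes(g, 30, 20, n_founders = 2,
                                 block_length = 1e9, maf_floor = 0.05,
                                 seed = 5)
  pairs <- combn(20, 2)
  r2s <- apply(pairs, 2, function(p) {
    r2(perf$dosage[p[1], ], perf$dosage[p[2], ])
  })
  expect_equal(r2s, rep(1, ncol(pairs)), tolerance = 1e-12)
})

test_that("snp simulator produces distance-decaying LD", {
  g <- simulate_genome(1, 1e6, 0, 0, seed = 1)
  snp <- simulate_snp_genotypes(g, 60, 300, n_founders = 10,
                                block_length = 2e4, maf_floor = 0.05,
                                seed = 8)
  pos <- snp$markers$pos
  # adjacent pairs vs pairs more than 10 blocks apart
  adj <- vapply(seq_len(299), function(i) {
    r2(snp$dosage[i, ], snp$dosage[i + 1, ])
  }, 1.0)
  far_idx <- which(outer(pos, pos, function(a, b) b - a) > 2e5,
                   arr.ind = TRUE)
  far_idx <- far_idx[sample.int(nrow(far_idx), 300), , drop = FALSE]
  far <- vapply(seq_len(nrow(far_idx)), function(k) {
    r2(snp$dosage[far_idx[k, 1], ], snp$dosage[far_idx[k, 2], ])
  }, 1.0)
  expect_gt(mean(adj, na.rm = TRUE), mean(far, na.rm = TRUE))
})

test_that("snp simulator errors when the MAF floor is unreachable", {
  g <- simulate_genome(1, 100, 0, 0, seed = 1)
  # more SNPs than the chromosome has distinct positions
  expect_error(
    simulate_snp_genotypes(g, 4, 500, n_founders = 2,
                           block_length = 1e4, maf_floor = 0.05,
                           seed = 1, max_redraws = 2),
    "could not reach"
  )
})

test_that("cn matrix: baseline, planted shifts, noise calibration", {
  g <- simulate_genome(1, 1e6, 20, 0, seed = 2)
  s0 <- simulate_population_cnvs(g, 10, 10, n_loci = 0, seed = 1)
  cn0 <- simulate_cn_matrix(g, s0$truth, noise_sd = 0, seed = 1)
  expect_true(all(cn0$cn == 2.0))

  # plant one DEL locus exactly on a gene, carried by all of pop2 only
  gene <- g$genes[1, ]
  truth <- cnvpop:::cnv_truth(
    loci = data.frame(locus_id = "L1", chrom = gene$chrom,
                      start = gene$start, end = gene$end, svtype = "DEL",
                      freq_pop1 = 0, freq_pop2 = 1, differentiated = TRUE,
                      stringsAsFactors = FALSE),
    carriers = data.frame(locus_id = "L1",
                          accession = sprintf("W%03d", 1:10),
                          stringsAsFactors = FALSE),
    populations = s0$truth$populations,
    differentiated_genes = gene$gene_id, seed = 1)
  cn1 <- simulate_cn_matrix(g, truth, noise_sd = 0, seed = 1)
  wild <- truth$populations$accession[truth$populations$population == "wild"]
  cult <- setdiff(truth$populations$accession, wild)
  expect_equal(unname(rowMeans(cn1$cn[gene$gene_id, wild, drop = FALSE])), 1.0)
  expect_equal(unname(rowMeans(cn1$cn[gene$gene_id, cult, drop = FALSE])), 2.0)

  # noise_sd 0.2 at n = 200: per-gene sample SD within chi-square-style
  # bounds [0.1, 0.3] for unplanted genes
  sbig <- simulate_population_cnvs(g, 100, 100, n_loci = 0, seed = 3)
  cn2 <- simulate_cn_matrix(g, sbig$truth, noise_sd = 0.2, seed = 4)
  sds <- apply(cn2$cn, 1, sd)
  expect_true(all(sds > 0.1 & sds < 0.3))
})

test_that("call tables round-trip through write_cnv_calls/read_cnv_calls", {
  g <- simulate_genome(2, 1e6, 0, 0, seed = 1)
  s <- simulate_population_cnvs(g, 15, 10, n_loci = 12,
                                freq_pop1 = c(0.3, 1), freq_pop2 = c(0.3, 1),
                                jitter_sd = 25, seed = 6)
  for (dialect in c("0half", "1incl")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_cnv_calls(s$calls, path, coords = dialect)
    expect_identical(read_cnv_calls(path), s$calls)
  }
})

test_that("planted loci are recovered exactly as CNVRs at zero jitter", {
  g <- simulate_genome(2, 2e6, 0, 0, seed = 1)
  s <- simulate_population_cnvs(g, 40, 20, n_loci = 15,
                                freq_pop1 = c(0.6, 1), freq_pop2 = c(0.6, 1),
                                jitter_sd = 0, seed = 13)
  cnvrs <- merge_to_cnvrs(filter_calls(s$calls), min_carriers = 10)
  loci <- s$truth$loci[order(s$truth$loci$chrom, s$truth$loci$start), ]
  # all loci have expected carriers >= 0.6*60 = 36 >> 10, so every locus
  # must come back as exactly one CNVR with identical extent
  expect_equal(nrow(cnvrs), nrow(loci))
  expect_equal(cnvrs$chrom, loci$chrom)
  expect_equal(cnvrs$start, loci$start)
  expect_equal(cnvrs$end, loci$end)
})
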