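as_cnvr_df <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

test_that("cn_variable_genes uses the union fraction with strict cutoff", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 0L,
                      end = 1000L, stringsAsFactors = FALSE)

  # single CNVR covering 501/1000 -> fraction 0.501 > 0.5 -> included
  out <- cn_variable_genes(genes, as_cnvr_df("chr1", 0, 501))
  expect_equal(out$fraction, 0.501)

  # exactly half is NOT included (strict inequality)
  expect_equal(nrow(cn_variable_genes(genes, as_cnvr_df("chr1", 0, 500))),
               0L)

  # two overlapping CNVRs: union 550 bp -> 0.55
  out2 <- cn_variable_genes(genes, as_cnvr_df("chr1", c(0, 200),
                                              c(300, 550)))
  expect_equal(out2$covered_bp, 550L)
  expect_equal(out2$fraction, 0.55)

  # gene fully inside a CNVR -> fraction 1
  out3 <- cn_variable_genes(genes, as_cnvr_df("chr1", 0, 5000))
  expect_equal(out3$fraction, 1.0)
})

test_that("cn_variable_genes is monotone in min_frac", {
  set.seed(9)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:30), chrom = "chr1",
                      start = seq(0L, 29000L, by = 1000L),
                      end = seq(0L, 29000L, by = 1000L) + 800L,
                      stringsAsFactors = FALSE)
  cn_start <- sample.int(29000, 40)
  cnvrs <- as_cnvr_df("chr1", cn_start, cn_start + sample(100:900, 40,
                                                          replace = TRUE))
  prev <- cn_variable_genes(genes, cnvrs, min_frac = 0.2)$gene_id
  for (f in c(0.4, 0.6, 0.8)) {
    cur <- cn_variable_genes(genes, cnvrs, min_frac = f)$gene_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("feature_impact percentages match hand-counted fixtures", {
  # 10 kb genome, one 2 kb gene with a 1 kb exon; DEL [500,1500)
  # overlaps the exon (gene at [1000,3000), exon [1000,2000)) by 500 bp
  g <- genome_model(
    data.frame(chrom = "chr1", length = 10000L),
    genes = data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                       end = 3000L, strand = "+",
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                       end = 2000L, stringsAsFactors = FALSE))
  calls <- make_calls("S1", "chr1", 500, 1500, "DEL")
  fi <- feature_impact(g, calls, flank_bp = 500L)
  row <- function(cl) fi[fi$feature_class == cl, ]
  expect_equal(row("exon")$del_pct, 50.0)
  expect_equal(row("exon")$total_bp, 1000)
  expect_equal(row("intron")$del_pct, 0.0)
  expect_equal(row("gene_body")$del_pct, 100 * 500 / 2000)
  expect_equal(row("flank_upstream")$del_pct, 100.0)  # [500,1000) covered
  expect_equal(row("CDS")$dup_pct, 0.0)

  # no calls -> all zero
  fi0 <- feature_impact(g, calls[0, , drop = FALSE])
  expect_true(all(fi0$del_pct == 0 & fi0$dup_pct == 0, na.rm = TRUE))

  # whole-chromosome DEL -> every class 100% for DEL
  fi1 <- feature_impact(g, make_calls("S1", "chr1", 0, 10000, "DEL"))
  expect_true(all(fi1$del_pct[fi1$total_bp > 0] == 100))
})

test_that("base-pair accounting conserves totals against per-base scan", {
  set.seed(33)
  for (rep in 1:5) {
    L <- 50000L
    n_genes <- 6L
    g <- simulate_genome(1, L, n_genes, 0, seed = rep,
                         gene_length_range = c(2000L, 4000L))
    chrom <- g$chromosomes$chrom[1]
    start <- sample.int(L - 3000L, 12)
    calls <- make_calls(sprintf("S%02d", 1:12), chrom, start,
                        start + sample(100:3000, 12, replace = TRUE),
                        sample(c("DEL", "DUP"), 12, replace = TRUE))
    fi <- feature_impact(g, calls, flank_bp = 1000L)

    # brute-force per-base class assignment with the documented
    # precedence: gene bodies (exon over intron) first, then upstream
    # flanks where still unassigned, then downstream flanks, then
    # intergenic; 1-based vector index = 0-based position + 1
    cls <- rep("intergenic", L)
    for (i in seq_len(nrow(g$genes))) {
      gn <- g$genes[i, ]
      cls[(gn$start + 1L):gn$end] <- "intron"
    }
    for (i in seq_len(nrow(g$exons))) {
      ex <- g$exons[i, ]
      cls[(ex$start + 1L):ex$end] <- "exon"
    }
    flank_of <- function(gn, which) {
      upstream <- (gn$strand == "+") == (which == "up")
      if (upstream) {
        lo <- max(0L, gn$start - 1000L); hi <- gn$start
      } else {
        lo <- gn$end; hi <- min(L, gn$end + 1000L)
      }
      if (hi <= lo) integer() else lo:(hi - 1L)
    }
    for (i in seq_len(nrow(g$genes))) {
      p <- flank_of(g$genes[i, ], "up")
      p <- p[cls[p + 1L] == "intergenic"]
      cls[p + 1L] <- "flank_upstream"
    }
    for (i in seq_len(nrow(g$genes))) {
      p <- flank_of(g$genes[i, ], "down")
      p <- p[cls[p + 1L] == "intergenic"]
      cls[p + 1L] <- "flank_downstream"
    }
    del_cov <- dup_cov <- logical(L)
    for (i in seq_len(nrow(calls))) {
      span <- (calls$start[i] + 1L):calls$end[i]
      if (calls$svtype[i] == "DEL") del_cov[span] <- TRUE else
        dup_cov[span] <- TRUE
    }
    for (cl in c("exon", "intron", "flank_upstream", "flank_downstream",
                 "intergenic")) {
      in_cl <- cls == cl
      want_total <- sum(in_cl)
      want_del <- sum(in_cl & del_cov)
      want_dup <- sum(in_cl & dup_cov)
      got <- fi[fi$feature_class == cl, ]
      expect_equal(got$total_bp, want_total, info = cl)
      expect_equal(got$del_bp, want_del, info = cl)
      expect_equal(got$dup_bp, want_dup, info = cl)
    }
    # disjoint classes sum to the DEL union length exactly
    disjoint <- c("exon", "intron", "flank_upstream", "flank_downstream",
                  "intergenic")
    expect_equal(sum(fi$del_bp[fi$feature_class %in% disjoint]),
                 sum(del_cov))
    expect_equal(sum(fi$total_bp[fi$feature_class %in% disjoint]), L)
  }
})

test_that("flank precedence resolves up/down collisions deterministically", {
  # two genes 1 kb apart on opposite strands: the gap is upstream flank
  # of both; upstream must win over downstream and bases counted once
  g <- genome_model(
    data.frame(chrom = "chr1", length = 10000L),
    genes = data.frame(gene_id = c("a", "b"), chrom = "chr1",
                       start = c(2000L, 4000L), end = c(3000L, 5000L),
                       strand = c("-", "+"), stringsAsFactors = FALSE))
  fi <- feature_impact(g, make_calls("s", "chr1", 0, 1, "DEL")[0, ],
                       flank_bp = 2000L)
  fu <- fi$total_bp[fi$feature_class == "flank_upstream"]
  fd <- fi$total_bp[fi$feature_class == "flank_downstream"]
  # gap [3000,4000) is upstream of both genes -> 1000 bp counted once;
  # plus [5000,7000) upstream of none... gene a '-' upstream is [3000,5000)
  # clipped by gene b body -> [3000,4000); gene b '+' upstream [2000,4000)
  # minus gene a body -> [3000,4000). Downstream: a' [0,2000), b [5000,7000)
  expect_equal(fu, 1000)
  expect_equal(fd, 4000)
  expect_equal(sum(fi$total_bp[fi$feature_class %in%
    c("exon", "intron", "flank_upstream", "flank_downstream",
      "intergenic")]), 10000)
})

test_that("window_density counts feature starts per window", {
  g3 <- genome_model(data.frame(chrom = "chr1", length = 3000000L))
  # one feature at 1.5 Mb: second 1-Mb window
  feats <- data.frame(chrom = "chr1", start = 1500000L)
  wd <- window_density(feats, g3, window_bp = 1000000L)
  expect_equal(wd$count, c(0L, 1L, 0L))

  # empty feature set -> all zeros
  wd0 <- window_density(feats[0, , drop = FALSE], g3,
                        window_bp = 1000000L)
  expect_equal(wd0$count, rep(0L, 3))

  # sliding 1 Mb / 500 kb on 3 Mb -> 5 windows
  wds <- window_density(feats, g3, window_bp = 1000000L,
                        step_bp = 500000L)
  expect_equal(nrow(wds), 5L)
  expect_equal(wds$win_start, c(0, 0.5e6, 1e6, 1.5e6, 2e6))
  expect_equal(wds$count, c(0L, 0L, 1L, 1L, 0L))

  # chromosome shorter than one window -> single clipped window
  gshort <- genome_model(data.frame(chrom = "chr1", length = 400000L))
  wdc <- window_density(feats[0, , drop = FALSE], gshort,
                        window_bp = 1000000L)
  expect_equal(nrow(wdc), 1L)
  expect_equal(wdc$win_end, 400000)
})

test_that("density_correlation matches hand covariance arithmetic", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(density_correlation(a, a)$r, 1)
  expect_equal(density_correlation(a, -a)$r, -1)

  b <- c(2, 1, 4, 3, 6)
  got <- density_correlation(a, b)
  num <- mean(a * b) - mean(a) * mean(b)
  den <- sqrt((mean(a^2) - mean(a)^2) * (mean(b^2) - mean(b)^2))
  expect_equal(got$r, num / den, tolerance = 1e-12)
  expect_true(got$p_value > 0 && got$p_value <= 1)
  expect_error(density_correlation(a, b[1:3]), "equal length")
})

test_that("term_enrichment matches the hypergeometric oracle", {
  # term genes == study genes, 10 of 100: p = 1 / C(100, 10)
  universe <- sprintf("g%03d", 1:100)
  study <- universe[1:10]
  tm <- data.frame(gene = study, term = "T1", stringsAsFactors = FALSE)
  out <- term_enrichment(study, universe, tm)
  expect_equal(out$p_value, 1 / choose(100, 10), tolerance = 1e-10)

  # a term disjoint from the study is never enriched (p = 1)
  tm2 <- rbind(tm, data.frame(gene = universe[90:95], term = "T2"))
  out2 <- term_enrichment(study, universe, tm2)
  expect_equal(out2$p_value[out2$term == "T2"], 1, tolerance = 1e-10)

  # exhaustive hypergeometric-tail oracle on small universes
  set.seed(61)
  for (rep in 1:20) {
    Nu <- sample(8:25, 1)
    uni <- sprintf("u%02d", seq_len(Nu))
    st <- sample(uni, sample(2:(Nu - 2), 1))
    tg <- sample(uni, sample(2:(Nu - 2), 1))
    k <- length(intersect(st, tg))
    got <- term_enrichment(st, uni,
                           data.frame(gene = tg, term = "T",
                                      stringsAsFactors = FALSE))
    # oracle: sum the hypergeometric pmf over the upper tail by
    # enumeration of achievable overlap counts
    K <- length(tg); n <- length(st)
    kk <- k:min(K, n)
    want <- sum(choose(K, kk) * choose(Nu - K, n - kk) / choose(Nu, n))
    expect_equal(got$p_value, want, tolerance = 1e-10)
  }
})

test_that("term_enrichment applies BH and skips empty terms", {
  # BH on (0.01, 0.02, 0.03, 0.04): adjusted = (0.04, 0.04, 0.04, 0.04)
  # all significant at 0.05 — verified through p.adjust equivalence on
  # the output of a constructed 4-term problem
  p_raw <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p_raw, "BH"), rep(0.04, 4))

  universe <- sprintf("g%02d", 1:40)
  study <- universe[1:10]
  tm <- rbind(
    data.frame(gene = universe[1:8], term = "A"),
    data.frame(gene = universe[c(1:4, 30:33)], term = "B"),
    data.frame(gene = "not_in_universe", term = "ghost"))
  out <- term_enrichment(study, universe, tm)
  expect_equal(attr(out, "skipped"), "ghost")
  expect_equal(out$p_adj, p.adjust(out$p_value, "BH"))
  expect_error(term_enrichment(c(study, "alien"), universe, tm), "subset")
})

test_that("te_overlap_fraction counts CNVRs touching TEs", {
  cnvrs <- as_cnvr_df("chr1", c(0, 1000, 2000, 3000),
                      c(500, 1500, 2500, 3500))
  expect_equal(te_overlap_fraction(cnvrs,
                                   as_cnvr_df("chr1", 0, 1)[0, ]), 0)
  expect_equal(te_overlap_fraction(cnvrs, as_cnvr_df("chr1", 0, 4000)), 1)
  # 3 of 4 overlap
  tes <- as_cnvr_df("chr1", c(400, 1400, 2400), c(600, 1600, 2600))
  expect_equal(te_overlap_fraction(cnvrs, tes), 0.75)
})
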