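test_that("single-linkage clustering joins CTSSs within max_gap per strand", {
  t1 <- tbl(c(100, 105, 160), c(5, 5, 5), tpm = c(5, 5, 5))
  cl <- cluster_ctss(t1, max_gap = 20)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$start, c(100L, 160L))
  expect_equal(cl$end, c(105L, 160L))
  # identical positions on opposite strands never merge
  t2 <- ctss_table(c("chr1", "chr1"), c(100L, 100L), c("+", "-"), c(2, 2),
                   tpm = c(2, 2))
  expect_equal(nrow(cluster_ctss(t2)), 2L)
  expect_equal(nrow(cluster_ctss(t1[0, ])), 0L)
  expect_error(cluster_ctss(t1, max_gap = -1), "max_gap")
})

test_that("clustering equals the brute-force linkage oracle", {
  for (s in 1:4) {
    set.seed(s)
    n <- sample(50:200, 1)
    t1 <- ctss_table(sample(c("chr1", "chr2"), n, TRUE),
                     sample(1:400, n), sample(c("+", "-"), n, TRUE),
                     sample(1:20, n, TRUE))
    t1$tpm <- t1$count
    gap <- sample(c(5, 20, 50), 1)
    cl <- cluster_ctss(t1, max_gap = gap, min_tpm = 0)
    members <- attr(cl, "members")
    got <- partition_signature(split(
      paste(members$chrom, members$pos, members$strand),
      members$cluster_id))
    want <- partition_signature(
      brute_linkage(t1$chrom, t1$pos, t1$strand, gap))
    expect_equal(got, want)
  }
})

test_that("interquantile summaries follow cumulative-sum arithmetic", {
  mk <- function(pos, tpm, strand = "+") {
    data.frame(chrom = "chr1", pos = pos, strand = strand, tpm = tpm)
  }
  # 10 equal positions: q0.1 at the first, q0.9 at the ninth
  s <- summarize_cluster(mk(101:110, rep(1, 10)))
  expect_equal(s$q_low_pos, 101L)
  expect_equal(s$q_high_pos, 109L)
  expect_equal(s$iq_width, 9L)
  expect_equal(s$shape_class, "broad")
  # single CTSS
  s1 <- summarize_cluster(mk(55, 4))
  expect_equal(s1$iq_width, 1L)
  expect_equal(s1$shape_class, "sharp")
  # one CTSS holding 98% of the signal absorbs both quantiles
  s2 <- summarize_cluster(mk(100:102, c(1, 98, 1)))
  expect_equal(s2$q_low_pos, 101L)
  expect_equal(s2$q_high_pos, 101L)
  expect_equal(s2$iq_width, 1L)
  expect_equal(s2$dominant_pos, 101L)
  # minus strand mirrors: cumulative runs 3' <- 5' in genomic terms
  sm <- summarize_cluster(mk(101:110, c(9, rep(1, 9)), strand = "-"))
  expect_equal(sm$dominant_pos, 101L)
  expect_lte(sm$q_low_pos, sm$q_high_pos)
  # dominant tie breaks toward the 5' end of the strand
  tie_p <- summarize_cluster(mk(c(10, 11), c(5, 5), "+"))
  expect_equal(tie_p$dominant_pos, 10L)
  tie_m <- summarize_cluster(mk(c(10, 11), c(5, 5), "-"))
  expect_equal(tie_m$dominant_pos, 11L)
})

test_that("quantile positions bracket the dominant and fit the span", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(1:30, 1)
    cl <- data.frame(chrom = "c", pos = sort(sample(1:100, n)),
                     strand = sample(c("+", "-"), 1),
                     tpm = stats::runif(n, 0.1, 50))
    s <- summarize_cluster(cl)
    expect_lte(s$start, s$q_low_pos)
    expect_lte(s$q_low_pos, s$q_high_pos)
    expect_lte(s$q_high_pos, s$end)
    expect_lte(s$iq_width, s$end - s$start + 1L)
    expect_equal(s$dominant_tpm, max(cl$tpm))
  }
})

test_that("consensus clusters union overlapping clusters and conserve totals", {
  a <- cluster_ctss(tbl(c(100, 110, 300), c(5, 5, 8), tpm = c(5, 5, 8)))
  b <- cluster_ctss(tbl(c(105, 120, 700), c(4, 4, 2), tpm = c(4, 4, 2)))
  cons <- merge_consensus(list(s1 = a, s2 = b))
  # overlapping 100-110 / 105-120 merge; 300 and 700 stay separate
  expect_equal(nrow(cons), 3L)
  merged <- cons[cons$start == 100, ]
  expect_equal(merged$end, 120L)
  expect_equal(merged$tpm_s1, 10)
  expect_equal(merged$tpm_s2, 8)
  # a sample with no signal in a region reports 0 there
  expect_equal(cons$tpm_s2[cons$start == 300], 0)
  expect_equal(cons$tpm_s1[cons$start == 700], 0)
  # per-sample totals across consensus regions conserve cluster totals
  expect_equal(sum(cons$tpm_s1), sum(a$total_tpm))
  expect_equal(sum(cons$tpm_s2), sum(b$total_tpm))
})

test_that("consensus regions do not depend on sample order", {
  set.seed(21)
  mk <- function() {
    n <- 40
    t1 <- ctss_table(rep("chr1", n), sample(1:2000, n),
                     sample(c("+", "-"), n, TRUE), sample(2:9, n, TRUE))
    t1$tpm <- t1$count
    cluster_ctss(t1)
  }
  sets <- list(a = mk(), b = mk(), c = mk())
  r1 <- merge_consensus(sets)
  r2 <- merge_consensus(sets[c("c", "a", "b")])
  key <- function(x) paste(x$chrom, x$strand, x$start, x$end)
  expect_setequal(key(r1), key(r2))
  for (s in names(sets)) {
    expect_equal(x <- r1[[paste0("tpm_", s)]][order(key(r1))],
                 r2[[paste0("tpm_", s)]][order(key(r2))])
  }
})

test_that("genomic location annotation applies the stated precedence", {
  ann <- list(
    transcripts = data.frame(chrom = "chr1", start = 1000, end = 5000,
                             strand = "+"),
    exons = data.frame(chrom = "chr1", start = c(1000, 3000),
                       end = c(1200, 3300), strand = "+"),
    utr5 = data.frame(chrom = "chr1", start = 1000, end = 1100,
                      strand = "+"))
  mk_cl <- function(pos, strand = "+") {
    cl <- cluster_ctss(tbl(pos, rep(5, length(pos)), strand = strand,
                           tpm = rep(5, length(pos))), max_gap = 0)
    cl
  }
  expect_equal(annotate_location(mk_cl(1000), ann), "promoter")
  # inside both the promoter window (500..1100) and an exon: promoter wins
  expect_equal(annotate_location(mk_cl(1050), ann), "promoter")
  expect_equal(annotate_location(mk_cl(1150), ann), "exon")
  expect_equal(annotate_location(mk_cl(3100), ann), "exon")
  expect_equal(annotate_location(mk_cl(2000), ann), "intron")
  expect_equal(annotate_location(mk_cl(2000, "-"), ann), "antisense")
  expect_equal(annotate_location(mk_cl(20000), ann), "intergenic")
  bad <- mk_cl(10)
  bad$chrom <- "chrX"
  expect_error(annotate_location(bad, ann), "chrX")
})

test_that("subsampling draws without replacement to the exact target", {
  t1 <- tbl(1:50, rep(20, 50))
  same <- subsample_library(t1, fraction = 1)
  expect_equal(same$count, t1$count)
  sub <- subsample_library(t1, n_tags = 123, seed = 5)
  expect_equal(sum(sub$count), 123)
  expect_true(all(sub$count <= 20))
  expect_error(subsample_library(t1, fraction = 1.2), "fraction")
  expect_error(subsample_library(t1, n_tags = 1e6), "exceeds")
})
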