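toy_genome <- c(chr1 = "ACGTACGTACGTACGTACGTCATGTTACGTACGTACGTAC")

test_that("initiator composition is strand-aware and normalized", {
  # chr1[21:22] = "CA": a + CTSS at 22 reads initiator CA
  t_plus <- tbl(22, 5)
  comp <- ctss_composition(t_plus, toy_genome)
  expect_equal(unname(comp$dinuc_freq["CA"]), 1)
  expect_equal(unname(comp$base_freq["A"]), 1)
  # a - CTSS over plus-strand "TG" reverse-complements to CA:
  # chr1[23:24] = "TG", so a - CTSS at 23 reads initiator CA
  t_minus <- tbl(23, 5, strand = "-")
  comp_m <- ctss_composition(t_minus, toy_genome)
  expect_equal(unname(comp_m$dinuc_freq["CA"]), 1)
  expect_equal(sum(comp_m$dinuc_freq), 1, tolerance = 1e-12)
  # chromosome-edge CTSS excluded with a warning
  expect_warning(ctss_composition(tbl(1, 2), toy_genome), "edge")
})

test_that("dinucleotide density matrices are indicators of the pattern", {
  polyA <- c(chrA = paste(rep("A", 4000), collapse = ""))
  cl <- cluster_ctss(tbl(2000, 10, chrom = "chrA", tpm = 10))
  ww <- dinuc_density_matrix(cl, polyA, "WW", flank = 50)
  gc <- dinuc_density_matrix(cl, polyA, "GC", flank = 50)
  expect_true(all(ww == 1))
  expect_true(all(gc == 0))
  set.seed(3)
  rnd <- c(chrA = paste(sample(c("A", "C", "G", "T"), 4000, TRUE),
                        collapse = ""))
  m <- dinuc_density_matrix(cl, rnd, "TA", flank = 50)
  expect_true(all(m %in% c(0, 1)))
  expect_equal(ncol(m), 101L)
})

test_that("implanted TATA elements appear as a TA stripe at -30 in sharp rows", {
  g <- generate_genome(n_promoters = 80, sharp_fraction = 1, seed = 17)
  lib <- simulate_library(g, depth_tags = 8e4, seed = 18)
  cl <- cluster_ctss(normalize_power_law(lib))
  m <- dinuc_density_matrix(cl, g$genome, "TA", flank = 60)
  # TATAAA at -30 always contains TA at its first two bases
  expect_gt(mean(m[, "-30"]), 0.9)
  expect_lt(mean(m[, "-45"]), 0.4)
})

test_that("sequence features are invariant under genome reverse-complement", {
  g <- generate_genome(n_promoters = 40, seed = 23)
  lib <- simulate_library(g, depth_tags = 4e4, seed = 24)
  cl <- cluster_ctss(normalize_power_law(lib))
  m1 <- dinuc_density_matrix(cl, g$genome, "TA", flank = 30)
  # reverse-complement the chromosome and flip every strand
  L <- nchar(g$genome[["chrS"]])
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", g$genome[["chrS"]]),
                           "")[[1]]), collapse = "")
  cl2 <- cl
  cl2$strand <- ifelse(cl$strand == "+", "-", "+")
  cl2$dominant_pos <- L + 1L - cl$dominant_pos
  tmp <- L + 1L - cl2$end; cl2$end <- L + 1L - cl2$start; cl2$start <- tmp
  m2 <- dinuc_density_matrix(cl2, c(chrS = rc), "TA", flank = 30)
  # rows are ordered by iq_width in both; matrices must agree entirely
  expect_equal(m1, m2, ignore_attr = TRUE)
})

test_that("PWM scanning applies the score-range threshold rule", {
  pwm <- tata_pwm()
  expect_gt(pwm$max_score, pwm$min_score)
  # consensus TATAAA.. at -30 from the CTSS: best window hits
  g <- generate_genome(n_promoters = 30, sharp_fraction = 1, seed = 29)
  lib <- simulate_library(g, depth_tags = 3e4, seed = 30)
  cl <- cluster_ctss(normalize_power_law(lib))
  sc <- scan_pwm(cl, g$genome, pwm)
  expect_gte(sc$percent_hit, 90)
  expect_true(all(sc$best_offset[sc$hit] >= -35 & sc$best_offset[sc$hit] <= -25))
})

test_that("PWM hits equal a brute-force all-window scorer", {
  pwm <- tata_pwm()
  set.seed(37)
  genome <- c(chrT = paste(sample(c("A", "C", "G", "T"), 5000, TRUE),
                           collapse = ""))
  pos <- seq(200, 4800, by = 240)
  cl <- cluster_ctss(tbl(pos, rep(10, length(pos)), chrom = "chrT",
                         tpm = rep(10, length(pos))))
  sc <- scan_pwm(cl, genome, pwm, search_window = c(-35, -25))
  thr <- pwm$min_score + 0.8 * (pwm$max_score - pwm$min_score)
  for (i in seq_len(nrow(cl))) {
    # brute: score every window whose start lies in [-35, -25]
    a <- cl$dominant_pos[i] - 35
    b <- cl$dominant_pos[i] - 25 + pwm$length - 1
    best <- brute_pwm_best(pwm, substr(genome[["chrT"]], a, b))
    expect_equal(sc$best_score[i], best)
    expect_equal(sc$hit[i], !is.na(best) && best >= thr)
  }
  # uniform-random G/C sequence essentially never matches a TATA box
  gc_only <- c(chrT = paste(sample(c("G", "C"), 5000, TRUE), collapse = ""))
  sc_gc <- scan_pwm(cl, gc_only, pwm)
  expect_lt(sc_gc$percent_hit, 5)
})

test_that("ambiguous bases make a window unscorable, not a hit", {
  genome <- c(chrN = paste0(paste(rep("A", 60), collapse = ""), "N",
                            paste(rep("A", 60), collapse = "")))
  cl <- cluster_ctss(tbl(89, 10, chrom = "chrN", tpm = 10))
  # every 8-mer window starting in [-35, -28] from 89 covers position 61
  # (the N), so no window is scorable
  sc <- scan_pwm(cl, genome, tata_pwm(), search_window = c(-35, -28))
  expect_true(is.na(sc$best_score[1]))
  expect_false(sc$hit[1])
})

test_that("WW periodicity recovers the implanted 10.5-bp phase", {
  g <- generate_genome(n_promoters = 200, sharp_fraction = 0, seed = 43)
  lib <- simulate_library(g, depth_tags = 2e5, seed = 44)
  cl <- cluster_ctss(normalize_power_law(lib))
  broad <- cl[cl$shape_class == "broad", ]
  attr(broad, "members") <- attr(cl, "members")
  pe <- ww_periodicity(broad, g$genome)
  expect_equal(pe$period, 10.5, tolerance = 0.5 / 10.5)
  expect_gt(pe$peak_to_median, 3)
  # random-CTSS alignment attenuates the phased signal
  pe_r <- ww_periodicity(broad, g$genome, align = "random", seed = 5)
  expect_lt(pe_r$amplitude, pe$amplitude)
  expect_error(ww_periodicity(broad, g$genome, region = c(1, 30)),
               "shorter")
})

test_that("random sequence shows no significant spectral peak", {
  set.seed(47)
  rnd <- c(chrR = paste(sample(c("A", "C", "G", "T"), 3e5, TRUE),
                        collapse = ""))
  fake <- cluster_ctss(tbl(seq(1000, by = 500, length.out = 400),
                           rep(10, 400), chrom = "chrR",
                           tpm = rep(10, 400)))
  pe <- ww_periodicity(fake, rnd)
  expect_lt(pe$peak_to_median, 3)
})

test_that("interval overlays tally overlaps and split by shape class", {
  t1 <- tbl(c(100, 101, 500, 2000, 2001, 2002, 2010, 5000), rep(5, 8),
            tpm = rep(5, 8))
  cl <- cluster_ctss(t1, max_gap = 20)
  expect_equal(nrow(cl), 4L)
  # intervals covering 2 of the 4 cluster windows
  iv <- data.frame(chrom = "chr1", start = c(90, 1990), end = c(120, 1995))
  ov <- interval_overlay(cl, intervals = iv, flank = 50)
  expect_equal(ov$overall$overlap_fraction, 0.5)
  none <- interval_overlay(cl, intervals = iv[0, ], flank = 50)
  expect_equal(none$overall$overlap_fraction, 0)
  every <- interval_overlay(cl,
                            intervals = data.frame(chrom = "chr1",
                                                   start = 1, end = 6000),
                            flank = 50)
  expect_equal(every$overall$overlap_fraction, 1)
  expect_equal(every$sharp$n + every$broad$n, nrow(cl))
})

test_that("coverage profiles average strand-oriented positional signal", {
  cov <- data.frame(chrom = "chr1", start = 95, end = 105, value = 2)
  cl <- cluster_ctss(tbl(100, 9, tpm = 9))
  ov <- interval_overlay(cl, coverage = cov, flank = 10)
  prof <- ov$overall$profile
  expect_equal(unname(prof["0"]), 2)
  expect_equal(unname(prof["5"]), 2)
  expect_equal(unname(prof["-10"]), 0)
  # unsorted coverage is sorted with a warning
  cov2 <- data.frame(chrom = "chr1", start = c(200, 95), end = c(210, 105),
                     value = c(1, 2))
  expect_warning(interval_overlay(cl, coverage = cov2, flank = 10),
                 "unsorted")
})
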