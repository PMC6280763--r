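test_that("generated genomes carry the promised promoter features", {
  g <- generate_genome(n_promoters = 60, sharp_fraction = 0.5, seed = 3)
  tr <- g$truth
  expect_equal(nrow(tr), 60L)
  expect_equal(sum(tr$class == "sharp"), 30L)
  expect_true(all(tr$spread[tr$class == "sharp"] <= 3))
  expect_true(all(tr$spread[tr$class == "broad"] >= 5))
  # every truth record resolves against the emitted genome: CA initiator
  chars <- strsplit(g$genome[["chrS"]], "")[[1]]
  for (i in seq_len(nrow(tr))) {
    if (tr$strand[i] == "+") {
      expect_equal(paste0(chars[tr$dominant_pos[i] - 1],
                          chars[tr$dominant_pos[i]]), "CA")
    } else {
      expect_equal(paste0(chars[tr$dominant_pos[i]],
                          chars[tr$dominant_pos[i] + 1]), "TG")
    }
  }
  # TATA hit rate on sharp truth positions
  sharp <- tr[tr$class == "sharp", ]
  fake_cl <- data.frame(chrom = sharp$chrom, strand = sharp$strand,
                        dominant_pos = sharp$dominant_pos)
  sc <- scan_pwm(fake_cl, g$genome)
  expect_gte(sc$percent_hit, 90)
  # broad island GC well above background
  gc_at <- function(a, b) mean(chars[a:b] %in% c("G", "C"))
  broad <- tr[tr$class == "broad", ]
  island_gc <- mean(mapply(gc_at, broad$island_start, broad$island_end))
  expect_gt(island_gc, 0.40 + 0.10)
  expect_error(generate_genome(n_promoters = 100, chrom_length = 1000),
               "too short")
})

test_that("genome generation is bit-reproducible under a fixed seed", {
  g1 <- generate_genome(n_promoters = 20, seed = 7)
  g2 <- generate_genome(n_promoters = 20, seed = 7)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth, g2$truth)
  expect_identical(simulate_library(g1, 1e4, seed = 2),
                   simulate_library(g2, 1e4, seed = 2))
})

test_that("simulated libraries honour depth, dominants and slope", {
  g <- generate_genome(n_promoters = 400, seed = 13)
  lib <- simulate_library(g, depth_tags = 5e5, seed = 14)
  expect_equal(sum(lib$count), 5e5)
  expect_error(simulate_library(g, depth_tags = 10), "at least")
  # clustering recovers the true dominant CTSS for nearly all promoters
  cl <- cluster_ctss(normalize_power_law(lib))
  pairs <- pair_clusters_to_truth(cl, g$truth)
  hit <- cl$dominant_pos[pairs$cluster] ==
    g$truth$dominant_pos[pairs$promoter]
  expect_gte(sum(hit) / nrow(g$truth), 0.95)
})

test_that("library counts inherit the configured power-law slope", {
  # sharp promoters put ~90% of tags on one CTSS, so dominant counts track
  # the Pareto weights; the depth is chosen so that tail sits inside the
  # default fit range
  g <- generate_genome(n_promoters = 2000, sharp_fraction = 1, seed = 15)
  lib <- simulate_library(g, depth_tags = 1.2e5, seed = 115)
  fit <- fit_power_law(lib, fit_range = c(10, 1000))
  expect_equal(fit$alpha, 1.25, tolerance = 0.1 / 1.25)
})

test_that("degradation narrows clusters and biases toward G starts", {
  g <- generate_genome(n_promoters = 150, seed = 23)
  lib <- simulate_library(g, depth_tags = 3e5, seed = 24)
  same <- simulate_degradation(lib, 1)
  expect_equal(same$count, lib$count)
  deg <- simulate_degradation(lib, 0.01, seed = 25)
  iq_parent <- cluster_ctss(normalize_power_law(lib))$iq_width
  iq_deg <- cluster_ctss(normalize_power_law(deg))$iq_width
  expect_lt(median(iq_deg), median(iq_parent))
  # PCR resampling restores the original depth
  amp <- simulate_degradation(lib, 0.05, pcr_cycles = 8, seed = 26)
  expect_equal(sum(amp$count), sum(lib$count))
  # G-capture bias raises the G share among +1 bases
  gshare <- function(t1) {
    comp <- ctss_composition(t1, g$genome)
    unname(comp$base_freq["G"])
  }
  biased <- simulate_degradation(lib, 0.3, g_bias = 0.8,
                                 genome = g$genome, seed = 27)
  expect_gt(gshare(biased), gshare(lib))
  expect_error(simulate_degradation(lib, 0), "fraction")
  expect_error(simulate_degradation(lib, 0.5, g_bias = 1), "g_bias")
  expect_error(simulate_degradation(lib, 0.5, g_bias = 0.5), "genome")
})

test_that("carrier spiking hits the leftover fraction with exact flags", {
  g <- generate_genome(n_promoters = 50, seed = 33)
  lib <- simulate_library(g, depth_tags = 1e5, seed = 34)
  d <- design_carrier()
  none <- spike_carrier(lib, d, 0)
  expect_equal(sum(none$table$count), sum(lib$count))
  expect_false(any(none$carrier_origin))
  sp <- spike_carrier(lib, d, 0.27, seed = 35)
  share <- sum(sp$table$count[sp$carrier_origin]) / sum(sp$table$count)
  expect_equal(share, 0.27, tolerance = 0.04)
  # flags partition the table exactly
  expect_equal(sum(sp$carrier_origin) + sum(!sp$carrier_origin),
               nrow(sp$table))
  expect_true(all(sp$table$chrom[sp$carrier_origin] == "carrier"))
  expect_true(all(sp$table$chrom[!sp$carrier_origin] != "carrier"))
})

test_that("two-condition experiments implant roles and are internally consistent", {
  g <- generate_genome(n_promoters = 120, seed = 43)
  tc <- generate_two_conditions(g, n_specific_a = 15, n_specific_b = 15,
                                n_switch = 10, switch_distance = 80,
                                depth_tags = 2e5, seed = 44)
  expect_equal(table(tc$truth$role)[["switch"]], 10L)
  expect_equal(sum(tc$truth$role == "ubiquitous"), 80L)
  sw <- tc$truth[tc$truth$role == "switch", ]
  expect_true(all(abs(sw$dominant_b - sw$dominant_a) == 80))
  expect_error(generate_two_conditions(g, switch_distance = 0),
               "switch_distance")
  expect_error(generate_two_conditions(g, n_specific_a = 200),
               "exceed")
  # ubiquitous promoters correlate strongly across conditions at the
  # consensus level
  ca <- cluster_ctss(normalize_power_law(tc$table_a))
  cb <- cluster_ctss(normalize_power_law(tc$table_b))
  cons <- merge_consensus(list(a = ca, b = cb), max_gap = 150)
  ubi <- tc$truth[tc$truth$role == "ubiquitous", ]
  gr_u <- GenomicRanges::GRanges(ubi$chrom,
                                 IRanges::IRanges(ubi$dominant_a,
                                                  ubi$dominant_a),
                                 strand = ubi$strand)
  gr_c <- GenomicRanges::GRanges(cons$chrom,
                                 IRanges::IRanges(cons$start, cons$end),
                                 strand = cons$strand)
  sel <- IRanges::overlapsAny(gr_c, gr_u)
  expect_gt(stats::cor(cons$tpm_a[sel], cons$tpm_b[sel]), 0.95)
})
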