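test_that("constants and D match an independent transliteration", {
  for (n in c(4L, 7L, 12L, 25L, 50L)) {
    k <- tajima_constants(n)
    a1 <- sum(1 / seq_len(n - 1))
    expect_equal(k$a1, a1, tolerance = 1e-12)
    for (S in c(1L, 3L, 17L, 100L)) {
      pi <- S / a1 * runif(1, 0.3, 1.8)
      expect_equal(tajimas_d(n, S, pi), oracle_tajima(n, S, pi),
                   tolerance = 1e-12, info = paste(n, S))
    }
  }
  # numerator identity: pi = S/a1 gives D = 0
  expect_equal(tajimas_d(9, 10, 10 / sum(1 / (1:8))), 0, tolerance = 1e-12)
  # frozen oracle value: 4 haplotypes, 3 singletons, pi = 1.5
  expect_equal(tajimas_d(4, 3, 1.5), -0.7544511, tolerance = 1e-6)
  # S = 0 is undefined, not 0
  expect_true(is.na(tajimas_d(5, 0, 0)))
  expect_error(tajimas_d(1, 3, 1), "n must be")
})

test_that("depth filters implement both quoted rules", {
  gm <- structure(list(chrom = "chr16", chrom_length = 300L,
                       positions = c(10L, 20L, 30L),
                       geno = matrix(c(0L, 1L), 4, 3,
                                     dimnames = list(paste0("s", 1:4), NULL)),
                       depth = matrix(6L, 4, 3,
                                      dimnames = list(paste0("s", 1:4), NULL)),
                       sample_ids = paste0("s", 1:4), group = "g"),
                  class = "sg_genomat")
  gm$depth[1, 2] <- 5L            # one individual below 6 at site 2
  gm$depth[c(1, 2), 3] <- 5L      # two individuals below 6 at site 3
  wg <- depth_filter(gm, "whole_genome")
  expect_identical(wg$positions, c(10L, 20L)) # site 3 dropped
  rad <- depth_filter(gm, "rad")
  expect_identical(rad$positions, 10L)        # sites 2 and 3 dropped
  # all depths exactly 6: kept everywhere
  gm$depth[] <- 6L
  expect_identical(depth_filter(gm, "whole_genome")$positions, gm$positions)
  expect_identical(depth_filter(gm, "rad")$positions, gm$positions)
})

test_that("windowed scan tiles the chromosome and handles empty windows", {
  gm <- structure(list(chrom = "c", chrom_length = 250000L,
                       positions = c(5L, 50L, 70000L),
                       geno = matrix(c(1L, 0L, 0L, 0L,
                                       1L, 1L, 0L, 0L,
                                       0L, 1L, 0L, 0L), 4, 3,
                                     dimnames = list(paste0("s", 1:4), NULL)),
                       depth = matrix(10L, 4, 3),
                       sample_ids = paste0("s", 1:4), group = "g"),
                  class = "sg_genomat")
  st <- windowed_scan(gm, window_bp = 100000L)
  expect_identical(nrow(st), 3L)
  expect_identical(st$S, c(3L, 0L, 0L))
  expect_true(is.na(st$D[2]) && is.na(st$D[3]))
  expect_identical(st$p_flag[2], "undefined")
  # pi by hand: allele counts 1, 2, 1 over 6 pairs
  expect_equal(st$pi[1], (1 * 3 + 2 * 2 + 1 * 3) / 6)
  expect_equal(st$D[1], oracle_tajima(4, 3, st$pi[1]), tolerance = 1e-12)
  # tiling identity: scanning two disjoint halves equals one scan
  left <- gm; left$chrom_length <- 100000L
  keep <- gm$positions <= 100000L
  left$positions <- gm$positions[keep]
  left$geno <- gm$geno[, keep, drop = FALSE]
  left$depth <- gm$depth[, keep, drop = FALSE]
  st_l <- windowed_scan(left, window_bp = 100000L)
  expect_equal(st_l$D[1], st$D[1])
  expect_error(windowed_scan(gm, window_bp = 0), ">= 1")
})

test_that("beta-distribution significance flags the tails and respects the support", {
  expect_identical(tajima_significance(0, 7), "ns")
  expect_identical(tajima_significance(-3, 7), "significantly_negative")
  expect_identical(tajima_significance(3, 7), "significantly_positive")
  expect_identical(tajima_significance(NA_real_, 7), "undefined")
  expect_identical(tajima_significance(-1, 3), "undefined")
  # the flag flips from ns to significant moving toward the support bound
  flags <- tajima_significance(seq(0, -1.7, by = -0.1), 6)
  expect_identical(flags[1], "ns")
  expect_identical(flags[length(flags)], "significantly_negative")
  expect_true(all(which(flags == "significantly_negative") >
                    max(which(flags == "ns"))))
})

test_that("neutral panels give near-zero mean D; founder bottleneck drives D negative", {
  cfg <- sg_sim_config(seed = 71, snp_chrom_length = 1e6)
  gm <- simulate_genotype_matrix(cfg, n_samples = 7)
  st <- windowed_scan(depth_filter(gm, "whole_genome"))
  expect_lt(abs(mean(st$D, na.rm = TRUE)), 0.8) # loose per-run bound
  bcfg <- cfg; bcfg$bottleneck$enabled <- TRUE
  gb <- simulate_genotype_matrix(bcfg, n_samples = 7, group = "Sb_invicta")
  sb <- windowed_scan(depth_filter(gb, "whole_genome"))
  expect_lt(mean(sb$D, na.rm = TRUE), 0)
  expect_gt(sum(sb$p_flag == "significantly_negative"),
            sum(st$p_flag == "significantly_negative"))
})

test_that("segment summaries tally signs, significance and the defined-window mean", {
  st <- data.frame(chrom = "c", start = seq(1, 1000001, by = 100000),
                   end = seq(100000, 1100000, by = 100000),
                   n = 6, S = c(0, rep(10, 10)),
                   pi = c(0, rep(3, 10)),
                   D = c(NA, -1, -1, -1.6, -1.6, 1, 1, 2.6, -0.2, 0.1, 0),
                   p_flag = c("undefined", "ns", "ns", "significantly_negative",
                              "significantly_negative", "ns", "ns",
                              "significantly_positive", "ns", "ns", "ns"),
                   stringsAsFactors = FALSE)
  seg <- segment_summary(st, c(1, 1100000))
  expect_identical(seg$n_windows, 11L)
  expect_identical(seg$n_defined, 10L)
  expect_equal(seg$mean_D, mean(st$D, na.rm = TRUE))
  expect_identical(seg$n_negative, 5L)
  expect_identical(seg$n_significant_negative, 2L)
  expect_identical(seg$n_positive, 4L)
  expect_identical(seg$n_significant_positive, 1L)
  # all-windows-negative fixture
  st2 <- st[4:5, ]
  seg2 <- segment_summary(st2, c(300001, 500000))
  expect_equal(seg2$mean_D, -1.6)
  expect_identical(seg2$n_negative, 2L)
  # undefined-only segment: mean undefined, counts 0
  seg3 <- segment_summary(st, c(1, 100000))
  expect_true(is.na(seg3$mean_D))
  expect_identical(seg3$n_negative, 0L)
  expect_error(segment_summary(st, c(2e6, 3e6)), "empty segment")
})

test_that("VCF subset round-trips the genotype matrix", {
  cfg <- sg_sim_config(seed = 73, snp_chrom_length = 3e5)
  gm <- simulate_genotype_matrix(cfg, n_samples = 5)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_subset(gm, path)
  back <- read_vcf_subset(path, group = gm$group)
  expect_identical(back$positions, gm$positions)
  expect_identical(unname(back$geno), unname(gm$geno))
  expect_identical(unname(back$depth), unname(gm$depth))
  expect_identical(back$chrom_length, gm$chrom_length)
  expect_identical(back$sample_ids, gm$sample_ids)
})
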