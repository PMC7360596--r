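test_that("substitution counting excludes gap and ambiguous columns pairwise", {
  expect_identical(unname(count_substitutions("ACGT", "ACGT")), c(0L, 4L))
  expect_identical(unname(count_substitutions("ACGT", "ACGA")), c(1L, 4L))
  expect_identical(unname(count_substitutions("AC-T", "ACGT")), c(0L, 3L))
  expect_identical(unname(count_substitutions("ANGT", "ACGT")), c(0L, 3L))
  expect_error(count_substitutions("ACG", "ACGT"), "unequal")
})

test_that("JC69 correction matches the closed form and respects its domain", {
  expect_identical(jc69_correct(0), 0)
  expect_equal(jc69_correct(0.1), 0.1073256, tolerance = 1e-6)
  expect_error(jc69_correct(0.75), "saturat")
  expect_error(jc69_correct(-0.01), "non-negative")
  # strictly increasing and convex; d >= p
  p <- seq(0, 0.7, by = 0.01)
  d <- jc69_correct(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(diff(d)) > 0))
  expect_true(all(d >= p))
  # series expansion d ~ p + (2/3) p^2 for small p
  ps <- seq(0.0005, 0.0095, by = 0.001)
  expect_true(all(abs(jc69_correct(ps) - (ps + 2 / 3 * ps^2)) < 1e-5))
})

test_that("JC estimate agrees with an established implementation on one alignment", {
  cfg <- invicta_cfg(seed = 31, seq_length = 5000)
  rows <- simulate_haplotypes(cfg)$blocks[[1]]$rows
  m <- pairwise_matrix(list(sg_block("b", rows)))
  bin <- ape::as.DNAbin(t(sapply(rows, function(s) strsplit(s, "")[[1]])))
  ref <- as.matrix(ape::dist.dna(bin, model = "JC69"))
  expect_equal(m$d[rownames(ref), colnames(ref)], ref, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pairwise matrix pools counts across blocks before correction", {
  b1 <- blk(s1 = "AAAA", s2 = "AAAT", id = "b1")
  b2 <- blk(s1 = "CCCCCC", s2 = "CCCCCA", id = "b2")
  m <- pairwise_matrix(list(b1, b2), c("s1", "s2"))
  # pooled: 2 diffs over 10 valid sites, then one correction
  expect_equal(m$d["s1", "s2"], jc69_correct(0.2))
  expect_identical(m$valid_sites["s1", "s2"], 10)
  # NOT the mean of per-block corrected distances (nonlinear correction)
  per_block <- mean(c(jc69_correct(0.25), jc69_correct(1 / 6)))
  expect_false(isTRUE(all.equal(m$d["s1", "s2"], per_block)))
  # identical samples give 0; zero valid sites give NA, not 0
  b3 <- blk(s1 = "NNNN", s2 = "ACGT", s3 = "ACGT", id = "b3")
  m3 <- pairwise_matrix(list(b3))
  expect_true(is.na(m3$d["s1", "s2"]))
  expect_identical(m3$d["s2", "s3"], 0)
})

test_that("sample order only permutes the matrix", {
  cfg <- sg_sim_config(seq_length = 2000, n_blocks = 2, seed = 13)
  blocks <- simulate_haplotypes(cfg)$blocks
  ids <- names(blocks[[1]]$rows)
  m1 <- pairwise_matrix(blocks, ids)
  m2 <- pairwise_matrix(blocks, rev(ids))
  expect_equal(m2$d[ids, ids], m1$d)
  expect_identical(m1$d, t(m1$d))
  expect_true(all(diag(m1$d) == 0))
})

test_that("distance estimate is unbiased against the true path length", {
  # one simulated pair with known true divergence, 3 SE tolerance
  cfg <- invicta_cfg(seed = 17, seq_length = 1e5)
  sim <- simulate_haplotypes(cfg)
  m <- pairwise_matrix(sim$blocks, c("invB_1", "invB_2"))
  tr <- sim$truth$true_tree
  dd <- ape::dist.nodes(tr)
  d_true <- dd[match("invB_1", tr$tip.label), match("invB_2", tr$tip.label)]
  p_true <- 0.75 * (1 - exp(-4 * d_true / 3))
  se_d <- sqrt(p_true * (1 - p_true) / 1e5) / (1 - 4 * p_true / 3)
  expect_lt(abs(m$d["invB_1", "invB_2"] - d_true), 3 * se_d)
})

test_that("one-read-per-locus selection is deterministic and truth-faithful when error-free", {
  cfg <- sg_sim_config(seed = 19, rad_locus_count = 80, rad_locus_length = 60,
                       depth_distribution = list(type = "poisson", mean = 8))
  rad <- simulate_rad_dataset(cfg)
  sel1 <- select_one_read_per_locus(rad, seed = 3)
  sel2 <- select_one_read_per_locus(rad, seed = 3)
  expect_identical(sel1, sel2)
  # loci missing any sample are dropped
  min_depth <- vapply(rad$loci, function(l) min(lengths(l$reads)), integer(1))
  expect_length(sel1, sum(min_depth >= 1L))
  # with error rate 0 the selected reads ARE the truth: distances match
  # those computed from the underlying haplotypes over the same loci
  m_sel <- pairwise_matrix(sel1, rad$samples)
  kept <- which(min_depth >= 1L)
  truth_blocks <- lapply(kept, function(k) {
    loc <- rad$loci[[k]]
    rows <- vapply(rad$samples, function(s) loc$reads[[s]][1], character(1))
    sg_block(loc$locus_id, rows, loc$interval)
  })
  m_truth <- pairwise_matrix(truth_blocks, rad$samples)
  expect_equal(m_sel$d, m_truth$d, tolerance = 1e-12)
  # depth-1 selection is the unique read
  cfg1 <- sg_sim_config(seed = 19, rad_locus_count = 10, rad_locus_length = 30,
                        depth_distribution = list(type = "constant", mean = 1))
  rad1 <- simulate_rad_dataset(cfg1)
  s1 <- select_one_read_per_locus(rad1, seed = 1)
  expect_identical(unname(s1[[1]]$rows),
                   unname(vapply(rad1$loci[[1]]$reads, `[`, character(1), 1)))
})

test_that("group summaries count pairs as in the violin-plot panels", {
  ids <- c(paste0("gA_", 1:7), paste0("gB_", 1:7))
  n <- length(ids)
  d <- matrix(0.002, n, n, dimnames = list(ids, ids)); diag(d) <- 0
  m <- structure(list(sample_ids = ids, d = d,
                      valid_sites = matrix(1000, n, n), units = "per_site"),
                 class = "sg_distmat")
  assignment <- data.frame(sample_id = ids,
                           group = rep(c("gA", "gB"), each = 7))
  s <- group_distance_summary(m, assignment)
  expect_identical(s$n_pairs[s$group_a == "gA" & s$group_b == "gA"], 21L)
  expect_identical(s$n_pairs[s$group_a == "gA" & s$group_b == "gB"], 49L)
  expect_true(all(s$mean_per_1000 == 2))
  # all-zero matrix: mean 0, SD 0
  m0 <- m; m0$d[] <- 0
  s0 <- group_distance_summary(m0, assignment)
  expect_true(all(s0$mean_per_1000 == 0) && all(s0$sd_per_1000 == 0))
  # within-group summary of a singleton group errors
  a2 <- data.frame(sample_id = ids, group = c("solo", rep("rest", 13)))
  expect_error(group_distance_summary(
    m, a2, pairs = data.frame(group_a = "solo", group_b = "solo")),
    "fewer than 2")
})

test_that("distance matrices round-trip through square and long TSV", {
  cfg <- sg_sim_config(seq_length = 1000, n_blocks = 1, seed = 23)
  m <- pairwise_matrix(simulate_haplotypes(cfg)$blocks)
  sq <- withr::local_tempfile(fileext = ".tsv")
  lg <- withr::local_tempfile(fileext = ".tsv")
  write_distmat(m, sq, long_path = lg)
  back <- read_distmat(sq, long_path = lg)
  expect_equal(back$d, m$d, tolerance = 1e-9)
  expect_equal(back$valid_sites[1, 2], m$valid_sites[1, 2])
})
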