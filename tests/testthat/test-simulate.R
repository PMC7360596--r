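test_that("config validation rejects degenerate inputs", {
  expect_error(sg_sim_config(branch_times = list(outgroup = 25, speciation = -1,
                                                 supergene = 1, sb_species = 0.9,
                                                 within = 0.5)),
               "positive")
  expect_error(sg_sim_config(group_sizes = c(outgroup = 0L, SB_invicta = 4L,
                                             SB_richteri = 4L, Sb_invicta = 2L,
                                             Sb_richteri = 2L)),
               "required group")
  expect_error(sg_sim_config(sb_rate_multiplier = -0.1), ">= 0")
  expect_error(sg_sim_config(seq_length = 0), "seq_length")
  expect_error(sg_sim_config(topology = "sb_basal"),
               "supergene age > speciation age")
})

test_that("fixed seed makes simulation byte-identical; seeds differ otherwise", {
  cfg <- sg_sim_config(seq_length = 2000, n_blocks = 3, seed = 42)
  s1 <- simulate_haplotypes(cfg)
  s2 <- simulate_haplotypes(cfg)
  expect_identical(s1$blocks, s2$blocks)
  expect_identical(s1$truth$per_edge_subs, s2$truth$per_edge_subs)
  cfg2 <- cfg; cfg2$seed <- 43L
  s3 <- simulate_haplotypes(cfg2)
  expect_false(identical(s1$blocks, s3$blocks))
})

test_that("blocks concatenate to seq_length and carry all group labels", {
  cfg <- sg_sim_config(seq_length = 5000, n_blocks = 7, seed = 1)
  sim <- simulate_haplotypes(cfg)
  expect_length(sim$blocks, 7)
  total <- sum(vapply(sim$blocks, function(b) nchar(b$rows[[1]]), integer(1)))
  expect_identical(total, 5000L)
  expect_setequal(names(sim$blocks[[1]]$rows), sg_groups(cfg)$sample_id)
  # contiguous non-overlapping intervals
  iv <- t(vapply(sim$blocks, function(b) b$region_interval, integer(2)))
  expect_identical(iv[1, 1], 1L)
  expect_identical(iv[nrow(iv), 2], 5000L)
  expect_true(all(iv[-1, 1] == head(iv[, 2], -1) + 1L))
})

test_that("zero rate multiplier collapses the Sb clade to identical sequences", {
  cfg <- sg_sim_config(seq_length = 5000, n_blocks = 1, seed = 11,
                       sb_rate_multiplier = 0)
  sim <- simulate_haplotypes(cfg)
  rows <- sim$blocks[[1]]$rows
  sb <- rows[grepl("^(invb|richb)_", names(rows))]
  expect_true(all(sb == sb[[1]]))
  # and the truth tree has zero-length Sb branches
  d <- count_substitutions(sb[[1]], sb[[2]])
  expect_identical(unname(d["n_diff"]), 0L)
})

test_that("symmetric tree with lambda = 1 has equal true SB and Sb depths; lambda scales them exactly", {
  for (lam in c(1, 1.4, 2)) {
    cfg <- invicta_cfg(seed = 2, lambda = lam, seq_length = 100)
    sim <- simulate_haplotypes(cfg)
    tr <- sim$truth$true_tree
    sgn <- mrca_node(tr, grep("^(invB|invb)_", tr$tip.label, value = TRUE))
    sb <- path_lengths_from_node(tr, sgn, grep("^invb_", tr$tip.label, value = TRUE))
    sB <- path_lengths_from_node(tr, sgn, grep("^invB_", tr$tip.label, value = TRUE))
    expect_equal(mean(sb) / mean(sB), lam, tolerance = 1e-12)
  }
})

test_that("observed mismatch fraction matches the JC69 closed form on a known branch", {
  # one species pair whose true path length is read off the truth tree;
  # expectation p = 0.75 (1 - exp(-4 d / 3)), checked within 3 binomial SDs
  cfg <- invicta_cfg(seed = 9, lambda = 1, seq_length = 2e5)
  sim <- simulate_haplotypes(cfg)
  tr <- sim$truth$true_tree
  rows <- sim$blocks[[1]]$rows
  dd <- ape::dist.nodes(tr)
  pair <- c("invB_1", "invb_1")
  d_true <- dd[match(pair[1], tr$tip.label), match(pair[2], tr$tip.label)]
  p_exp <- 0.75 * (1 - exp(-4 * d_true / 3))
  cnt <- count_substitutions(rows[[pair[1]]], rows[[pair[2]]])
  p_obs <- cnt["n_diff"] / cnt["n_valid"]
  se <- sqrt(p_exp * (1 - p_exp) / cnt["n_valid"])
  expect_lt(abs(p_obs - p_exp), 3 * se)
  # and at d = 0.1 specifically the formula value is ~0.0936
  expect_equal(0.75 * (1 - exp(-4 * 0.1 / 3)), 0.09362, tolerance = 1e-4)
})

test_that("RAD simulation: error-free reads equal the true haplotype slice and depths obey the distribution", {
  cfg <- sg_sim_config(seed = 4, rad_locus_count = 30, rad_locus_length = 50,
                       depth_distribution = list(type = "constant", mean = 6),
                       seq_length = 1500, n_blocks = 1)
  rad <- simulate_rad_dataset(cfg)
  expect_length(rad$loci, 30)
  depths <- vapply(rad$loci, function(l) min(lengths(l$reads)), integer(1))
  expect_true(all(depths == 6L)) # all loci pass a ">= 6 reads everywhere" rule
  # reads are identical within a stack at error rate 0
  stacks <- rad$loci[[1]]$reads
  expect_true(all(vapply(stacks, function(r) all(r == r[1]), logical(1))))
  # determinism
  rad2 <- simulate_rad_dataset(cfg)
  expect_identical(rad$loci, rad2$loci)
})

test_that("RAD reads carry errors at the configured rate", {
  cfg <- sg_sim_config(seed = 4, rad_locus_count = 50, rad_locus_length = 100,
                       rad_error_rate = 0.05,
                       depth_distribution = list(type = "constant", mean = 2))
  rad <- simulate_rad_dataset(cfg)
  reads <- unlist(lapply(rad$loci, function(l) l$reads))
  # compare duplicate reads of the same sample/locus: mismatches ~ 2 e (1-e)...
  # simpler: reads in one stack differ only by errors
  diffs <- vapply(rad$loci[1:50], function(l) {
    r <- l$reads[[1]]
    count_substitutions(r[1], r[2])["n_diff"]
  }, integer(1))
  rate <- sum(diffs) / (50 * 100)
  # two error-bearing copies: expected mismatch fraction ~ 2*0.05*(1-0.05) + small
  expect_gt(rate, 0.05)
  expect_lt(rate, 0.15)
})

test_that("genotype matrix invariants: strictly increasing positions, depths recorded, founder clone has zero diversity", {
  cfg <- sg_sim_config(seed = 6, snp_chrom_length = 5e5)
  gm <- simulate_genotype_matrix(cfg, n_samples = 5)
  expect_true(all(diff(gm$positions) > 0))
  expect_identical(dim(gm$depth), dim(gm$geno))
  expect_true(all(gm$geno %in% c(0L, 1L)))
  # segregating by construction
  expect_true(all(colSums(gm$geno) > 0 & colSums(gm$geno) < 5))

  bcfg <- cfg
  bcfg$bottleneck <- list(enabled = TRUE, founders = 1L, private_mu = 0)
  g0 <- simulate_genotype_matrix(bcfg, n_samples = 5)
  expect_identical(ncol(g0$geno), 0L) # single clone, no post-founding mutations
})

test_that("hit fixtures round-trip through the BLAST tabular writer/reader", {
  expect_identical(make_hit_fixture(list()), list())
  spec <- list(
    list(query_id = "q1",
         hits = data.frame(subject_id = c("scaffold00008", "chr2"),
                           evalue = c(1e-20, 1e-3),
                           n_base_matches = c(900L, 100L),
                           pct_mismatch = c(4, 8),
                           n_mismatches = c(2L, 9L),
                           bitscore = c(800, 60))),
    list(query_id = "q2",
         hits = data.frame(subject_id = "scaffold00028", evalue = 1e-9,
                           n_base_matches = 300L, pct_mismatch = 2,
                           n_mismatches = 1L, bitscore = 200)))
  groups <- make_hit_fixture(spec)
  expect_length(groups, 2)
  expect_identical(nrow(groups[[1]]$hits), 2L)
  path <- withr::local_tempfile(fileext = ".blast6")
  write_blast_tab(groups, path)
  back <- read_blast_tab(path)
  expect_identical(length(back), 2L)
  for (i in 1:2) {
    expect_identical(back[[i]]$query_id, groups[[i]]$query_id)
    expect_identical(back[[i]]$hits$subject_id, groups[[i]]$hits$subject_id)
    expect_identical(back[[i]]$hits$n_mismatches, groups[[i]]$hits$n_mismatches)
    expect_equal(back[[i]]$hits$n_base_matches, groups[[i]]$hits$n_base_matches)
  }
  # unsorted hits are rejected
  expect_error(sg_hitgroup("bad", data.frame(subject_id = c("a", "b"),
                                             evalue = c(1e-3, 1e-9))),
               "sorted")
})
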