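# Independent oracles used by the tests. These re-derive expected behaviour
# through a different code path than the implementation they check.

# literal clause-by-clause transcription of the genome-scaffold uniqueness
# rule: top hit in region with E <= 1e-4; reject if a second hit has
# E <= 1e-4, or >= half the top's base matches, or <= half the top's
# mismatch percentage
oracle_genome_filter <- function(hits, region_subjects, e_max = 1e-4) {
  ok <- hits$subject_id[1] %in% region_subjects && hits$evalue[1] <= e_max
  if (ok && nrow(hits) >= 2) {
    bad <- hits$evalue[2] <= e_max ||
      hits$n_base_matches[2] >= 0.5 * hits$n_base_matches[1] ||
      hits$pct_mismatch[2] <= 0.5 * hits$pct_mismatch[1]
    ok <- !bad
  }
  ok
}

oracle_rad_filter <- function(hits, max_mismatch = 4) {
  ok <- hits$n_mismatches[1] <= max_mismatch
  if (ok && nrow(hits) >= 2)
    ok <- !(hits$n_mismatches[2] <= 2 * hits$n_mismatches[1])
  ok
}

# random hit-group generators (sorted best-first by construction)
random_genome_group <- function(id, region_subjects) {
  n_hits <- sample(1:3, 1)
  ev <- sort(10^runif(n_hits, -8, 0))
  subj <- sample(c(region_subjects, "off_region"), n_hits, replace = TRUE)
  hits <- data.frame(subject_id = subj, evalue = ev,
                     n_base_matches = sample(50:2000, n_hits),
                     pct_mismatch = runif(n_hits, 0, 10),
                     bitscore = sort(runif(n_hits, 50, 500), decreasing = TRUE),
                     stringsAsFactors = FALSE)
  sgevo::sg_hitgroup(id, hits, mode = "genome")
}

random_rad_group <- function(id) {
  n_hits <- sample(1:3, 1)
  mm <- sort(sample(0:12, n_hits, replace = TRUE))
  hits <- data.frame(subject_id = paste0("s", seq_len(n_hits)),
                     n_mismatches = mm, stringsAsFactors = FALSE)
  sgevo::sg_hitgroup(id, hits, mode = "rad")
}

# independent transliteration of the Tajima (1989) statistic, written as
# one monolithic expression (no shared code with the package)
oracle_tajima <- function(n, S, pi) {
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  v <- (2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
          (n + 2) / (a1 * n) + a2 / a1^2) / (a1^2 + a2)
  u <- ((n + 1) / (3 * (n - 1)) - 1 / a1) / a1
  (pi - S / a1) / sqrt(u * S + v * S * (S - 1))
}

# quick block builder for distance tests
blk <- function(..., id = "b1", interval = NULL) {
  rows <- c(...)
  if (is.null(interval)) interval <- c(1L, nchar(rows[[1]]))
  sgevo::sg_block(id, rows, region_interval = interval)
}

# two-group simulation config used in several dating tests: one species,
# seven SB vs seven Sb haplotypes plus an outgroup
invicta_cfg <- function(seed, lambda = 1.4, seq_length = 2e5, n_blocks = 1L,
                        supergene = 1.05, outgroup = 25, within = 0.5) {
  sgevo::sg_sim_config(
    topology = "invicta_only",
    group_sizes = c(outgroup = 1L, SB_invicta = 7L, SB_richteri = 0L,
                    Sb_invicta = 7L, Sb_richteri = 0L),
    branch_times = list(outgroup = outgroup, speciation = outgroup / 2,
                        supergene = supergene, sb_species = supergene * 0.8,
                        within = within),
    sb_rate_multiplier = lambda,
    seq_length = seq_length, n_blocks = n_blocks, seed = seed)
}
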