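## RAD-seq emulation: per-locus per-sample read stacks drawn from the true
## haplotypes, with configurable depth distribution and sequencing error.

draw_depths <- function(dist, n) {
  switch(dist$type,
         constant = rep(as.integer(round(dist$mean)), n),
         poisson = rpois(n, dist$mean))
}

apply_read_errors <- function(seq_int, error_rate) {
  if (error_rate <= 0) return(seq_int)
  idx <- which(runif(length(seq_int)) < error_rate)
  if (length(idx))
    seq_int[idx] <- ((seq_int[idx] - 1L + sample.int(3L, length(idx), replace = TRUE)) %% 4L) + 1L
  seq_int
}

#' Simulate a RAD-seq dataset over the supergene region
#'
#' Evolves haplotypes along the configured genealogy (as in
#' [simulate_haplotypes()], over `rad_locus_count * rad_locus_length` sites),
#' cuts them into fixed-length loci, and generates per-sample read stacks:
#' each sample's depth at each locus is drawn from the configured depth
#' distribution and each read is that sample's true haplotype slice with
#' independent per-base errors at `rad_error_rate`.
#'
#' @param config an [sg_sim_config()].
#' @return list with `samples` (ids, outgroup excluded), `loci` (each a list
#'   with `locus_id`, `interval` and `reads`, a per-sample list of read
#'   strings whose length is the sample's depth) and `truth` (the `sg_truth`
#'   of the underlying haplotypes).
#' @export
simulate_rad_dataset <- function(config) {
  stopifnot(inherits(config, "sg_sim_config"))
  if (config$rad_locus_length < 1L) stop("rad_locus_length must be >= 1")
  hap_cfg <- config
  hap_cfg$seq_length <- config$rad_locus_count * config$rad_locus_length
  hap_cfg$n_blocks <- 1L
  hap_cfg$confidence_low_frac <- 0
  sim <- simulate_haplotypes(hap_cfg)
  hap <- lapply(sim$blocks[[1]]$rows, seq_to_int)
  samples <- setdiff(names(hap), group_tip_labels("outgroup", 1L))

  set.seed(child_seed(config$seed, "rad"))
  llen <- config$rad_locus_length
  loci <- vector("list", config$rad_locus_count)
  for (k in seq_len(config$rad_locus_count)) {
    from <- (k - 1L) * llen + 1L; to <- k * llen
    depths <- draw_depths(config$depth_distribution, length(samples))
    reads <- lapply(seq_along(samples), function(i) {
      truth_slice <- hap[[samples[i]]][from:to]
      if (depths[i] == 0L) return(character(0))
      vapply(seq_len(depths[i]), function(r)
        int_to_seq(apply_read_errors(truth_slice, config$rad_error_rate)),
        character(1))
    })
    names(reads) <- samples
    loci[[k]] <- list(locus_id = sprintf("locus_%05d", k),
                      interval = c(from, to), reads = reads)
  }
  list(samples = samples, loci = loci, truth = sim$truth)
}
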