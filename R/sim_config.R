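#' Simulation configuration
#'
#' Builds and validates the configuration for the supergene simulator. The
#' defaults emulate the study system: an outgroup that diverged 25 time units
#' (million years) ago, a speciation split between the two socially
#' polymorphic species at 1.2, a supergene (SB/Sb) split at 1.05 nested inside
#' the richteri subtree, a background substitution rate chosen so that the
#' SB-to-supergene-node path is about 2.1 substitutions per 1,000 sites, and a
#' 1.4-fold rate acceleration on all branches inside the Sb clade.
#'
#' @param topology one of `"fig_supergene_nested"` (Sb clade nested within the
#'   richteri subtree; speciation precedes supergene formation),
#'   `"sb_basal"` (the Sb clade split precedes speciation) or
#'   `"invicta_only"` (one species: SB vs Sb plus outgroup, the whole-genome
#'   design of seven SB and seven Sb haploid males).
#' @param group_sizes named integer vector with entries `outgroup`,
#'   `SB_invicta`, `SB_richteri`, `Sb_invicta`, `Sb_richteri`. Groups not
#'   present in the chosen topology may be 0; required groups must be >= 1.
#' @param branch_times named numeric list/vector of node ages (arbitrary time
#'   units, by convention MY): `outgroup` (root age), `speciation`,
#'   `supergene`, `sb_species` (split of the two species' Sb haplotypes inside
#'   the Sb clade) and `within` (age of the star coalescence within each
#'   haplotype group).
#' @param base_rate substitutions/site/time on non-Sb branches (r_B).
#' @param sb_rate_multiplier lambda >= 0 applied to every branch inside the Sb
#'   clade (including its stem).
#' @param seq_length total alignment length in sites.
#' @param n_blocks number of alignment blocks the sequence is split into.
#' @param confidence_low_frac fraction of alignment columns given a synthetic
#'   confidence score below 60 (the rest score in [60, 100]); 0 disables
#'   confidence annotation.
#' @param rad_locus_length,rad_locus_count RAD locus geometry.
#' @param rad_error_rate per-base sequencing error rate for simulated reads.
#' @param depth_distribution list with `type` = `"constant"` or `"poisson"`
#'   and `mean`; governs per-sample read/locus depths.
#' @param snp_theta population-scaled mutation rate per 100-kb window for the
#'   neutral coalescent SNP simulator.
#' @param snp_chrom_length chromosome length (bp) for the SNP simulator.
#' @param bottleneck list with `enabled`, `founders` (founder haplotypes for
#'   the introduced-range group) and `private_mu` (expected private mutations
#'   per haplotype per window accumulated since founding; the default of 30
#'   reproduces a SNP density of roughly 200 segregating sites per 100-kb
#'   window in a six-haplotype panel, the density observed in the
#'   introduced-range derived-haplotype group).
#' @param seed integer seed; fixing it makes every simulator output
#'   byte-identical across runs.
#' @return an object of class `sg_sim_config` (a validated list).
#' @export
sg_sim_config <- function(topology = c("fig_supergene_nested", "sb_basal", "invicta_only"),
                          group_sizes = c(outgroup = 1L, SB_invicta = 4L,
                                          SB_richteri = 4L, Sb_invicta = 2L,
                                          Sb_richteri = 2L),
                          branch_times = list(outgroup = 25, speciation = 1.2,
                                              supergene = 1.05, sb_species = 0.9,
                                              within = 0.75),
                          base_rate = 0.002,
                          sb_rate_multiplier = 1.4,
                          seq_length = 5e5,
                          n_blocks = 25L,
                          confidence_low_frac = 0,
                          rad_locus_length = 90L,
                          rad_locus_count = 500L,
                          rad_error_rate = 0,
                          depth_distribution = list(type = "poisson", mean = 20),
                          snp_theta = 10,
                          snp_chrom_length = 2e6,
                          bottleneck = list(enabled = FALSE, founders = 1L,
                                            private_mu = 30),
                          seed = 1L) {
  topology <- match.arg(topology)
  bt <- as.list(branch_times)
  need_bt <- c("outgroup", "speciation", "supergene", "sb_species", "within")
  if (!all(need_bt %in% names(bt)))
    stop("branch_times must name: ", paste(need_bt, collapse = ", "))
  bt <- lapply(bt[need_bt], as.numeric)
  if (any(unlist(bt) <= 0)) stop("all branch times must be strictly positive")
  if (bt$outgroup <= max(bt$speciation, bt$supergene))
    stop("outgroup age must exceed all ingroup node ages")
  if (topology %in% c("fig_supergene_nested", "invicta_only") &&
      bt$speciation < bt$supergene && topology == "fig_supergene_nested")
    stop("nested-supergene topology requires speciation age >= supergene age")
  if (topology == "sb_basal" && bt$supergene <= bt$speciation)
    stop("sb_basal topology requires supergene age > speciation age")
  if (bt$sb_species >= bt$supergene)
    stop("sb_species age must be younger than the supergene age")
  if (bt$within >= min(bt$sb_species, bt$speciation, bt$supergene))
    stop("within-group age must be younger than every split age")

  gs <- group_sizes
  req <- switch(topology,
    fig_supergene_nested = c("outgroup", "SB_invicta", "SB_richteri",
                             "Sb_invicta", "Sb_richteri"),
    sb_basal = c("outgroup", "SB_invicta", "SB_richteri",
                 "Sb_invicta", "Sb_richteri"),
    invicta_only = c("outgroup", "SB_invicta", "Sb_invicta"))
  if (!all(req %in% names(gs)))
    stop("group_sizes must name: ", paste(req, collapse = ", "))
  if (any(gs[req] < 1L))
    stop("group size 0 for a required group: ",
         paste(req[gs[req] < 1L], collapse = ", "))
  if (any(gs < 0L)) stop("group sizes must be non-negative")

  if (base_rate <= 0) stop("base_rate must be strictly positive")
  if (sb_rate_multiplier < 0) stop("sb_rate_multiplier must be >= 0")
  if (seq_length < 1) stop("seq_length must be >= 1")
  if (n_blocks < 1 || n_blocks > seq_length) stop("invalid n_blocks")
  if (rad_locus_length < 1) stop("rad_locus_length must be >= 1")
  if (rad_locus_count < 1) stop("rad_locus_count must be >= 1")
  if (rad_error_rate < 0 || rad_error_rate > 1) stop("invalid rad_error_rate")
  if (confidence_low_frac < 0 || confidence_low_frac > 1)
    stop("invalid confidence_low_frac")
  if (!depth_distribution$type %in% c("constant", "poisson"))
    stop("depth_distribution$type must be 'constant' or 'poisson'")
  if (depth_distribution$mean <= 0) stop("depth mean must be positive")
  if (snp_theta <= 0 || snp_chrom_length < 1) stop("invalid SNP parameters")
  if (isTRUE(bottleneck$enabled) && bottleneck$founders < 1L)
    stop("bottleneck founders must be >= 1")

  structure(list(topology = topology,
                 group_sizes = vapply(gs, as.integer, integer(1)),
                 branch_times = bt,
                 base_rate = base_rate,
                 sb_rate_multiplier = sb_rate_multiplier,
                 seq_length = as.integer(seq_length),
                 n_blocks = as.integer(n_blocks),
                 confidence_low_frac = confidence_low_frac,
                 rad_locus_length = as.integer(rad_locus_length),
                 rad_locus_count = as.integer(rad_locus_count),
                 rad_error_rate = rad_error_rate,
                 depth_distribution = depth_distribution,
                 snp_theta = snp_theta,
                 snp_chrom_length = as.integer(snp_chrom_length),
                 bottleneck = bottleneck,
                 seed = as.integer(seed)),
            class = "sg_sim_config")
}

#' @export
print.sg_sim_config <- function(x, ...) {
  cat("Supergene simulation config\n")
  cat("  topology:", x$topology, "\n")
  gs <- x$group_sizes[x$group_sizes > 0]
  cat("  groups:  ", paste(names(gs), gs, sep = "=", collapse = ", "), "\n")
  cat("  ages:    ", paste(names(x$branch_times),
                           unlist(x$branch_times), sep = "=", collapse = ", "), "\n")
  cat(sprintf("  base rate %g subs/site/time, Sb multiplier %g\n",
              x$base_rate, x$sb_rate_multiplier))
  cat(sprintf("  %d sites in %d blocks; seed %d\n",
              x$seq_length, x$n_blocks, x$seed))
  invisible(x)
}

# tip labels per group: invB_1..n, richB_, invb_, richb_, fugax_1
group_tip_labels <- function(group, n) {
  if (n == 0L) return(character(0))
  pre <- switch(group, outgroup = "fugax", SB_invicta = "invB",
                SB_richteri = "richB", Sb_invicta = "invb",
                Sb_richteri = "richb")
  paste0(pre, "_", seq_len(n))
}

#' Group assignment table for simulated samples
#'
#' @param config an [sg_sim_config()].
#' @param range range label attached to every sample (`"native"` or
#'   `"introduced"`).
#' @return data.frame with columns `sample_id`, `group`, `range`.
#' @export
sg_groups <- function(config, range = "native") {
  gs <- config$group_sizes
  groups <- switch(config$topology,
    invicta_only = c("outgroup", "SB_invicta", "Sb_invicta"),
    c("outgroup", "SB_invicta", "SB_richteri", "Sb_invicta", "Sb_richteri"))
  out <- do.call(rbind, lapply(groups, function(g) {
    labs <- group_tip_labels(g, gs[[g]])
    if (length(labs) == 0L) return(NULL)
    data.frame(sample_id = labs, group = g, range = range,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
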