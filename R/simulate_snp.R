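## SNP-table simulation for the Tajima's D analysis: a haploid panel on a
## linear chromosome. Each 100-kb window carries an independent neutral
## coalescent genealogy with infinite-sites mutations; the founder-bottleneck
## variant instead collapses the panel onto a single founder haplotype plus
## per-sample private mutations, the signature expected of an
## introduced-range group descended from one clone.

# derived-allele carriers for one mutation on a coalescent tree: tips below
# a branch chosen with probability proportional to its length
mutation_carriers <- function(tree, edge_pick) {
  chi <- tree$edge[edge_pick, 2]
  ntip <- ape::Ntip(tree)
  if (chi <= ntip) return(chi)
  tips <- integer(0); frontier <- chi
  while (length(frontier)) {
    rows <- which(tree$edge[, 1] %in% frontier)
    kids <- tree$edge[rows, 2]
    tips <- c(tips, kids[kids <= ntip])
    frontier <- kids[kids > ntip]
  }
  tips
}

#' Simulate a haploid SNP genotype matrix
#'
#' Generates biallelic sites (0 = ancestral, 1 = derived) with strictly
#' increasing positions on a linear chromosome, plus per-sample read depths.
#' Without a bottleneck, each `window_bp` window gets an independent neutral
#' constant-size coalescent genealogy (via [ape::rcoal()]) and a
#' Poisson(`snp_theta`/2 x total branch length) number of infinite-sites
#' mutations placed on branches proportionally to length. With
#' `bottleneck$enabled`, all samples descend from `founders` haplotypes
#' (founder variation is shared, hence invariant within the panel when
#' `founders = 1`) and each sample accumulates Poisson(`private_mu`)
#' private singleton mutations per window.
#'
#' @param config an [sg_sim_config()]; fields `snp_theta`,
#'   `snp_chrom_length`, `depth_distribution` and `bottleneck` are used.
#' @param n_samples panel size (default 7).
#' @param group group label for the panel (default `"Sb_invicta"`).
#' @param window_bp genealogy/window granularity (default 100000).
#' @param chrom chromosome name.
#' @return object of class `sg_genomat`: list with `chrom`, `chrom_length`,
#'   `positions` (strictly increasing), `geno` (samples x sites 0/1 matrix),
#'   `depth` (same shape), `sample_ids`, `group`.
#' @export
simulate_genotype_matrix <- function(config, n_samples = 7L,
                                     group = "Sb_invicta",
                                     window_bp = 100000L,
                                     chrom = "chr16") {
  stopifnot(inherits(config, "sg_sim_config"))
  set.seed(child_seed(config$seed, "snp"))
  L <- config$snp_chrom_length
  nwin <- max(1L, ceiling(L / window_bp))
  bott <- isTRUE(config$bottleneck$enabled)
  pos_all <- integer(0)
  geno_cols <- list()
  for (w in seq_len(nwin)) {
    w0 <- (w - 1L) * window_bp
    wlen <- min(window_bp, L - w0)
    if (wlen < 1L) break
    if (!bott) {
      tr <- ape::rcoal(n_samples)
      tot <- sum(tr$edge.length)
      S <- rpois(1L, config$snp_theta / 2 * tot)
      if (S > 0L) {
        picks <- sample.int(nrow(tr$edge), S, replace = TRUE,
                            prob = tr$edge.length)
        for (s in seq_len(S)) {
          carriers <- mutation_carriers(tr, picks[s])
          col <- integer(n_samples); col[carriers] <- 1L
          if (all(col == 1L) || all(col == 0L)) next # not segregating
          geno_cols[[length(geno_cols) + 1L]] <- col
          pos_all <- c(pos_all, w0 + sample.int(wlen, 1L))
        }
      }
    } else {
      founders <- config$bottleneck$founders
      # founder assignment only matters for founders > 1: founder lineages
      # differ by mutations drawn from a shared coalescent at depth theta
      if (founders > 1L) {
        fr <- ape::rcoal(founders)
        tot <- sum(fr$edge.length)
        Sf <- rpois(1L, config$snp_theta / 2 * tot)
        assign <- sample.int(founders, n_samples, replace = TRUE)
        if (Sf > 0L) {
          picks <- sample.int(nrow(fr$edge), Sf, replace = TRUE,
                              prob = fr$edge.length)
          for (s in seq_len(Sf)) {
            carriers <- mutation_carriers(fr, picks[s])
            col <- as.integer(assign %in% carriers)
            if (all(col == 1L) || all(col == 0L)) next
            geno_cols[[length(geno_cols) + 1L]] <- col
            pos_all <- c(pos_all, w0 + sample.int(wlen, 1L))
          }
        }
      }
      # private post-founding mutations: singletons
      k_priv <- rpois(n_samples, config$bottleneck$private_mu)
      for (i in seq_len(n_samples)) {
        if (k_priv[i] == 0L) next
        for (s in seq_len(k_priv[i])) {
          col <- integer(n_samples); col[i] <- 1L
          geno_cols[[length(geno_cols) + 1L]] <- col
          pos_all <- c(pos_all, w0 + sample.int(wlen, 1L))
        }
      }
    }
  }
  if (length(geno_cols)) {
    geno <- do.call(cbind, geno_cols)
    # strictly increasing positions: sort, then nudge duplicates
    ord <- order(pos_all)
    pos_all <- pos_all[ord]; geno <- geno[, ord, drop = FALSE]
    while (anyDuplicated(pos_all)) {
      dup <- which(duplicated(pos_all))
      pos_all[dup] <- pos_all[dup] + 1L
      ord <- order(pos_all)
      pos_all <- pos_all[ord]; geno <- geno[, ord, drop = FALSE]
    }
  } else {
    geno <- matrix(integer(0), nrow = n_samples, ncol = 0)
  }
  sample_ids <- paste0(sub("_.*$", "", group), "_snp_", seq_len(n_samples))
  rownames(geno) <- sample_ids
  depth <- matrix(draw_depths(config$depth_distribution,
                              n_samples * ncol(geno)),
                  nrow = n_samples,
                  dimnames = list(sample_ids, NULL))
  structure(list(chrom = chrom, chrom_length = L,
                 positions = as.integer(pos_all),
                 geno = geno, depth = depth,
                 sample_ids = sample_ids, group = group),
            class = "sg_genomat")
}

#' @export
print.sg_genomat <- function(x, ...) {
  cat(sprintf("Haploid SNP matrix (%s, group %s): %d samples x %d sites over %d bp\n",
              x$chrom, x$group, length(x$sample_ids), ncol(x$geno),
              x$chrom_length))
  invisible(x)
}

# subset an sg_genomat to a set of site indices
genomat_subset <- function(m, keep) {
  m$positions <- m$positions[keep]
  m$geno <- m$geno[, keep, drop = FALSE]
  m$depth <- m$depth[, keep, drop = FALSE]
  m
}
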