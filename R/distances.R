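## Substitution counting and Jukes-Cantor corrected pairwise distances.
## Columns where either member of a pair carries a gap or an ambiguous base
## are excluded for that pair only (pairwise deletion), and substitution
## counts are pooled across blocks per pair before the (nonlinear) correction.

#' Count substitutions between two aligned rows
#'
#' Columns where either row has anything but A/C/G/T (gap, N, other
#' ambiguity) are excluded from both counts.
#'
#' @param rowA,rowB aligned sequences of equal length (character strings).
#' @return integer vector `c(n_diff, n_valid)`.
#' @export
count_substitutions <- function(rowA, rowB) {
  a <- seq_to_int(rowA); b <- seq_to_int(rowB)
  if (length(a) != length(b)) stop("rows have unequal lengths")
  valid <- a > 0L & b > 0L
  c(n_diff = sum(a[valid] != b[valid]), n_valid = sum(valid))
}

#' Jukes-Cantor (1969) distance correction
#'
#' Corrects an observed mismatch proportion for multiple substitutions at the
#' same site: `d = -(3/4) * log(1 - (4/3) * p)`. Strictly increasing and
#' convex on its domain, with `d >= p` and `d = 0` iff `p = 0`.
#'
#' @param p observed proportion of differing sites, in `[0, 0.75)`.
#' @return corrected distance in substitutions/site (vectorized).
#' @export
jc69_correct <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 0.75))
    stop("p >= 0.75: divergence saturated, JC69 correction undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' JC-corrected pairwise distance matrix over alignment blocks
#'
#' For each sample pair, substitution and valid-site counts are pooled across
#' all blocks first, then a single observed proportion is corrected with
#' [jc69_correct()]. Pairs with zero valid sites get `NA` distances (flagged,
#' never 0). Distances are stored in substitutions/site.
#'
#' @param blocks list of [sg_block()] objects; every block must contain all
#'   requested samples.
#' @param samples sample ids to include (default: the samples of the first
#'   block).
#' @return object of class `sg_distmat`: list with `sample_ids`, `d`
#'   (symmetric numeric matrix, zero diagonal), `valid_sites` (symmetric
#'   integer matrix) and `units = "per_site"`.
#' @export
pairwise_matrix <- function(blocks, samples = NULL) {
  if (length(blocks) == 0L) stop("no blocks")
  if (is.null(samples)) samples <- names(blocks[[1]]$rows)
  if (length(samples) < 2L) stop("need at least two samples")
  n <- length(samples)
  diff <- matrix(0, n, n, dimnames = list(samples, samples))
  valid <- matrix(0, n, n, dimnames = list(samples, samples))
  for (b in blocks) {
    if (!all(samples %in% names(b$rows)))
      stop("block ", b$block_id, " is missing requested samples")
    ints <- lapply(b$rows[samples], seq_to_int)
    ok <- lapply(ints, function(v) v > 0L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      v <- ok[[i]] & ok[[j]]
      nv <- sum(v)
      nd <- sum(ints[[i]][v] != ints[[j]][v])
      diff[i, j] <- diff[i, j] + nd
      valid[i, j] <- valid[i, j] + nv
    }
  }
  diff <- diff + t(diff); valid <- valid + t(valid)
  d <- matrix(NA_real_, n, n, dimnames = list(samples, samples))
  pos <- valid > 0
  d[pos] <- jc69_correct(diff[pos] / valid[pos])
  diag(d) <- 0
  structure(list(sample_ids = samples, d = d,
                 valid_sites = valid, units = "per_site"),
            class = "sg_distmat")
}

#' @export
print.sg_distmat <- function(x, ...) {
  cat(sprintf("JC-corrected distance matrix: %d samples, units %s\n",
              length(x$sample_ids), x$units))
  cat(sprintf("  mean off-diagonal distance %.4g; min valid sites %s\n",
              mean(x$d[upper.tri(x$d)], na.rm = TRUE),
              format(min(x$valid_sites[upper.tri(x$valid_sites)]))))
  invisible(x)
}

#' @export
as.matrix.sg_distmat <- function(x, ...) x$d

#' @export
as.dist.sg_distmat <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(m$d, diag = diag, upper = upper)

#' Pick one read per locus per sample from a RAD dataset
#'
#' Loci for which any sample lacks reads are dropped (every retained locus
#' has all samples aligned); at each retained locus one read is drawn
#' uniformly per sample. Deterministic under a fixed seed.
#'
#' @param rad a dataset from [simulate_rad_dataset()].
#' @param seed integer seed for the draw.
#' @return list of [sg_block()] objects, one per retained locus, with the
#'   selected read as each sample's row.
#' @export
select_one_read_per_locus <- function(rad, seed = 1L) {
  if (length(rad$loci) == 0L) stop("empty RAD dataset")
  set.seed(child_seed(seed, "select"))
  samples <- rad$samples
  out <- list()
  for (loc in rad$loci) {
    depths <- vapply(loc$reads, length, integer(1))
    if (any(depths[samples] == 0L)) next
    rows <- vapply(samples, function(s) {
      rd <- loc$reads[[s]]
      rd[[sample.int(length(rd), 1L)]]
    }, character(1))
    out[[length(out) + 1L]] <- sg_block(loc$locus_id, rows,
                                        region_interval = loc$interval)
  }
  out
}

#' Summarize distances within and between haplotype groups
#'
#' Within-group summaries use unordered distinct pairs; between-group
#' summaries use all cross pairs. Values are displayed in substitutions per
#' 1,000 sites.
#'
#' @param m an `sg_distmat`.
#' @param assignment data.frame with `sample_id` and `group` (e.g. from
#'   [sg_groups()]); every summarized sample must be assigned exactly once.
#' @param pairs optional data.frame with columns `group_a`, `group_b`
#'   selecting which summaries to compute; default: all within-group (size
#'   >= 2) and all between-group combinations.
#' @return data.frame with `group_a`, `group_b`, `n_pairs`, `mean_per_1000`,
#'   `sd_per_1000`.
#' @export
group_distance_summary <- function(m, assignment, pairs = NULL) {
  stopifnot(inherits(m, "sg_distmat"))
  if (anyDuplicated(assignment$sample_id))
    stop("samples assigned more than once")
  groups <- unique(assignment$group)
  members <- lapply(groups, function(g)
    intersect(assignment$sample_id[assignment$group == g], m$sample_ids))
  names(members) <- groups
  if (is.null(pairs)) {
    within <- data.frame(group_a = groups, group_b = groups,
                         stringsAsFactors = FALSE)
    within <- within[vapply(members[within$group_a], length, integer(1)) >= 2L, ]
    betw <- if (length(groups) >= 2L) {
      cmb <- utils::combn(groups, 2)
      data.frame(group_a = cmb[1, ], group_b = cmb[2, ],
                 stringsAsFactors = FALSE)
    } else NULL
    pairs <- rbind(within, betw)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    ga <- pairs$group_a[k]; gb <- pairs$group_b[k]
    ma <- members[[ga]]; mb <- members[[gb]]
    if (ga == gb) {
      if (length(ma) < 2L)
        stop("group ", ga, " has fewer than 2 members for a within-group summary")
      idx <- utils::combn(ma, 2)
      vals <- m$d[cbind(idx[1, ], idx[2, ])]
    } else {
      vals <- as.vector(m$d[ma, mb, drop = FALSE])
    }
    data.frame(group_a = ga, group_b = gb, n_pairs = length(vals),
               mean_per_1000 = mean(vals) * 1000,
               sd_per_1000 = if (length(vals) > 1L) sd(vals) * 1000 else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- distance matrix I/O ---------------------------------------------------

#' Write / read a distance matrix as TSV
#'
#' `write_distmat` emits both a square matrix TSV (`path`) and, if
#' `long_path` is given, a long-form TSV with columns `sample_a`, `sample_b`,
#' `d_per_1000`, `valid_sites`.
#'
#' @param m an `sg_distmat`.
#' @param path square-matrix TSV path.
#' @param long_path optional long-form TSV path.
#' @return `read_distmat` returns an `sg_distmat` (valid-site counts are
#'   restored only if the long form is supplied).
#' @export
write_distmat <- function(m, path, long_path = NULL) {
  write.table(format(m$d, digits = 12, trim = TRUE), path, sep = "\t",
              quote = FALSE, col.names = NA)
  if (!is.null(long_path)) {
    idx <- utils::combn(m$sample_ids, 2)
    long <- data.frame(sample_a = idx[1, ], sample_b = idx[2, ],
                       d_per_1000 = m$d[cbind(idx[1, ], idx[2, ])] * 1000,
                       valid_sites = m$valid_sites[cbind(idx[1, ], idx[2, ])],
                       stringsAsFactors = FALSE)
    write.table(long, long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_distmat
#' @export
read_distmat <- function(path, long_path = NULL) {
  d <- as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE))
  valid <- matrix(NA_integer_, nrow(d), ncol(d), dimnames = dimnames(d))
  if (!is.null(long_path)) {
    long <- read.table(long_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    for (k in seq_len(nrow(long))) {
      a <- long$sample_a[k]; b <- long$sample_b[k]
      valid[a, b] <- valid[b, a] <- long$valid_sites[k]
    }
    diag(valid) <- 0L
  }
  structure(list(sample_ids = rownames(d), d = d, valid_sites = valid,
                 units = "per_site"), class = "sg_distmat")
}
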