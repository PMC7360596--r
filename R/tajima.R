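## Tajima's D from the 1989 formulas, computed per non-overlapping window
## along a chromosome, with depth filters and the beta-distribution
## significance approximation.

#' Tajima (1989) constants
#'
#' The full constants table for sample size `n`: `a1 = sum 1/i`,
#' `a2 = sum 1/i^2` (i = 1..n-1), `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2+a2)`.
#'
#' @param n number of haplotypes (>= 2).
#' @return named list of the constants.
#' @export
tajima_constants <- function(n) {
  if (n < 2L) stop("n must be >= 2")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))`, where `pi` is the mean
#' number of pairwise differences (absolute, per window), `S` the number of
#' segregating sites and the constants come from [tajima_constants()].
#' Undefined (NA, not 0) when `S = 0`.
#'
#' @param n number of haplotypes (>= 2).
#' @param S segregating sites.
#' @param pi mean pairwise differences.
#' @return Tajima's D, or `NA_real_` when `S = 0`.
#' @export
tajimas_d <- function(n, S, pi) {
  if (n < 2L) stop("n must be >= 2")
  if (S < 0 || pi < 0) stop("S and pi must be non-negative")
  if (S == 0L) return(NA_real_)
  k <- tajima_constants(n)
  (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Depth-filter a SNP matrix
#'
#' Whole-genome mode keeps sites where at most one individual has depth
#' below `min_depth` ("less than 6 reads in more than one individual" drops
#' the site); RAD mode keeps only sites where every individual has depth at
#' least `min_depth`.
#'
#' @param m an `sg_genomat`.
#' @param mode `"whole_genome"` or `"rad"`.
#' @param min_depth read-depth threshold (default 6).
#' @return the filtered `sg_genomat`.
#' @export
depth_filter <- function(m, mode = c("whole_genome", "rad"), min_depth = 6L) {
  mode <- match.arg(mode)
  if (ncol(m$geno) == 0L) return(m)
  low <- colSums(m$depth < min_depth)
  keep <- if (mode == "whole_genome") low <= 1L else low == 0L
  genomat_subset(m, which(keep))
}

#' Non-overlapping windowed Tajima's D scan
#'
#' Tiles the chromosome with consecutive windows of `window_bp` (step =
#' width) and computes per-window segregating sites, mean pairwise
#' differences and Tajima's D over the haploid calls. Sites with any missing
#' call are dropped listwise within their window. Windows without
#' segregating sites have `D = NA`.
#'
#' @param m a (filtered) `sg_genomat`.
#' @param window_bp window width in bp (default 100000).
#' @param alpha significance level passed to [tajima_significance()].
#' @return data.frame of class `sg_windowstat` with columns `chrom`, `start`,
#'   `end` (1-based closed), `n`, `S`, `pi`, `D`, `p_flag`.
#' @export
windowed_scan <- function(m, window_bp = 100000L, alpha = 0.05) {
  if (window_bp < 1L) stop("window_bp must be >= 1")
  n <- length(m$sample_ids)
  nwin <- max(1L, ceiling(m$chrom_length / window_bp))
  rows <- lapply(seq_len(nwin), function(w) {
    start <- (w - 1L) * window_bp + 1L
    end <- min(w * window_bp, m$chrom_length)
    idx <- which(m$positions >= start & m$positions <= end)
    if (length(idx)) {
      g <- m$geno[, idx, drop = FALSE]
      complete <- colSums(is.na(g)) == 0L
      g <- g[, complete, drop = FALSE]
      seg <- colSums(g) > 0L & colSums(g) < n
      g <- g[, seg, drop = FALSE]
      S <- ncol(g)
      pi <- if (S > 0L) {
        j <- colSums(g)
        sum(j * (n - j)) / (n * (n - 1) / 2)
      } else 0
    } else { S <- 0L; pi <- 0 }
    D <- tajimas_d(n, S, pi)
    data.frame(chrom = m$chrom, start = start, end = end, n = n,
               S = S, pi = pi, D = D,
               p_flag = tajima_significance(D, n, alpha = alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sg_windowstat", class(out))
  out
}

#' Beta-distribution significance of Tajima's D
#'
#' Tajima's (1989) approximation: D is confined to its theoretical support
#' `[Dmin, Dmax]` (functions of `n`), and its null distribution is taken as
#' the beta distribution on that interval with shape parameters
#' moment-matched to mean 0 and variance 1. The flag is two-sided at level
#' `alpha`; values beyond the support bound are significant at the matching
#' sign. For `n < 4` the approximation is unreliable and the flag is
#' `"undefined"`.
#'
#' @param D Tajima's D (NA gives `"undefined"`).
#' @param n number of haplotypes.
#' @param alpha two-sided significance level (default 0.05).
#' @return one of `"significantly_negative"`, `"significantly_positive"`,
#'   `"ns"`, `"undefined"` (vectorized over `D`).
#' @export
tajima_significance <- function(D, n, alpha = 0.05) {
  vapply(D, function(d) {
    if (is.na(d)) return("undefined")
    if (n < 4L) return("undefined")
    k <- tajima_constants(n)
    dmin <- (2 / n - 1 / k$a1) / sqrt(k$e2)
    dmax_frac <- if (n %% 2L == 0L) n / (2 * (n - 1)) else (n + 1) / (2 * n)
    dmax <- (dmax_frac - 1 / k$a1) / sqrt(k$e2)
    if (d <= dmin) return("significantly_negative")
    if (d >= dmax) return("significantly_positive")
    # beta on [dmin, dmax] with mean 0, variance 1:
    # density prop. to (dmax - D)^(alpha1-1) (D - dmin)^(beta1-1)
    alpha1 <- -(1 + dmin * dmax) * dmax / (dmax - dmin)
    beta1 <- (1 + dmin * dmax) * dmin / (dmax - dmin)
    x <- (d - dmin) / (dmax - dmin)
    p_low <- pbeta(x, beta1, alpha1)
    if (p_low < alpha / 2) "significantly_negative"
    else if (p_low > 1 - alpha / 2) "significantly_positive"
    else "ns"
  }, character(1))
}

#' Summarize a segment of a windowed scan
#'
#' Mean D and sign/significance counts over the windows of a scan whose
#' intervals fall inside `segment_interval`; the mean and counts use only
#' windows with defined D.
#'
#' @param stats an `sg_windowstat` data.frame from [windowed_scan()].
#' @param segment_interval length-2 numeric, 1-based closed bp interval.
#' @return list with `n_windows` (windows in segment), `n_defined`, `mean_D`
#'   (NA if no defined windows), `n_negative`, `n_significant_negative`,
#'   `n_positive`, `n_significant_positive`.
#' @export
segment_summary <- function(stats, segment_interval) {
  sel <- stats[stats$start >= segment_interval[1] &
               stats$end <= segment_interval[2], ]
  if (nrow(sel) == 0L) stop("empty segment: no windows inside the interval")
  def <- sel[!is.na(sel$D), ]
  list(n_windows = nrow(sel),
       n_defined = nrow(def),
       mean_D = if (nrow(def)) mean(def$D) else NA_real_,
       n_negative = sum(def$D < 0),
       n_significant_negative = sum(def$p_flag == "significantly_negative"),
       n_positive = sum(def$D > 0),
       n_significant_positive = sum(def$p_flag == "significantly_positive"))
}

#' Write a windowed scan / segment summary as TSV
#'
#' @param stats an `sg_windowstat` data.frame.
#' @param path file path.
#' @export
write_window_tsv <- function(stats, path) {
  write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
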