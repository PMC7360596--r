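## The core inference: rate-acceleration test on root-to-tip paths,
## ratio-calibrated dating of the supergene node against the outgroup split,
## and the rate-decomposition ordering test between supergene formation and
## speciation.

#' Rate-acceleration factor between Sb and SB path sets
#'
#' Compares the summed branch lengths from the SB/Sb divergence node to the
#' Sb tips against those to the SB tips. The acceleration factor is the ratio
#' of means, `lambda = mean(sb) / mean(sB)`; its SD comes from first-order
#' (delta-method) propagation of the two per-group SDs, and the difference
#' between path sets is tested with a two-sided Wilcoxon rank-sum test
#' (exact for small samples without ties).
#'
#' @param sb_paths path lengths to the derived-haplotype (Sb) tips.
#' @param sB_paths path lengths to the ancestral-haplotype (SB) tips.
#' @return list with `lambda`, `sd`, `wilcoxon_p`, and the two group
#'   means/SDs (`mean_sb`, `sd_sb`, `mean_sB`, `sd_sB`).
#' @export
acceleration_factor <- function(sb_paths, sB_paths) {
  if (length(sb_paths) < 2L || length(sB_paths) < 2L)
    stop("need at least 2 paths per side")
  m_b <- mean(sb_paths); m_B <- mean(sB_paths)
  if (m_B == 0) stop("zero mean SB path length")
  s_b <- sd(sb_paths); s_B <- sd(sB_paths)
  lambda <- m_b / m_B
  sd_l <- lambda * sqrt((s_b / m_b)^2 + (s_B / m_B)^2)
  p <- if (isTRUE(all.equal(sort(sb_paths), sort(sB_paths)))) 1 else
    suppressWarnings(wilcox.test(sb_paths, sB_paths,
                                 alternative = "two.sided")$p.value)
  list(lambda = lambda, sd = sd_l, wilcoxon_p = p,
       mean_sb = m_b, sd_sb = s_b, mean_sB = m_B, sd_sB = s_B)
}

# tips of a group-assignment class; SB = ancestral, Sb = derived
assignment_tips <- function(assignment, which = c("SB", "Sb", "outgroup")) {
  which <- match.arg(which)
  if (which == "outgroup")
    return(assignment$sample_id[assignment$group == "outgroup"])
  assignment$sample_id[grepl(paste0("^", which, "_"), assignment$group)]
}

#' Depth ratio of the supergene node to the calibration node
#'
#' The ratio of the SB--Sb divergence depth to the ingroup--outgroup
#' divergence depth, both measured as mean path length from the SB tips only:
#' numerator to `mrca(SB, Sb)`, denominator to `mrca(ingroup, outgroup)`
#' (the root of an outgroup-rooted tree). Using only SB paths keeps the
#' ratio unaffected by the accelerated Sb rate. Invariant to rescaling all
#' branch lengths.
#'
#' @param tree rooted `phylo` containing SB tips, Sb tips and the outgroup.
#' @param assignment group-assignment data.frame (`sample_id`, `group` with
#'   values like `SB_invicta`, `Sb_invicta`, `outgroup`).
#' @param sb_tips,sB_tips,outgroup_tips optional explicit tip sets,
#'   overriding the assignment.
#' @return list with `ratio`, `num` (mean SB depth to the supergene node),
#'   `den` (mean SB depth to the calibration node), and the two node ids.
#' @export
relative_ratio <- function(tree, assignment = NULL, sb_tips = NULL,
                           sB_tips = NULL, outgroup_tips = NULL) {
  if (!is.null(assignment)) {
    if (is.null(sB_tips)) sB_tips <- assignment_tips(assignment, "SB")
    if (is.null(sb_tips)) sb_tips <- assignment_tips(assignment, "Sb")
    if (is.null(outgroup_tips)) outgroup_tips <- assignment_tips(assignment, "outgroup")
  }
  sB_tips <- intersect(sB_tips, tree$tip.label)
  sb_tips <- intersect(sb_tips, tree$tip.label)
  sg_node <- mrca_node(tree, c(sB_tips, sb_tips))
  cal_node <- mrca_node(tree, c(sB_tips, sb_tips, outgroup_tips))
  if (sg_node == cal_node)
    stop("supergene node coincides with the calibration node")
  num <- mean(path_lengths_from_node(tree, sg_node, sB_tips))
  den <- mean(path_lengths_from_node(tree, cal_node, sB_tips))
  list(ratio = num / den, num = num, den = den,
       supergene_node = sg_node, calibration_node = cal_node)
}

#' Bootstrap replicates of the depth ratio
#'
#' Nonparametric bootstrap over the SB tips: resample tips with replacement
#' and recompute the ratio of mean depths on the fixed rooted tree.
#'
#' @inheritParams relative_ratio
#' @param n_boot number of replicates.
#' @param seed integer seed.
#' @return numeric vector of bootstrap ratios.
#' @export
bootstrap_ratio <- function(tree, assignment = NULL, sb_tips = NULL,
                            sB_tips = NULL, outgroup_tips = NULL,
                            n_boot = 1000L, seed = 1L) {
  if (!is.null(assignment)) {
    if (is.null(sB_tips)) sB_tips <- assignment_tips(assignment, "SB")
    if (is.null(sb_tips)) sb_tips <- assignment_tips(assignment, "Sb")
    if (is.null(outgroup_tips)) outgroup_tips <- assignment_tips(assignment, "outgroup")
  }
  sB_tips <- intersect(sB_tips, tree$tip.label)
  sb_tips <- intersect(sb_tips, tree$tip.label)
  sg_node <- mrca_node(tree, c(sB_tips, sb_tips))
  cal_node <- mrca_node(tree, c(sB_tips, sb_tips, outgroup_tips))
  num_paths <- path_lengths_from_node(tree, sg_node, sB_tips)
  den_paths <- path_lengths_from_node(tree, cal_node, sB_tips)
  set.seed(child_seed(seed, "boot"))
  vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(sB_tips), replace = TRUE)
    mean(num_paths[idx]) / mean(den_paths[idx])
  }, numeric(1))
}

#' Calibration specification
#'
#' A fossil-informed calibration age with its 95% interval, e.g. the
#' outgroup divergence at 25 (18--32) MYA.
#'
#' @param point point age in MYA.
#' @param ci_low,ci_high 95% bounds, `0 < ci_low <= point <= ci_high`.
#' @return object of class `sg_calibration`.
#' @export
sg_calibration <- function(point = 25, ci_low = 18, ci_high = 32) {
  if (!(0 < ci_low && ci_low <= point && point <= ci_high))
    stop("calibration must satisfy 0 < ci_low <= point <= ci_high")
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high),
            class = "sg_calibration")
}

#' Ratio-calibrated node age
#'
#' `age = calibration_point * R`, where `R` is the depth ratio of the dated
#' node to the calibration node. The confidence interval combines the
#' calibration interval with the sampling distribution of `R`: the 2.5% and
#' 97.5% bootstrap quantiles of `R` are multiplied by the matching
#' calibration bounds (a conservative outer product). With no bootstrap
#' replicates the CI reflects calibration uncertainty only.
#'
#' @param R depth ratio (> 0).
#' @param cal an [sg_calibration()].
#' @param R_boot optional bootstrap replicates of `R` (see
#'   [bootstrap_ratio()]).
#' @return list with `age_point`, `age_low`, `age_high` (MYA).
#' @export
calibrated_age <- function(R, cal = sg_calibration(), R_boot = NULL) {
  if (R <= 0) stop("R must be > 0")
  q <- if (is.null(R_boot)) c(R, R) else
    unname(quantile(R_boot, c(0.025, 0.975), type = 7))
  list(age_point = cal$point * R,
       age_low = cal$ci_low * q[1],
       age_high = cal$ci_high * q[2])
}

#' Event-ordering test: supergene formation vs speciation
#'
#' Decomposes the SB--Sb distance within one species,
#' `D_morph = t * r_B + t * r_b = t * r_B * (1 + lambda)`, to obtain the
#' supergene component `t * r_B = D_morph / (1 + lambda)`, and halves the
#' between-species SB--SB distance to obtain the speciation component
#' `s * r_B = D_species / 2`. Speciation preceded supergene formation iff
#' `s * r_B > t * r_B`. When the underlying pairwise-distance sets are
#' supplied, the comparison is additionally tested with a two-sided Wilcoxon
#' rank-sum test on the transformed sets, and the verdict is
#' `"indistinguishable"` when that test is not significant at `alpha`.
#'
#' @param D_morph mean SB--Sb distance within one species (per 1,000 sites,
#'   or any unit -- the verdict is scale-invariant).
#' @param D_species mean between-species SB--SB distance (same unit).
#' @param lambda acceleration factor (> 0).
#' @param morph_pairs,species_pairs optional vectors of the pairwise
#'   distances underlying the two means.
#' @param alpha significance level for the Wilcoxon comparison.
#' @return list with `t_rB`, `s_rB`, `verdict` in
#'   `c("speciation_first", "supergene_first", "indistinguishable")`, and
#'   `wilcoxon_p` (NA without pair sets).
#' @export
ordering_test <- function(D_morph, D_species, lambda,
                          morph_pairs = NULL, species_pairs = NULL,
                          alpha = 0.05) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (D_morph <= 0 || D_species <= 0) stop("distances must be > 0")
  t_rB <- D_morph / (1 + lambda)
  s_rB <- D_species / 2
  p <- NA_real_
  if (!is.null(morph_pairs) && !is.null(species_pairs)) {
    p <- suppressWarnings(
      wilcox.test(species_pairs / 2, morph_pairs / (1 + lambda),
                  alternative = "two.sided")$p.value)
    verdict <- if (p >= alpha) "indistinguishable"
               else if (s_rB > t_rB) "speciation_first" else "supergene_first"
  } else {
    verdict <- if (s_rB == t_rB) "indistinguishable"
               else if (s_rB > t_rB) "speciation_first" else "supergene_first"
  }
  list(t_rB = t_rB, s_rB = s_rB, verdict = verdict, wilcoxon_p = p)
}

#' Rescale a coalescent-calibrated age to a different generation time
#'
#' Ages derived from a number-of-generations estimate scale linearly with the
#' assumed generation time: an estimate made at `gen_assumed` years per
#' generation becomes `age * gen_alternative / gen_assumed` under the
#' alternative. (E.g. a 1.1 MYA speciation estimate at 6-year generations is
#' 0.55 MYA at 3-year generations.)
#'
#' @param age_mya age estimate in MYA.
#' @param gen_assumed generation time (years) behind the estimate.
#' @param gen_alternative alternative generation time (years).
#' @return rescaled age in MYA.
#' @export
generation_rescale <- function(age_mya, gen_assumed = 6, gen_alternative = 3) {
  if (gen_assumed <= 0 || gen_alternative <= 0)
    stop("generation times must be positive")
  age_mya * gen_alternative / gen_assumed
}

#' Fit the supergene dating model to a tree
#'
#' The package's central estimator. Given a tree of supergene haplotypes
#' plus an outgroup and a group assignment, it (i) roots the tree on the
#' outgroup if needed, (ii) estimates the Sb/SB rate-acceleration factor
#' from the path lengths off the SB--Sb divergence node, (iii) computes the
#' depth ratio of the supergene node to the calibration node from SB paths
#' only, (iv) converts it to an absolute age with a bootstrap-combined
#' confidence interval, and (v) when a distance matrix is supplied, runs the
#' event-ordering test between supergene formation and speciation.
#'
#' @param tree a `phylo` (rooted or unrooted) whose tips match `assignment`.
#' @param assignment group-assignment data.frame (`sample_id`, `group` in
#'   `SB_invicta`, `SB_richteri`, `Sb_invicta`, `Sb_richteri`, `outgroup`).
#' @param calibration an [sg_calibration()] for the outgroup split.
#' @param distmat optional `sg_distmat` used for the ordering test
#'   (needs SB and Sb tips of one species plus SB tips of the other).
#' @param n_boot bootstrap replicates for the age CI.
#' @param seed seed for the bootstrap.
#' @return object of class `sg_dating` with components `lambda`
#'   (acceleration estimate, SD and Wilcoxon p), `ratio`, `age`, `ordering`
#'   (or NULL), plus the rooted tree and inputs. Has `print`, `summary` and
#'   `coef` methods.
#' @export
sg_date <- function(tree, assignment, calibration = sg_calibration(),
                    distmat = NULL, n_boot = 1000L, seed = 1L) {
  og <- assignment_tips(assignment, "outgroup")
  og <- intersect(og, tree$tip.label)
  if (length(og) == 0L) stop("no outgroup tips in the tree")
  if (!ape::is.rooted(tree) || length(og) > 0L)
    tree <- root_with_outgroup(tree, og)
  sB <- intersect(assignment_tips(assignment, "SB"), tree$tip.label)
  sb <- intersect(assignment_tips(assignment, "Sb"), tree$tip.label)
  if (length(sB) < 2L || length(sb) < 2L)
    stop("need at least two SB and two Sb tips")

  sg_node <- mrca_node(tree, c(sB, sb))
  sb_paths <- path_lengths_from_node(tree, sg_node, sb)
  sB_paths <- path_lengths_from_node(tree, sg_node, sB)
  acc <- acceleration_factor(sb_paths, sB_paths)

  rr <- relative_ratio(tree, sb_tips = sb, sB_tips = sB, outgroup_tips = og)
  rb <- bootstrap_ratio(tree, sb_tips = sb, sB_tips = sB, outgroup_tips = og,
                        n_boot = n_boot, seed = seed)
  age <- calibrated_age(rr$ratio, calibration, R_boot = rb)

  ordering <- NULL
  if (!is.null(distmat)) {
    a <- assignment
    ri_B <- intersect(a$sample_id[a$group == "SB_richteri"], distmat$sample_ids)
    ri_b <- intersect(a$sample_id[a$group == "Sb_richteri"], distmat$sample_ids)
    in_B <- intersect(a$sample_id[a$group == "SB_invicta"], distmat$sample_ids)
    if (length(ri_B) >= 1L && length(ri_b) >= 1L && length(in_B) >= 1L) {
      morph <- as.vector(distmat$d[ri_B, ri_b, drop = FALSE]) * 1000
      species <- as.vector(distmat$d[in_B, ri_B, drop = FALSE]) * 1000
      ordering <- ordering_test(mean(morph), mean(species), acc$lambda,
                                morph_pairs = morph, species_pairs = species)
    }
  }

  structure(list(lambda = acc, ratio = rr, ratio_boot = rb, age = age,
                 ordering = ordering, calibration = calibration,
                 tree = tree, assignment = assignment,
                 n_boot = n_boot, seed = seed),
            class = "sg_dating")
}

#' @export
print.sg_dating <- function(x, ...) {
  cat("Supergene dating fit\n")
  cat(sprintf("  acceleration factor (Sb/SB): %.2f +/- %.2f (Wilcoxon p = %.3g)\n",
              x$lambda$lambda, x$lambda$sd, x$lambda$wilcoxon_p))
  cat(sprintf("  depth ratio R = %.4f (1:%.1f)\n",
              x$ratio$ratio, 1 / x$ratio$ratio))
  cat(sprintf("  supergene age: %.1f (%.1f-%.1f) MYA [calibration %g (%g-%g)]\n",
              x$age$age_point, x$age$age_low, x$age$age_high,
              x$calibration$point, x$calibration$ci_low, x$calibration$ci_high))
  if (!is.null(x$ordering))
    cat(sprintf("  ordering: t*rB = %.2f, s*rB = %.2f -> %s\n",
                x$ordering$t_rB, x$ordering$s_rB, x$ordering$verdict))
  invisible(x)
}

#' @export
summary.sg_dating <- function(object, ...) {
  x <- object
  cat("Supergene dating fit\n\n")
  cat(sprintf("Paths from the SB-Sb divergence node (substitutions per 1,000 sites):\n"))
  cat(sprintf("  Sb tips: %.2f +/- %.2f (n = %d)\n",
              x$lambda$mean_sb * 1000, x$lambda$sd_sb * 1000,
              sum(grepl("^Sb_", x$assignment$group))))
  cat(sprintf("  SB tips: %.2f +/- %.2f (n = %d)\n",
              x$lambda$mean_sB * 1000, x$lambda$sd_sB * 1000,
              sum(grepl("^SB_", x$assignment$group))))
  print(x)
  invisible(x)
}

#' @export
coef.sg_dating <- function(object, ...) {
  c(lambda = object$lambda$lambda,
    ratio = object$ratio$ratio,
    age_mya = object$age$age_point)
}

#' @export
plot.sg_dating <- function(x, ...) {
  grp <- x$assignment$group[match(x$tree$tip.label, x$assignment$sample_id)]
  cols <- c(SB_invicta = "darkgreen", SB_richteri = "forestgreen",
            Sb_invicta = "purple3", Sb_richteri = "purple4",
            outgroup = "grey40")
  ape::plot.phylo(x$tree, tip.color = cols[grp], ...)
  invisible(x)
}

#' Write a plain-text + TSV dating report
#'
#' @param fit an `sg_dating` object.
#' @param tsv_path TSV path for the numeric results.
#' @param txt_path optional human-readable report path.
#' @export
write_dating_report <- function(fit, tsv_path, txt_path = NULL) {
  tab <- data.frame(
    quantity = c("lambda", "lambda_sd", "lambda_wilcoxon_p", "ratio_R",
                 "age_point_mya", "age_low_mya", "age_high_mya",
                 "t_rB", "s_rB"),
    value = c(fit$lambda$lambda, fit$lambda$sd, fit$lambda$wilcoxon_p,
              fit$ratio$ratio, fit$age$age_point, fit$age$age_low,
              fit$age$age_high,
              if (is.null(fit$ordering)) NA else fit$ordering$t_rB,
              if (is.null(fit$ordering)) NA else fit$ordering$s_rB),
    stringsAsFactors = FALSE)
  write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w"); on.exit(close(con))
    sink(con); print(fit); sink()
  }
  invisible(tsv_path)
}
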