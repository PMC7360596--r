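## Haplotype simulator: JC69 evolution along a supergene genealogy with a
## lineage-specific rate multiplier on the Sb clade.

# newick fragment for a star clade of `labels` coalescing at age `w`,
# attached to a parent node of age `parent_age`
clade_newick <- function(labels, w, parent_age) {
  if (length(labels) == 1L) return(sprintf("%s:%.10g", labels, parent_age))
  tips <- paste(sprintf("%s:%.10g", labels, w), collapse = ",")
  sprintf("(%s):%.10g", tips, parent_age - w)
}

# true genealogy in TIME units as an ape phylo
build_time_tree <- function(config) {
  bt <- config$branch_times
  gs <- config$group_sizes
  lab <- function(g) group_tip_labels(g, gs[[g]])
  w <- bt$within
  nwk <- switch(config$topology,
    fig_supergene_nested = {
      sb <- sprintf("(%s,%s):%.10g",
                    clade_newick(lab("Sb_richteri"), w, bt$sb_species),
                    clade_newick(lab("Sb_invicta"), w, bt$sb_species),
                    bt$supergene - bt$sb_species)
      b <- sprintf("(%s,%s):%.10g",
                   clade_newick(lab("SB_richteri"), w, bt$supergene), sb,
                   bt$speciation - bt$supergene)
      ing <- sprintf("(%s,%s):%.10g",
                     clade_newick(lab("SB_invicta"), w, bt$speciation), b,
                     bt$outgroup - bt$speciation)
      sprintf("(%s,%s:%.10g);", ing, lab("outgroup")[1], bt$outgroup)
    },
    sb_basal = {
      sbpair <- sprintf("(%s,%s):%.10g",
                        clade_newick(lab("SB_invicta"), w, bt$speciation),
                        clade_newick(lab("SB_richteri"), w, bt$speciation),
                        bt$supergene - bt$speciation)
      sb <- sprintf("(%s,%s):%.10g",
                    clade_newick(lab("Sb_richteri"), w, bt$sb_species),
                    clade_newick(lab("Sb_invicta"), w, bt$sb_species),
                    bt$supergene - bt$sb_species)
      ing <- sprintf("(%s,%s):%.10g", sbpair, sb,
                     bt$outgroup - bt$supergene)
      sprintf("(%s,%s:%.10g);", ing, lab("outgroup")[1], bt$outgroup)
    },
    invicta_only = {
      ing <- sprintf("(%s,%s):%.10g",
                     clade_newick(lab("SB_invicta"), w, bt$supergene),
                     clade_newick(lab("Sb_invicta"), w, bt$supergene),
                     bt$outgroup - bt$supergene)
      sprintf("(%s,%s:%.10g);", ing, lab("outgroup")[1], bt$outgroup)
    })
  ape::read.tree(text = nwk)
}

# indices of edges inside (and including the stem of) the clade spanned by
# `tips`; BFS over the edge matrix
subtree_edges <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (length(idx) == 1L) return(which(tree$edge[, 2] == idx))
  node <- ape::getMRCA(tree, idx)
  keep <- which(tree$edge[, 2] == node) # stem
  frontier <- node
  while (length(frontier)) {
    rows <- which(tree$edge[, 1] %in% frontier)
    keep <- c(keep, rows)
    frontier <- tree$edge[rows, 2]
    frontier <- frontier[frontier > ape::Ntip(tree)]
  }
  sort(unique(keep))
}

sb_tip_labels <- function(tree) {
  grep("^(invb|richb)_", tree$tip.label, value = TRUE)
}

# expected-substitutions tree: time lengths x rate, with lambda on Sb branches
time_to_subs_tree <- function(time_tree, base_rate, lambda) {
  tr <- time_tree
  rate <- rep(base_rate, nrow(tr$edge))
  sb <- sb_tip_labels(tr)
  if (length(sb)) rate[subtree_edges(tr, sb)] <- base_rate * lambda
  tr$edge.length <- tr$edge.length * rate
  tr
}

#' Simulate supergene haplotype alignments with known truth
#'
#' Evolves sequences under the Jukes-Cantor (1969) model (equal base
#' frequencies, one substitution rate) along the genealogy implied by the
#' configuration, applying the Sb rate multiplier to every branch inside the
#' Sb clade (including its stem). On a branch of expected length `d`
#' substitutions/site each site changes with probability
#' `0.75 * (1 - exp(-4 d / 3))`, the JC69 transition probability to a
#' different base. There is no indel process; gaps and ambiguity enter only
#' through downstream masking.
#'
#' @param config an [sg_sim_config()].
#' @return list with `blocks` (a list of [sg_block()] objects that concatenate
#'   to `seq_length` sites) and `truth` (class `sg_truth`: the true tree with
#'   branch lengths in substitutions/site, the time tree, `true_lambda`,
#'   `true_supergene_age`, `true_speciation_age`, per-edge realized
#'   substitution counts and per-site mutation counts).
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sg_sim_config"))
  set.seed(child_seed(config$seed, "haplotypes"))
  time_tree <- build_time_tree(config)
  tree <- time_to_subs_tree(time_tree, config$base_rate, config$sb_rate_multiplier)

  L <- config$seq_length
  ntip <- ape::Ntip(tree)
  edges <- tree$edge
  # preorder = reversed postorder: parents always precede children
  ord <- rev(ape::reorder.phylo(tree, "postorder", index.only = TRUE))
  root <- edges[ord[1], 1]

  seqs <- vector("list", max(edges))
  seqs[[root]] <- sample.int(4L, L, replace = TRUE)
  pending <- tabulate(edges[, 1], nbins = max(edges)) # children left per node
  mut_counts <- integer(L)
  edge_subs <- integer(nrow(edges))

  for (e in ord) {
    par <- edges[e, 1]; chi <- edges[e, 2]
    d <- tree$edge.length[e]
    p <- 0.75 * (1 - exp(-4 * d / 3))
    s <- seqs[[par]]
    if (p > 0) {
      idx <- which(runif(L) < p)
      if (length(idx)) {
        s[idx] <- ((s[idx] - 1L + sample.int(3L, length(idx), replace = TRUE)) %% 4L) + 1L
        mut_counts[idx] <- mut_counts[idx] + 1L
        edge_subs[e] <- length(idx)
      }
    }
    seqs[[chi]] <- s
    pending[par] <- pending[par] - 1L
    if (pending[par] == 0L && par != root) seqs[par] <- list(NULL)
    if (pending[root] == 0L) seqs[root] <- list(NULL)
  }

  tip_seqs <- lapply(seq_len(ntip), function(i) seqs[[i]])
  names(tip_seqs) <- tree$tip.label

  # split into contiguous blocks
  bounds <- floor(seq(0, L, length.out = config$n_blocks + 1L))
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    from <- bounds[b] + 1L; to <- bounds[b + 1L]
    rows <- vapply(tip_seqs, function(s) int_to_seq(s[from:to]), character(1))
    conf <- NULL
    if (config$confidence_low_frac > 0) {
      ncol <- to - from + 1L
      low <- runif(ncol) < config$confidence_low_frac
      conf <- ifelse(low, runif(ncol, 0, 59.99), runif(ncol, 60, 100))
    }
    blocks[[b]] <- sg_block(block_id = sprintf("block_%04d", b),
                            rows = rows,
                            region_interval = c(from, to),
                            column_confidence = conf)
  }

  bt <- config$branch_times
  truth <- structure(list(
    true_tree = tree,
    time_tree = time_tree,
    true_lambda = config$sb_rate_multiplier,
    true_supergene_age = bt$supergene,
    true_speciation_age = if (config$topology == "invicta_only") NA_real_ else bt$speciation,
    base_rate = config$base_rate,
    per_edge_subs = edge_subs,
    per_site_mut_counts = mut_counts,
    topology = config$topology), class = "sg_truth")

  list(blocks = blocks, truth = truth)
}

#' @export
print.sg_truth <- function(x, ...) {
  cat("Simulation truth record\n")
  cat(sprintf("  topology %s; lambda %g; supergene age %g; speciation age %s\n",
              x$topology, x$true_lambda, x$true_supergene_age,
              format(x$true_speciation_age)))
  cat(sprintf("  %d tips; %d realized substitutions over %d sites\n",
              ape::Ntip(x$true_tree), sum(x$per_edge_subs),
              length(x$per_site_mut_counts)))
  invisible(x)
}

#' Write / read a truth record as a flat key-value text file
#'
#' Scalar truth fields plus the two trees (as newick strings) in
#' tab-separated `key<TAB>value` lines. Per-edge and per-site counts are not
#' serialized.
#'
#' @param truth an `sg_truth` object.
#' @param path file path.
#' @return `read_truth` returns a list with the scalar fields and `phylo`
#'   trees.
#' @export
write_truth <- function(truth, path) {
  lines <- c(
    paste0("topology\t", truth$topology),
    paste0("true_lambda\t", format(truth$true_lambda, digits = 15)),
    paste0("true_supergene_age\t", format(truth$true_supergene_age, digits = 15)),
    paste0("true_speciation_age\t", format(truth$true_speciation_age, digits = 15)),
    paste0("base_rate\t", format(truth$base_rate, digits = 15)),
    paste0("true_tree\t", ape::write.tree(truth$true_tree)),
    paste0("time_tree\t", ape::write.tree(truth$time_tree)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  kv <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("key", "value"), quote = "")
  get <- function(k) kv$value[kv$key == k]
  list(topology = get("topology"),
       true_lambda = as.numeric(get("true_lambda")),
       true_supergene_age = as.numeric(get("true_supergene_age")),
       true_speciation_age = as.numeric(get("true_speciation_age")),
       base_rate = as.numeric(get("base_rate")),
       true_tree = ape::read.tree(text = get("true_tree")),
       time_tree = ape::read.tree(text = get("time_tree")))
}
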