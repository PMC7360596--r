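## Tree construction and structural queries for the dating analysis. Trees
## are ape "phylo" objects with branch lengths in substitutions/site; newick
## read/write goes through ape.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (via [ape::nj()]). Negative branch lengths, a
#' known NJ artifact on noisy matrices, are clamped to zero with the deficit
#' moved to the sibling branch so that path lengths through the parent are
#' approximately preserved. On an additive matrix the tree reproduces every
#' pairwise distance exactly.
#'
#' @param m an `sg_distmat` or a symmetric numeric matrix; must contain no
#'   undefined (NA) off-diagonal entries and at least 3 samples.
#' @return an unrooted `phylo` tree.
#' @export
build_nj_tree <- function(m) {
  d <- if (inherits(m, "sg_distmat")) m$d else as.matrix(m)
  if (nrow(d) < 3L) stop("need at least 3 samples")
  off <- d[upper.tri(d)]
  if (anyNA(off)) stop("distance matrix has undefined entries")
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tr)
}

# set negative edges to 0, adding the (negative) deficit onto the sibling;
# bounded iteration, then any residual negatives are clamped outright
clamp_negative_branches <- function(tree) {
  for (it in seq_len(nrow(tree$edge))) {
    neg <- which(tree$edge.length < -1e-12)
    if (length(neg) == 0L) break
    e <- neg[which.min(tree$edge.length[neg])]
    par <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == par), e)
    if (length(sibs)) {
      s <- sibs[which.max(tree$edge.length[sibs])]
      tree$edge.length[s] <- tree$edge.length[s] + tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Root a tree with an outgroup
#'
#' Checks that the outgroup tips form a clade, roots on the branch separating
#' them from the ingroup (ingroup branch lengths preserved), and places the
#' root along that branch. With `position = "midpoint"` (default) the root is
#' positioned so that the outgroup tip depth equals the mean ingroup tip
#' depth -- a molecular-clock midpoint, the only identifiable placement with
#' a single outgroup; a numeric `position` in \[0, 1\] instead splits the
#' branch at that fraction (measured from the ingroup side).
#'
#' @param tree unrooted `phylo`.
#' @param outgroup_tips tip labels of the outgroup.
#' @param position `"midpoint"` or a numeric fraction.
#' @return rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_tips, position = "midpoint") {
  if (!all(outgroup_tips %in% tree$tip.label))
    stop("unknown outgroup tips")
  if (length(outgroup_tips) > 1L &&
      !ape::is.monophyletic(tree, outgroup_tips))
    stop("outgroup tips do not form a clade")
  rt <- ape::root(tree, outgroup = outgroup_tips, resolve.root = TRUE)
  root <- ape::Ntip(rt) + 1L
  kids <- which(rt$edge[, 1] == root)
  if (length(kids) != 2L) return(rt) # already trifurcating; leave as is
  og_idx <- match(outgroup_tips, rt$tip.label)
  side_tips <- lapply(kids, function(e) {
    chi <- rt$edge[e, 2]
    if (chi <= ape::Ntip(rt)) chi else {
      cl <- ape::extract.clade(rt, chi)
      match(cl$tip.label, rt$tip.label)
    }
  })
  og_side <- which(vapply(side_tips, function(t) all(t %in% og_idx), logical(1)))
  if (length(og_side) != 1L) return(rt)
  in_side <- setdiff(seq_along(kids), og_side)
  e_og <- kids[og_side]; e_in <- kids[in_side]
  B <- rt$edge.length[e_og] + rt$edge.length[e_in] # total root-branch length
  dd <- ape::dist.nodes(rt)
  in_tips <- side_tips[[in_side]]
  # depth of ingroup tips from the ingroup-side attachment point
  attach_in <- rt$edge[e_in, 2]
  d_in <- mean(dd[attach_in, in_tips]) +
    if (attach_in <= ape::Ntip(rt)) 0 else 0
  og_attach <- rt$edge[e_og, 2]
  d_og <- mean(dd[og_attach, og_idx])
  if (identical(position, "midpoint")) {
    # x from ingroup attachment: d_in + x = d_og + (B - x)
    x <- (B + d_og - d_in) / 2
    x <- min(max(x, 0), B)
  } else {
    x <- B * as.numeric(position)
  }
  rt$edge.length[e_in] <- x
  rt$edge.length[e_og] <- B - x
  rt
}

#' Most recent common ancestor of a tip set
#'
#' @param tree a `phylo`.
#' @param tips tip labels; a single tip is its own MRCA.
#' @return node number.
#' @export
mrca_node <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("unknown tips: ", paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

#' Summed branch lengths from an ancestral node to tips
#'
#' @param tree a `phylo`.
#' @param node node number, an ancestor of (or equal to) every requested tip.
#' @param tips tip labels.
#' @return named numeric vector of path lengths (substitutions/site).
#' @export
path_lengths_from_node <- function(tree, node, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("unknown tips: ", paste(tips[is.na(idx)], collapse = ", "))
  for (i in idx) {
    if (i == node) next
    anc <- i
    repeat {
      row <- which(tree$edge[, 2] == anc)
      if (length(row) == 0L) { anc <- NA; break }
      anc <- tree$edge[row, 1]
      if (anc == node) break
    }
    if (is.na(anc)) stop("node is not an ancestor of tip ", tree$tip.label[i])
  }
  dd <- ape::dist.nodes(tree)
  setNames(dd[node, idx], tips)
}

#' Is a tip set monophyletic?
#'
#' TRUE iff the tip set is exactly the tip set of some subtree of the rooted
#' tree. A single tip is trivially monophyletic.
#'
#' @param tree rooted `phylo`.
#' @param tips tip labels.
#' @return logical.
#' @export
is_monophyletic_clade <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("unknown tips: ", paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(TRUE)
  node <- ape::getMRCA(tree, idx)
  cl <- ape::extract.clade(tree, node)
  setequal(cl$tip.label, tips)
}
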