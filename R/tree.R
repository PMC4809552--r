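#' Parse a rooted phylogeny from a newick string
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is
#' an ape `phylo` object and is used as-is by the likelihood engine; edges
#' are identified by their row index in `tree$edge`.
#'
#' @param text A newick string with branch lengths.
#' @return A `phylo` object.
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.2):0.05,C:0.3):0;")
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed newick string: ", substr(text, 1, 60))
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate leaf name(s) in newick: ", paste(dup, collapse = ", "))
  if (is.null(tr$edge.length))
    stop("newick string has no branch lengths")
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    stop("all branch lengths must be finite and >= 0")
  tr
}

#' Serialize a phylogeny to newick
#' @param tree A `phylo` object.
#' @return A newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Per-edge branch scale multipliers
#'
#' A branch scale map is a plain numeric vector with one nonnegative
#' multiplier per row of `tree$edge`; unspecified edges default to 1.
#' The conserved rate scale rho (all edges) and the acceleration scale
#' lambda (one stem edge) are both expressed this way.
#'
#' @param tree A `phylo` object.
#' @param scale Scalar applied to every edge (default 1).
#' @param edges Optional integer edge indices given individual multipliers.
#' @param edge_scale Multipliers for `edges` (recycled).
#' @return Numeric vector of length `nrow(tree$edge)`.
#' @export
branch_scales <- function(tree, scale = 1, edges = NULL, edge_scale = NULL) {
  s <- rep(as.numeric(scale), length.out = nrow(tree$edge))
  if (!is.null(edges)) {
    if (any(edges < 1 | edges > nrow(tree$edge))) stop("edge index out of range")
    s[edges] <- rep(as.numeric(edge_scale), length.out = length(edges))
  }
  if (any(!is.finite(s)) || any(s < 0)) stop("branch scales must be >= 0")
  s
}

#' Stem edge of a clade
#'
#' Returns the index (row of `tree$edge`) of the branch subtending the most
#' recent common ancestor of `leaves` — the clade's "ancestral lineage".
#' Errors if the leaf set is not monophyletic or if its MRCA is the root
#' (a root clade has no stem edge).
#'
#' @param tree A `phylo` object.
#' @param leaves Character vector of leaf names (>= 1).
#' @return Integer edge index.
#' @export
clade_stem_edge <- function(tree, leaves) {
  miss <- setdiff(leaves, tree$tip.label)
  if (length(miss)) stop("leaves not in tree: ", paste(miss, collapse = ", "))
  if (length(leaves) == 1L) {
    node <- match(leaves, tree$tip.label)
  } else {
    if (!ape::is.monophyletic(tree, leaves))
      stop("focal leaf set is not monophyletic in the tree")
    node <- ape::getMRCA(tree, leaves)
  }
  e <- which(tree$edge[, 2] == node)
  if (!length(e)) stop("clade MRCA is the root; no stem edge exists")
  e
}

#' Graft a new leaf next to an existing one
#'
#' Inserts a new internal node on the branch above `sister_leaf`, at a
#' distance `stem_fraction * t` rootward of the sister tip (where `t` is the
#' sister's pendant branch length), and attaches `new_leaf` there with
#' pendant length `new_branch_length`. All other leaf-to-leaf path lengths
#' are preserved. Used to add extra focal-clade genomes, recovered only as
#' contigs, into the test tree.
#'
#' @param tree A `phylo` object.
#' @param sister_leaf Existing leaf name.
#' @param new_leaf New leaf name (must not collide).
#' @param stem_fraction Where to split the sister branch, in `[0, 1]`;
#'   0 attaches at the sister tip itself.
#' @param new_branch_length Pendant branch length for the new leaf.
#' @return A `phylo` object with one more leaf.
#' @export
graft_leaf <- function(tree, sister_leaf, new_leaf,
                       stem_fraction = 0.5, new_branch_length = 0.05) {
  if (!sister_leaf %in% tree$tip.label)
    stop("unknown sister leaf: ", sister_leaf)
  if (new_leaf %in% tree$tip.label)
    stop("leaf name already present: ", new_leaf)
  if (stem_fraction < 0 || stem_fraction > 1)
    stop("'stem_fraction' must be in [0, 1]")
  if (new_branch_length < 0) stop("'new_branch_length' must be >= 0")
  tip <- match(sister_leaf, tree$tip.label)
  t_sister <- tree$edge.length[which(tree$edge[, 2] == tip)]
  out <- phytools::bind.tip(tree, new_leaf,
                            edge.length = new_branch_length,
                            where = tip, position = stem_fraction * t_sister)
  # bind.tip drops edge.length when position is 0 (attachment at the tip
  # itself); restore the requested pendant length
  i <- which(out$edge[, 2] == match(new_leaf, out$tip.label))
  out$edge.length[i] <- new_branch_length
  out
}

#' Remove a leaf, restoring the unsplit branch
#' @param tree A `phylo` object.
#' @param leaf Leaf name to remove.
#' @return A `phylo` object.
#' @export
prune_leaf <- function(tree, leaf) {
  if (!leaf %in% tree$tip.label) stop("unknown leaf: ", leaf)
  ape::drop.tip(tree, leaf)
}
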