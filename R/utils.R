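# Internal helpers shared across modules.

# parent vector indexed by ape node id (0 for the root)
.parents <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  p <- integer(n)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

.root_of <- function(tree) {
  length(tree$tip.label) + 1L
}

# children as a list indexed by node id
.children <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(n)))
}

# Build an ape "phylo" from a parent-pointer forest over arbitrary ids.
# `parent` is an integer vector indexed by id (0 marks the root); ids with no
# children are tips and must have a label.  Returns the tree plus the id ->
# ape-id map so callers can track nodes across rebuilds.
.phylo_from_parents <- function(parent, labels) {
  n_all <- length(parent)
  has_child <- rep(FALSE, n_all)
  has_child[parent[parent > 0L]] <- TRUE
  tip_ids <- which(!has_child)
  int_ids <- which(has_child)
  root_id <- which(parent == 0L)
  if (length(root_id) != 1L)
    stop("exactly one root required, found ", length(root_id))
  ntip <- length(tip_ids)
  map <- integer(n_all)
  map[tip_ids] <- seq_len(ntip)
  map[root_id] <- ntip + 1L
  others <- setdiff(int_ids, root_id)
  map[others] <- ntip + 1L + seq_along(others)
  nonroot <- which(parent > 0L)
  edge <- cbind(map[parent[nonroot]], map[nonroot])
  tree <- structure(list(
    edge = edge,
    tip.label = labels[tip_ids],
    Nnode = length(int_ids)
  ), class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  list(tree = tree, map = map)
}

# node ages from an ultrametric set of edge lengths; tolerance is relative
# to tree height
.ages_from_lengths <- function(tree, tol = 1e-6, context = "tree") {
  if (is.null(tree$edge.length))
    stop("branch lengths required to compute node ages")
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth)
  ntip <- length(tree$tip.label)
  tip_dev <- height - depth[seq_len(ntip)]
  worst <- which.max(abs(tip_dev))
  if (height > 0 && abs(tip_dev[worst]) > tol * height)
    stop(sprintf(
      "%s is not ultrametric within tolerance: tip '%s' deviates by %.3g (tree height %.3g)",
      context, tree$tip.label[worst], tip_dev[worst], height))
  ages <- height - depth
  ages[seq_len(ntip)] <- 0
  ages
}

.is_binary <- function(tree) {
  deg <- tabulate(tree$edge[, 1], nbins = length(tree$tip.label) + tree$Nnode)
  all(deg[deg > 0L] == 2L)
}

.set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# tip labels descending from each node, as a list indexed by node id
.clade_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")$edge
  sets <- vector("list", n)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po))) {
    sets[[po[e, 1]]] <- c(sets[[po[e, 1]]], sets[[po[e, 2]]])
  }
  sets
}
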