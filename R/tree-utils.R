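# Light helpers over ape's "phylo" representation.

tree_root <- function(tree) {
  n <- length(tree$tip.label)
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
}

# list indexed by node id -> integer vector of child node ids
children_list <- function(tree) {
  n_nodes <- max(tree$edge)
  ch <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

# branch length of the edge above each node (NA for root), indexed by node id
branch_above <- function(tree) {
  n_nodes <- max(tree$edge)
  bl <- rep(NA_real_, n_nodes)
  bl[tree$edge[, 2]] <- tree$edge.length
  bl
}

# internal+leaf node ids in postorder (children before parents)
postorder_nodes <- function(tree) {
  reord <- ape::reorder.phylo(tree, "postorder")
  c(reord$edge[, 2][!duplicated(reord$edge[, 2])], tree_root(tree))
}

# parent of each node (NA for root)
parent_vec <- function(tree) {
  p <- rep(NA_integer_, max(tree$edge))
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

#' Read a Newick tree with validation
#'
#' Multifurcations are preserved; duplicate leaf labels are rejected.
#'
#' @param path file containing one Newick string.
#' @return an \code{ape::phylo} tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path))
    abort_category("missing_file_error", sprintf("tree file not found: %s", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort_category("parse_error", conditionMessage(e)))
  if (is.null(tree)) abort_category("parse_error", sprintf("unparseable Newick in %s", path))
  if (anyDuplicated(tree$tip.label))
    abort_category("validation_error",
                   sprintf("duplicate leaf names: %s",
                           paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                                 collapse = ", ")))
  tree
}

#' @rdname read_newick
#' @param tree a phylo object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

# Neighbor-joining plumbing tree from JC-corrected distances on an alignment.
nj_tree_from_alignment <- function(aln) {
  d <- jc_distance_matrix(aln)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Pairwise Jukes-Cantor-corrected nucleotide distances over an alignment.
jc_distance_matrix <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  valid <- m %in% NUC
  dim(valid) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- valid[i, ] & valid[j, ]
    L <- sum(use)
    p <- if (L == 0L) 0 else sum(m[i, use] != m[j, use]) / L
    dij <- if (p >= 0.75) 10 else -0.75 * log(1 - 4 * p / 3)
    d[i, j] <- d[j, i] <- dij
  }
  d
}
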