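# Parsimony-based homoplasy ratio h/m: homoplasic vs non-homoplasic alleles
# on the strain tree, a within-species recombination proxy.

#' Minimum parsimony changes for a single site
#'
#' Generalized Fitch small parsimony via dynamic programming over state sets;
#' works on multifurcating trees.  Leaves with missing states (anything
#' outside A/C/G/T) are pruned for the site.
#'
#' @param tree phylo.
#' @param site_pattern named character vector leaf -> state.
#' @return minimum number of state changes, or NA when fewer than two
#'   informative leaves remain.
#' @export
fitch_min_changes <- function(tree, site_pattern) {
  states <- toupper(site_pattern[tree$tip.label])
  names(states) <- tree$tip.label
  informative <- states %in% NUC
  if (sum(informative) < 2L) return(NA_integer_)
  n_tip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  INF <- .Machine$integer.max %/% 4L
  cost <- matrix(INF, n_nodes, 4L)
  for (i in seq_len(n_tip)) {
    if (informative[i]) cost[i, match(states[i], NUC)] <- 0L
    else cost[i, ] <- 0L  # missing leaf constrains nothing
  }
  ch <- children_list(tree)
  for (v in postorder_nodes(tree)) {
    if (v <= n_tip) next
    acc <- integer(4L)
    for (w in ch[[v]]) {
      m <- min(cost[w, ])
      acc <- acc + pmin(cost[w, ], m + 1L)
    }
    cost[v, ] <- acc
  }
  min(cost[tree_root(tree), ])
}

# Binary state-vs-rest Fitch: minimum number of changes of the indicator
# character "carries `state`" on the tree.  Under clonal evolution with
# unique mutations an allele needs exactly one change; needing two or more
# (a second origin or a reversal) marks it homoplasic.
state_min_changes <- function(tree, states, state) {
  n_tip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  INF <- .Machine$integer.max %/% 4L
  # columns: 1 = node carries `state`, 2 = node carries any other state
  cost <- matrix(0L, n_nodes, 2L)
  for (i in seq_len(n_tip)) {
    s <- states[tree$tip.label[i]]
    if (!s %in% NUC) next        # missing leaf constrains nothing
    if (s == state) cost[i, 2L] <- INF else cost[i, 1L] <- INF
  }
  ch <- children_list(tree)
  for (v in postorder_nodes(tree)) {
    if (v <= n_tip) next
    acc <- c(0L, 0L)
    for (w in ch[[v]]) {
      m <- min(cost[w, ])
      acc <- acc + pmin(cost[w, ], m + 1L)
    }
    cost[v, ] <- acc
  }
  min(cost[tree_root(tree), ])
}

#' Classify alleles as homoplasic or not
#'
#' For each polymorphic column, every non-majority state is one counted
#' allele; the allele is homoplasic when the binary character "carries this
#' state" requires more than one change on the tree (a repeated origin or a
#' reversal, i.e. recurrent mutation or recombination).  Gap/ambiguous
#' leaves are treated as missing per site.  h/m over all columns is the
#' recombination proxy.
#'
#' @param tree strain tree (leaves must be a subset of alignment rows).
#' @param alignment a \code{codon_alignment} or named character vector of
#'   equal-length nucleotide sequences.
#' @return list with h, m, ratio (NA when m == 0), n_polymorphic_sites.
#' @export
classify_homoplasy <- function(tree, alignment) {
  if (!all(tree$tip.label %in% names(alignment)))
    abort_category("validation_error", "tree leaves missing from alignment")
  m <- aln_matrix(alignment)[tree$tip.label, , drop = FALSE]
  h_count <- m_count <- 0L
  n_poly <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    obs <- col[col %in% NUC]
    if (length(obs) < 2L) next
    tab <- sort(table(obs), decreasing = TRUE)
    if (length(tab) < 2L) next
    n_poly <- n_poly + 1L
    # majority state is the ancestral proxy; ties broken lexicographically
    cand <- names(tab)[tab == max(tab)]
    major <- sort(cand)[1]
    states <- col
    names(states) <- rownames(m)
    for (allele in setdiff(names(tab), major)) {
      changes <- state_min_changes(tree, states, allele)
      if (changes > 1L) h_count <- h_count + 1L else m_count <- m_count + 1L
    }
  }
  list(h = h_count, m = m_count,
       ratio = if (m_count > 0) h_count / m_count else NA_real_,
       n_polymorphic_sites = n_poly)
}
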