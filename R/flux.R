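# Per-branch gene gain/loss inference under a two-state continuous-time
# Markov model (absent <-> present), posterior event calls, turnover T = G/L,
# and per-branch dS/dN from marginal ancestral sequence reconstruction.

# 2x2 transition matrix for the gain/loss chain; rows/cols: (absent, present)
gl_pmat <- function(gain, loss, t) {
  r <- gain + loss
  if (r == 0 || t == 0) return(diag(2))
  e <- exp(-r * t)
  matrix(c((loss + gain * e) / r, gain * (1 - e) / r,
           loss * (1 - e) / r, (gain + loss * e) / r),
         2, 2, byrow = TRUE)
}

# Aggregate presence matrix into unique leaf patterns with counts.
pattern_pack <- function(presence) {
  key <- apply(presence, 2, paste, collapse = "")
  u <- !duplicated(key)
  pat <- t(presence[, u, drop = FALSE])          # npat x nstrains
  counts <- as.vector(table(key)[key[u]])
  list(patterns = pat, counts = counts, map = match(key, key[u]))
}

# Conditional (upward) likelihoods per node for all patterns.
# Returns list of npat x 2 matrices indexed by node id, plus messages
# M[[child]] = PL_child %*% t(P_child) (likelihood of child subtree given
# parent state).
gl_prune <- function(tree, patterns, gain, loss) {
  n_tip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  npat <- nrow(patterns)
  bl <- branch_above(tree)
  ch <- children_list(tree)
  PL <- vector("list", n_nodes)
  M <- vector("list", n_nodes)
  for (i in seq_len(n_tip)) {
    x <- patterns[, i]
    PL[[i]] <- cbind(absent = as.numeric(x == 0), present = as.numeric(x == 1))
  }
  for (v in postorder_nodes(tree)) {
    if (v > n_tip) {
      acc <- matrix(1, npat, 2)
      for (w in ch[[v]]) acc <- acc * M[[w]]
      PL[[v]] <- acc
    }
    if (!is.na(bl[v]))
      M[[v]] <- PL[[v]] %*% t(gl_pmat(gain, loss, bl[v]))
  }
  list(PL = PL, M = M)
}

# Log-likelihood of the presence matrix under (gain, loss, root prior),
# conditioned on families being observable (present in >= 1 strain).
gl_loglik <- function(tree, pack, gain, loss,
                      root_prior = gain / (gain + loss)) {
  root <- tree_root(tree)
  prior <- c(1 - root_prior, root_prior)
  pr <- gl_prune(tree, pack$patterns, gain, loss)
  lik <- as.vector(pr$PL[[root]] %*% prior)
  zero <- gl_prune(tree, matrix(0, 1, length(tree$tip.label)), gain, loss)
  lik0 <- sum(zero$PL[[root]] * rep(prior, each = 1))
  if (any(lik <= 0)) return(-Inf)
  sum(pack$counts * log(lik)) - sum(pack$counts) * log1p(-min(lik0, 1 - 1e-12))
}

#' Fit gain and loss rates by maximum likelihood
#'
#' Two-state continuous-time Markov chain over family presence (gain:
#' absent -> present; loss: present -> absent), pruned over all families with
#' correction for unobservable all-absent families, maximized over
#' \code{n_restarts} random initializations.  The root presence prior is a
#' free third parameter: tying it to the stationary distribution forces the
#' gain rate upward whenever most families are ancestral, which badly biases
#' loss-dominated data.
#'
#' @param tree phylo whose tips match the matrix strains.
#' @param matrix a \code{gene_family_matrix}.
#' @param n_restarts random restarts (default 100).
#' @param seed integer seed.
#' @return list of class \code{gain_loss_model}: gain_rate, loss_rate,
#'   root_prior, log_likelihood, boundary_flag.
#' @export
fit_gain_loss_rates <- function(tree, matrix, n_restarts = 100, seed = 1) {
  pres <- matrix$presence[tree$tip.label, , drop = FALSE]
  if (ncol(pres) < 1) abort_category("argument_error", "need >= 1 family")
  pack <- pattern_pack(pres)
  negll <- function(par)
    -gl_loglik(tree, pack, exp(par[1]), exp(par[2]), stats::plogis(par[3]))
  # moment-flavored starting point: event density per unit tree length
  tl <- sum(tree$edge.length)
  base <- log(max(ncol(pres) * 0.1 / max(tl, 1e-6), 1e-3))
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- if (r == 1) c(base, 0, 0) else stats::rnorm(3, c(base, 0, 0), 2)
      fit <- tryCatch(
        stats::optim(init, negll, method = "L-BFGS-B",
                     lower = c(log(1e-9), log(1e-9), -30),
                     upper = c(log(1e8), log(1e8), 30)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value - 1e-9 ||
          (abs(fit$value - best$value) <= 1e-9 && fit$par[1] < best$par[1]))
        best <- fit
    }
    if (is.null(best)) abort_category("optimization_error", "no restart converged")
    gain <- exp(best$par[1]); loss <- exp(best$par[2])
    structure(list(gain_rate = gain, loss_rate = loss,
                   root_prior = stats::plogis(best$par[3]),
                   log_likelihood = -best$value,
                   boundary_flag = loss <= 1.5e-9 || gain <= 1.5e-9),
              class = "gain_loss_model")
  })
}

#' Marginal ancestral presence posteriors
#'
#' Up-down message passing under a fitted gain/loss model; returns the
#' posterior probability that each family is present at each node.  Leaf
#' posteriors equal the observations.
#'
#' @param tree phylo.
#' @param matrix a \code{gene_family_matrix}.
#' @param model a \code{gain_loss_model}.
#' @return numeric matrix nodes x families of presence probabilities; row
#'   names are tip labels and \code{n<id>} for internal nodes.
#' @export
ancestral_posteriors <- function(tree, matrix, model) {
  pres <- matrix$presence[tree$tip.label, , drop = FALSE]
  pack <- pattern_pack(pres)
  gain <- model$gain_rate; loss <- model$loss_rate
  prior <- c(1 - model$root_prior, model$root_prior)
  pr <- gl_prune(tree, pack$patterns, gain, loss)
  n_tip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  npat <- nrow(pack$patterns)
  bl <- branch_above(tree)
  ch <- children_list(tree)
  root <- tree_root(tree)
  D <- vector("list", n_nodes)
  D[[root]] <- matrix(prior, npat, 2, byrow = TRUE)
  for (v in rev(postorder_nodes(tree))) {
    if (v <= n_tip) next
    for (w in ch[[v]]) {
      sib <- matrix(1, npat, 2)
      for (u in setdiff(ch[[v]], w)) sib <- sib * pr$M[[u]]
      D[[w]] <- (D[[v]] * sib) %*% gl_pmat(gain, loss, bl[w])
    }
  }
  post_pat <- matrix(NA_real_, n_nodes, npat)
  for (v in seq_len(n_nodes)) {
    joint <- pr$PL[[v]] * D[[v]]
    post_pat[v, ] <- joint[, 2] / rowSums(joint)
  }
  post <- post_pat[, pack$map, drop = FALSE]
  rownames(post) <- c(tree$tip.label,
                      sprintf("n%d", (n_tip + 1):n_nodes))
  colnames(post) <- colnames(pres)
  post
}

#' Call per-branch gain and loss events from posteriors
#'
#' At threshold \eqn{\tau}, a gain is called on a branch when the parent is
#' confidently absent (posterior presence <= \eqn{\tau}) and the child
#' confidently present (>= 1 - \eqn{\tau}); losses symmetrically.  Branch
#' rates are event counts divided by branch length; turnover T = G/L.
#'
#' @param posteriors output of \code{\link{ancestral_posteriors}}.
#' @param tree phylo.
#' @param threshold posterior certainty threshold in (0, 0.5] (default 0.2).
#' @return list with \code{records} (data.frame branch_id, branch_length,
#'   n_gains, n_losses, gains, losses, turnover) and \code{calls}
#'   (data.frame family_id, branch_id, event).
#' @export
branch_events <- function(posteriors, tree, threshold = 0.2) {
  if (threshold <= 0 || threshold > 0.5)
    abort_category("argument_error", "threshold must be in (0, 0.5]")
  n_tip <- length(tree$tip.label)
  node_names <- rownames(posteriors)
  recs <- list(); calls <- list()
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; c_ <- tree$edge[i, 2]
    bl <- tree$edge.length[i]
    pp <- posteriors[p, ]; pc <- posteriors[c_, ]
    gain <- pp <= threshold & pc >= 1 - threshold
    loss <- pp >= 1 - threshold & pc <= threshold
    bid <- node_names[c_]
    ng <- sum(gain); nl <- sum(loss)
    g_rate <- if (bl > 0) ng / bl else NA_real_
    l_rate <- if (bl > 0) nl / bl else NA_real_
    recs[[i]] <- data.frame(
      branch_id = bid, branch_length = bl, n_gains = ng, n_losses = nl,
      gains = g_rate, losses = l_rate,
      turnover = if (!is.na(l_rate) && nl > 0) ng / nl else NA_real_,
      stringsAsFactors = FALSE)
    if (ng > 0)
      calls[[length(calls) + 1L]] <- data.frame(
        family_id = names(which(gain)), branch_id = bid, event = "gain",
        stringsAsFactors = FALSE)
    if (nl > 0)
      calls[[length(calls) + 1L]] <- data.frame(
        family_id = names(which(loss)), branch_id = bid, event = "loss",
        stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, recs),
       calls = if (length(calls)) do.call(rbind, calls)
               else data.frame(family_id = character(0),
                               branch_id = character(0),
                               event = character(0)))
}

# --- per-branch dS/dN ------------------------------------------------------

jc_pmat <- function(t) {
  same <- 0.25 + 0.75 * exp(-4 * t / 3)
  diff <- (1 - same) / 3
  m <- matrix(diff, 4, 4); diag(m) <- same
  m
}

# Marginal MAP ancestral nucleotide reconstruction under JC for one block of
# alignment columns.  Returns a character matrix nodes x sites (tips keep
# their observed characters).
reconstruct_ancestral_block <- function(tree, block) {
  n_tip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  nsite <- ncol(block)
  bl <- branch_above(tree)
  ch <- children_list(tree)
  root <- tree_root(tree)
  PL <- vector("list", n_nodes); M <- vector("list", n_nodes)
  for (i in seq_len(n_tip)) {
    x <- match(block[tree$tip.label[i], ], NUC)
    L <- matrix(0, nsite, 4)
    L[cbind(seq_len(nsite), x)] <- 1
    L[is.na(x), ] <- 1  # gaps/ambiguity uninformative
    PL[[i]] <- L
  }
  for (v in postorder_nodes(tree)) {
    if (v > n_tip) {
      acc <- matrix(1, nsite, 4)
      for (w in ch[[v]]) acc <- acc * M[[w]]
      # renormalize rows to dodge underflow on long trees
      acc <- acc / pmax(rowSums(acc), .Machine$double.xmin)
      PL[[v]] <- acc
    }
    if (!is.na(bl[v])) M[[v]] <- PL[[v]] %*% t(jc_pmat(bl[v]))
  }
  D <- vector("list", n_nodes)
  D[[root]] <- matrix(0.25, nsite, 4)
  for (v in rev(postorder_nodes(tree))) {
    if (v <= n_tip) next
    for (w in ch[[v]]) {
      sib <- matrix(1, nsite, 4)
      for (u in setdiff(ch[[v]], w)) sib <- sib * M[[u]]
      D[[w]] <- (D[[v]] * sib) %*% jc_pmat(bl[w])
    }
  }
  out <- matrix("", n_nodes, nsite)
  for (i in seq_len(n_tip)) out[i, ] <- block[tree$tip.label[i], ]
  for (v in (n_tip + 1L):n_nodes) {
    joint <- PL[[v]] * D[[v]]
    out[v, ] <- NUC[max.col(joint, ties.method = "first")]
  }
  out
}

#' Per-branch dS/dN from ancestral reconstruction
#'
#' The core concatenate is subdivided into fragments (default 150,000 bp,
#' rounded down to whole codons); within each fragment, ancestral sequences
#' are reconstructed by marginal posterior under a Jukes-Cantor model and
#' NG86 synonymous/nonsynonymous changes are counted on every branch.  The
#' branch value is the unweighted mean of fragment-level dS/dN, undefined
#' when no fragment yields nonzero nonsynonymous divergence.
#'
#' @param tree phylo with branch lengths.
#' @param core_alignment a \code{codon_alignment} over the tree's tips.
#' @param fragment_length fragment size in nucleotides (default 150000).
#' @return data.frame branch_id, dsdn, n_fragments_used.
#' @export
branch_dsdn <- function(tree, core_alignment, fragment_length = 150000) {
  L <- aln_length(core_alignment)
  frag_len <- max(3L, (as.integer(fragment_length) %/% 3L) * 3L)
  starts <- seq(1L, L, by = frag_len)
  n_tip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  node_names <- c(tree$tip.label, sprintf("n%d", (n_tip + 1):n_nodes))
  aln_m <- aln_matrix(core_alignment)
  per_branch <- vector("list", nrow(tree$edge))
  frag_vals <- matrix(NA_real_, nrow(tree$edge), length(starts))
  for (f in seq_along(starts)) {
    cols <- starts[f]:min(starts[f] + frag_len - 1L, L)
    if (length(cols) < 3L) next
    anc <- reconstruct_ancestral_block(tree, aln_m[, cols, drop = FALSE])
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1]; c_ <- tree$edge[i, 2]
      pd <- pairwise_dnds(paste(anc[p, ], collapse = ""),
                          paste(anc[c_, ], collapse = ""))
      if (!is.na(pd$dn) && !is.na(pd$ds) && pd$dn > 0 && pd$ds > 0)
        frag_vals[i, f] <- pd$ds / pd$dn
    }
  }
  data.frame(
    branch_id = node_names[tree$edge[, 2]],
    dsdn = apply(frag_vals, 1, function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)),
    n_fragments_used = rowSums(!is.na(frag_vals)),
    stringsAsFactors = FALSE)
}

#' Spearman correlation of turnover with branch dS/dN
#'
#' @param records data.frame with columns turnover and branch_dsdn (merge of
#'   \code{branch_events} records and \code{branch_dsdn} output).
#' @return list with rho, p_value, n_branches, category (positive_significant
#'   / nonsignificant / negative_significant), skipped.
#' @export
turnover_correlation <- function(records) {
  ok <- !is.na(records$turnover) & !is.na(records$branch_dsdn)
  if (sum(ok) < 4)
    return(list(rho = NA_real_, p_value = NA_real_, n_branches = sum(ok),
                category = NA_character_, skipped = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(records$turnover[ok], records$branch_dsdn[ok],
                    method = "spearman"))
  rho <- unname(ct$estimate); p <- ct$p.value
  cat_ <- if (!is.na(p) && p < 0.05)
    if (rho > 0) "positive_significant" else "negative_significant"
  else "nonsignificant"
  list(rho = rho, p_value = p, n_branches = sum(ok), category = cat_,
       skipped = FALSE)
}
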