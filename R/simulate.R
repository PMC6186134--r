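# Synthetic-data generator: every downstream stage of the pipeline is
# testable against known ground truth produced here.

#' Simulate a Kingman coalescent strain genealogy
#'
#' Branch lengths are expressed in expected substitutions per neutral site:
#' coalescent time (units of 2Ne generations) is multiplied by
#' \code{theta_per_site / 2}, so the expected distance between two random
#' strains equals \code{theta_per_site}.
#'
#' @param n_strains number of sampled strains (>= 2).
#' @param theta_per_site population-scaled mutation rate per site (> 0).
#' @param seed integer seed.
#' @param labels optional tip labels (default \code{s01, s02, ...}).
#' @return a rooted binary \code{phylo} tree.
#' @export
simulate_strain_genealogy <- function(n_strains, theta_per_site, seed,
                                      labels = NULL) {
  if (!is.numeric(n_strains) || n_strains < 2)
    abort_category("argument_error", "n_strains must be >= 2")
  if (theta_per_site <= 0)
    abort_category("argument_error", "theta_per_site must be > 0")
  n <- as.integer(n_strains)
  if (is.null(labels)) labels <- sprintf("s%02d", seq_len(n))
  with_seed(seed, {
    active <- seq_len(n)
    height <- numeric(2L * n - 1L)
    edge <- matrix(0L, 2L * n - 2L, 2L)
    elen <- numeric(2L * n - 2L)
    h <- 0
    nxt <- n + 1L
    e <- 1L
    while (length(active) > 1L) {
      k <- length(active)
      h <- h + stats::rexp(1L, rate = k * (k - 1) / 2)
      pick <- sample(k, 2L)
      a <- active[pick[1]]; b <- active[pick[2]]
      height[nxt] <- h
      edge[e, ] <- c(nxt, a); elen[e] <- h - height[a]; e <- e + 1L
      edge[e, ] <- c(nxt, b); elen[e] <- h - height[b]; e <- e + 1L
      active <- c(setdiff(active, c(a, b)), nxt)
      nxt <- nxt + 1L
    }
    # relabel internal ids so the root is n+1 (ape convention)
    relab <- c(seq_len(n), rev(seq.int(n + 1L, 2L * n - 1L)))
    edge[] <- relab[edge]
    tree <- structure(list(edge = edge,
                           edge.length = elen * theta_per_site / 2,
                           tip.label = labels, Nnode = n - 1L),
                      class = "phylo")
    ape::reorder.phylo(tree, "cladewise")
  })
}

#' Simulate neutral four-state sites on a genealogy
#'
#' Jukes-Cantor evolution with substitution rate 1 per unit branch length,
#' i.e. branch lengths are expected substitutions per site.  Used to emulate
#' four-fold degenerate site matrices for Watterson's estimator.
#'
#' @param tree phylo with branch lengths in substitutions/site.
#' @param n_sites number of independent sites.
#' @param seed integer seed.
#' @return character matrix strains x sites over A/C/G/T.
#' @export
simulate_neutral_sites <- function(tree, n_sites, seed) {
  with_seed(seed, {
    nodes <- rev(postorder_nodes(tree))  # preorder: root first
    bl <- branch_above(tree)
    n_tip <- length(tree$tip.label)
    states <- matrix(0L, max(tree$edge), n_sites)
    root <- tree_root(tree)
    states[root, ] <- sample.int(4L, n_sites, replace = TRUE)
    par <- parent_vec(tree)
    for (v in nodes) {
      if (v == root) next
      t <- bl[v]
      p_diff <- 0.75 * (1 - exp(-4 * t / 3))
      x <- states[par[v], ]
      flip <- stats::runif(n_sites) < p_diff
      if (any(flip)) {
        shift <- sample.int(3L, sum(flip), replace = TRUE)
        x[flip] <- ((x[flip] - 1L + shift) %% 4L) + 1L
      }
      states[v, ] <- x
    }
    out <- matrix(NUC[states[seq_len(n_tip), ]], n_tip, n_sites)
    rownames(out) <- tree$tip.label
    out
  })
}

# Symmetric MG94-like codon rate matrix over the 61 sense codons.  Single
# nucleotide changes only; transitions scaled by kappa, nonsynonymous changes
# by omega, changes to stops forbidden.  The base transversion rate is
# 1/(kappa+2) so that a four-fold degenerate third position accumulates one
# expected synonymous substitution per unit branch length.
codon_rate_matrix <- function(omega, kappa) {
  env <- ng86_tables()
  sense <- env$sense
  ns <- length(sense)
  beta <- 1 / (kappa + 2)
  Q <- matrix(0, ns, ns, dimnames = list(sense, sense))
  split3 <- strsplit(sense, "")
  for (i in seq_len(ns)) {
    ci <- split3[[i]]
    for (pos in 1:3) {
      for (b in setdiff(NUC, ci[pos])) {
        cj <- ci; cj[pos] <- b
        cjs <- paste(cj, collapse = "")
        j <- match(cjs, sense)
        if (is.na(j)) next  # stop codon
        r <- beta
        if (is_transition(ci[pos], b)) r <- r * kappa
        if (env$aa[env$index[sense[i]]] != env$aa[env$index[cjs]]) r <- r * omega
        Q[i, j] <- r
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Transition-probability factory: returns function(t) -> 61x61 row-stochastic
# matrix, via one eigendecomposition (Q is symmetric).
codon_pmat_factory <- function(omega, kappa) {
  Q <- codon_rate_matrix(omega, kappa)
  eg <- eigen(Q, symmetric = TRUE)
  V <- eg$vectors
  lam <- eg$values
  function(t) {
    P <- V %*% (t(V) * exp(lam * t))
    P[P < 0] <- 0
    P / rowSums(P)
  }
}

#' Evolve an in-frame codon alignment along a tree
#'
#' A continuous-time codon substitution process with single-nucleotide steps:
#' transitions are scaled by \code{kappa}, nonsynonymous changes by
#' \code{omega}, and paths to stop codons have rate zero.  The root sequence
#' is drawn uniformly from sense codons.  Branch lengths are interpreted as
#' expected synonymous substitutions per four-fold degenerate site.
#'
#' @param tree phylo with branch lengths.
#' @param omega nonsynonymous/synonymous rate ratio (> 0).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param n_codons number of codon sites.
#' @param seed integer seed.
#' @return a \code{codon_alignment} over the tree's tips.
#' @export
evolve_codon_alignment <- function(tree, omega, kappa, n_codons, seed) {
  if (omega <= 0) abort_category("argument_error", "omega must be > 0")
  if (kappa <= 0) abort_category("argument_error", "kappa must be > 0")
  if (n_codons < 1) abort_category("argument_error", "n_codons must be >= 1")
  if (is.null(tree$edge.length))
    abort_category("argument_error", "tree must have branch lengths")
  env <- ng86_tables()
  sense <- env$sense
  pmat <- codon_pmat_factory(omega, kappa)
  with_seed(seed, {
    nodes <- rev(postorder_nodes(tree))
    bl <- branch_above(tree)
    par <- parent_vec(tree)
    root <- tree_root(tree)
    n_tip <- length(tree$tip.label)
    states <- matrix(0L, max(tree$edge), n_codons)
    states[root, ] <- sample.int(length(sense), n_codons, replace = TRUE)
    for (v in nodes) {
      if (v == root) next
      P <- pmat(bl[v])
      x <- states[par[v], ]
      y <- integer(n_codons)
      for (s in unique(x)) {
        idx <- which(x == s)
        y[idx] <- sample.int(length(sense), length(idx), replace = TRUE,
                             prob = P[s, ])
      }
      states[v, ] <- y
    }
    seqs <- apply(states[seq_len(n_tip), , drop = FALSE], 1,
                  function(row) paste(sense[row], collapse = ""))
    codon_alignment(stats::setNames(seqs, tree$tip.label))
  })
}

#' Simulate gene-content evolution on a tree
#'
#' Infinitely-many-genes convention: per-branch Poisson gains each create a
#' novel family present in that lineage; every family present at the top of a
#' branch is lost with probability \code{1 - exp(-loss_rate * bl)}.  Families
#' gained on a branch are observed intact at the branch's child.
#'
#' @param tree phylo with branch lengths.
#' @param root_gene_count families present at the root.
#' @param gain_rate gains per unit branch length (>= 0).
#' @param loss_rate per-family loss rate per unit branch length (> 0 unless
#'   \code{gain_rate} is 0).
#' @param seed integer seed.
#' @return list with \code{matrix} (a \code{gene_family_matrix} restricted to
#'   families observed in >= 1 strain), \code{events} (data.frame family_id,
#'   branch_id, event), \code{root_families}, \code{all_families}.
#' @export
simulate_gene_content <- function(tree, root_gene_count, gain_rate, loss_rate,
                                  seed) {
  if (gain_rate < 0 || loss_rate < 0)
    abort_category("argument_error", "rates must be >= 0")
  if (loss_rate == 0 && gain_rate > 0)
    abort_category("argument_error",
                   "loss_rate must be > 0 when gain_rate > 0 (unbounded growth)")
  node_name <- function(v, tree) {
    if (v <= length(tree$tip.label)) tree$tip.label[v] else sprintf("n%d", v)
  }
  with_seed(seed, {
    root <- tree_root(tree)
    ch <- children_list(tree)
    bl <- branch_above(tree)
    n_tip <- length(tree$tip.label)
    root_families <- if (root_gene_count > 0)
      sprintf("F%05d", seq_len(root_gene_count)) else character(0)
    gained <- 0L
    ev_fam <- ev_branch <- ev_type <- character(0)
    leaf_content <- vector("list", n_tip)
    recurse <- function(v, present) {
      for (w in ch[[v]]) {
        t <- bl[w]
        keep <- present
        if (loss_rate > 0 && length(keep) > 0 && t > 0) {
          lost <- stats::runif(length(keep)) < (1 - exp(-loss_rate * t))
          if (any(lost)) {
            ev_fam <<- c(ev_fam, keep[lost])
            ev_branch <<- c(ev_branch, rep(node_name(w, tree), sum(lost)))
            ev_type <<- c(ev_type, rep("loss", sum(lost)))
            keep <- keep[!lost]
          }
        }
        n_gain <- if (gain_rate > 0 && t > 0) stats::rpois(1L, gain_rate * t) else 0L
        if (n_gain > 0) {
          new_ids <- sprintf("G%06d", gained + seq_len(n_gain))
          gained <<- gained + n_gain
          ev_fam <<- c(ev_fam, new_ids)
          ev_branch <<- c(ev_branch, rep(node_name(w, tree), n_gain))
          ev_type <<- c(ev_type, rep("gain", n_gain))
          keep <- c(keep, new_ids)
        }
        if (w <= n_tip) leaf_content[[w]] <<- keep else recurse(w, keep)
      }
    }
    recurse(root, root_families)
    all_fams <- c(root_families, sprintf("G%06d", seq_len(gained)))
    observed <- sort(unique(unlist(leaf_content)))
    observed <- all_fams[all_fams %in% observed]
    pres <- matrix(0L, n_tip, length(observed),
                   dimnames = list(tree$tip.label, observed))
    for (i in seq_len(n_tip))
      pres[i, match(intersect(leaf_content[[i]], observed), observed)] <- 1L
    events <- data.frame(family_id = ev_fam, branch_id = ev_branch,
                         event = ev_type, stringsAsFactors = FALSE)
    list(matrix = gene_family_matrix(pres), events = events,
         root_families = root_families, all_families = all_fams)
  })
}

#' Inject recombination tracts into an alignment
#'
#' Each event copies a contiguous tract from a random donor strain onto a
#' random recipient strain, emulating homologous recombination within the
#' species.  Transferred polymorphic sites (donor differs from recipient) are
#' logged.
#'
#' @param alignment a \code{codon_alignment}.
#' @param tree strain tree (used only to check leaf concordance; transfer is
#'   uniform over strain pairs).
#' @param n_events number of recombination events (>= 0).
#' @param tract_length tract length in nucleotides (>= 1).
#' @param seed integer seed.
#' @return list with \code{alignment} and \code{log} (data.frame site_index,
#'   donor_strain, recipient_strain).
#' @export
inject_recombination <- function(alignment, tree = NULL, n_events,
                                 tract_length, seed) {
  L <- aln_length(alignment)
  if (tract_length < 1 || tract_length > L)
    abort_category("argument_error", "tract_length must be in [1, alignment length]")
  if (n_events < 0) abort_category("argument_error", "n_events must be >= 0")
  strains <- names(alignment)
  log <- data.frame(site_index = integer(0), donor_strain = character(0),
                    recipient_strain = character(0), stringsAsFactors = FALSE)
  if (n_events == 0) return(list(alignment = alignment, log = log))
  seqs <- unclass(alignment)
  with_seed(seed, {
    for (e in seq_len(n_events)) {
      pair <- sample(strains, 2L)
      donor <- pair[1]; recip <- pair[2]
      start <- sample.int(L - tract_length + 1L, 1L)
      end <- start + tract_length - 1L
      d <- substr(seqs[[donor]], start, end)
      r <- substr(seqs[[recip]], start, end)
      if (d != r) {
        diff_at <- which(strsplit(d, "")[[1]] != strsplit(r, "")[[1]])
        log <- rbind(log, data.frame(site_index = start + diff_at - 1L,
                                     donor_strain = donor,
                                     recipient_strain = recip,
                                     stringsAsFactors = FALSE))
        substr(seqs[[recip]], start, end) <- d
      }
    }
    list(alignment = codon_alignment(seqs), log = log)
  })
}

#' Simulate a universal-gene hit table with paralog contamination
#'
#' For each (gene, strain) pair a rank-1 hit is drawn from an "ortholog"
#' distribution of log10 e-values; with probability \code{paralog_fraction}
#' the true ortholog is replaced by a paralog hit from a weaker distribution.
#' Additional rank >= 2 confirmed-paralog hits are emitted.  All e-values are
#' at most 1e-5 by construction.
#'
#' @param n_strains number of strains.
#' @param n_universal number of universal genes (default 44).
#' @param paralog_fraction probability the rank-1 hit is a paralog, in [0,1).
#' @param seed integer seed.
#' @param ortho_mean,para_mean,log_sd means/sd of the two log10 e-value
#'   distributions (defaults separated by 60 log10 units).
#' @param extra_paralog_prob probability a (gene, strain) also has a rank-2
#'   paralog hit.
#' @param strain_ids optional strain labels.
#' @return list with \code{hits} (a \code{hit_table}) and \code{truth}
#'   (data.frame with \code{is_ortholog} for every rank-1 hit).
#' @export
make_hit_table <- function(n_strains, n_universal = 44, paralog_fraction, seed,
                           ortho_mean = -80, para_mean = -20, log_sd = 5,
                           extra_paralog_prob = 0.8, strain_ids = NULL) {
  if (paralog_fraction < 0 || paralog_fraction >= 1)
    abort_category("argument_error", "paralog_fraction must be in [0,1)")
  if (is.null(strain_ids)) strain_ids <- sprintf("s%02d", seq_len(n_strains))
  genes <- sprintf("U%02d", seq_len(n_universal))
  draw <- function(n, mean) pmin(stats::rnorm(n, mean, log_sd), -5 - 1e-9)
  with_seed(seed, {
    grid <- expand.grid(strain_id = strain_ids, query_gene = genes,
                        stringsAsFactors = FALSE)
    n <- nrow(grid)
    is_para <- stats::runif(n) < paralog_fraction
    lge <- ifelse(is_para, draw(n, para_mean), draw(n, ortho_mean))
    rank1 <- data.frame(query_gene = grid$query_gene,
                        strain_id = grid$strain_id,
                        protein_id = sprintf("%s|%s|r1", grid$strain_id,
                                             grid$query_gene),
                        e_value = 10^lge, rank = 1L, stringsAsFactors = FALSE)
    has2 <- stats::runif(n) < extra_paralog_prob
    rank2 <- data.frame(query_gene = grid$query_gene[has2],
                        strain_id = grid$strain_id[has2],
                        protein_id = sprintf("%s|%s|r2", grid$strain_id[has2],
                                             grid$query_gene[has2]),
                        e_value = 10^draw(sum(has2), para_mean), rank = 2L,
                        stringsAsFactors = FALSE)
    hits <- hit_table(rbind(rank1, rank2))
    truth <- data.frame(query_gene = grid$query_gene,
                        strain_id = grid$strain_id,
                        protein_id = rank1$protein_id,
                        is_ortholog = !is_para, stringsAsFactors = FALSE)
    list(hits = hits, truth = truth)
  })
}

#' Simulate family presence under the two-state gain/loss chain
#'
#' Parametric counterpart of \code{\link{fit_gain_loss_rates}}: each family
#' evolves independently on the tree under the absent <-> present chain
#' (gain rate, loss rate), root state drawn from the stationary
#' distribution, conditioned by rejection on being present in at least one
#' strain.  Unlike \code{\link{simulate_gene_content}} (infinitely-many-genes
#' convention, where \code{gain_rate} is a per-lineage family creation rate)
#' the rates here are per family and are directly recoverable by the ML fit.
#'
#' @param tree phylo with branch lengths.
#' @param n_families number of observable families to simulate.
#' @param gain_rate,loss_rate per-family rates per unit branch length.
#' @param seed integer seed.
#' @return list with \code{matrix} (a \code{gene_family_matrix}) and
#'   \code{states} (nodes x families 0/1 matrix of true states).
#' @export
simulate_two_state_content <- function(tree, n_families, gain_rate, loss_rate,
                                       seed) {
  if (gain_rate < 0 || loss_rate < 0 || gain_rate + loss_rate == 0)
    abort_category("argument_error", "need nonnegative rates, not both zero")
  n_tip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  root <- tree_root(tree)
  bl <- branch_above(tree)
  par <- parent_vec(tree)
  nodes <- rev(postorder_nodes(tree))
  pi_p <- gain_rate / (gain_rate + loss_rate)
  with_seed(seed, {
    done <- 0L
    states <- matrix(0L, n_nodes, n_families)
    while (done < n_families) {
      batch <- max(2L * (n_families - done), 100L)
      st <- matrix(0L, n_nodes, batch)
      st[root, ] <- as.integer(stats::runif(batch) < pi_p)
      for (v in nodes) {
        if (v == root) next
        P <- gl_pmat(gain_rate, loss_rate, bl[v])
        x <- st[par[v], ]
        u <- stats::runif(batch)
        st[v, ] <- ifelse(x == 1L, as.integer(u < P[2, 2]),
                          as.integer(u < P[1, 2]))
      }
      ok <- which(colSums(st[seq_len(n_tip), , drop = FALSE]) > 0)
      take <- ok[seq_len(min(length(ok), n_families - done))]
      if (length(take) > 0) {
        states[, done + seq_along(take)] <- st[, take]
        done <- done + length(take)
      }
    }
    colnames(states) <- sprintf("F%05d", seq_len(n_families))
    pres <- states[seq_len(n_tip), , drop = FALSE]
    rownames(pres) <- tree$tip.label
    list(matrix = gene_family_matrix(pres), states = states)
  })
}

#' Simulate Brownian-motion traits on a tree
#'
#' @param tree phylo with branch lengths.
#' @param n_traits number of independent traits.
#' @param seed integer seed.
#' @param sigma2 BM rate.
#' @return matrix tips x traits.
#' @export
simulate_bm_traits <- function(tree, n_traits = 1, seed, sigma2 = 1) {
  with_seed(seed, {
    nodes <- rev(postorder_nodes(tree))
    bl <- branch_above(tree)
    par <- parent_vec(tree)
    root <- tree_root(tree)
    n_tip <- length(tree$tip.label)
    x <- matrix(0, max(tree$edge), n_traits)
    for (v in nodes) {
      if (v == root) next
      x[v, ] <- x[par[v], ] + stats::rnorm(n_traits, 0, sqrt(sigma2 * bl[v]))
    }
    out <- x[seq_len(n_tip), , drop = FALSE]
    rownames(out) <- tree$tip.label
    out
  })
}
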