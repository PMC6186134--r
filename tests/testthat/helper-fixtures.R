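# Shared fixtures and independent oracle implementations used across tests.
# Oracles are deliberately written as brute-force enumerations, independent
# of the package's own algorithms.

quartet_tree <- function() ape::read.tree(text = "((A:1,B:1):0.5,(C:1,D:1):0.5);")

tiny_config <- function(...) {
  defaults <- list(n_species = 2, strains_per_species = 15,
                   theta_per_site = 0.05, omega = 0.3, kappa = 2,
                   n_universal_genes = 5, n_codons_per_gene = 30,
                   n_core_codons = 60, root_gene_count = 50,
                   gain_rate = 200, loss_rate = 1,
                   recombination_events = 0, paralog_fraction = 0.1, seed = 7)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

with_seed_order <- function(n, seed) { set.seed(seed); sample(n) }

GC_STD <- Biostrings::GENETIC_CODE

# Brute-force syn/nonsyn site count of a codon (independent enumeration).
oracle_site_count <- function(codon) {
  aa0 <- GC_STD[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (GC_STD[[mut]] == "*") next
      valid <- valid + 1
      if (GC_STD[[mut]] == aa0) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

# Brute-force pathway-averaged (syn, nonsyn) difference counts between two
# sense codons: recursive walk over all orderings of the differing positions,
# dropping paths through stops.
oracle_path_counts <- function(c1, c2) {
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diffpos) == 0) return(c(0, 0))
  walk <- function(cur, remaining) {
    if (length(remaining) == 0) return(list(c(0, 0)))
    paths <- list()
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (GC_STD[[nxt]] == "*") next
      step <- if (GC_STD[[cur]] == GC_STD[[nxt]]) c(1, 0) else c(0, 1)
      for (tail in walk(nxt, setdiff(remaining, pos)))
        paths[[length(paths) + 1]] <- step + tail
    }
    paths
  }
  paths <- walk(c1, diffpos)
  if (length(paths) == 0) return(c(NA_real_, NA_real_))
  colMeans(do.call(rbind, paths))
}

# Brute-force Fitch: minimize changes over all 4^{n internal} labelings.
oracle_fitch <- function(tree, pattern) {
  nuc <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  states <- pattern[tree$tip.label]
  if (sum(states %in% nuc) < 2) return(NA_integer_)
  grid <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  node_state <- function(lab, v) {
    if (v <= n_tip) match(states[v], nuc) else lab[v - n_tip]
  }
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- grid[r, ]
    ch <- 0
    for (e in seq_len(nrow(tree$edge))) {
      a <- node_state(lab, tree$edge[e, 1])
      b <- node_state(lab, tree$edge[e, 2])
      if (is.na(b)) next  # missing leaf unconstrained
      if (a != b) ch <- ch + 1
    }
    best <- min(best, ch)
  }
  best
}

# Brute-force likelihood of a single presence pattern under the 2-state
# gain/loss chain: sum over all internal-state assignments.
oracle_gl_lik <- function(tree, pattern, gain, loss) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  root <- n_tip + 1L
  prior <- c(loss, gain) / (gain + loss)
  pm <- function(t) {
    r <- gain + loss; e <- exp(-r * t)
    matrix(c((loss + gain * e) / r, gain * (1 - e) / r,
             loss * (1 - e) / r, (gain + loss * e) / r), 2, 2, byrow = TRUE)
  }
  grid <- as.matrix(expand.grid(rep(list(0:1), n_int)))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    lab <- grid[r, ]
    state <- function(v) if (v <= n_tip) pattern[v] else lab[v - n_tip]
    p <- prior[state(root) + 1]
    for (e in seq_len(nrow(tree$edge))) {
      a <- state(tree$edge[e, 1]); b <- state(tree$edge[e, 2])
      p <- p * pm(tree$edge.length[e])[a + 1, b + 1]
    }
    total <- total + p
  }
  total
}

# Replay a gene-content event log down the tree and return leaf presence.
replay_event_log <- function(tree, root_families, events) {
  n_tip <- length(tree$tip.label)
  ch <- nepan:::children_list(tree)
  name_of <- function(v) if (v <= n_tip) tree$tip.label[v] else sprintf("n%d", v)
  leaves <- list()
  recurse <- function(v, present) {
    for (w in ch[[v]]) {
      ev <- events[events$branch_id == name_of(w), ]
      present_w <- setdiff(present, ev$family_id[ev$event == "loss"])
      present_w <- c(present_w, ev$family_id[ev$event == "gain"])
      if (w <= n_tip) leaves[[tree$tip.label[w]]] <<- present_w
      else recurse(w, present_w)
    }
  }
  recurse(nepan:::tree_root(tree), root_families)
  leaves
}
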