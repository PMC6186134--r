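# Cross-species statistics: phylogenetically independent contrasts,
# correlations, Ne-dissimilarity vs phylogenetic distance, lifestyle
# contrasts, PCA and the trait correlation network.

LIFESTYLES <- c("free_living", "commensal", "obligate_pathogen",
                "plant_pathogen", "obligate_intracellular", "unknown")

# Prune tree to species with trait data, resolve multifurcations with
# zero-length edges, and floor non-positive branch lengths at the 1st
# percentile of positive lengths (contrasts divide by branch lengths).
prepare_pic_tree <- function(tree, species) {
  drop <- setdiff(tree$tip.label, species)
  if (length(drop) > 0) tree <- ape::drop.tip(tree, drop)
  if (!ape::is.binary.phylo(tree)) tree <- ape::multi2di(tree)
  pos <- tree$edge.length[tree$edge.length > 0]
  if (length(pos) == 0)
    abort_category("argument_error", "tree has no positive branch lengths")
  floor_len <- stats::quantile(pos, 0.01)
  tree$edge.length[tree$edge.length <= 0] <- floor_len
  tree
}

#' Phylogenetically independent contrasts (Felsenstein)
#'
#' At each internal node the contrast is \eqn{(x_i - x_j)/\sqrt{b_i + b_j}};
#' the ancestral value is the branch-length-weighted average and the parent
#' branch is extended by \eqn{b_i b_j/(b_i + b_j)}.  Leaves without trait
#' values are pruned; multifurcations are resolved with zero-length edges and
#' non-positive lengths floored at the 1st percentile of positive lengths.
#'
#' @param tree phylo with branch lengths.
#' @param trait named numeric vector species -> value.
#' @return list with \code{contrasts} (one per internal node),
#'   \code{variances} (the b_i + b_j used), \code{node_ids}, \code{tree}.
#' @export
pic_contrasts <- function(tree, trait) {
  trait <- trait[!is.na(trait)]
  tree <- prepare_pic_tree(tree, names(trait))
  if (length(tree$tip.label) < 2)
    abort_category("argument_error", "need >= 2 species with trait values")
  n_tip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  x <- rep(NA_real_, n_nodes)
  x[seq_len(n_tip)] <- trait[tree$tip.label]
  b <- branch_above(tree)
  ch <- children_list(tree)
  contrasts <- variances <- rep(NA_real_, n_nodes)
  for (v in postorder_nodes(tree)) {
    if (v <= n_tip) next
    kids <- ch[[v]]
    bi <- b[kids[1]]; bj <- b[kids[2]]
    contrasts[v] <- (x[kids[1]] - x[kids[2]]) / sqrt(bi + bj)
    variances[v] <- bi + bj
    x[v] <- (x[kids[1]] / bi + x[kids[2]] / bj) / (1 / bi + 1 / bj)
    if (!is.na(b[v])) b[v] <- b[v] + bi * bj / (bi + bj)
  }
  keep <- which(!is.na(contrasts))
  list(contrasts = contrasts[keep], variances = variances[keep],
       node_ids = keep, tree = tree)
}

#' Phylogenetically corrected trait correlation
#'
#' Contrasts for both traits are computed on the shared pruned tree;
#' \code{method = "spearman"} rank-correlates the contrast pairs (as the
#' source analyses report) and \code{method = "pearson"} uses the orthodox
#' Pearson correlation through the origin.
#'
#' @param tree phylo.
#' @param x,y named numeric trait vectors.
#' @param method "spearman" or "pearson".
#' @return list with rho, p_value, n_contrasts.
#' @export
pic_correlation <- function(tree, x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(names(x)[!is.na(x)], names(y)[!is.na(y)])
  shared <- intersect(shared, tree$tip.label)
  if (length(shared) < 4)
    abort_category("argument_error", "need >= 4 shared species")
  tr <- prepare_pic_tree(tree, shared)
  cx <- pic_contrasts(tr, x[shared])$contrasts
  cy <- pic_contrasts(tr, y[shared])$contrasts
  n <- length(cx)
  if (method == "spearman") {
    ct <- suppressWarnings(stats::cor.test(cx, cy, method = "spearman"))
    list(rho = unname(ct$estimate), p_value = ct$p.value, n_contrasts = n)
  } else {
    r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
    tstat <- r * sqrt((n - 1) / max(1 - r^2, 1e-300))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    list(rho = r, p_value = p, n_contrasts = n)
  }
}

#' Ne dissimilarity versus phylogenetic distance
#'
#' For every unordered species pair, the patristic distance and
#' \eqn{|Ne_i - Ne_j|}; Spearman's rho over pairs, with both the plain
#' Spearman p and a Mantel-style permutation p (pairs are non-independent).
#'
#' @param tree phylo over the species.
#' @param ne named numeric vector of Ne (or dS/dN) values.
#' @param n_perm Mantel permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list with pairs (data.frame), rho, p_spearman, p_mantel.
#' @export
ne_dissimilarity_vs_distance <- function(tree, ne, n_perm = 999, seed = 1) {
  sp <- intersect(tree$tip.label, names(ne)[!is.na(ne)])
  if (length(sp) < 3) abort_category("argument_error", "need >= 3 species")
  tr <- prepare_pic_tree(tree, sp)
  pd <- stats::cophenetic(tr)[sp, sp]
  idx <- which(upper.tri(pd), arr.ind = TRUE)
  dist_v <- pd[idx]
  dis_v <- abs(ne[sp[idx[, 1]]] - ne[sp[idx[, 2]]])
  pairs <- data.frame(species_i = sp[idx[, 1]], species_j = sp[idx[, 2]],
                      phylo_distance = dist_v, ne_dissimilarity = unname(dis_v))
  if (stats::sd(dis_v) == 0 || stats::sd(dist_v) == 0)
    return(list(pairs = pairs, rho = NA_real_, p_spearman = NA_real_,
                p_mantel = NA_real_))
  rho <- stats::cor(dist_v, dis_v, method = "spearman")
  p_sp <- suppressWarnings(
    stats::cor.test(dist_v, dis_v, method = "spearman")$p.value)
  p_mt <- with_seed(seed, {
    hits <- 0L
    nev <- ne[sp]
    for (b in seq_len(n_perm)) {
      perm <- sample(nev)
      dis_p <- abs(perm[idx[, 1]] - perm[idx[, 2]])
      if (abs(stats::cor(dist_v, dis_p, method = "spearman")) >= abs(rho))
        hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
  list(pairs = pairs, rho = rho, p_spearman = p_sp, p_mantel = p_mt)
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pairwise lifestyle comparison of Ne proxies
#'
#' Two-sided Wilcoxon rank-sum tests between lifestyle categories on
#' \code{ne_relative} (dS/dN); plant pathogens are excluded and groups with
#' fewer than 3 species are skipped.  Raw p-values carry the conventional
#' star coding; Holm-adjusted p-values are reported alongside.
#'
#' @param table data.frame with columns species_id, lifestyle, ne_relative.
#' @param trait column to compare (default "ne_relative").
#' @return data.frame group1, group2, n1, n2, p_value, p_holm, stars.
#' @export
lifestyle_comparison <- function(table, trait = "ne_relative") {
  tab <- table[!is.na(table[[trait]]) &
                 table$lifestyle != "plant_pathogen" &
                 table$lifestyle != "unknown", ]
  groups <- split(tab[[trait]], tab$lifestyle)
  groups <- groups[vapply(groups, length, 1L) >= 3]
  if (length(groups) < 2)
    abort_category("argument_error", "need >= 2 lifestyle groups with >= 3 species")
  gn <- names(groups)
  rows <- list()
  for (i in seq_len(length(gn) - 1L)) for (j in (i + 1L):length(gn)) {
    w <- suppressWarnings(stats::wilcox.test(groups[[i]], groups[[j]]))
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = gn[i], group2 = gn[j],
      n1 = length(groups[[i]]), n2 = length(groups[[j]]),
      p_value = w$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_value, "holm")
  out$stars <- p_stars(out$p_value)
  out
}

#' PCA and correlation network of species traits
#'
#' PCA on z-scored quantitative columns (complete rows); pairwise Spearman
#' correlations with p-values; network edges retained at p <= 0.01 with
#' weight -log10(p).
#'
#' @param table data.frame of species traits (non-numeric columns ignored).
#' @param p_cutoff edge retention threshold (default 0.01).
#' @return list with loadings, explained_variance, correlation, p_values,
#'   edges (data.frame trait_a, trait_b, rho, p_value, weight).
#' @export
pca_and_network <- function(table, p_cutoff = 0.01) {
  num <- table[vapply(table, is.numeric, TRUE)]
  const <- vapply(num, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                    all(is.na(v)), TRUE)
  if (any(const)) {
    warning(sprintf("dropping constant columns: %s",
                    paste(names(num)[const], collapse = ", ")))
    num <- num[!const]
  }
  if (ncol(num) < 3)
    abort_category("argument_error", "need >= 3 usable numeric columns")
  complete <- num[stats::complete.cases(num), , drop = FALSE]
  pca <- stats::prcomp(complete, center = TRUE, scale. = TRUE)
  expl <- pca$sdev^2 / sum(pca$sdev^2)
  k <- ncol(num)
  rho <- pmat <- matrix(NA_real_, k, k, dimnames = list(names(num), names(num)))
  edges <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- stats::complete.cases(num[[i]], num[[j]])
    if (sum(ok) < 4) next
    ct <- suppressWarnings(stats::cor.test(num[[i]][ok], num[[j]][ok],
                                           method = "spearman"))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    pmat[i, j] <- pmat[j, i] <- ct$p.value
    if (!is.na(ct$p.value) && ct$p.value <= p_cutoff)
      edges[[length(edges) + 1L]] <- data.frame(
        trait_a = names(num)[i], trait_b = names(num)[j],
        rho = unname(ct$estimate), p_value = ct$p.value,
        weight = -log10(ct$p.value), stringsAsFactors = FALSE)
  }
  diag(rho) <- 1
  list(loadings = pca$rotation, explained_variance = expl,
       correlation = rho, p_values = pmat,
       edges = if (length(edges)) do.call(rbind, edges)
               else data.frame(trait_a = character(0), trait_b = character(0),
                               rho = numeric(0), p_value = numeric(0),
                               weight = numeric(0)))
}
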