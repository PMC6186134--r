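# Ortholog identification, strain QC, BRH family clustering and pan-/core-
# genome statistics.

#' Hit table of universal-protein searches
#'
#' @param records data.frame with columns query_gene, strain_id, protein_id,
#'   e_value, rank.  Records with e-value above 1e-5 are rejected.
#' @return data.frame of class \code{hit_table}.
#' @export
hit_table <- function(records) {
  need <- c("query_gene", "strain_id", "protein_id", "e_value", "rank")
  if (!all(need %in% names(records)))
    abort_category("validation_error",
                   paste("hit table must have columns:", paste(need, collapse = ", ")))
  if (any(records$e_value > 1e-5))
    abort_category("validation_error", "hit table contains e-values > 1e-5")
  if (any(records$e_value <= 0))
    abort_category("validation_error", "e-values must be positive")
  structure(records[need], class = c("hit_table", "data.frame"))
}

#' Gene family presence/absence matrix
#'
#' @param presence binary matrix strains x families with dimnames.
#' @param family_members optional named list: family id -> data.frame with
#'   strain_id, protein_id.  When omitted, one synthetic member per presence
#'   cell is assumed (paralog-free).
#' @return object of class \code{gene_family_matrix}.
#' @export
gene_family_matrix <- function(presence, family_members = NULL) {
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    abort_category("validation_error", "presence matrix needs strain and family names")
  if (!all(presence %in% c(0L, 1L)))
    abort_category("validation_error", "presence matrix must be binary")
  paralog <- stats::setNames(rep(FALSE, ncol(presence)), colnames(presence))
  if (!is.null(family_members)) {
    for (f in names(family_members)) {
      tab <- table(family_members[[f]]$strain_id)
      paralog[f] <- any(tab > 1L)
    }
  }
  structure(list(presence = presence, family_members = family_members,
                 paralogous_flags = paralog),
            class = "gene_family_matrix")
}

#' @export
print.gene_family_matrix <- function(x, ...) {
  cat(sprintf("gene_family_matrix: %d strains x %d families (%d paralogous)\n",
              nrow(x$presence), ncol(x$presence), sum(x$paralogous_flags)))
  invisible(x)
}

# Floor for zero e-values before taking log10.
EVALUE_FLOOR <- 1e-300

#' Classify potential orthologs against confirmed paralogs
#'
#' For each universal gene, the best hit per strain (rank 1) is a potential
#' ortholog and rank >= 2 hits are confirmed paralogs.  A potential ortholog
#' with log10 e-value x is accepted when it is closer to the median log10
#' e-value of potential orthologs (M_o) than to the mean log10 e-value of
#' confirmed paralogs (M_p); exact ties are resolved conservatively to
#' paralog.  Genes without confirmed paralogs accept all potential orthologs.
#'
#' @param hits a \code{hit_table}.
#' @return data.frame of ortholog calls (gene_id, strain_id, protein_id,
#'   e_value, verdict).
#' @export
classify_orthologs <- function(hits) {
  if (nrow(hits) == 0)
    abort_category("argument_error", "empty hit table")
  out <- list()
  for (g in unique(hits$query_gene)) {
    h <- hits[hits$query_gene == g, ]
    pot <- h[h$rank == 1L, ]
    if (nrow(pot) == 0) next  # gene reported absent
    par <- h[h$rank >= 2L, ]
    lx <- log10(pmax(pot$e_value, EVALUE_FLOOR))
    if (nrow(par) == 0) {
      verdict <- rep("ortholog", nrow(pot))
    } else {
      m_o <- stats::median(lx)
      m_p <- mean(log10(pmax(par$e_value, EVALUE_FLOOR)))
      verdict <- ifelse(abs(lx - m_o) < abs(lx - m_p), "ortholog", "paralog")
    }
    out[[g]] <- data.frame(gene_id = g, strain_id = pot$strain_id,
                           protein_id = pot$protein_id, e_value = pot$e_value,
                           verdict = verdict, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$strain_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Quality-filter strains by universal ortholog count
#'
#' Strains with fewer than 42 of the universal orthologs are excluded as
#' likely incomplete assemblies; for Mycoplasma, whose genomes are highly
#' reduced, four missing proteins are tolerated (threshold 40).
#'
#' @param calls output of \code{\link{classify_orthologs}}.
#' @param n_universal size of the universal gene set (default 44).
#' @param mycoplasma logical; relax the threshold by two.
#' @return character vector of retained strain ids.
#' @export
qc_filter_strains <- function(calls, n_universal = 44, mycoplasma = FALSE) {
  threshold <- if (mycoplasma) n_universal - 4L else n_universal - 2L
  ok <- calls[calls$verdict == "ortholog", ]
  counts <- table(ok$strain_id)
  strains <- unique(calls$strain_id)
  n_ok <- as.integer(counts[strains])
  n_ok[is.na(n_ok)] <- 0L
  sort(strains[n_ok >= threshold])
}

#' Deduplicate near-identical strains and subsample large species
#'
#' While any strain pair is closer than \code{d_min} (substitutions/site),
#' one member of the closest pair is removed uniformly at random; species
#' with more than \code{max_strains} survivors are randomly subsampled down,
#' and species left with fewer than \code{min_strains} are excluded.
#'
#' @param strain_ids strains under consideration.
#' @param distances symmetric pairwise distance matrix over strain_ids.
#' @param max_strains subsampling cap (default 400).
#' @param min_strains exclusion floor (default 15).
#' @param d_min duplicate threshold (default 5e-5).
#' @param seed integer seed.
#' @return list with \code{retained} (character; empty when excluded) and
#'   \code{excluded} (logical species-level flag).
#' @export
dedup_and_subsample <- function(strain_ids, distances, max_strains = 400,
                                min_strains = 15, d_min = 0.00005, seed = 1) {
  check_symmetric(distances)
  distances <- distances[strain_ids, strain_ids, drop = FALSE]
  with_seed(seed, {
    keep <- sort(strain_ids)
    repeat {
      d <- distances[keep, keep, drop = FALSE]
      d[upper.tri(d, diag = TRUE)] <- NA
      close <- which(d < d_min, arr.ind = TRUE)
      if (nrow(close) == 0L) break
      # process closest pair first; ties broken by lexical ids
      vals <- d[close]
      cand <- close[order(vals, rownames(d)[close[, 1]],
                          colnames(d)[close[, 2]]), , drop = FALSE][1, ]
      pair <- c(rownames(d)[cand[1]], colnames(d)[cand[2]])
      drop <- sample(pair, 1L)
      keep <- setdiff(keep, drop)
    }
    if (length(keep) > max_strains) keep <- sort(sample(keep, max_strains))
    if (length(keep) < min_strains)
      return(list(retained = character(0), excluded = TRUE))
    list(retained = keep, excluded = FALSE)
  })
}

# Minimal union-find used for transitive family clustering.
uf_new <- function(n) seq_len(n)
uf_find <- function(uf, i) {
  while (uf[i] != i) { uf[i] <- uf[uf[i]]; i <- uf[i] }
  i
}

#' Cluster proteins into families by transitive best reciprocal hits
#'
#' A directed hit is a best hit when it has the highest identity among hits
#' from its query to the subject's strain.  A pair is accepted when it is the
#' best hit in both directions, identity >= 70\% and alignment coverage
#' >= 80\% of both proteins.  Families are connected components of the
#' accepted-pair graph; unmatched proteins form singleton families.
#'
#' @param pairwise_hits data.frame with columns protein_a, protein_b,
#'   percent_identity, coverage_a, coverage_b (directed: a is the query).
#' @param protein_strains data.frame protein_id, strain_id covering every
#'   protein in the species (defines singletons).
#' @param min_identity,min_coverage acceptance thresholds (70, 0.80).
#' @return a \code{gene_family_matrix}.
#' @export
cluster_brh_families <- function(pairwise_hits, protein_strains,
                                 min_identity = 70, min_coverage = 0.80) {
  if (anyDuplicated(protein_strains$protein_id))
    abort_category("identifier_error",
                   "a protein id maps to more than one strain")
  prot <- protein_strains$protein_id
  strain_of <- stats::setNames(protein_strains$strain_id, prot)
  h <- pairwise_hits
  if (nrow(h) > 0) {
    bad <- !(h$protein_a %in% prot) | !(h$protein_b %in% prot)
    if (any(bad))
      abort_category("identifier_error", "hit references unknown protein id")
    h <- h[h$protein_a != h$protein_b, , drop = FALSE]
  }
  accepted <- matrix(character(0), 0, 2)
  if (nrow(h) > 0) {
    h$strain_b <- strain_of[h$protein_b]
    # best directed hit per (query protein, subject strain): max identity,
    # ties broken by lexical subject id for determinism
    key <- paste(h$protein_a, h$strain_b, sep = "\r")
    ord <- order(key, -h$percent_identity, h$protein_b)
    h <- h[ord, ]
    best <- h[!duplicated(key[ord]), , drop = FALSE]
    bkey <- paste(best$protein_a, best$protein_b, sep = "\r")
    rkey <- paste(best$protein_b, best$protein_a, sep = "\r")
    reciprocal <- bkey %in% rkey
    pass <- reciprocal & best$percent_identity >= min_identity &
      best$coverage_a >= min_coverage & best$coverage_b >= min_coverage
    acc <- best[pass, , drop = FALSE]
    # keep each unordered pair once
    a <- pmin(acc$protein_a, acc$protein_b)
    b <- pmax(acc$protein_a, acc$protein_b)
    pk <- paste(a, b, sep = "\r")
    both <- table(pk)
    ok <- names(both)[both == 2L]  # accepted in both directions
    if (length(ok) > 0) {
      sp <- strsplit(ok, "\r", fixed = TRUE)
      accepted <- do.call(rbind, sp)
    }
  }
  uf <- uf_new(length(prot))
  idx <- stats::setNames(seq_along(prot), prot)
  if (nrow(accepted) > 0) {
    for (r in seq_len(nrow(accepted))) {
      ra <- uf_find(uf, idx[accepted[r, 1]])
      rb <- uf_find(uf, idx[accepted[r, 2]])
      if (ra != rb) uf[rb] <- ra
    }
  }
  comp <- vapply(seq_along(prot), function(i) uf_find(uf, i), integer(1))
  fam_of <- match(comp, sort(unique(comp)))
  fam_ids <- sprintf("FAM%05d", seq_len(max(fam_of)))
  strains <- sort(unique(protein_strains$strain_id))
  members <- split(data.frame(strain_id = unname(strain_of[prot]),
                              protein_id = prot, stringsAsFactors = FALSE),
                   fam_ids[fam_of])
  pres <- matrix(0L, length(strains), length(fam_ids),
                 dimnames = list(strains, fam_ids))
  for (f in names(members))
    pres[unique(members[[f]]$strain_id), f] <- 1L
  gene_family_matrix(pres, members)
}

#' Pan-genome size with harmonic normalization
#'
#' \eqn{N_{pan}} counts every family including singletons; because it grows
#' with the number of sampled strains it is normalized as
#' \eqn{P = N_{pan}/\alpha} with \eqn{\alpha = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param matrix a \code{gene_family_matrix}.
#' @return list with n_strains, n_pan, alpha, p_normalized.
#' @export
pan_genome_stats <- function(matrix) {
  n <- nrow(matrix$presence)
  if (n < 2) abort_category("argument_error", "need >= 2 strains")
  n_pan <- sum(colSums(matrix$presence) > 0)
  alpha <- harmonic_alpha(n)
  list(n_strains = n, n_pan = n_pan, alpha = alpha,
       p_normalized = n_pan / alpha)
}

#' Divergence-maximizing pan-genome subsample (Ps)
#'
#' Repeatedly identifies the pair of most similar strains on the core-genome
#' distance matrix and discards one member at random, until \code{k} strains
#' remain; Ps is the pan-genome size of the survivors.
#'
#' @param matrix a \code{gene_family_matrix}.
#' @param core_distances symmetric distance matrix over the strains.
#' @param k target sample size (default 13).
#' @param seed integer seed.
#' @return list with \code{ps} (NA when n < k), \code{retained}.
#' @export
subsample_pan <- function(matrix, core_distances, k = 13, seed = 1) {
  strains <- rownames(matrix$presence)
  if (length(strains) < k)
    return(list(ps = NA_integer_, retained = character(0), available = FALSE))
  check_symmetric(core_distances)
  with_seed(seed, {
    keep <- sort(strains)
    while (length(keep) > k) {
      d <- core_distances[keep, keep, drop = FALSE]
      d[upper.tri(d, diag = TRUE)] <- NA
      cand <- which(d == min(d, na.rm = TRUE), arr.ind = TRUE)
      cand <- cand[order(rownames(d)[cand[, 1]], colnames(d)[cand[, 2]]), ,
                   drop = FALSE][1, ]
      pair <- c(rownames(d)[cand[1]], colnames(d)[cand[2]])
      keep <- setdiff(keep, sample(pair, 1L))
    }
    sub <- matrix$presence[keep, , drop = FALSE]
    list(ps = sum(colSums(sub) > 0), retained = keep, available = TRUE)
  })
}

#' Core-genome families
#'
#' A family belongs to the core genome when present in at least
#' \code{threshold} of the strains and free of paralogs.
#'
#' @param matrix a \code{gene_family_matrix}.
#' @param threshold presence fraction (default 0.85).
#' @return character vector of core family ids.
#' @export
core_genome <- function(matrix, threshold = 0.85) {
  if (threshold <= 0 || threshold > 1)
    abort_category("argument_error", "threshold must be in (0,1]")
  frac <- colMeans(matrix$presence)
  fams <- colnames(matrix$presence)
  fams[frac >= threshold & !matrix$paralogous_flags[fams]]
}
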