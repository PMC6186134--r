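# Genetic-code tables and NG86 counting primitives.
#
# The bacterial code (translation table 11) equals the standard code for all
# sense codons; TAA, TAG and TGA are stops.  All tables are built once and
# cached in the package namespace environment.

.codon_env <- new.env(parent = emptyenv())

NUC <- c("A", "C", "G", "T")

codon_universe <- function() {
  if (!is.null(.codon_env$codons)) return(invisible(.codon_env))
  codons <- as.vector(outer(outer(NUC, NUC, paste0), NUC, paste0))
  codons <- sort(codons)
  gc <- Biostrings::GENETIC_CODE  # standard code == table 11 on sense codons
  aa <- unname(gc[codons])
  is_stop <- aa == "*"
  .codon_env$codons <- codons
  .codon_env$aa <- aa
  .codon_env$is_stop <- is_stop
  .codon_env$sense <- codons[!is_stop]
  .codon_env$index <- stats::setNames(seq_along(codons), codons)
  invisible(.codon_env)
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# Single-nucleotide neighbors of a codon at a given position.
codon_neighbors <- function(codon, pos) {
  base <- substr(codon, pos, pos)
  vapply(setdiff(NUC, base), function(b) {
    s <- codon
    substr(s, pos, pos) <- b
    s
  }, character(1))
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' NG86-style site counting: each codon position contributes one site, split
#' between synonymous and nonsynonymous in proportion to its single-nucleotide
#' neighbors.  Mutations to stop codons are excluded from the denominator, so
#' a position whose only non-stop neighbor is synonymous counts as a full
#' synonymous site.
#'
#' @param codon a 3-character string over A/C/G/T coding a sense codon.
#' @return named numeric vector \code{c(s_sites=, n_sites=)}, summing to 3.
#' @export
count_syn_nonsyn_sites <- function(codon) {
  env <- codon_universe()
  codon <- toupper(codon)
  if (!codon %in% env$sense)
    abort_category("argument_error", sprintf("not a sense codon: %s", codon))
  aa0 <- env$aa[env$index[codon]]
  s_tot <- 0
  for (pos in 1:3) {
    nb <- codon_neighbors(codon, pos)
    aan <- env$aa[env$index[nb]]
    keep <- aan != "*"
    denom <- sum(keep)
    if (denom > 0) s_tot <- s_tot + sum(aan[keep] == aa0) / denom
  }
  c(s_sites = s_tot, n_sites = 3 - s_tot)
}

# Average (syn, nonsyn) difference counts between two sense codons over all
# minimal mutational pathways, excluding pathways through stop codons.
# Returns c(sd, nd) or c(NA, NA) when every pathway is blocked.
ng86_path_counts <- function(c1, c2) {
  env <- codon_universe()
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diffpos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- permutations_of(diffpos)
  sds <- nds <- numeric(0)
  for (ord in perms) {
    cur <- c1
    sd <- nd <- 0
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (env$is_stop[env$index[nxt]]) { ok <- FALSE; break }
      if (env$aa[env$index[cur]] == env$aa[env$index[nxt]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { sds <- c(sds, sd); nds <- c(nds, nd) }
  }
  if (length(sds) == 0L) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = mean(sds), nd = mean(nds))
}

permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# Lazily built lookup tables over the full 64-codon universe:
#   $sites  : 64 x 2 matrix of (s_sites, n_sites), NA rows for stops
#   $sd, $nd: 64 x 64 matrices of pathway-averaged difference counts
#   $fourfold_prefix: the 16 dinucleotide prefixes flagged 4-fold degenerate
ng86_tables <- function() {
  env <- codon_universe()
  if (!is.null(env$sd)) return(env)
  n <- length(env$codons)
  sites <- matrix(NA_real_, n, 2, dimnames = list(env$codons, c("s", "n")))
  for (cd in env$sense) sites[cd, ] <- count_syn_nonsyn_sites(cd)
  sd <- nd <- matrix(NA_real_, n, n, dimnames = list(env$codons, env$codons))
  for (a in env$sense) for (b in env$sense) {
    v <- ng86_path_counts(a, b)
    sd[a, b] <- v[1]; nd[a, b] <- v[2]
  }
  prefixes <- as.vector(outer(NUC, NUC, paste0))
  ff <- vapply(prefixes, function(p) {
    aas <- env$aa[env$index[paste0(p, NUC)]]
    all(aas != "*") && length(unique(aas)) == 1L
  }, logical(1))
  env$sites <- sites
  env$sd <- sd
  env$nd <- nd
  env$fourfold_prefix <- stats::setNames(ff, prefixes)
  env
}

# Jukes-Cantor distance from a proportion of differing sites.
jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)  # saturated
  -0.75 * log(1 - 4 * p / 3)
}
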