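# NG86 pairwise divergence, the dS-window species average, Watterson's theta
# on four-fold degenerate sites, and the nearly-neutral dN/dS <-> Ne map.

#' Pairwise dN/dS by NG86 counting
#'
#' Synonymous/nonsynonymous site counts are averaged over the two sequences;
#' per-codon differences are averaged over all minimal mutational pathways
#' (pathways through stop codons excluded); proportions are converted to
#' distances with the Jukes-Cantor correction d = -(3/4) log(1 - 4p/3).
#' Codons containing gaps, ambiguity or stops in either sequence are skipped.
#'
#' @param seq_a,seq_b in-frame nucleotide sequences of equal length.
#' @param name_a,name_b strain labels carried into the result.
#' @return list with dn, ds, dnds (NA when ds == 0), n_codons_used,
#'   saturated (TRUE when either proportion reaches 3/4).
#' @export
pairwise_dnds <- function(seq_a, seq_b, name_a = "a", name_b = "b") {
  if (nchar(seq_a) != nchar(seq_b))
    abort_category("argument_error", "sequences must have equal length")
  env <- ng86_tables()
  ng86_pair_core(codon_index(seq_a, env), codon_index(seq_b, env),
                 name_a, name_b, env)
}

# Shared NG86 core operating on codon index vectors.
ng86_pair_core <- function(ia, ib, name_a, name_b, env) {
  use <- !is.na(ia) & !is.na(ib)
  ia <- ia[use]; ib <- ib[use]
  sd_v <- env$sd[cbind(ia, ib)]
  nd_v <- env$nd[cbind(ia, ib)]
  path_ok <- !is.na(sd_v)  # all-blocked pathway pairs are skipped entirely
  ia <- ia[path_ok]; ib <- ib[path_ok]
  sd_v <- sd_v[path_ok]; nd_v <- nd_v[path_ok]
  n_used <- length(ia)
  res <- list(strain_a = name_a, strain_b = name_b, dn = NA_real_,
              ds = NA_real_, dnds = NA_real_, n_codons_used = n_used,
              saturated = FALSE)
  if (n_used == 0L) return(res)
  S <- (sum(env$sites[ia, "s"]) + sum(env$sites[ib, "s"])) / 2
  N <- (sum(env$sites[ia, "n"]) + sum(env$sites[ib, "n"])) / 2
  ps <- if (S > 0) sum(sd_v) / S else 0
  pn <- if (N > 0) sum(nd_v) / N else 0
  if (ps >= 0.75 || pn >= 0.75) { res$saturated <- TRUE; return(res) }
  res$ds <- jc_correct(ps)
  res$dn <- jc_correct(pn)
  res$dnds <- if (res$ds > 0) res$dn / res$ds else NA_real_
  res
}

# codon index vector (into the 64-codon universe) with NA for codons that are
# ambiguous, gapped or stops
codon_index <- function(seq, env = ng86_tables()) {
  n_cod <- nchar(seq) %/% 3L
  cods <- substring(toupper(seq), 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  idx <- env$index[cods]
  idx[is.na(idx) | env$is_stop[idx]] <- NA_integer_
  unname(idx)
}

#' All pairwise divergences within an alignment
#'
#' @param aln a \code{codon_alignment}.
#' @return data.frame with one row per unordered strain pair.
#' @export
alignment_pairwise_dnds <- function(aln) {
  env <- ng86_tables()
  strains <- names(aln)
  n <- length(strains)
  idx <- lapply(seq_len(n), function(i) codon_index(aln[[i]], env))
  rows <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    k <- k + 1L
    rows[[k]] <- as.data.frame(
      ng86_pair_core(idx[[i]], idx[[j]], strains[i], strains[j], env),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Species-level dS/dN inside the divergence window
#'
#' dN/dS drifts with divergence time, so pairs are only comparable inside a
#' common window; the species value is the unweighted mean of pairwise dN/dS
#' over pairs with 0.1 <= dS <= 0.3 (bounds inclusive).
#'
#' @param pairs data.frame from \code{\link{alignment_pairwise_dnds}}.
#' @param window numeric length-2 inclusive dS bounds.
#' @return list with mean_dnds, mean_dsdn (reciprocal), n_pairs_in_window,
#'   excluded (TRUE when no pair qualifies).
#' @export
species_dsdn <- function(pairs, window = c(0.1, 0.3)) {
  ok <- !is.na(pairs$ds) & !is.na(pairs$dnds) &
    pairs$ds >= window[1] & pairs$ds <= window[2]
  if (!any(ok))
    return(list(mean_dnds = NA_real_, mean_dsdn = NA_real_,
                n_pairs_in_window = 0L, excluded = TRUE))
  m <- mean(pairs$dnds[ok])
  list(mean_dnds = m, mean_dsdn = if (m > 0) 1 / m else NA_real_,
       n_pairs_in_window = sum(ok), excluded = FALSE)
}

#' Four-fold degenerate alignment columns
#'
#' Returns nucleotide column indices of codon third positions whose context
#' is four-fold degenerate in every sequence (all four third-position states
#' synonymous given each row's first two positions); codons with gaps or
#' ambiguity anywhere in the column are excluded.
#'
#' @param aln a \code{codon_alignment}.
#' @return integer vector of alignment column indices (1-based).
#' @export
fourfold_sites <- function(aln) {
  if (length(aln) == 0L || aln_length(aln) == 0L) return(integer(0))
  env <- ng86_tables()
  cm <- codon_matrix(aln)
  ok <- apply(cm, 2, function(col) {
    idx <- env$index[col]
    if (any(is.na(idx)) || any(env$is_stop[idx])) return(FALSE)
    all(env$fourfold_prefix[substr(col, 1, 2)])
  })
  which(ok) * 3L
}

#' Watterson's estimator of theta per site
#'
#' \eqn{\hat\theta_W = S / (a_n L)} with S the number of segregating columns
#' and \eqn{a_n = \sum_{i=1}^{n-1} 1/i}.  Columns containing non-ACGT states
#' are dropped from both S and L.
#'
#' @param columns character matrix sequences x sites (e.g. the four-fold
#'   columns of a core-genome concatenate).
#' @param n_sequences sample size (defaults to \code{nrow(columns)}).
#' @return theta per site (NA when no usable column).
#' @export
watterson_theta <- function(columns, n_sequences = nrow(columns)) {
  if (n_sequences < 2)
    abort_category("argument_error", "need >= 2 sequences")
  if (is.null(dim(columns))) columns <- matrix(columns, ncol = 1L)
  ok <- columns %in% NUC
  dim(ok) <- dim(columns)
  valid <- colSums(ok) == nrow(columns)
  columns <- columns[, valid, drop = FALSE]
  L <- ncol(columns)
  if (L == 0L) return(NA_real_)
  first <- matrix(columns[1L, ], nrow(columns), L, byrow = TRUE)
  S <- sum(colSums(columns != first) > 0)
  S / (harmonic_alpha(n_sequences) * L)
}

#' Absolute Ne from theta
#'
#' For haploids \eqn{\theta = 2 N_e \mu}, so \eqn{N_e = \theta / (2\mu)}.
#'
#' @param theta_per_site Watterson's theta per site.
#' @param mu mutation rate per site per generation (> 0).
#' @export
ne_from_theta <- function(theta_per_site, mu) {
  if (!is.numeric(mu) || mu <= 0)
    abort_category("argument_error", "mu must be > 0")
  theta_per_site / (2 * mu)
}

#' Nearly-neutral fixation map
#'
#' \eqn{f(x) = x / (1 - e^{-x})} with \eqn{x = N_e s}: the ratio of fixation
#' probabilities of selected to neutral mutations, giving the expected dN/dS
#' under uniformly deleterious nonsynonymous mutations.  Evaluated with a
#' series expansion near 0 and an exp-underflow-safe branch for large |x|.
#'
#' @param x numeric vector of Ne*s values.
#' @return f(x), in (0, 1] for x <= 0.
#' @export
nearly_neutral_map <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-5
  out[small] <- 1 + x[small] / 2 + x[small]^2 / 12
  big_neg <- x <= -30
  y <- -x[big_neg]
  out[big_neg] <- y * exp(-y)          # x/(1-e^-x) -> -x e^x for x << 0
  mid <- !small & !big_neg
  out[mid] <- x[mid] / (-expm1(-x[mid]))  # expm1 avoids cancellation near 0
  out
}

# Inverse of nearly_neutral_map on (0, 1) for x < 0: bracketed root-finding
# on log10(-x) followed by Newton polishing to machine precision.
nearly_neutral_inverse <- function(dnds, lo = -20, hi = 4) {
  if (dnds <= 0 || dnds >= 1)
    abort_category("argument_error", "dnds must be in (0,1) for inversion")
  g <- function(u) nearly_neutral_map(-10^u) - dnds
  u <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  x <- -10^u
  for (k in 1:6) {
    if (x > -1e-8) { fx <- 1 + x / 2; fp <- 0.5 }
    else if (x > -30) {
      E <- exp(-x); D <- -expm1(-x)
      fx <- x / D
      fp <- (D - x * E) / D^2
    } else {
      ex <- exp(x); D <- 1 - ex
      fx <- -x * ex / D
      fp <- ex * (-(1 + x) * D - x * ex) / D^2
    }
    step <- (fx - dnds) / fp
    x_new <- x - step
    if (!is.finite(x_new) || x_new >= 0) break
    x <- x_new
    if (abs(step) < abs(x) * 1e-15) break
  }
  x
}

#' Calibrate the selection coefficient from reference species
#'
#' Given species with both a dN/dS and an absolute Ne (from theta), solves
#' \eqn{f(N_e s) = dN/dS} for s per species and returns the arithmetic mean.
#' Species with dN/dS >= 1 are skipped with a warning.
#'
#' @param calibration data.frame with columns mean_dnds and ne_absolute.
#' @return mean selection coefficient (negative).
#' @export
calibrate_s <- function(calibration) {
  use <- calibration$mean_dnds > 0 & calibration$mean_dnds < 1 &
    calibration$ne_absolute > 0
  if (any(!use))
    warning(sprintf("%d calibration species skipped (dN/dS outside (0,1))",
                    sum(!use)))
  if (!any(use))
    abort_category("argument_error", "no usable calibration species")
  s_vals <- mapply(function(dnds, ne) nearly_neutral_inverse(dnds) / ne,
                   calibration$mean_dnds[use], calibration$ne_absolute[use])
  mean(s_vals)
}

#' Absolute Ne from dN/dS and a calibrated selection coefficient
#'
#' Solves \eqn{f(N_e s) = dN/dS} for Ne at fixed s by bracketed root-finding.
#'
#' @param mean_dnds species dN/dS in (0, 1).
#' @param s_mean calibrated selection coefficient (< 0).
#' @return Ne (NA with a warning when dN/dS >= 1).
#' @export
ne_from_dnds <- function(mean_dnds, s_mean) {
  if (s_mean >= 0) abort_category("argument_error", "s_mean must be < 0")
  if (is.na(mean_dnds) || mean_dnds >= 1 || mean_dnds <= 0) {
    warning("dN/dS outside (0,1); absolute Ne undefined")
    return(NA_real_)
  }
  nearly_neutral_inverse(mean_dnds) / s_mean
}
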