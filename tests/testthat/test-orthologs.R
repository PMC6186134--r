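# ortholog_families: classification rule, QC, dedup, BRH clustering,
# pan-/core-genome statistics

mk_hits <- function(...) hit_table(do.call(rbind, list(...)))
hit_row <- function(gene, strain, prot, log10e, rank)
  data.frame(query_gene = gene, strain_id = strain, protein_id = prot,
             e_value = 10^log10e, rank = rank, stringsAsFactors = FALSE)

test_that("ortholog rule follows the median/mean distance comparison", {
  # no confirmed paralogs: all potential orthologs accepted
  h <- mk_hits(hit_row("g1", "s1", "p1", -80, 1),
               hit_row("g1", "s2", "p2", -78, 1),
               hit_row("g1", "s3", "p3", -75, 1))
  calls <- classify_orthologs(h)
  expect_true(all(calls$verdict == "ortholog"))
  # M_o = -80, M_p = -10; candidate at -70 is closer to M_o
  h2 <- mk_hits(hit_row("g1", "s1", "a1", -80, 1),
                hit_row("g1", "s2", "a2", -80, 1),
                hit_row("g1", "s3", "a3", -80, 1),
                hit_row("g1", "s4", "cand", -70, 1),
                hit_row("g1", "s1", "par1", -10, 2),
                hit_row("g1", "s2", "par2", -10, 2))
  # median of {-80,-80,-80,-70} = -80; mean paralog = -10
  calls2 <- classify_orthologs(h2)
  expect_equal(calls2$verdict[calls2$protein_id == "cand"], "ortholog")
  # exact equidistance resolves to paralog (conservative)
  h3 <- mk_hits(hit_row("g1", "s1", "a1", -80, 1),
                hit_row("g1", "s2", "a2", -80, 1),
                hit_row("g1", "s3", "tie", -45, 1),
                hit_row("g1", "s1", "par", -10, 2))
  calls3 <- classify_orthologs(h3)
  expect_equal(calls3$verdict[calls3$protein_id == "tie"], "paralog")
})

test_that("classify_orthologs is idempotent and order-invariant", {
  ht <- make_hit_table(12, 8, 0.25, seed = 4)$hits
  c1 <- classify_orthologs(ht)
  c2 <- classify_orthologs(ht)
  shuffled <- hit_table(ht[with_seed_order(nrow(ht), 99), ])
  c3 <- classify_orthologs(shuffled)
  expect_identical(c1, c2)
  expect_identical(c1, c3)
})

test_that("QC thresholds follow the 42-of-44 rule with Mycoplasma relaxation", {
  mk_calls <- function(strain, n_ok) data.frame(
    gene_id = sprintf("U%02d", 1:44), strain_id = strain,
    protein_id = paste0(strain, 1:44), e_value = 1e-50,
    verdict = c(rep("ortholog", n_ok), rep("paralog", 44 - n_ok)))
  calls <- rbind(mk_calls("s41", 41), mk_calls("s40", 40), mk_calls("s44", 44))
  expect_setequal(qc_filter_strains(calls, 44, mycoplasma = FALSE), c("s44"))
  expect_setequal(qc_filter_strains(calls, 44, mycoplasma = TRUE),
                  c("s40", "s41", "s44"))
})

test_that("dedup removes near-identical strains, caps and floors counts", {
  ids <- sprintf("t%03d", 1:20)
  d <- matrix(0.01, 20, 20, dimnames = list(ids, ids)); diag(d) <- 0
  d["t001", "t002"] <- d["t002", "t001"] <- 0.00004
  res <- dedup_and_subsample(ids, d, seed = 1)
  expect_length(res$retained, 19)
  expect_length(intersect(c("t001", "t002"), res$retained), 1)
  # subsample down to max_strains
  ids2 <- sprintf("u%03d", 1:450)
  set.seed(11)
  m <- matrix(stats::runif(450 * 450, 0.001, 0.2), 450, 450,
              dimnames = list(ids2, ids2))
  m <- (m + t(m)) / 2; diag(m) <- 0
  res2 <- dedup_and_subsample(ids2, m, seed = 2)
  expect_length(res2$retained, 400)
  # below the 15-strain floor the species is excluded
  ids3 <- sprintf("v%02d", 1:14)
  d3 <- matrix(0.01, 14, 14, dimnames = list(ids3, ids3)); diag(d3) <- 0
  res3 <- dedup_and_subsample(ids3, d3, seed = 3)
  expect_true(res3$excluded)
  expect_length(res3$retained, 0)
  expect_error(dedup_and_subsample(ids3, d3 + upper.tri(d3) * 0.1, seed = 1),
               class = "validation_error")
})

test_that("BRH clustering enforces thresholds and transitivity", {
  ps <- data.frame(protein_id = c("A", "B", "C", "D", "E"),
                   strain_id = c("s1", "s2", "s3", "s1", "s2"))
  hit <- function(a, b, id, ca = 0.9, cb = 0.9)
    data.frame(protein_a = a, protein_b = b, percent_identity = id,
               coverage_a = ca, coverage_b = cb)
  # 69.9% identity rejected even when reciprocal
  fam <- cluster_brh_families(rbind(hit("A", "B", 69.9), hit("B", "A", 69.9)), ps)
  expect_equal(ncol(fam$presence), 5)  # all singletons
  # chain A-B, B-C accepted; A,B,C one family by transitivity
  fam2 <- cluster_brh_families(rbind(hit("A", "B", 90), hit("B", "A", 90),
                                     hit("B", "C", 85), hit("C", "B", 85)), ps)
  expect_equal(ncol(fam2$presence), 3)  # {A,B,C}, {D}, {E}
  big <- names(which(vapply(fam2$family_members, nrow, 1L) == 3))
  expect_setequal(fam2$family_members[[big]]$protein_id, c("A", "B", "C"))
  # low coverage rejected on either side
  fam3 <- cluster_brh_families(rbind(hit("A", "B", 90, ca = 0.7),
                                     hit("B", "A", 90)), ps)
  expect_equal(ncol(fam3$presence), 5)
  # no hits at all: N_pan = number of proteins
  expect_equal(pan_genome_stats(cluster_brh_families(hit("A", "B", 50)[0, ], ps))$n_pan, 5)
  # a protein assigned to two strains is an identifier error
  ps_bad <- rbind(ps, data.frame(protein_id = "A", strain_id = "s9"))
  expect_error(cluster_brh_families(hit("A", "B", 90), ps_bad),
               class = "identifier_error")
  # paralogous flag: two members from one strain
  ps4 <- data.frame(protein_id = c("A", "D", "B"), strain_id = c("s1", "s1", "s2"))
  fam4 <- cluster_brh_families(rbind(hit("A", "B", 90), hit("B", "A", 90),
                                     hit("D", "B", 88), hit("B", "D", 88)), ps4)
  # best hit from B to s1 is A (higher identity), so D-B is not reciprocal-best
  expect_equal(sum(fam4$paralogous_flags), 0)
})

test_that("family clustering equals brute-force connected components", {
  for (r in 1:5) {
    set.seed(100 + r)
    n <- 30
    ps <- data.frame(protein_id = sprintf("p%02d", 1:n),
                     strain_id = sprintf("s%02d", 1:n))  # one protein per strain
    pairs <- t(utils::combn(n, 2))
    take <- pairs[stats::runif(nrow(pairs)) < 0.05, , drop = FALSE]
    hits <- do.call(rbind, lapply(seq_len(nrow(take)), function(k) {
      a <- ps$protein_id[take[k, 1]]; b <- ps$protein_id[take[k, 2]]
      rbind(data.frame(protein_a = a, protein_b = b, percent_identity = 95,
                       coverage_a = 0.9, coverage_b = 0.9),
            data.frame(protein_a = b, protein_b = a, percent_identity = 95,
                       coverage_a = 0.9, coverage_b = 0.9))
    }))
    fam <- cluster_brh_families(hits, ps)
    # oracle: components by repeated neighborhood expansion
    adj <- lapply(1:n, function(i) integer(0))
    for (k in seq_len(nrow(take))) {
      adj[[take[k, 1]]] <- c(adj[[take[k, 1]]], take[k, 2])
      adj[[take[k, 2]]] <- c(adj[[take[k, 2]]], take[k, 1])
    }
    seen <- rep(FALSE, n); comps <- 0
    for (i in 1:n) {
      if (seen[i]) next
      comps <- comps + 1
      frontier <- i
      while (length(frontier)) {
        seen[frontier] <- TRUE
        frontier <- setdiff(unique(unlist(adj[frontier])), which(seen))
      }
    }
    expect_equal(ncol(fam$presence), comps)
  }
})

test_that("pan-genome statistics use the exact harmonic alpha", {
  mk <- function(n, npan) {
    m <- matrix(1L, n, npan,
                dimnames = list(sprintf("s%d", 1:n), sprintf("f%d", 1:npan)))
    gene_family_matrix(m)
  }
  st <- pan_genome_stats(mk(2, 100))
  expect_equal(st$alpha, 1)
  expect_equal(st$p_normalized, 100)
  expect_equal(pan_genome_stats(mk(13, 10))$alpha, 3.103211, tolerance = 1e-6)
  expect_equal(pan_genome_stats(mk(4, 11))$p_normalized, 6.0)
  expect_error(pan_genome_stats(mk(1, 5)), class = "argument_error")
})

test_that("divergence-maximizing subsample drops clones and private families", {
  n <- 15
  ids <- sprintf("s%02d", 1:n)
  pres <- matrix(1L, n, 20, dimnames = list(ids, sprintf("f%02d", 1:20)))
  pres["s01", 1:5] <- 0L
  gfm <- gene_family_matrix(pres)
  # star distances with one clone pair s01/s02
  d <- matrix(0.1, n, n, dimnames = list(ids, ids)); diag(d) <- 0
  d["s01", "s02"] <- d["s02", "s01"] <- 1e-6
  res <- subsample_pan(gfm, d, k = 14, seed = 5)
  expect_length(intersect(c("s01", "s02"), res$retained), 1)
  # n == k keeps everything: ps equals n_pan
  res2 <- subsample_pan(gfm, d, k = 15, seed = 1)
  expect_equal(res2$ps, 20)
  # families private to removed strains do not count
  pres2 <- pres; pres2[, "f20"] <- 0L; pres2["s02", "f20"] <- 1L
  gfm2 <- gene_family_matrix(pres2)
  set.seed(1)
  drop_s02 <- FALSE
  for (sd_ in 1:20) {  # one of the two clone members goes at random
    r <- subsample_pan(gfm2, d, k = 14, seed = sd_)
    if (!("s02" %in% r$retained)) { drop_s02 <- TRUE; expect_equal(r$ps, 19) }
  }
  expect_true(drop_s02)
  expect_false(subsample_pan(gfm, d, k = 16, seed = 1)$available)
})

test_that("core genome applies the 85% threshold and paralog exclusion", {
  ids <- sprintf("s%02d", 1:14)
  pres <- matrix(0L, 14, 3, dimnames = list(ids, c("f1", "f2", "f3")))
  pres[1:12, "f1"] <- 1L   # 85.7%
  pres[, "f2"] <- 1L       # 100% but paralogous
  pres[1:11, "f3"] <- 1L   # 78.6%
  members <- list(
    f1 = data.frame(strain_id = ids[1:12], protein_id = paste0("a", 1:12)),
    f2 = data.frame(strain_id = c(ids, "s01"), protein_id = paste0("b", 1:15)),
    f3 = data.frame(strain_id = ids[1:11], protein_id = paste0("c", 1:11)))
  gfm <- gene_family_matrix(pres, members)
  expect_identical(core_genome(gfm), "f1")
  # |core| non-increasing in threshold
  sizes <- vapply(c(0.5, 0.7, 0.85, 0.95, 1), function(th)
    length(core_genome(gfm, th)), 1L)
  expect_true(all(diff(sizes) <= 0))
})
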