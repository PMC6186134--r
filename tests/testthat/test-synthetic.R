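# synthetic_data: generators are deterministic under seed and match their
# distributional identities

test_that("coalescent genealogy matches the pairwise-diversity identity", {
  theta <- 0.02
  # n = 2: distance between the two tips is theta * Exp(1)
  dists <- vapply(1:1000, function(r) {
    tr <- simulate_strain_genealogy(2, theta, seed = r)
    sum(tr$edge.length)
  }, 1)
  se <- stats::sd(dists) / sqrt(length(dists))
  expect_lt(abs(mean(dists) - theta), 3 * se)
  expect_error(simulate_strain_genealogy(1, 0.01, 1), class = "argument_error")
  expect_error(simulate_strain_genealogy(5, 0, 1), class = "argument_error")
})

test_that("generators are seed-deterministic and seed-sensitive", {
  t1 <- simulate_strain_genealogy(8, 0.01, seed = 5)
  t2 <- simulate_strain_genealogy(8, 0.01, seed = 5)
  t3 <- simulate_strain_genealogy(8, 0.01, seed = 6)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
  a1 <- evolve_codon_alignment(t1, 0.5, 2, 50, seed = 9)
  a2 <- evolve_codon_alignment(t1, 0.5, 2, 50, seed = 9)
  a3 <- evolve_codon_alignment(t1, 0.5, 2, 50, seed = 10)
  expect_identical(unclass(a1), unclass(a2))
  expect_false(identical(unclass(a1), unclass(a3)))
  # the caller's RNG stream is untouched
  set.seed(123); before <- .Random.seed
  invisible(simulate_strain_genealogy(5, 0.01, seed = 42))
  expect_identical(before, .Random.seed)
})

test_that("codon evolution respects frame, time and omega ordering", {
  tr <- quartet_tree()
  tr0 <- tr; tr0$edge.length[] <- 0
  a0 <- evolve_codon_alignment(tr0, 0.5, 2, 40, seed = 1)
  expect_length(unique(unclass(a0)), 1)  # no time, no change
  expect_error(evolve_codon_alignment(tr, 0, 2, 10, 1), class = "argument_error")
  trn <- tr; trn$edge.length <- NULL
  expect_error(evolve_codon_alignment(trn, 0.5, 2, 10, 1),
               class = "argument_error")
  # omega ordering on a two-taxon tree (kappa = 1 so NG86 is unbiased)
  two <- ape::read.tree(text = "(a:0.15,b:0.15);")
  est <- vapply(c(0.1, 0.9), function(om) {
    vals <- vapply(1:8, function(r) {
      aln <- evolve_codon_alignment(two, om, 1, 3000, seed = 100 * om + r)
      pairwise_dnds(aln[[1]], aln[[2]])$dnds
    }, 1)
    mean(vals)
  }, 1)
  expect_lt(est[1], est[2])
  expect_lt(est[1], 0.3)
  expect_gt(est[2], 0.5)
})

test_that("gene-content simulation conserves event bookkeeping", {
  tr <- simulate_strain_genealogy(10, 0.1, seed = 3)
  # no events
  g0 <- simulate_gene_content(tr, 20, 0, 0, seed = 1)
  expect_true(all(g0$matrix$presence == 1L))
  expect_equal(nrow(g0$events), 0)
  # loss-only dynamics
  gl <- simulate_gene_content(tr, 200, 0, 3, seed = 2)
  expect_true(all(rowSums(gl$matrix$presence) <= 200))
  expect_setequal(unique(gl$events$event), "loss")
  expect_error(simulate_gene_content(tr, 10, 1, 0, seed = 1),
               class = "argument_error")
  # replay property: leaf presence equals replay of the event log
  for (r in 1:5) {
    g <- simulate_gene_content(tr, 30, 50, 1.5, seed = 10 + r)
    leaves <- replay_event_log(tr, g$root_families, g$events)
    for (s in rownames(g$matrix$presence)) {
      present <- colnames(g$matrix$presence)[g$matrix$presence[s, ] == 1L]
      expect_setequal(present, intersect(leaves[[s]],
                                         colnames(g$matrix$presence)))
    }
  }
})

test_that("gain counts match the Poisson mean identity", {
  tr <- quartet_tree()
  L <- sum(tr$edge.length)
  rate <- 4
  gains <- vapply(1:400, function(r)
    sum(simulate_gene_content(tr, 5, rate, 1e-9, seed = r)$events$event == "gain"),
    1)
  se <- stats::sd(gains) / sqrt(length(gains))
  expect_lt(abs(mean(gains) - rate * L), 3 * se)
})

test_that("recombination injection is logged and bounded", {
  tr <- simulate_strain_genealogy(6, 0.05, seed = 4)
  aln <- evolve_codon_alignment(tr, 0.5, 2, 200, seed = 5)
  r0 <- inject_recombination(aln, tr, 0, 50, seed = 1)
  expect_identical(unclass(r0$alignment), unclass(aln))
  expect_equal(nrow(r0$log), 0)
  # identical sequences transfer nothing
  same <- codon_alignment(c(x = "ATGATG", y = "ATGATG"))
  rs <- inject_recombination(same, NULL, 5, 3, seed = 2)
  expect_equal(nrow(rs$log), 0)
  expect_error(inject_recombination(aln, tr, 1, tract_length = 10000, seed = 1),
               class = "argument_error")
  # a single event leaves recipient identical to donor across its tract at
  # every logged site (later events may overwrite, so test one event)
  r1 <- inject_recombination(aln, tr, 1, 90, seed = 3)
  if (nrow(r1$log) > 0) {
    m_old <- do.call(rbind, strsplit(unclass(aln), ""))
    rownames(m_old) <- names(aln)
    m_new <- do.call(rbind, strsplit(unclass(r1$alignment), ""))
    rownames(m_new) <- names(r1$alignment)
    for (k in seq_len(nrow(r1$log))) {
      expect_equal(
        unname(m_new[r1$log$recipient_strain[k], r1$log$site_index[k]]),
        unname(m_new[r1$log$donor_strain[k], r1$log$site_index[k]]))
      # and the site really was polymorphic beforehand
      expect_false(m_old[r1$log$recipient_strain[k], r1$log$site_index[k]] ==
                     m_old[r1$log$donor_strain[k], r1$log$site_index[k]])
    }
  }
})

test_that("hit tables respect thresholds and truth labels", {
  ht0 <- make_hit_table(10, 20, 0, seed = 1)
  expect_true(all(ht0$truth$is_ortholog))
  expect_true(all(ht0$hits$e_value <= 1e-5))
  ht <- make_hit_table(10, 20, 0.3, seed = 2)
  expect_true(all(ht$hits$e_value <= 1e-5))
  expect_gt(mean(!ht$truth$is_ortholog), 0.15)
  expect_error(make_hit_table(5, 5, 1, seed = 1), class = "argument_error")
})

test_that("generate_dataset is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(tiny_config(n_species = 2), out_dir = d1)
  generate_dataset(tiny_config(n_species = 2), out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # every species loads cleanly and has the configured strain count
  for (sp in c("sp01", "sp02")) {
    ds <- load_species_dataset(file.path(d1, sp))
    expect_length(ds$strain_ids, 15)
  }
})
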