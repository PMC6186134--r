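# divergence_ne: NG86 counting, dS window, four-fold theta, nearly-neutral map

test_that("site counts match enumeration for representative codons", {
  expect_equal(unname(count_syn_nonsyn_sites("TTT")["s_sites"]), 1 / 3)
  expect_equal(unname(count_syn_nonsyn_sites("ATG")["s_sites"]), 0)
  expect_equal(unname(count_syn_nonsyn_sites("GGG")["s_sites"]), 1)
  # TAT: two of the three third-position neighbors are stops, excluded from
  # the denominator, so the position is fully synonymous
  expect_equal(unname(count_syn_nonsyn_sites("TAT")["s_sites"]), 1)
  expect_error(count_syn_nonsyn_sites("TAA"), class = "argument_error")
  # s + n == 3 always
  for (cd in c("AAA", "CGT", "TGG", "ATA"))
    expect_equal(sum(count_syn_nonsyn_sites(cd)), 3)
})

test_that("pairwise dN/dS handles canonical cases", {
  same <- pairwise_dnds("TTTAAA", "TTTAAA")
  expect_equal(same$ds, 0)
  expect_equal(same$dn, 0)
  expect_true(is.na(same$dnds))
  # one synonymous difference in a longer context (a lone codon saturates the
  # JC correction, which is flagged rather than estimated)
  one_syn <- pairwise_dnds("TTTAAAGGGCCC", "TTCAAAGGGCCC")
  expect_gt(one_syn$ds, 0)
  expect_equal(one_syn$dn, 0)
  expect_true(pairwise_dnds("TTT", "TTC")$saturated)
  expect_equal(unname(nepan:::ng86_path_counts("TTT", "TTC")), c(1, 0))
  expect_error(pairwise_dnds("TTT", "TTTAAA"), class = "argument_error")
  # gapped/ambiguous codons are skipped
  gap <- pairwise_dnds("TTT---AAA", "TTTAAAAAA")
  expect_equal(gap$n_codons_used, 2)
})

test_that("pathway averaging equals brute-force enumeration on sampled pairs", {
  env <- nepan:::ng86_tables()
  sense <- env$sense
  set.seed(42)
  for (k in 1:120) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    got <- nepan:::ng86_path_counts(c1, c2)
    want <- oracle_path_counts(c1, c2)
    expect_equal(unname(got), unname(want), tolerance = 1e-12,
                 label = paste(c1, c2))
  }
})

test_that("NG86 is unbiased at neutrality (omega = 1, kappa = 1)", {
  two <- ape::read.tree(text = "(a:0.1,b:0.1);")
  vals <- vapply(1:200, function(r) {
    aln <- evolve_codon_alignment(two, 1, 1, 800, seed = 4000 + r)
    pairwise_dnds(aln[[1]], aln[[2]])$dnds
  }, 1)
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 3 * se)
})

test_that("species averaging respects the inclusive dS window", {
  pairs <- data.frame(ds = c(0.05, 0.2, 0.31), dnds = c(0.5, 0.25, 0.9))
  res <- species_dsdn(pairs)
  expect_equal(res$n_pairs_in_window, 1)
  expect_equal(res$mean_dnds, 0.25)
  # inclusive bounds
  pairs2 <- data.frame(ds = c(0.1, 0.3), dnds = c(0.10, 0.30))
  res2 <- species_dsdn(pairs2)
  expect_equal(res2$n_pairs_in_window, 2)
  expect_equal(res2$mean_dnds, 0.20)
  expect_equal(res2$mean_dsdn, 5.0)
  # no qualifying pair: excluded flag
  res3 <- species_dsdn(data.frame(ds = c(0.01, 0.05), dnds = c(0.5, 0.5)))
  expect_true(res3$excluded)
  # order invariance
  res4 <- species_dsdn(pairs2[2:1, ])
  expect_equal(res4$mean_dnds, res2$mean_dnds)
})

test_that("four-fold site detection requires degeneracy in every row", {
  aln <- codon_alignment(c(a = "GGATTTGCA", b = "GGGTTCGCC"))
  ff <- fourfold_sites(aln)
  # codon 1 GGN (Gly, 4-fold) and codon 3 GCN (Ala, 4-fold); TTN is not
  expect_equal(ff, c(3L, 9L))
  mixed <- codon_alignment(c(a = "GGA", b = "TTA"))  # TTA context is 2-fold
  expect_length(fourfold_sites(mixed), 0)
  gapped <- codon_alignment(c(a = "GG-", b = "GGA"))
  expect_length(fourfold_sites(gapped), 0)
  expect_length(fourfold_sites(codon_alignment(character(0))), 0)
})

test_that("Watterson's estimator matches its closed form", {
  m <- matrix("A", 5, 100)
  m[1, 1:4] <- "G"  # 4 segregating columns
  expect_equal(watterson_theta(m), 4 / ((25 / 12) * 100), tolerance = 1e-12)
  expect_equal(watterson_theta(matrix("C", 4, 50)), 0)
  m2 <- matrix(c("A", "G"), 2, 10)
  m2[2, ] <- "A"; m2[2, 1] <- "G"; m2[1, ] <- "A"
  expect_equal(watterson_theta(m2), 1 / 10)  # n = 2: a_n = 1
  expect_error(watterson_theta(matrix("A", 1, 5)), class = "argument_error")
})

test_that("theta converts to Ne and back", {
  expect_equal(ne_from_theta(0.0192, 1e-9), 9.6e6)
  expect_equal(ne_from_theta(0, 1e-9), 0)
  expect_equal(ne_from_theta(0.01, 2e-9), ne_from_theta(0.01, 1e-9) / 2)
  expect_error(ne_from_theta(0.01, 0), class = "argument_error")
})

test_that("the nearly-neutral map is stable, monotone and invertible", {
  expect_equal(nearly_neutral_map(0), 1)
  expect_equal(nearly_neutral_map(-1e-9), 1, tolerance = 1e-8)
  expect_equal(nearly_neutral_map(-2), 0.313035, tolerance = 1e-6)
  grid <- -exp(seq(log(1e-6), log(50), length.out = 200))
  vals <- nearly_neutral_map(sort(grid))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals < 1))
  # underflow-safe far tail
  expect_gt(nearly_neutral_map(-700), 0)
})

test_that("calibration and inversion recover each other", {
  # forward x = -2 at Ne = 2e8 implies s = -1e-8
  cal <- data.frame(mean_dnds = nearly_neutral_map(-2), ne_absolute = 2e8)
  expect_equal(calibrate_s(cal), -1e-8, tolerance = 1e-6)
  # mean of identical species equals the single-species value
  expect_equal(calibrate_s(rbind(cal, cal)), calibrate_s(cal))
  # dnds >= 1 is skipped with a warning, errors when nothing remains
  expect_warning(s2 <- calibrate_s(rbind(cal, data.frame(mean_dnds = 1,
                                                         ne_absolute = 1e8))))
  expect_equal(s2, -1e-8, tolerance = 1e-6)
  expect_error(suppressWarnings(
    calibrate_s(data.frame(mean_dnds = 1, ne_absolute = 1e8))))
  expect_equal(ne_from_dnds(nearly_neutral_map(-2), -1e-8), 2e8,
               tolerance = 1e-8)
  expect_warning(expect_true(is.na(ne_from_dnds(1.2, -1e-8))))
  # monotone: f decreases in Ne at fixed s < 0, so smaller dN/dS maps to a
  # LARGER Ne (stronger purifying selection needs a bigger population)
  expect_gt(ne_from_dnds(0.2, -1e-8), ne_from_dnds(0.4, -1e-8))
})
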