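test_that("placements are uniform over coding bases and conserve counts", {
  models <- gene_model_table(c("A", "B"),
                             c(paste(rep("M", 100), collapse = ""),
                               paste(rep("M", 50), collapse = "")))
  # single-codon gene: every placement lands on residue 1
  one <- gene_model_table("solo", "M")
  set.seed(1)
  p <- permute_placements(one, c(solo = 5L))
  expect_true(all(p$residue == 1L))

  # count conservation per gene
  set.seed(2)
  p <- permute_placements(models, c(A = 2L, B = 1L))
  expect_equal(sum(p$gene_id == "A"), 2L)
  expect_equal(sum(p$gene_id == "B"), 1L)
  expect_error(permute_placements(models, c(Z = 1L)), "named by gene ids")

  # uniformity over residues: chi-square on 1e5 draws over 100 codons
  set.seed(5)
  draws <- permute_placements(models, c(A = 100000L))
  tab <- tabulate(draws$residue, nbins = 100)
  expect_gt(chisq.test(tab)$p.value, 0.001)
  # and base-level positions cover the full coding range
  expect_gte(min(draws$cdna_pos), 1L)
  expect_lte(max(draws$cdna_pos), 300L)
})

test_that("Monte-Carlo p agrees with closed-form and brute-force enumeration", {
  # two mutations in one 1000-codon gene, threshold 10:
  # favourable ordered residue pairs = 1000 + 2 * sum_{d=1..9} (1000 - d)
  seqs <- paste(rep("M", 1000), collapse = "")
  models <- gene_model_table(c("A", "B"), c(seqs, seqs))
  aln <- paralog_alignment(c(A = seqs, B = seqs))
  p_exact <- (1000 + 2 * sum(1000 - (1:9))) / 1000^2
  expect_equal(p_exact, 0.01891)
  expect_equal(cluster_exact_p(models, aln, c(A = 2L), 10L), p_exact,
               tolerance = 1e-12)

  obs <- data.frame(gene_id = c("A", "A"), residue = c(100L, 104L))
  ct <- cluster_permutation_test(models, aln, obs, n_permutations = 1e5,
                                 window = 10L, seed = 3)
  expect_equal(ct$observed_span, 5L)
  expect_equal(ct$threshold, 10L)
  se <- sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(ct$p_value - p_exact), 3 * se)

  # tiny gapped family: closed form equals residue-grid brute force
  fam <- generate_paralog_family(2, 12, divergence = 0.2, indel_rate = 0.1,
                                 seed = 4)
  counts <- setNames(c(2L, 1L), fam$models$gene_id)
  for (t in c(1L, 3L, 6L)) {
    expect_equal(
      cluster_exact_p(fam$models, fam$alignment, counts, t),
      cluster_brute_force_p(fam$models, fam$alignment, counts, t),
      tolerance = 1e-12)
  }
})

test_that("small instances match exact enumeration at one million permutations", {
  fam <- generate_paralog_family(3, 60, divergence = 0.15, indel_rate = 0.05,
                                 seed = 17)
  obs <- data.frame(gene_id = fam$models$gene_id[c(1, 1, 2, 3)],
                    residue = c(10L, 20L, 15L, 40L))
  ct <- cluster_permutation_test(fam$models, fam$alignment, obs,
                                 n_permutations = 1e6, window = 9L,
                                 seed = 23)
  counts <- setNames(as.integer(table(obs$gene_id)),
                     names(table(obs$gene_id)))
  p_exact <- cluster_exact_p(fam$models, fam$alignment, counts,
                             ct$threshold)
  se <- sqrt(p_exact * (1 - p_exact) / 1e6)
  expect_lt(abs(ct$p_value - p_exact), 4 * se)
})

test_that("degenerate geometry gives certainty", {
  # one gene of three codons: every pair of placements spans <= 3
  models <- gene_model_table("G", "MMM")
  aln <- paralog_alignment(c(G = "MMM"))
  obs <- data.frame(gene_id = c("G", "G"), residue = c(1L, 3L))
  ct <- cluster_permutation_test(models, aln, obs, n_permutations = 1000,
                                 window = 3L, seed = 2)
  expect_equal(ct$p_value, 1)
  # coincident mutations: observed span 1
  obs1 <- data.frame(gene_id = c("G", "G"), residue = c(2L, 2L))
  ct1 <- cluster_permutation_test(models, aln, obs1, n_permutations = 1000,
                                  window = 1L, seed = 2)
  expect_equal(ct1$observed_span, 1L)
})

test_that("the permutation test is seed-reproducible", {
  fam <- generate_paralog_family(3, 100, divergence = 0.1, indel_rate = 0.03,
                                 seed = 5)
  obs <- data.frame(gene_id = fam$models$gene_id[c(1, 2, 3)],
                    residue = c(30L, 35L, 40L))
  a <- cluster_permutation_test(fam$models, fam$alignment, obs,
                                n_permutations = 2e4, seed = 99)
  b <- cluster_permutation_test(fam$models, fam$alignment, obs,
                                n_permutations = 2e4, seed = 99)
  expect_identical(a$n_success, b$n_success)
  # block size is internal bookkeeping, not part of the contract's inputs
  c2 <- cluster_permutation_test(fam$models, fam$alignment, obs,
                                 n_permutations = 2e4, seed = 100)
  expect_s3_class(c2, "cluster_test_result")
})

test_that("null-drawn observations give approximately uniform p-values", {
  fam <- synthetic_b56_family()
  counts <- c(PPP2R5B = 1L, PPP2R5C = 1L, PPP2R5D = 2L)
  set.seed(310)
  seeds <- sample.int(1e6, 500)
  pvals <- vapply(seq_len(500), function(i) {
    obs <- permute_placements(fam$models, counts)
    cluster_permutation_test(fam$models, fam$alignment, obs,
                             n_permutations = 2000, window = 9L,
                             seed = seeds[i])$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.001)
})

test_that("a planted nine-column cluster is detected at p below 1e-3", {
  fam <- synthetic_b56_family()
  expect_gte(fam$alignment$width, 500L)
  obs <- b56_observed_mutations()
  expect_equal(aligned_span(fam$alignment, obs), 9L)
  ct <- cluster_permutation_test(fam$models, fam$alignment, obs,
                                 n_permutations = 1e6, window = 9L,
                                 seed = 12)
  expect_lt(ct$p_value, 1e-3)
  # conservative estimator never reports zero
  ct1 <- cluster_permutation_test(fam$models, fam$alignment, obs,
                                  n_permutations = 1e4, window = 9L,
                                  seed = 12, add_one = TRUE)
  expect_gt(ct1$p_value, 0)
})
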