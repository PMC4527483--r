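test_that("kinship estimator recovers the canonical values", {
  # identical samples: kinship exactly 0.5
  set.seed(19)
  gts <- sample(c("hom_ref", "het", "hom_alt"), 200, replace = TRUE,
                prob = c(0.25, 0.5, 0.25))
  mk <- function(id) data.frame(sample_id = id, chrom = "G",
                                pos = seq_along(gts), ref = "A", alt = "C",
                                genotype = gts, stringsAsFactors = FALSE)
  rep_same <- estimate_relatedness(mk("s1"), mk("s2"))
  expect_equal(rep_same$kinship, 0.5)
  expect_equal(rep_same$opposite_homozygote_rate, 0)

  # simulated parent/offspring: zero opposite homozygotes, kinship ~ 0.25
  coh <- small_cohort(n_trios = 1, rate = 0, nbg = 3000, seed = 11,
                      genes = big_genes())
  pc <- coh$calls[coh$calls$sample_id == "P0001", ]
  mc <- coh$calls[coh$calls$sample_id == "M0001", ]
  fc <- coh$calls[coh$calls$sample_id == "F0001", ]
  for (parent in list(mc, fc)) {
    r <- estimate_relatedness(pc, parent)
    expect_equal(r$opposite_homozygote_rate, 0)
    expect_gte(r$kinship, 0.177); expect_lte(r$kinship, 0.354)
    expect_equal(r$verdict, "parent_offspring_consistent")
  }

  # the two parents are unrelated: kinship within +/- 0.05 of zero
  coh10k <- small_cohort(n_trios = 1, rate = 0, nbg = 10000, seed = 11,
                       genes = big_genes())
  mc <- coh10k$calls[coh10k$calls$sample_id == "M0001", ]
  fc <- coh10k$calls[coh10k$calls$sample_id == "F0001", ]
  unrel <- estimate_relatedness(mc, fc)
  expect_lt(abs(unrel$kinship), 0.05)
  expect_equal(unrel$verdict, "inconsistent")

  # too few shared sites is an error, not a verdict
  expect_error(estimate_relatedness(mk("s1")[1:10, ], mk("s2")[1:10, ]),
               "insufficient shared sites")
})

test_that("de novo filter applies read-support, carriage and coverage rules", {
  site <- function(sample, gt, dp, ad, pos = 30L)
    data.frame(sample_id = sample, chrom = "GA", pos = pos, ref = "G",
               alt = "A", genotype = gt, depth = dp, alt_reads = ad,
               stringsAsFactors = FALSE)
  base <- rbind(site("kid", "het", 30L, 15L),
                site("mum", "hom_ref", 30L, 0L),
                site("dad", "hom_ref", 30L, 0L))
  call <- function(calls, ...)
    call_de_novo_candidates(calls, "kid", "mum", "dad",
                            check_relatedness = FALSE, ...)
  expect_equal(nrow(call(base)), 1L)

  # proband support below three reads: removed
  low <- base; low$alt_reads[1] <- 2L
  expect_equal(nrow(call(low)), 0L)
  expect_equal(nrow(call(low, min_alt_reads = 2L)), 1L)

  # allele present in a parent: removed however well-supported
  inherited <- base
  inherited$genotype[2] <- "het"; inherited$alt_reads[2] <- 14L
  expect_equal(nrow(call(inherited)), 0L)

  # parent under-covered: cannot exclude inheritance, removed
  shallow <- base; shallow$depth[3] <- 5L
  expect_equal(nrow(call(shallow)), 0L)
  expect_equal(nrow(call(shallow, min_parent_depth = 5L)), 1L)

  # parent record missing entirely: treated as under-covered
  expect_equal(nrow(call(base[1:2, ])), 0L)

  # candidate coordinates: cdna = pos, protein = ceiling(cdna / 3)
  got <- call(base)
  expect_equal(got$cdna_pos, 30L)
  expect_equal(got$protein_pos, 10L)
  expect_equal(got$alt_fraction, 0.5)
})

test_that("candidate calling recovers the simulated truth table exactly", {
  coh <- small_cohort(n_trios = 500, rate = 2e-3, nbg = 60, seed = 42)
  cand <- call_cohort_de_novo(coh, min_parent_depth = 1L)
  got <- sort(paste(cand$trio_id, cand$gene_id, cand$cdna_pos))
  want <- sort(paste(coh$truth$trio_id, coh$truth$gene_id,
                     coh$truth$cdna_pos))
  expect_identical(got, want)   # precision = recall = 1
})

test_that("raising filter thresholds never adds candidates", {
  coh <- small_cohort(n_trios = 60, rate = 8e-3, nbg = 40, mean_depth = 8,
                      seed = 13)
  key <- function(d) paste(d$trio_id, d$chrom, d$pos)
  prev <- NULL
  for (mar in 1:6) {
    cur <- call_cohort_de_novo(coh, min_alt_reads = mar,
                               min_parent_depth = 1L)
    if (!is.null(prev)) expect_true(all(key(cur) %in% prev))
    prev <- key(cur)
  }
  prev <- NULL
  for (mpd in c(1L, 4L, 7L, 10L, 14L)) {
    cur <- call_cohort_de_novo(coh, min_parent_depth = mpd)
    if (!is.null(prev)) expect_true(all(key(cur) %in% prev))
    prev <- key(cur)
  }
})

test_that("parentage failure blocks candidate calling", {
  coh <- small_cohort(n_trios = 2, rate = 0, nbg = 500, seed = 31)
  # true trio passes with the check on
  expect_silent(call_de_novo_candidates(coh$calls, "P0001", "M0001",
                                        "F0001"))
  # swap in an unrelated "father" from the other trio
  expect_error(call_de_novo_candidates(coh$calls, "P0001", "M0001",
                                       "F0002"),
               "parentage check failed")
})

test_that("mosaicism test matches the exact binomial and flags one-sided", {
  r <- assess_mosaicism(10, 20)
  expect_equal(r$alt_fraction, 0.5)
  expect_equal(r$p_value, 1.0)
  expect_false(r$flagged)

  # frozen against full pmf enumeration (minlike two-sided)
  r <- assess_mosaicism(3, 30)
  expect_equal(r$p_value, 8.430332e-06, tolerance = 1e-6)
  expect_equal(r$p_value, binom_two_sided_oracle(3, 30), tolerance = 1e-12)
  expect_true(r$flagged)

  # alt excess is never called mosaic, whatever the p-value
  r <- assess_mosaicism(c(12, 27), c(20, 30))
  expect_false(any(r$flagged))

  # shallow sites get no verdict
  r <- assess_mosaicism(2, 8)
  expect_true(r$insufficient_depth)
  expect_true(is.na(r$p_value))
  expect_error(assess_mosaicism(9, 5), "alt_reads <= depth")
})

test_that("mosaicism test is conservative under the heterozygous null", {
  set.seed(202)
  depth <- 30L
  alt <- rbinom(2000, depth, 0.5)
  r <- assess_mosaicism(alt, rep(depth, 2000))
  reject <- mean(r$p_value < 0.05)
  expect_lte(reject, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})
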