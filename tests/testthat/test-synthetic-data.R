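test_that("paralog family simulation yields the true alignment it logs", {
  # no mutation: identical sequences, gap-free alignment
  fam0 <- generate_paralog_family(3, 50, divergence = 0, indel_rate = 0,
                                  seed = 1)
  expect_equal(length(unique(fam0$models$protein_sequence)), 1L)
  expect_false(any(grepl("-", fam0$alignment$aligned, fixed = TRUE)))

  # no indels: width equals ancestor length and residue i sits in column i
  fam1 <- generate_paralog_family(4, 80, divergence = 0.3, indel_rate = 0,
                                  seed = 2)
  expect_equal(fam1$alignment$width, 80L)
  for (g in fam1$alignment$gene_ids)
    expect_equal(residue_to_column(fam1$alignment, g, 1:80), 1:80)

  # with indels: width = ancestor + total insertions; every residue's
  # column matches an independent replay of the logged event history
  fam <- generate_paralog_family(3, 200, divergence = 0.1,
                                 indel_rate = 0.02, seed = 7)
  n_ins <- sum(vapply(fam$history, function(h) length(h$insert_after),
                      integer(1)))
  expect_equal(fam$alignment$width, 200L + n_ins)
  replay <- reconstruct_col_maps(fam, 200L)
  expect_identical(unname(fam$alignment$col_map), replay)

  # round trip: residue -> column -> residue is the identity
  for (g in fam$alignment$gene_ids) {
    map <- fam$alignment$col_map[[g]]
    res <- seq_along(map)
    expect_identical(match(residue_to_column(fam$alignment, g, res), map),
                     res)
  }

  expect_error(generate_paralog_family(3, 5, 0.1, 0.02, 1), "ancestor_length")
  expect_error(generate_paralog_family(3, 50, 0.9, 0.02, 1), "divergence")
  expect_error(generate_paralog_family(3, 50, 0.1, 0.5, 1), "indel_rate")
})

test_that("trio cohorts plant de novo events with the promised structure", {
  # zero rates: nothing planted
  genes <- tiny_genes()
  cfg0 <- simulation_config(5, genes,
                            rate_per_gene = c(GA = 0, GB = 0, GC = 0),
                            n_background_sites = 10, seed = 3)
  expect_equal(nrow(generate_trio_cohort(cfg0)$truth), 0L)

  # planted events: proband het, both parents hom-ref with depth >= 1
  coh <- small_cohort(n_trios = 80, rate = 5e-3, nbg = 20, seed = 5)
  expect_gt(nrow(coh$truth), 0L)
  for (r in seq_len(nrow(coh$truth))) {
    tr <- coh$trios[coh$trios$trio_id == coh$truth$trio_id[r], ]
    site <- coh$calls[coh$calls$chrom == coh$truth$gene_id[r] &
                        coh$calls$pos == coh$truth$cdna_pos[r], ]
    expect_equal(site$genotype[site$sample_id == tr$proband], "het")
    expect_equal(site$genotype[site$sample_id == tr$mother], "hom_ref")
    expect_equal(site$genotype[site$sample_id == tr$father], "hom_ref")
    expect_true(all(site$depth >= 1L))
  }

  # cohort-wide planted count ~ Binomial(2 * n_trios, mu): 3 sd check
  cfg <- simulation_config(5000, data.frame(gene_id = "G", cds_length = 999L),
                           rate_per_gene = c(G = 1e-3),
                           n_background_sites = 0, seed = 1)
  k <- nrow(generate_trio_cohort(cfg)$truth)
  expect_lt(abs(k - 10), 3 * sqrt(2 * 5000 * 1e-3 * (1 - 1e-3)))

  # alt reads at het calls are Binomial(depth, 0.5): mean fraction near 0.5
  hets <- coh$calls[coh$calls$genotype == "het", ]
  expect_lt(abs(mean(hets$alt_reads / hets$depth) - 0.5), 0.02)
  expect_true(all(hets$alt_reads >= 0 & hets$alt_reads <= hets$depth))
})

test_that("non-planted variants are Mendelian-consistent by construction", {
  coh <- small_cohort(n_trios = 40, rate = 5e-3, nbg = 50, seed = 8)
  expect_equal(count_mendelian_violations(coh), 0L)
})

test_that("identical configs reproduce byte-identical outputs", {
  cfg <- simulation_config(10, tiny_genes(),
                           rate_per_gene = c(GA = 1e-3, GB = 1e-3, GC = 1e-3),
                           n_background_sites = 30, seed = 77)
  a <- generate_trio_cohort(cfg)
  b <- generate_trio_cohort(cfg)
  expect_identical(a, b)
  fa <- tempfile(fileext = ".vcf"); fb <- tempfile(fileext = ".vcf")
  write_cohort_vcf(a, fa); write_cohort_vcf(b, fb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
})

test_that("control cohorts hit the requested carrier fraction", {
  cfg <- simulation_config(2, tiny_genes(),
                           rate_per_gene = c(GA = 1e-4, GB = 1e-4, GC = 1e-4),
                           n_controls = 1000, seed = 3)
  expect_equal(sum(generate_control_cohort(cfg, 0)$carrier), 0L)
  expect_equal(sum(generate_control_cohort(cfg, 1)$carrier), 1000L)
  k <- sum(generate_control_cohort(cfg, 0.01)$carrier)
  expect_gte(k, qbinom(0.005, 1000, 0.01))
  expect_lte(k, qbinom(0.995, 1000, 0.01))
  expect_error(generate_control_cohort(cfg, 1.5), "carrier_fraction")
})

test_that("cohorts survive the VCF and TSV round trips", {
  coh <- small_cohort(n_trios = 6, rate = 1e-2, nbg = 15, seed = 21)
  sorted <- coh$calls[order(coh$calls$chrom, coh$calls$pos,
                            coh$calls$sample_id), ]
  rownames(sorted) <- NULL

  vcf <- tempfile(fileext = ".vcf")
  write_cohort_vcf(coh, vcf)
  expect_equal(readLines(vcf, n = 1), "##fileformat=VCFv4.2")
  expect_equal(read_variant_vcf(vcf), sorted)

  tsv <- tempfile(fileext = ".tsv")
  write_variant_tsv(coh$calls, tsv)
  expect_equal(read_variant_tsv(tsv), coh$calls)

  rates <- synthetic_rate_table(data.frame(gene_id = c("a", "b"),
                                           cds_length = c(300L, 600L)))
  rt <- tempfile(fileext = ".tsv")
  write_rate_table(rates, rt)
  expect_equal(read_rate_table(rt), rates)
})

test_that("configuration validation rejects malformed inputs", {
  genes <- tiny_genes()
  rates <- c(GA = 1e-4, GB = 1e-4, GC = 1e-4)
  expect_error(simulation_config(0, genes, rates), "n_trios")
  bad <- genes; bad$cds_length[1] <- 100L  # not a multiple of 3
  expect_error(simulation_config(5, bad, rates), "multiples of 3")
  expect_error(simulation_config(5, genes, c(GA = 1e-4, GB = 1e-4)),
               "one rate per gene")
  expect_error(simulation_config(5, genes, replace(rates, 1, 1.2)), "rates")
})
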