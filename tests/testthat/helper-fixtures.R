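# Shared fixtures and independent oracles for the test suite.

tiny_genes <- function() {
  data.frame(gene_id = c("GA", "GB", "GC"),
             cds_length = c(1500L, 900L, 1200L),
             stringsAsFactors = FALSE)
}

# larger coding space for cohorts with many background polymorphisms
big_genes <- function() {
  data.frame(gene_id = c("GA", "GB", "GC"),
             cds_length = c(15000L, 9000L, 12000L),
             stringsAsFactors = FALSE)
}

small_cohort <- function(n_trios = 50, rate = 2e-3, nbg = 60,
                         mean_depth = 40, seed = 42, genes = tiny_genes(),
                         planted_cluster = NULL) {
  cfg <- simulation_config(
    n_trios = n_trios, genes = genes,
    rate_per_gene = stats::setNames(rep(rate, nrow(genes)), genes$gene_id),
    n_background_sites = nbg, mean_depth = mean_depth,
    planted_cluster = planted_cluster, seed = seed)
  generate_trio_cohort(cfg)
}

# Mendelian-violation count over non-planted sites: any child genotype that
# cannot arise from the parental pair.
count_mendelian_violations <- function(cohort) {
  calls <- cohort$calls
  truth_key <- paste(cohort$truth$gene_id, cohort$truth$cdna_pos)
  viol <- 0L
  for (i in seq_len(nrow(cohort$trios))) {
    t <- cohort$trios[i, ]
    pc <- calls[calls$sample_id == t$proband, ]
    mc <- calls[calls$sample_id == t$mother, ]
    fc <- calls[calls$sample_id == t$father, ]
    key <- function(d) paste(d$chrom, d$pos)
    im <- match(key(pc), key(mc)); if_ <- match(key(pc), key(fc))
    keep <- !(key(pc) %in% truth_key) & !is.na(im) & !is.na(if_)
    dose <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
    p <- dose[pc$genotype[keep]]
    m <- dose[mc$genotype[im[keep]]]
    f <- dose[fc$genotype[if_[keep]]]
    # feasible child doses given parental doses
    min_d <- (m == 2L) + (f == 2L)
    max_d <- (m > 0L) + (f > 0L)
    viol <- viol + sum(p < min_d | p > max_d)
  }
  viol
}

# Independent reconstruction of each gene's residue -> column map from the
# simulator's event history (never touches the aligned strings).
reconstruct_col_maps <- function(family, ancestor_length) {
  hist <- family$history
  gene_ids <- names(hist)
  L <- ancestor_length
  ins_flag <- sapply(gene_ids, function(g) {
    v <- logical(L); v[hist[[g]]$insert_after] <- TRUE; v
  })                                     # L x n_genes
  ins_per_pos <- rowSums(ins_flag)
  # column of ancestral position i = i + insertions after earlier positions
  col_anc <- seq_len(L) + as.integer(c(0, cumsum(ins_per_pos))[seq_len(L)])
  lapply(gene_ids, function(g) {
    h <- hist[[g]]
    gi <- match(g, gene_ids)
    cols <- integer(0)
    for (i in seq_len(L)) {
      if (!(i %in% h$deleted)) cols <- c(cols, col_anc[i])
      if (ins_flag[i, gi]) {
        before <- if (gi > 1L) sum(ins_flag[i, seq_len(gi - 1L)]) else 0L
        cols <- c(cols, col_anc[i] + 1L + before)
      }
    }
    cols
  })
}

# Two-sided exact binomial p against 0.5 by full pmf enumeration (minlike).
binom_two_sided_oracle <- function(k, n) {
  pk <- stats::dbinom(0:n, n, 0.5)
  sum(pk[pk <= pk[k + 1L] * (1 + 1e-12)])
}

# Two-sided Fisher p by explicit hypergeometric enumeration via lchoose.
fisher_oracle <- function(a, m, b, n) {
  k <- a + b
  x <- max(0L, k - n):min(k, m)
  lp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  p <- exp(lp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, b) - lchoose(m + n, k))
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Upper Poisson tail by direct log-space pmf summation (60 terms).
poisson_tail_oracle <- function(lambda, k) {
  i <- k:(k + 60L)
  sum(exp(i * log(lambda) - lambda - lgamma(i + 1)))
}

# Brute-force clustered-span probability by residue-grid enumeration
# (feasible only for tiny gene sets).
cluster_brute_force_p <- function(models, alignment, counts, threshold) {
  counts <- counts[counts > 0]
  draws <- list()
  for (g in names(counts)) {
    map <- alignment$col_map[[g]]
    for (j in seq_len(counts[[g]])) draws[[length(draws) + 1L]] <- map
  }
  grid <- do.call(expand.grid, draws)
  span <- apply(grid, 1L, function(r) max(r) - min(r) + 1L)
  mean(span <= threshold)
}
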