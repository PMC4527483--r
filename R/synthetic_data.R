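AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration for trio cohorts
#'
#' Bundles and validates everything the cohort generator needs: cohort
#' sizes, the gene set with coding lengths, per-gene per-transmission de
#' novo rates, the number of inherited polymorphic background sites, mean
#' sequencing depth and the RNG seed. The same config (same seed) always
#' reproduces byte-identical cohorts.
#'
#' @param n_trios number of proband-mother-father trios (>= 1).
#' @param genes `data.frame` with columns `gene_id`, `cds_length`; coding
#'   lengths must be positive multiples of 3.
#' @param rate_per_gene named numeric, per-transmission de novo mutation
#'   probability for each gene (all in (0, 1); a gene set rate of 0 is
#'   allowed and simply plants nothing). Names must match `genes$gene_id`.
#' @param n_controls number of control samples for [generate_control_cohort()].
#' @param n_background_sites inherited polymorphic sites shared across the
#'   cohort (allele frequency 0.5), used for relatedness checks and for
#'   exercising the Mendelian filters.
#' @param mean_depth mean of the per-call Poisson depth (floored at 1 read).
#' @param planted_cluster optional `data.frame` with columns `gene_id`,
#'   `residue`: extra de novo events planted at those residues (one per
#'   randomly chosen trio), used to create a true clustering signal.
#' @param seed integer RNG seed.
#' @return a validated object of class `simulation_config`.
#' @export
simulation_config <- function(n_trios, genes, rate_per_gene,
                              n_controls = 0L, n_background_sites = 100L,
                              mean_depth = 40, planted_cluster = NULL,
                              seed = 1L) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "cds_length") %in% names(genes)))
  if (n_trios < 1L) stop("n_trios must be >= 1")
  if (any(genes$cds_length <= 0L) || any(genes$cds_length %% 3L != 0L))
    stop("coding lengths must be positive multiples of 3")
  if (is.null(names(rate_per_gene)) ||
      !setequal(names(rate_per_gene), genes$gene_id))
    stop("rate_per_gene must be named by gene_id, one rate per gene")
  if (any(rate_per_gene < 0) || any(rate_per_gene >= 1))
    stop("rates must lie in [0, 1)")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (!is.null(planted_cluster)) {
    stopifnot(is.data.frame(planted_cluster),
              all(c("gene_id", "residue") %in% names(planted_cluster)),
              all(planted_cluster$gene_id %in% genes$gene_id))
  }
  structure(
    list(n_trios = as.integer(n_trios), n_controls = as.integer(n_controls),
         genes = genes[, c("gene_id", "cds_length")],
         rate_per_gene = rate_per_gene[match(genes$gene_id,
                                             names(rate_per_gene))],
         n_background_sites = as.integer(n_background_sites),
         mean_depth = mean_depth, planted_cluster = planted_cluster,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# depth ~ Poisson(mean), floored at 1 so every call has at least one read
sim_depth <- function(n, mean_depth) pmax(1L, stats::rpois(n, mean_depth))

# alt-read count given genotype and depth; no sequencing error is simulated
sim_alt_reads <- function(genotype, depth) {
  ifelse(genotype == "het", stats::rbinom(length(depth), depth, 0.5),
         ifelse(genotype == "hom_alt", depth, 0L))
}

random_base_pair <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  data.frame(ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

#' Generate a simulated trio cohort with planted de novo mutations
#'
#' Each trio contributes two transmissions, and within every transmission a
#' de novo event arises in gene g with probability `rate_per_gene[g]`,
#' placed uniformly over the gene's coding bases; so the cohort-wide planted
#' count per gene is Binomial(2 * n_trios, rate) by construction. Planted
#' events appear as heterozygous calls in the proband and hom-ref calls
#' (with simulated depth) in both parents. Background sites are biallelic
#' polymorphisms at allele frequency 0.5: parental genotypes are drawn in
#' Hardy-Weinberg proportions and the proband inherits one allele from each
#' parent, so non-planted variants are Mendelian-consistent by construction.
#' Heterozygous calls carry alt reads ~ Binomial(depth, 0.5); depth is
#' Poisson(`mean_depth`) floored at one read.
#'
#' Coordinates: each gene is its own contig, `chrom == gene_id` and `pos` is
#' the 1-based coding base, so `pos` doubles as the cDNA position.
#'
#' @param config a [simulation_config()].
#' @return an object of class `trio_cohort`: a list with `trios` (trio_id,
#'   proband, mother, father), `calls` (long variant table: sample_id,
#'   chrom, pos, ref, alt, genotype, depth, alt_reads) and `truth` (the
#'   planted de novo events: trio_id, gene_id, cdna_pos, ref, alt).
#' @export
generate_trio_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nt <- config$n_trios
  trios <- data.frame(
    trio_id = sprintf("T%04d", seq_len(nt)),
    proband = sprintf("P%04d", seq_len(nt)),
    mother = sprintf("M%04d", seq_len(nt)),
    father = sprintf("F%04d", seq_len(nt)),
    stringsAsFactors = FALSE
  )
  genes <- config$genes

  # --- planted de novo events: k ~ Binomial(2, mu_g) per trio and gene
  truth <- list()
  for (gi in seq_len(nrow(genes))) {
    mu <- config$rate_per_gene[[gi]]
    if (mu <= 0) next
    k <- stats::rbinom(nt, 2L, mu)
    hit <- which(k > 0L)
    for (t in hit) {
      pos <- sample.int(genes$cds_length[gi], k[t], replace = TRUE)
      truth[[length(truth) + 1L]] <- data.frame(
        trio_id = trios$trio_id[t], gene_id = genes$gene_id[gi],
        cdna_pos = pos, stringsAsFactors = FALSE)
    }
  }
  # optional planted cluster: one extra event per row, each in a random trio
  if (!is.null(config$planted_cluster)) {
    pc <- config$planted_cluster
    t_idx <- sample.int(nt, nrow(pc), replace = nrow(pc) > nt)
    # place at the first base of the residue's codon
    truth[[length(truth) + 1L]] <- data.frame(
      trio_id = trios$trio_id[t_idx], gene_id = pc$gene_id,
      cdna_pos = 3L * (as.integer(pc$residue) - 1L) + 1L,
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(trio_id = character(), gene_id = character(),
               cdna_pos = integer(), stringsAsFactors = FALSE)

  # one ref/alt pair per distinct planted site (recurrent events share it)
  site_key <- paste(truth$gene_id, truth$cdna_pos)
  usite <- !duplicated(site_key)
  if (nrow(truth)) {
    ra <- random_base_pair(sum(usite))
    idx <- match(site_key, site_key[usite])
    truth$ref <- ra$ref[idx]
    truth$alt <- ra$alt[idx]
  } else {
    truth$ref <- character(0); truth$alt <- character(0)
  }

  calls <- list()
  # planted sites: calls for the three trio members only
  if (nrow(truth)) {
    ti <- match(truth$trio_id, trios$trio_id)
    nr <- nrow(truth)
    ids <- c(rbind(trios$proband[ti], trios$mother[ti], trios$father[ti]))
    gt <- rep(c("het", "hom_ref", "hom_ref"), nr)
    dp <- sim_depth(3L * nr, config$mean_depth)
    rep3 <- rep(seq_len(nr), each = 3L)
    calls[[1L]] <- data.frame(
      sample_id = ids, chrom = truth$gene_id[rep3], pos = truth$cdna_pos[rep3],
      ref = truth$ref[rep3], alt = truth$alt[rep3], genotype = gt, depth = dp,
      alt_reads = sim_alt_reads(gt, dp), stringsAsFactors = FALSE)
  }

  # background inherited sites, shared cohort-wide, avoiding planted sites;
  # drawn without replacement over the pooled coding space
  nbg <- config$n_background_sites
  if (nbg > 0L) {
    offs <- cumsum(c(0L, genes$cds_length))
    total <- offs[length(offs)]
    taken_idx <- unique(offs[match(truth$gene_id, genes$gene_id)] +
                          truth$cdna_pos)
    avail <- setdiff(seq_len(total), taken_idx)
    if (nbg > length(avail))
      stop("n_background_sites (", nbg, ") exceeds the free coding space (",
           length(avail), " bases)")
    pick <- sort(sample(avail, nbg))
    bg_gene <- findInterval(pick - 0.5, offs)
    bg_pos <- pick - offs[bg_gene]
    ra <- random_base_pair(nbg)
    # parental haplotypes at every (site, trio): HW proportions at freq 0.5;
    # the child inherits one random allele from each parent, so Mendelian
    # consistency holds by construction
    N <- nbg * nt
    m1 <- stats::rbinom(N, 1L, 0.5); m2 <- stats::rbinom(N, 1L, 0.5)
    f1 <- stats::rbinom(N, 1L, 0.5); f2 <- stats::rbinom(N, 1L, 0.5)
    from_m <- ifelse(stats::runif(N) < 0.5, m1, m2)
    from_f <- ifelse(stats::runif(N) < 0.5, f1, f2)
    gt_code <- c("hom_ref", "het", "hom_alt")
    p_gt <- gt_code[from_m + from_f + 1L]
    m_gt <- gt_code[m1 + m2 + 1L]
    f_gt <- gt_code[f1 + f2 + 1L]
    # interleave proband/mother/father rows per (site, trio)
    site_i <- rep(rep(seq_len(nbg), each = nt), each = 3L)
    trio_i <- rep(rep(seq_len(nt), nbg), each = 3L)
    member <- rep_len(1:3, 3L * N)
    ids_mat <- cbind(trios$proband, trios$mother, trios$father)
    gt <- c(rbind(p_gt, m_gt, f_gt))
    dp <- sim_depth(3L * N, config$mean_depth)
    calls[[length(calls) + 1L]] <- data.frame(
      sample_id = ids_mat[cbind(trio_i, member)],
      chrom = genes$gene_id[bg_gene[site_i]], pos = bg_pos[site_i],
      ref = ra$ref[site_i], alt = ra$alt[site_i], genotype = gt,
      depth = dp, alt_reads = sim_alt_reads(gt, dp),
      stringsAsFactors = FALSE)
  }

  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample_id = character(), chrom = character(),
               pos = integer(), ref = character(), alt = character(),
               genotype = character(), depth = integer(),
               alt_reads = integer(), stringsAsFactors = FALSE)
  calls <- calls[order(calls$chrom, calls$pos, calls$sample_id), ]
  calls$pos <- as.integer(calls$pos)
  calls$depth <- as.integer(calls$depth)
  calls$alt_reads <- as.integer(calls$alt_reads)
  truth$cdna_pos <- as.integer(truth$cdna_pos)
  rownames(calls) <- NULL
  rownames(truth) <- NULL
  structure(list(trios = trios, calls = calls, truth = truth,
                 config = config),
            class = "trio_cohort")
}

#' @exportS3Method
print.trio_cohort <- function(x, ...) {
  cat("Simulated trio cohort:", nrow(x$trios), "trios,",
      nrow(x$calls), "calls,", nrow(x$truth), "planted de novo events\n")
  invisible(x)
}

#' Generate a control-cohort carrier table
#'
#' Emulates a population control series screened for qualifying variants in
#' the gene set: each control carries one with probability
#' `carrier_fraction`, independently.
#'
#' @param config a [simulation_config()] (uses `n_controls` and `seed`).
#' @param carrier_fraction probability in \[0, 1\] that a control carries a
#'   qualifying variant.
#' @return `data.frame` with columns `sample_id`, `carrier` (logical).
#' @export
generate_control_cohort <- function(config, carrier_fraction) {
  stopifnot(inherits(config, "simulation_config"))
  if (carrier_fraction < 0 || carrier_fraction > 1)
    stop("carrier_fraction must lie in [0, 1]")
  if (config$n_controls < 1L) stop("config$n_controls must be >= 1")
  set.seed(config$seed + 1L)  # decoupled from the trio stream
  data.frame(
    sample_id = sprintf("C%04d", seq_len(config$n_controls)),
    carrier = stats::rbinom(config$n_controls, 1L, carrier_fraction) == 1L,
    stringsAsFactors = FALSE
  )
}

#' Simulate a paralog family with its true alignment
#'
#' Evolves `n_genes` protein sequences from one random ancestor of
#' `ancestor_length` residues. Each ancestral residue is independently
#' substituted (probability `divergence`, uniform over the 19 alternative
#' residues) or deleted (probability `indel_rate / 2`); after each ancestral
#' position a single-residue insertion occurs with probability
#' `indel_rate / 2`. Insertions in different genes are never homologous, so
#' each insertion opens its own alignment column; the returned alignment is
#' the true one implied by this history, and its width equals
#' `ancestor_length` plus the total number of insertions across genes.
#'
#' @param n_genes number of paralogs (>= 2 for a useful family).
#' @param ancestor_length ancestor protein length in residues (>= 10).
#' @param divergence per-residue substitution probability, in \[0, 0.5\].
#' @param indel_rate per-position indel probability, in \[0, 0.1\]; split
#'   evenly between deletion and insertion.
#' @param seed integer RNG seed.
#' @param gene_ids optional gene names (default `"G1"`, `"G2"`, ...).
#' @return list with `models` (gene-model `data.frame`), `alignment` (a
#'   [paralog_alignment()]) and `history` (per-gene event log: substituted
#'   ancestral positions, deleted ancestral positions, insertion positions
#'   and residues — the raw material for reconstruction oracles).
#' @export
generate_paralog_family <- function(n_genes, ancestor_length, divergence,
                                    indel_rate, seed,
                                    gene_ids = sprintf("G%d", seq_len(n_genes))) {
  if (ancestor_length < 10L) stop("ancestor_length must be >= 10")
  if (divergence < 0 || divergence > 0.5)
    stop("divergence must lie in [0, 0.5]")
  if (indel_rate < 0 || indel_rate > 0.1)
    stop("indel_rate must lie in [0, 0.1]")
  stopifnot(n_genes >= 1L, length(gene_ids) == n_genes)
  set.seed(seed)
  L <- as.integer(ancestor_length)
  ancestor <- sample(AA20, L, replace = TRUE)

  history <- vector("list", n_genes)
  names(history) <- gene_ids
  for (g in seq_len(n_genes)) {
    res <- ancestor
    sub_at <- which(stats::runif(L) < divergence)
    for (i in sub_at) res[i] <- sample(setdiff(AA20, ancestor[i]), 1L)
    del_at <- which(stats::runif(L) < indel_rate / 2)
    ins_at <- which(stats::runif(L) < indel_rate / 2)   # insert after pos i
    # a gene must keep at least one residue
    if (length(del_at) == L && length(ins_at) == 0L)
      del_at <- del_at[-sample.int(L, 1L)]
    history[[g]] <- list(
      residues = res, substituted = sub_at, deleted = del_at,
      insert_after = ins_at,
      inserted = sample(AA20, length(ins_at), replace = TRUE))
  }

  # global column order: for each ancestral position i, the ancestral column
  # then each gene's insertion column (gene order fixed)
  ins_count <- vapply(history, function(h) length(h$insert_after), integer(1))
  width <- L + sum(ins_count)
  aligned <- character(n_genes)
  for (g in seq_len(n_genes)) {
    h <- history[[g]]
    cols <- character(0)
    for (i in seq_len(L)) {
      cols <- c(cols, if (i %in% h$deleted) "-" else h$residues[i])
      for (g2 in seq_len(n_genes)) {
        h2 <- history[[g2]]
        j <- match(i, h2$insert_after)
        if (!is.na(j))
          cols <- c(cols, if (g2 == g) h2$inserted[j] else "-")
      }
    }
    aligned[g] <- paste(cols, collapse = "")
  }
  names(aligned) <- gene_ids
  alignment <- paralog_alignment(aligned)
  models <- gene_model_table(gene_ids, ungap_alignment(alignment))
  list(models = models, alignment = alignment, history = history)
}

#' Synthetic per-gene de novo rate table from coding lengths
#'
#' First-principles stand-in for empirically calibrated gene-specific
#' mutation rates: rate = cds_length x per-base SNV rate x fraction of
#' coding changes that alter the protein. Defaults use the conventional
#' human germline per-base rate of 1.2e-8 per transmission and a
#' non-synonymous fraction of 0.7.
#'
#' @param models gene-model `data.frame` (needs `gene_id`, `cds_length`).
#' @param per_base_rate per-base per-transmission mutation rate.
#' @param nonsynonymous_fraction fraction of coding point mutations that are
#'   protein-altering.
#' @return named numeric vector of per-gene per-transmission rates.
#' @export
synthetic_rate_table <- function(models, per_base_rate = 1.2e-8,
                                 nonsynonymous_fraction = 0.7) {
  stats::setNames(models$cds_length * per_base_rate * nonsynonymous_fraction,
                  models$gene_id)
}
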