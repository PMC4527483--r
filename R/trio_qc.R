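#' KING-robust relatedness between two samples
#'
#' Estimates the kinship coefficient from two samples' genotype vectors with
#' the within-family robust estimator
#' `kinship = (n_het_shared - 2 * n_opposite_hom) / (n_het_a + n_het_b)`,
#' where `n_het_shared` counts sites at which both samples are heterozygous
#' and `n_opposite_hom` counts sites at which one is hom-ref and the other
#' hom-alt. Parent-offspring pairs have expected kinship 0.25 and, barring
#' genotyping error, zero opposite homozygotes; unrelated pairs have
#' expected kinship 0. The verdict is `parent_offspring_consistent` iff
#' kinship lies in [0.177, 0.354] (the conventional first-degree window,
#' midpoints between 2^-2 and its neighbours on the log2 scale) and the
#' opposite-homozygote rate is below 0.005.
#'
#' @param calls_a,calls_b calls `data.frame`s for the two samples (columns
#'   chrom, pos, ref, alt, genotype).
#' @param min_shared_sites minimum number of shared biallelic sites with
#'   non-missing genotypes in both samples (default 50); fewer is an error,
#'   not a verdict.
#' @return object of class `relatedness_report`: `pair`, `n_sites`,
#'   `kinship`, `opposite_homozygote_rate`, `verdict`.
#' @export
estimate_relatedness <- function(calls_a, calls_b, min_shared_sites = 50L) {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  a <- calls_a[calls_a$genotype != "missing", , drop = FALSE]
  b <- calls_b[calls_b$genotype != "missing", , drop = FALSE]
  i <- match(key(a), key(b))
  ok <- !is.na(i)
  ga <- a$genotype[ok]
  gb <- b$genotype[i[ok]]
  n <- length(ga)
  if (n < min_shared_sites)
    stop("insufficient shared sites for relatedness estimate: ", n,
         " < ", min_shared_sites)
  n_het_a <- sum(ga == "het")
  n_het_b <- sum(gb == "het")
  n_het_shared <- sum(ga == "het" & gb == "het")
  n_opp <- sum((ga == "hom_ref" & gb == "hom_alt") |
                 (ga == "hom_alt" & gb == "hom_ref"))
  if (n_het_a + n_het_b == 0L)
    stop("no heterozygous sites in either sample; kinship undefined")
  kinship <- (n_het_shared - 2 * n_opp) / (n_het_a + n_het_b)
  opp_rate <- n_opp / n
  verdict <- if (kinship >= 0.177 && kinship <= 0.354 && opp_rate < 0.005)
    "parent_offspring_consistent" else "inconsistent"
  structure(
    list(pair = c(calls_a$sample_id[1], calls_b$sample_id[1]),
         n_sites = n, kinship = kinship,
         opposite_homozygote_rate = opp_rate, verdict = verdict),
    class = "relatedness_report"
  )
}

#' @exportS3Method
print.relatedness_report <- function(x, ...) {
  cat(sprintf("Relatedness %s vs %s: kinship %.4f, opp-hom rate %.5f (%d sites) -> %s\n",
              x$pair[1], x$pair[2], x$kinship, x$opposite_homozygote_rate,
              x$n_sites, x$verdict))
  invisible(x)
}

#' Call de novo candidates in one trio
#'
#' Applies the trio filter: keep exactly the proband variants where (a) the
#' proband's alt-supporting reads number at least `min_alt_reads`, (b)
#' neither parent carries the alternate allele (both called hom-ref), and
#' (c) both parents are covered by at least `min_parent_depth` reads at the
#' site — a site insufficiently covered in a parent cannot exclude
#' inheritance, so it is dropped. A missing parental record counts as
#' insufficient coverage. Biological parentage is verified first with
#' [estimate_relatedness()] unless `check_relatedness = FALSE`; an
#' inconsistent pair aborts the call rather than returning candidates.
#'
#' Coordinates follow the simulator convention (`chrom` is the gene,
#' `pos` the 1-based coding base), so `cdna_pos = pos` and
#' `protein_pos = ceiling(pos / 3)`.
#'
#' @param calls cohort calls `data.frame` (long format).
#' @param proband,mother,father sample ids of the trio members.
#' @param trio_id label for the output (defaults to the proband id).
#' @param min_alt_reads minimum proband alt-read support (default 3:
#'   variants supported by fewer than three reads are removed).
#' @param min_parent_depth minimum parental depth at the site (default 7).
#' @param check_relatedness verify parentage before filtering.
#' @param min_shared_sites passed to [estimate_relatedness()].
#' @return `data.frame` of candidates sorted by (chrom, pos): trio_id,
#'   gene_id, chrom, pos, ref, alt, cdna_pos, protein_pos, depth,
#'   alt_reads, alt_fraction.
#' @export
call_de_novo_candidates <- function(calls, proband, mother, father,
                                    trio_id = proband,
                                    min_alt_reads = 3L,
                                    min_parent_depth = 7L,
                                    check_relatedness = TRUE,
                                    min_shared_sites = 50L) {
  pc <- calls[calls$sample_id == proband, , drop = FALSE]
  mc <- calls[calls$sample_id == mother, , drop = FALSE]
  fc <- calls[calls$sample_id == father, , drop = FALSE]
  if (check_relatedness) {
    for (parent in list(mc, fc)) {
      rep <- estimate_relatedness(pc, parent,
                                  min_shared_sites = min_shared_sites)
      if (rep$verdict != "parent_offspring_consistent")
        stop("parentage check failed for pair ",
             paste(rep$pair, collapse = "/"),
             " (kinship ", signif(rep$kinship, 3), "); refusing to call")
    }
  }
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  carried <- pc$genotype %in% c("het", "hom_alt") &
    pc$alt_reads >= min_alt_reads
  cand <- pc[carried, , drop = FALSE]
  im <- match(key(cand), key(mc))
  if_ <- match(key(cand), key(fc))
  parent_ok <- !is.na(im) & !is.na(if_) &
    mc$genotype[im] == "hom_ref" & fc$genotype[if_] == "hom_ref" &
    mc$depth[im] >= min_parent_depth & fc$depth[if_] >= min_parent_depth
  parent_ok[is.na(parent_ok)] <- FALSE
  cand <- cand[parent_ok, , drop = FALSE]
  out <- data.frame(
    trio_id = rep_len(trio_id, nrow(cand)),
    gene_id = cand$chrom, chrom = cand$chrom, pos = cand$pos,
    ref = cand$ref, alt = cand$alt,
    cdna_pos = cand$pos,
    protein_pos = as.integer(ceiling(cand$pos / 3)),
    depth = cand$depth, alt_reads = cand$alt_reads,
    alt_fraction = cand$alt_reads / cand$depth,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call de novo candidates for every trio in a cohort
#'
#' Convenience loop over [call_de_novo_candidates()] for a simulated
#' cohort's trio table.
#'
#' @param cohort a `trio_cohort`.
#' @inheritParams call_de_novo_candidates
#' @return row-bound candidate `data.frame` across all trios.
#' @export
call_cohort_de_novo <- function(cohort, min_alt_reads = 3L,
                                min_parent_depth = 7L,
                                check_relatedness = FALSE,
                                min_shared_sites = 50L) {
  res <- lapply(seq_len(nrow(cohort$trios)), function(i) {
    t <- cohort$trios[i, ]
    call_de_novo_candidates(cohort$calls, t$proband, t$mother, t$father,
                            trio_id = t$trio_id,
                            min_alt_reads = min_alt_reads,
                            min_parent_depth = min_parent_depth,
                            check_relatedness = check_relatedness,
                            min_shared_sites = min_shared_sites)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assess mosaicism from the alt-allele read fraction
#'
#' A constitutive heterozygous variant should draw its alt reads as
#' Binomial(depth, 0.5); post-zygotic mosaicism depletes the alternate
#' allele. Each site gets a two-sided exact binomial test against 0.5
#' ([stats::binom.test()]); a site is flagged as possibly mosaic only when
#' the test rejects at `alpha` AND the alt fraction is below 0.5 (an excess
#' of alt reads is never evidence of mosaicism). Sites with depth below 10
#' carry too little information for a verdict: they are returned with
#' `insufficient_depth = TRUE` and NA p-value and flag.
#'
#' @param alt_reads,depth integer vectors (recycled to equal length).
#' @param alpha significance level for the flag (default 0.05).
#' @return `data.frame`: alt_reads, depth, alt_fraction, p_value, flagged,
#'   insufficient_depth.
#' @export
assess_mosaicism <- function(alt_reads, depth, alpha = 0.05) {
  n <- max(length(alt_reads), length(depth))
  alt_reads <- rep_len(as.integer(alt_reads), n)
  depth <- rep_len(as.integer(depth), n)
  if (any(alt_reads < 0L) || any(alt_reads > depth))
    stop("need 0 <= alt_reads <= depth")
  p <- rep(NA_real_, n)
  ok <- depth >= 10L
  p[ok] <- vapply(which(ok), function(i)
    stats::binom.test(alt_reads[i], depth[i], p = 0.5)$p.value, numeric(1))
  frac <- alt_reads / depth
  data.frame(
    alt_reads = alt_reads, depth = depth, alt_fraction = frac,
    p_value = p,
    flagged = ifelse(ok, p < alpha & frac < 0.5, NA),
    insufficient_depth = !ok
  )
}
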