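#' Write a cohort's calls as a minimal VCF 4.2
#'
#' Emits one contig per gene, all samples as columns, FORMAT `GT:DP:AD`
#' (AD = ref,alt read counts). Samples without a call at a site are written
#' as missing (`./.:.:.`). The output is plain text, readable by any VCF
#' parser.
#'
#' @param cohort a `trio_cohort` (or any list with a `calls` data.frame and
#'   a `trios` table) — alternatively pass a calls `data.frame` directly.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  calls <- if (is.data.frame(cohort)) cohort else cohort$calls
  samples <- sort(unique(calls$sample_id))
  site <- unique(calls[, c("chrom", "pos", "ref", "alt")])
  site <- site[order(site$chrom, site$pos), , drop = FALSE]
  key_of <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  skey <- key_of(site)
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
  cell <- matrix("./.:.:.", nrow = nrow(site), ncol = length(samples),
                 dimnames = list(NULL, samples))
  ri <- match(key_of(calls), skey)
  ci <- match(calls$sample_id, samples)
  cell[cbind(ri, ci)] <- sprintf("%s:%d:%d,%d", gt_code[calls$genotype],
                                 calls$depth,
                                 calls$depth - calls$alt_reads,
                                 calls$alt_reads)
  contigs <- unique(site$chrom)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=trioburden",
    sprintf("##contig=<ID=%s>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(site$chrom, site$pos, ".", site$ref, site$alt, ".", ".",
                ".", "GT:DP:AD",
                apply(cell, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF with GT:DP:AD into a long calls table
#'
#' Parses with [vcfR::read.vcfR()] and returns the same long format the
#' simulator produces (one row per sample per site, genotypes coded
#' hom_ref / het / hom_alt / missing). Sites and samples with missing
#' genotypes are kept, coded `missing` with NA depth.
#'
#' @param path VCF file (plain or gzipped).
#' @return calls `data.frame`: sample_id, chrom, pos, ref, alt, genotype,
#'   depth, alt_reads.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(gt)
  ns <- length(samples); nv <- nrow(gt)
  gt_chr <- gsub("|", "/", as.vector(gt), fixed = TRUE)
  geno <- rep("missing", length(gt_chr))
  geno[gt_chr %in% "0/0"] <- "hom_ref"
  geno[gt_chr %in% c("0/1", "1/0")] <- "het"
  geno[gt_chr %in% "1/1"] <- "hom_alt"
  alt_reads <- suppressWarnings(
    as.integer(vapply(strsplit(as.vector(ad), ",", fixed = TRUE),
                      function(x) if (length(x) >= 2L) x[2] else NA_character_,
                      character(1))))
  out <- data.frame(
    sample_id = rep(samples, each = nv),
    chrom = rep(fix[, "CHROM"], ns),
    pos = rep(as.integer(fix[, "POS"]), ns),
    ref = rep(fix[, "REF"], ns),
    alt = rep(fix[, "ALT"], ns),
    genotype = geno,
    depth = as.integer(as.vector(dp)),
    alt_reads = alt_reads,
    stringsAsFactors = FALSE
  )
  out <- out[out$genotype != "missing" | !is.na(out$depth), , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$sample_id), ]
  rownames(out) <- NULL
  out
}

#' Flat-file writers and readers for the pipeline's tables
#'
#' All tables travel as plain TSV: variant calls (the same long format the
#' VCF carries), planted-truth tables, per-gene rate tables (columns
#' `gene`, `rate`) and phenotype tables.
#'
#' @param calls,truth,phenotypes a `data.frame` to write.
#' @param rates named numeric vector of per-gene rates.
#' @param path file path.
#' @return readers return a `data.frame` (or named numeric for rates);
#'   writers return `path` invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_variant_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_variant_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname table_io
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
write_rate_table <- function(rates, path) {
  utils::write.table(
    data.frame(gene = names(rates), rate = unname(rates)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_rate_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "rate") %in% names(tab)))
    stop("rate table must have columns gene, rate")
  r <- stats::setNames(as.numeric(tab$rate), tab$gene)
  if (any(!is.finite(r)) || any(r <= 0) || any(r >= 1))
    stop("rates must lie strictly in (0, 1)")
  r
}

#' @rdname table_io
#' @export
write_phenotype_table <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname table_io
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("case_id", "gene", "cdna", "protein", "inheritance",
            "age_years", "height_sd", "hc_sd", "intellectual_disability")
  if (!all(need %in% names(tab)))
    stop("phenotype TSV must have columns: ", paste(need, collapse = ", "))
  if (is.character(tab$intellectual_disability))
    tab$intellectual_disability <-
      tolower(tab$intellectual_disability) %in% c("yes", "true", "1")
  tab
}
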