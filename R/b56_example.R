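#' Synthetic stand-in for the PP2A-B56 paralog family
#'
#' The three B56-family genes analysed in the worked example (PPP2R5B,
#' PPP2R5C, PPP2R5D) with their true protein lengths (497, 524 and 602
#' residues) but *synthetic* sequences: the real sequences and a curated
#' family alignment are not redistributed here, so a deterministic stand-in
#' is built instead. The three proteins are derived from one random
#' ancestor the length of the longest paralog; the shorter paralogs are
#' windows of it (shorter N/C-termini, as in the real family) and each gene
#' carries independent substitutions. The alignment therefore has only
#' terminal gaps, with offsets chosen so that the four reported mutations
#' (B56beta Ser161, B56gamma Thr157, B56delta Glu198 and Glu200) occupy a
#' nine-column aligned window — the observed configuration the clustering
#' analysis starts from. Geometry (lengths, offsets, the observed span) is
#' what the permutation test consumes; the residue letters themselves are
#' arbitrary.
#'
#' @param divergence per-residue substitution probability applied to each
#'   gene copy (default 0.25).
#' @return list with `models` (gene-model `data.frame` with RefSeq
#'   accessions), `alignment` (a [paralog_alignment()]) and `offsets`
#'   (named leading-gap counts).
#' @export
synthetic_b56_family <- function(divergence = 0.25) {
  lengths <- c(PPP2R5B = 497L, PPP2R5C = 524L, PPP2R5D = 602L)
  offsets <- c(PPP2R5B = 34L, PPP2R5C = 35L, PPP2R5D = 0L)
  accession <- c(PPP2R5B = "NM_006244", PPP2R5C = "NM_001161725",
                 PPP2R5D = "NM_006245")
  # deterministic construction; leave the caller's RNG stream untouched
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(56215L)
  W <- max(offsets + lengths)
  ancestor <- sample(AA20, W, replace = TRUE)
  aligned <- vapply(names(lengths), function(g) {
    res <- ancestor[(offsets[[g]] + 1L):(offsets[[g]] + lengths[[g]])]
    sub_at <- which(stats::runif(lengths[[g]]) < divergence)
    for (i in sub_at) res[i] <- sample(setdiff(AA20, res[i]), 1L)
    paste(c(rep("-", offsets[[g]]), res,
            rep("-", W - offsets[[g]] - lengths[[g]])), collapse = "")
  }, character(1))
  alignment <- paralog_alignment(aligned)
  models <- gene_model_table(names(lengths), ungap_alignment(alignment),
                             accession = accession[names(lengths)])
  list(models = models, alignment = alignment, offsets = offsets)
}

#' Published B56 mutations and case phenotypes
#'
#' `b56_observed_mutations()` returns the four de novo mutations reported
#' in the trio series (HGVS cDNA notation with protein labels), with each
#' residue recomputed from the cDNA coordinate via [parse_cdna()] and
#' [cdna_to_protein()]. `b56_case_phenotypes()` returns the five-case
#' phenotype table (growth standard-deviation scores, intellectual
#' disability, inheritance). Both are bundled transcriptions of the
#' published case tables.
#'
#' @return `data.frame`s; see Details.
#' @export
b56_observed_mutations <- function() {
  path <- system.file("extdata", "b56_observed_mutations.tsv",
                      package = "trioburden", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$residue <- vapply(seq_len(nrow(tab)), function(i)
    cdna_to_protein(parse_cdna(tab$cdna[i]),
                    protein_label = tab$protein[i]), integer(1))
  data.frame(gene_id = tab$gene, cdna = tab$cdna, protein = tab$protein,
             residue = tab$residue, stringsAsFactors = FALSE)
}

#' @rdname b56_observed_mutations
#' @export
b56_case_phenotypes <- function() {
  read_phenotypes(system.file("extdata", "b56_case_phenotypes.tsv",
                              package = "trioburden", mustWork = TRUE))
}
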