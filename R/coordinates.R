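#' Build a gene-model table
#'
#' A gene model records one paralog's coding geometry: the coding length in
#' bases (excluding the stop codon), the protein length in residues and the
#' protein sequence itself. Coding length is always three times the protein
#' length, and every variant coordinate handled by this package is expressed
#' 1-based on this coding sequence (HGVS `c.` convention).
#'
#' @param gene_id character vector of gene symbols.
#' @param protein_sequence character vector of residue strings (no gaps).
#' @param accession optional transcript accessions (e.g. RefSeq `NM_` ids).
#' @return A `data.frame` with columns `gene_id`, `accession`, `cds_length`,
#'   `protein_length`, `protein_sequence`.
#' @seealso [read_gene_models()], [paralog_alignment()]
#' @export
gene_model_table <- function(gene_id, protein_sequence, accession = NA_character_) {
  stopifnot(length(gene_id) == length(protein_sequence))
  if (anyDuplicated(gene_id)) stop("duplicated gene_id in gene model table")
  if (any(grepl("-", protein_sequence, fixed = TRUE)))
    stop("protein sequences must be ungapped")
  plen <- nchar(protein_sequence)
  if (any(plen < 1L)) stop("empty protein sequence")
  data.frame(
    gene_id = as.character(gene_id),
    accession = rep_len(as.character(accession), length(gene_id)),
    cds_length = 3L * plen,
    protein_length = plen,
    protein_sequence = as.character(protein_sequence),
    stringsAsFactors = FALSE
  )
}

#' Read gene models from TSV (+ optional protein FASTA)
#'
#' The TSV must have columns `gene`, `accession`, `cds_length`,
#' `protein_length`. If `fasta` is given, protein sequences are read with
#' [Biostrings::readAAStringSet()] and matched to genes by FASTA name; their
#' lengths must agree with `protein_length`.
#'
#' @param path TSV file path.
#' @param fasta optional plain-FASTA file of protein sequences.
#' @return gene-model `data.frame` (see [gene_model_table()]); without
#'   `fasta` the `protein_sequence` column is `NA`.
#' @export
read_gene_models <- function(path, fasta = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "accession", "cds_length", "protein_length")
  if (!all(need %in% names(tab)))
    stop("gene-model TSV must have columns: ", paste(need, collapse = ", "))
  if (any(tab$cds_length != 3L * tab$protein_length))
    stop("cds_length must equal 3 * protein_length")
  out <- data.frame(
    gene_id = tab$gene, accession = tab$accession,
    cds_length = as.integer(tab$cds_length),
    protein_length = as.integer(tab$protein_length),
    protein_sequence = NA_character_, stringsAsFactors = FALSE
  )
  if (!is.null(fasta)) {
    aa <- Biostrings::readAAStringSet(fasta)
    idx <- match(out$gene_id, names(aa))
    if (anyNA(idx)) stop("FASTA is missing sequences for: ",
                         paste(out$gene_id[is.na(idx)], collapse = ", "))
    out$protein_sequence <- as.character(aa[idx])
    if (any(nchar(out$protein_sequence) != out$protein_length))
      stop("FASTA sequence lengths disagree with protein_length")
  }
  out
}

#' Construct a paralog alignment
#'
#' Wraps a set of equal-length gap-containing residue strings (gap character
#' `-`) into an object holding, for every gene, the strictly increasing map
#' from ungapped residue index to alignment column. This shared column
#' coordinate system is what makes "the two mutations are close" meaningful
#' across different paralogs.
#'
#' @param aligned named character vector of aligned sequences (or a named
#'   `Biostrings::AAStringSet`).
#' @return An object of class `paralog_alignment` with fields `gene_ids`,
#'   `aligned`, `width` and `col_map` (per-gene integer vectors).
#' @export
paralog_alignment <- function(aligned) {
  if (inherits(aligned, "AAStringSet")) aligned <- as.character(aligned)
  if (is.null(names(aligned)) || any(names(aligned) == ""))
    stop("aligned sequences must be named by gene")
  w <- unique(nchar(aligned))
  if (length(w) != 1L) stop("aligned sequences differ in length")
  col_map <- lapply(aligned, function(s) {
    which(strsplit(s, "", fixed = TRUE)[[1]] != "-")
  })
  structure(
    list(gene_ids = names(aligned), aligned = aligned,
         width = as.integer(w), col_map = col_map),
    class = "paralog_alignment"
  )
}

#' @exportS3Method
print.paralog_alignment <- function(x, ...) {
  cat("Paralog alignment:", length(x$gene_ids), "genes,",
      x$width, "columns\n")
  for (g in x$gene_ids)
    cat(sprintf("  %-12s %d residues\n", g, length(x$col_map[[g]])))
  invisible(x)
}

#' Read / write an aligned FASTA
#'
#' Thin wrappers over [Biostrings::readAAStringSet()] /
#' [Biostrings::writeXStringSet()] returning or consuming a
#' [paralog_alignment()].
#'
#' @param path aligned-FASTA file.
#' @return `read_paralog_alignment`: a `paralog_alignment`.
#' @export
read_paralog_alignment <- function(path) {
  paralog_alignment(Biostrings::readAAStringSet(path))
}

#' @rdname read_paralog_alignment
#' @param alignment a `paralog_alignment`.
#' @export
write_paralog_alignment <- function(alignment, path) {
  aa <- Biostrings::AAStringSet(alignment$aligned)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Ungapped sequences of an alignment
#'
#' @param alignment a `paralog_alignment`.
#' @return named character vector of gap-free protein sequences.
#' @export
ungap_alignment <- function(alignment) {
  vapply(alignment$aligned, function(s) gsub("-", "", s, fixed = TRUE),
         character(1))
}

#' Map residues to alignment columns
#'
#' @param alignment a `paralog_alignment`.
#' @param gene_id single gene id present in the alignment.
#' @param residue integer vector of 1-based residue indices.
#' @return integer vector of 1-based alignment columns.
#' @export
residue_to_column <- function(alignment, gene_id, residue) {
  stopifnot(inherits(alignment, "paralog_alignment"))
  if (!gene_id %in% alignment$gene_ids)
    stop("unknown gene in alignment: ", gene_id)
  map <- alignment$col_map[[gene_id]]
  residue <- as.integer(residue)
  if (any(residue < 1L) || any(residue > length(map)))
    stop("residue out of range for ", gene_id,
         " (protein length ", length(map), ")")
  map[residue]
}

#' Inclusive aligned span of a mutation set
#'
#' Maps each (gene, residue) mutation into alignment columns and returns the
#' inclusive width between the two furthest mutations,
#' `max(column) - min(column) + 1`. Two mutations in the same column have
#' span 1; "within a window of w residues" means span <= w.
#'
#' @param alignment a `paralog_alignment`.
#' @param mutations `data.frame` with columns `gene_id`, `residue`; at least
#'   two rows (duplicates allowed — recurrent mutations count once per
#'   occurrence but do not change the span).
#' @return integer span in alignment columns.
#' @export
aligned_span <- function(alignment, mutations) {
  stopifnot(is.data.frame(mutations),
            all(c("gene_id", "residue") %in% names(mutations)))
  if (nrow(mutations) < 2L)
    stop("aligned_span needs at least 2 mutations")
  cols <- integer(nrow(mutations))
  for (g in unique(mutations$gene_id)) {
    i <- mutations$gene_id == g
    cols[i] <- residue_to_column(alignment, g, mutations$residue[i])
  }
  as.integer(max(cols) - min(cols) + 1L)
}

# --- HGVS-style cDNA notation -----------------------------------------------

#' Parse restricted HGVS cDNA notation
#'
#' Supports exactly two forms: substitutions `c.<pos><ref>><alt>` (e.g.
#' `c.592G>A`) and in-frame deletions `c.<start>_<end>del<bases>` (e.g.
#' `c.468_470delAAC`, deleted length divisible by 3). Anything else —
#' intronic offsets, duplications, frameshifts — raises an
#' unsupported-notation error.
#'
#' @param text a single HGVS-like string.
#' @return a `cdna_variant` object with fields `kind`
#'   (`"substitution"` or `"inframe_deletion"`), `cdna_start`, `cdna_end`,
#'   `ref`, `alt` (substitutions) or `deleted` (deletions).
#' @export
parse_cdna <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", text))[[1]]
  if (length(m) == 4L) {
    pos <- as.integer(m[2])
    v <- list(kind = "substitution", cdna_start = pos, cdna_end = pos,
              ref = m[3], alt = m[4])
    return(structure(v, class = "cdna_variant"))
  }
  m <- regmatches(text, regexec("^c\\.([0-9]+)_([0-9]+)del([ACGT]+)$", text))[[1]]
  if (length(m) == 4L) {
    s <- as.integer(m[2]); e <- as.integer(m[3])
    if (e < s) stop("unsupported notation (end < start): ", text)
    len <- e - s + 1L
    if (len %% 3L != 0L)
      stop("unsupported notation (deletion not in frame): ", text)
    if (nchar(m[4]) != len)
      stop("deleted bases disagree with coordinates: ", text)
    v <- list(kind = "inframe_deletion", cdna_start = s, cdna_end = e,
              deleted = m[4])
    return(structure(v, class = "cdna_variant"))
  }
  stop("unsupported notation: ", text)
}

#' Format a cdna_variant back to HGVS text
#'
#' Round-trips with [parse_cdna()]: `format_cdna(parse_cdna(x)) == x` for all
#' supported notation.
#'
#' @param variant a `cdna_variant`.
#' @return HGVS-like string.
#' @export
format_cdna <- function(variant) {
  stopifnot(inherits(variant, "cdna_variant"))
  if (variant$kind == "substitution") {
    sprintf("c.%d%s>%s", variant$cdna_start, variant$ref, variant$alt)
  } else {
    sprintf("c.%d_%ddel%s", variant$cdna_start, variant$cdna_end,
            variant$deleted)
  }
}

#' @exportS3Method
print.cdna_variant <- function(x, ...) {
  cat(format_cdna(x), "\n")
  invisible(x)
}

#' Map a cDNA variant to its protein residue
#'
#' Substitutions map to `ceiling(cdna_start / 3)`. In-frame deletions map to
#' the first codon wholly contained in the deleted interval; when the
#' deletion is out of codon phase no codon is wholly removed, and the residue
#' of the last deleted base is used (which reproduces the HGVS 3'-normalised
#' label in that case). A supplied `protein_label` (e.g. `"p.Thr157del"`)
#' always takes precedence, since 3' normalisation cannot in general be
#' undone without the transcript sequence.
#'
#' @param variant a `cdna_variant` (or a bare 1-based coding position, taken
#'   as a substitution).
#' @param cds_length optional coding length for bounds checking.
#' @param protein_label optional HGVS protein annotation whose residue number
#'   is used verbatim for deletions.
#' @return 1-based protein residue (integer).
#' @export
cdna_to_protein <- function(variant, cds_length = NULL, protein_label = NULL) {
  if (is.numeric(variant))
    variant <- structure(list(kind = "substitution",
                              cdna_start = as.integer(variant),
                              cdna_end = as.integer(variant)),
                         class = "cdna_variant")
  stopifnot(inherits(variant, "cdna_variant"))
  if (!is.null(cds_length) && variant$cdna_end > cds_length)
    stop("cDNA position ", variant$cdna_end, " beyond cds_length ", cds_length)
  if (variant$cdna_start < 1L) stop("cDNA position must be >= 1")
  if (variant$kind == "substitution")
    return(as.integer(ceiling(variant$cdna_start / 3)))
  if (!is.null(protein_label)) {
    m <- regmatches(protein_label,
                    regexec("^p\\.[A-Za-z]{3}([0-9]+)", protein_label))[[1]]
    if (length(m) != 2L) stop("cannot parse protein label: ", protein_label)
    return(as.integer(m[2]))
  }
  # first codon j with both ends inside [start, end]; codon j covers bases
  # 3j-2 .. 3j
  j <- ceiling(variant$cdna_start / 3)
  if (3L * j - 2L < variant$cdna_start) j <- j + 1L
  if (3L * j <= variant$cdna_end) return(as.integer(j))
  as.integer(ceiling(variant$cdna_end / 3))
}
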