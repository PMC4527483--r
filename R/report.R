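#' Summarise a phenotype table
#'
#' Computes the headline phenotype summary of a case series: median height
#' and head-circumference standard-deviation scores (middle order
#' statistic; mean of the two central values for even n), the fraction of
#' cases with intellectual disability, and how many cases exceed +2 s.d.
#' for each growth score. Missing values are excluded pairwise from each
#' summary.
#'
#' @param records phenotype `data.frame` (see [read_phenotypes()]); needs
#'   `height_sd`, `hc_sd`, `intellectual_disability`. Must be non-empty.
#' @return list: `n`, `median_height_sd`, `median_hc_sd`,
#'   `fraction_intellectual_disability`, `n_height_gt2`, `n_hc_gt2`.
#' @export
summarize_phenotypes <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("phenotype table is empty")
  list(
    n = nrow(records),
    median_height_sd = stats::median(records$height_sd, na.rm = TRUE),
    median_hc_sd = stats::median(records$hc_sd, na.rm = TRUE),
    fraction_intellectual_disability =
      mean(records$intellectual_disability, na.rm = TRUE),
    n_height_gt2 = sum(records$height_sd > 2, na.rm = TRUE),
    n_hc_gt2 = sum(records$hc_sd > 2, na.rm = TRUE)
  )
}

#' Annotate mutations against residue regions
#'
#' Flags each (gene, residue) mutation as inside or outside a named region
#' (1-based inclusive intervals), e.g. to ask whether mutations fall in a
#' functional surface loop of the protein.
#'
#' @param mutations `data.frame` with columns `gene_id`, `residue`.
#' @param regions `data.frame` with columns `gene_id`, `region_name`,
#'   `start_residue`, `end_residue` (may be empty: everything is "out").
#' @return `mutations` with added columns `in_region` (logical) and
#'   `region_name` (NA when outside all regions).
#' @export
annotate_region <- function(mutations, regions) {
  stopifnot(is.data.frame(mutations),
            all(c("gene_id", "residue") %in% names(mutations)))
  if (nrow(regions) > 0 &&
      any(regions$start_residue > regions$end_residue))
    stop("malformed region: start_residue > end_residue")
  mutations$in_region <- FALSE
  mutations$region_name <- NA_character_
  for (i in seq_len(nrow(regions))) {
    hit <- mutations$gene_id == regions$gene_id[i] &
      mutations$residue >= regions$start_residue[i] &
      mutations$residue <= regions$end_residue[i]
    mutations$in_region[hit] <- TRUE
    mutations$region_name[hit] <- regions$region_name[i]
  }
  mutations
}

#' @rdname annotate_region
#' @param path region TSV with columns `gene`, `name`, `start`, `end`.
#' @export
read_regions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "name", "start", "end")
  if (!all(need %in% names(tab)))
    stop("region TSV must have columns: ", paste(need, collapse = ", "))
  data.frame(gene_id = tab$gene, region_name = tab$name,
             start_residue = as.integer(tab$start),
             end_residue = as.integer(tab$end), stringsAsFactors = FALSE)
}

#' Assemble a run report
#'
#' Collects the outputs of any subset of pipeline stages into one
#' serialisable document, together with input-file hashes, the seed and the
#' package version. Omitted stages are marked absent rather than dropped,
#' so downstream consumers see a fixed schema. With `timestamp = NULL` the
#' report is fully deterministic for identical inputs.
#'
#' @param candidates de novo candidate `data.frame`, or NULL.
#' @param relatedness list of `relatedness_report`s, or NULL.
#' @param burden a `burden_result`, or NULL.
#' @param carriers a `carrier_test`, or NULL.
#' @param cluster a `cluster_test_result`, or NULL.
#' @param phenotypes a [summarize_phenotypes()] list, or NULL.
#' @param inputs character vector of input file paths to hash (md5).
#' @param seed the run's seed, recorded for reproducibility.
#' @param timestamp POSIXct or string; NULL omits it.
#' @return a `run_report` list.
#' @export
build_report <- function(candidates = NULL, relatedness = NULL,
                         burden = NULL, carriers = NULL, cluster = NULL,
                         phenotypes = NULL, inputs = character(),
                         seed = NULL, timestamp = NULL) {
  stage <- function(x, payload) {
    if (is.null(x)) list(present = FALSE)
    else c(list(present = TRUE), payload(x))
  }
  hashes <- if (length(inputs)) {
    h <- tools::md5sum(inputs)
    stats::setNames(as.list(unname(h)), basename(inputs))
  } else NULL
  report <- list(
    meta = list(
      tool = "trioburden",
      version = as.character(utils::packageVersion("trioburden")),
      seed = seed,
      timestamp = if (is.null(timestamp)) NULL else as.character(timestamp),
      input_md5 = hashes
    ),
    stages = list(
      candidates = stage(candidates, function(x)
        list(n = nrow(x), records = x)),
      relatedness = stage(relatedness, function(x)
        list(pairs = lapply(x, function(r)
          list(pair = r$pair, kinship = r$kinship,
               opposite_homozygote_rate = r$opposite_homozygote_rate,
               n_sites = r$n_sites, verdict = r$verdict)))),
      burden = stage(burden, function(x)
        list(gene_set = x$gene_set, n_probands = x$n_probands,
             transmissions = x$transmissions,
             lambda_expected = x$lambda_expected,
             observed = x$observed, p_value = x$p_value)),
      carriers = stage(carriers, function(x)
        list(table = as.vector(x$table), p_value = x$p_value,
             degenerate = x$degenerate)),
      cluster = stage(cluster, function(x)
        list(observed_span = x$observed_span, window = x$window,
             threshold = x$threshold,
             n_permutations = x$n_permutations,
             n_success = x$n_success, p_value = x$p_value,
             seed = x$seed)),
      phenotypes = stage(phenotypes, function(x) x)
    )
  )
  class(report) <- "run_report"
  report
}

#' Write / read / validate a run report
#'
#' Reports travel as JSON ([jsonlite]); serialise -> parse -> serialise is
#' the identity.
#'
#' @param report a `run_report`.
#' @param path JSON file path.
#' @return `read_report` returns a `run_report`; `validate_report` returns
#'   TRUE or stops; `write_report` returns `path` invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  report <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(report) <- "run_report"
  report
}

#' @rdname write_report
#' @export
validate_report <- function(report) {
  stopifnot(is.list(report), is.list(report$meta),
            identical(report$meta$tool, "trioburden"),
            is.list(report$stages))
  need <- c("candidates", "relatedness", "burden", "carriers", "cluster",
            "phenotypes")
  missing <- setdiff(need, names(report$stages))
  if (length(missing))
    stop("report is missing stage section(s): ",
         paste(missing, collapse = ", "))
  for (s in need)
    if (!isTRUE(report$stages[[s]]$present) &&
        !isFALSE(report$stages[[s]]$present))
      stop("stage ", s, " lacks a logical 'present' field")
  TRUE
}
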