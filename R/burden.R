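#' Expected de novo count for a gene set
#'
#' The Poisson expectation of the burden test: the sum of the gene-specific
#' per-transmission de novo mutation rates over the gene set, multiplied by
#' the number of transmissions — twice the number of probands, since each
#' trio contributes two parental gametes.
#'
#' @param rates named numeric vector of per-gene per-transmission rates
#'   (e.g. from [read_rate_table()] or [synthetic_rate_table()]).
#' @param gene_set character vector of gene ids; every gene must be present
#'   in `rates`.
#' @param n_probands number of sequenced trios (>= 1).
#' @return the expected count `lambda = sum(rates[gene_set]) * 2 * n_probands`.
#' @export
expected_de_novo_count <- function(rates, gene_set, n_probands) {
  if (n_probands < 1L) stop("n_probands must be >= 1")
  missing <- setdiff(gene_set, names(rates))
  if (length(missing))
    stop("no rate for gene(s): ", paste(missing, collapse = ", "))
  sum(rates[gene_set]) * 2 * n_probands
}

#' Upper-tail Poisson probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`, i.e. the probability of observing
#' at least the observed number of de novo mutations under the rate-based
#' expectation. Computed on the upper tail directly
#' (`ppois(k - 1, lambda, lower.tail = FALSE)`), which is numerically exact
#' down to tiny lambda — no cancellation against 1 occurs for the minute
#' expectations typical of three-gene sets.
#'
#' @param lambda_expected Poisson mean (> 0); vectorised.
#' @param observed observed count k (>= 0); vectorised.
#' @return `P(X >= k)`, in (0, 1].
#' @export
poisson_tail_p <- function(lambda_expected, observed) {
  if (any(lambda_expected <= 0)) stop("lambda must be > 0")
  if (any(observed < 0)) stop("observed count must be >= 0")
  stats::ppois(observed - 1, lambda_expected, lower.tail = FALSE)
}

#' Two-sided Fisher's exact test for carrier counts
#'
#' Compares carrier frequencies between cases and controls by enumerating
#' every 2x2 table with the observed margins and summing the hypergeometric
#' probabilities of all tables no more likely than the observed one (the
#' minimum-likelihood definition, with relative tolerance 1e-7 on the
#' probability comparison). A zero margin (no carriers anywhere, or an
#' empty cohort) makes every table equally likely; the test is then
#' degenerate and returns p = 1.
#'
#' @param case_carriers,case_total,control_carriers,control_total
#'   non-negative counts, carriers not exceeding totals, totals positive.
#' @return object of class `carrier_test`: the 2x2 table, `p_value` and a
#'   `degenerate` flag.
#' @export
fisher_exact_two_sided <- function(case_carriers, case_total,
                                   control_carriers, control_total) {
  stopifnot(case_carriers >= 0, control_carriers >= 0,
            case_total > 0, control_total > 0,
            case_carriers <= case_total,
            control_carriers <= control_total)
  k <- case_carriers + control_carriers   # total carriers
  m <- case_total; n <- control_total
  degenerate <- (k == 0L) || (k == m + n)
  if (degenerate) {
    p <- 1
  } else {
    x <- max(0L, k - n):min(k, m)         # feasible case-carrier counts
    probs <- stats::dhyper(x, m, n, k)
    p_obs <- stats::dhyper(case_carriers, m, n, k)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  structure(
    list(table = matrix(c(case_carriers, case_total - case_carriers,
                          control_carriers, control_total - control_carriers),
                        nrow = 2,
                        dimnames = list(c("carrier", "non_carrier"),
                                        c("case", "control"))),
         p_value = p, degenerate = degenerate),
    class = "carrier_test"
  )
}

#' @exportS3Method
print.carrier_test <- function(x, ...) {
  cat(sprintf("Carrier comparison: %d/%d cases vs %d/%d controls; two-sided Fisher p = %.4g%s\n",
              x$table["carrier", "case"], sum(x$table[, "case"]),
              x$table["carrier", "control"], sum(x$table[, "control"]),
              x$p_value, if (x$degenerate) " (degenerate margins)" else ""))
  invisible(x)
}

#' Gene-set de novo burden test
#'
#' Tests whether the observed number of de novo mutations in a gene set
#' across a trio cohort exceeds the expectation from gene-specific mutation
#' rates: the expected count is `sum(rates) * 2 * n_probands`
#' ([expected_de_novo_count()]) and the p-value is the upper Poisson tail
#' `P(X >= observed)` at that mean ([poisson_tail_p()]).
#'
#' @inheritParams expected_de_novo_count
#' @param observed observed de novo count in the gene set.
#' @return object of class `burden_result`: `lambda_expected`, `observed`,
#'   `p_value`, `n_probands`, `transmissions`, `gene_set`.
#' @export
burden_test <- function(rates, gene_set, n_probands, observed) {
  lam <- expected_de_novo_count(rates, gene_set, n_probands)
  structure(
    list(lambda_expected = lam, observed = as.integer(observed),
         p_value = poisson_tail_p(lam, observed),
         n_probands = as.integer(n_probands),
         transmissions = 2L * as.integer(n_probands),
         gene_set = gene_set),
    class = "burden_result"
  )
}

#' @exportS3Method
print.burden_result <- function(x, ...) {
  cat(sprintf("De novo burden over {%s}: observed %d vs expected %.4g in %d transmissions; P(X >= %d) = %.4g\n",
              paste(x$gene_set, collapse = ", "), x$observed,
              x$lambda_expected, x$transmissions, x$observed, x$p_value))
  invisible(x)
}
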