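#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on the observed margins, the table count follows a
#' hypergeometric distribution; the two-sided p-value is the sum of the
#' point probabilities of all tables no more likely than the observed one
#' (the minimum-likelihood rule), with a relative tolerance of 1e-7 on the
#' likelihood comparison. Probabilities are summed in log space so tables
#' with totals in the thousands remain stable.
#'
#' @param table A 2x2 matrix of non-negative counts `[[a, b], [c, d]]`.
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  if (any(table < 0)) abort("contingency table entries must be >= 0")
  if (all(table == 0)) abort("contingency table must have a positive entry")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + c   # column-1 total
  n0 <- b + d  # column-2 total
  k <- a + b   # row-1 total
  lo <- max(0, k - n0); hi <- min(k, m)
  supp <- lo:hi
  logp <- dhyper(supp, m, n0, k, log = TRUE)
  obs <- logp[supp == a]
  keep <- logp <= obs + log(1 + 1e-7)
  p <- exp(obs) * sum(exp(logp[keep] - obs))
  min(1, p)
}

#' Expected escaper count for a stratum
#'
#' The whole-X escape rate scaled to the stratum size, rounded to the
#' nearest integer (halves away from zero).
#'
#' @param stratum_size Number of genes in the stratum.
#' @param whole_escape_rate Escape rate on the whole chromosome, between
#'   0 and 1.
#' @return Integer expected count.
#' @export
expected_escapers <- function(stratum_size, whole_escape_rate) {
  stopifnot(whole_escape_rate >= 0, whole_escape_rate <= 1,
            stratum_size >= 0)
  as.integer(floor(stratum_size * whole_escape_rate + 0.5))
}

#' Test a stratum's escaper count against the chromosome-wide expectation
#'
#' Builds the observed-vs-expected 2x2 table (row 1 the stratum's observed
#' escapers/non-escapers, row 2 the expected split in a same-sized
#' pseudo-group at the whole-X escape rate) and applies
#' [fisher_exact_two_sided()]. An alternative construction comparing the
#' stratum against the rest of the chromosome is available via
#' `construction = "rest_of_x"`.
#'
#' @param stratum_escapers Observed escapers in the stratum.
#' @param stratum_size Genes in the stratum.
#' @param whole_escapers Escapers on the whole chromosome.
#' @param whole_size Genes on the whole chromosome.
#' @param construction `"expected"` (default) or `"rest_of_x"`.
#' @return A list: the `table`, the `expected` count and the `p` value.
#' @export
escape_enrichment <- function(stratum_escapers, stratum_size,
                              whole_escapers, whole_size,
                              construction = c("expected", "rest_of_x")) {
  construction <- match.arg(construction)
  if (stratum_size > whole_size || stratum_escapers > whole_escapers) {
    abort("stratum counts cannot exceed whole-chromosome counts")
  }
  if (stratum_escapers > stratum_size) {
    abort("escapers cannot exceed stratum size")
  }
  expected <- expected_escapers(stratum_size, whole_escapers / whole_size)
  tab <- if (construction == "expected") {
    matrix(c(stratum_escapers, stratum_size - stratum_escapers,
             expected, stratum_size - expected),
           nrow = 2, byrow = TRUE)
  } else {
    matrix(c(stratum_escapers, stratum_size - stratum_escapers,
             whole_escapers - stratum_escapers,
             (whole_size - stratum_size) -
               (whole_escapers - stratum_escapers)),
           nrow = 2, byrow = TRUE)
  }
  list(table = tab, expected = expected, p = fisher_exact_two_sided(tab))
}

#' Escape-by-stratum association table for a locus set
#'
#' For each old/new stratum represented among the loci, counts observed
#' escapers, computes the expected count from the whole-set escape rate,
#' and tests the difference.
#'
#' @param loci Locus tibble carrying `status` and `stratum` columns.
#' @return A tibble: stratum, n, observed and expected escapers, p.
#' @export
strata_escape_tests <- function(loci) {
  usable <- loci[loci$status != "ambiguous", , drop = FALSE]
  whole_n <- nrow(usable)
  whole_esc <- sum(usable$status == "escaper")
  rows <- lapply(c("old", "new"), function(s) {
    in_s <- usable[usable$stratum == s, , drop = FALSE]
    if (nrow(in_s) == 0) return(NULL)
    obs <- sum(in_s$status == "escaper")
    fit <- escape_enrichment(obs, nrow(in_s), whole_esc, whole_n)
    tibble(stratum = s, n = nrow(in_s), observed_escapers = obs,
           expected_escapers = fit$expected, p = fit$p)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(stratum = character(), n = integer(),
                  observed_escapers = integer(),
                  expected_escapers = integer(), p = double())
  }
  out
}
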