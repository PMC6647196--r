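#' Chi-square goodness-of-fit test for Mendelian segregation
#'
#' Tests observed phenotype counts of a two-class segregating population
#' against an expected Mendelian ratio (3:1 for a dominant locus in an F2,
#' 1:1 in a BC1). No continuity correction is applied: for a goodness-of-fit
#' test this is the standard convention, and it is the one that reproduces
#' published chi-square values for these population sizes.
#'
#' @param n_fuzzless,n_fuzzy observed counts of the two phenotype classes
#'   (mutant-like and wild-like).
#' @param expected_ratio length-2 positive numeric, expected
#'   fuzzless:fuzzy ratio, e.g. `c(3, 1)`.
#' @return list with `chi2` (statistic), `df` (degrees of freedom, classes
#'   minus one), `p`, and `observed_ratio` (majority/minority, 2 d.p.).
#' @examples
#' chi_square_gof(3004, 1006, c(3, 1))   # chi2 ~ 0.02
#' chi_square_gof(315, 292, c(1, 1))     # chi2 ~ 0.87
#' @export
chi_square_gof <- function(n_fuzzless, n_fuzzy, expected_ratio = c(3, 1)) {
  stopifnot(length(expected_ratio) == 2, all(expected_ratio > 0),
            n_fuzzless >= 0, n_fuzzy >= 0)
  obs <- c(n_fuzzless, n_fuzzy)
  if (sum(obs) == 0) stop("total count must be positive")
  prob <- expected_ratio / sum(expected_ratio)
  if (any(prob * sum(obs) == 0)) stop("zero expected count")
  ct <- suppressWarnings(stats::chisq.test(obs, p = prob))
  list(chi2 = unname(ct$statistic),
       df = unname(ct$parameter),
       p = unname(ct$p.value),
       observed_ratio = observed_ratio(n_fuzzless, n_fuzzy))
}

#' Observed segregation ratio
#'
#' Majority over minority class count, rounded to 2 decimal places, i.e. the
#' "x:1" form in which segregation tables report it.
#'
#' @inheritParams chi_square_gof
#' @return numeric scalar (the `x` of "x:1").
#' @examples
#' observed_ratio(3004, 1006)  # 2.99
#' @export
observed_ratio <- function(n_fuzzless, n_fuzzy) {
  minority <- min(n_fuzzless, n_fuzzy)
  if (minority == 0) stop("minority class is empty; ratio undefined")
  round(max(n_fuzzless, n_fuzzy) / minority, 2)
}

#' Segregation analysis of one or more populations
#'
#' Convenience wrapper applying [chi_square_gof()] row-wise to a counts
#' table, producing a segregation report.
#'
#' @param counts data.frame with columns `label`, `n_fuzzless`, `n_fuzzy`,
#'   `ratio_fuzzless`, `ratio_fuzzy` (the expected ratio components).
#' @return data.frame with the inputs plus `observed_ratio`, `chi2`, `df`
#'   and `p`.
#' @export
segregation_report <- function(counts) {
  need <- c("label", "n_fuzzless", "n_fuzzy", "ratio_fuzzless", "ratio_fuzzy")
  stopifnot(all(need %in% names(counts)))
  res <- lapply(seq_len(nrow(counts)), function(i) {
    g <- chi_square_gof(counts$n_fuzzless[i], counts$n_fuzzy[i],
                        c(counts$ratio_fuzzless[i], counts$ratio_fuzzy[i]))
    data.frame(observed_ratio = g$observed_ratio, chi2 = g$chi2,
               df = g$df, p = g$p)
  })
  cbind(counts, do.call(rbind, res))
}
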