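#' Default minor-allele-frequency bin edges
#'
#' Four bins as MAF fractions: \[0, 0.001\], (0.001, 0.01\], (0.01, 0.1\],
#' (0.1, 1\] - i.e. <=0.1%, 0.1-1%, 1-10%, >10%. The lowest bin is closed
#' on both sides so that a MAF of exactly 0.1% is "very rare".
#'
#' @return Numeric vector of 5 break points.
#' @export
mafBinEdges <- function() c(0, 0.001, 0.01, 0.1, 1)

#' Assign variants to MAF bins
#'
#' @param maf Minor allele frequencies as fractions in \[0, 1\].
#' @param binEdges Break points (default [mafBinEdges()]); intervals are
#'   right-closed, with the lowest also left-closed.
#' @return Factor of bin labels, one per variant; every variant falls in
#'   exactly one bin.
#' @export
binVariants <- function(maf, binEdges = mafBinEdges()) {
  if (any(maf < min(binEdges) | maf > max(binEdges), na.rm = TRUE))
    stop("MAF outside the binning range")
  cut(maf, breaks = binEdges, include.lowest = TRUE, right = TRUE)
}

#' Per-MAF-bin disruption summary
#'
#' Combines MAF binning with [disruptionRate()] and attaches the expected
#' number of missense variants per genome falling in each bin.
#'
#' @param maf,disruptive Per-variant MAF and disruptive flag.
#' @param genomeCounts Expected per-genome variant count per bin, in bin
#'   order (e.g. from [generateGenomeComposition()] or an external site
#'   frequency spectrum summary).
#' @param binEdges Break points (default [mafBinEdges()]).
#' @return data.frame with one row per bin: `bin`, `n_tested`,
#'   `n_disruptive`, `rate`, `se`, `genome_count`.
#' @export
mafBinSummary <- function(maf, disruptive, genomeCounts,
                          binEdges = mafBinEdges()) {
  bins <- binVariants(maf, binEdges)
  out <- disruptionRate(disruptive, bins)
  names(out)[names(out) == "stratum"] <- "bin"
  names(out)[names(out) == "n"] <- "n_tested"
  if (length(genomeCounts) != nrow(out))
    stop("'genomeCounts' must supply one count per bin")
  if (any(genomeCounts < 0)) stop("'genomeCounts' must be non-negative")
  out$genome_count <- genomeCounts
  out
}

#' Per-genome burden of interaction-disruptive missense variants
#'
#' Weights the MAF-stratified disruption rates by the expected per-genome
#' composition of missense variants over the same bins:
#' `expected = sum_b rate_b * genome_count_b`, with the standard error of
#' the aggregate rate propagated from the per-bin binomial standard errors
#' treating the composition as fixed:
#' `sem = sqrt(sum_b w_b^2 se_b^2)`, `w_b = genome_count_b / total`.
#'
#' @param bins data.frame as from [mafBinSummary()] (needs columns `rate`,
#'   `se`, `genome_count`).
#' @param totalMissense Total missense variants per genome; must match the
#'   summed `genome_count` (within rounding).
#' @return List of class `"BurdenEstimate"` with `total_missense`,
#'   `expected_disruptive`, `rate`, `sem`.
#' @export
perGenomeBurden <- function(bins, totalMissense = sum(bins$genome_count)) {
  if (totalMissense <= 0) stop("'totalMissense' must be positive")
  if (abs(sum(bins$genome_count) - totalMissense) > 1e-6 * totalMissense)
    stop("bin genome counts do not sum to 'totalMissense'")
  if (anyNA(bins$rate))
    stop("every bin with genome mass needs an estimated rate")
  expected <- sum(bins$rate * bins$genome_count)
  w <- bins$genome_count / totalMissense
  se <- ifelse(is.na(bins$se), 0, bins$se)
  out <- list(total_missense = totalMissense,
              expected_disruptive = expected,
              rate = expected / totalMissense,
              sem = sqrt(sum(w^2 * se^2)))
  class(out) <- "BurdenEstimate"
  out
}

#' @export
print.BurdenEstimate <- function(x, ...) {
  cat(sprintf(
    "Per-genome burden: %.0f of %.0f missense variants disruptive (%.1f%% +/- %.1f%% SEM)\n",
    x$expected_disruptive, x$total_missense, 100 * x$rate, 100 * x$sem))
  invisible(x)
}

#' Exome-wide count of disruptive missense variants
#'
#' Scales the mean per-individual disruption rate to a population-level
#' missense-variant total, propagating the rate's SEM multiplicatively.
#'
#' @param meanRate Mean disruption rate per individual (fraction).
#' @param totalMissensePopulation Total missense variants in the
#'   population-scale catalogue.
#' @param sem Optional SEM of `meanRate`.
#' @return List with `count` and `se` (`NA` when `sem` is missing).
#' @export
exomeWideCount <- function(meanRate, totalMissensePopulation, sem = NULL) {
  list(count = meanRate * totalMissensePopulation,
       se = if (is.null(sem)) NA_real_ else sem * totalMissensePopulation)
}

#' Chi-square trend test across MAF bins
#'
#' Pearson chi-square on the 2 x k disruptive/non-disruptive table.
#'
#' @param bins data.frame with columns `n_tested` and `n_disruptive`.
#' @return List with `statistic`, `df`, `p` (see [chiSquare2xk()]).
#' @export
trendTest <- function(bins) {
  chiSquare2xk(bins$n_disruptive, bins$n_tested)
}
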