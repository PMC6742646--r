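## base-2 Shannon entropy of a probability vector (zeros contribute 0)
.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence between two distributions
#'
#' Equal-weight, base-2 formulation:
#' `JSD(P, Q) = H((P + Q)/2) - (H(P) + H(Q))/2`, bounded in \[0, 1\] bits.
#'
#' @param p,q Probability vectors over the same support (renormalized).
#' @return The divergence in bits.
#' @export
jsDivergence <- function(p, q) {
  if (length(p) != length(q)) stop("'p' and 'q' need the same support")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be non-negative")
  if (sum(p) == 0 || sum(q) == 0) stop("distributions must have mass")
  p <- p / sum(p)
  q <- q / sum(q)
  .entropy2((p + q) / 2) - (.entropy2(p) + .entropy2(q)) / 2
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## BLOSUM62 amino-acid background frequencies (Henikoff & Henikoff),
## renormalized over the 20 standard residues
.blosum62Background <- function() {
  f <- c(A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
         G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
         M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
         S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)
  f[.AA20] / sum(f)
}

#' Per-position conservation from an MSA by Jensen-Shannon divergence
#'
#' Scores each alignment column by the divergence between its amino-acid
#' distribution and a background distribution. Gap characters are excluded
#' from column distributions; columns with more than `maxGapFraction` gaps
#' are flagged low-confidence, and all-gap columns get an `NA` score. The
#' track is `usable` only when the alignment holds at least `minHomologs`
#' sequences.
#'
#' @param msa An `AAStringSet` (Biostrings), character vector of aligned
#'   sequences, or character matrix (sequences x columns).
#' @param background `"uniform"` (default), `"blosum62"`, or a named
#'   numeric vector of amino-acid frequencies.
#' @param minHomologs Homolog threshold for a usable track (default 50).
#' @param maxGapFraction Gap fraction above which a column is flagged
#'   (default 0.3).
#' @return data.frame with `position`, `score`, `gap_fraction`,
#'   `low_confidence`; attributes `n_homologs` and `usable`.
#' @export
jsdConservation <- function(msa, background = c("uniform", "blosum62"),
                            minHomologs = 50L, maxGapFraction = 0.3) {
  if (is(msa, "AAStringSet"))
    msa <- as.character(msa)
  if (is.character(msa)) {
    if (length(unique(nchar(msa))) != 1L)
      stop("aligned sequences must have equal length")
    msa <- do.call(rbind, strsplit(toupper(msa), ""))
  }
  if (is.numeric(background)) {
    q <- background[.AA20]
    if (anyNA(q)) stop("custom background must name all 20 amino acids")
    q <- q / sum(q)
  } else {
    q <- switch(match.arg(background),
                uniform = stats::setNames(rep(1 / 20, 20), .AA20),
                blosum62 = .blosum62Background())
  }
  ncolumns <- ncol(msa)
  score <- gapFrac <- numeric(ncolumns)
  for (j in seq_len(ncolumns)) {
    col <- msa[, j]
    gap <- !(col %in% .AA20)
    gapFrac[j] <- mean(gap)
    if (all(gap)) {
      score[j] <- NA_real_
      next
    }
    p <- table(factor(col[!gap], levels = .AA20))
    score[j] <- jsDivergence(as.numeric(p), q)
  }
  out <- data.frame(position = seq_len(ncolumns), score = score,
                    gap_fraction = gapFrac,
                    low_confidence = gapFrac > maxGapFraction | is.na(score))
  attr(out, "n_homologs") <- nrow(msa)
  attr(out, "usable") <- nrow(msa) >= minHomologs
  out
}

#' Fay and Wu's H from a window's site frequency spectrum
#'
#' `H = theta_pi - theta_H` over the unfolded (derived-allele-polarized)
#' site frequency spectrum of one window, with
#' `theta_pi = sum_i 2 s_i i (n - i) / (n (n - 1))` and
#' `theta_H  = sum_i 2 s_i i^2 / (n (n - 1))`.
#' Negative values flag an excess of high-frequency derived alleles, the
#' signature of a completed selective sweep nearby.
#'
#' @param s Vector of length `n - 1`: `s[i]` is the number of sites whose
#'   derived allele is carried by exactly `i` of the `n` chromosomes.
#' @param n Number of sampled chromosomes (>= 2).
#' @return H (0 for a window without segregating sites).
#' @examples
#' fayWuH(c(0, 0, 1), 4)  # one site at derived count 3: -1
#' fayWuH(c(1, 0, 0), 4)  # one singleton: +1/3
#' @export
fayWuH <- function(s, n) {
  if (n < 2) stop("'n' must be >= 2")
  if (length(s) != n - 1)
    stop("'s' must have n - 1 entries (derived counts 1..n-1); ",
         "a derived count of n or more is not a segregating site")
  if (any(s < 0)) stop("site counts must be non-negative")
  i <- seq_len(n - 1)
  thetaPi <- sum(2 * s * i * (n - i)) / (n * (n - 1))
  thetaH <- sum(2 * s * i^2) / (n * (n - 1))
  thetaPi - thetaH
}

#' Flag genomic windows under putative positive selection
#'
#' Within each population group, windows whose H statistic lies at or
#' below the group's 5th percentile are significant; ties at the
#' percentile value are all flagged, so with all-distinct values exactly
#' `ceiling(0.05 N)` windows are flagged. Windows with fewer than
#' `minSnps` polarized SNPs have no measurable H: they are excluded from
#' the percentile computation and get an `NA` flag.
#'
#' @param windows data.frame with columns `h` and optionally `group`
#'   (population) and `n_snps`.
#' @param percentile Percentile threshold (default 5).
#' @param minSnps Minimum polarized SNPs for a measurable H (default 3).
#' @return The input with added logical column `significant`.
#' @export
flagSelectedWindows <- function(windows, percentile = 5, minSnps = 3L) {
  grp <- if ("group" %in% names(windows)) windows$group else "all"
  measurable <- if ("n_snps" %in% names(windows))
    windows$n_snps >= minSnps else rep(TRUE, nrow(windows))
  sig <- rep(NA, nrow(windows))
  for (g in unique(grp)) {
    idx <- which(grp == g & measurable)
    if (length(idx) == 0L) next
    h <- windows$h[idx]
    kth <- sort(h)[ceiling(percentile / 100 * length(h))]
    sig[idx] <- h <= kth
  }
  windows$significant <- sig
  windows
}

#' Enrichment of disruptive variants in selected regions
#'
#' Among variants lying in windows with a measurable H statistic, compares
#' the fraction of disruptive variants falling in significant windows with
#' the corresponding fraction for non-disruptive variants (one-tailed
#' pooled-Z test, disruptive > non-disruptive).
#'
#' @param disruptive Logical per variant.
#' @param inSignificant Logical per variant: lies in a flagged window
#'   (`NA` = no measurable window; dropped).
#' @return List with `summary` (per-class n, fraction, se) and `test`.
#' @export
selectionEnrichment <- function(disruptive, inSignificant) {
  keep <- !is.na(inSignificant)
  disruptive <- disruptive[keep]
  inSignificant <- inSignificant[keep]
  cls <- ifelse(disruptive, "disruptive", "non-disruptive")
  summary <- disruptionRate(inSignificant, cls)
  names(summary)[names(summary) %in% c("n_disruptive", "rate")] <-
    c("n_in_significant", "fraction")
  d <- summary[summary$stratum == "disruptive", ]
  nd <- summary[summary$stratum == "non-disruptive", ]
  test <- if (nrow(d) == 1 && nrow(nd) == 1 && d$n > 0 && nd$n > 0)
    twoPropZ(d$n_in_significant, d$n, nd$n_in_significant, nd$n,
             tail = "greater")
  else NULL
  list(summary = summary, test = test)
}

#' Similarity score for a candidate duplicate-protein pair
#'
#' `Score = alpha * PercentIdentity * Coverage_Avg + (1 - alpha) *
#' Coverage_Avg` with `alpha = 0.95` and `Coverage_Avg` the mean of the
#' two proteins' alignment coverages. All inputs are fractions in
#' \[0, 1\], so the score is bounded by 1 (perfect duplicates). Pairs with
#' identity below `minIdentity` carry no appreciable similarity and score
#' `NA`.
#'
#' @param percentIdentity Pairwise percent identity as a fraction.
#' @param coverageA,coverageB Alignment coverage of each protein.
#' @param alpha Identity weight (default 0.95).
#' @param minIdentity Exclusion threshold (default 0.40).
#' @return Numeric score(s) in \[0, 1\], `NA` for excluded pairs.
#' @examples
#' duplicateScore(0.5, 0.8, 0.8)  # 0.42
#' @export
duplicateScore <- function(percentIdentity, coverageA, coverageB,
                           alpha = 0.95, minIdentity = 0.40) {
  if (any(c(percentIdentity, coverageA, coverageB) < 0) ||
      any(c(percentIdentity, coverageA, coverageB) > 1))
    stop("identity and coverages must be fractions in [0, 1]")
  covAvg <- (coverageA + coverageB) / 2
  score <- alpha * percentIdentity * covAvg + (1 - alpha) * covAvg
  score[percentIdentity < minIdentity] <- NA_real_
  score
}

#' Score a table of candidate duplicate pairs
#'
#' Drops pairs below the identity threshold, then applies
#' [duplicateScore()].
#'
#' @param pairs data.frame with columns `protein_a`, `protein_b`,
#'   `percent_identity`, `coverage_a`, `coverage_b`.
#' @param alpha,minIdentity See [duplicateScore()].
#' @return The retained rows with added `coverage_avg` and `score`.
#' @export
scoreDuplicatePairs <- function(pairs, alpha = 0.95, minIdentity = 0.40) {
  keep <- pairs$percent_identity >= minIdentity
  out <- pairs[keep, , drop = FALSE]
  out$coverage_avg <- (out$coverage_a + out$coverage_b) / 2
  out$score <- duplicateScore(out$percent_identity, out$coverage_a,
                              out$coverage_b, alpha, minIdentity)
  out
}

#' Interface residues from solvent-accessibility change
#'
#' A residue is an interface residue when its solvent-accessible surface
#' area shrinks by strictly more than 1 A^2 upon binding.
#'
#' @param sasaUnbound,sasaBound Per-residue SASA (A^2) in the unbound and
#'   bound states (same residue order, 1-based positions).
#' @param cutoff Minimum SASA change (default 1, strict inequality).
#' @return Integer vector of interface residue positions.
#' @export
interfaceResidues <- function(sasaUnbound, sasaBound, cutoff = 1) {
  if (length(sasaUnbound) != length(sasaBound))
    stop("bound and unbound SASA vectors must align")
  which(sasaUnbound - sasaBound > cutoff)
}

#' Classify variant positions relative to an interaction interface
#'
#' A domain is an interacting domain when it is annotated as mediating
#' protein-protein interactions and contains at least `minInterface`
#' interface residues. A variant position is `on_interface` when it hits
#' an interface residue or lies inside an interacting domain, else `away`.
#'
#' @param variantPositions Integer residue positions to classify.
#' @param sasaUnbound,sasaBound Per-residue SASA (see
#'   [interfaceResidues()]).
#' @param domains data.frame with columns `start`, `end`, `mediates_ppi`;
#'   may be empty.
#' @param minInterface Interface residues required for an interacting
#'   domain (default 5).
#' @return data.frame with `position` and `label`
#'   (`on_interface`/`away`).
#' @export
interfaceClassify <- function(variantPositions, sasaUnbound, sasaBound,
                              domains = NULL, minInterface = 5L) {
  ir <- interfaceResidues(sasaUnbound, sasaBound)
  inDomain <- rep(FALSE, length(variantPositions))
  if (!is.null(domains) && nrow(domains)) {
    interacting <- vapply(seq_len(nrow(domains)), function(i) {
      isTRUE(domains$mediates_ppi[i]) &&
        sum(ir >= domains$start[i] & ir <= domains$end[i]) >= minInterface
    }, logical(1))
    for (i in which(interacting))
      inDomain <- inDomain | (variantPositions >= domains$start[i] &
                                variantPositions <= domains$end[i])
  }
  label <- ifelse(variantPositions %in% ir | inDomain, "on_interface",
                  "away")
  data.frame(position = variantPositions, label = label,
             stringsAsFactors = FALSE)
}

#' Interface enrichment of disrupted interactions
#'
#' Compares the fraction of disrupted interactions for variants on the
#' interface versus away from it (one-tailed pooled-Z test).
#'
#' @param label `"on_interface"`/`"away"` per variant-interaction pair.
#' @param disrupted Logical per pair.
#' @return List with `summary` and `test` (as [selectionEnrichment()]).
#' @export
interfaceEnrichment <- function(label, disrupted) {
  summary <- disruptionRate(disrupted, label)
  names(summary)[names(summary) == "rate"] <- "fraction"
  on <- summary[summary$stratum == "on_interface", ]
  away <- summary[summary$stratum == "away", ]
  test <- if (nrow(on) == 1 && nrow(away) == 1 && on$n > 0 && away$n > 0)
    twoPropZ(on$n_disruptive, on$n, away$n_disruptive, away$n,
             tail = "greater")
  else NULL
  list(summary = summary, test = test)
}

#' Cumulative mean allele frequency by conservation cutoff
#'
#' For each conservation cutoff, averages the global allele frequency over
#' all variants whose conservation score is at least the cutoff,
#' separately for disruptive and non-disruptive variants. The curve is
#' defined only where at least one variant remains.
#'
#' @param score Per-variant conservation score (JSD or phyloP-like).
#' @param maf Per-variant global allele frequency.
#' @param disruptive Logical per variant.
#' @param cutoffs Cutoff grid (default 0.2 to 1.0 by 0.1).
#' @return data.frame with `cutoff`, `class`, `n`, `mean_af`.
#' @export
afByConservationCutoff <- function(score, maf, disruptive,
                                   cutoffs = seq(0.2, 1, by = 0.1)) {
  out <- lapply(cutoffs, function(cc) {
    do.call(rbind, lapply(c(TRUE, FALSE), function(d) {
      sel <- !is.na(score) & score >= cc & disruptive == d
      data.frame(cutoff = cc,
                 class = if (d) "disruptive" else "non-disruptive",
                 n = sum(sel),
                 mean_af = if (any(sel)) mean(maf[sel]) else NA_real_)
    }))
  })
  do.call(rbind, out)
}
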