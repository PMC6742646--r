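#' Local sequencing-error estimate at a position
#'
#' Estimates the inherent per-position sequencing error as the average
#' fraction of non-wild-type reads over the 10 non-targeted positions
#' closest (by coordinate distance) to the query position. The query
#' position itself and every targeted position are excluded; positions
#' covered by fewer than `minCoverage` reads are excluded as
#' noise-dominated. Equidistant candidates tied at the 10th place are all
#' included, so the neighbourhood may contain 11 or more positions.
#'
#' @param pileup An [AllelePileup-class].
#' @param design A [PoolDesign-class] (its targeted positions are excluded).
#' @param position Query position (1-based, must be present in the pileup).
#' @param k Number of neighbours to average over (default 10).
#' @param minCoverage Minimum read depth for a position to contribute
#'   (default 10).
#' @return Estimated sequencing-error probability (a single number).
#' @examples
#' cnt <- matrix(0L, 11, 6, dimnames = list(NULL, alleleAlphabet()))
#' cnt[, "A"] <- 990L; cnt[, "C"] <- 10L
#' pu <- AllelePileup("ORF1", 1:11, cnt, rep("A", 11))
#' de <- PoolDesign("ORF1", 4, data.frame(position = 6, mut_allele = "C"))
#' estimateSeqErr(pu, de, 6)  # 0.01
#' @export
estimateSeqErr <- function(pileup, design, position, k = 10L,
                           minCoverage = 10L) {
  stopifnot(is(pileup, "AllelePileup"), is(design, "PoolDesign"))
  pos <- positions(pileup)
  dp <- depth(pileup)
  excl <- unique(c(targeted(design)$position, position))
  usable <- !(pos %in% excl) & dp >= minCoverage & dp > 0
  if (!any(usable))
    stop("no usable non-targeted positions with coverage; pool unusable")
  cand <- which(usable)
  d <- abs(pos[cand] - position)
  ord <- order(d)
  keep <- if (length(cand) <= k) seq_along(cand) else {
    cutoff <- d[ord[k]]
    which(d <= cutoff)          # ties at the k-th distance are all included
  }
  idx <- cand[keep]
  cnt <- alleleCounts(pileup)
  nonwt <- dp[idx] - cnt[cbind(idx, match(wtAllele(pileup)[idx],
                                          alleleAlphabet()))]
  mean(nonwt / dp[idx])
}

#' Expected mutant-allele read fraction in a pool
#'
#' The fraction of reads expected to carry a mutant allele at a position if
#' the mutation truly occurred in one of the pooled clones:
#' `1/TotalMutations` from the mutant clone, plus sequencing errors in the
#' other clones converting wild type to the mutant allele, minus sequencing
#' errors in the mutant clone converting the mutant allele away:
#' \deqn{E = 1/T + (T-1)\,\epsilon - (A-1)\,\epsilon}
#' with `T` the number of pooled clones, `A` the allele alphabet size and
#' \eqn{\epsilon} the local sequencing error.
#'
#' @param totalMutations Number of ORF copies in the pool (>= 1).
#' @param seqErr Sequencing-error probability at the position.
#' @param alleles Allele alphabet size (default 6).
#' @return Expected mutant read fraction in (0, 1].
#' @examples
#' expectedFraction(4, 0)        # 0.25
#' expectedFraction(5, 0.001)    # 0.199
#' @export
expectedFraction <- function(totalMutations, seqErr, alleles = 6L) {
  if (any(totalMutations < 1)) stop("'totalMutations' must be >= 1")
  if (any(seqErr < 0 | seqErr > 1)) stop("'seqErr' must be a probability")
  if (any(alleles < 2)) stop("'alleles' must be >= 2")
  e <- 1 / totalMutations + (totalMutations - 1) * seqErr -
    (alleles - 1) * seqErr
  if (any(e <= 0))
    stop("expected fraction is non-positive; sequencing error too high ",
         "relative to pool size")
  e
}

#' Mutation score: observed over expected mutant fraction
#'
#' The score for a candidate mutation is the observed mutant-allele read
#' fraction divided by the expected fraction ([expectedFraction()]).
#' Scores at or above 0.5 call a true mutation.
#'
#' @param observed Observed mutant-allele read fraction.
#' @param expected Expected fraction (> 0).
#' @return Score (>= 0).
#' @examples
#' mutationScore(0.125, 0.25)  # 0.5, a boundary call
#' @export
mutationScore <- function(observed, expected) {
  if (any(expected <= 0)) stop("'expected' must be > 0")
  if (any(observed < 0 | observed > 1)) stop("'observed' must be in [0,1]")
  observed / expected
}

## per-position seq-err for every position of a pileup (self excluded);
## shared by the desired-mutation call and the off-target scan
.seqErrProfile <- function(pileup, design, k, minCoverage) {
  vapply(positions(pileup), function(p)
    estimateSeqErr(pileup, design, p, k = k, minCoverage = minCoverage),
    numeric(1))
}

#' Call mutant clones from a pooled pileup
#'
#' For each targeted (position, allele) in the design, computes the
#' mutation score and calls the desired mutation when the score reaches
#' `threshold` (boundary inclusive). Every non-targeted position is then
#' scanned for unwanted off-target mutations using the same scoring scheme
#' and pool size; a clone is accepted only when its desired mutation is
#' called and no off-target mutation is found. Positions below
#' `minCoverage` are flagged and skipped in the off-target scan; a targeted
#' position with zero coverage makes that call uncallable rather than
#' silently failing.
#'
#' @param pileup An [AllelePileup-class].
#' @param design A [PoolDesign-class].
#' @param threshold Score threshold for calling a mutation (default 0.5).
#' @param k,minCoverage Passed to [estimateSeqErr()].
#' @return A list with elements
#'   \item{desired}{data.frame, one row per targeted mutation: position,
#'     alleles, observed/expected fractions, seq_err, score, flags
#'     `called`, `callable`.}
#'   \item{off_targets}{data.frame of non-targeted positions whose best
#'     non-reference allele scored at or above the threshold.}
#'   \item{accepted}{logical: desired called on every target and no
#'     off-target found.}
#'   \item{max_undesired_score}{largest score seen at any non-targeted
#'     position (0 when none is computable).}
#'   \item{mean_depth, mean_quality}{pool-level summaries used in ranking.}
#' @seealso [rankClones()]
#' @export
callClones <- function(pileup, design, threshold = 0.5, k = 10L,
                       minCoverage = 10L) {
  stopifnot(is(pileup, "AllelePileup"), is(design, "PoolDesign"))
  tg <- targeted(design)
  pos <- positions(pileup)
  if (!all(tg$position %in% pos))
    stop("design targets positions absent from the pileup")
  cnt <- alleleCounts(pileup)
  dp <- depth(pileup)
  wt <- wtAllele(pileup)
  ab <- alleleAlphabet()
  tm <- totalMutations(design)
  na <- nAlleles(design)
  se <- .seqErrProfile(pileup, design, k, minCoverage)

  ## desired calls
  di <- match(tg$position, pos)
  desired <- data.frame(
    orf_id = orfId(pileup),
    position = tg$position,
    wt_allele = wt[di],
    mut_allele = tg$mut_allele,
    observed_fraction = NA_real_, seq_err = se[di],
    expected_fraction = NA_real_, score = NA_real_,
    callable = dp[di] > 0, called = FALSE,
    stringsAsFactors = FALSE)
  ok <- desired$callable
  if (any(ok)) {
    obs <- cnt[cbind(di[ok], match(tg$mut_allele[ok], ab))] / dp[di][ok]
    exp <- expectedFraction(tm, se[di][ok], na)
    desired$observed_fraction[ok] <- obs
    desired$expected_fraction[ok] <- exp
    desired$score[ok] <- mutationScore(obs, exp)
    desired$called[ok] <- desired$score[ok] >= threshold
  }

  ## off-target scan over all non-targeted, adequately covered positions
  scan <- which(!(pos %in% tg$position) & dp >= minCoverage)
  off <- data.frame(position = integer(), wt_allele = character(),
                    mut_allele = character(), observed_fraction = numeric(),
                    expected_fraction = numeric(), score = numeric(),
                    stringsAsFactors = FALSE)
  maxUndesired <- 0
  if (length(scan)) {
    exp <- expectedFraction(tm, se[scan], na)
    frac <- cnt[scan, , drop = FALSE] / dp[scan]
    frac[cbind(seq_along(scan), match(wt[scan], ab))] <- 0  # ignore WT allele
    best <- max.col(frac, ties.method = "first")
    obs <- frac[cbind(seq_along(best), best)]
    score <- obs / exp
    maxUndesired <- max(score)
    hit <- score >= threshold
    if (any(hit))
      off <- data.frame(position = pos[scan][hit],
                        wt_allele = wt[scan][hit],
                        mut_allele = ab[best[hit]],
                        observed_fraction = obs[hit],
                        expected_fraction = exp[hit],
                        score = score[hit], stringsAsFactors = FALSE)
  }

  desired$accepted <- desired$callable & desired$called & nrow(off) == 0L
  list(orf_id = orfId(pileup),
       desired = desired,
       off_targets = off,
       accepted = all(desired$callable & desired$called) && nrow(off) == 0L,
       max_undesired_score = maxUndesired,
       mean_depth = mean(dp),
       mean_quality = if (all(is.na(meanQual(pileup)))) NA_real_
                      else mean(meanQual(pileup), na.rm = TRUE))
}

#' Rank clone reports
#'
#' Orders clone reports lexicographically by: desired-mutation score
#' (descending), maximum undesired-mutation score (ascending), mean
#' sequencing coverage (descending) and mean base quality (descending).
#' Ties left unresolved keep their input order (stable sort).
#'
#' @param reports A list of reports as returned by [callClones()], or a
#'   data.frame with columns `desired_score`, `max_undesired_score`,
#'   `mean_depth`, `mean_quality`.
#' @return The reports reordered; for list input, the reordered list with
#'   attribute `"order"` giving the permutation.
#' @export
rankClones <- function(reports) {
  if (is.data.frame(reports)) {
    tab <- reports
  } else {
    tab <- data.frame(
      desired_score = vapply(reports, function(r)
        min(r$desired$score, na.rm = TRUE), numeric(1)),
      max_undesired_score = vapply(reports, function(r)
        r$max_undesired_score, numeric(1)),
      mean_depth = vapply(reports, function(r) r$mean_depth, numeric(1)),
      mean_quality = vapply(reports, function(r) r$mean_quality, numeric(1)))
  }
  q <- tab$mean_quality
  q[is.na(q)] <- -Inf
  o <- order(-tab$desired_score, tab$max_undesired_score,
             -tab$mean_depth, -q)
  if (is.data.frame(reports)) {
    out <- reports[o, , drop = FALSE]
  } else {
    out <- reports[o]
  }
  attr(out, "order") <- o
  out
}

#' Validate a variant-to-ORF mapping
#'
#' A clone library ORF is a valid representative for a transcript-annotated
#' variant when (i) the two protein sequences are identical within a 31
#' amino-acid window centred on the target position (truncated at sequence
#' termini), and (ii) either their global identity exceeds 95%, or the ORF
#' is an exact substring of the transcript spanning at least one third of
#' it.
#'
#' @param orfProtein,transcriptProtein Amino-acid sequences (single
#'   strings, same coordinate frame at the target position).
#' @param targetPosition 1-based residue position of the variant in the ORF.
#' @param globalIdentity Global percent identity between the two sequences,
#'   as a fraction in \[0, 1\] (from an external pairwise-alignment summary).
#' @param window Window width in residues (default 31).
#' @return `TRUE` if the mapping is valid, else `FALSE`.
#' @examples
#' validateOrfMapping("MKTAYIAKQR", "MKTAYIAKQR", 5, 1.0)   # TRUE
#' @export
validateOrfMapping <- function(orfProtein, transcriptProtein, targetPosition,
                               globalIdentity, window = 31L) {
  orf <- strsplit(orfProtein, "")[[1]]
  tr <- strsplit(transcriptProtein, "")[[1]]
  if (length(orf) == 0L || length(tr) == 0L)
    stop("sequences must be non-empty")
  if (targetPosition < 1L || targetPosition > length(orf))
    stop("'targetPosition' outside the ORF")
  half <- (window - 1L) %/% 2L
  lo <- max(1L, targetPosition - half)
  hi <- min(length(orf), length(tr), targetPosition + half)
  if (lo > length(tr))
    return(FALSE)
  windowOk <- identical(orf[lo:hi], tr[lo:hi])
  subsetOk <- grepl(orfProtein, transcriptProtein, fixed = TRUE) &&
    nchar(orfProtein) >= nchar(transcriptProtein) / 3
  windowOk && (globalIdentity > 0.95 || subsetOk)
}
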