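# shared fixture builders (built in code, nothing read from disk)

# a flat pileup: every position pure WT apart from explicit overrides
flatPileup <- function(L = 30L, depth = 1000L, wt = "A",
                       orf = "ORFX") {
  cnt <- matrix(0L, L, 6L, dimnames = list(NULL, alleleAlphabet()))
  cnt[, wt] <- depth
  AllelePileup(orf, seq_len(L), cnt, rep(wt, L))
}

setCounts <- function(pileup, position, counts) {
  cnt <- alleleCounts(pileup)
  cnt[position, ] <- counts
  AllelePileup(orfId(pileup), positions(pileup), cnt, wtAllele(pileup),
               meanQual(pileup))
}

# brute-force nearest-neighbour seq-err oracle (ties at the k-th distance
# all included), independent of estimateSeqErr's implementation
bruteSeqErr <- function(pileup, design, position, k = 10L,
                        minCoverage = 10L) {
  pos <- positions(pileup)
  cnt <- alleleCounts(pileup)
  dp <- rowSums(cnt)
  excl <- unique(c(targeted(design)$position, position))
  cand <- setdiff(pos[dp >= minCoverage & dp > 0], excl)
  d <- sort(unique(abs(cand - position)))
  picked <- integer()
  for (dd in d) {
    ring <- cand[abs(cand - position) == dd]
    picked <- c(picked, ring)
    if (length(picked) >= k) break
  }
  fr <- vapply(picked, function(p) {
    i <- match(p, pos)
    (dp[i] - cnt[i, wtAllele(pileup)[i]]) / dp[i]
  }, numeric(1))
  mean(fr)
}
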