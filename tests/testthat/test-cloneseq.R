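test_that("expected mutant fraction follows the pool model", {
  expect_equal(expectedFraction(4, 0), 0.25)
  expect_equal(expectedFraction(5, 0.001), 0.199)
  expect_equal(expectedFraction(1, 0.002), 0.99)
  # zero-error closed form: exactly 1/totalMutations
  for (tm in 1:12)
    expect_identical(expectedFraction(tm, 0), 1 / tm)
  # pathological error rates are rejected, not silently scored
  expect_error(expectedFraction(2, 0.2), "non-positive")
  expect_error(expectedFraction(0, 0.001))
  expect_error(expectedFraction(4, -0.1), "probability")
})

test_that("mutation score is observed over expected, boundary inclusive", {
  expect_equal(mutationScore(0.25, 0.25), 1.0)
  expect_equal(mutationScore(0.125, 0.25), 0.5)
  expect_equal(mutationScore(0.10, 0.25), 0.4)
  expect_error(mutationScore(0.1, 0), "> 0")
  # a boundary score of exactly 0.5 calls the mutation
  pu <- flatPileup(L = 25L, depth = 1000L)
  pu <- setCounts(pu, 13L, c(A = 875L, C = 125L, G = 0L, T = 0L,
                             ins = 0L, del = 0L))
  de <- PoolDesign("ORFX", 2L, data.frame(position = 13, mut_allele = "C"))
  rep <- callClones(pu, de)  # seq_err 0 -> expected 0.5, observed 0.125
  expect_equal(rep$desired$score, 0.25)
  expect_false(rep$desired$called)
  pu2 <- setCounts(pu, 13L, c(A = 750L, C = 250L, G = 0L, T = 0L,
                              ins = 0L, del = 0L))
  rep2 <- callClones(pu2, de)
  expect_equal(rep2$desired$score, 0.5)
  expect_true(rep2$desired$called)
})

test_that("score is invariant under uniform depth scaling", {
  cfg <- simConfig(seed = 11, pool = list(depth = 500L, orf_length = 60L))
  pool <- generatePool(cfg)
  rep1 <- callClones(pool$pileup, pool$design)
  scaled <- AllelePileup(orfId(pool$pileup), positions(pool$pileup),
                         alleleCounts(pool$pileup) * 7L,
                         wtAllele(pool$pileup))
  rep2 <- callClones(scaled, pool$design)
  expect_equal(rep2$desired$score, rep1$desired$score)
})

test_that("local sequencing error matches the nearest-neighbour rule", {
  # 10 neighbours each with non-WT fraction 0.01 -> 0.01
  pu <- flatPileup(L = 21L, depth = 1000L)
  for (i in setdiff(1:21, 11))
    pu <- setCounts(pu, i, c(A = 990L, C = 10L, G = 0L, T = 0L,
                             ins = 0L, del = 0L))
  de <- PoolDesign("ORFX", 4L, data.frame(position = 11, mut_allele = "G"))
  expect_equal(estimateSeqErr(pu, de, 11), 0.01)

  # two available neighbours with fractions 0 and 0.02 -> mean 0.01
  pu2 <- flatPileup(L = 3L, depth = 1000L)
  pu2 <- setCounts(pu2, 3L, c(A = 980L, C = 20L, G = 0L, T = 0L,
                              ins = 0L, del = 0L))
  de2 <- PoolDesign("ORFX", 4L, data.frame(position = 2, mut_allele = "G"))
  expect_equal(estimateSeqErr(pu2, de2, 2), 0.01)

  # no usable neighbour at all signals an unusable pool
  puEmpty <- flatPileup(L = 2L, depth = 0L)
  expect_error(estimateSeqErr(puEmpty, de2, 2), "unusable")
})

test_that("seq-err estimate equals a brute-force neighbour search", {
  set.seed(42)
  for (rep in 1:10) {
    L <- sample(15:60, 1)
    cnt <- matrix(0L, L, 6L, dimnames = list(NULL, alleleAlphabet()))
    wt <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    for (i in seq_len(L)) {
      cnt[i, wt[i]] <- sample(c(0L, 5L, 200L, 1000L), 1,
                              prob = c(.05, .1, .4, .45))
      cnt[i, sample(setdiff(alleleAlphabet(), wt[i]), 1)] <-
        sample(0:10, 1)
    }
    pu <- AllelePileup("R", seq_len(L), cnt, wt)
    tgt <- sort(sample.int(L, sample(1:3, 1)))
    de <- PoolDesign("R", 4L, data.frame(position = tgt, mut_allele = "ins"))
    q <- sample(tgt, 1)
    got <- try(estimateSeqErr(pu, de, q), silent = TRUE)
    want <- try(bruteSeqErr(pu, de, q), silent = TRUE)
    if (inherits(want, "try-error")) {
      expect_s3_class(got, "try-error")
    } else {
      expect_equal(got, want)
    }
  }
  # equidistant ring entirely excluded (targeted) -> next ring used
  pu <- flatPileup(L = 9L, depth = 1000L)
  pu <- setCounts(pu, 1L, c(A = 900L, C = 100L, G = 0L, T = 0L,
                            ins = 0L, del = 0L))
  pu <- setCounts(pu, 9L, c(A = 900L, C = 100L, G = 0L, T = 0L,
                            ins = 0L, del = 0L))
  de <- PoolDesign("ORFX", 4L,
                   data.frame(position = c(4, 6), mut_allele = "C"))
  expect_equal(estimateSeqErr(pu, de, 5, k = 2L), bruteSeqErr(pu, de, 5, k = 2L))
})

test_that("planted mutations are called and off-targets rejected", {
  cfg <- simConfig(seed = 5, pool = list(total_mutations = 4L,
                                         depth = 100000L,
                                         seq_err = 0.001,
                                         orf_length = 120L))
  pool <- generatePool(cfg)
  rep <- callClones(pool$pileup, pool$design)
  expect_true(all(abs(rep$desired$observed_fraction - 0.25) < 0.01))
  expect_true(all(abs(rep$desired$score - 1) < 0.05))
  expect_true(rep$accepted)
  expect_identical(nrow(rep$off_targets), 0L)

  # a planted off-target mutation at clone fraction rejects the pool
  cfgOff <- simConfig(seed = 5, pool = list(total_mutations = 4L,
                                            depth = 100000L,
                                            seq_err = 0.001,
                                            orf_length = 120L,
                                            off_targets = 1L))
  poolOff <- generatePool(cfgOff)
  repOff <- callClones(poolOff$pileup, poolOff$design)
  expect_false(repOff$accepted)
  offTruth <- poolOff$truth[poolOff$truth$type == "off_target", ]
  expect_true(all(offTruth$position %in% repOff$off_targets$position))
})

test_that("error-free WT-only pools yield no calls anywhere", {
  pu <- flatPileup(L = 40L, depth = 5000L)
  de <- PoolDesign("ORFX", 4L, data.frame(position = 20, mut_allele = "T"))
  rep <- callClones(pu, de)
  expect_false(rep$desired$called)
  expect_identical(nrow(rep$off_targets), 0L)
  expect_false(rep$accepted)
})

test_that("targeted positions with zero coverage are flagged uncallable", {
  pu <- flatPileup(L = 30L, depth = 1000L)
  pu <- setCounts(pu, 15L, rep(0L, 6))
  de <- PoolDesign("ORFX", 4L, data.frame(position = 15, mut_allele = "C"))
  rep <- callClones(pu, de)
  expect_false(rep$desired$callable)
  expect_false(rep$accepted)
})

test_that("clone ranking is lexicographic and matches a brute-force sort", {
  base <- data.frame(desired_score = 1, max_undesired_score = 0.1,
                     mean_depth = 100, mean_quality = 30)
  a <- base; a$desired_score <- 1.2
  expect_identical(attr(rankClones(rbind(base, a)), "order"), c(2L, 1L))
  b <- base; b$max_undesired_score <- 0.05
  expect_identical(attr(rankClones(rbind(base, b)), "order"), c(2L, 1L))

  set.seed(7)
  tab <- data.frame(
    desired_score = sample(c(0.6, 0.9, 1.1), 20, TRUE),
    max_undesired_score = sample(c(0.05, 0.2), 20, TRUE),
    mean_depth = sample(c(100, 500), 20, TRUE),
    mean_quality = sample(c(20, 35), 20, TRUE))
  cmp <- function(i, j) {  # brute-force pairwise comparison oracle
    if (tab$desired_score[i] != tab$desired_score[j])
      return(tab$desired_score[i] > tab$desired_score[j])
    if (tab$max_undesired_score[i] != tab$max_undesired_score[j])
      return(tab$max_undesired_score[i] < tab$max_undesired_score[j])
    if (tab$mean_depth[i] != tab$mean_depth[j])
      return(tab$mean_depth[i] > tab$mean_depth[j])
    if (tab$mean_quality[i] != tab$mean_quality[j])
      return(tab$mean_quality[i] > tab$mean_quality[j])
    i < j  # stability
  }
  ord <- attr(rankClones(tab), "order")
  for (k in seq_len(length(ord) - 1))
    expect_true(cmp(ord[k], ord[k + 1]))
})

test_that("ORF-to-transcript mapping validation applies both criteria", {
  seqChars <- function(n) paste(sample(c("A", "G", "L", "S", "T", "V"),
                                       n, replace = TRUE), collapse = "")
  set.seed(1)
  orf <- seqChars(60)
  expect_true(validateOrfMapping(orf, orf, 30, 1.0))

  # one mismatch 5 residues from the target breaks the 31-aa window
  tr <- orf
  substr(tr, 35, 35) <- if (substr(tr, 35, 35) == "A") "G" else "A"
  expect_false(validateOrfMapping(orf, tr, 30, 0.98))

  # mismatch outside the window: fine if global identity is high
  tr2 <- orf
  substr(tr2, 60, 60) <- if (substr(tr2, 60, 60) == "A") "G" else "A"
  expect_true(validateOrfMapping(orf, tr2, 30, 59 / 60))

  # exact subset spanning 40% of the transcript at 80% global identity
  long <- paste0(orf, seqChars(90))  # orf spans 60/150 = 40%
  expect_true(validateOrfMapping(orf, long, 30, 0.80))
  # exact subset spanning under a third is not enough at low identity
  longer <- paste0(orf, seqChars(150))  # 60/210 < 1/3
  expect_false(validateOrfMapping(orf, longer, 30, 0.80))

  expect_error(validateOrfMapping(orf, orf, 100, 1.0), "outside")
})
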