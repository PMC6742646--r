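test_that("Jensen-Shannon divergence has the right geometry", {
  u <- rep(1 / 20, 20)
  # column equal to the background: zero divergence
  expect_equal(jsDivergence(u, u), 0)
  # invariant column against a uniform background
  inv <- c(1, rep(0, 19))
  expect_equal(jsDivergence(inv, u), 0.855, tolerance = 1e-3)
  # symmetry and the 1-bit bound; disjoint supports are maximal
  set.seed(2)
  for (i in 1:10) {
    p <- runif(20); q <- runif(20)
    expect_equal(jsDivergence(p, q), jsDivergence(q, p))
    expect_lte(jsDivergence(p, q), 1)
    expect_gte(jsDivergence(p, q), 0)
  }
  disjoint <- c(rep(1, 10), rep(0, 10))
  expect_equal(jsDivergence(disjoint, 1 - disjoint), 1)
})

test_that("MSA conservation tracks flag gaps and homolog shortfalls", {
  msa <- c("ACDE", "ACDF", "AC-W", "AC--")
  tr <- jsdConservation(msa, minHomologs = 3)
  expect_equal(tr$gap_fraction, c(0, 0, 0.5, 0.25))
  expect_true(tr$low_confidence[3])
  expect_true(attr(tr, "usable"))
  # invariant column scores the closed-form maximum for this background
  expect_equal(tr$score[1], jsDivergence(c(1, rep(0, 19)), rep(1 / 20, 20)))
  # all-gap column: undefined, flagged
  tr2 <- jsdConservation(c("A-", "C-", "G-"), minHomologs = 2)
  expect_true(is.na(tr2$score[2]) && tr2$low_confidence[2])
  # fewer than 50 homologs makes the track unusable
  expect_false(attr(jsdConservation(msa), "usable"))
})

test_that("Fay and Wu's H matches hand-derived and brute-force values", {
  expect_equal(fayWuH(c(0, 0, 1), 4), -1.0)   # one site at derived count 3
  expect_equal(fayWuH(c(1, 0, 0), 4), 1 / 3)  # one singleton
  expect_equal(fayWuH(rep(0, 9), 10), 0)      # no segregating sites
  expect_error(fayWuH(c(1, 1), 4), "n - 1")
  expect_error(fayWuH(c(1, -1, 0), 4), "non-negative")

  # brute-force theta_pi from explicit haplotype matrices
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(4:10, 1)
    nsites <- sample(5:20, 1)
    hap <- matrix(rbinom(n * nsites, 1, 0.3), nrow = n)
    dc <- colSums(hap)
    keep <- dc >= 1 & dc <= n - 1
    s <- tabulate(dc[keep], nbins = n - 1)
    pairs <- combn(n, 2)
    thetaPiBF <- mean(apply(pairs, 2, function(ij)
      sum(hap[ij[1], ] != hap[ij[2], ])))
    i <- seq_len(n - 1)
    thetaH <- sum(2 * s * i^2) / (n * (n - 1))
    expect_equal(fayWuH(s, n), thetaPiBF - thetaH)
  }
})

test_that("selection flags take the bottom five percent with ties", {
  # all distinct: exactly ceiling(0.05 N) windows flagged
  set.seed(17)
  for (N in c(20, 53, 100)) {
    w <- data.frame(h = sample(seq_len(1000), N))
    fl <- flagSelectedWindows(w)
    expect_identical(sum(fl$significant), as.integer(ceiling(0.05 * N)))
  }
  # all-equal h: the tie rule flags everything at the percentile value
  flEq <- flagSelectedWindows(data.frame(h = rep(-2, 40)))
  expect_true(all(flEq$significant))
  # thresholds are computed within population groups
  w <- data.frame(h = c(seq(-10, 9), seq(100, 119)),
                  group = rep(c("AFR", "EUR"), each = 20))
  fl <- flagSelectedWindows(w)
  expect_identical(sum(fl$significant[fl$group == "EUR"]), 1L)
  # windows without a measurable statistic are excluded
  w2 <- data.frame(h = c(-5, 1, 2, 3), n_snps = c(1, 5, 5, 5))
  fl2 <- flagSelectedWindows(w2)
  expect_true(is.na(fl2$significant[1]))
  expect_identical(sum(fl2$significant, na.rm = TRUE), 1L)
  # empty input passes through empty
  expect_identical(nrow(flagSelectedWindows(data.frame(h = numeric()))), 0L)
})

test_that("sweep-like windows are enriched among flagged regions", {
  cfg <- simConfig(seed = 8, sfs = list(n_windows = 200L, frac_sweep = 0.1))
  gen <- generateWindowSfs(cfg)
  fl <- flagSelectedWindows(gen$windows)
  tab <- table(flagged = fl$significant, sweep = fl$is_sweep)
  rateSweep <- mean(fl$significant[fl$is_sweep], na.rm = TRUE)
  rateNeutral <- mean(fl$significant[!fl$is_sweep], na.rm = TRUE)
  expect_gt(rateSweep, rateNeutral)
  # the enrichment summary reports the same proportions with a Z-test
  enr <- selectionEnrichment(fl$is_sweep, fl$significant)
  expect_lt(enr$test$p, 0.05)
})

test_that("duplicate-gene scores are weighted identity times coverage", {
  expect_equal(duplicateScore(1.0, 1.0, 1.0), 1.0)
  expect_equal(duplicateScore(0.5, 0.8, 0.8), 0.42)
  expect_true(is.na(duplicateScore(0.39, 1, 1)))  # below identity filter
  # monotone non-decreasing in identity and in each coverage
  set.seed(23)
  for (i in 1:20) {
    id <- runif(1, 0.4, 0.99); ca <- runif(1); cb <- runif(1)
    eps <- runif(1, 0, 0.01)
    expect_gte(duplicateScore(min(id + eps, 1), ca, cb),
               duplicateScore(id, ca, cb))
    expect_gte(duplicateScore(id, min(ca + eps, 1), cb),
               duplicateScore(id, ca, cb))
    expect_gte(duplicateScore(id, ca, min(cb + eps, 1)),
               duplicateScore(id, ca, cb))
  }
  pairs <- data.frame(protein_a = c("P1", "P2"), protein_b = c("Q1", "Q2"),
                      percent_identity = c(0.39, 0.5),
                      coverage_a = c(1, 0.8), coverage_b = c(1, 0.8))
  scored <- scoreDuplicatePairs(pairs)
  expect_identical(nrow(scored), 1L)
  expect_equal(scored$score, 0.42)
})

test_that("interface classification follows the SASA and domain rules", {
  unb <- c(50, 30, 20, 10, 45, 60, 5, 80, 12, 33)
  bnd <- unb - c(1.5, 1.0, 0.5, 5, 2, 1.1, 0, 3, 2, 2)
  ir <- interfaceResidues(unb, bnd)
  expect_true(1 %in% ir)        # 1.5 A^2 change
  expect_false(2 %in% ir)       # exactly 1 A^2: strict inequality
  expect_identical(ir, c(1L, 4L, 5L, 6L, 8L, 9L, 10L))

  # interacting domain needs mediates_ppi AND >= 5 interface residues
  domains <- data.frame(start = c(1, 7), end = c(6, 10),
                        mediates_ppi = c(TRUE, TRUE))
  got <- interfaceClassify(c(2, 3, 7), unb, bnd, domains)
  # domain 1 spans residues 1-6 holding 4 interface residues: not enough
  expect_identical(got$label[got$position == 2], "away")
  # interface residue hit
  cls1 <- interfaceClassify(1, unb, bnd, domains)
  expect_identical(cls1$label, "on_interface")
  # domain 2 (residues 7-10) holds 3 interface residues: still not enough
  expect_identical(got$label[got$position == 7], "away")
  # relax to a domain with five interface residues
  dom5 <- data.frame(start = 1, end = 10, mediates_ppi = TRUE)
  expect_identical(interfaceClassify(2, unb, bnd, dom5)$label, "on_interface")
  # without the annotation flag the same domain does not count
  dom0 <- data.frame(start = 1, end = 10, mediates_ppi = FALSE)
  expect_identical(interfaceClassify(2, unb, bnd, dom0)$label, "away")

  enr <- interfaceEnrichment(rep(c("on_interface", "away"), c(60, 40)),
                             c(rep(TRUE, 20), rep(FALSE, 40),
                               rep(TRUE, 2), rep(FALSE, 38)))
  expect_equal(enr$summary$fraction[enr$summary$stratum == "on_interface"],
               1 / 3)
  expect_lt(enr$test$p, 0.01)
})

test_that("cumulative AF-by-conservation curves match direct filtering", {
  score <- c(0.25, 0.45, 0.65, 0.95)
  maf <- c(0.10, 0.02, 0.005, 0.001)
  disr <- c(FALSE, TRUE, TRUE, FALSE)
  got <- afByConservationCutoff(score, maf, disr)
  for (cc in unique(got$cutoff)) {
    for (d in c(TRUE, FALSE)) {
      sel <- score >= cc & disr == d
      row <- got[got$cutoff == cc &
                   got$class == ifelse(d, "disruptive", "non-disruptive"), ]
      expect_identical(row$n, sum(sel))
      if (any(sel)) expect_equal(row$mean_af, mean(maf[sel]))
      else expect_true(is.na(row$mean_af))
    }
  }
  # single variant: constant curve until its score excludes it
  one <- afByConservationCutoff(0.65, 0.01, TRUE)
  d <- one[one$class == "disruptive", ]
  expect_true(all(d$mean_af[d$cutoff <= 0.65] == 0.01))
  expect_true(all(is.na(d$mean_af[d$cutoff > 0.65])))
})
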