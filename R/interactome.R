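#' Call one interaction perturbation from Y2H growth readouts
#'
#' A mutant x interaction test is `untestable` when the bait or the mutant
#' construct autoactivates the reporter, `disrupted` when mutant growth is
#' at most half of the wild-type level on the same selective medium in all
#' three replicate screens (either medium qualifies), and `intact`
#' otherwise. Growth readouts are expressed relative to the wild-type
#' interaction (WT = 1.0).
#'
#' @param medium1,medium2 Numeric length-3 growth readouts (mutant relative
#'   to WT) on the two selective media; `medium2` may be `NULL` when only
#'   one medium was scored.
#' @param baitAutoactivator,mutantAutoactivator Autoactivation flags.
#' @return One of `"disrupted"`, `"intact"`, `"untestable"`.
#' @examples
#' callDisruption(c(0.4, 0.4, 0.4))   # disrupted
#' callDisruption(c(0.4, 0.4, 0.6))   # intact: not reproducible
#' @export
callDisruption <- function(medium1, medium2 = NULL,
                           baitAutoactivator = FALSE,
                           mutantAutoactivator = FALSE) {
  if (baitAutoactivator || mutantAutoactivator) return("untestable")
  check <- function(g) {
    if (length(g) != 3L || anyNA(g)) stop("each medium needs 3 screens")
    if (any(g < 0)) stop("growth readouts must be >= 0")
    all(g <= 0.5)
  }
  hit <- check(medium1)
  if (!is.null(medium2)) hit <- hit || check(medium2)
  if (hit) "disrupted" else "intact"
}

#' Call perturbations for a table of interaction tests
#'
#' @param tests data.frame with columns `variant_id`, `bait`, `prey`,
#'   `m1_s1`, `m1_s2`, `m1_s3` (and optionally `m2_s1..m2_s3`),
#'   `bait_autoactivator`, `mutant_autoactivator`.
#' @return The input with an added `call` column
#'   (`disrupted`/`intact`/`untestable`); row order is irrelevant to every
#'   downstream summary.
#' @export
callDisruptions <- function(tests) {
  g1 <- as.matrix(tests[, c("m1_s1", "m1_s2", "m1_s3")])
  if (anyNA(g1)) stop("each medium needs 3 screens")
  if (any(g1 < 0)) stop("growth readouts must be >= 0")
  hit <- rowSums(g1 <= 0.5) == 3L
  if (all(c("m2_s1", "m2_s2", "m2_s3") %in% names(tests))) {
    g2 <- as.matrix(tests[, c("m2_s1", "m2_s2", "m2_s3")])
    if (anyNA(g2)) stop("each medium needs 3 screens")
    if (any(g2 < 0)) stop("growth readouts must be >= 0")
    hit <- hit | rowSums(g2 <= 0.5) == 3L
  }
  auto <- (!is.null(tests$bait_autoactivator) & tests$bait_autoactivator) |
    (!is.null(tests$mutant_autoactivator) & tests$mutant_autoactivator)
  tests$call <- ifelse(auto, "untestable",
                       ifelse(hit, "disrupted", "intact"))
  tests
}

#' Classify a variant by its disruption profile
#'
#' Variants tested against two or more partners fall into three classes:
#' `non-disruptive` (no tested interaction perturbed), `partially
#' disruptive` (some but not all), `null-like` (all perturbed). Variants
#' tested against a single partner support only a binary disrupted/intact
#' call and are `unclassifiable` for the three-way scheme.
#'
#' @param nTested Number of testable partners (>= 1).
#' @param nDisrupted Number of disrupted partners.
#' @return The category string.
#' @export
classifyVariant <- function(nTested, nDisrupted) {
  if (nTested < 1) stop("variant must have at least one tested partner")
  if (nDisrupted > nTested) stop("disrupted partners exceed tested partners")
  if (nTested < 2) return("unclassifiable")
  if (nDisrupted == 0) "non-disruptive"
  else if (nDisrupted == nTested) "null-like"
  else "partially disruptive"
}

#' Build per-variant disruption profiles from perturbation records
#'
#' Untestable records are dropped from numerator and denominator alike.
#'
#' @param records data.frame with columns `variant_id`, `bait`, `prey`,
#'   `call` (as from [callDisruptions()]).
#' @return data.frame with one row per variant: `variant_id`, `n_tested`,
#'   `n_disrupted`, `disruptive` (logical, >= 1 disruption), `category`,
#'   and list-columns `tested`/`disrupted` of interaction keys.
#' @export
disruptionProfiles <- function(records) {
  rec <- records[records$call != "untestable", , drop = FALSE]
  key <- paste(rec$bait, rec$prey, sep = "|")
  idx <- split(seq_len(nrow(rec)), rec$variant_id)
  tested <- lapply(idx, function(i) unique(key[i]))
  disrupted <- lapply(idx, function(i)
    unique(key[i][rec$call[i] == "disrupted"]))
  nt <- lengths(tested)
  nd <- lengths(disrupted)
  out <- data.frame(variant_id = names(idx), n_tested = nt,
                    n_disrupted = nd, disruptive = nd >= 1L,
                    category = mapply(classifyVariant, nt, nd),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$tested <- unname(tested)
  out$disrupted <- unname(disrupted)
  out
}

#' Degree distribution of disruptive variants
#'
#' Tallies, over disruptive variants only, how many disrupt exactly k
#' interactions, and the corresponding fractions.
#'
#' @param nDisrupted Integer vector: interactions disrupted per variant
#'   (zeros, i.e. non-disruptive variants, are excluded from the
#'   denominator), or a profile data.frame from [disruptionProfiles()].
#' @return data.frame with `k`, `n_variants`, `fraction` over all k >= 1
#'   observed.
#' @examples
#' d <- degreeDistribution(c(rep(1, 205), rep(2, 93)))
#' d$fraction[d$k == 1]  # 0.688
#' @export
degreeDistribution <- function(nDisrupted) {
  if (is.data.frame(nDisrupted)) nDisrupted <- nDisrupted$n_disrupted
  k <- nDisrupted[nDisrupted >= 1L]
  if (length(k) == 0L)
    return(data.frame(k = integer(), n_variants = integer(),
                      fraction = numeric()))
  tab <- table(k)
  data.frame(k = as.integer(names(tab)),
             n_variants = as.integer(tab),
             fraction = as.numeric(tab) / length(k))
}

#' Disruption rate per stratum
#'
#' Fraction of disruptive variants within each stratum (MAF bin, gene set,
#' source database, ...), with the standard error of the proportion.
#'
#' @param disruptive Logical vector, one entry per variant.
#' @param stratum Factor (or coercible) of the same length.
#' @return data.frame with `stratum`, `n`, `n_disruptive`, `rate`, `se`;
#'   empty strata are reported with `n = 0` and `NA` rate.
#' @export
disruptionRate <- function(disruptive, stratum) {
  stratum <- as.factor(stratum)
  n <- as.integer(table(stratum))
  nd <- as.integer(tapply(disruptive, stratum, sum, default = 0L))
  rate <- ifelse(n > 0, nd / n, NA_real_)
  data.frame(stratum = levels(stratum), n = n, n_disruptive = nd,
             rate = rate, se = sqrt(rate * (1 - rate) / n))
}

#' PCA recovery fraction per category
#'
#' Fraction of ORF pairs whose fluorescence reading exceeds the detection
#' threshold, per category (disrupted, intact, positive reference set,
#' random reference set).
#'
#' @param readings Numeric fluorescence readings.
#' @param category Category label per reading.
#' @param threshold Detection threshold; readings strictly above it are
#'   scored as detected.
#' @return data.frame with `category`, `n`, `n_recovered`, `fraction`, `se`.
#' @export
pcaRecovery <- function(readings, category, threshold) {
  category <- as.factor(category)
  n <- as.integer(table(category))
  nr <- as.integer(tapply(readings > threshold, category, sum, default = 0L))
  frac <- ifelse(n > 0, nr / n, NA_real_)
  data.frame(category = levels(category), n = n, n_recovered = nr,
             fraction = frac, se = sqrt(frac * (1 - frac) / n))
}

## normalized disease-string equality: trim + case-fold
.sameDisease <- function(a, b) {
  norm <- function(s) tolower(trimws(s))
  norm(a) == norm(b)
}

#' Disease concordance of same-gene mutation pairs sharing disruption
#' profiles
#'
#' Unordered pairs of same-gene mutations with non-empty disease labels
#' that share at least one tested interaction are compared. Pairs are
#' tallied in overlapping categories - sharing two or more disrupted
#' interactions, sharing one or more, sharing none - and in the exclusive
#' partition (exactly >= 2 shared / exactly 1 / none). A pair is
#' concordant when the disease labels are equal after trimming and case
#' folding. One-tailed pooled-Z tests compare each sharing category with
#' the no-shared-disruption category.
#'
#' @param profiles data.frame from [disruptionProfiles()] plus columns
#'   `gene` and `disease` (empty string or `NA` disease drops the variant).
#' @return List with data.frames `overlapping` and `exclusive`
#'   (`category`, `n_pairs`, `n_same_disease`, `fraction`, `se`) and
#'   `tests` (one-tailed Z-tests); all empty when no pair is comparable.
#' @export
sharedProfileConcordance <- function(profiles) {
  pr <- profiles[!is.na(profiles$disease) & nzchar(profiles$disease), ,
                 drop = FALSE]
  nshared <- integer()
  same <- logical()
  if (nrow(pr) >= 2L) {
    for (g in unique(pr$gene)) {
      idx <- which(pr$gene == g)
      if (length(idx) < 2L) next
      cmb <- utils::combn(idx, 2L)
      for (j in seq_len(ncol(cmb))) {
        a <- cmb[1L, j]; b <- cmb[2L, j]
        if (length(intersect(pr$tested[[a]], pr$tested[[b]])) == 0L) next
        nshared <- c(nshared,
                     length(intersect(pr$disrupted[[a]], pr$disrupted[[b]])))
        same <- c(same, .sameDisease(pr$disease[a], pr$disease[b]))
      }
    }
  }
  mk <- function(cats, sel) {
    n <- vapply(sel, sum, integer(1))
    ns <- vapply(sel, function(s) sum(same[s]), integer(1))
    frac <- ifelse(n > 0, ns / n, NA_real_)
    data.frame(category = cats, n_pairs = n, n_same_disease = ns,
               fraction = frac, se = sqrt(frac * (1 - frac) / n))
  }
  overlapping <- mk(
    c("shared_disrupted_ge2", "shared_disrupted_ge1", "no_shared_disrupted"),
    list(nshared >= 2L, nshared >= 1L, nshared == 0L))
  exclusive <- mk(
    c("shared_disrupted_ge2", "shared_disrupted_1", "no_shared_disrupted"),
    list(nshared >= 2L, nshared == 1L, nshared == 0L))
  tests <- NULL
  none <- overlapping[overlapping$category == "no_shared_disrupted", ]
  if (none$n_pairs > 0) {
    tests <- do.call(rbind, lapply(
      c("shared_disrupted_ge2", "shared_disrupted_ge1"), function(cat) {
        row <- overlapping[overlapping$category == cat, ]
        if (row$n_pairs == 0) return(NULL)
        zt <- twoPropZ(row$n_same_disease, row$n_pairs,
                       none$n_same_disease, none$n_pairs, tail = "greater")
        data.frame(comparison = paste(cat, "vs none"), z = zt$z, p = zt$p)
      }))
  }
  list(overlapping = overlapping, exclusive = exclusive,
       tests = if (is.null(tests))
         data.frame(comparison = character(), z = numeric(), p = numeric())
       else tests)
}
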