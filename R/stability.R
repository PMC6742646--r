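#' Stability scores from a dual-fluorescence plate
#'
#' Computes, for every sample well of a plate, the protein-stability score
#' as background-corrected GFP over background-corrected mCherry:
#' \deqn{score = (GFP - \bar G_{bg}) / (mCherry - \bar M_{bg})}
#' where both backgrounds come from the plate's GFP-negative control wells
#' (empty-vector transfections that express neither fluorophore above
#' background). Wells whose background-corrected mCherry falls below a
#' floor - by default 3 SD above the background-control mean - failed
#' transfection and are marked invalid. Scores may be negative when GFP is
#' below background, which is the signature of an unstable protein.
#'
#' @param plate data.frame with columns `well`, `role` (one of `sample`,
#'   `mcherry_control`, `gfp_negative_control`), `construct`, `gfp`,
#'   `mcherry`.
#' @param mcherryFloorSd mCherry validity floor in background SDs above
#'   the background mean (default 3).
#' @return The sample rows with added `score` and `valid` columns.
#' @examples
#' plate <- data.frame(
#'   well = 1:6, role = c(rep("gfp_negative_control", 4), "sample", "sample"),
#'   construct = c(rep("empty", 4), "WT", "mut"),
#'   gfp = c(100, 100, 100, 100, 1000, 80),
#'   mcherry = c(50, 50, 50, 50, 500, 500))
#' scoreStabilityPlate(plate)$score  # 2.0 and a negative score
#' @export
scoreStabilityPlate <- function(plate, mcherryFloorSd = 3) {
  need <- c("role", "construct", "gfp", "mcherry")
  if (!all(need %in% names(plate)))
    stop("plate table needs columns: ", paste(need, collapse = ", "))
  if (any(plate$gfp < 0 | plate$mcherry < 0))
    stop("fluorescence readings must be non-negative")
  bg <- plate[plate$role == "gfp_negative_control", , drop = FALSE]
  if (nrow(bg) < 4L)
    stop("plate needs >= 4 GFP-negative control wells")
  if (sum(plate$role == "mcherry_control") < 4L)
    stop("plate needs >= 4 mCherry-positive control wells")
  gfpBg <- mean(bg$gfp)
  mchBg <- mean(bg$mcherry)
  mchSd <- stats::sd(bg$mcherry)
  floor <- mcherryFloorSd * ifelse(is.na(mchSd), 0, mchSd)
  smp <- plate[plate$role == "sample", , drop = FALSE]
  mch <- smp$mcherry - mchBg
  smp$valid <- mch > floor
  smp$score <- ifelse(smp$valid, (smp$gfp - gfpBg) / mch, NA_real_)
  smp
}

#' Classify a mutant protein's stability
#'
#' A mutant whose stability score is negative (GFP below background, i.e.
#' below the plate reader's detection threshold) is `unstable`; otherwise
#' a mutant-to-wild-type score ratio below 0.5 is `moderately stable` and
#' anything above both thresholds is `stable`. Invalid measurements give
#' `invalid`.
#'
#' @param wtScore Wild-type stability score (> 0; wild types are
#'   pre-screened for stable expression).
#' @param mutScore Mutant stability score (may be negative); `NA` for an
#'   invalid well.
#' @return List with `ratio` and `category`.
#' @examples
#' classifyStability(2.0, 0.8)$category   # moderately stable
#' classifyStability(2.0, -0.1)$category  # unstable
#' @export
classifyStability <- function(wtScore, mutScore) {
  if (is.na(wtScore) || wtScore <= 0)
    stop("'wtScore' must be positive; WT proteins are pre-screened")
  if (is.na(mutScore))
    return(list(ratio = NA_real_, category = "invalid"))
  ratio <- mutScore / wtScore
  category <- if (mutScore < 0) "unstable"
              else if (ratio < 0.5) "moderately stable"
              else "stable"
  list(ratio = ratio, category = category)
}

#' Score and classify all WT/mutant pairs on a set of plates
#'
#' @param plates data.frame of plate readings (columns of
#'   [scoreStabilityPlate()] plus `plate_id`); each mutant shares a plate
#'   with its wild-type construct, identified by `construct == "WT:<id>"`
#'   and a `pair_id` column naming the wild-type gene.
#' @param mcherryFloorSd Passed to [scoreStabilityPlate()].
#' @return data.frame with one row per mutant: `variant_id`, `wt_score`,
#'   `mut_score`, `ratio`, `category`.
#' @export
stabilityMeasurements <- function(plates, mcherryFloorSd = 3) {
  out <- list()
  for (pid in unique(plates$plate_id)) {
    sc <- scoreStabilityPlate(plates[plates$plate_id == pid, , drop = FALSE],
                              mcherryFloorSd = mcherryFloorSd)
    for (gene in unique(sc$pair_id)) {
      rows <- sc[sc$pair_id == gene, , drop = FALSE]
      wt <- rows[rows$construct == "WT", , drop = FALSE]
      mut <- rows[rows$construct != "WT", , drop = FALSE]
      if (nrow(wt) != 1L)
        stop("each pair needs exactly one WT well per plate")
      for (i in seq_len(nrow(mut))) {
        cl <- classifyStability(wt$score, mut$score[i])
        out[[length(out) + 1L]] <- data.frame(
          variant_id = mut$construct[i], wt_score = wt$score,
          mut_score = mut$score[i], ratio = cl$ratio,
          category = cl$category, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Relate stability ratios to interaction-disruption categories
#'
#' Groups mutant-to-wild-type stability ratios by the variants'
#' disruption categories and runs one-tailed Mann-Whitney tests for the
#' expected ordering (non-disruptive > partially disruptive > null-like).
#' Also counts interaction-disruptive variants whose protein is unstable.
#'
#' @param measurements data.frame from [stabilityMeasurements()].
#' @param profiles data.frame from [disruptionProfiles()] (columns
#'   `variant_id`, `category`, `disruptive`).
#' @return List with `groups` (per-category n and median ratio), `ratios`
#'   (named list of ratio vectors), `tests` (one-tailed U-tests) and
#'   `n_disruptive_unstable`.
#' @export
stabilityByDisruption <- function(measurements, profiles) {
  m <- merge(measurements, profiles[, c("variant_id", "category",
                                        "disruptive")],
             by = "variant_id", suffixes = c("_stability", "_disruption"))
  cats <- c("non-disruptive", "partially disruptive", "null-like")
  ratios <- lapply(cats, function(cc)
    m$ratio[m$category_disruption == cc & !is.na(m$ratio)])
  names(ratios) <- cats
  groups <- data.frame(
    category = cats,
    n = vapply(ratios, length, integer(1)),
    median_ratio = vapply(ratios, function(r)
      if (length(r)) stats::median(r) else NA_real_, numeric(1)))
  cmp <- list(c("non-disruptive", "partially disruptive"),
              c("partially disruptive", "null-like"))
  tests <- do.call(rbind, lapply(cmp, function(pair) {
    x <- ratios[[pair[1]]]; y <- ratios[[pair[2]]]
    if (length(x) < 1 || length(y) < 1)
      return(data.frame(comparison = paste(pair, collapse = " > "),
                        u = NA_real_, p = NA_real_))
    mw <- mannWhitneyU(x, y, tail = "greater")
    data.frame(comparison = paste(pair, collapse = " > "),
               u = mw$u, p = mw$p)
  }))
  list(groups = groups, ratios = ratios, tests = tests,
       n_disruptive_unstable = sum(m$disruptive &
                                     m$category_stability == "unstable",
                                   na.rm = TRUE))
}
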