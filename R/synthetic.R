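#' Simulation configuration with planted ground truth
#'
#' Collects every tunable of the synthetic-data generators. Defaults
#' emulate the study conditions of a pooled-mutagenesis edgotyping screen:
#' pools of four mutant clones sequenced to ~1000x with a 0.1% error rate;
#' a perturbation network whose per-MAF-bin disruption probabilities fall
#' from 20.0% (MAF <= 0.1%) to 9.6% (MAF > 10%); a per-genome missense
#' composition of 13,595 variants dominated by common alleles; 96-well
#' dual-fluorescence plates with four controls of each role; alignments of
#' 60 homologs; and 1 kb windows over 20 sampled chromosomes.
#'
#' Each generator seeds its own random-number stream from `seed` plus a
#' fixed per-generator offset, so adding one generator never perturbs
#' another's output and identical configs give byte-identical outputs.
#'
#' @param seed Master seed (integer).
#' @param pool List: `total_mutations`, `depth`, `seq_err`, `orf_length`.
#' @param network List: `n_genes`, `n_variants`, `mean_partners`,
#'   `bin_probs` (4 disruption probabilities, rare to common),
#'   `bin_composition` (MAF-bin mix of tested variants),
#'   `p_concordant` (probability two same-gene disease mutations share a
#'   label).
#' @param genome List: `total_missense`, `bin_weights` (per-genome SFS
#'   mix over the 4 MAF bins).
#' @param plate List: background means/SDs and signal levels for GFP and
#'   mCherry, plus `mutant_ratios`, the planted mutant:WT stability
#'   ratios.
#' @param msa List: `n_homologs`, `length`, `conservation` (per-column
#'   probability of the consensus residue; recycled).
#' @param sfs List: `n_chromosomes`, `window_length`, `n_windows`,
#'   `frac_sweep`, `theta` (expected pairwise diversity scale),
#'   `sweep_skew` (0 = neutral; 1 = all mass on high-frequency derived
#'   classes).
#' @return A validated list of class `"SimulationConfig"`.
#' @export
simConfig <- function(seed = 1L,
                      pool = list(),
                      network = list(),
                      genome = list(),
                      plate = list(),
                      msa = list(),
                      sfs = list()) {
  merge <- function(def, usr) {
    bad <- setdiff(names(usr), names(def))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    def[names(usr)] <- usr
    def
  }
  cfg <- list(
    seed = as.integer(seed),
    pool = merge(list(total_mutations = 4L, depth = 1000L, seq_err = 0.001,
                      orf_length = 300L, off_targets = 0L), pool),
    network = merge(list(n_genes = 100L, n_variants = 1000L,
                         mean_partners = 2,
                         bin_probs = c(0.200, 0.170, 0.130, 0.096),
                         bin_composition = c(0.25, 0.25, 0.25, 0.25),
                         p_concordant = 0.7), network),
    genome = merge(list(total_missense = 13595,
                        bin_weights = c(0.05, 0.08, 0.15, 0.72)), genome),
    plate = merge(list(gfp_bg_mean = 100, gfp_bg_sd = 5,
                       mch_bg_mean = 50, mch_bg_sd = 3,
                       gfp_signal = 2000, mch_signal = 1000,
                       signal_cv = 0.02,
                       mutant_ratios = c(1.0, 0.9, 0.4, -0.05)), plate),
    msa = merge(list(n_homologs = 60L, length = 50L,
                     conservation = 0.5), msa),
    sfs = merge(list(n_chromosomes = 20L, window_length = 1000L,
                     n_windows = 40L, frac_sweep = 0.25, theta = 5,
                     sweep_skew = 0.9), sfs))
  probs <- c(cfg$pool$seq_err, cfg$network$bin_probs,
             cfg$network$bin_composition, cfg$network$p_concordant,
             cfg$genome$bin_weights, cfg$sfs$frac_sweep, cfg$sfs$sweep_skew)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (length(cfg$network$bin_probs) != 4L)
    stop("'bin_probs' must have length 4")
  counts <- c(cfg$pool$total_mutations, cfg$pool$depth, cfg$pool$orf_length,
              cfg$network$n_genes, cfg$network$n_variants,
              cfg$genome$total_missense, cfg$msa$n_homologs,
              cfg$sfs$n_chromosomes, cfg$sfs$window_length,
              cfg$sfs$n_windows)
  if (any(counts <= 0)) stop("all counts must be positive")
  class(cfg) <- "SimulationConfig"
  cfg
}

## fixed per-generator seed offsets (see simConfig)
.seedFor <- function(config, generator) {
  off <- c(pool = 101L, network = 202L, genome = 303L, plate = 404L,
           msa = 505L, sfs = 606L)
  set.seed(config$seed + off[[generator]])
}

#' Generate a pooled-sequencing pileup with a planted mutation
#'
#' Simulates the pooled reads of one mutagenized ORF: `total_mutations`
#' clones contribute equally, one desired single-base mutation is planted
#' per clone (each at read fraction `1/total_mutations` before error), and
#' every read is corrupted with probability `seq_err`, the error
#' distributed uniformly over the five non-true alleles (insertions and
#' deletions receive the same per-allele share as substitutions).
#' Optional off-target mutations are planted at non-targeted positions at
#' the same clone fraction.
#'
#' @param config A [simConfig()].
#' @param orfId Identifier for the simulated ORF.
#' @return List with `pileup` ([AllelePileup-class]), `design`
#'   ([PoolDesign-class]) and `truth` (data.frame of planted mutations
#'   with their type and clone fraction).
#' @export
generatePool <- function(config, orfId = "ORF1") {
  stopifnot(inherits(config, "SimulationConfig"))
  p <- config$pool
  if (p$seq_err < 0 || p$seq_err > 1)
    stop("'seq_err' must be a probability")
  .seedFor(config, "pool")
  ab <- alleleAlphabet()
  L <- p$orf_length
  tm <- p$total_mutations
  wt <- sample(ab[1:4], L, replace = TRUE)
  nPlant <- min(tm + p$off_targets, L)
  plantPos <- sort(sample.int(L, nPlant))
  desired <- plantPos[seq_len(min(tm, nPlant))]
  offtgt <- setdiff(plantPos, desired)
  plantAllele <- vapply(plantPos, function(i)
    sample(setdiff(ab, wt[i]), 1L), character(1))
  names(plantAllele) <- plantPos

  counts <- matrix(0L, L, 6L, dimnames = list(NULL, ab))
  e <- p$seq_err
  for (i in seq_len(L)) {
    base <- stats::setNames(numeric(6), ab)
    if (i %in% plantPos) {
      base[wt[i]] <- 1 - 1 / tm
      base[plantAllele[[as.character(i)]]] <-
        base[plantAllele[[as.character(i)]]] + 1 / tm
    } else {
      base[wt[i]] <- 1
    }
    ## symmetric read error: true allele kept with 1 - e, otherwise
    ## replaced uniformly by one of the 5 other alleles
    probs <- base * (1 - e) + (e / 5) * (1 - base)
    counts[i, ] <- stats::rmultinom(1L, p$depth, probs)[, 1L]
  }
  design <- PoolDesign(orfId, tm,
                       data.frame(position = desired,
                                  mut_allele = plantAllele[as.character(desired)]))
  truth <- data.frame(
    orf_id = orfId, position = plantPos,
    wt_allele = wt[plantPos],
    mut_allele = plantAllele[as.character(plantPos)],
    type = ifelse(plantPos %in% desired, "desired", "off_target"),
    clone_fraction = 1 / tm, stringsAsFactors = FALSE)
  list(pileup = AllelePileup(orfId, seq_len(L), counts, wt),
       design = design, truth = truth)
}

## log-uniform MAF within the b-th default bin
.mafInBin <- function(bin, n) {
  edges <- mafBinEdges()
  lo <- pmax(edges[bin], 1e-5)
  hi <- edges[bin + 1L]
  exp(stats::runif(n, log(lo), log(hi)))
}

#' Generate a perturbation network with planted disruption probabilities
#'
#' Variants are assigned a MAF bin from the tested-composition mix and a
#' log-uniform MAF within the bin; each variant x interaction pair is
#' disrupted independently with its bin's planted probability. Growth
#' readouts on two selective media across three screens are drawn
#' consistently with the planted call (all screens <= 0.5 x WT iff
#' disrupted). Disease labels are drawn per gene from two label pools so
#' that two same-gene mutations share a label with probability
#' `p_concordant`.
#'
#' @param config A [simConfig()].
#' @return List with `variants` (variant table incl. planted bin, MAF,
#'   disease label), `tests` (interaction-test table for
#'   [callDisruptions()]) and `truth` (per variant x interaction planted
#'   disruption flags).
#' @export
generateNetwork <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  nw <- config$network
  if (nw$n_variants < 1L || nw$n_genes < 1L)
    stop("empty network requested")
  .seedFor(config, "network")
  nv <- nw$n_variants
  bin <- sample.int(4L, nv, replace = TRUE,
                    prob = nw$bin_composition / sum(nw$bin_composition))
  gene <- paste0("G", sample.int(nw$n_genes, nv, replace = TRUE))
  maf <- .mafInBin(bin, nv)
  nPartners <- 1L + stats::rpois(nv, max(nw$mean_partners - 1, 0))
  ## same-gene pairs share a label with probability p_concordant:
  ## each variant draws label X with probability q, q^2 + (1-q)^2 = p_c
  q <- (1 + sqrt(max(2 * nw$p_concordant - 1, 0))) / 2
  disease <- ifelse(stats::runif(nv) < q,
                    paste0("disease_", gene, "_A"),
                    paste0("disease_", gene, "_B"))
  variants <- data.frame(
    variant_id = paste0("V", seq_len(nv)), gene = gene,
    maf_bin = bin, maf = maf, n_partners = nPartners,
    disease = disease, stringsAsFactors = FALSE)

  rows <- rep(seq_len(nv), nPartners)
  prey <- unlist(lapply(nPartners, function(k) paste0("P", seq_len(k))))
  disrupted <- stats::runif(length(rows)) < nw$bin_probs[bin[rows]]
  draw <- function(hit, n) {
    lo <- ifelse(hit, 0.05, 0.55)
    hi <- ifelse(hit, 0.45, 1.00)
    matrix(stats::runif(3 * n, rep(lo, each = 3), rep(hi, each = 3)),
           ncol = 3, byrow = TRUE)
  }
  m1 <- draw(disrupted, length(rows))
  m2 <- draw(disrupted, length(rows))
  tests <- data.frame(
    variant_id = variants$variant_id[rows],
    bait = variants$gene[rows], prey = prey,
    m1_s1 = m1[, 1], m1_s2 = m1[, 2], m1_s3 = m1[, 3],
    m2_s1 = m2[, 1], m2_s2 = m2[, 2], m2_s3 = m2[, 3],
    bait_autoactivator = FALSE, mutant_autoactivator = FALSE,
    stringsAsFactors = FALSE)
  truth <- data.frame(variant_id = tests$variant_id, bait = tests$bait,
                      prey = tests$prey, disrupted = disrupted,
                      maf_bin = bin[rows], stringsAsFactors = FALSE)
  list(variants = variants, tests = tests, truth = truth)
}

#' Per-genome MAF-bin composition from SFS weights
#'
#' Splits a per-genome missense-variant total across the four MAF bins in
#' proportion to the supplied site-frequency-spectrum weights.
#'
#' @param config A [simConfig()]; uses `genome$total_missense` and
#'   `genome$bin_weights`.
#' @return data.frame with `bin`, `weight`, `genome_count`; counts are
#'   non-negative and sum exactly to the requested total.
#' @export
generateGenomeComposition <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  g <- config$genome
  if (g$total_missense <= 0) stop("'total_missense' must be positive")
  w <- g$bin_weights / sum(g$bin_weights)
  edges <- mafBinEdges()
  data.frame(bin = levels(binVariants(0.5, edges))[seq_along(w)],
             weight = w, genome_count = w * g$total_missense)
}

#' Generate dual-fluorescence plates with planted stability ratios
#'
#' Builds one plate per wild-type gene: four mCherry-positive/GFP-negative
#' control wells, four GFP-background control wells, one wild-type sample
#' well and one well per planted mutant ratio. A planted ratio r means the
#' mutant's background-corrected GFP is r times the wild type's (negative
#' r puts GFP below background, the unstable signature); mCherry signal is
#' shared, so the downstream score ratio recovers r.
#'
#' @param config A [simConfig()].
#' @param nPairs Number of WT/mutant-set plates to generate (default 3).
#' @return List with `plates` (readings for [stabilityMeasurements()]) and
#'   `truth` (planted ratio and expected category per mutant).
#' @export
generatePlates <- function(config, nPairs = 3L) {
  stopifnot(inherits(config, "SimulationConfig"))
  pl <- config$plate
  .seedFor(config, "plate")
  rn <- function(n, mean, sd) stats::rnorm(n, mean, sd)
  out <- list()
  truth <- list()
  for (g in seq_len(nPairs)) {
    gene <- paste0("GENE", g)
    plateId <- paste0("plate_", g)
    ctrl <- data.frame(
      plate_id = plateId,
      well = paste0("C", 1:8),
      role = rep(c("mcherry_control", "gfp_negative_control"), each = 4L),
      pair_id = NA_character_, construct = "empty",
      gfp = rn(8, pl$gfp_bg_mean, pl$gfp_bg_sd),
      mcherry = c(rn(4, pl$mch_signal, pl$signal_cv * pl$mch_signal),
                  rn(4, pl$mch_bg_mean, pl$mch_bg_sd)),
      stringsAsFactors = FALSE)
    ratios <- pl$mutant_ratios
    ids <- c("WT", paste0(gene, "_M", seq_along(ratios)))
    gfpAbove <- pl$gfp_signal * c(1, ratios)
    smp <- data.frame(
      plate_id = plateId,
      well = paste0("S", seq_along(ids)),
      role = "sample", pair_id = gene, construct = ids,
      gfp = pmax(0, rn(length(ids), pl$gfp_bg_mean + gfpAbove,
                       pl$signal_cv * pl$gfp_signal)),
      mcherry = rn(length(ids), pl$mch_bg_mean + pl$mch_signal,
                   pl$signal_cv * pl$mch_signal),
      stringsAsFactors = FALSE)
    out[[g]] <- rbind(ctrl, smp)
    truth[[g]] <- data.frame(
      variant_id = ids[-1L], ratio = ratios,
      category = ifelse(ratios < 0, "unstable",
                        ifelse(ratios < 0.5, "moderately stable", "stable")),
      stringsAsFactors = FALSE)
  }
  list(plates = do.call(rbind, out), truth = do.call(rbind, truth))
}

#' Generate a protein MSA with a planted conservation profile
#'
#' Each column j draws, per homolog, the consensus residue with
#' probability `conservation[j]` and a uniformly random residue otherwise;
#' a column with conservation 1 is invariant.
#'
#' @param config A [simConfig()].
#' @param file Optional path; when given the alignment is also written as
#'   FASTA.
#' @return List with `msa` (a Biostrings `AAStringSet`) and `truth`
#'   (consensus sequence and per-column conservation).
#' @export
generateMsa <- function(config, file = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  m <- config$msa
  .seedFor(config, "msa")
  cons <- rep_len(m$conservation, m$length)
  consensus <- sample(.AA20, m$length, replace = TRUE)
  mat <- vapply(seq_len(m$length), function(j) {
    keep <- stats::runif(m$n_homologs) < cons[j]
    ifelse(keep, consensus[j],
           sample(.AA20, m$n_homologs, replace = TRUE))
  }, character(m$n_homologs))
  seqs <- apply(mat, 1L, paste, collapse = "")
  msa <- Biostrings::AAStringSet(seqs)
  names(msa) <- paste0("homolog_", seq_along(msa))
  if (!is.null(file)) Biostrings::writeXStringSet(msa, file)
  list(msa = msa,
       truth = data.frame(position = seq_len(m$length),
                          consensus = consensus, conservation = cons))
}

#' Generate per-window site frequency spectra
#'
#' Neutral windows draw their unfolded SFS from the standard neutral shape
#' (expected class counts proportional to 1/i); sweep-like windows mix in
#' a high-frequency-derived component with weight `sweep_skew`
#' (class probability proportional to i), emulating the excess of
#' high-frequency derived alleles left by a completed sweep. The number of
#' segregating sites per window is Poisson with mean
#' `theta * sum(1/i)`.
#'
#' @param config A [simConfig()].
#' @return List with `windows` (chrom/start/end, planted `is_sweep`,
#'   `n_snps`, computed `h`) and `sfs` (windows x derived-count matrix).
#' @export
generateWindowSfs <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  sf <- config$sfs
  .seedFor(config, "sfs")
  n <- sf$n_chromosomes
  i <- seq_len(n - 1L)
  neutral <- (1 / i) / sum(1 / i)
  high <- i / sum(i)
  nSweep <- round(sf$frac_sweep * sf$n_windows)
  isSweep <- seq_len(sf$n_windows) <= nSweep
  S <- stats::rpois(sf$n_windows, sf$theta * sum(1 / i))
  sfs <- t(vapply(seq_len(sf$n_windows), function(w) {
    pr <- if (isSweep[w])
      (1 - sf$sweep_skew) * neutral + sf$sweep_skew * high
    else neutral
    if (S[w] == 0) integer(n - 1L)
    else stats::rmultinom(1L, S[w], pr)[, 1L]
  }, integer(n - 1L)))
  windows <- data.frame(
    chrom = "chrS", start = (seq_len(sf$n_windows) - 1L) * sf$window_length,
    end = seq_len(sf$n_windows) * sf$window_length,
    is_sweep = isSweep, n_snps = rowSums(sfs),
    h = apply(sfs, 1L, fayWuH, n = n))
  list(windows = windows, sfs = sfs)
}
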