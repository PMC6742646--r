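#' @import methods
NULL

#' Allele alphabet used throughout the clone-calling stage
#'
#' The six-allele alphabet observed in pooled-sequencing pileups:
#' the four nucleotides plus insertion and deletion.
#'
#' @return Character vector of length 6.
#' @export
alleleAlphabet <- function() c("A", "C", "G", "T", "ins", "del")

#' AllelePileup: per-position allele counts for one ORF
#'
#' Holds the pooled-sequencing read counts for a single ORF over the
#' six-allele alphabet (A, C, G, T, insertion, deletion), together with the
#' per-position wild-type (reference) allele and an optional per-position
#' mean base quality. Coordinates are 1-based along the ORF nucleotide
#' sequence.
#'
#' @slot orfId Single ORF identifier.
#' @slot positions Integer vector of strictly increasing 1-based positions.
#' @slot counts Integer matrix, one row per position, columns named by
#'   [alleleAlphabet()]; non-negative read counts.
#' @slot wtAllele Character vector, the reference allele at each position.
#' @slot meanQual Numeric vector of per-position mean base qualities
#'   (may be all `NA` when qualities were not recorded).
#'
#' @seealso [AllelePileup()], [readPileup()], [callClones()]
#' @export
setClass("AllelePileup",
  representation(
    orfId = "character",
    positions = "integer",
    counts = "matrix",
    wtAllele = "character",
    meanQual = "numeric"
  )
)

setValidity("AllelePileup", function(object) {
  msg <- character()
  if (length(object@orfId) != 1L || is.na(object@orfId))
    msg <- c(msg, "'orfId' must be a single non-NA string")
  np <- length(object@positions)
  if (np == 0L)
    msg <- c(msg, "pileup must contain at least one position")
  if (np > 1L && any(diff(object@positions) <= 0L))
    msg <- c(msg, "'positions' must be strictly increasing")
  if (!identical(colnames(object@counts), alleleAlphabet()))
    msg <- c(msg, "count columns must be named A, C, G, T, ins, del")
  if (nrow(object@counts) != np)
    msg <- c(msg, "'counts' must have one row per position")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(object@wtAllele) != np)
    msg <- c(msg, "'wtAllele' must have one entry per position")
  if (!all(object@wtAllele %in% alleleAlphabet()))
    msg <- c(msg, "'wtAllele' entries must be in the allele alphabet")
  if (length(object@meanQual) != np)
    msg <- c(msg, "'meanQual' must have one entry per position")
  if (length(msg)) msg else TRUE
})

#' Construct an AllelePileup
#'
#' @param orfId ORF identifier.
#' @param positions Integer vector of 1-based positions.
#' @param counts Matrix of read counts with columns `A, C, G, T, ins, del`.
#' @param wtAllele Character vector of reference alleles.
#' @param meanQual Optional numeric vector of mean base qualities.
#' @return An [AllelePileup-class] object.
#' @examples
#' cnt <- matrix(0L, 3, 6, dimnames = list(NULL, alleleAlphabet()))
#' cnt[, "A"] <- 100L
#' AllelePileup("ORF1", 1:3, cnt, rep("A", 3))
#' @export
AllelePileup <- function(orfId, positions, counts, wtAllele, meanQual = NULL) {
  if (is.null(meanQual)) meanQual <- rep(NA_real_, length(positions))
  storage.mode(counts) <- "integer"
  colnames(counts) <- alleleAlphabet()
  new("AllelePileup",
      orfId = as.character(orfId),
      positions = as.integer(positions),
      counts = counts,
      wtAllele = as.character(wtAllele),
      meanQual = as.numeric(meanQual))
}

#' PoolDesign: mutagenesis design for one pooled ORF
#'
#' Describes the pooled mutagenesis attempt for one ORF: how many mutant
#' clones were pooled (`TotalMutations`, i.e. the number of ORF copies in
#' the pool), which positions were targeted and with which desired mutant
#' allele, and the size of the allele alphabet.
#'
#' @slot orfId ORF identifier.
#' @slot totalMutations Number of mutant clones pooled for this ORF.
#' @slot targeted data.frame with columns `position`, `mut_allele`.
#' @slot alleles Size of the allele alphabet (default 6).
#' @seealso [PoolDesign()], [expectedFraction()]
#' @export
setClass("PoolDesign",
  representation(
    orfId = "character",
    totalMutations = "integer",
    targeted = "data.frame",
    alleles = "integer"
  )
)

setValidity("PoolDesign", function(object) {
  msg <- character()
  if (length(object@totalMutations) != 1L || object@totalMutations < 1L)
    msg <- c(msg, "'totalMutations' must be a single integer >= 1")
  if (length(object@alleles) != 1L || object@alleles < 2L)
    msg <- c(msg, "'alleles' must be >= 2")
  if (!all(c("position", "mut_allele") %in% names(object@targeted)))
    msg <- c(msg, "'targeted' needs columns 'position' and 'mut_allele'")
  else {
    if (any(object@targeted$position < 1L))
      msg <- c(msg, "targeted positions must be >= 1")
    if (!all(object@targeted$mut_allele %in% alleleAlphabet()))
      msg <- c(msg, "targeted mutant alleles must be in the allele alphabet")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PoolDesign
#'
#' @param orfId ORF identifier.
#' @param totalMutations Number of ORF copies (mutant clones) in the pool.
#' @param targeted data.frame with columns `position` (1-based nt) and
#'   `mut_allele` (desired mutant allele).
#' @param alleles Allele alphabet size, default 6.
#' @return A [PoolDesign-class] object.
#' @export
PoolDesign <- function(orfId, totalMutations, targeted, alleles = 6L) {
  targeted$position <- as.integer(targeted$position)
  targeted$mut_allele <- as.character(targeted$mut_allele)
  new("PoolDesign",
      orfId = as.character(orfId),
      totalMutations = as.integer(totalMutations),
      targeted = targeted[, c("position", "mut_allele")],
      alleles = as.integer(alleles))
}

#' @describeIn AllelePileup ORF identifier.
#' @param object,x An object.
#' @export
setGeneric("orfId", function(object) standardGeneric("orfId"))

#' @rdname AllelePileup
#' @export
setMethod("orfId", "AllelePileup", function(object) object@orfId)

#' @rdname PoolDesign-class
#' @param object A `PoolDesign`.
#' @export
setMethod("orfId", "PoolDesign", function(object) object@orfId)

#' @describeIn AllelePileup 1-based positions covered by the pileup.
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))

#' @rdname AllelePileup
#' @export
setMethod("positions", "AllelePileup", function(object) object@positions)

#' @describeIn AllelePileup Count matrix (positions x alleles).
#' @export
setGeneric("alleleCounts", function(object) standardGeneric("alleleCounts"))

#' @rdname AllelePileup
#' @export
setMethod("alleleCounts", "AllelePileup", function(object) object@counts)

#' @describeIn AllelePileup Reference allele per position.
#' @export
setGeneric("wtAllele", function(object) standardGeneric("wtAllele"))

#' @rdname AllelePileup
#' @export
setMethod("wtAllele", "AllelePileup", function(object) object@wtAllele)

#' @describeIn AllelePileup Per-position total read depth.
#' @export
setGeneric("depth", function(object) standardGeneric("depth"))

#' @rdname AllelePileup
#' @export
setMethod("depth", "AllelePileup", function(object) rowSums(object@counts))

#' @describeIn AllelePileup Per-position mean base quality (possibly NA).
#' @export
setGeneric("meanQual", function(object) standardGeneric("meanQual"))

#' @rdname AllelePileup
#' @export
setMethod("meanQual", "AllelePileup", function(object) object@meanQual)

#' @describeIn PoolDesign-class Number of ORF copies in the pool.
#' @export
setGeneric("totalMutations", function(object) standardGeneric("totalMutations"))

#' @rdname PoolDesign-class
#' @export
setMethod("totalMutations", "PoolDesign", function(object) object@totalMutations)

#' @describeIn PoolDesign-class Targeted (position, mutant allele) table.
#' @export
setGeneric("targeted", function(object) standardGeneric("targeted"))

#' @rdname PoolDesign-class
#' @export
setMethod("targeted", "PoolDesign", function(object) object@targeted)

#' @describeIn PoolDesign-class Allele alphabet size.
#' @export
setGeneric("nAlleles", function(object) standardGeneric("nAlleles"))

#' @rdname PoolDesign-class
#' @export
setMethod("nAlleles", "PoolDesign", function(object) object@alleles)

setMethod("show", "AllelePileup", function(object) {
  cat("AllelePileup for", object@orfId, "\n")
  cat(" ", length(object@positions), "positions,",
      "mean depth", round(mean(rowSums(object@counts)), 1), "\n")
})

setMethod("show", "PoolDesign", function(object) {
  cat("PoolDesign for", object@orfId, "\n")
  cat("  totalMutations:", object@totalMutations,
      "| targeted positions:", nrow(object@targeted),
      "| alleles:", object@alleles, "\n")
})

#' Read and write pileup tables
#'
#' Pileup TSVs carry one row per ORF position with columns `orf_id`, `pos`,
#' `wt`, `count_A`, `count_C`, `count_G`, `count_T`, `count_ins`,
#' `count_del` and optionally `mean_qual`.
#'
#' @param file Path to a TSV file.
#' @param orf For files holding several ORFs, which one to load
#'   (default: the first).
#' @return `readPileup()` returns an [AllelePileup-class];
#'   `writePileup()` writes `x` and returns `file` invisibly.
#' @export
readPileup <- function(file, orf = NULL) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (is.null(orf)) orf <- tab$orf_id[1L]
  tab <- tab[tab$orf_id == orf, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for ORF '", orf, "' in ", file)
  cols <- paste0("count_", alleleAlphabet())
  cnt <- as.matrix(tab[, cols])
  colnames(cnt) <- alleleAlphabet()
  mq <- if ("mean_qual" %in% names(tab)) tab$mean_qual else NULL
  AllelePileup(orf, tab$pos, cnt, tab$wt, mq)
}

#' @rdname readPileup
#' @param x An [AllelePileup-class] to write.
#' @export
writePileup <- function(x, file) {
  stopifnot(is(x, "AllelePileup"))
  cnt <- alleleCounts(x)
  tab <- data.frame(orf_id = orfId(x), pos = positions(x), wt = wtAllele(x))
  for (a in alleleAlphabet()) tab[[paste0("count_", a)]] <- cnt[, a]
  if (!all(is.na(meanQual(x)))) tab$mean_qual <- meanQual(x)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read and write pool-design tables
#'
#' Pool-design TSVs carry one row per targeted mutation with columns
#' `orf_id`, `total_mutations`, `position`, `mut_allele` and optionally
#' `alleles`.
#'
#' @param file Path to a TSV file.
#' @param orf Which ORF to load (default: the first).
#' @return `readPoolDesign()` returns a [PoolDesign-class];
#'   `writePoolDesign()` writes `x` and returns `file` invisibly.
#' @export
readPoolDesign <- function(file, orf = NULL) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (is.null(orf)) orf <- tab$orf_id[1L]
  tab <- tab[tab$orf_id == orf, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for ORF '", orf, "' in ", file)
  alleles <- if ("alleles" %in% names(tab)) tab$alleles[1L] else 6L
  PoolDesign(orf, tab$total_mutations[1L],
             tab[, c("position", "mut_allele")], alleles)
}

#' @rdname readPoolDesign
#' @param x A [PoolDesign-class] to write.
#' @export
writePoolDesign <- function(x, file) {
  stopifnot(is(x, "PoolDesign"))
  tab <- cbind(orf_id = orfId(x), total_mutations = totalMutations(x),
               targeted(x), alleles = nAlleles(x))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
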