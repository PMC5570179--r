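# Per-column sequence conservation by Jensen-Shannon divergence against the
# BLOSUM62 background distribution (the Capra & Singh estimator), rescaling
# to [30, 70], differential on-/off-target scoring, and mapping of scores
# onto reference-structure residues.

.shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence conservation score of one alignment column
#'
#' The column's amino-acid distribution p (with a small pseudocount) is
#' compared with the background q: JSD = H((p+q)/2) - (H(p) + H(q))/2 in
#' bits, which is bounded by 1, and the result is multiplied by
#' (1 - gap fraction) so gappy columns score low. 'X' and '-' both count
#' as gaps.
#'
#' @param column character vector of single letters (one per sequence).
#' @param background named 20-vector of amino-acid frequencies summing to 1
#'   (default \code{\link{blosum62Background}}).
#' @param pseudocount per-amino-acid pseudocount (default 1e-7).
#' @return score in [0, 1]; 0 for all-gap columns (with a warning) and for
#'   columns whose distribution equals the background.
#' @export
jsdColumnScore <- function(column, background = blosum62Background(),
                           pseudocount = 1e-7) {
  if (!length(column)) stop("empty column")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  column <- toupper(column)
  isGap <- column %in% c("-", ".", "X")
  gapFrac <- mean(isGap)
  if (all(isGap)) {
    warning("all-gap column scored 0")
    return(0)
  }
  aa <- column[!isGap]
  counts <- table(factor(aa, levels = .AA_ORDER))
  p <- as.numeric(counts) + pseudocount
  p <- p / sum(p)
  q <- as.numeric(background[.AA_ORDER])
  r <- (p + q) / 2
  jsd <- .shannon(r) - (.shannon(p) + .shannon(q)) / 2
  score <- max(0, min(1, jsd)) * (1 - gapFrac)
  score
}

#' Rescale raw column scores to the [30, 70] display range
#'
#' Linear min-max map \code{30 + 40 * (s - min) / (max - min)}; a constant
#' input degenerates to 50 everywhere. For any non-constant input the
#' maximum maps to exactly 70 and the minimum to exactly 30.
#'
#' @param raw numeric vector of raw scores.
#' @return numeric vector in [30, 70].
#' @export
rescaleScores <- function(raw) {
  if (!length(raw)) stop("need at least one score")
  rng <- range(raw)
  if (diff(rng) == 0) return(rep(50, length(raw)))
  30 + 40 * (raw - rng[1]) / diff(rng)
}

#' Per-column conservation profile of an alignment
#'
#' @param msa an AAStringSet of aligned rows (see
#'   \code{\link{readMsaFasta}}).
#' @param background background distribution (default BLOSUM62 marginals).
#' @param pseudocount per-amino-acid pseudocount (default 1e-7).
#' @return a \linkS4class{ConservationProfile} with mode "conservation".
#' @export
conservationProfile <- function(msa, background = blosum62Background(),
                                pseudocount = 1e-7) {
  m <- msaMatrix(msa)
  raw <- apply(m, 2, jsdColumnScore, background = background,
               pseudocount = pseudocount)
  new("ConservationProfile", raw = as.numeric(raw),
      rescaled = rescaleScores(raw), residueScores = numeric(0),
      mode = "conservation")
}

#' Differential on-target/off-target conservation profile
#'
#' The conservation profile is computed twice, once for the on-target
#' alignment with the off-target row appended and once without it; the raw
#' differential score per column is the absolute difference of the two raw
#' scores, rescaled to [30, 70]. Low rescaled values mean the on- and
#' off-targets look alike at that column; high values flag residues that
#' distinguish them.
#'
#' @param msaOn AAStringSet of on-target rows.
#' @param offSequence the aligned off-target row (character string or
#'   length-1 AAStringSet) of the same width.
#' @param background,pseudocount as in \code{\link{conservationProfile}}.
#' @return a \linkS4class{ConservationProfile} with mode "differential".
#' @export
differentialConservation <- function(msaOn, offSequence,
                                     background = blosum62Background(),
                                     pseudocount = 1e-7) {
  off <- toupper(as.character(offSequence)[1])
  w <- unique(nchar(as.character(msaOn)))
  if (length(w) != 1L || nchar(off) != w)
    stop("off-target width ", nchar(off), " does not match alignment width ",
         paste(w, collapse = "/"))
  withOff <- Biostrings::AAStringSet(c(as.character(msaOn), off = off))
  rawOn  <- rawScores(conservationProfile(msaOn, background, pseudocount))
  rawAll <- rawScores(conservationProfile(withOff, background, pseudocount))
  rawDiff <- abs(rawAll - rawOn)
  new("ConservationProfile", raw = rawDiff,
      rescaled = rescaleScores(rawDiff), residueScores = numeric(0),
      mode = "differential")
}

#' Map a conservation profile onto a reference structure
#'
#' The MSA row most similar to the structure-derived sequence is taken as
#' the reference row (its identity must exceed \code{minIdentity}); each of
#' its non-gap columns then maps, in order, to the corresponding structure
#' residue through a pairwise alignment of the degapped row with the
#' structure sequence. Structure residues absent from the MSA row (e.g. an
#' N-terminal tag) are left unscored with a warning.
#'
#' @param profile a \linkS4class{ConservationProfile}.
#' @param msa the alignment the profile was computed from.
#' @param reference a \linkS4class{ProteinStructure}.
#' @param minIdentity identity floor for the reference-row match
#'   (default 0.9).
#' @return the profile with \code{residueScores} filled (names are residue
#'   keys).
#' @export
mapScoresToStructure <- function(profile, msa, reference, minIdentity = 0.9) {
  a <- atoms(reference)
  a <- a[!a$hetero, , drop = FALSE]
  rt <- residueTable(ProteinStructure("x", a))
  structSeq <- paste(.aa321(rt$resname), collapse = "")

  rows <- as.character(msa)
  best <- NULL
  for (i in seq_along(rows)) {
    degapped <- gsub("-", "", rows[i], fixed = TRUE)
    al <- .alignChains(list(seq = degapped), list(seq = structSeq))
    if (is.null(best) || al$identity > best$identity)
      best <- list(row = i, identity = al$identity, al = al,
                   degapped = degapped)
  }
  if (best$identity <= minIdentity)
    stop(sprintf(paste0("no MSA row matches the structure (best: '%s' at ",
                        "identity %.2f, need > %.2f)"),
                 names(msa)[best$row], best$identity, minIdentity))

  refRow <- strsplit(rows[best$row], "")[[1]]
  colOfRowPos <- which(refRow != "-")          # row position -> MSA column
  # row position -> structure residue index, through the pairwise alignment
  rowToStruct <- stats::setNames(best$al$memIdx, best$al$refIdx)

  scores <- numeric(0)
  for (pos in seq_along(colOfRowPos)) {
    si <- rowToStruct[as.character(pos)]
    if (is.na(si) || is.null(si)) next
    scores[rt$key[si]] <- rescaledScores(profile)[colOfRowPos[pos]]
  }
  unscored <- setdiff(rt$key, names(scores))
  if (length(unscored))
    warning(length(unscored), " structure residue(s) not covered by the MSA ",
            "reference row are unscored")
  initialize(profile, residueScores = scores)
}
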