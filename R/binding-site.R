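#' Define a binding site from a bound ligand
#'
#' Site residues are all reference residues having at least one heavy atom
#' within \code{radius} of any heavy atom of the ligand; the site centre is
#' the centroid of the ligand heavy atoms. Hydrogens never count towards the
#' radius test.
#'
#' @param reference the reference \linkS4class{ProteinStructure}.
#' @param ligand the ligand as a \linkS4class{ProteinStructure} (HETATM or
#'   ATOM records accepted).
#' @param radius inclusion radius in Angstrom (default 5).
#' @return a \linkS4class{BindingSite}.
#' @export
defineSiteFromLigand <- function(reference, ligand, radius = 5) {
  lig <- heavyAtoms(ligand)
  if (!nrow(lig)) stop("ligand has no heavy atoms")
  center <- colMeans(atomCoords(lig))
  .resolveSite(reference, atomCoords(lig), center, radius, source = "ligand")
}

#' Define a binding site from a point and radius
#'
#' As \code{\link{defineSiteFromLigand}} with the point replacing the ligand
#' centroid: a residue is included if any of its heavy atoms lies within
#' \code{radius} of \code{center}.
#'
#' @param reference the reference structure.
#' @param center 3-vector, Angstrom.
#' @param radius inclusion radius, Angstrom.
#' @return a \linkS4class{BindingSite}.
#' @export
defineSiteFromPoint <- function(reference, center, radius = 5) {
  stopifnot(length(center) == 3L, all(is.finite(center)), radius > 0)
  .resolveSite(reference, matrix(center, nrow = 1), center, radius, source = "point")
}

.resolveSite <- function(reference, probeCoords, center, radius, source) {
  prot <- heavyAtoms(reference)
  prot <- prot[!prot$hetero, , drop = FALSE]
  if (!nrow(prot)) stop("reference has no protein heavy atoms")
  pc <- atomCoords(prot)
  # min distance of each protein heavy atom to any probe atom
  d2 <- apply(probeCoords, 1, function(p)
    (pc[, 1] - p[1])^2 + (pc[, 2] - p[2])^2 + (pc[, 3] - p[3])^2)
  if (is.null(dim(d2))) d2 <- matrix(d2, ncol = nrow(probeCoords))
  mind <- sqrt(apply(d2, 1, min))
  key <- residueKey(prot$chain, prot$resno, prot$insert)
  inKeys <- unique(key[mind <= radius])
  rt <- residueTable(ProteinStructure("ref", prot))
  sel <- rt[rt$key %in% inKeys, , drop = FALSE]
  if (!nrow(sel)) {
    agg <- tapply(mind, key, min)
    stop(sprintf(paste0("no residue within %.2f A of the site; nearest residue ",
                        "%s at %.2f A"), radius, names(which.min(agg)), min(agg)))
  }
  new("BindingSite", center = as.numeric(center), radius = radius,
      residues = sel, source = source)
}

# BLOSUM62 with the X row/column zeroed so nonstandard residues score 0
# against everything.
.alignEnv <- new.env(parent = emptyenv())
.blosum62X0 <- function() {
  if (is.null(.alignEnv$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["X", ] <- 0L
    m[, "X"] <- 0L
    .alignEnv$mat <- m
  }
  .alignEnv$mat
}

# One-letter sequence of the protein (non-hetero) residues of a chain, plus
# the residue table rows it came from.
.chainSequence <- function(structure, chain) {
  a <- atoms(structure)
  a <- a[!a$hetero & a$chain == chain, , drop = FALSE]
  if (!nrow(a)) return(NULL)
  rt <- residueTable(ProteinStructure("x", a))
  list(seq = paste(.aa321(rt$resname), collapse = ""), residues = rt)
}

# Global Needleman-Wunsch alignment of two chain sequences; returns the
# residue-index correspondence and identity over aligned columns.
.alignChains <- function(refInfo, memInfo) {
  aln <- Biostrings::pairwiseAlignment(
    refInfo$seq, memInfo$seq, type = "global",
    substitutionMatrix = .blosum62X0(), gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  # pattern()/subject() views clip unaligned (end-gapped) flanks; their
  # start() gives the sequence offset of the first shown position
  pOff <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  sOff <- Biostrings::start(Biostrings::subject(aln)) - 1L
  pPos <- pOff + cumsum(p != "-")
  sPos <- sOff + cumsum(s != "-")
  both <- p != "-" & s != "-"
  aligned <- sum(both)
  list(refIdx = pPos[both], memIdx = sPos[both], aligned = aligned,
       identity = if (aligned) sum(p[both] == s[both]) / aligned else 0)
}

#' Map site residues of the reference onto an ensemble member
#'
#' Chains are paired by identical chain id when the member has it, otherwise
#' by the best-identity pairing over all chain pairs. Each paired chain is
#' globally aligned (Needleman-Wunsch, BLOSUM62, affine gaps) and reference
#' site residues are mapped through aligned columns. Site residues falling
#' in gaps are reported UNMAPPED (NA member key); residues mapping to a
#' different residue type are flagged as mutations.
#'
#' @param site a \linkS4class{BindingSite} on the reference.
#' @param reference the reference structure.
#' @param member an ensemble member structure.
#' @param minIdentity mapping fails below this overall identity fraction
#'   (default 0.2).
#' @return a \linkS4class{ResidueMapping}.
#' @export
mapSiteResidues <- function(site, reference, member, minIdentity = 0.2) {
  refChains <- unique(siteResidues(site)$chain)
  memChains <- unique(atoms(member)$chain[!atoms(member)$hetero])
  pairs <- data.frame(ref_key = character(0), member_key = character(0),
                      ref_resname = character(0), member_resname = character(0),
                      mutated = logical(0), stringsAsFactors = FALSE)
  totAligned <- 0L; totIdent <- 0
  for (ch in refChains) {
    refInfo <- .chainSequence(reference, ch)
    if (is.null(refInfo) || nrow(refInfo$residues) < 5L)
      stop("reference chain ", ch, " has fewer than 5 residues")
    # pair by identical id when available, else best identity over all chains
    if (ch %in% memChains) {
      cand <- ch
    } else {
      cand <- memChains
    }
    best <- NULL; bestCh <- NA_character_
    for (mc in cand) {
      memInfo <- .chainSequence(member, mc)
      if (is.null(memInfo) || nrow(memInfo$residues) < 5L) next
      al <- .alignChains(refInfo, memInfo)
      if (is.null(best) || al$identity > best$al$identity) {
        best <- list(al = al, memInfo = memInfo); bestCh <- mc
      }
    }
    if (is.null(best))
      stop("no member chain with >= 5 residues to pair with reference chain ", ch)
    al <- best$al; memInfo <- best$memInfo
    totAligned <- totAligned + al$aligned
    totIdent <- totIdent + al$identity * al$aligned
    refRes <- refInfo$residues; memRes <- memInfo$residues
    siteKeys <- siteResidues(site)$key[siteResidues(site)$chain == ch]
    ri <- match(siteKeys, refRes$key)
    ok <- !is.na(ri)               # site residue is a protein residue here
    ri <- ri[ok]; siteKeys <- siteKeys[ok]
    hit <- match(ri, al$refIdx)
    mi <- al$memIdx[hit]
    chainPairs <- data.frame(
      ref_key = siteKeys,
      member_key = ifelse(is.na(hit), NA_character_, memRes$key[mi]),
      ref_resname = refRes$resname[ri],
      member_resname = ifelse(is.na(hit), NA_character_, memRes$resname[mi]),
      mutated = ifelse(is.na(hit), NA,
                       refRes$resname[ri] != memRes$resname[mi]),
      stringsAsFactors = FALSE)
    pairs <- rbind(pairs, chainPairs)
  }
  identity <- if (totAligned) totIdent / totAligned else 0
  if (identity < minIdentity)
    stop(sprintf("sequence mapping failed: identity %.2f below floor %.2f",
                 identity, minIdentity))
  if (any(is.na(pairs$member_key)))
    warning(sum(is.na(pairs$member_key)), " site residue(s) unmapped in ",
            member@id, "; excluded from superposition and RMSD")
  new("ResidueMapping", pairs = pairs, identity = identity)
}
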