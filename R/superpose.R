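#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation mapping point set \code{b} onto
#' point set \code{a} (row-wise correspondence) that minimizes the RMSD.
#' A reflection in the SVD solution is corrected so the rotation is always
#' proper. Collinear (rank-deficient) point sets are solved but flagged via
#' the \code{degenerate} attribute of the returned RMSD.
#'
#' @param a,b N x 3 coordinate matrices (N >= 3), Angstrom.
#' @return list with \code{transform} (a \linkS4class{RigidTransform}) and
#'   \code{rmsd} (post-fit RMSD, Angstrom).
#' @export
kabsch <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b) || ncol(a) != 3L || ncol(b) != 3L)
    stop("point sets must be N x 3 with equal N")
  if (nrow(a) < 3L) stop("insufficient points for superposition (need >= 3, got ",
                         nrow(a), ")")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  H <- crossprod(bc, ac)                     # maps b-frame onto a-frame
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  fitted <- bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - ac)^2)))
  tr <- new("RigidTransform", rotation = R,
            translation = as.numeric(ca - R %*% cb))
  attr(rmsd, "degenerate") <- degenerate
  list(transform = tr, rmsd = rmsd)
}

#' Apply a rigid transform
#' @param x a coordinate matrix (N x 3) or \linkS4class{ProteinStructure}.
#' @param transform a \linkS4class{RigidTransform}.
#' @return object of the same kind with transformed coordinates.
#' @export
applyTransform <- function(x, transform) {
  if (is(x, "ProteinStructure")) {
    crd <- applyTransform(atomCoords(x), transform)
    a <- atoms(x)
    a$x <- crd[, 1]; a$y <- crd[, 2]; a$z <- crd[, 3]
    return(ProteinStructure(x@id, a))
  }
  sweep(as.matrix(x) %*% t(transform@rotation), 2, transform@translation, "+")
}

# Per-residue coordinate bundles of the site residues: backbone atoms as a
# named matrix, side-chain heavy-atom geometric centre (all heavy atoms for
# glycine / side-chain-less residues), keyed by residue key.
.siteResidueCoords <- function(structure, keys) {
  a <- heavyAtoms(structure)
  akey <- residueKey(a$chain, a$resno, a$insert)
  sel <- akey %in% keys
  a <- a[sel, , drop = FALSE]
  akey <- akey[sel]
  crd <- as.matrix(a[, c("x", "y", "z")])
  name <- a$name
  idxByKey <- split(seq_along(akey), akey)
  out <- lapply(idxByKey, function(idx) {
    nm <- name[idx]
    bbSel <- nm %in% c("N", "CA", "C", "O")
    bb <- crd[idx[bbSel], , drop = FALSE]
    rownames(bb) <- nm[bbSel]
    scSel <- !nm %in% .BACKBONE_NAMES
    ctrIdx <- if (any(scSel)) idx[scSel] else idx
    list(bb = bb, center = colMeans(crd[ctrIdx, , drop = FALSE]))
  })
  out[intersect(keys, names(out))]
}

# Paired site backbone coordinates of reference vs member through a mapping.
# Residues need N, CA and C in both; O is included when present in both.
.pairedBackbone <- function(member, reference, site, mapping) {
  p <- mappingPairs(mapping)
  p <- p[!is.na(p$member_key), , drop = FALSE]
  refC <- .siteResidueCoords(reference, p$ref_key)
  memC <- .siteResidueCoords(member, p$member_key)
  refM <- NULL; memM <- NULL; resKey <- character(0); nPerRes <- integer(0)
  missing <- character(0)
  for (i in seq_len(nrow(p))) {
    rc <- refC[[p$ref_key[i]]]; mc <- memC[[p$member_key[i]]]
    if (is.null(rc) || is.null(mc)) { missing <- c(missing, p$ref_key[i]); next }
    core <- c("N", "CA", "C")
    if (!all(core %in% rownames(rc$bb)) || !all(core %in% rownames(mc$bb))) {
      missing <- c(missing, p$ref_key[i]); next
    }
    names <- core
    if ("O" %in% rownames(rc$bb) && "O" %in% rownames(mc$bb)) names <- c(names, "O")
    refM <- rbind(refM, rc$bb[names, , drop = FALSE])
    memM <- rbind(memM, mc$bb[names, , drop = FALSE])
    resKey <- c(resKey, p$ref_key[i]); nPerRes <- c(nPerRes, length(names))
  }
  list(ref = refM, mem = memM, residues = resKey, nPerRes = nPerRes,
       missing = missing)
}

#' Superpose an ensemble member onto the reference binding site
#'
#' Fits the member to the reference on the paired backbone atoms
#' (N, CA, C and O when present) of the mapped site residues, then applies
#' the fitted transform to all member atoms.
#'
#' @param member,reference structures.
#' @param site a \linkS4class{BindingSite}.
#' @param mapping the \linkS4class{ResidueMapping} of member onto reference.
#' @return list with \code{structure} (transformed member), \code{rmsd}
#'   (fitted site-backbone RMSD) and \code{transform}.
#' @export
superposeMember <- function(member, reference, site, mapping) {
  pb <- .pairedBackbone(member, reference, site, mapping)
  if (length(unique(pb$residues)) < 3L)
    stop("superposition needs >= 3 mapped site residues with complete ",
         "backbone; unusable residues: ",
         paste(pb$missing, collapse = ", "))
  fit <- kabsch(pb$ref, pb$mem)
  list(structure = applyTransform(member, fit$transform),
       rmsd = as.numeric(fit$rmsd), transform = fit$transform)
}

# Per-residue RMSD of member vs reference under a metric, for already
# superposed structures. backbone: RMSD over that residue's paired backbone
# atoms; sidechain_center: distance between side-chain geometric centres.
.perResidueRmsd <- function(member, reference, site, mapping,
                            metric = c("backbone", "sidechain_center")) {
  metric <- match.arg(metric)
  p <- mappingPairs(mapping)
  p <- p[!is.na(p$member_key), , drop = FALSE]
  refC <- .siteResidueCoords(reference, p$ref_key)
  memC <- .siteResidueCoords(member, p$member_key)
  out <- stats::setNames(rep(NA_real_, nrow(p)), p$ref_key)
  for (i in seq_len(nrow(p))) {
    rc <- refC[[p$ref_key[i]]]; mc <- memC[[p$member_key[i]]]
    if (is.null(rc) || is.null(mc)) next
    if (metric == "backbone") {
      names <- intersect(rownames(rc$bb), rownames(mc$bb))
      if (!length(names)) next
      out[i] <- sqrt(mean(rowSums((rc$bb[names, , drop = FALSE] -
                                   mc$bb[names, , drop = FALSE])^2)))
    } else {
      out[i] <- sqrt(sum((rc$center - mc$center)^2))
    }
  }
  out
}

#' Binding-site RMSD between two superposed structures
#'
#' \code{backbone}: RMSD pooled over the paired N, CA, C, O atoms of the
#' site residues. \code{sidechain_center}: RMSD over the per-residue
#' geometric centres of side-chain heavy atoms (all heavy atoms for
#' glycine).
#'
#' @param member,reference superposed structures.
#' @param site a \linkS4class{BindingSite}.
#' @param mapping \linkS4class{ResidueMapping} of member onto reference.
#' @param metric \code{"backbone"} (default) or \code{"sidechain_center"}.
#' @return RMSD in Angstrom.
#' @export
siteRmsd <- function(member, reference, site, mapping,
                     metric = c("backbone", "sidechain_center")) {
  metric <- match.arg(metric)
  if (metric == "backbone") {
    pb <- .pairedBackbone(member, reference, site, mapping)
    if (is.null(pb$ref)) stop("backbone RMSD unresolvable: no paired backbone atoms")
    return(sqrt(mean(rowSums((pb$ref - pb$mem)^2))))
  }
  d <- .perResidueRmsd(member, reference, site, mapping, metric)
  d <- d[!is.na(d)]
  if (!length(d)) stop("sidechain_center RMSD unresolvable for all residues")
  sqrt(mean(d^2))
}

#' Superpose every ensemble member onto the reference
#'
#' @param ensemble a \linkS4class{StructureEnsemble}.
#' @param site a \linkS4class{BindingSite} on the reference.
#' @param minIdentity mapping identity floor (see
#'   \code{\link{mapSiteResidues}}).
#' @return list with \code{ensemble} (members replaced by superposed
#'   copies), \code{mappings} (per-member \linkS4class{ResidueMapping}) and
#'   \code{fitRmsd} (per-member fitted backbone RMSD).
#' @export
superposeEnsemble <- function(ensemble, site, minIdentity = 0.2) {
  ref <- referenceStructure(ensemble)
  mem <- members(ensemble)
  mappings <- lapply(mem, function(m) mapSiteResidues(site, ref, m, minIdentity))
  fits <- Map(function(m, mp) superposeMember(m, ref, site, mp), mem, mappings)
  StructureEnsemble(ref, lapply(fits, `[[`, "structure"), ensemble@labels) -> ens
  list(ensemble = ens, mappings = mappings,
       fitRmsd = vapply(fits, `[[`, numeric(1), "rmsd"))
}

#' Binding-site RMSD statistics across an ensemble
#'
#' Computes (i) the member-by-member site RMSD matrix, each member having
#' been independently fitted to the reference (no pairwise re-fitting);
#' (ii) the per-member mean over site residues of the residue RMSD versus
#' the reference; (iii) the per-residue maximum over members of that residue
#' RMSD; and (iv) the underlying member x residue RMSD matrix.
#'
#' @param superposed result of \code{\link{superposeEnsemble}}.
#' @param site a \linkS4class{BindingSite}.
#' @param metric \code{"backbone"} or \code{"sidechain_center"}.
#' @return list with \code{matrix}, \code{perMemberMean},
#'   \code{perResidueMax}, \code{perResidue}, \code{metric}.
#' @export
rmsdStats <- function(superposed, site,
                      metric = c("backbone", "sidechain_center")) {
  metric <- match.arg(metric)
  ens <- superposed$ensemble
  ref <- referenceStructure(ens)
  mem <- members(ens)
  maps <- superposed$mappings
  n <- length(mem)
  keys <- siteResidues(site)$key

  # cache per-member residue bundles, indexed by reference key
  bundles <- lapply(seq_len(n), function(i) {
    p <- mappingPairs(maps[[i]])
    p <- p[!is.na(p$member_key), , drop = FALSE]
    b <- .siteResidueCoords(mem[[i]], p$member_key)
    stats::setNames(b[p$member_key], p$ref_key)
  })
  refBundle <- .siteResidueCoords(ref, keys)

  pairRmsd <- function(bi, bj) {
    common <- intersect(names(bi), names(bj))
    if (metric == "backbone") {
      sq <- 0; cnt <- 0L
      for (k in common) {
        nm <- intersect(rownames(bi[[k]]$bb), rownames(bj[[k]]$bb))
        if (!length(nm)) next
        sq <- sq + sum((bi[[k]]$bb[nm, , drop = FALSE] -
                        bj[[k]]$bb[nm, , drop = FALSE])^2)
        cnt <- cnt + length(nm)
      }
      if (!cnt) return(NA_real_)
      sqrt(sq / cnt)
    } else {
      d2 <- vapply(common, function(k)
        sum((bi[[k]]$center - bj[[k]]$center)^2), numeric(1))
      if (!length(d2)) return(NA_real_)
      sqrt(mean(d2))
    }
  }

  mat <- matrix(0, n, n, dimnames = list(ens@labels, ens@labels))
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    mat[i, j] <- mat[j, i] <- pairRmsd(bundles[[i]], bundles[[j]])
  }

  perRes <- matrix(NA_real_, n, length(keys), dimnames = list(ens@labels, keys))
  for (i in seq_len(n)) {
    v <- .perResidueRmsd(mem[[i]], ref, site, maps[[i]], metric)
    perRes[i, names(v)] <- v
  }
  list(matrix = mat,
       perMemberMean = rowMeans(perRes, na.rm = TRUE),
       perResidueMax = apply(perRes, 2, function(c)
         if (all(is.na(c))) NA_real_ else max(c, na.rm = TRUE)),
       perResidue = perRes, metric = metric)
}
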