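# Grid-based cavity detection: protein masking by vdW + probe radius, a
# LIGSITE-style 7-direction buriedness scan, and connected-component
# filtering around the site centre.

#' Build the shared analysis grid over a binding site
#'
#' An axis-aligned cubic grid covering the site sphere plus a margin,
#' snapped so the site centre lies exactly on a grid point. All members of
#' a run share this grid.
#'
#' @param site a \linkS4class{BindingSite}.
#' @param margin extra extent beyond the site radius, Angstrom (default 2).
#' @param spacing isotropic grid spacing, Angstrom, in [0.25, 2] (default 1).
#' @return a \linkS4class{Grid3D} of zeros.
#' @export
buildPocketGrid <- function(site, margin = 2, spacing = 1) {
  if (spacing < 0.25 || spacing > 2)
    stop("spacing must be in [0.25, 2] A, got ", spacing)
  half <- ceiling((siteRadius(site) + margin) / spacing)
  dims <- rep(2L * as.integer(half) + 1L, 3)
  if (prod(dims) > 1e7)
    stop("grid would have ", prod(dims), " points (> 1e7); increase spacing")
  origin <- siteCenter(site) - half * spacing
  Grid3D(origin = origin, spacing = spacing, dims = dims)
}

# linear index (1-based) from 1-based ijk rows
.lin3 <- function(ijk, dims) {
  ijk[, 1] + (ijk[, 2] - 1L) * dims[1] + (ijk[, 3] - 1L) * dims[1] * dims[2]
}

# Mark grid points within (vdW(element) + probe) of any heavy atom.
.proteinMask <- function(structure, grid, probeRadius) {
  a <- heavyAtoms(structure)
  if (!nrow(a)) stop("structure has no heavy atoms")
  d <- grid@dims; o <- grid@origin; s <- grid@spacing
  mask <- array(FALSE, dim = d)
  radii <- vdwRadius(a$element) + probeRadius
  crd <- atomCoords(a)
  for (t in seq_len(nrow(a))) {
    r <- radii[t]; p <- crd[t, ]
    lo <- pmax(ceiling((p - r - o) / s) + 1L, 1L)
    hi <- pmin(floor((p + r - o) / s) + 1L, d)
    if (any(lo > hi)) next
    xs <- o[1] + (lo[1]:hi[1] - 1L) * s
    ys <- o[2] + (lo[2]:hi[2] - 1L) * s
    zs <- o[3] + (lo[3]:hi[3] - 1L) * s
    dx2 <- (xs - p[1])^2; dy2 <- (ys - p[2])^2; dz2 <- (zs - p[3])^2
    within <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r * r
    mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      as.vector(mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]) | as.vector(within)
  }
  mask
}

# The 7 LIGSITE scan directions: 3 axes + 4 cube diagonals.
.SCAN_DIRS <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# 26-connected component labelling of a boolean mask; returns an integer
# array (0 = background) with components labelled in arbitrary order.
.labelComponents26 <- function(mask, dims) {
  lab <- array(0L, dim = dims)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  map <- integer(prod(dims)); map[idx] <- seq_along(idx)
  ijk <- arrayInd(idx, dims)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  offsets <- offsets[offsets[, 3] > 0 |
                     (offsets[, 3] == 0 & offsets[, 2] > 0) |
                     (offsets[, 3] == 0 & offsets[, 2] == 0 & offsets[, 1] > 0),
                     , drop = FALSE]   # half-neighbourhood (13 offsets)
  edges <- NULL
  for (r in seq_len(nrow(offsets))) {
    nijk <- sweep(ijk, 2, offsets[r, ], "+")
    inb <- nijk[, 1] >= 1L & nijk[, 1] <= dims[1] &
           nijk[, 2] >= 1L & nijk[, 2] <= dims[2] &
           nijk[, 3] >= 1L & nijk[, 3] <= dims[3]
    if (!any(inb)) next
    nlin <- .lin3(nijk[inb, , drop = FALSE], dims)
    hit <- mask[nlin]
    if (!any(hit)) next
    edges <- rbind(edges, cbind(map[idx[inb][hit]], map[nlin[hit]]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' Detect the binding-site cavity of one structure on a grid
#'
#' Three steps: (1) grid points within vdW(element) + probeRadius of any
#' heavy atom are protein; (2) every free point inside the site sphere is
#' scanned along 7 directions (x, y, z axes and the 4 cube diagonals) up to
#' \code{scanDepth} each way, and is buried if at least
#' \code{minBuriedDirections} directions hit protein on both sides;
#' (3) the pocket is the set of buried free points restricted to
#' 26-connected components that intersect the half-radius sphere around the
#' site centre (discarding surface grooves far from the site).
#'
#' @param structure a structure superposed into the reference frame.
#' @param grid the shared \linkS4class{Grid3D} from
#'   \code{\link{buildPocketGrid}}.
#' @param site the \linkS4class{BindingSite} the grid was built for.
#' @param probeRadius probe radius added to vdW radii, Angstrom (default 1.4).
#' @param minBuriedDirections burial threshold out of 7 (default 5).
#' @param scanDepth scan depth per direction, Angstrom (default 10).
#' @return a \linkS4class{PocketGrid}.
#' @export
detectPocket <- function(structure, grid, site, probeRadius = 1.4,
                         minBuriedDirections = 5L, scanDepth = 10) {
  d <- grid@dims
  protein <- .proteinMask(structure, grid, probeRadius)

  crd <- gridPointCoords(grid)
  inSite <- rowSums(sweep(crd, 2, siteCenter(site))^2) <= siteRadius(site)^2
  cand <- which(!protein & array(inSite, dim = d))
  pocket <- array(FALSE, dim = d)
  if (length(cand)) {
    ijk <- arrayInd(cand, d)
    nBuried <- integer(length(cand))
    for (r in seq_len(nrow(.SCAN_DIRS))) {
      dir <- .SCAN_DIRS[r, ]
      stepLen <- grid@spacing * sqrt(sum(dir^2))
      nSteps <- floor(scanDepth / stepLen)
      hitPos <- hitNeg <- logical(length(cand))
      for (s in seq_len(nSteps)) {
        for (sgn in c(1L, -1L)) {
          nijk <- sweep(ijk, 2, sgn * s * dir, "+")
          inb <- nijk[, 1] >= 1L & nijk[, 1] <= d[1] &
                 nijk[, 2] >= 1L & nijk[, 2] <= d[2] &
                 nijk[, 3] >= 1L & nijk[, 3] <= d[3]
          hit <- logical(length(cand))
          if (any(inb)) hit[inb] <- protein[.lin3(nijk[inb, , drop = FALSE], d)]
          if (sgn > 0) hitPos <- hitPos | hit else hitNeg <- hitNeg | hit
        }
      }
      nBuried <- nBuried + (hitPos & hitNeg)
    }
    pocket[cand[nBuried >= minBuriedDirections]] <- TRUE

    if (any(pocket)) {
      lab <- .labelComponents26(pocket, d)
      nearCenter <- rowSums(sweep(crd, 2, siteCenter(site))^2) <=
        (siteRadius(site) / 2)^2
      keep <- unique(lab[lab > 0L & array(nearCenter, dim = d)])
      pocket <- array(lab %in% keep & lab > 0L, dim = d)
    }
  }
  stopifnot(!any(pocket & protein))   # disjointness by construction
  new("PocketGrid", origin = grid@origin, spacing = grid@spacing,
      dims = d, values = pocket, structureId = structure@id)
}

#' Geometric and physicochemical statistics of a detected pocket
#'
#' Volume is the pocket point count times spacing^3. Surface area counts
#' 6-adjacent faces between pocket points and solvent (free non-protein,
#' non-pocket points, or points outside the grid), times spacing^2. Lining
#' residues have at least one side-chain heavy atom within
#' \code{contactDistance} of a pocket point; each pocket point inherits the
#' physicochemical properties (donor/acceptor/positive/negative/
#' hydrophobic) of the side-chain atoms it contacts.
#'
#' @param pocket a \linkS4class{PocketGrid}.
#' @param structure the structure the pocket was detected in (same frame).
#' @param contactDistance contact cutoff, Angstrom (default 4).
#' @param probeRadius probe radius used during detection, needed to
#'   reconstruct the protein mask for the solvent test (default 1.4).
#' @return a \linkS4class{PocketStats}.
#' @export
pocketStats <- function(pocket, structure, contactDistance = 4,
                        probeRadius = 1.4) {
  d <- pocket@dims; s <- pocket@spacing
  pmask <- pocket@values
  idx <- which(pmask)
  volume <- length(idx) * s^3

  protein <- .proteinMask(structure, pocket, probeRadius)
  surface <- 0L
  if (length(idx)) {
    ijk <- arrayInd(idx, d)
    for (ax in 1:3) for (sgn in c(-1L, 1L)) {
      nijk <- ijk
      nijk[, ax] <- nijk[, ax] + sgn
      inb <- nijk[, ax] >= 1L & nijk[, ax] <= d[ax]
      # outside the grid counts as solvent
      nSolv <- sum(!inb)
      if (any(inb)) {
        nlin <- .lin3(nijk[inb, , drop = FALSE], d)
        nSolv <- nSolv + sum(!protein[nlin] & !pmask[nlin])
      }
      surface <- surface + nSolv
    }
  }

  lining <- character(0)
  counts <- stats::setNames(integer(length(.POCKET_PROPERTIES)), .POCKET_PROPERTIES)
  if (length(idx)) {
    a <- heavyAtoms(structure)
    a <- a[!a$hetero & !a$name %in% .BACKBONE_NAMES, , drop = FALSE]  # side chains
    if (nrow(a)) {
      pc <- sweep((arrayInd(idx, d) - 1) * s, 2, pocket@origin, "+")
      ac <- atomCoords(a)
      cd2 <- contactDistance^2
      akey <- residueKey(a$chain, a$resno, a$insert)
      pointProps <- vector("list", length(idx))
      liningHit <- logical(nrow(a))
      for (t in seq_len(nrow(a))) {
        d2 <- (pc[, 1] - ac[t, 1])^2 + (pc[, 2] - ac[t, 2])^2 +
              (pc[, 3] - ac[t, 3])^2
        touch <- d2 <= cd2
        if (!any(touch)) next
        liningHit[t] <- TRUE
        props <- atomProperties(a$resname[t], a$name[t], a$element[t])
        if (length(props)) for (w in which(touch))
          pointProps[[w]] <- union(pointProps[[w]], props)
      }
      lining <- unique(akey[liningHit])
      for (prop in .POCKET_PROPERTIES)
        counts[prop] <- sum(vapply(pointProps, function(p) prop %in% p, logical(1)))
    }
  }
  new("PocketStats", structureId = pocket@structureId, volume = volume,
      surfaceArea = surface * s^2, liningResidues = lining,
      propertyCounts = counts)
}

#' Compare pocket lining residues across members with the reference
#'
#' @param memberStats list of \linkS4class{PocketStats}, one per member.
#' @param referenceStats \linkS4class{PocketStats} of the reference.
#' @return data.frame: residue key, fraction of members lining the pocket,
#'   whether it lines the reference pocket, and a new/lost flag.
#' @export
liningResidueComparison <- function(memberStats, referenceStats) {
  refSet <- liningResidues(referenceStats)
  allKeys <- unique(c(refSet, unlist(lapply(memberStats, liningResidues))))
  frac <- vapply(allKeys, function(k)
    mean(vapply(memberStats, function(s) k %in% liningResidues(s), logical(1))),
    numeric(1))
  inRef <- allKeys %in% refSet
  flag <- rep("", length(allKeys))
  flag[!inRef & frac > 0] <- "new"
  flag[inRef & frac == 0] <- "lost"
  data.frame(key = allKeys, member_fraction = frac, in_reference = inRef,
             flag = flag, row.names = NULL, stringsAsFactors = FALSE)
}
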