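# Transient-pocket analysis: per-point occurrence frequencies across the
# ensemble, appearing/disappearing/conserved regions relative to the
# reference pocket, compact sub-pocket decomposition and per-member opening
# profiles.

.checkSharedGeometry <- function(grids) {
  g1 <- grids[[1]]
  for (g in grids[-1]) {
    if (!identical(g@dims, g1@dims) || abs(g@spacing - g1@spacing) > 1e-9 ||
        max(abs(g@origin - g1@origin)) > 1e-9)
      stop("grids do not share origin/spacing/dims")
  }
  invisible(TRUE)
}

#' Per-point pocket occurrence frequency across ensemble members
#'
#' @param pockets list of \linkS4class{PocketGrid} on a shared grid
#'   (the reference pocket is normally not included).
#' @return a \linkS4class{Grid3D} with values in [0, 1]: the fraction of
#'   members in which each point is pocket.
#' @export
frequencyGrid <- function(pockets) {
  if (!length(pockets)) stop("need at least one pocket grid")
  .checkSharedGeometry(pockets)
  acc <- Reduce(`+`, lapply(pockets, function(p) p@values * 1))
  g <- pockets[[1]]
  Grid3D(origin = g@origin, spacing = g@spacing, dims = g@dims,
         values = acc / length(pockets))
}

#' Appearing, disappearing and conserved pocket regions
#'
#' Relative to the reference pocket: a point is \emph{appearing} if it is
#' not pocket in the reference but is pocket in at least
#' \code{thresholdFraction} of the members; \emph{disappearing} if it is
#' pocket in the reference but closed in at least that fraction;
#' \emph{conserved} if its frequency is at least \code{conservedFraction}.
#' Appearing and disappearing sets are disjoint by construction.
#'
#' @param freq frequency \linkS4class{Grid3D} from
#'   \code{\link{frequencyGrid}}.
#' @param referencePocket the reference \linkS4class{PocketGrid}.
#' @param thresholdFraction occurrence threshold in (0, 1] (the standard
#'   choices are 0.25 and 0.5).
#' @param conservedFraction threshold for conserved regions (default 0.9).
#' @return list with logical \code{appearing}, \code{disappearing},
#'   \code{conserved} \linkS4class{Grid3D}s and the thresholds used.
#' @export
transientRegions <- function(freq, referencePocket, thresholdFraction,
                             conservedFraction = 0.9) {
  if (thresholdFraction <= 0 || thresholdFraction > 1)
    stop("thresholdFraction must be in (0, 1], got ", thresholdFraction)
  .checkSharedGeometry(list(freq, referencePocket))
  refMask <- referencePocket@values
  f <- freq@values
  appearing <- !refMask & (f >= thresholdFraction)
  disappearing <- refMask & ((1 - f) >= thresholdFraction)
  conserved <- f >= conservedFraction
  stopifnot(!any(appearing & disappearing))
  mk <- function(v) Grid3D(freq@origin, freq@spacing, freq@dims, values = v)
  list(appearing = mk(appearing), disappearing = mk(disappearing),
       conserved = mk(conserved), thresholdFraction = thresholdFraction,
       conservedFraction = conservedFraction)
}

#' Split a pocket region into compact sub-pockets
#'
#' Sub-pockets are the 26-connected components of the region mask;
#' components smaller than \code{minPoints} are discarded. Labels are
#' assigned by decreasing size, ties broken by the smallest linear grid
#' index.
#'
#' @param region a logical \linkS4class{Grid3D} (e.g. the appearing region).
#' @param minPoints minimum component size in grid points (default 5,
#'   about 5 Angstrom^3 at 1 Angstrom spacing).
#' @return a \linkS4class{SubPocketSet}.
#' @export
splitSubpockets <- function(region, minPoints = 5L) {
  mask <- region@values
  if (!is.logical(mask)) mask <- mask > 0
  lab0 <- .labelComponents26(mask, region@dims)
  comps <- setdiff(unique(as.integer(lab0)), 0L)
  info <- lapply(comps, function(c) {
    pts <- which(lab0 == c)
    list(size = length(pts), minIdx = min(pts), pts = pts)
  })
  keep <- vapply(info, function(x) x$size >= minPoints, logical(1))
  info <- info[keep]
  ord <- order(-vapply(info, `[[`, integer(1), "size"),
               vapply(info, `[[`, integer(1), "minIdx"))
  info <- info[ord]
  lab <- array(0L, dim = region@dims)
  tab <- data.frame(label = integer(0), size = integer(0),
                    cx = numeric(0), cy = numeric(0), cz = numeric(0))
  for (i in seq_along(info)) {
    lab[info[[i]]$pts] <- i
    ctr <- colMeans(sweep((arrayInd(info[[i]]$pts, region@dims) - 1) *
                          region@spacing, 2, region@origin, "+"))
    tab <- rbind(tab, data.frame(label = i, size = info[[i]]$size,
                                 cx = ctr[1], cy = ctr[2], cz = ctr[3]))
  }
  new("SubPocketSet",
      grid = Grid3D(region@origin, region@spacing, region@dims, values = lab),
      table = tab)
}

#' Per-member opening profile of a sub-pocket
#'
#' For each member, the fraction of the sub-pocket's grid points that are
#' pocket in that member -- the extent of opening of a transient
#' sub-pocket across the ensemble.
#'
#' @param subpockets a \linkS4class{SubPocketSet}.
#' @param label sub-pocket label.
#' @param pockets list of per-member \linkS4class{PocketGrid}s.
#' @return numeric vector of fractions in [0, 1], one per member.
#' @export
openingSeries <- function(subpockets, label, pockets) {
  pts <- subPocketPoints(subpockets, label)
  if (!length(pts)) stop("sub-pocket ", label, " is empty")
  .checkSharedGeometry(c(list(subpockets@grid), pockets))
  vapply(pockets, function(p) sum(p@values[pts]) / length(pts), numeric(1))
}
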