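# Deterministic generators for synthetic test systems: spherical-hollow
# shell structures built from pseudo-alanine residues on concentric
# Fibonacci-lattice layers, ensembles with planted sub-pocket opening
# events and planted site
# conformation clusters, and toy alignments with planted conserved and
# divergent columns. These stand in for simulation-generated ensembles so
# every pipeline stage can be exercised without external data.

# Idealized alanine heavy-atom template (N, CA, C, O, CB), centred on its
# heavy-atom centroid; extent ~1.5 A.
.ALA_TEMPLATE <- local({
  m <- rbind(N  = c(-1.458,  0.000,  0.000),
             CA = c( 0.000,  0.000,  0.000),
             C  = c( 0.551,  1.417,  0.000),
             O  = c( 1.772,  1.563,  0.000),
             CB = c( 0.540, -0.770, -1.200))
  sweep(m, 2, colMeans(m))
})

# Radial gap between the nominal hollow radius and the innermost wall
# layer. Calibrated so that after vdW + probe masking the free cavity
# radius matches the nominal hollow radius (see the methods vignette).
.SHELL_INNER_OFFSET <- 4.0

.randomRotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Deterministic quasi-uniform points on a sphere (Fibonacci lattice) with
# areal spacing ~ ptSpacing.
.fibSphere <- function(radius, ptSpacing) {
  n <- max(20L, ceiling(4 * pi * radius^2 / ptSpacing^2))
  i <- seq_len(n)
  z <- 1 - 2 * (i - 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(rho * cos(phi), rho * sin(phi), z)
}

# Wall anchor points: two concentric spherical layers with a sharp inner
# surface at hollowRadius + .SHELL_INNER_OFFSET.
.shellLattice <- function(hollowRadius, wallSpacing) {
  rIn <- hollowRadius + .SHELL_INNER_OFFSET
  rbind(.fibSphere(rIn, wallSpacing), .fibSphere(rIn + wallSpacing, wallSpacing))
}

#' Build a spherical-hollow shell structure of pseudo-alanines
#'
#' Alanine residues (full heavy-atom backbone plus CB) are anchored on two
#' concentric spherical Fibonacci-lattice layers around the origin,
#' forming a closed wall that encloses a hollow of the requested radius.
#' The inner layer radius is calibrated so that, after vdW + probe
#' masking, the free cavity radius matches \code{hollowRadius}. Residue
#' orientations come from an internal fixed-seed generator, so the
#' structure is bit-identical across calls.
#'
#' @param hollowRadius nominal cavity radius, Angstrom.
#' @param wallSpacing wall lattice spacing, Angstrom (default 3; must be
#'   small enough for vdW + probe spheres of adjacent wall atoms to
#'   overlap, i.e. <= ~3.5).
#' @param id structure id (default "shell").
#' @return a \linkS4class{ProteinStructure} (chain A, residues ALA).
#' @export
makeShellStructure <- function(hollowRadius, wallSpacing = 3, id = "shell") {
  stopifnot(hollowRadius >= 0, wallSpacing > 0)
  pts <- .shellLattice(hollowRadius, wallSpacing)
  if (!nrow(pts)) stop("degenerate shell: no lattice points")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(42L)   # orientations are part of the deterministic geometry
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    R <- .randomRotation()
    crd <- sweep(.ALA_TEMPLATE %*% t(R), 2, pts[i, ], "+")
    rows[[i]] <- data.frame(name = rownames(.ALA_TEMPLATE),
                            element = c("N", "C", "C", "O", "C"),
                            resname = "ALA", chain = "A", resno = i,
                            x = crd[, 1], y = crd[, 2], z = crd[, 3],
                            stringsAsFactors = FALSE)
  }
  ProteinStructure(id, do.call(rbind, rows))
}

#' Synthetic ensemble with planted pocket dynamics
#'
#' Members are copies of the shell structure of
#' \code{\link{makeShellStructure}} with, optionally: (a) Gaussian
#' coordinate noise; (b) a planted side sub-pocket, opened by displacing
#' the wall residues within \code{subpocketAperture} of the wall point in
#' direction \code{subpocketDirection} radially outwards by
#' \code{subpocketShift}, in exactly
#' \code{round(subpocketOpenFraction * nMembers)} members (seeded choice);
#' (c) \code{conformationalClusters} planted site conformations realized
#' as cluster-specific rigid displacements of all CB atoms (side-chain
#' shifts that leave the backbone untouched); and (d) a random rigid
#' jitter per member so superposition is exercised. The reference is the
#' clean closed shell.
#'
#' @param nMembers number of ensemble members (default 10).
#' @param hollowRadius,wallSpacing shell geometry (defaults 6 and 3).
#' @param subpocketOpenFraction fraction of members with the sub-pocket
#'   open (default 0 = no planting).
#' @param subpocketDirection unit direction of the planted sub-pocket
#'   (default +z).
#' @param subpocketAperture radius of the displaced wall patch, Angstrom
#'   (default 6.5).
#' @param subpocketShift outward displacement of the patch, Angstrom
#'   (default 4).
#' @param conformationalClusters number of planted clusters (0 = none; up
#'   to 7 supported).
#' @param clusterSeparation side-chain offset magnitude between clusters,
#'   Angstrom (default 5).
#' @param clusterSpread within-cluster side-chain jitter (per-residue RMSD
#'   scale), Angstrom (default 0.3).
#' @param noiseSigma Gaussian coordinate noise sd, Angstrom (default 0.05).
#' @param rigidJitter apply a random rigid transform per member
#'   (default TRUE).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return list with \code{ensemble} (a \linkS4class{StructureEnsemble}),
#'   \code{openMembers} (logical), \code{clusterAssignment} (integer,
#'   0-based; NA when no clusters planted).
#' @export
makeToyEnsemble <- function(nMembers = 10, hollowRadius = 6, wallSpacing = 3,
                            subpocketOpenFraction = 0,
                            subpocketDirection = c(0, 0, 1),
                            subpocketAperture = 6.5, subpocketShift = 4,
                            conformationalClusters = 0,
                            clusterSeparation = 5, clusterSpread = 0.3,
                            noiseSigma = 0.05, rigidJitter = TRUE,
                            seed = 1L) {
  stopifnot(nMembers >= 1, noiseSigma >= 0)
  ref <- makeShellStructure(hollowRadius, wallSpacing, id = "reference")
  refAtoms <- atoms(ref)
  dirU <- subpocketDirection / sqrt(sum(subpocketDirection^2))
  wallPoint <- dirU * (hollowRadius + .SHELL_INNER_OFFSET + wallSpacing)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  nOpen <- round(subpocketOpenFraction * nMembers)
  openMembers <- logical(nMembers)
  openMembers[sample.int(nMembers, nOpen)] <- TRUE

  k <- conformationalClusters
  clusterAssignment <- rep(NA_integer_, nMembers)
  clusterDirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0),
                       c(0, -1, 0), c(0, 0, -1), c(1, 1, 1) / sqrt(3))
  if (k > 0) {
    if (k > nrow(clusterDirs)) stop("at most ", nrow(clusterDirs), " clusters supported")
    clusterAssignment <- (seq_len(nMembers) - 1L) %% k
  }

  # residues whose centroid lies in the sub-pocket patch
  resCentroids <- do.call(rbind, lapply(split(refAtoms[, c("x", "y", "z")],
                                              refAtoms$resno), colMeans))
  patchRes <- as.integer(rownames(resCentroids)[
    sqrt(rowSums(sweep(resCentroids, 2, wallPoint)^2)) <= subpocketAperture])

  mems <- vector("list", nMembers)
  for (m in seq_len(nMembers)) {
    a <- refAtoms
    if (openMembers[m] && length(patchRes)) {
      hit <- a$resno %in% patchRes
      nrm <- sqrt(a$x[hit]^2 + a$y[hit]^2 + a$z[hit]^2)
      a$x[hit] <- a$x[hit] * (1 + subpocketShift / nrm)
      a$y[hit] <- a$y[hit] * (1 + subpocketShift / nrm)
      a$z[hit] <- a$z[hit] * (1 + subpocketShift / nrm)
    }
    if (k > 0) {
      v <- clusterDirs[clusterAssignment[m] + 1L, ] * clusterSeparation
      jit <- stats::rnorm(3, sd = clusterSpread / sqrt(3) / sqrt(2))
      cb <- a$name == "CB"
      a$x[cb] <- a$x[cb] + v[1] + jit[1]
      a$y[cb] <- a$y[cb] + v[2] + jit[2]
      a$z[cb] <- a$z[cb] + v[3] + jit[3]
    }
    if (noiseSigma > 0) {
      n <- nrow(a)
      a$x <- a$x + stats::rnorm(n, sd = noiseSigma)
      a$y <- a$y + stats::rnorm(n, sd = noiseSigma)
      a$z <- a$z + stats::rnorm(n, sd = noiseSigma)
    }
    if (rigidJitter) {
      R <- .randomRotation()
      t <- stats::runif(3, -2, 2)
      crd <- sweep(as.matrix(a[, c("x", "y", "z")]) %*% t(R), 2, t, "+")
      a$x <- crd[, 1]; a$y <- crd[, 2]; a$z <- crd[, 3]
    }
    mems[[m]] <- ProteinStructure(sprintf("member_%02d", m), a)
  }
  list(ensemble = StructureEnsemble(ref, mems),
       openMembers = openMembers, clusterAssignment = clusterAssignment)
}

#' Toy alignment with planted conserved and divergent columns
#'
#' On-target rows are identical at \code{conservedColumns} (one seeded
#' letter per column) and independently random elsewhere. The off-target
#' row equals the on-target consensus except at
#' \code{offDivergentColumns}, where it carries a different letter. This
#' emulates an on-target group of homologues plus one off-target with a
#' few selectivity-determining positions.
#'
#' @param nOn number of on-target rows (default 5).
#' @param width alignment width (default 40).
#' @param conservedColumns integer column indices fully conserved among
#'   on-targets.
#' @param offDivergentColumns columns where the off-target differs from
#'   the on-target consensus (ideally a subset of the conserved columns,
#'   where the differential signal is strongest).
#' @param seed integer seed.
#' @return list with \code{msa} (AAStringSet of on-target rows) and
#'   \code{off} (the off-target row as a character string).
#' @export
makeToyMsa <- function(nOn = 5, width = 40, conservedColumns = integer(0),
                       offDivergentColumns = integer(0), seed = 1L) {
  stopifnot(nOn >= 2, width >= 1,
            all(conservedColumns %in% seq_len(width)),
            all(offDivergentColumns %in% seq_len(width)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  m <- matrix(sample(.AA_ORDER, nOn * width, replace = TRUE), nOn, width)
  for (c in conservedColumns) m[, c] <- sample(.AA_ORDER, 1)
  consensus <- apply(m, 2, function(col) names(which.max(table(col))))
  off <- consensus
  for (c in offDivergentColumns)
    off[c] <- sample(setdiff(.AA_ORDER, consensus[c]), 1)
  msa <- Biostrings::AAStringSet(apply(m, 1, paste, collapse = ""))
  names(msa) <- sprintf("on_%02d", seq_len(nOn))
  list(msa = msa, off = paste(off, collapse = ""))
}

#' The binding site of a toy shell system
#'
#' Convenience wrapper: the site of a shell ensemble is centred at the
#' origin with a radius that reaches the inner wall layer, so the wall
#' residues become site residues.
#'
#' @param hollowRadius,wallSpacing shell geometry used to build the
#'   ensemble.
#' @param reference the reference shell structure.
#' @return a \linkS4class{BindingSite}.
#' @export
shellSite <- function(reference, hollowRadius, wallSpacing = 3) {
  defineSiteFromPoint(reference, c(0, 0, 0),
                      radius = hollowRadius + .SHELL_INNER_OFFSET + 2 * wallSpacing)
}
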