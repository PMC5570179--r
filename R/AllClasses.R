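#' @import methods
NULL

.ATOM_COLS <- c("serial", "name", "element", "resname", "chain", "resno",
                "insert", "x", "y", "z", "occ", "b", "hetero")

#' Residue key strings
#'
#' A residue within a structure is uniquely identified by
#' \code{(chain, resno, insert)}; the key string is
#' \code{"<chain>:<resno><insert>"}. The residue name is deliberately not
#' part of the key so that mutants in homologous structures share keys.
#'
#' @param chain chain identifiers.
#' @param resno residue sequence numbers.
#' @param insert insertion codes (\code{""} when absent).
#' @return character vector of keys.
#' @export
residueKey <- function(chain, resno, insert = "") {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  sprintf("%s:%d%s", chain, as.integer(resno), insert)
}

# ---- ProteinStructure -------------------------------------------------------

#' ProteinStructure: one conformation of a protein
#'
#' Holds an ordered atom table (PDB column conventions) for a single
#' conformation. Residues are derived from the atoms and keep atom order.
#'
#' @slot id structure identifier.
#' @slot atoms data.frame with columns serial, name, element, resname, chain,
#'   resno, insert, x, y, z, occ, b, hetero.
#' @export
setClass("ProteinStructure", slots = c(id = "character", atoms = "data.frame"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  miss <- setdiff(.ATOM_COLS, names(a))
  if (length(miss)) return(paste("atom table missing columns:", paste(miss, collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(c(a$x, a$y, a$z)))) return("non-finite atom coordinates")
    if (any(is.na(a$element) | a$element == "")) return("empty element symbols (inference failed)")
  }
  if (length(object@id) != 1L) return("id must be length 1")
  TRUE
})

#' Construct a ProteinStructure from an atom table
#'
#' @param id structure identifier.
#' @param atoms atom data.frame; missing optional columns (occ, b, hetero,
#'   insert, element) are filled with defaults, elements inferred from atom
#'   names where blank.
#' @return a \linkS4class{ProteinStructure}.
#' @export
ProteinStructure <- function(id, atoms) {
  n <- nrow(atoms)
  if (is.null(atoms$serial))  atoms$serial  <- seq_len(n)
  if (is.null(atoms$insert))  atoms$insert  <- rep("", n)
  if (is.null(atoms$occ))     atoms$occ     <- rep(1, n)
  if (is.null(atoms$b))       atoms$b       <- rep(0, n)
  if (is.null(atoms$hetero))  atoms$hetero  <- rep(FALSE, n)
  if (is.null(atoms$element)) atoms$element <- rep("", n)
  atoms$insert[is.na(atoms$insert) | atoms$insert == " "] <- ""
  blank <- is.na(atoms$element) | atoms$element == ""
  if (any(blank)) atoms$element[blank] <- inferElement(atoms$name[blank])
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  new("ProteinStructure", id = id, atoms = atoms[.ATOM_COLS])
}

#' Infer the element symbol from a PDB atom name
#'
#' Used when the element column of a PDB record is blank. Follows the PDB
#' convention that the element occupies the first one or two characters of
#' the right-justified atom name; digits and greek-position letters are
#' stripped.
#'
#' @param name atom name(s).
#' @return element symbol(s).
#' @export
inferElement <- function(name) {
  vapply(name, function(nm) {
    s <- gsub("[0-9']", "", trimws(nm))
    if (!nchar(s)) return("X")
    two <- toupper(substr(s, 1, 2))
    if (two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE")) return(substr(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))), 1, 2))
    toupper(substr(s, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

#' @describeIn ProteinStructure atom table accessor
#' @param x,object a ProteinStructure.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @export
setMethod("atoms", "ProteinStructure", function(x) x@atoms)

#' Heavy (non-hydrogen, non-deuterium) atom subset
#' @param x a ProteinStructure.
#' @return atom data.frame restricted to heavy atoms.
#' @export
heavyAtoms <- function(x) {
  a <- atoms(x)
  a[!(toupper(a$element) %in% c("H", "D")), , drop = FALSE]
}

#' Atom coordinates as an N x 3 matrix
#' @param x a ProteinStructure or atom data.frame.
#' @export
atomCoords <- function(x) {
  a <- if (is(x, "ProteinStructure")) atoms(x) else x
  as.matrix(a[, c("x", "y", "z")])
}

#' Residue table of a structure
#'
#' One row per residue, in order of first atom appearance.
#'
#' @param x a ProteinStructure.
#' @return data.frame with key, chain, resno, insert, resname.
#' @export
residueTable <- function(x) {
  a <- atoms(x)
  key <- residueKey(a$chain, a$resno, a$insert)
  keep <- !duplicated(key)
  data.frame(key = key[keep], chain = a$chain[keep], resno = a$resno[keep],
             insert = a$insert[keep], resname = a$resname[keep],
             stringsAsFactors = FALSE)
}

#' Per-atom residue keys
#' @param x a ProteinStructure.
#' @export
atomResidueKeys <- function(x) {
  a <- atoms(x)
  residueKey(a$chain, a$resno, a$insert)
}

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  cat("ProteinStructure \"", object@id, "\": ", nrow(a), " atoms, ",
      nrow(residueTable(object)), " residues, chains: ",
      paste(unique(a$chain), collapse = ","), "\n", sep = "")
})

# ---- StructureEnsemble ------------------------------------------------------

#' StructureEnsemble: a reference plus ensemble members
#'
#' @slot reference the reference \linkS4class{ProteinStructure}.
#' @slot members list of member structures.
#' @slot labels per-member provenance strings.
#' @export
setClass("StructureEnsemble",
         slots = c(reference = "ProteinStructure", members = "list",
                   labels = "character"))

setValidity("StructureEnsemble", function(object) {
  if (!length(object@members)) return("members must be non-empty")
  if (!all(vapply(object@members, is, logical(1), class2 = "ProteinStructure")))
    return("all members must be ProteinStructure")
  if (length(object@labels) != length(object@members))
    return("labels length must match members")
  TRUE
})

#' @rdname StructureEnsemble-class
#' @param reference reference structure.
#' @param members list of member structures.
#' @param labels optional provenance labels (default: member ids).
#' @export
StructureEnsemble <- function(reference, members, labels = NULL) {
  if (is.null(labels)) labels <- vapply(members, function(m) m@id, character(1))
  new("StructureEnsemble", reference = reference, members = members, labels = labels)
}

#' @export
setGeneric("nMembers", function(x) standardGeneric("nMembers"))
#' @describeIn StructureEnsemble number of members
#' @param x a StructureEnsemble.
#' @export
setMethod("nMembers", "StructureEnsemble", function(x) length(x@members))

#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @describeIn StructureEnsemble member list accessor
#' @export
setMethod("members", "StructureEnsemble", function(x) x@members)

#' @export
setGeneric("referenceStructure", function(x) standardGeneric("referenceStructure"))
#' @describeIn StructureEnsemble reference accessor
#' @export
setMethod("referenceStructure", "StructureEnsemble", function(x) x@reference)

setMethod("show", "StructureEnsemble", function(object) {
  cat("StructureEnsemble: reference \"", object@reference@id, "\" + ",
      length(object@members), " members\n", sep = "")
})

# ---- BindingSite ------------------------------------------------------------

#' BindingSite: centre, radius and resolved site residues
#'
#' @slot center 3-vector, Angstrom.
#' @slot radius inclusion radius, Angstrom.
#' @slot residues residue table rows of the reference that belong to the site.
#' @slot source "ligand" or "point".
#' @export
setClass("BindingSite",
         slots = c(center = "numeric", radius = "numeric",
                   residues = "data.frame", source = "character"))

setValidity("BindingSite", function(object) {
  if (length(object@center) != 3L || !all(is.finite(object@center)))
    return("center must be a finite 3-vector")
  if (object@radius <= 0) return("radius must be positive")
  if (!nrow(object@residues)) return("site has no residues")
  TRUE
})

#' @export
setGeneric("siteResidues", function(x) standardGeneric("siteResidues"))
#' @describeIn BindingSite site residue table accessor
#' @param x a BindingSite.
#' @export
setMethod("siteResidues", "BindingSite", function(x) x@residues)

#' @export
setGeneric("siteCenter", function(x) standardGeneric("siteCenter"))
#' @describeIn BindingSite site centre accessor
#' @export
setMethod("siteCenter", "BindingSite", function(x) x@center)

#' @export
setGeneric("siteRadius", function(x) standardGeneric("siteRadius"))
#' @describeIn BindingSite inclusion radius accessor
#' @export
setMethod("siteRadius", "BindingSite", function(x) x@radius)

setMethod("show", "BindingSite", function(object) {
  cat(sprintf("BindingSite (%s): center (%.2f, %.2f, %.2f), radius %.1f A, %d residues\n",
              object@source, object@center[1], object@center[2], object@center[3],
              object@radius, nrow(object@residues)))
})

# ---- ResidueMapping ---------------------------------------------------------

#' ResidueMapping: reference-to-member site residue correspondence
#'
#' Built from a global sequence alignment so homologues with gaps, insertions
#' or mutations remain comparable. Unmapped reference residues carry
#' \code{NA} member keys.
#'
#' @slot pairs data.frame with ref_key, member_key (NA = unmapped),
#'   ref_resname, member_resname, mutated.
#' @slot identity alignment identity fraction in [0, 1].
#' @export
setClass("ResidueMapping", slots = c(pairs = "data.frame", identity = "numeric"))

setValidity("ResidueMapping", function(object) {
  p <- object@pairs
  if (anyDuplicated(p$ref_key)) return("reference keys must be unique")
  mk <- p$member_key[!is.na(p$member_key)]
  if (anyDuplicated(mk)) return("mapping must be injective over mapped keys")
  TRUE
})

#' @export
setGeneric("mappingPairs", function(x) standardGeneric("mappingPairs"))
#' @describeIn ResidueMapping pair table accessor
#' @param x a ResidueMapping.
#' @export
setMethod("mappingPairs", "ResidueMapping", function(x) x@pairs)

setMethod("show", "ResidueMapping", function(object) {
  p <- object@pairs
  cat(sprintf("ResidueMapping: %d/%d residues mapped (%d mutated), identity %.2f\n",
              sum(!is.na(p$member_key)), nrow(p), sum(p$mutated, na.rm = TRUE),
              object@identity))
})

# ---- RigidTransform ---------------------------------------------------------

#' RigidTransform: proper rotation plus translation
#'
#' @slot rotation 3 x 3 orthonormal matrix with determinant +1.
#' @slot translation 3-vector, Angstrom.
#' @export
setClass("RigidTransform", slots = c(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) return("rotation not orthonormal")
  if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det = +1)")
  if (length(object@translation) != 3L) return("translation must be a 3-vector")
  TRUE
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform: translation (",
      paste(sprintf("%.3f", object@translation), collapse = ", "), ")\n", sep = "")
})

# ---- Grid3D / PocketGrid ----------------------------------------------------

#' Grid3D: axis-aligned regular scalar grid
#'
#' Point \code{(i, j, k)} (0-based) sits at
#' \code{origin + spacing * c(i, j, k)}.
#'
#' @slot origin 3-vector, Angstrom.
#' @slot spacing isotropic spacing, Angstrom.
#' @slot dims integer 3-vector (nx, ny, nz).
#' @slot values array of dimension dims (numeric or logical).
#' @export
setClass("Grid3D", slots = c(origin = "numeric", spacing = "numeric",
                             dims = "integer", values = "array"))

setValidity("Grid3D", function(object) {
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    return("origin must be a finite 3-vector")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    return("spacing must be a positive scalar")
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be three positive integers")
  if (!identical(dim(object@values), as.integer(object@dims)))
    return("values dimension does not match dims")
  TRUE
})

#' @rdname Grid3D-class
#' @param origin,spacing,dims grid geometry.
#' @param values optional array (default all-zero numeric).
#' @export
Grid3D <- function(origin, spacing, dims, values = NULL) {
  dims <- as.integer(dims)
  if (is.null(values)) values <- array(0, dim = dims)
  if (is.null(dim(values))) dim(values) <- dims
  new("Grid3D", origin = as.numeric(origin), spacing = as.numeric(spacing),
      dims = dims, values = values)
}

#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @describeIn Grid3D values accessor
#' @param x a Grid3D.
#' @export
setMethod("gridValues", "Grid3D", function(x) x@values)

#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @describeIn Grid3D origin accessor
#' @export
setMethod("gridOrigin", "Grid3D", function(x) x@origin)

#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @describeIn Grid3D spacing accessor
#' @export
setMethod("gridSpacing", "Grid3D", function(x) x@spacing)

#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
#' @describeIn Grid3D dims accessor
#' @export
setMethod("gridDims", "Grid3D", function(x) x@dims)

#' Cartesian coordinates of every grid point
#' @param grid a Grid3D.
#' @return (nx*ny*nz) x 3 matrix in array (x-fastest) linear order.
#' @export
gridPointCoords <- function(grid) {
  d <- grid@dims
  ijk <- arrayInd(seq_len(prod(d)), d) - 1L
  sweep(ijk * grid@spacing, 2, grid@origin, "+")
}

setMethod("show", "Grid3D", function(object) {
  cat(sprintf("Grid3D: %d x %d x %d, spacing %.2f A, origin (%.2f, %.2f, %.2f)\n",
              object@dims[1], object@dims[2], object@dims[3], object@spacing,
              object@origin[1], object@origin[2], object@origin[3]))
})

#' PocketGrid: boolean pocket occupancy for one structure
#'
#' @slot structureId id of the structure the pocket was detected in.
#' @export
setClass("PocketGrid", contains = "Grid3D", slots = c(structureId = "character"))

setValidity("PocketGrid", function(object) {
  if (!is.logical(object@values)) return("PocketGrid values must be logical")
  TRUE
})

setMethod("show", "PocketGrid", function(object) {
  cat(sprintf("PocketGrid (%s): %d pocket points of %d (volume %.1f A^3)\n",
              object@structureId, sum(object@values), prod(object@dims),
              sum(object@values) * object@spacing^3))
})

# ---- PocketStats ------------------------------------------------------------

#' PocketStats: geometric and physicochemical pocket descriptors
#'
#' @slot structureId structure id.
#' @slot volume pocket volume, Angstrom^3 (point count times spacing^3).
#' @slot surfaceArea exposed face area, Angstrom^2.
#' @slot liningResidues residue keys lining the pocket.
#' @slot propertyCounts grid-point counts per physicochemical property.
#' @export
setClass("PocketStats",
         slots = c(structureId = "character", volume = "numeric",
                   surfaceArea = "numeric", liningResidues = "character",
                   propertyCounts = "integer"))

#' @export
setGeneric("pocketVolume", function(x) standardGeneric("pocketVolume"))
#' @describeIn PocketStats volume accessor
#' @param x a PocketStats.
#' @export
setMethod("pocketVolume", "PocketStats", function(x) x@volume)

#' @export
setGeneric("surfaceArea", function(x) standardGeneric("surfaceArea"))
#' @describeIn PocketStats surface-area accessor
#' @export
setMethod("surfaceArea", "PocketStats", function(x) x@surfaceArea)

#' @export
setGeneric("liningResidues", function(x) standardGeneric("liningResidues"))
#' @describeIn PocketStats lining-residue accessor
#' @export
setMethod("liningResidues", "PocketStats", function(x) x@liningResidues)

setMethod("show", "PocketStats", function(object) {
  cat(sprintf("PocketStats (%s): volume %.1f A^3, surface %.1f A^2, %d lining residues\n",
              object@structureId, object@volume, object@surfaceArea,
              length(object@liningResidues)))
})

# ---- ClusteringResult -------------------------------------------------------

#' ClusteringResult: cluster labels and medoid representatives
#'
#' @slot labels 0-based cluster label per ensemble member.
#' @slot representatives one member index (1-based) per cluster, the medoid.
#' @slot method "single_linkage" or "kmeans".
#' @slot threshold RMSD threshold, Angstrom.
#' @slot seed integer seed (length 0 when not applicable).
#' @slot converged FALSE when threshold-driven k-means exhausted max_k.
#' @export
setClass("ClusteringResult",
         slots = c(labels = "integer", representatives = "integer",
                   method = "character", threshold = "numeric",
                   seed = "integer", converged = "logical"))

setValidity("ClusteringResult", function(object) {
  k <- max(object@labels) + 1L
  if (length(object@representatives) != k)
    return("one representative required per cluster")
  if (!all(sort(unique(object@labels)) == seq_len(k) - 1L))
    return("labels must be consecutive 0-based integers")
  for (c in seq_len(k) - 1L)
    if (object@labels[object@representatives[c + 1L]] != c)
      return("representative must belong to its cluster")
  TRUE
})

#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @describeIn ClusteringResult label accessor
#' @param x a ClusteringResult.
#' @export
setMethod("clusterLabels", "ClusteringResult", function(x) x@labels)

#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
#' @describeIn ClusteringResult representative accessor
#' @export
setMethod("representatives", "ClusteringResult", function(x) x@representatives)

#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @describeIn ClusteringResult number of clusters
#' @export
setMethod("nClusters", "ClusteringResult", function(x) max(x@labels) + 1L)

setMethod("show", "ClusteringResult", function(object) {
  cat(sprintf("ClusteringResult (%s, threshold %.2f A): %d members in %d clusters\n",
              object@method, object@threshold, length(object@labels),
              max(object@labels) + 1L))
})

# ---- SubPocketSet -----------------------------------------------------------

#' SubPocketSet: compact connected sub-regions of a pocket region
#'
#' @slot grid Grid3D of integer labels (0 = background, 1..n = sub-pockets,
#'   ordered by decreasing size).
#' @slot table one row per sub-pocket: label, size, centroid coordinates.
#' @export
setClass("SubPocketSet", slots = c(grid = "Grid3D", table = "data.frame"))

#' @export
setGeneric("subPocketTable", function(x) standardGeneric("subPocketTable"))
#' @describeIn SubPocketSet summary table accessor
#' @param x a SubPocketSet.
#' @export
setMethod("subPocketTable", "SubPocketSet", function(x) x@table)

#' Grid-point indices of one sub-pocket
#' @param x a SubPocketSet.
#' @param label sub-pocket label.
#' @return integer vector of linear grid indices.
#' @export
subPocketPoints <- function(x, label) which(gridValues(x@grid) == label)

setMethod("show", "SubPocketSet", function(object) {
  cat(sprintf("SubPocketSet: %d sub-pockets (sizes %s)\n", nrow(object@table),
              paste(object@table$size, collapse = ", ")))
})

# ---- ConservationProfile ----------------------------------------------------

#' ConservationProfile: per-column conservation mapped to residues
#'
#' @slot raw per-column Jensen-Shannon scores in [0, 1] (or absolute
#'   differences for the differential mode).
#' @slot rescaled per-column scores rescaled to [30, 70].
#' @slot residueScores named numeric: rescaled score per reference residue key
#'   (empty until mapped onto a structure).
#' @slot mode "conservation" or "differential".
#' @export
setClass("ConservationProfile",
         slots = c(raw = "numeric", rescaled = "numeric",
                   residueScores = "numeric", mode = "character"))

setValidity("ConservationProfile", function(object) {
  if (length(object@raw) != length(object@rescaled))
    return("raw and rescaled must have equal length")
  if (length(object@rescaled) &&
      (min(object@rescaled) < 30 - 1e-9 || max(object@rescaled) > 70 + 1e-9))
    return("rescaled scores must lie in [30, 70]")
  if (!object@mode %in% c("conservation", "differential"))
    return("mode must be 'conservation' or 'differential'")
  TRUE
})

#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))
#' @describeIn ConservationProfile raw column scores
#' @param x a ConservationProfile.
#' @export
setMethod("rawScores", "ConservationProfile", function(x) x@raw)

#' @export
setGeneric("rescaledScores", function(x) standardGeneric("rescaledScores"))
#' @describeIn ConservationProfile rescaled column scores
#' @export
setMethod("rescaledScores", "ConservationProfile", function(x) x@rescaled)

#' @export
setGeneric("residueScores", function(x) standardGeneric("residueScores"))
#' @describeIn ConservationProfile per-residue rescaled scores
#' @export
setMethod("residueScores", "ConservationProfile", function(x) x@residueScores)

setMethod("show", "ConservationProfile", function(object) {
  cat(sprintf("ConservationProfile (%s): %d columns, %d residues mapped\n",
              object@mode, length(object@raw), length(object@residueScores)))
})
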