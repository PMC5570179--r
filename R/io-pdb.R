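#' Read a PDB file into ProteinStructure objects
#'
#' Parses ATOM and HETATM records (via bio3d), resolving alternate locations
#' to a single conformer: the highest-occupancy copy is kept, ties going to
#' the alphabetically first altLoc. Multi-model files (trajectory snapshots
#' exported as MODEL blocks) yield one structure per model when
#' \code{modelPolicy = "all"}.
#'
#' @param path PDB file path.
#' @param modelPolicy \code{"first"} (default) or \code{"all"}.
#' @param id structure id; default the file name without extension.
#' @return list of \linkS4class{ProteinStructure} (length 1 for
#'   \code{modelPolicy = "first"}).
#' @export
readPdb <- function(path, modelPolicy = c("first", "all"), id = NULL) {
  modelPolicy <- match.arg(modelPolicy)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L)
    stop("no ATOM/HETATM records in '", path, "'")
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))

  # altLoc resolution: keep highest occupancy, ties -> alphabetically first
  alt <- a$alt; alt[is.na(alt)] <- ""
  occ <- a$o; occ[is.na(occ)] <- 1
  grp <- paste(a$chain, a$resno, a$insert, a$resid, a$elety, sep = "\r")
  ord <- order(grp, -occ, alt)
  keep <- ord[!duplicated(grp[ord])]
  keep <- sort(keep)

  elem <- a$elesy
  elem[is.na(elem) | trimws(elem) == ""] <- ""
  elem <- trimws(elem)
  blank <- elem == ""
  if (any(blank)) elem[blank] <- inferElement(a$elety[blank])

  ins <- a$insert
  ins[is.na(ins)] <- ""

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nModels <- nrow(xyz)
  sel <- if (modelPolicy == "first") 1L else seq_len(nModels)

  xyzCols <- bio3d::atom2xyz(keep)
  lapply(sel, function(m) {
    crd <- matrix(xyz[m, xyzCols], ncol = 3, byrow = TRUE)
    at <- data.frame(serial = a$eleno[keep], name = a$elety[keep],
                     element = elem[keep], resname = a$resid[keep],
                     chain = a$chain[keep], resno = a$resno[keep],
                     insert = ins[keep], x = crd[, 1], y = crd[, 2],
                     z = crd[, 3], occ = occ[keep],
                     b = ifelse(is.na(a$b[keep]), 0, a$b[keep]),
                     hetero = a$type[keep] == "HETATM",
                     stringsAsFactors = FALSE)
    sid <- if (nModels > 1L && modelPolicy == "all") sprintf("%s_m%d", id, m) else id
    ProteinStructure(sid, at)
  })
}

.formatAtomName <- function(name, element) {
  ifelse(nchar(name) >= 4L | nchar(element) >= 2L, name, paste0(" ", name))
}

.pdbRecord <- function(a) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(a$hetero, "HETATM", "ATOM"),
          a$serial %% 100000L, .formatAtomName(a$name, a$element), "",
          a$resname, a$chain, a$resno, ifelse(a$insert == "", " ", a$insert),
          a$x, a$y, a$z, a$occ, a$b, toupper(a$element))
}

#' Write ProteinStructure(s) to a PDB file
#'
#' A list of structures is written as a multi-model file (MODEL/ENDMDL
#' blocks); a single structure as a plain coordinate file. Coordinates are
#' truncated to the fixed-width PDB precision of 3 decimals.
#'
#' @param x a \linkS4class{ProteinStructure} or list thereof.
#' @param path output file path.
#' @param bfactor optional named numeric (residue key -> value) written into
#'   the B-factor column, e.g. rescaled conservation scores for viewers.
#' @return invisibly, \code{path}.
#' @export
writePdb <- function(x, path, bfactor = NULL) {
  if (is(x, "ProteinStructure")) x <- list(x)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(x) > 1L
  for (m in seq_along(x)) {
    a <- atoms(x[[m]])
    if (!is.null(bfactor)) {
      key <- residueKey(a$chain, a$resno, a$insert)
      hit <- key %in% names(bfactor)
      a$b[hit] <- bfactor[key[hit]]
    }
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(.pdbRecord(a), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Split a structure into single-chain structures
#'
#' HETATM records are dropped; chains left with no ATOM records (e.g. a
#' ligand-only chain) are omitted. Output ids are \code{"<id>_<chain>"}.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @return list of single-chain structures.
#' @export
splitChains <- function(structure) {
  a <- atoms(structure)
  a <- a[!a$hetero, , drop = FALSE]
  chains <- unique(a$chain)
  out <- lapply(chains, function(ch) {
    sub <- a[a$chain == ch, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    ProteinStructure(paste0(structure@id, "_", ch), sub)
  })
  Filter(Negate(is.null), out)
}
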