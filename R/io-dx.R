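#' Write a Grid3D as an OpenDX scalar grid
#'
#' Emits the "object 1 class gridpositions" dialect used by most molecular
#' viewers. Per DX convention the last (z) index varies fastest in the data
#' stream. Values are written with 17 significant digits so a read/write
#' round trip is value-faithful.
#'
#' @param grid a \linkS4class{Grid3D} (logical values are written as 0/1).
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeDxGrid <- function(grid, path) {
  d <- grid@dims
  o <- grid@origin
  s <- grid@spacing
  v <- as.numeric(aperm(grid@values * 1, c(3, 2, 1)))  # z fastest
  n <- length(v)
  hdr <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", o[1], o[2], o[3]),
    sprintf("delta %.6f 0 0", s),
    sprintf("delta 0 %.6f 0", s),
    sprintf("delta 0 0 %.6f", s),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n))
  vals <- formatC(v, digits = 17, format = "g")
  pad <- (3 - n %% 3) %% 3
  if (pad) vals <- c(vals, rep(NA_character_, pad))
  body <- apply(matrix(vals, ncol = 3, byrow = TRUE), 1,
                function(r) paste(r[!is.na(r)], collapse = " "))
  ftr <- c("attribute \"dep\" string \"positions\"",
           "object \"regular positions regular connections\" class field",
           "component \"positions\" value 1",
           "component \"connections\" value 2",
           "component \"data\" value 3")
  writeLines(c(hdr, body, ftr), path)
  invisible(path)
}

#' Read an OpenDX scalar grid written by \code{writeDxGrid}
#'
#' @param path DX file path.
#' @return a \linkS4class{Grid3D} with numeric values.
#' @export
readDxGrid <- function(path) {
  ln <- readLines(path)
  gp <- grep("class gridpositions counts", ln, value = TRUE)[1]
  if (is.na(gp)) stop("not an OpenDX gridpositions file: ", path)
  d <- as.integer(strsplit(trimws(sub(".*counts", "", gp)), "\\s+")[[1]])
  o <- as.numeric(strsplit(trimws(sub("origin", "", grep("^origin", ln, value = TRUE)[1])), "\\s+")[[1]])
  deltas <- grep("^delta", ln, value = TRUE)
  dmat <- t(vapply(deltas, function(x)
    as.numeric(strsplit(trimws(sub("delta", "", x)), "\\s+")[[1]]), numeric(3)))
  s <- max(dmat)
  if (max(abs(dmat - diag(s, 3))) > 1e-9)
    stop("only axis-aligned isotropic DX grids are supported")
  start <- grep("data follows", ln)[1] + 1L
  n <- prod(d)
  vals <- numeric(0)
  i <- start
  while (length(vals) < n && i <= length(ln)) {
    if (grepl("^[a-zA-Z]", trimws(ln[i]))) break
    vals <- c(vals, as.numeric(strsplit(trimws(ln[i]), "\\s+")[[1]]))
    i <- i + 1L
  }
  if (length(vals) != n)
    stop("DX data block has ", length(vals), " values, expected ", n)
  arr <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  Grid3D(origin = o, spacing = s, dims = d, values = arr)
}
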