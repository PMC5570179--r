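# Independent brute-force oracles. These deliberately re-derive each result
# with the most literal implementation possible (full distance scans,
# coordinate-space ray marching, direct entropy arithmetic) and share no
# code with the package internals they check.

# Brute-force cavity detection: full-distance protein mask, per-point ray
# marching in coordinate space, flood-fill component filter.
oracleDetectPocket <- function(structure, grid, site, probeRadius = 1.4,
                               minBuried = 5L, scanDepth = 10) {
  a <- heavyAtoms(structure)
  d <- gridDims(grid); o <- gridOrigin(grid); sp <- gridSpacing(grid)
  n <- prod(d)
  ijk <- arrayInd(seq_len(n), d)
  crd <- sweep((ijk - 1) * sp, 2, o, "+")
  radii <- vdwRadius(a$element) + probeRadius
  ac <- atomCoords(a)
  protein <- rep(FALSE, n)
  for (t in seq_len(nrow(a))) {
    d2 <- (crd[, 1] - ac[t, 1])^2 + (crd[, 2] - ac[t, 2])^2 +
          (crd[, 3] - ac[t, 3])^2
    protein <- protein | (d2 <= radii[t]^2)
  }
  ctr <- siteCenter(site)
  inSite <- (crd[, 1] - ctr[1])^2 + (crd[, 2] - ctr[2])^2 +
            (crd[, 3] - ctr[3])^2 <= siteRadius(site)^2
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  protArr <- array(protein, dim = d)
  buried <- rep(FALSE, n)
  for (p in which(!protein & inSite)) {
    cnt <- 0L
    for (r in seq_len(nrow(dirs))) {
      dir <- dirs[r, ]
      nSteps <- floor(scanDepth / (sp * sqrt(sum(dir^2))))
      hits <- c(FALSE, FALSE)
      for (sgn in 1:2) {
        for (s in seq_len(nSteps)) {
          q <- ijk[p, ] + c(1, -1)[sgn] * s * dir
          if (any(q < 1) || any(q > d)) next
          if (protArr[q[1], q[2], q[3]]) { hits[sgn] <- TRUE; break }
        }
      }
      if (all(hits)) cnt <- cnt + 1L
    }
    buried[p] <- cnt >= minBuried
  }
  # flood fill (26-connectivity), keep components touching the half sphere
  lab <- integer(n)
  cur <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  linOf <- function(q) q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
  for (p in which(buried)) {
    if (lab[p] > 0L) next
    cur <- cur + 1L
    queue <- p; lab[p] <- cur
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (r in seq_len(nrow(offs))) {
        q <- ijk[u, ] + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        v <- linOf(q)
        if (buried[v] && lab[v] == 0L) { lab[v] <- cur; queue <- c(queue, v) }
      }
    }
  }
  nearCtr <- (crd[, 1] - ctr[1])^2 + (crd[, 2] - ctr[2])^2 +
             (crd[, 3] - ctr[3])^2 <= (siteRadius(site) / 2)^2
  keep <- unique(lab[lab > 0L & nearCtr])
  array(lab %in% keep & lab > 0L, dim = d)
}

# Direct per-pair site RMSD by explicit atom pairing through residue keys.
oracleBackboneRmsd <- function(sa, sb, keys) {
  collect <- function(s) {
    at <- atoms(s)
    k <- residueKey(at$chain, at$resno, at$insert)
    sel <- k %in% keys & at$name %in% c("N", "CA", "C", "O")
    at <- at[sel, ]
    rownames(at) <- paste(residueKey(at$chain, at$resno, at$insert), at$name)
    at
  }
  aa <- collect(sa); bb <- collect(sb)
  common <- intersect(rownames(aa), rownames(bb))
  da <- as.matrix(aa[common, c("x", "y", "z")])
  db <- as.matrix(bb[common, c("x", "y", "z")])
  sqrt(mean(rowSums((da - db)^2)))
}

# Direct Jensen-Shannon score of a column: literal entropy arithmetic.
oracleJsd <- function(column, background, pseudocount = 1e-7) {
  aaOrder <- names(background)
  gaps <- column %in% c("-", ".", "X")
  if (all(gaps)) return(0)
  p <- numeric(length(aaOrder)); names(p) <- aaOrder
  for (x in column[!gaps]) p[x] <- p[x] + 1
  p <- p + pseudocount
  p <- p / sum(p)
  q <- background / sum(background)
  m <- (p + q) / 2
  H <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  (H(m) - (H(p) + H(q)) / 2) * (1 - mean(gaps))
}
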