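# Shared fixtures, computed lazily and cached so expensive objects (shell
# detection, superposed ensembles) are built once per test run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

shellRef <- function() fixture("shellRef", makeShellStructure(6, 3, id = "reference"))
shellSiteFx <- function() fixture("shellSite", shellSite(shellRef(), 6, 3))
shellGrid <- function() fixture("shellGrid", buildPocketGrid(shellSiteFx(), 2, 1))
shellRefPocket <- function() fixture("shellRefPocket",
  detectPocket(shellRef(), shellGrid(), shellSiteFx()))

# 10-member ensemble with the sub-pocket planted open in 60% of members,
# superposed, with per-member pockets -- reused across transient tests.
plantedRun <- function() fixture("plantedRun", {
  toy <- makeToyEnsemble(nMembers = 10, subpocketOpenFraction = 0.6, seed = 3)
  sup <- suppressWarnings(superposeEnsemble(toy$ensemble, shellSiteFx()))
  pockets <- lapply(members(sup$ensemble), detectPocket,
                    grid = shellGrid(), site = shellSiteFx())
  list(toy = toy, sup = sup, pockets = pockets,
       freq = frequencyGrid(pockets))
})

# Pocket of the clean open-state structure in the analysis frame (the
# planted ground-truth mask lives in the superposed frame, because the
# backbone fit of an open member carries a small systematic residual from
# the displaced patch).
plantedMask <- function() fixture("plantedMask", {
  toyC <- makeToyEnsemble(nMembers = 1, subpocketOpenFraction = 1,
                          noiseSigma = 0, rigidJitter = FALSE, seed = 3)
  openClean <- members(toyC$ensemble)[[1]]
  mp <- mapSiteResidues(shellSiteFx(), shellRef(), openClean)
  fitted <- superposeMember(openClean, shellRef(), shellSiteFx(), mp)$structure
  openP <- detectPocket(fitted, shellGrid(), shellSiteFx())
  gridValues(openP) & !gridValues(shellRefPocket())
})

# Small chain builder: one residue per letter, CA spaced 3.8 A along x,
# using the alanine backbone template but arbitrary residue names. Gives
# structures with distinctive sequences for alignment tests.
makeChainStructure <- function(letters1, id = "chain", chain = "A",
                               resnoStart = 1L, yOffset = 0) {
  template <- rbind(N  = c(-1.458, 0.5, 0), CA = c(0, 0, 0),
                    C  = c(0.551, 1.417, 0), O = c(1.772, 1.563, 0),
                    CB = c(0.540, -0.770, -1.200))
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  letters1 <- strsplit(letters1, "")[[1]]
  rows <- lapply(seq_along(letters1), function(i) {
    crd <- sweep(template, 2, c(3.8 * (i - 1), yOffset, 0), "+")
    data.frame(name = rownames(template), element = c("N", "C", "C", "O", "C"),
               resname = aa3[[letters1[i]]], chain = chain,
               resno = resnoStart + i - 1L,
               x = crd[, 1], y = crd[, 2], z = crd[, 3],
               stringsAsFactors = FALSE)
  })
  ProteinStructure(id, do.call(rbind, rows))
}

# Rand index between two labelings.
randIndex <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# A random proper rotation matrix.
randomRotationMatrix <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3))) -> Q
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
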