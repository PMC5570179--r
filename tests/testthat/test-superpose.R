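# Kabsch superposition and RMSD primitives.

test_that("kabsch recovers identity, pure translations and pure rotations", {
  set.seed(1)
  a <- matrix(rnorm(30), 10, 3)
  fit <- kabsch(a, a)
  expect_lt(as.numeric(fit$rmsd), 1e-12)
  expect_lt(max(abs(fit$transform@rotation - diag(3))), 1e-9)

  b <- sweep(a, 2, c(5, 5, 5), "+")
  expect_lt(as.numeric(kabsch(a, b)$rmsd), 1e-9)

  R <- randomRotationMatrix()
  b <- a %*% t(R)
  fit <- kabsch(a, b)
  expect_lt(as.numeric(fit$rmsd), 1e-9)
  expect_lt(max(abs(fit$transform@rotation %*% R - diag(3))), 1e-6)
})

test_that("kabsch RMSD under a known rotation plus noise matches the
           explicit residual", {
  set.seed(2)
  a <- matrix(rnorm(45), 15, 3)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)  # 90 deg z
  noise <- matrix(rnorm(45, sd = 0.05), 15, 3)
  b <- (a + noise) %*% t(Rz)
  fit <- kabsch(a, b)
  # residual after undoing the known rotation, an upper bound the fit
  # cannot exceed and (for small noise) nearly attains
  resid <- sqrt(mean(rowSums((b %*% Rz - a)^2)))
  expect_lte(as.numeric(fit$rmsd), resid + 1e-12)
  expect_gt(as.numeric(fit$rmsd), 0.8 * resid)
})

test_that("kabsch rejects short inputs, flags collinear sets, enforces
           proper rotations", {
  a <- matrix(rnorm(6), 2, 3)
  expect_error(kabsch(a, a), "insufficient")
  line <- cbind(1:5, 0, 0)
  fit <- kabsch(line, line)
  expect_true(attr(fit$rmsd, "degenerate"))
  # a reflected point set must still produce det(R) = +1
  set.seed(3)
  a <- matrix(rnorm(30), 10, 3)
  b <- a; b[, 1] <- -b[, 1]
  fit <- kabsch(a, b)
  expect_equal(det(fit$transform@rotation), 1, tolerance = 1e-9)
})

test_that("kabsch result is invariant under a common rigid transform", {
  set.seed(4)
  a <- matrix(rnorm(30), 10, 3)
  b <- a + matrix(rnorm(30, sd = 0.3), 10, 3)
  base <- as.numeric(kabsch(a, b)$rmsd)
  for (i in 1:5) {
    R <- randomRotationMatrix(); t <- rnorm(3, sd = 10)
    a2 <- sweep(a %*% t(R), 2, t, "+")
    b2 <- sweep(b %*% t(R), 2, t, "+")
    expect_equal(as.numeric(kabsch(a2, b2)$rmsd), base, tolerance = 1e-9)
  }
})

test_that("a rigidly displaced member superposes to RMSD ~ 0 and refitting
           is idempotent", {
  ref <- shellRef()
  site <- shellSiteFx()
  R <- randomRotationMatrix()
  tr <- new("RigidTransform", rotation = R, translation = c(3, -7, 2))
  mem <- applyTransform(ref, tr)
  mem@id <- "moved"
  mp <- mapSiteResidues(site, ref, mem)
  fit <- superposeMember(mem, ref, site, mp)
  expect_lt(fit$rmsd, 1e-6)
  refit <- superposeMember(fit$structure, ref, site, mp)
  expect_lt(max(abs(refit$transform@rotation - diag(3))), 1e-9)
  expect_lt(max(abs(refit$transform@translation)), 1e-9)
})

test_that("side-chain-only motion leaves backbone RMSD at zero but moves the
           side-chain-centre metric", {
  ref <- makeChainStructure("ACDEFGHIKL")
  a <- atoms(ref)
  a$x[a$name == "CB" & a$resno == 5] <- a$x[a$name == "CB" & a$resno == 5] + 2
  mem <- ProteinStructure("rot", a)
  site <- defineSiteFromPoint(ref, c(3.8 * 4, 0, 0), radius = 6)
  mp <- mapSiteResidues(site, ref, mem)
  expect_equal(siteRmsd(mem, ref, site, mp, "backbone"), 0)
  expect_gt(siteRmsd(mem, ref, site, mp, "sidechain_center"), 0)
})

test_that("site RMSD matches the closed-form value for scripted displacements", {
  ref <- makeChainStructure("ACDEFGHIKL")
  site <- defineSiteFromPoint(ref, c(3.8 * 4.5, 0, 0), radius = 30)  # all 10
  K <- nrow(siteResidues(site))
  expect_equal(K, 10L)
  # one residue's 4 backbone atoms displaced 1 A along x:
  # pooled backbone RMSD = sqrt(4 * 1 / (4K)) = 1 / sqrt(K)
  a <- atoms(ref)
  move <- a$resno == 3 & a$name %in% c("N", "CA", "C", "O")
  a$x[move] <- a$x[move] + 1
  mem <- ProteinStructure("d", a)
  mp <- mapSiteResidues(site, ref, mem)
  expect_equal(siteRmsd(mem, ref, site, mp, "backbone"), 1 / sqrt(K),
               tolerance = 1e-12)
  # single-residue site, 4 backbone atoms each displaced 2 A -> RMSD 2
  one <- defineSiteFromPoint(ref, atomCoords(ref)[atoms(ref)$name == "CA", ][3, ],
                             radius = 0.1)
  a2 <- atoms(ref)
  move2 <- a2$resno == 3 & a2$name %in% c("N", "CA", "C", "O")
  a2$z[move2] <- a2$z[move2] + 2
  mem2 <- ProteinStructure("d2", a2)
  mp2 <- mapSiteResidues(one, ref, mem2)
  expect_equal(siteRmsd(mem2, ref, one, mp2, "backbone"), 2, tolerance = 1e-12)
  # glycine under sidechain_center uses its backbone atoms
  gly <- makeChainStructure("ACGEF")
  gsite <- defineSiteFromPoint(gly, c(7.6, 0, 0), radius = 2)
  gmp <- mapSiteResidues(gsite, gly, gly)
  expect_equal(siteRmsd(gly, gly, gsite, gmp, "sidechain_center"), 0)
})

test_that("ensemble RMSD statistics agree with a brute-force recomputation", {
  ref <- makeChainStructure("ACDEFGHIKL")
  site <- defineSiteFromPoint(ref, c(3.8 * 4.5, 0, 0), radius = 30)
  keys <- siteResidues(site)$key
  mems <- lapply(1:3, function(i) {
    a <- atoms(ref)
    sel <- a$resno == i + 2   # a different flexible residue per member
    a$y[sel] <- a$y[sel] + i
    ProteinStructure(paste0("m", i), a)
  })
  ens <- StructureEnsemble(ref, mems)
  sup <- superposeEnsemble(ens, site)
  st <- rmsdStats(sup, site, "backbone")
  expect_true(isSymmetric(st$matrix))
  expect_equal(unname(diag(st$matrix)), rep(0, 3))
  for (i in 1:3) for (j in 1:3) if (i != j)
    expect_equal(st$matrix[i, j],
                 oracleBackboneRmsd(members(sup$ensemble)[[i]],
                                    members(sup$ensemble)[[j]], keys),
                 tolerance = 1e-9)
  # locality: the displaced residues dominate the per-residue maxima (the
  # refit spreads a small residual over the untouched residues)
  ord <- names(sort(st$perResidueMax, decreasing = TRUE))
  expect_setequal(ord[1:3], c("A:3", "A:4", "A:5"))
  others <- st$perResidueMax[!names(st$perResidueMax) %in% ord[1:3]]
  expect_lt(max(others), 0.5 * min(st$perResidueMax[ord[1:3]]))
})

test_that("an ensemble of identical copies yields all-zero statistics", {
  ref <- makeChainStructure("ACDEFGHIKL")
  site <- defineSiteFromPoint(ref, c(19, 0, 0), radius = 30)
  ens <- StructureEnsemble(ref, lapply(1:3, function(i) {
    s <- ref; s@id <- paste0("c", i); s
  }))
  st <- rmsdStats(superposeEnsemble(ens, site), site, "backbone")
  expect_equal(max(abs(st$matrix)), 0, tolerance = 1e-9)
  expect_equal(max(st$perMemberMean), 0, tolerance = 1e-9)
  expect_equal(max(st$perResidueMax), 0, tolerance = 1e-9)
})
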