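# Grid construction, cavity detection and pocket statistics.

test_that("the analysis grid covers the site sphere plus margin and is
           centre-snapped", {
  s <- makeChainStructure("ACDEF")
  site <- defineSiteFromPoint(s, c(7.6, 0, 0), radius = 5)
  g <- buildPocketGrid(site, margin = 2, spacing = 1)
  expect_identical(gridDims(g), rep(15L, 3))      # 2 * (5 + 2) / 1 + 1
  # the centre lies exactly on a grid point
  rel <- (siteCenter(site) - gridOrigin(g)) / gridSpacing(g)
  expect_equal(rel, round(rel), tolerance = 1e-12)
  expect_error(buildPocketGrid(site, 2, 0.1), "spacing")
  g2 <- buildPocketGrid(site, margin = 2, spacing = 1)
  expect_identical(g, g2)                          # determinism
})

test_that("cavity detection matches the brute-force oracle bit for bit on a
           noisy shell", {
  toy <- makeToyEnsemble(nMembers = 2, hollowRadius = 3, noiseSigma = 0.2,
                         rigidJitter = FALSE, seed = 11)
  ref <- referenceStructure(toy$ensemble)
  site <- defineSiteFromPoint(ref, c(0, 0, 0), radius = 8)
  g <- buildPocketGrid(site, 2, 1)
  for (s in c(list(ref), members(toy$ensemble))) {
    p <- detectPocket(s, g, site)
    expect_identical(gridValues(p), oracleDetectPocket(s, g, site))
  }
  expect_gt(sum(gridValues(detectPocket(ref, g, site))), 0)
})

test_that("removing a wall patch destroys burial near the opening", {
  ref <- makeShellStructure(4, 3)
  site <- defineSiteFromPoint(ref, c(0, 0, 0), radius = 9)
  g <- buildPocketGrid(site, 2, 1)
  closed <- gridValues(detectPocket(ref, g, site))
  # remove the entire upper-hemisphere wall: rays from upper cavity points
  # now escape in most directions, so burial collapses there
  a <- atoms(ref)
  ctr <- do.call(rbind, lapply(split(a[, c("x", "y", "z")], a$resno), colMeans))
  drop <- as.integer(rownames(ctr)[ctr[, 3] > 0.5])
  open <- ProteinStructure("open", a[!a$resno %in% drop, ])
  openP <- gridValues(detectPocket(open, g, site))
  # oracle equivalence holds on the opened structure too
  expect_identical(openP, oracleDetectPocket(open, g, site))
  # cavity points towards the opening lose burial; the pocket there shrinks
  d <- gridDims(g)
  crd <- gridPointCoords(g)
  upper <- array(crd[, 3] > 1, d)
  expect_lt(sum(openP & upper), sum(closed & upper))
  expect_gt(sum(closed & !openP), 0)
  expect_lt(sum(openP), sum(closed))
})

test_that("no heavy atoms raises an error and a zero hollow yields no pocket", {
  g <- Grid3D(c(-5, -5, -5), 1, c(11, 11, 11))
  s <- ProteinStructure("h", data.frame(
    name = "H1", element = "H", resname = "ALA", chain = "A", resno = 1L,
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
  site <- list()
  flat <- makeShellStructure(0, 3)
  fsite <- defineSiteFromPoint(flat, c(0, 0, 0), radius = 6)
  fg <- buildPocketGrid(fsite, 2, 1)
  expect_error(detectPocket(s, fg, fsite), "no heavy atoms")
  expect_equal(sum(gridValues(detectPocket(flat, fg, fsite))), 0L)
})

test_that("detection is invariant to translation by whole grid spacings", {
  ref <- makeShellStructure(4, 3)
  site <- defineSiteFromPoint(ref, c(0, 0, 0), radius = 9)
  g <- buildPocketGrid(site, 2, 1)
  base <- detectPocket(ref, g, site)
  shift <- c(3, -2, 5)   # integer multiples of spacing 1
  a <- atoms(ref)
  a$x <- a$x + shift[1]; a$y <- a$y + shift[2]; a$z <- a$z + shift[3]
  moved <- ProteinStructure("t", a)
  siteT <- defineSiteFromPoint(moved, shift, radius = 9)
  gT <- Grid3D(gridOrigin(g) + shift, gridSpacing(g), gridDims(g))
  expect_identical(gridValues(detectPocket(moved, gT, siteT)),
                   gridValues(base))
})

test_that("volume and surface follow the point-count formulas", {
  v <- array(FALSE, c(8, 8, 8))
  v[3:6, 3:6, 3:6] <- TRUE                       # 4^3 block
  pg <- new("PocketGrid", origin = c(0, 0, 0), spacing = 0.5,
            dims = c(8L, 8L, 8L), values = v, structureId = "cube")
  empty <- ProteinStructure("far", data.frame(
    name = "CA", element = "C", resname = "ALA", chain = "A", resno = 1L,
    x = 100, y = 100, z = 100, stringsAsFactors = FALSE))
  st <- pocketStats(pg, empty)
  expect_equal(pocketVolume(st), 64 * 0.5^3)
  expect_equal(surfaceArea(st), 6 * 16 * 0.5^2)  # isolated cube: 6 faces
  expect_length(liningResidues(st), 0)
  # empty pocket
  pg0 <- new("PocketGrid", origin = c(0, 0, 0), spacing = 1,
             dims = c(4L, 4L, 4L), values = array(FALSE, c(4, 4, 4)),
             structureId = "none")
  st0 <- pocketStats(pg0, empty)
  expect_equal(pocketVolume(st0), 0)
  expect_equal(surfaceArea(st0), 0)
})

test_that("an inserted Asp side chain is typed negative/acceptor and lines
           the pocket", {
  ref <- shellRef()
  site <- shellSiteFx()
  g <- shellGrid()
  p <- shellRefPocket()
  # place an ASP with carboxylate oxygens just inside the cavity wall
  asp <- data.frame(
    name = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
    element = c("N", "C", "C", "O", "C", "C", "O", "O"),
    resname = "ASP", chain = "B", resno = 999L,
    x = c(10.2, 9.5, 10.0, 10.8, 8.4, 7.6, 6.9, 7.6),
    y = 0, z = c(0.8, 0, -1.2, -1.5, 0.6, -0.2, 0.6, -1.4),
    stringsAsFactors = FALSE)
  withAsp <- ProteinStructure("asp", rbind(atoms(ref),
                                           atoms(ProteinStructure("a", asp))))
  st <- pocketStats(p, withAsp, contactDistance = 4)
  expect_true("B:999" %in% liningResidues(st))
  expect_gt(st@propertyCounts[["negative"]], 0)
  expect_gt(st@propertyCounts[["acceptor"]], 0)
  # oracle: distance scan of OD1/OD2 against pocket points
  idx <- which(gridValues(p))
  pc <- sweep((arrayInd(idx, gridDims(p)) - 1) * gridSpacing(p), 2,
              gridOrigin(p), "+")
  od <- asp[asp$name %in% c("OD1", "OD2"), c("x", "y", "z")]
  nNeg <- sum(apply(pc, 1, function(q)
    any(sqrt(rowSums(sweep(as.matrix(od), 2, q)^2)) <= 4)))
  expect_equal(unname(st@propertyCounts[["negative"]]), nNeg)
})

test_that("lining residue fractions count members exactly", {
  mk <- function(keys) new("PocketStats", structureId = "x", volume = 1,
                           surfaceArea = 1, liningResidues = keys,
                           propertyCounts = integer(0))
  refSt <- mk(c("A:1", "A:2"))
  mems <- list(mk(c("A:1", "A:3")), mk(c("A:1", "A:3")), mk(c("A:1")),
               mk(c("A:1", "A:3")), mk(c("A:1")))
  tab <- liningResidueComparison(mems, refSt)
  expect_equal(tab$member_fraction[tab$key == "A:3"], 0.6)
  expect_equal(tab$flag[tab$key == "A:3"], "new")
  expect_equal(tab$flag[tab$key == "A:2"], "lost")
  expect_equal(tab$member_fraction[tab$key == "A:1"], 1)
  expect_equal(tab$flag[tab$key == "A:1"], "")
  same <- liningResidueComparison(list(refSt, refSt), refSt)
  expect_true(all(same$member_fraction == 1))
  expect_true(all(same$flag == ""))
})
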