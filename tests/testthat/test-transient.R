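# Frequency grids, appearing/disappearing regions, sub-pockets, opening
# profiles.

mkPocket <- function(mask, dims = dim(mask), id = "p") {
  new("PocketGrid", origin = c(0, 0, 0), spacing = 1,
      dims = as.integer(dims), values = mask, structureId = id)
}

test_that("frequency grids average boolean occupancy exactly", {
  d <- c(4L, 4L, 4L)
  m1 <- array(FALSE, d); m1[1, 1, 1] <- TRUE
  f1 <- frequencyGrid(list(mkPocket(m1)))
  expect_identical(gridValues(f1), m1 * 1)       # single member: its grid
  set.seed(7)
  stack <- lapply(1:8, function(i) mkPocket(array(runif(64) < 0.3, d)))
  f <- frequencyGrid(stack)
  manual <- Reduce(`+`, lapply(stack, function(p) p@values * 1)) / 8
  expect_identical(gridValues(f), manual)
  expect_true(all(gridValues(f) >= 0 & gridValues(f) <= 1))
  bad <- mkPocket(array(FALSE, c(3, 3, 3)))
  expect_error(frequencyGrid(list(stack[[1]], bad)), "share")
})

test_that("appearing/disappearing/conserved follow their threshold
           definitions and are disjoint", {
  d <- c(3L, 3L, 3L)
  ref <- array(FALSE, d); ref[1, 1, 1] <- TRUE; ref[2, 2, 2] <- TRUE
  # point (3,3,3): pocket in 3 of 4 members, absent in reference
  # point (1,1,1): reference pocket, closed in all members
  # point (2,2,2): reference pocket, open in all members
  mems <- lapply(1:4, function(i) {
    m <- array(FALSE, d)
    m[2, 2, 2] <- TRUE
    if (i <= 3) m[3, 3, 3] <- TRUE
    mkPocket(m)
  })
  freq <- frequencyGrid(mems)
  expect_equal(gridValues(freq)[3, 3, 3], 0.75)
  tr <- transientRegions(freq, mkPocket(ref), 0.25)
  expect_true(gridValues(tr$appearing)[3, 3, 3])
  expect_true(gridValues(tr$disappearing)[1, 1, 1])
  expect_false(gridValues(tr$disappearing)[2, 2, 2])
  expect_false(any(gridValues(tr$appearing) & gridValues(tr$disappearing)))
  expect_true(gridValues(tr$conserved)[2, 2, 2])
  tr8 <- transientRegions(freq, mkPocket(ref), 0.8)
  expect_false(gridValues(tr8$appearing)[3, 3, 3])   # 0.75 < 0.8
  expect_error(transientRegions(freq, mkPocket(ref), 0), "threshold")
  expect_error(transientRegions(freq, mkPocket(ref), 1.2), "threshold")
})

test_that("identical members and reference produce no transient regions", {
  pr <- shellRefPocket()
  freq <- frequencyGrid(list(pr, pr, pr))
  for (thr in c(0.25, 0.5)) {
    tr <- transientRegions(freq, pr, thr)
    expect_equal(sum(gridValues(tr$appearing)), 0L)
    expect_equal(sum(gridValues(tr$disappearing)), 0L)
  }
})

test_that("region thresholds are monotone: stricter thresholds keep fewer
           points", {
  run <- plantedRun()
  sizes <- vapply(c(0.25, 0.5, 0.75), function(thr)
    sum(gridValues(transientRegions(run$freq, shellRefPocket(), thr)$appearing)),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
  cons <- vapply(c(0.5, 0.7, 0.9), function(cf)
    sum(gridValues(transientRegions(run$freq, shellRefPocket(), 0.5,
                                    cf)$conserved)), numeric(1))
  expect_true(all(diff(cons) <= 0))
})

test_that("sub-pocket decomposition keeps 26-connected components above the
           size floor, ordered by size", {
  d <- c(10L, 10L, 10L)
  m <- array(FALSE, d)
  m[2:5, 2:5, 2:3] <- TRUE                    # blob of 32
  m[8:9, 8:9, 8:9] <- TRUE                    # blob of 8, separated
  g <- Grid3D(c(0, 0, 0), 1, d, m)
  sp <- splitSubpockets(g, minPoints = 10)
  expect_equal(nrow(subPocketTable(sp)), 1L)  # small blob dropped
  expect_equal(subPocketTable(sp)$size, 32L)
  sp2 <- splitSubpockets(g, minPoints = 5)
  expect_equal(subPocketTable(sp2)$size, c(32L, 8L))   # decreasing size
  # flood-fill recount oracle: each label holds exactly one planted blob
  blobA <- array(FALSE, d); blobA[2:5, 2:5, 2:3] <- TRUE
  blobB <- array(FALSE, d); blobB[8:9, 8:9, 8:9] <- TRUE
  expect_identical(sort(subPocketPoints(sp2, 1)), which(blobA))
  expect_identical(sort(subPocketPoints(sp2, 2)), which(blobB))
  empty <- splitSubpockets(Grid3D(c(0, 0, 0), 1, d, array(FALSE, d)), 5)
  expect_equal(nrow(subPocketTable(empty)), 0L)
  # single diagonal chain is one 26-connected component
  dg <- array(FALSE, c(5L, 5L, 5L))
  for (i in 1:5) dg[i, i, i] <- TRUE
  spd <- splitSubpockets(Grid3D(c(0, 0, 0), 1, c(5L, 5L, 5L), dg), 1)
  expect_equal(nrow(subPocketTable(spd)), 1L)
  expect_equal(subPocketTable(spd)$size, 5L)
})

test_that("opening profiles equal exact set-intersection fractions", {
  d <- c(6L, 6L, 6L)
  m <- array(FALSE, d); m[1:5, 1:4, 1] <- TRUE     # 20-point sub-pocket
  sp <- splitSubpockets(Grid3D(c(0, 0, 0), 1, d, m), 5)
  pts <- subPocketPoints(sp, 1)
  expect_length(pts, 20L)
  mems <- lapply(c(0, 5, 10, 15, 20), function(k) {
    mm <- array(FALSE, d)
    mm[pts[seq_len(k)]] <- TRUE
    mkPocket(mm, d)
  })
  expect_equal(openingSeries(sp, 1, mems), c(0, 0.25, 0.5, 0.75, 1))
  expect_error(openingSeries(sp, 2, mems), "empty")
})

test_that("the mean opening fraction equals the mean point frequency
           (consistency identity)", {
  run <- plantedRun()
  tr <- transientRegions(run$freq, shellRefPocket(), 0.5)
  sp <- splitSubpockets(tr$appearing, 5)
  expect_gt(nrow(subPocketTable(sp)), 0)
  pts <- subPocketPoints(sp, 1)
  os <- openingSeries(sp, 1, run$pockets)
  expect_equal(mean(os), mean(gridValues(run$freq)[pts]), tolerance = 1e-12)
})

test_that("a 60%-planted sub-pocket is recovered at threshold 0.5 and
           missed at 0.75", {
  run <- plantedRun()
  planted <- plantedMask()
  a50 <- gridValues(transientRegions(run$freq, shellRefPocket(), 0.5)$appearing)
  jac <- sum(planted & a50) / sum(planted | a50)
  expect_gte(jac, 0.9)
  a75 <- gridValues(transientRegions(run$freq, shellRefPocket(), 0.75)$appearing)
  jac75 <- sum(planted & a75) / sum(planted | a75)
  expect_lt(jac75, 0.1)
  # the opening profile separates open from closed members
  sp <- splitSubpockets(Grid3D(shellGrid()@origin, 1, gridDims(shellGrid()),
                               array(a50, gridDims(shellGrid()))), 5)
  os <- openingSeries(sp, 1, run$pockets)
  expect_true(all(os[run$toy$openMembers] > 0.8))
  expect_true(all(os[!run$toy$openMembers] < 0.2))
})
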