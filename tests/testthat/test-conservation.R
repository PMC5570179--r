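# Jensen-Shannon conservation scoring, rescaling and structure mapping.

test_that("JSD column scores hit their analytic anchors", {
  bg <- blosum62Background()
  # a column whose composition equals the background scores 0 (no
  # pseudocount)
  col <- rep(names(bg), round(bg * 1000))
  expect_equal(jsdColumnScore(col, pseudocount = 0), 0, tolerance = 1e-12)
  expect_warning(sc <- jsdColumnScore(rep("-", 6)), "all-gap")
  expect_equal(sc, 0)
  # X counts as gap
  expect_warning(expect_equal(jsdColumnScore(c("X", "X", "-")), 0), "all-gap")
  # scores stay in [0, 1] for random columns
  set.seed(8)
  for (i in 1:50) {
    col <- sample(c(names(bg), "-"), 8, replace = TRUE)
    s <- suppressWarnings(jsdColumnScore(col))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("JSD agrees with an independent entropy-arithmetic oracle", {
  bg <- blosum62Background()
  cols <- list(rep("A", 6), c("A", "A", "A", "L", "L", "K"),
               c("A", "-", "C", "C", "W", "-"), c("D", "E", "D", "E"))
  for (col in cols)
    expect_equal(jsdColumnScore(col), oracleJsd(col, bg), tolerance = 1e-12)
  # gap penalty: a half-gap column scores half the score of its non-gap part
  expect_equal(jsdColumnScore(c("W", "W", "-", "-")),
               jsdColumnScore(c("W", "W")) * 0.5, tolerance = 1e-12)
})

test_that("rescaling maps extremes to exactly 30 and 70 and preserves order", {
  expect_equal(rescaleScores(c(0, 0.5, 1)), c(30, 50, 70))
  expect_equal(rescaleScores(rep(0.3, 5)), rep(50, 5))
  set.seed(9)
  raw <- runif(20)
  r <- rescaleScores(raw)
  expect_equal(min(r), 30); expect_equal(max(r), 70)
  expect_identical(order(r), order(raw))
  expect_error(rescaleScores(numeric(0)), "at least one")
})

test_that("conservation profiles are invariant to row order and rank
           planted conserved columns on top", {
  toy <- makeToyMsa(6, 30, conservedColumns = c(4, 11, 19), seed = 10)
  prof <- conservationProfile(toy$msa)
  expect_true(all(rawScores(prof) >= 0 & rawScores(prof) <= 1))
  shuffled <- toy$msa[c(3, 1, 6, 2, 5, 4)]
  expect_equal(rawScores(conservationProfile(shuffled)), rawScores(prof))
  # planted fully conserved columns rank in the top decile
  rk <- rank(-rawScores(prof))
  expect_true(all(rk[c(4, 11, 19)] <= 3))
  # identical sequences: every column fully conserved, but the background
  # term still differentiates letters, so only a constant-composition
  # alignment degenerates to the all-50 rescaling
  same <- Biostrings::AAStringSet(rep("AAAA", 3))
  names(same) <- paste0("s", 1:3)
  expect_equal(rescaledScores(conservationProfile(same)), rep(50, 4))
  ident <- Biostrings::AAStringSet(rep("ACDW", 3))
  names(ident) <- paste0("s", 1:3)
  expect_true(all(rawScores(conservationProfile(ident)) > 0.3))
})

test_that("differential profiles are zero for identical sequences and peak
           strictly at a single divergent column", {
  rows <- Biostrings::AAStringSet(rep("ACDEFGHIKL", 4))
  names(rows) <- paste0("on", 1:4)
  dz <- differentialConservation(rows, "ACDEFGHIKL")
  expect_lt(max(abs(rawScores(dz))), 1e-5)   # only the pseudocount shifts
  d1 <- differentialConservation(rows, "ACDEFWHIKL")   # column 6 differs
  expect_equal(which.max(rawScores(d1)), 6L)
  expect_true(all(rawScores(d1)[-6] < rawScores(d1)[6]))
  expect_error(differentialConservation(rows, "ACD"), "width")
})

test_that("a duplicated on-target row perturbs the profile less than a
           divergent off-target", {
  toy <- makeToyMsa(5, 30, conservedColumns = 1:30, seed = 12)
  dupDiff <- differentialConservation(toy$msa, as.character(toy$msa[[1]]))
  off <- strsplit(as.character(toy$msa[[1]]), "")[[1]]
  off[c(7, 8, 9)] <- c("W", "W", "W")
  divDiff <- differentialConservation(toy$msa, paste(off, collapse = ""))
  expect_lt(max(rawScores(dupDiff)), max(rawScores(divDiff)))
})

test_that("planted divergent columns are the argmax of the raw differential
           profile across seeds", {
  hits <- 0L
  for (s in 1:25) {
    toy <- makeToyMsa(5, 40, conservedColumns = c(5, 12, 20),
                      offDivergentColumns = 12, seed = s)
    d <- differentialConservation(toy$msa, toy$off)
    hits <- hits + (which.max(rawScores(d)) == 12L)
  }
  expect_equal(hits, 25L)
})

test_that("profile scores map onto structure residues through the reference
           row", {
  s <- makeChainStructure("ACDEFGHIKL")
  msa <- Biostrings::AAStringSet(c(ref = "ACDEFGHIKL",
                                   hom = "ACDEYGHIKL",
                                   far = "ACDEWGHIKL"))
  prof <- conservationProfile(msa)
  mapped <- mapScoresToStructure(prof, msa, s)
  expect_length(residueScores(mapped), 10L)
  expect_equal(unname(residueScores(mapped)),
               unname(rescaledScores(prof)))
  expect_equal(names(residueScores(mapped)), paste0("A:", 1:10))
})

test_that("an internal gap in the reference row shifts downstream column
           assignments by one", {
  s <- makeChainStructure("ACDEFGHIK")                  # 9 residues
  msa <- Biostrings::AAStringSet(c(ref = "ACDE-FGHIK",  # gap at column 5
                                   hom = "ACDEWFGHIK"))
  prof <- conservationProfile(msa)
  mapped <- suppressWarnings(mapScoresToStructure(prof, msa, s))
  rs <- residueScores(mapped)
  resc <- rescaledScores(prof)
  expect_equal(unname(rs[paste0("A:", 1:4)]), unname(resc[1:4]))
  expect_equal(unname(rs[paste0("A:", 5:9)]), unname(resc[6:10]))
})

test_that("structure residues missing from the MSA row stay unscored and a
           bad match errors", {
  s <- makeChainStructure("WWACDEFGHIKL")               # 2-residue tag
  msa <- Biostrings::AAStringSet(c(ref = "ACDEFGHIKL", hom = "ACDEYGHIKL"))
  prof <- conservationProfile(msa)
  expect_warning(mapped <- mapScoresToStructure(prof, msa, s), "unscored")
  expect_false(any(paste0("A:", 1:2) %in% names(residueScores(mapped))))
  expect_length(residueScores(mapped), 10L)
  bad <- Biostrings::AAStringSet(c(a = "WYWYWYWYWY", b = "YWYWYWYWYW"))
  expect_error(
    mapScoresToStructure(conservationProfile(bad), bad,
                         makeChainStructure("ACDEFGHIKL")),
    "no MSA row matches")
})
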