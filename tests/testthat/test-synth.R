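test_that("generators are byte-deterministic under a fixed seed", {
  t1 <- writePDB(makeConfidenceTrack(seed = 42, chainLength = 30,
                                     segments = list(c(5, 12)))$structure)
  t2 <- writePDB(makeConfidenceTrack(seed = 42, chainLength = 30,
                                     segments = list(c(5, 12)))$structure)
  expect_identical(t1, t2)

  e1 <- writePDB(makePoseEnsemble(seed = 5, sizes = c(4, 3),
                                  nResidues = 4)$ensemble)
  e2 <- writePDB(makePoseEnsemble(seed = 5, sizes = c(4, 3),
                                  nResidues = 4)$ensemble)
  expect_identical(e1, e2)

  j1 <- writePDB(makeTrajectory(seed = 6, nFrames = 5,
                                receptorResidues = 3)$trajectory)
  j2 <- writePDB(makeTrajectory(seed = 6, nFrames = 5,
                                receptorResidues = 3)$trajectory)
  expect_identical(j1, j2)

  c1 <- writePDB(makeToyComplex(seed = 7, contacts = list(c(1, 1)))$structure)
  c2 <- writePDB(makeToyComplex(seed = 7, contacts = list(c(1, 1)))$structure)
  expect_identical(c1, c2)
})

test_that("planted confidence segments are recovered with mergeGap 0", {
  fx <- makeConfidenceTrack(seed = 10, chainLength = 320,
                            segments = list(c(208, 217), c(221, 229)))
  fr <- extractConfidentFragments(fx$track, mergeGap = 0)
  runs <- unlist(lapply(fr, `[[`, "runs"), recursive = FALSE)
  expect_equal(runs, fx$truth)

  none <- makeConfidenceTrack(seed = 11, chainLength = 40,
                              segments = list())
  expect_length(extractConfidentFragments(none$track, mergeGap = 0), 0L)

  full <- makeConfidenceTrack(seed = 12, chainLength = 25,
                              segments = list(c(1, 25)))
  fr_full <- extractConfidentFragments(full$track, mergeGap = 0)
  expect_equal(fr_full[[1]]$runs, list(c(1L, 25L)))
  expect_error(makeConfidenceTrack(seed = 1, chainLength = 30,
                                   segments = list(c(2, 10), c(8, 14))),
               "overlap")
  expect_error(makeConfidenceTrack(seed = 1, chainLength = 10,
                                   segments = list(c(5, 20))),
               "outside")
})

test_that("toy complexes realize exactly the requested contact map", {
  fx0 <- makeToyComplex(seed = 1, contacts = list())
  expect_equal(sum(contactCounts(
    interfacialContacts(fx0$structure, "A", "B"))), 0)
  expect_equal(sum(deltaSASA(fx0$structure, "A", "B")$interface), 0L)

  fx3 <- makeToyComplex(seed = 2, contacts = list(c(1, 1), c(4, 3),
                                                  c(6, 5)))
  ct <- interfacialContacts(fx3$structure, "A", "B")
  expect_equal(contactPairs(ct)[, c("resnoR", "resnoL")],
               data.frame(resnoR = c(1L, 4L, 6L),
                          resnoL = c(1L, 3L, 5L)))
  expect_error(makeToyComplex(seed = 1, contacts = list(c(1, 1), c(1, 2))),
               "repeats")
  expect_error(makeToyComplex(seed = 1, contacts = list(c(1, 1)),
                              contactDistance = 1.0), "2.5")
})

test_that("pose ensembles respect the declared spread and separation", {
  fx <- makePoseEnsemble(seed = 30, sizes = c(6, 4), nResidues = 6)
  m <- pairwiseRMSD(fx$ensemble)
  part <- fx$truth$partition
  within <- c(m[part[[1]], part[[1]]], m[part[[2]], part[[2]]])
  across <- m[part[[1]], part[[2]]]
  expect_true(all(within <= 2 * fx$truth$spread + 1e-9))
  expect_true(all(across >= 4 * fx$truth$spread))
  expect_error(makePoseEnsemble(seed = 1, sizes = c(2, 2), spread = 0.2,
                                separation = 0.3), "4 \\* spread")
})

test_that("ideal peptide geometry hits standard bond lengths", {
  for (conf in c("extended", "helical")) {
    p <- makePeptideChain("GFDNYGDPLGVF", conformation = conf)
    a <- atoms(p)
    expect_equal(nResidues(p), 12L)
    expect_equal(paste(aaThreeToOne(residueTable(p)$resname),
                       collapse = ""), "GFDNYGDPLGVF")
    xyz <- function(resno, name) {
      r <- a[a$resno == resno & a$name == name, c("x", "y", "z")]
      if (!nrow(r)) return(NULL)
      as.numeric(r)
    }
    blen <- function(p1, p2) sqrt(sum((p1 - p2)^2))
    ideal <- c(n_ca = 1.458, ca_c = 1.525, c_o = 1.231, ca_cb = 1.530,
               c_n = 1.329)
    for (i in 1:12) {
      expect_equal(blen(xyz(i, "N"), xyz(i, "CA")), ideal["n_ca"],
                   tolerance = 0.02, ignore_attr = TRUE)
      expect_equal(blen(xyz(i, "CA"), xyz(i, "C")), ideal["ca_c"],
                   tolerance = 0.02, ignore_attr = TRUE)
      expect_equal(blen(xyz(i, "C"), xyz(i, "O")), ideal["c_o"],
                   tolerance = 0.02, ignore_attr = TRUE)
      if (i < 12)
        expect_equal(blen(xyz(i, "C"), xyz(i + 1, "N")), ideal["c_n"],
                     tolerance = 0.02, ignore_attr = TRUE)
      if (!is.null(xyz(i, "CB")))
        expect_equal(blen(xyz(i, "CA"), xyz(i, "CB")), ideal["ca_cb"],
                     tolerance = 0.02, ignore_attr = TRUE)
    }
  }
  g <- makePeptideChain("G")
  expect_equal(nResidues(g), 1L)
  expect_false("CB" %in% atoms(g)$name)
  expect_error(makePeptideChain("AZB"), "unknown")
})

test_that("trajectory generator truths drive the metric examples", {
  still <- makeTrajectory(seed = 2, nFrames = 8, receptorResidues = 4,
                          sigma = 0)
  expect_true(all(rmsdSeries(still$trajectory)$rmsd < 1e-12))

  one_hot <- makeTrajectory(seed = 3, nFrames = 2000,
                            receptorResidues = 5,
                            sigma = c(0, 0, 0.1, 0, 0))
  rf <- rmsfProfile(one_hot$trajectory,
                    fitSelection = function(a) a$resno != 3)
  expect_equal(rf$rmsf[3], 0.1 * sqrt(3), tolerance = 0.05)
  expect_true(all(rf$rmsf[-3] < 0.02))
})
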