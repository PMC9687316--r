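test_that("residue-list notation parses, including hyphens and gaps", {
  rl <- parseResidueList("K82, N83, X, F85")
  expect_equal(rl$aa, c("K", "N", "X", "F"))
  expect_equal(rl$resno, c(82L, 83L, 84L, 85L))
  expect_true(rl$gap[3])

  hy <- parseResidueList("L183, X, R-185")
  expect_equal(hy$resno, 183:185)
  expect_equal(hy$aa, c("L", "X", "R"))
  expect_identical(parseResidueList("R185")$aa,
                   parseResidueList("R-185")$aa)

  expect_equal(nrow(parseResidueList("")), 0L)
  expect_equal(parseResidueList("ILE210, TYR211")$aa, c("I", "Y"))
})

test_that("monotonicity violations error strictly and repair leniently", {
  expect_error(parseResidueList("S231, X, M223"), "M223")
  rl <- parseResidueList("S231, X, M223", lenient = TRUE)
  expect_equal(rl$resno, c(231L, 232L, 233L))
  expect_true(rl$repaired[3])
  expect_error(parseResidueList("Z100"), "unknown residue")
  expect_error(parseResidueList("X, K10"), "cannot open")
})

test_that("stretch extraction honors the single-gap rule", {
  # two missing residues split
  rl <- parseResidueList("I10, F13")
  st <- extractStretches(rl)
  expect_equal(st$start, c(10L, 13L))
  expect_equal(st$length, c(1L, 1L))

  # multiple isolated gaps stay in one stretch
  rl2 <- parseResidueList("L183, X, R185, X, V187, X, P189, K190")
  st2 <- extractStretches(rl2)
  expect_equal(nrow(st2), 1L)
  expect_equal(st2$length, 8L)
  expect_equal(st2$gaps, "184,186,188")
})

test_that("the printed blocks give the published stretch lengths", {
  lists <- read_bundled_lists()
  lec1 <- extractStretches(lists[["LEC1"]])
  expect_true(all(c(8, 12) %in% lec1$length))
  s8 <- lec1[lec1$length == 8, ]
  expect_equal(c(s8$start, s8$end), c(71L, 78L))
  s12 <- lec1[lec1$length == 12, ]
  expect_equal(c(s12$start, s12$end), c(131L, 142L))
  expect_equal(sort(as.integer(strsplit(s12$gaps, ",")[[1]])),
               c(136L, 140L))
})

test_that("no emitted stretch contains adjacent gaps, and re-parsing is stable", {
  lists <- read_bundled_lists()
  for (rl in lists) {
    st <- extractStretches(rl)
    for (i in seq_len(nrow(st))) {
      gaps <- as.integer(strsplit(st$gaps[i], ",")[[1]])
      if (length(gaps) > 1) expect_true(all(diff(sort(gaps)) >= 2))
      # idempotence: serialize the stretch back to notation and re-extract
      seqs <- buildPeptide(st[i, ], rl)
      span <- seq(st$start[i], st$end[i])
      toks <- ifelse(span %in% gaps, "X",
                     paste0(substring(seqs, match(span, span),
                                      match(span, span)), span))
      again <- extractStretches(parseResidueList(paste(toks,
                                                       collapse = ", ")))
      expect_equal(nrow(again), 1L)
      expect_equal(again$start, st$start[i])
      expect_equal(again$end, st$end[i])
    }
  }
})

test_that("random residue sets match the brute-force stretch oracle", {
  set.seed(77)
  for (rep in 1:1000) {
    present <- sort(sample(1:60, sample(1:25, 1)))
    rl <- data.frame(aa = "A", resno = present, gap = FALSE,
                     repaired = FALSE)
    got <- extractStretches(rl)
    want <- stretches_brute(present)
    expect_equal(nrow(got), length(want))
    expect_equal(got$start, vapply(want, `[`, numeric(1), 1))
    expect_equal(got$end, vapply(want, `[`, numeric(1), 2))
  }
})

test_that("glycine bridging reproduces the published peptides", {
  lists <- read_bundled_lists()
  lec1 <- lists[["LEC1"]]
  st <- extractStretches(lec1)
  s12 <- st[st$start == 131, ]
  expect_equal(buildPeptide(s12, lec1), "GFDNYGDPLGVF")

  # both fixture files carry a WUS block; the second is the fragment-2 one
  wus2 <- lists[which(names(lists) == "WUS")[2]][[1]]
  stw <- extractStretches(wus2)
  s9 <- stw[stw$length == 9, ]
  expect_equal(buildPeptide(s9, wus2), "KNGFYWGQN")

  # gapless stretch: verbatim substring
  rl <- parseResidueList("I8, K9, R10, I11")
  expect_equal(buildPeptide(extractStretches(rl)[1, ], rl), "IKRI")
})

test_that("length in positions spanned always equals end - start + 1", {
  lists <- read_bundled_lists()
  peps <- selectPeptides(lists, minLen = 1)
  expect_true(all(nchar(peps$sequence) == peps$end - peps$start + 1))
  expect_true(all(nchar(peps$sequence) == peps$length))
})

test_that("the minimum-length filter selects exactly the published seven", {
  peps <- selectPeptides(read_bundled_lists(), minLen = 8)
  expect_equal(nrow(peps), 7L)
  expect_setequal(peps$sequence,
                  c("GFDNYGDPLGVF", "EVAVIVFGKGG", "KNGFYWGQN",
                    "LGRGVGPK", "WGNNGSGM", "RIMGKTGP", "VAVIVFGK"))
  expect_equal(peps$id, paste0("P", 1:7))

  expect_equal(nrow(selectPeptides(read_bundled_lists(), minLen = 100)), 0L)

  # lowering the filter admits the shorter stretches of a block
  lists <- read_bundled_lists()
  lec2 <- lists[["LEC2"]]
  all_st <- extractStretches(lec2)
  low <- selectPeptides(list(lec2), minLen = 1)
  expect_equal(nrow(low), nrow(all_st))
  expect_true(any(low$length == 6) && any(low$length == 1))
})

test_that("no stretch of length >= 8 beyond the published ones exists", {
  lists <- read_bundled_lists()
  long <- do.call(rbind, lapply(lists, extractStretches))
  long <- long[long$length >= 8, ]
  expect_equal(nrow(long), 7L)
})

test_that("peptide FASTA export round-trips sequences and headers", {
  peps <- selectPeptides(read_bundled_lists())
  f <- tempfile(fileext = ".fasta")
  peptidesToFasta(peps, f)
  back <- Biostrings::readAAStringSet(f)
  expect_equal(length(back), 7L)
  expect_equal(as.character(back, use.names = FALSE), peps$sequence)
  expect_true(all(grepl("^P[0-9]+\\|", names(back))))
})

test_that("overlap scoring counts residues inside the site, and partitions", {
  tab <- read.delim(fixture_tables_path("peptide_interface_residues.tsv"))
  sites <- dnaBindingSites()
  expected <- c(P1 = 13, P2.dock89 = 10, P2.dock10 = 12, P3 = 12, P4 = 8,
                P5 = 8, P6 = 10, P7 = 12)
  got <- vapply(seq_len(nrow(tab)), function(i) {
    res <- parseResidueTokens(tab$residues[i])$resno
    site <- sites[sites$fragment == tab$fragment[i], ]
    overlapScore(res, site)$count
  }, numeric(1))
  expect_equal(unname(got), unname(expected))

  expect_equal(overlapScore(integer(0), c(210, 276))$count, 0)
  # complement partition over the numbering line
  res <- parseResidueTokens(tab$residues[1])$resno
  inside <- overlapScore(res, c(210, 276))$count
  below <- overlapScore(res, c(1, 209))$count
  above <- overlapScore(res, c(277, 10000))$count
  expect_equal(inside + below + above, length(unique(res)))
  expect_error(overlapScore(res, c(276, 210)), "malformed")
})
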