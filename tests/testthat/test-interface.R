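test_that("an isolated atom matches the closed-form sphere area", {
  s <- atoms_structure(single_atom_structure("C"))
  got <- sasa(s)$total
  expect_equal(got, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
})

test_that("a fully caged atom has zero accessible area", {
  # central carbon inside a closed shell of carbons on a 2 A sphere
  i <- seq_len(42) - 0.5
  phi <- acos(1 - 2 * i / 42)
  th <- pi * (1 + sqrt(5)) * i
  shell <- 2 * cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  rows <- do.call(rbind, lapply(seq_len(nrow(shell)), function(k)
    single_atom_structure("C", shell[k, 1], shell[k, 2], shell[k, 3],
                          resno = k + 1)))
  a <- rbind(single_atom_structure("C"), rows)
  res <- sasa(atoms_structure(a))
  expect_equal(res$atom$area[1], 0)
})

test_that("two-sphere areas track the analytic cap formula over distance", {
  R <- 1.7 + 1.4
  for (d in c(0.8, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5)) {
    a <- rbind(single_atom_structure("C", 0, 0, 0),
               single_atom_structure("C", d, 0, 0, resno = 2))
    got <- sasa(atoms_structure(a))$total
    want <- 2 * two_sphere_exposed(R, R, d)
    expect_equal(got, want, tolerance = 0.01)
  }
})

test_that("quadrature converges: doubling points barely moves the answer", {
  a <- rbind(single_atom_structure("C", 0, 0, 0),
             single_atom_structure("N", 2.4, 0, 0, resno = 2))
  s <- atoms_structure(a)
  a1 <- sasa(s, nPoints = 960)$total
  a2 <- sasa(s, nPoints = 1920)$total
  expect_lt(abs(a2 - a1) / a1, 0.005)
})

test_that("unknown elements fail by name unless a fallback radius is set", {
  s <- atoms_structure(single_atom_structure("XX", name = "XX"))
  expect_error(sasa(s), "XX")
  r <- defaultRadii(fallback = 1.7)
  expect_gt(sasa(s, radii = r)$total, 0)
})

test_that("well-separated chains bury nothing", {
  fx <- makeToyComplex(seed = 1, nReceptor = 4, nLigand = 3,
                       contacts = list())
  prof <- deltaSASA(fx$structure, "A", "B")
  expect_true(all(abs(prof$dsasa) < 1e-6))
  expect_equal(sum(prof$interface), 0L)
  # additivity: joint SASA equals the sum of the parts
  a <- atoms(fx$structure)
  part <- function(ch) atoms_structure(a[a$chain == ch, ])
  expect_equal(sasa(fx$structure)$total,
               sasa(part("A"))$total + sasa(part("B"))$total,
               tolerance = 1e-9)
})

test_that("planted contacts are exactly the residues with positive dSASA", {
  fx <- makeToyComplex(seed = 2, nReceptor = 8, nLigand = 6,
                       contacts = list(c(3, 2)))
  prof <- deltaSASA(fx$structure, "A", "B")
  iface <- prof[prof$interface, ]
  expect_equal(iface$resno[iface$side == "receptor"], 3L)
  expect_equal(iface$resno[iface$side == "ligand"], 2L)
  expect_true(all(prof$dsasa > -1e-6))
})

test_that("contact detection equals a brute-force all-pairs scan", {
  fx <- makeToyComplex(seed = 3, nReceptor = 9, nLigand = 7,
                       contacts = list(c(2, 1), c(5, 4), c(8, 6)))
  ct <- interfacialContacts(fx$structure, "A", "B")
  expect_equal(sum(contactCounts(ct)), 3)
  got <- contactPairs(ct)[, c("resnoR", "resnoL")]
  # independent O(n^2) scan
  a <- atoms(fx$structure)
  ar <- a[a$chain == "A", ]
  al <- a[a$chain == "B", ]
  want <- list()
  for (i in unique(ar$resno)) for (j in unique(al$resno)) {
    xi <- as.matrix(ar[ar$resno == i, c("x", "y", "z")])
    xj <- as.matrix(al[al$resno == j, c("x", "y", "z")])
    dmin <- min(sqrt(outer(rowSums(xi^2), rowSums(xj^2), "+") -
                       2 * xi %*% t(xj)))
    if (dmin <= 5.5) want[[length(want) + 1]] <- c(i, j)
  }
  want <- do.call(rbind, want)
  expect_equal(unname(as.matrix(got)), unname(want))
  # planted truth agrees too
  expect_equal(unname(as.matrix(got)),
               unname(do.call(rbind, fx$truth)))
})

test_that("contact classification is total and swap-symmetric", {
  fx <- makeToyComplex(seed = 4, nReceptor = 6, nLigand = 6,
                       sequenceR = "ADKSTW", sequenceL = "FRENQY",
                       contacts = list(c(1, 2), c(4, 5)))
  all_apolar <- setNames(rep("apolar", 20), names(boomdock:::.AA1TO3))
  ct <- interfacialContacts(fx$structure, "A", "B", scheme = all_apolar)
  expect_equal(unname(contactCounts(ct)["aa"]), 2)
  expect_equal(sum(contactCounts(ct)), 2)

  ct1 <- interfacialContacts(fx$structure, "A", "B")
  ct2 <- interfacialContacts(fx$structure, "B", "A")
  expect_equal(contactCounts(ct1), contactCounts(ct2))
  expect_equal(ct1@pairs$resnoR, ct2@pairs$resnoL)
  sep <- makeToyComplex(seed = 5, contacts = list())
  expect_equal(sum(contactCounts(
    interfacialContacts(sep$structure, "A", "B"))), 0)
})

test_that("the affinity model is an exact weighted sum of its terms", {
  zero <- c(cc = 0, cp = 0, ca = 0, pp = 0, pa = 0, aa = 0)
  model <- list(weights = c(pp = 1, aa = 1), intercept = -1,
                temperature = 298.15)
  expect_equal(bindingAffinity(zero, model = model), -1)
  expect_equal(bindingAffinity(c(cc = 0, cp = 0, ca = 0, pp = 2, pa = 0,
                                 aa = 3), model = model), 4)
  set.seed(31)
  for (rep in 1:25) {
    counts <- setNames(rpois(6, 8), c("cc", "cp", "ca", "pp", "pa", "aa"))
    nis <- c(nis_apolar = runif(1, 0, 100), nis_charged = runif(1, 0, 100))
    w <- setNames(rnorm(8), c(names(counts), names(nis)))
    m <- list(weights = w, intercept = rnorm(1), temperature = 298.15)
    want <- sum(w * c(counts, nis)[names(w)]) + m$intercept
    expect_equal(bindingAffinity(counts, nis, m), want)
  }
  expect_error(bindingAffinity(zero[-4], model = model), "pp")
})

test_that("dG/Kd conversion is exact and self-inverse", {
  expect_equal(kdFromDG(0), 1)
  RT <- 1.9872e-3 * 298.15
  expect_equal(kdFromDG(RT * log(1e-9)), 1e-9)
  expect_equal(dgFromKd(kdFromDG(-8.1)), -8.1)
  # a printed (dG, Kd) pair is consistent within the dG rounding width
  expect_equal(kdFromDG(-8.1), 1.1e-6, tolerance = 0.07)
  expect_error(kdFromDG(-5, T = -1), "positive")
})

test_that("every printed affinity/Kd pair obeys dG = RT ln Kd within 0.06", {
  pairs <- read.delim(fixture_tables_path("affinity_kd_pairs.tsv"))
  expect_equal(nrow(pairs), 20L)
  resid <- abs(pairs$dG_kcal_mol - dgFromKd(pairs$Kd_M, T = 298.15))
  expect_true(all(resid <= 0.06))
})

test_that("interface reports keep Kd thermodynamically consistent", {
  fx <- makeToyComplex(seed = 6, nReceptor = 6, nLigand = 5,
                       sequenceR = "ADKSTW", sequenceL = "FRENQ",
                       contacts = list(c(2, 2), c(5, 4)))
  rep <- interfaceReport(fx$structure, "A", "B")
  expect_s4_class(rep, "InterfaceReport")
  expect_equal(rep@kd, kdFromDG(rep@dG, rep@temperature))
  cols <- polarContactColumns(rep@contacts)
  expect_gte(cols$folded["polar_polar"], cols$strict["polar_polar"])
  out <- writeInterfaceReport(rep)
  expect_equal(out$table$dG, round(rep@dG, 1))
})
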