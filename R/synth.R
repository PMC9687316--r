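# Synthetic inputs with stored ground truth. Every generator is seeded and
# deterministic: the same seed yields byte-identical structures, so all
# downstream stages are testable offline against known answers.

.IDEAL <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  omega = 180)

.PHIPSI <- list(extended = c(phi = -120, psi = 120),
                helical = c(phi = -57, psi = -47))

#' Build an ideal-geometry peptide structure
#'
#' Constructs heavy-atom backbone coordinates (N, CA, C, O, plus CB for
#' non-glycine residues) from standard bond lengths and angles at fixed
#' backbone torsions: extended (phi/psi = -120/120) or helical (-57/-47).
#' No rotamers or side chains beyond CB -- this is an idealized chain for
#' testing and for standing in as a modelled peptide, not a physically
#' relaxed conformation.
#'
#' @param sequence one-letter amino-acid string (standard 20 codes).
#' @param conformation `"extended"` or `"helical"`.
#' @param chain chain identifier.
#' @param id structure identifier.
#' @param startResno first residue number.
#' @param offset length-3 translation applied to all atoms, Angstrom.
#' @param bscore B-factor value written on every atom.
#' @return a [ProteinStructure-class].
#' @examples
#' pep <- makePeptideChain("GFDNYGDPLGVF")
#' nResidues(pep)
#' @export
makePeptideChain <- function(sequence, conformation = c("extended",
                                                        "helical"),
                             chain = "A", id = "peptide", startResno = 1L,
                             offset = c(0, 0, 0), bscore = 0) {
  conformation <- match.arg(conformation)
  aa1 <- strsplit(toupper(sequence), "")[[1]]
  if (!length(aa1)) stop("empty sequence")
  bad <- setdiff(aa1, names(.AA1TO3))
  if (length(bad))
    stop("unknown one-letter code(s): ", paste(unique(bad), collapse = ", "))
  tor <- .PHIPSI[[conformation]]
  a <- build_backbone(aa1, tor["phi"], tor["psi"], chain, startResno,
                      bscore)
  a[, c("x", "y", "z")] <- sweep(as.matrix(a[, c("x", "y", "z")]), 2,
                                 as.numeric(offset), FUN = "+")
  new("ProteinStructure", id = id, atoms = a, title = "")
}

build_backbone <- function(aa1, phi, psi, chain, startResno, bscore) {
  g <- .IDEAL
  n_res <- length(aa1)
  # backbone trace
  N <- CA <- C <- vector("list", n_res)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_n_ca, 0, 0)
  ang <- (180 - g$a_n_ca_c) * pi / 180
  C[[1]] <- CA[[1]] + g$b_ca_c * c(cos(ang), sin(ang), 0)
  if (n_res > 1) {
    for (i in 2:n_res) {
      N[[i]] <- nerf_place(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                           g$b_c_n, g$a_ca_c_n, psi)
      CA[[i]] <- nerf_place(CA[[i - 1]], C[[i - 1]], N[[i]],
                            g$b_n_ca, g$a_c_n_ca, g$omega)
      C[[i]] <- nerf_place(C[[i - 1]], N[[i]], CA[[i]],
                           g$b_ca_c, g$a_n_ca_c, phi)
    }
  }
  rows <- list()
  serial <- 0L
  add <- function(rows, nm, el, xyz, resno, resname) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      serial = serial, name = nm, altloc = "", resname = resname,
      chain = chain, resno = resno, icode = "", x = xyz[1], y = xyz[2],
      z = xyz[3], occupancy = 1, bscore = bscore, element = el,
      stringsAsFactors = FALSE)
    rows
  }
  for (i in seq_len(n_res)) {
    resname <- .AA1TO3[[aa1[i]]]
    resno <- startResno + i - 1L
    rows <- add(rows, "N", "N", N[[i]], resno, resname)
    rows <- add(rows, "CA", "C", CA[[i]], resno, resname)
    rows <- add(rows, "C", "C", C[[i]], resno, resname)
    o_tor <- if (i < n_res) 180 else psi + 180
    o_a <- if (i < n_res) N[[i + 1]] else N[[i]]
    rows <- add(rows, "O", "O",
                nerf_place(o_a, CA[[i]], C[[i]], g$b_c_o, g$a_ca_c_o,
                           o_tor), resno, resname)
    if (aa1[i] != "G") {
      # ideal CB from the local backbone frame (preserves L-chirality)
      b <- CA[[i]] - N[[i]]
      c_ <- C[[i]] - CA[[i]]
      a_ <- pracma_cross(b, c_)
      cb <- CA[[i]] - 0.58273431 * a_ + 0.56802827 * b - 0.54067466 * c_
      rows <- add(rows, "CB", "C", cb, resno, resname)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic predicted structure with a planted confidence track
#'
#' Builds an extended chain and writes per-residue confidence scores into
#' the B-factor column: strictly above 90 on the planted segments, at or
#' below 90 elsewhere. The default segment layout reproduces the
#' two-fragment run structure of the receptor protein this toolkit was
#' built around (five runs separated by gaps of at most 13 residues, then a
#' 19-residue gap, then three more runs).
#'
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param chainLength chain length in residues (numbered from
#'   `startResno`).
#' @param segments list of inclusive `c(start, end)` residue-number runs to
#'   plant with high confidence; must be disjoint and within the chain.
#' @param startResno first residue number (default 1).
#' @param chain chain id.
#' @return list with `structure`, `track` (its [confidenceTrack()]) and
#'   `truth` (the planted runs).
#' @export
makeConfidenceTrack <- function(seed, chainLength = 400,
                                segments = list(c(208, 217), c(221, 229),
                                                c(243, 268), c(271, 285),
                                                c(295, 296), c(316, 317),
                                                c(324, 328), c(339, 358)),
                                startResno = 1L, chain = "A") {
  set.seed(seed)
  resnos <- seq(startResno, length.out = chainLength)
  covered <- integer(0)
  for (s in segments) {
    s <- as.integer(s)
    if (length(s) != 2L || s[1] > s[2] || !all(s %in% resnos))
      stop("segment outside the chain: ", paste(s, collapse = "-"))
    span <- seq(s[1], s[2])
    if (length(intersect(covered, span)))
      stop("overlapping segments at ", paste(s, collapse = "-"))
    covered <- c(covered, span)
  }
  sequence <- paste(sample(names(.AA1TO3), chainLength, replace = TRUE),
                    collapse = "")
  s <- makePeptideChain(sequence, "extended", chain = chain,
                        id = "synthetic_prediction",
                        startResno = startResno)
  a <- atoms(s)
  score <- stats::runif(chainLength, 50, 90)
  hi <- resnos %in% covered
  score[hi] <- stats::runif(sum(hi), 91, 99)
  a$bscore <- score[match(a$resno, resnos)]
  s@atoms <- a
  list(structure = s,
       track = confidenceTrack(s),
       truth = lapply(segments, as.integer))
}

#' Synthetic two-chain complex with an exactly known contact map
#'
#' Places two chains of ideal-geometry residues (poly-alanine by default,
#' mutable) so that exactly the requested receptor--ligand residue pairs
#' have a heavy-atom distance within 5.5 Angstrom. To make the contact map
#' exactly controllable, residues sit as ideal-geometry units on a
#' `spacing`-Angstrom grid rather than as a covalently continuous backbone;
#' ligand residues not involved in a contact are parked 30 Angstrom away.
#' The realized contact map is verified by a brute-force scan and any
#' deviation from the request is an error (infeasible placement).
#'
#' @param seed integer seed (kept for interface uniformity; the
#'   construction is deterministic).
#' @param nReceptor,nLigand chain lengths (residues; chains "A" and "B").
#' @param contacts list of `c(receptor_index, ligand_index)` residue pairs
#'   to place in contact; indices must not repeat on either side.
#' @param contactDistance minimal heavy-atom distance planted for each
#'   contact, Angstrom; must lie in [2.5, 5.5] (no clashes, still a
#'   contact).
#' @param sequenceR,sequenceL chain sequences (default poly-A).
#' @param spacing grid spacing between residue units, Angstrom.
#' @return list with `structure` (chains A = receptor, B = ligand) and
#'   `truth` (the planted residue-number pairs).
#' @export
makeToyComplex <- function(seed = 1, nReceptor = 8, nLigand = 6,
                           contacts = list(), contactDistance = 4.0,
                           sequenceR = NULL, sequenceL = NULL,
                           spacing = 12) {
  set.seed(seed)
  if (contactDistance < 2.5 || contactDistance > 5.5)
    stop("contactDistance must lie in [2.5, 5.5] Angstrom")
  if (is.null(sequenceR)) sequenceR <- strrep("A", nReceptor)
  if (is.null(sequenceL)) sequenceL <- strrep("A", nLigand)
  if (nchar(sequenceR) != nReceptor || nchar(sequenceL) != nLigand)
    stop("sequence lengths disagree with chain lengths")
  ri <- vapply(contacts, `[`, numeric(1), 1)
  li <- vapply(contacts, `[`, numeric(1), 2)
  if (anyDuplicated(ri) || anyDuplicated(li))
    stop("infeasible placement: a residue index repeats across contacts")
  if (length(contacts) &&
      (any(ri < 1 | ri > nReceptor) || any(li < 1 | li > nLigand)))
    stop("contact index outside the chains")
  unit <- function(code) atoms(makePeptideChain(code, "extended"))
  place <- function(code, resno, chain, origin) {
    u <- unit(code)
    u$resno <- resno
    u$chain <- chain
    u[, c("x", "y", "z")] <- sweep(as.matrix(u[, c("x", "y", "z")]), 2,
                                   origin, FUN = "+")
    u
  }
  recept <- lapply(seq_len(nReceptor), function(i)
    place(substr(sequenceR, i, i), i, "A", c(spacing * (i - 1), 0, 0)))
  lig <- vector("list", nLigand)
  for (j in seq_len(nLigand)) {
    k <- match(j, li)
    if (is.na(k)) {
      lig[[j]] <- place(substr(sequenceL, j, j), j, "B",
                        c(spacing * (j - 1), 0, 30))
    } else {
      i <- ri[k]
      base_xy <- c(spacing * (i - 1), 0)
      rxyz <- as.matrix(recept[[i]][, c("x", "y", "z")])
      mind <- function(dz) {
        u <- unit(substr(sequenceL, j, j))
        lx <- sweep(as.matrix(u[, c("x", "y", "z")]), 2,
                    c(base_xy, dz), FUN = "+")
        min(sqrt(outer(rowSums(lx^2), rowSums(rxyz^2), "+") -
                   2 * lx %*% t(rxyz)))
      }
      dz <- stats::uniroot(function(z) mind(z) - contactDistance,
                           lower = 2.5, upper = 25, tol = 1e-9)$root
      lig[[j]] <- place(substr(sequenceL, j, j), j, "B", c(base_xy, dz))
    }
  }
  a <- do.call(rbind, c(recept, lig))
  a$serial <- seq_len(nrow(a))
  rownames(a) <- NULL
  s <- new("ProteinStructure", id = "synthetic_complex", atoms = a,
           title = "")
  # brute-force verification that the realized map equals the request
  realized <- contact_map_brute(a, "A", "B", 5.5)
  want <- if (length(contacts))
    sort(paste(ri, li, sep = "-")) else character(0)
  if (!identical(sort(paste(realized$resnoR, realized$resnoL, sep = "-")),
                 want))
    stop("infeasible placement: realized contact map differs from request")
  clash <- contact_map_brute(a, "A", "B", 2.5 - 1e-9)
  if (nrow(clash)) stop("infeasible placement: steric clash")
  list(structure = s,
       truth = lapply(contacts, function(p)
         c(receptor = as.integer(p[1]), ligand = as.integer(p[2]))))
}

# minimal cross-chain residue-pair distances by exhaustive scan
contact_map_brute <- function(a, chainR, chainL, threshold) {
  ar <- a[a$chain %in% chainR, ]
  al <- a[a$chain %in% chainL, ]
  xr <- as.matrix(ar[, c("x", "y", "z")])
  xl <- as.matrix(al[, c("x", "y", "z")])
  d <- sqrt(pmax(outer(rowSums(xr^2), rowSums(xl^2), "+") -
                   2 * xr %*% t(xl), 0))
  hit <- which(d <= threshold, arr.ind = TRUE)
  out <- unique(data.frame(resnoR = ar$resno[hit[, 1]],
                           resnoL = al$resno[hit[, 2]]))
  rownames(out) <- NULL
  out[order(out$resnoR, out$resnoL), , drop = FALSE]
}

#' Synthetic docked-pose ensemble with planted cluster structure
#'
#' Generates cluster centers as independent random deformation fields of a
#' base chain (deformations, not rigid moves, so superposition cannot erase
#' the separation), then fills each cluster with members jittered around its
#' center at fitted RMSD at most `spread`. Center separations are verified
#' to be at least `4 * spread` (and the generator aims for `separation`,
#' which defaults to `max(6 * spread, 0.5)` nm so the planted partition is
#' recoverable at the customary 0.3 nm cutoff). Frame order is shuffled;
#' the permutation is recorded in the truth.
#'
#' @param seed integer seed.
#' @param sizes integer cluster sizes; their sum is the ensemble size.
#' @param spread maximal member-to-center RMSD, nm.
#' @param separation target center-to-center fitted RMSD, nm.
#' @param nResidues length of the base chain.
#' @return list with `ensemble` (a [PoseEnsemble-class]) and `truth`
#'   (`partition`: list of frame-index vectors per planted cluster, largest
#'   first; `sizes`; `spread`; `separation`).
#' @export
makePoseEnsemble <- function(seed, sizes = c(50, 30, 20), spread = 0.05,
                             separation = max(6 * spread, 0.5),
                             nResidues = 12) {
  set.seed(seed)
  sizes <- as.integer(sizes)
  if (any(sizes < 1)) stop("cluster sizes must be positive")
  if (separation < 4 * spread)
    stop("separation must be at least 4 * spread")
  base <- makePeptideChain(strrep("A", nResidues), "extended",
                           id = "synthetic_ensemble")
  xyz <- as.matrix(atoms(base)[, c("x", "y", "z")])
  n_atoms <- nrow(xyz)
  k <- length(sizes)
  sigma_c <- separation * 10 / sqrt(6)
  for (attempt in 1:20) {
    fields <- lapply(seq_len(k), function(i)
      matrix(stats::rnorm(n_atoms * 3, sd = sigma_c), ncol = 3))
    centers <- lapply(fields, function(f) xyz + f)
    ok <- TRUE
    if (k > 1) {
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        d <- coord_rmsd(kabsch_superpose(centers[[j]], centers[[i]]),
                        centers[[i]]) / 10
        if (d < max(4 * spread, separation * 0.8)) ok <- FALSE
      }
    }
    if (ok) break
    sigma_c <- sigma_c * 1.3
  }
  if (!ok) stop("infeasible geometry: could not separate cluster centers")
  total <- sum(sizes)
  frames <- vector("list", total)
  labels <- integer(total)
  idx <- 1L
  for (ci in seq_len(k)) {
    for (m in seq_len(sizes[ci])) {
      g <- matrix(stats::rnorm(n_atoms * 3), ncol = 3)
      target <- spread * 10 * stats::runif(1, 0.25, 0.8)
      g <- g * (target / sqrt(mean(rowSums(g^2))))
      frames[[idx]] <- centers[[ci]] + g
      labels[idx] <- ci
      idx <- idx + 1L
    }
  }
  perm <- sample(total)
  coords <- array(NA_real_, dim = c(n_atoms, 3, total))
  for (i in seq_len(total)) coords[, , i] <- frames[[perm[i]]]
  labels <- labels[perm]
  topo <- base
  topo@atoms[, c("x", "y", "z")] <- coords[, , 1]
  ens <- new("PoseEnsemble", id = "synthetic_ensemble", topology = topo,
             coords = coords)
  partition <- lapply(seq_len(k), function(ci) which(labels == ci))
  ord <- order(-vapply(partition, length, integer(1)))
  list(ensemble = ens,
       truth = list(partition = partition[ord],
                    sizes = sort(sizes, decreasing = TRUE),
                    spread = spread, separation = separation))
}

#' Synthetic trajectory with controlled per-residue jitter
#'
#' Frames are the reference coordinates plus independent Gaussian jitter
#' per atom coordinate, with a per-residue standard deviation `sigma` (nm);
#' the expected RMSF of a residue is then `sigma * sqrt(3)`. Optionally the
#' ligand chain is rigidly displaced by `ligandOffset` (Angstrom) in every
#' frame after the first, so an RMSD series fitted on the receptor and
#' measured on the ligand reads the displacement directly.
#'
#' @param seed integer seed.
#' @param nFrames number of frames.
#' @param dt frame interval, ps.
#' @param receptorResidues,ligandResidues chain lengths ("A" and "B");
#'   `ligandResidues = 0` gives a single-chain trajectory.
#' @param sigma per-residue jitter standard deviation(s), nm; recycled over
#'   all residues of the complex.
#' @param ligandOffset optional length-3 displacement of chain B, Angstrom.
#' @return list with `trajectory` (a [Trajectory-class]) and `truth`
#'   (`sigma` per residue in nm, `ligandOffset`).
#' @export
makeTrajectory <- function(seed, nFrames = 100, dt = 2,
                           receptorResidues = 12, ligandResidues = 0,
                           sigma = 0.03, ligandOffset = NULL) {
  set.seed(seed)
  if (any(sigma < 0)) stop("sigma must be >= 0")
  rec <- makePeptideChain(strrep("A", receptorResidues), "extended",
                          chain = "A", id = "synthetic_trajectory")
  a <- atoms(rec)
  if (ligandResidues > 0) {
    ligs <- makePeptideChain(strrep("A", ligandResidues), "extended",
                             chain = "B", offset = c(0, 0, 20))
    la <- atoms(ligs)
    la$serial <- la$serial + max(a$serial)
    a <- rbind(a, la)
  }
  n_res <- sum(!duplicated(paste(a$chain, a$resno)))
  sig <- rep(sigma, length.out = n_res)
  res_index <- cumsum(!duplicated(paste(a$chain, a$resno)))
  sd_atom <- sig[res_index] * 10  # nm -> Angstrom
  ref <- as.matrix(a[, c("x", "y", "z")])
  n_atoms <- nrow(ref)
  coords <- array(NA_real_, dim = c(n_atoms, 3, nFrames))
  lig_rows <- a$chain == "B"
  for (f in seq_len(nFrames)) {
    jitter <- matrix(stats::rnorm(n_atoms * 3), ncol = 3) * sd_atom
    fr <- ref + jitter
    if (!is.null(ligandOffset) && f > 1L)
      fr[lig_rows, ] <- sweep(fr[lig_rows, , drop = FALSE], 2,
                              as.numeric(ligandOffset), FUN = "+")
    coords[, , f] <- fr
  }
  topo <- new("ProteinStructure", id = "synthetic_trajectory", atoms = a,
              title = "")
  traj <- new("Trajectory", id = "synthetic_trajectory", topology = topo,
              coords = coords, dt = dt)
  list(trajectory = traj,
       truth = list(sigma = sig, ligandOffset = ligandOffset))
}
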