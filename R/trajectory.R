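#' Build a Trajectory from an ensemble or multi-model PDB
#'
#' Trajectories are consumed as multi-model PDB (the lowest common
#' denominator across simulation engines); the frame interval comes from
#' sidecar metadata, not from the file.
#'
#' @param x a [PoseEnsemble-class], or anything [readEnsemble()] accepts.
#' @param dt frame interval, ps (default 2).
#' @return a [Trajectory-class].
#' @export
asTrajectory <- function(x, dt = 2) {
  ens <- if (is(x, "PoseEnsemble")) x else readEnsemble(x)
  new("Trajectory", id = ens@id, topology = ens@topology,
      coords = ens@coords, dt = dt)
}

#' RMSD time series with independent fit and measure selections
#'
#' Every frame is least-squares superposed on the reference using
#' `fitSelection` only, and the RMSD is then measured over
#' `measureSelection` (all atoms of it). Fitting on the receptor while
#' measuring the ligand keeps the ligand's translational motion in the
#' series -- the convention for reporting peptide RMSD in a complex;
#' fitting and measuring the same selection removes rigid motion.
#'
#' @param traj a [Trajectory-class] (or [PoseEnsemble-class]).
#' @param reference reference frame index (default 1) or an `n x 3`
#'   coordinate matrix.
#' @param fitSelection,measureSelection atom selections (see
#'   [pairwiseRMSD()] for accepted forms); `NULL` selects all atoms.
#' @return `data.frame` with `frame`, `time` (ps) and `rmsd` (nm).
#' @export
rmsdSeries <- function(traj, reference = 1L, fitSelection = NULL,
                       measureSelection = NULL) {
  stopifnot(is(traj, "PoseEnsemble"))
  a <- atoms(traj)
  fit_idx <- which(resolve_selection(fitSelection, a, "fitSelection"))
  mea_idx <- which(resolve_selection(measureSelection, a,
                                     "measureSelection"))
  ref <- if (is.matrix(reference)) reference else
    traj@coords[, , as.integer(reference), drop = TRUE]
  n <- nFrames(traj)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    moved <- kabsch_apply(traj@coords[, , i], ref, fit_idx)
    vals[i] <- coord_rmsd(moved[mea_idx, , drop = FALSE],
                          ref[mea_idx, , drop = FALSE]) / 10
  }
  dt <- if (is(traj, "Trajectory")) traj@dt else 1
  data.frame(frame = seq_len(n), time = (seq_len(n) - 1) * dt, rmsd = vals)
}

#' Per-residue RMSF profile
#'
#' Frames are superposed on the time-averaged structure (two fit passes:
#' first onto frame 1, then onto the resulting mean), and the fluctuation of
#' each residue is `sqrt(mean over frames and atoms of the squared
#' displacement from the mean atom position)`, in nm -- the average
#' fluctuation of the residue over all its atoms.
#'
#' @param traj a [Trajectory-class] with at least 2 frames.
#' @param fitSelection atom selection used for the superposition (default
#'   all atoms).
#' @return `data.frame` with `chain`, `resno`, `icode`, `resname`, `rmsf`
#'   (nm).
#' @export
rmsfProfile <- function(traj, fitSelection = NULL) {
  stopifnot(is(traj, "PoseEnsemble"))
  n <- nFrames(traj)
  if (n < 2L) stop("RMSF needs at least 2 frames")
  a <- atoms(traj)
  fit_idx <- which(resolve_selection(fitSelection, a, "fitSelection"))
  frames <- lapply(seq_len(n), function(i) traj@coords[, , i])
  ref <- frames[[1]]
  for (pass in 1:2) {
    fitted <- lapply(frames, kabsch_apply, target = ref, fit_idx = fit_idx)
    ref <- Reduce(`+`, fitted) / n
  }
  mean_pos <- ref
  sq <- Reduce(`+`, lapply(fitted, function(f) (f - mean_pos)^2)) / n
  per_atom <- rowSums(sq)  # mean squared displacement per atom, A^2
  key <- factor(.residue_key(a), levels = unique(.residue_key(a)))
  msd <- as.numeric(tapply(per_atom, key, mean))
  out <- a[!duplicated(key), c("chain", "resno", "icode", "resname")]
  out$rmsf <- sqrt(msd) / 10
  rownames(out) <- NULL
  out
}

# donor heavy atoms that bear a hydrogen, and acceptor atoms, per residue
# type; backbone N (except proline) donates, backbone O accepts
.HB_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG")
.HB_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH",
  MET = "SD", CYS = "SG")

hb_role_idx <- function(a, role) {
  tmpl <- if (role == "donor") .HB_DONORS else .HB_ACCEPTORS
  backbone <- if (role == "donor") a$name == "N" & a$resname != "PRO"
              else a$name %in% c("O", "OXT")
  side <- mapply(function(rn, nm) nm %in% (tmpl[[rn]] %||% character(0)),
                 a$resname, a$name)
  (backbone | side) & a$element %in% c("N", "O", "S")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-chain hydrogen bonds (distance criterion)
#'
#' Finds donor--acceptor pairs across the two chain sets with heavy-atom
#' distance at most `dMax` (default 3.5 Angstrom). Donors and acceptors are
#' N/O/S atoms assigned from per-residue-type templates; the criterion is
#' distance-only because docked and predicted models carry no hydrogens, so
#' no angle can be measured.
#'
#' @inheritParams deltaSASA
#' @param dMax donor--acceptor distance cutoff, Angstrom.
#' @return `data.frame`, one row per bond: donor and acceptor atom
#'   descriptors and the distance.
#' @export
hydrogenBonds <- function(complexed, receptorChains, ligandChains,
                          dMax = 3.5) {
  split_chains_check(complexed, receptorChains, ligandChains)
  a <- atoms(complexed)
  a <- a[a$element != "H", , drop = FALSE]
  out <- list()
  sides <- list(c("receptor", "ligand"), c("ligand", "receptor"))
  chains <- list(receptor = receptorChains, ligand = ligandChains)
  for (s in sides) {
    don <- a[a$chain %in% chains[[s[1]]] & hb_role_idx(a, "donor"), ]
    acc <- a[a$chain %in% chains[[s[2]]] & hb_role_idx(a, "acceptor"), ]
    if (!nrow(don) || !nrow(acc)) next
    xd <- as.matrix(don[, c("x", "y", "z")])
    xa <- as.matrix(acc[, c("x", "y", "z")])
    d2 <- outer(rowSums(xd^2), rowSums(xa^2), "+") - 2 * xd %*% t(xa)
    hit <- which(d2 <= dMax^2 + 1e-12, arr.ind = TRUE)
    if (!nrow(hit)) next
    out[[length(out) + 1L]] <- data.frame(
      donorChain = don$chain[hit[, 1]], donorResno = don$resno[hit[, 1]],
      donorResname = don$resname[hit[, 1]], donorAtom = don$name[hit[, 1]],
      acceptorChain = acc$chain[hit[, 2]],
      acceptorResno = acc$resno[hit[, 2]],
      acceptorResname = acc$resname[hit[, 2]],
      acceptorAtom = acc$name[hit[, 2]],
      dist = sqrt(pmax(d2[hit], 0)), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(donorChain = character(0), donorResno = integer(0),
                      donorResname = character(0), donorAtom = character(0),
                      acceptorChain = character(0),
                      acceptorResno = integer(0),
                      acceptorResname = character(0),
                      acceptorAtom = character(0), dist = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$dist), ]
  rownames(res) <- NULL
  res
}

#' Cross-chain hydrophobic contacts
#'
#' Default mode lists carbon--carbon heavy-atom pairs across the interface
#' at or below `dMax` (4 Angstrom by default), each atom annotated as
#' main-chain (N, CA, C, O, OXT) or side-chain -- the reporting style of
#' interaction diagrams. `mode = "permissive"` instead takes any heavy-atom
#' pair between two apolar-classified residues, matching diagram tools that
#' list N/O atoms of hydrophobic residues too.
#'
#' @inheritParams deltaSASA
#' @param dMax contact cutoff, Angstrom.
#' @param mode `"carbon"` (default) or `"permissive"`.
#' @param scheme residue classes, used by permissive mode.
#' @return `data.frame`, one row per atom pair with main/side annotation.
#' @export
hydrophobicContacts <- function(complexed, receptorChains, ligandChains,
                                dMax = 4.0, mode = c("carbon", "permissive"),
                                scheme = defaultResidueClasses()) {
  mode <- match.arg(mode)
  split_chains_check(complexed, receptorChains, ligandChains)
  a <- atoms(complexed)
  a <- a[a$element != "H", , drop = FALSE]
  keep <- if (mode == "carbon") a$element == "C"
          else scheme[aaThreeToOne(a$resname)] == "apolar"
  a <- a[keep & !is.na(keep), , drop = FALSE]
  ar <- a[a$chain %in% receptorChains, , drop = FALSE]
  al <- a[a$chain %in% ligandChains, , drop = FALSE]
  empty <- data.frame(chainR = character(0), resnoR = integer(0),
                      resnameR = character(0), atomR = character(0),
                      siteR = character(0), chainL = character(0),
                      resnoL = integer(0), resnameL = character(0),
                      atomL = character(0), siteL = character(0),
                      dist = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(ar) || !nrow(al)) return(empty)
  xr <- as.matrix(ar[, c("x", "y", "z")])
  xl <- as.matrix(al[, c("x", "y", "z")])
  d2 <- outer(rowSums(xr^2), rowSums(xl^2), "+") - 2 * xr %*% t(xl)
  hit <- which(d2 <= dMax^2 + 1e-12, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  main <- c("N", "CA", "C", "O", "OXT")
  res <- data.frame(
    chainR = ar$chain[hit[, 1]], resnoR = ar$resno[hit[, 1]],
    resnameR = ar$resname[hit[, 1]], atomR = ar$name[hit[, 1]],
    siteR = ifelse(ar$name[hit[, 1]] %in% main, "main", "side"),
    chainL = al$chain[hit[, 2]], resnoL = al$resno[hit[, 2]],
    resnameL = al$resname[hit[, 2]], atomL = al$name[hit[, 2]],
    siteL = ifelse(al$name[hit[, 2]] %in% main, "main", "side"),
    dist = sqrt(pmax(d2[hit], 0)), stringsAsFactors = FALSE)
  res <- res[order(res$dist), ]
  rownames(res) <- NULL
  res
}
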