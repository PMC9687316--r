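#' @import methods
NULL

.ATOM_COLS <- c("serial", "name", "altloc", "resname", "chain", "resno",
                "icode", "x", "y", "z", "occupancy", "bscore", "element")

#' ProteinStructure: a parsed macromolecular structure
#'
#' Container for one polymer structure: chains of residues of atoms, with
#' coordinates in Angstrom and the B-factor column preserved per atom (used
#' to carry per-residue confidence scores of predicted models, pLDDT
#' convention, 0--100). Waters and HETATM records are excluded at parse time.
#'
#' @slot id single identifier string.
#' @slot atoms `data.frame` with one row per atom and columns
#'   `serial`, `name`, `altloc`, `resname`, `chain`, `resno`, `icode`,
#'   `x`, `y`, `z`, `occupancy`, `bscore`, `element`. Residues are keyed by
#'   `(chain, resno, icode)` with author (1-based) residue numbering.
#' @slot title free-text metadata (may be empty).
#'
#' @seealso [readStructure()], [atoms()], [nResidues()], [carveFragment()]
#' @exportClass ProteinStructure
setClass("ProteinStructure",
         representation(id = "character", atoms = "data.frame",
                        title = "character"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  if (nrow(a) < 1L) return("structure must contain at least one atom")
  missing_cols <- setdiff(.ATOM_COLS, names(a))
  if (length(missing_cols))
    return(paste("atoms table lacks columns:",
                 paste(missing_cols, collapse = ", ")))
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("atom coordinates must be finite")
  if (any(!nzchar(a$element)))
    return("every atom needs a non-empty element symbol")
  TRUE
})

#' PoseEnsemble: M conformations over one atom topology
#'
#' Frames of a docked-pose ensemble (or any set of conformations of the same
#' complex). All frames share the atom set and ordering of `topology`;
#' coordinates are stored as an `n_atoms x 3 x n_frames` array in Angstrom.
#'
#' @slot id complex identifier.
#' @slot topology a [ProteinStructure-class] giving the shared atom table
#'   (its coordinates are those of the first frame).
#' @slot coords numeric array, `dim = c(n_atoms, 3, n_frames)`.
#'
#' @seealso [readEnsemble()], [pairwiseRMSD()], [gromosCluster()]
#' @exportClass PoseEnsemble
setClass("PoseEnsemble",
         representation(id = "character", topology = "ProteinStructure",
                        coords = "array"))

setValidity("PoseEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[1] != nrow(object@topology@atoms))
    return("coords atom dimension disagrees with topology")
  if (d[3] < 1L) return("ensemble needs at least one frame")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  TRUE
})

#' Trajectory: a time-ordered PoseEnsemble
#'
#' A [PoseEnsemble-class] whose frames are ordered in time, with the frame
#' interval in picoseconds.
#'
#' @slot dt frame interval, ps.
#' @seealso [rmsdSeries()], [rmsfProfile()]
#' @exportClass Trajectory
setClass("Trajectory", contains = "PoseEnsemble",
         representation(dt = "numeric"))

setValidity("Trajectory", function(object) {
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    return("dt must be a single positive frame interval (ps)")
  TRUE
})

#' ClusterResult: Daura/GROMOS clustering of a pose ensemble
#'
#' Clusters are ordered by decreasing size; each is a list with integer
#' elements `center` and `members` (1-based pose indices, `center` among
#' `members`). Groups of clusters of equal size are recorded in `ties` so a
#' non-unique "most populated cluster" is never silent.
#'
#' @slot clusters list of `list(center =, members =)`, size-ordered.
#' @slot cutoff neighbor cutoff used, nm.
#' @slot n number of poses clustered.
#' @slot ties list of integer vectors; each vector holds the indices (into
#'   `clusters`) of clusters sharing one size.
#'
#' @seealso [gromosCluster()], [representative()]
#' @exportClass ClusterResult
setClass("ClusterResult",
         representation(clusters = "list", cutoff = "numeric",
                        n = "integer", ties = "list"))

setValidity("ClusterResult", function(object) {
  idx <- sort(unlist(lapply(object@clusters, `[[`, "members")))
  if (!identical(as.integer(idx), seq_len(object@n)))
    return("clusters must partition 1..n")
  ok_center <- vapply(object@clusters, function(cl)
    cl$center %in% cl$members, logical(1))
  if (!all(ok_center)) return("every center must belong to its cluster")
  sizes <- vapply(object@clusters, function(cl) length(cl$members), integer(1))
  if (is.unsorted(rev(sizes))) return("clusters must be size-ordered")
  TRUE
})

#' ContactTable: classified interfacial contacts of a two-body complex
#'
#' A residue pair (one residue per side) is an interfacial contact when any
#' heavy-atom pair distance is at or below the threshold (5.5 Angstrom by
#' default). Pairs are classified by the polar/apolar/charged character of
#' the two residues and aggregated into the six unordered class-pair counts
#' `cc, cp, ca, pp, pa, aa`.
#'
#' @slot pairs `data.frame` of contacting residue pairs with minimal
#'   heavy-atom distance and both residue classes.
#' @slot counts named numeric of length 6 (`cc, cp, ca, pp, pa, aa`).
#' @slot threshold distance threshold, Angstrom.
#'
#' @seealso [interfacialContacts()], [bindingAffinity()]
#' @exportClass ContactTable
setClass("ContactTable",
         representation(pairs = "data.frame", counts = "numeric",
                        threshold = "numeric"))

setValidity("ContactTable", function(object) {
  if (!identical(sort(names(object@counts)),
                 sort(c("cc", "cp", "ca", "pp", "pa", "aa"))))
    return("counts must be named cc, cp, ca, pp, pa, aa")
  if (any(object@counts < 0)) return("contact counts must be >= 0")
  if (sum(object@counts) != nrow(object@pairs))
    return("counts must sum to the number of contact pairs")
  TRUE
})

#' InterfaceReport: the full interface characterization of one complex
#'
#' Bundles the per-residue delta-SASA profile, the interface residue set,
#' the classified contact table, and the contact-model binding affinity with
#' its dissociation constant at the stated temperature.
#'
#' @slot id complex identifier.
#' @slot deltaSASA `data.frame` with per-residue `dsasa` (Angstrom^2,
#'   unbound minus bound) and logical `interface` (`dsasa > 0`).
#' @slot contacts a [ContactTable-class].
#' @slot nis named numeric: percentage of apolar and charged residues on the
#'   non-interacting surface.
#' @slot dG binding affinity, kcal/mol.
#' @slot kd dissociation constant, M.
#' @slot temperature K.
#'
#' @seealso [interfaceReport()], [kdFromDG()]
#' @exportClass InterfaceReport
setClass("InterfaceReport",
         representation(id = "character", deltaSASA = "data.frame",
                        contacts = "ContactTable", nis = "numeric",
                        dG = "numeric", kd = "numeric",
                        temperature = "numeric"))

setValidity("InterfaceReport", function(object) {
  if (object@temperature <= 0) return("temperature must be positive (K)")
  expected <- exp(object@dG / (.GAS_CONSTANT_KCAL * object@temperature))
  if (is.finite(object@kd) &&
      abs(object@kd - expected) > 1e-9 * max(object@kd, expected))
    return("kd must equal exp(dG/(R*T))")
  TRUE
})

# R in kcal mol^-1 K^-1
.GAS_CONSTANT_KCAL <- 1.9872e-3
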