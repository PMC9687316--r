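#' Van der Waals radius set
#'
#' Element radii (Angstrom) and the solvent probe radius used by [sasa()].
#' The bundled table is a standard published element-radius set shipped as
#' an editable config file (`inst/extdata/config/vdw_radii.json`); the probe
#' defaults to 1.4 Angstrom (water).
#'
#' @param probe probe radius, Angstrom.
#' @param fallback radius used for elements missing from the table; `NA`
#'   (default) makes unknown elements an error in [sasa()].
#' @return list with `radii` (named numeric by element symbol), `probe`,
#'   `fallback`.
#' @export
defaultRadii <- function(probe = 1.4, fallback = NA_real_) {
  cfg <- read_config_json("vdw_radii.json")
  list(radii = unlist(cfg$radii), probe = probe, fallback = fallback,
       source = cfg$source)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For every atom, `nPoints` quasi-uniform points are placed on the sphere
#' of radius `r_vdw + probe`; the accessible fraction is the share of points
#' not inside any neighbor's expanded sphere, and the atom area is that
#' fraction times `4*pi*(r_vdw + probe)^2`. Residue areas are atom sums.
#' Doubling `nPoints` changes an isolated-sphere area by well under 0.5%;
#' 960 points is the conventional accuracy/speed compromise.
#'
#' @param structure a [ProteinStructure-class].
#' @param radii a radius set from [defaultRadii()].
#' @param nPoints sphere quadrature points per atom (default 960).
#' @return list with `atom` (`data.frame`, per-atom `area`), `residue`
#'   (`data.frame`, per-residue `area`), `total`, `nPoints`, `probe`.
#' @seealso [deltaSASA()]
#' @export
sasa <- function(structure, radii = defaultRadii(), nPoints = 960) {
  stopifnot(is(structure, "ProteinStructure"))
  a <- atoms(structure)
  r <- radii$radii[a$element]
  unknown <- which(is.na(r))
  if (length(unknown)) {
    if (is.na(radii$fallback))
      stop("no van der Waals radius for element '", a$element[unknown[1]],
           "' (atom serial ", a$serial[unknown[1]], ")")
    r[unknown] <- radii$fallback
  }
  R <- unname(r) + radii$probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pts <- sphere_points(nPoints)
  n <- nrow(xyz)
  area <- numeric(n)
  # neighbor search: atoms j with |xi - xj| < Ri + rj + probe can occlude i
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + R)^2 & d2 > 0)
    sp <- sweep(pts * R[i], 2, xyz[i, ], FUN = "+")
    accessible <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(accessible)) break
      live <- which(accessible)
      dd <- (sp[live, 1] - xyz[j, 1])^2 + (sp[live, 2] - xyz[j, 2])^2 +
        (sp[live, 3] - xyz[j, 3])^2
      accessible[live[dd < R[j]^2]] <- FALSE
    }
    area[i] <- 4 * pi * R[i]^2 * sum(accessible) / nPoints
  }
  atom_out <- cbind(a[, c("serial", "name", "chain", "resno", "icode",
                          "resname", "element")], area = area)
  key <- factor(.residue_key(a), levels = unique(.residue_key(a)))
  res_area <- as.numeric(tapply(area, key, sum))
  res_out <- cbind(residueTable(structure), area = res_area)
  list(atom = atom_out, residue = res_out, total = sum(area),
       nPoints = nPoints, probe = radii$probe)
}

#' Interface detection by buried surface area
#'
#' Computes, per residue, `dSASA = SASA(own side alone) - SASA(complex)`
#' over identical coordinates, so burial upon binding is positive. Residues
#' with `dSASA > 0` form the interface set -- the standard buried-surface
#' definition of interface residues.
#'
#' @param complexed a two-body complex as a [ProteinStructure-class].
#' @param receptorChains,ligandChains disjoint chain-id sets that together
#'   cover the complex.
#' @param radii radius set, see [defaultRadii()].
#' @param nPoints quadrature points, see [sasa()].
#' @return `data.frame` with per-residue `side` (`"receptor"`/`"ligand"`),
#'   `dsasa` (Angstrom^2) and logical `interface`.
#' @export
deltaSASA <- function(complexed, receptorChains, ligandChains,
                      radii = defaultRadii(), nPoints = 960) {
  split_chains_check(complexed, receptorChains, ligandChains)
  a <- atoms(complexed)
  bound <- sasa(complexed, radii, nPoints)$residue
  sub_structure <- function(chains) {
    keep <- a$chain %in% chains
    out <- a[keep, , drop = FALSE]
    rownames(out) <- NULL
    new("ProteinStructure", id = complexed@id, atoms = out, title = "")
  }
  unbound_r <- sasa(sub_structure(receptorChains), radii, nPoints)$residue
  unbound_l <- sasa(sub_structure(ligandChains), radii, nPoints)$residue
  unbound <- rbind(unbound_r, unbound_l)
  key <- function(df) paste(df$chain, df$resno, df$icode, sep = "\r")
  m <- match(key(bound), key(unbound))
  dsasa <- unbound$area[m] - bound$area
  out <- bound[, c("chain", "resno", "icode", "resname")]
  out$side <- ifelse(out$chain %in% receptorChains, "receptor", "ligand")
  out$dsasa <- dsasa
  out$interface <- dsasa > 0
  out
}

split_chains_check <- function(complexed, receptorChains, ligandChains) {
  stopifnot(is(complexed, "ProteinStructure"))
  if (!length(receptorChains) || !length(ligandChains))
    stop("receptor and ligand chain sets must both be non-empty")
  if (length(intersect(receptorChains, ligandChains)))
    stop("chain sets overlap: ",
         paste(intersect(receptorChains, ligandChains), collapse = ", "))
  present <- chainIds(complexed)
  uncovered <- setdiff(present, c(receptorChains, ligandChains))
  if (length(uncovered))
    stop("chains not assigned to either side: ",
         paste(uncovered, collapse = ", "))
  missing <- setdiff(c(receptorChains, ligandChains), present)
  if (length(missing))
    stop("chain(s) absent from the complex: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
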